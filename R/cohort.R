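# Cohort metadata and AWGS 2019 grip-strength labeling.
#
# Labels are a deterministic function of (sex, hand-grip strength). Only the
# HGS criterion is implemented: the guideline's gait-speed and muscle-mass
# criteria carry no numeric cutoffs in this pipeline and optional metadata
# columns never influence the label.

#' AWGS 2019 hand-grip-strength thresholds (kg)
#'
#' Sex-specific cutoffs below which a participant is labeled sarcopenia.
#' The defaults are the values applied to the study cohort: 26 kg for men
#' and 18 kg for women. The 2019 guideline's alternative 28 kg male cutoff
#' can be requested explicitly; it is never silently substituted.
#'
#' @param male,female Positive cutoffs in kilograms.
#' @return A named list with elements `male` and `female`.
#' @export
awgs_thresholds <- function(male = 26, female = 18) {
  sg_assert(is.numeric(male) && male > 0 && is.numeric(female) && female > 0,
            "thresholds must be positive numbers")
  list(male = male, female = female)
}

#' Label a participant by the AWGS hand-grip-strength criterion
#'
#' Returns `"sarcopenia"` iff the grip strength is strictly below the
#' sex-specific cutoff (strictly: a measurement exactly at 26/18 kg is
#' labeled `"normal"`). Vectorized over `sex` and `hgs_kg`.
#'
#' @param sex `"male"` or `"female"` (or `"M"`/`"F"`).
#' @param hgs_kg Non-negative hand-grip strength in kg (mean of three trials).
#' @param thresholds A list from [awgs_thresholds()].
#' @return Character vector of `"sarcopenia"` / `"normal"`.
#' @examples
#' label_awgs("female", 17.9)  # sarcopenia
#' label_awgs("female", 18.0)  # normal (boundary is exclusive)
#' @export
label_awgs <- function(sex, hgs_kg, thresholds = awgs_thresholds()) {
  sex <- normalize_sex(sex)
  sg_assert(is.numeric(hgs_kg) && all(is.finite(hgs_kg)) && all(hgs_kg >= 0),
            "hgs_kg must be finite and non-negative")
  sg_assert(length(sex) == length(hgs_kg) || length(sex) == 1 || length(hgs_kg) == 1,
            "sex and hgs_kg lengths are incompatible")
  cut <- ifelse(sex == "male", thresholds$male, thresholds$female)
  ifelse(hgs_kg < cut, "sarcopenia", "normal")
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s == "m"] <- "male"
  s[s == "f"] <- "female"
  bad <- !(s %in% c("male", "female"))
  if (any(bad)) {
    sg_abort(sprintf("unknown sex value(s): %s (thresholds are sex-specific)",
                     paste(unique(sex[bad]), collapse = ", ")),
             "sarcogait_invalid_input")
  }
  s
}

#' Build a cohort table
#'
#' A cohort table is a data.frame with one labeled row per participant and
#' unique participant ids; the label column is always recomputed from
#' (sex, hgs_kg) so it can never drift from the criterion.
#'
#' @param participant_id Character vector of unique ids.
#' @param sex,age_years,hgs_kg Per-participant metadata.
#' @param thresholds See [awgs_thresholds()].
#' @return A `cohort_table` (data.frame) with columns
#'   `participant_id,sex,age_years,hgs_kg,label`.
#' @export
cohort_table <- function(participant_id, sex, age_years, hgs_kg,
                         thresholds = awgs_thresholds()) {
  participant_id <- as.character(participant_id)
  sg_assert(!anyDuplicated(participant_id), "participant_ids must be unique")
  sg_assert(is.numeric(age_years) && all(age_years > 0) && all(age_years == floor(age_years)),
            "age_years must be positive integers")
  sex <- normalize_sex(sex)
  df <- data.frame(
    participant_id = participant_id,
    sex = sex,
    age_years = as.integer(age_years),
    hgs_kg = as.numeric(hgs_kg),
    label = label_awgs(sex, hgs_kg, thresholds),
    stringsAsFactors = FALSE
  )
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Summarize a labeled cohort
#'
#' Counts by label, by sex, and by decade age band. Each breakdown
#' partitions the cohort, so every breakdown sums to the total.
#'
#' @param cohort A [cohort_table()].
#' @return A list with `total`, `by_label`, `by_sex`, `by_age_band`.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "data.frame"))
  if (nrow(cohort) > 0) {
    unlabeled <- is.na(cohort$label) | !(cohort$label %in% c("sarcopenia", "normal"))
    if (any(unlabeled)) {
      sg_abort(sprintf("unlabeled participants: %s",
                       paste(cohort$participant_id[unlabeled], collapse = ", ")),
               "sarcogait_unlabeled")
    }
  }
  count_levels <- function(x, levels) {
    out <- stats::setNames(integer(length(levels)), levels)
    tab <- table(factor(x, levels = levels))
    out[names(tab)] <- as.integer(tab)
    out
  }
  bands <- c("<40", "40-59", "60-69", "70+")
  band <- if (nrow(cohort) == 0) character(0) else {
    cut(cohort$age_years, breaks = c(-Inf, 39, 59, 69, Inf), labels = bands)
  }
  list(
    total = nrow(cohort),
    by_label = count_levels(cohort$label, c("sarcopenia", "normal")),
    by_sex = count_levels(cohort$sex, c("male", "female")),
    by_age_band = count_levels(band, bands)
  )
}

#' Read / write a cohort CSV
#'
#' Format: UTF-8 CSV with header `participant_id,sex,age_years,hgs_kg[,label]`,
#' sex encoded `M`/`F`. Labels are recomputed on read; a stored label column
#' that disagrees with the criterion is an error.
#'
#' @param path File path.
#' @param thresholds See [awgs_thresholds()].
#' @return `read_cohort_csv` returns a [cohort_table()].
#' @export
read_cohort_csv <- function(path, thresholds = awgs_thresholds()) {
  # sex must be read as character: an unquoted F column would otherwise
  # be parsed as logical FALSE
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        colClasses = c(participant_id = "character",
                                       sex = "character"))
  need <- c("participant_id", "sex", "age_years", "hgs_kg")
  sg_assert(all(need %in% names(df)),
            sprintf("cohort CSV must have columns %s", paste(need, collapse = ",")))
  out <- cohort_table(df$participant_id, df$sex, df$age_years, df$hgs_kg, thresholds)
  if ("label" %in% names(df)) {
    bad <- df$label != out$label
    if (any(bad)) {
      sg_abort(sprintf("stored labels disagree with the HGS criterion for: %s",
                       paste(df$participant_id[bad], collapse = ", ")),
               "sarcogait_label_mismatch")
    }
  }
  out
}

#' @rdname read_cohort_csv
#' @param cohort A [cohort_table()].
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  out$sex <- ifelse(out$sex == "male", "M", "F")
  utils::write.csv(as.data.frame(out), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
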