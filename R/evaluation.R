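# Subject-level, class-stratified 4-fold cross-validation with a 20%
# within-training validation split, and accuracy aggregation.
#
# Folds are assigned at the participant level so that no person ever
# contributes sequences to more than one of {train, validation, test}
# within a round; the assertion is executed inside train_and_eval.

#' Subject-level class-stratified folds
#'
#' Participants of each class are shuffled (seeded) and dealt round-robin
#' across folds, so class counts differ by at most one between folds. With
#' the study composition (20 sarcopenia + 80 normal, 4 folds) every fold
#' holds exactly 5 + 20 = 25 participants.
#'
#' @param cohort A [cohort_table()].
#' @param n_folds Number of folds (default 4).
#' @param seed Integer seed for the within-class permutation.
#' @return A `fold_split`: data.frame `participant_id,label,fold` with a
#'   `class_counts` attribute (folds x classes).
#' @export
make_folds <- function(cohort, n_folds = 4, seed = 0) {
  sg_assert(sg_is_count(n_folds) && n_folds >= 2, "n_folds must be an integer >= 2")
  classes <- sort(unique(cohort$label))
  for (cl in classes) {
    m <- sum(cohort$label == cl)
    if (m < n_folds) {
      sg_abort(sprintf("class '%s' has %d participants but %d folds were requested",
                       cl, m, n_folds), "sarcogait_stratification_error")
    }
  }
  out <- NULL
  with_seed(derive_seed(seed, "folds"), {
    for (cl in classes) {
      ids <- cohort$participant_id[cohort$label == cl]
      ids <- ids[sample.int(length(ids))]
      out <- rbind(out, data.frame(participant_id = ids, label = cl,
                                   fold = rep(seq_len(n_folds), length.out = length(ids)),
                                   stringsAsFactors = FALSE))
    }
  })
  out <- out[order(out$fold, out$participant_id), ]
  rownames(out) <- NULL
  counts <- table(out$fold, out$label)
  attr(out, "class_counts") <- counts
  class(out) <- c("fold_split", "data.frame")
  out
}

#' Export fold assignments to CSV
#' @param folds A [make_folds()] result.
#' @param path Output CSV (`participant_id,fold`).
#' @export
write_folds_csv <- function(folds, path) {
  utils::write.csv(folds[, c("participant_id", "fold")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-class 20% validation split of the training participants
#'
#' Within each class, `round(fraction * class size)` participants are held
#' out for validation (seeded draw); the split is subject-level. With the
#' study's 15 + 60 training participants this yields 3 + 12.
#'
#' @param train_ids Character vector of training participant ids.
#' @param labels Class label per id.
#' @param fraction Validation fraction in (0, 1); default 0.20.
#' @param seed Integer seed.
#' @return list(train, validation) of disjoint id vectors covering input.
#' @export
make_validation_split <- function(train_ids, labels, fraction = 0.20, seed = 0) {
  sg_assert(is.numeric(fraction) && fraction > 0 && fraction < 1,
            "fraction must lie in (0, 1)")
  sg_assert(length(train_ids) == length(labels), "one label per id")
  val <- character(0)
  with_seed(derive_seed(seed, "valsplit"), {
    for (cl in sort(unique(labels))) {
      ids <- train_ids[labels == cl]
      k <- round(fraction * length(ids))
      if (k > 0) val <- c(val, ids[sample.int(length(ids), k)])
    }
  })
  list(train = setdiff(train_ids, val), validation = val)
}

#' Mean of the four fold accuracies
#'
#' @param per_fold Numeric accuracies in [0, 100], one per fold.
#' @param n_folds Expected number of folds (4 for the study protocol).
#' @return list(raw, reported) — the arithmetic mean and its half-to-even
#'   2-decimal rounding for reporting.
#' @export
average_accuracy <- function(per_fold, n_folds = 4) {
  if (length(per_fold) != n_folds) {
    sg_abort(sprintf("expected %d fold accuracies, got %d", n_folds, length(per_fold)),
             "sarcogait_invalid_input")
  }
  sg_assert(all(per_fold >= 0 & per_fold <= 100), "accuracies must lie in [0, 100]")
  m <- mean(per_fold)
  list(raw = m, reported = round(m, 2))
}

check_no_leakage <- function(train_p, val_p, test_p) {
  ok <- length(intersect(train_p, val_p)) == 0 &&
    length(intersect(train_p, test_p)) == 0 &&
    length(intersect(val_p, test_p)) == 0
  if (!ok) sg_abort("participant leakage across train/validation/test",
                    "sarcogait_leakage")
  invisible(TRUE)
}

label_to_int <- function(label) {
  # fixed coding shared by models and reports: 1 = normal, 2 = sarcopenia
  sg_assert(all(label %in% c("normal", "sarcopenia")), "unknown class label")
  ifelse(label == "sarcopenia", 2L, 1L)
}

#' Cross-validated training and evaluation
#'
#' For each fold k: train on the other folds minus a per-class 20%
#' validation subset, keep the epoch with the best validation accuracy,
#' and report sequence-level accuracy on fold k. The four fold accuracies
#' are averaged. Subject-level leakage is asserted every round.
#'
#' @param dataset A list with `x` (4-D feature array, samples last),
#'   `label` (character per sequence), `participant` (id per sequence).
#' @param folds A [make_folds()] result.
#' @param config A [train_config()].
#' @param model_builder `function(seed)` returning a fresh untrained
#'   `sarcogait_model`.
#' @param val_fraction Validation fraction (default 0.20).
#' @param augment Optional training-batch augmentation function.
#' @param seed Integer seed for splits and per-fold training.
#' @param verbose Print fold progress.
#' @return An `eval_result`: `per_fold` (percent), `average` (raw mean),
#'   `average_reported`, `confusion` (per-fold 2x2 counts), `histories`.
#' @export
train_and_eval <- function(dataset, folds, config, model_builder,
                           val_fraction = 0.20, augment = NULL, seed = 0,
                           verbose = FALSE) {
  sg_assert(all(c("x", "label", "participant") %in% names(dataset)),
            "dataset needs x, label, participant")
  n <- dim(dataset$x)[4]
  sg_assert(length(dataset$label) == n && length(dataset$participant) == n,
            "dataset fields must align with samples")
  sg_assert(all(dataset$participant %in% folds$participant_id),
            "every sequence's participant must be assigned to a fold")
  y_all <- label_to_int(dataset$label)
  n_folds <- max(folds$fold)
  per_fold <- numeric(n_folds)
  confusion <- vector("list", n_folds)
  histories <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    test_p <- folds$participant_id[folds$fold == k]
    rest <- folds[folds$fold != k, ]
    if (nrow(rest) == 0 || length(test_p) == 0) {
      sg_abort(sprintf("fold %d is empty", k), "sarcogait_invalid_input")
    }
    split <- make_validation_split(rest$participant_id, rest$label,
                                   fraction = val_fraction,
                                   seed = derive_seed(seed, paste0("fold", k)))
    check_no_leakage(split$train, split$validation, test_p)
    tr_idx <- which(dataset$participant %in% split$train)
    va_idx <- which(dataset$participant %in% split$validation)
    te_idx <- which(dataset$participant %in% test_p)
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("train-fold", k))
    model <- model_builder(derive_seed(seed, paste0("init-fold", k)))
    hist <- fit_classifier(model,
                           slice_batch(dataset$x, tr_idx), y_all[tr_idx], cfg,
                           x_val = if (length(va_idx)) slice_batch(dataset$x, va_idx) else NULL,
                           y_val = if (length(va_idx)) y_all[va_idx] else NULL,
                           augment = augment, verbose = verbose)
    pred <- predict_classes(model, slice_batch(dataset$x, te_idx))
    truth <- y_all[te_idx]
    per_fold[k] <- 100 * mean(pred == truth)
    confusion[[k]] <- table(factor(truth, levels = 1:2, labels = c("normal", "sarcopenia")),
                            factor(pred, levels = 1:2, labels = c("normal", "sarcopenia")),
                            dnn = c("truth", "predicted"))
    histories[[k]] <- hist
    if (verbose) message(sprintf("fold %d: accuracy %.2f%%", k, per_fold[k]))
  }
  avg <- average_accuracy(per_fold, n_folds = n_folds)
  structure(list(per_fold = per_fold, average = avg$raw,
                 average_reported = avg$reported, confusion = confusion,
                 histories = histories),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("Cross-validated evaluation\n")
  for (k in seq_along(x$per_fold)) cat(sprintf("  fold %d: %6.2f%%\n", k, x$per_fold[k]))
  cat(sprintf("  average: %.2f%%\n", x$average_reported))
  invisible(x)
}
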