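#' @keywords internal
"_PACKAGE"

# Shared validation / RNG helpers. All randomness in the package flows
# through R's RNG seeded by derive_seed(), so a single top-level seed
# determines every stochastic stage without cross-stage coupling.

sg_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "sarcogait_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

sg_assert <- function(cond, msg, class = "sarcogait_invalid_input") {
  if (!isTRUE(cond)) sg_abort(msg, class)
  invisible(TRUE)
}

#' Derive a stage seed from a master seed and a label
#'
#' Hashes a character label into the master seed so that each pipeline stage
#' (or each generated sequence) gets an independent, reproducible seed, and
#' changing one stage's label never shifts the seeds of the others.
#'
#' @param seed Master integer seed.
#' @param label Character scalar naming the consumer (e.g. "synth/P003/seq07").
#' @return An integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, label) {
  sg_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "seed must be a single finite number")
  codes <- utf8ToInt(as.character(label))
  h <- as.double(seed) %% 2147483647
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sg_is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x) && x >= 1
}
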