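# Shared fixtures, all built in code.

# small connected chain graph for model unit tests
toy_graph3 <- function() {
  joint_graph(node_names = c("a", "b", "c"),
              edges = matrix(c(0L, 1L, 1L, 2L), ncol = 2, byrow = TRUE),
              selection_map = 0:2)
}

# deterministic raw32 sequence with distinguishable values per (t, j, axis)
coded_raw32 <- function(T = 4) {
  co <- array(0, dim = c(T, 32, 3))
  for (t in seq_len(T)) for (j in 1:32) {
    co[t, j, ] <- c(t * 1000 + j, t * 1000 + j + 0.1, t * 1000 + j + 0.2)
  }
  skeleton_sequence(co, joint_set = "raw32")
}

# numeric gradient of sum(f(x) * dy) by central differences
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# a small labeled cohort table: n_s sarcopenia + n_n normal
tiny_cohort <- function(n_s = 4, n_n = 8) {
  n <- n_s + n_n
  sex <- rep(c("male", "female"), length.out = n)
  hgs <- ifelse(seq_len(n) <= n_s,
                ifelse(sex == "male", 20, 14),
                ifelse(sex == "male", 35, 25))
  cohort_table(sprintf("T%02d", seq_len(n)), sex, rep(50, n), hgs)
}

# centered Gaussian blob image for rotation mass checks
blob_image <- function(h = 41, w = 41, sigma = 4) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  pressure_image(exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * sigma^2)))
}
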