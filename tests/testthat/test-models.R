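# Classifier architecture contracts: probability outputs, the per-node
# oracle for the degenerate graph network, attention normalization, skip
# ablation, determinism, and the capacity smoke test.

test_that("stgcn_forward returns probability rows and checks shapes", {
  set.seed(21)
  g <- toy_graph3()
  cfg <- stgcn_config(block_channels = c(4, 6), temporal_kernel = 3,
                      input_branches = "position")
  m <- build_stgcn(cfg, graph = g, seed = 1)
  batch <- array(rnorm(5 * 3 * 12 * 3), c(5, 3, 12, 3))
  p <- stgcn_forward(m, batch)
  expect_equal(dim(p), c(5, 2))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  # per-sample independence: permuting the batch permutes outputs
  perm <- c(3, 1, 5, 2, 4)
  p2 <- stgcn_forward(m, batch[perm, , , , drop = FALSE])
  expect_equal(p2, p[perm, ], tolerance = 1e-9)
  # determinism
  expect_identical(stgcn_forward(m, batch), p)
  expect_error(stgcn_forward(m, batch[, , 1:2, , drop = FALSE]),
               "temporal kernel")
  expect_error(stgcn_forward(m, array(0, c(2, 5, 12, 3))),
               class = "sarcogait_shape_error")
})

test_that("identity adjacency + temporal kernel 1 reduces to a per-joint MLP", {
  set.seed(22)
  V <- 3
  cfg <- stgcn_config(block_channels = c(4, 5), temporal_kernel = 1,
                      temporal_strides = c(1, 1), input_branches = "position",
                      attention_enabled = FALSE, residual = FALSE,
                      input_bn = FALSE)
  m <- build_stgcn(cfg, adjacency = list(diag(V)), seed = 3)
  batch <- array(rnorm(4 * 3 * 6 * V), c(4, 3, 6, V))
  p <- stgcn_forward(m, batch)

  # brute-force oracle: walk each (sample, frame, joint) independently
  # through the same weights -- plain per-node matrix algebra, then average
  # and apply the head. Batch norm in eval mode is an affine map using the
  # running statistics.
  layers <- m$root$children
  bn_eval <- function(l, v) {
    l$params$gamma * (v - l$run_mean) / sqrt(l$run_var + l$meta$eps) + l$params$beta
  }
  oracle_one <- function(xv) {                  # xv: length-3 feature vector
    h <- xv
    for (blk in layers[1:2]) {
      seqs <- blk$children[[1]]$children        # main path of the block
      gc <- seqs[[1]]; b1 <- seqs[[2]]; tc <- seqs[[4]]; b2 <- seqs[[5]]
      h <- as.vector(gc$params$W1 %*% h)        # identity adjacency, 1 subset
      h <- bn_eval(b1, h)
      h <- pmax(h, 0)
      h <- as.vector(tc$params$W1 %*% h)        # kernel 1 temporal conv
      h <- bn_eval(b2, h)
      h <- pmax(h, 0)                           # closing relu (no residual)
    }
    h
  }
  for (n in 1:4) {
    acc <- 0
    for (t in 1:6) for (v in 1:V) acc <- acc + oracle_one(batch[n, , t, v])
    feat <- acc / (6 * V)                       # global average pool
    dense <- layers[[length(layers)]]
    logits <- as.vector(dense$params$W %*% feat + dense$params$b)
    probs <- exp(logits - max(logits)); probs <- probs / sum(probs)
    expect_equal(unname(p[n, ]), probs, tolerance = 1e-8)
  }
})

test_that("attention weights are non-negative and sum to one over joints", {
  set.seed(23)
  m <- build_stgcn(stgcn_config(block_channels = c(4), temporal_kernel = 3,
                                temporal_strides = 1),
                   graph = toy_graph3(), seed = 2)
  m$attn$params$a <- rnorm(3)                   # move off the uniform init
  w <- attention_weights(m)
  expect_length(w, 3)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  no_attn <- build_stgcn(stgcn_config(block_channels = c(4), temporal_kernel = 3,
                                      temporal_strides = 1,
                                      attention_enabled = FALSE),
                         graph = toy_graph3(), seed = 2)
  expect_null(attention_weights(no_attn))
})

test_that("cnn_forward produces softmax rows; skips change the function", {
  set.seed(24)
  cfg <- cnn_config_desk()
  m <- build_cnn(cfg, seed = 5)
  batch <- array(abs(rnorm(3 * 1 * 16 * 16)), c(3, 1, 16, 16))
  p <- cnn_forward(m, batch)
  expect_equal(dim(p), c(3, 2))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_identical(cnn_forward(m, batch), p)    # determinism
  # identical inputs give identical outputs
  z <- array(0, c(2, 1, 16, 16))
  pz <- cnn_forward(m, z)
  expect_equal(pz[1, ], pz[2, ], tolerance = 1e-12)
  expect_error(cnn_forward(m, array(0, c(2, 3, 16, 16))),
               class = "sarcogait_shape_error")
  # ablating the residual shortcuts changes outputs at matched seed
  m_noskip <- build_cnn(cnn_config_desk(skip_connections = FALSE), seed = 5)
  p_noskip <- cnn_forward(m_noskip, batch)
  expect_gt(max(abs(p_noskip - p)), 1e-6)
})

test_that("the full-profile CNN has the ResNet-18 shape", {
  cfg <- cnn_config()
  expect_equal(cfg$stage_widths, c(64, 128, 256, 512))
  expect_equal(sum(cfg$blocks_per_stage), 8)    # 8 residual blocks
  expect_equal(cfg$in_channels, 1)              # 1-channel input, no triplication
  m <- build_cnn(cfg, seed = 1)
  n_res <- sum(sapply(m$root$children, function(l) l$type == "residual"))
  expect_equal(n_res, 8)
})

test_that("both models overfit a 16-sample batch within 200 steps", {
  # small profiles here; the acceptance suite repeats this at desk scale
  set.seed(25)
  y <- rep(1:2, each = 8)
  x <- array(rnorm(3 * 30 * 25 * 16), c(3, 30, 25, 16))
  x[, , , y == 2] <- x[, , , y == 2] + 0.5
  m <- build_stgcn(stgcn_config(block_channels = c(8, 16), temporal_kernel = 9),
                   seed = 1)
  acc <- NA
  for (round in 1:4) {                          # 4 x 50 steps, stop early
    fit_classifier(m, x, y, train_config("stgcn", epochs = 50, batch_size = 16,
                                         seed = round, schedule = "none", lr = 0.05))
    acc <- mean(predict_classes(m, x) == y)
    if (acc >= 0.95) break
  }
  expect_gte(acc, 0.95)

  xc <- array(abs(rnorm(1 * 32 * 32 * 16)), c(1, 32, 32, 16))
  xc[1, 8:24, 8:24, y == 2] <- xc[1, 8:24, 8:24, y == 2] + 1
  mc <- build_cnn(cnn_config_desk(), seed = 1)
  accc <- NA
  for (round in 1:4) {
    fit_classifier(mc, xc, y, train_config("cnn", epochs = 50, batch_size = 16,
                                           seed = round, lr = 0.01))
    accc <- mean(predict_classes(mc, xc) == y)
    if (accc >= 0.95) break
  }
  expect_gte(accc, 0.95)
})

test_that("checkpoints round-trip through save/load", {
  set.seed(26)
  m <- build_stgcn(stgcn_config(block_channels = c(4), temporal_kernel = 3,
                                temporal_strides = 1),
                   graph = toy_graph3(), seed = 9)
  batch <- array(rnorm(2 * 3 * 8 * 3), c(2, 3, 8, 3))
  p <- stgcn_forward(m, batch)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path, graph = toy_graph3())
  expect_equal(stgcn_forward(m2, batch), p, tolerance = 1e-12)
})
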