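# Fold construction, validation split, accuracy aggregation, and the
# cross-validated training loop on a tiny mock model.

test_that("make_folds stratifies the 20+80 cohort into four 5+20 folds", {
  sc <- generate_cohort(cohort_spec(seed = 1))
  folds <- make_folds(sc$cohort, 4, seed = 7)
  counts <- attr(folds, "class_counts")
  expect_true(all(counts[, "sarcopenia"] == 5))
  expect_true(all(counts[, "normal"] == 20))
  expect_true(all(rowSums(counts) == 25))
})

test_that("make_folds partitions any cohort for any seed", {
  co <- tiny_cohort(4, 4)
  f44 <- make_folds(co, 4, seed = 0)
  counts <- attr(f44, "class_counts")
  expect_true(all(counts == 1))                  # minimal stratification
  for (seed in c(1, 2, 99)) {
    co2 <- tiny_cohort(5, 9)
    f <- make_folds(co2, 4, seed = seed)
    expect_setequal(f$participant_id, co2$participant_id)
    expect_equal(anyDuplicated(f$participant_id), 0)
    # class counts differ by at most one across folds
    cc <- attr(f, "class_counts")
    expect_true(all(apply(cc, 2, function(v) diff(range(v)) <= 1)))
  }
  expect_error(make_folds(tiny_cohort(3, 8), 4),
               class = "sarcogait_stratification_error")
})

test_that("fold assignments are seed-deterministic and exportable", {
  co <- tiny_cohort(4, 8)
  f1 <- make_folds(co, 4, seed = 5)
  f2 <- make_folds(co, 4, seed = 5)
  expect_identical(f1, f2)
  expect_false(identical(make_folds(co, 4, seed = 6)$participant_id,
                         f1$participant_id) &&
                 identical(make_folds(co, 4, seed = 6)$fold, f1$fold))
  path <- withr::local_tempfile(fileext = ".csv")
  write_folds_csv(f1, path)
  back <- utils::read.csv(path)
  expect_equal(back$fold, f1$fold)
})

test_that("the 20% validation split reproduces the study counts", {
  # 15 sarcopenia + 60 normal training participants -> 3 + 12 validation
  ids <- sprintf("P%02d", 1:75)
  labels <- rep(c("sarcopenia", "normal"), c(15, 60))
  sp <- make_validation_split(ids, labels, 0.20, seed = 3)
  val_lab <- labels[match(sp$validation, ids)]
  expect_equal(sum(val_lab == "sarcopenia"), 3)
  expect_equal(sum(val_lab == "normal"), 12)
  # 5 + 20 -> 1 + 4
  ids2 <- sprintf("Q%02d", 1:25)
  lab2 <- rep(c("sarcopenia", "normal"), c(5, 20))
  sp2 <- make_validation_split(ids2, lab2, 0.20, seed = 3)
  val2 <- lab2[match(sp2$validation, ids2)]
  expect_equal(as.integer(table(val2)[c("sarcopenia", "normal")]), c(1L, 4L))
  # partition property
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_error(make_validation_split(ids, labels, 1.2))
})

test_that("average_accuracy reproduces the published table arithmetic", {
  resnet <- average_accuracy(c(77.22, 76.68, 86.89, 67.87))
  stgcn <- average_accuracy(c(80.12, 79.95, 80.08, 74.39))
  expect_lt(abs(resnet$raw - 77.16), 0.01)
  expect_lt(abs(stgcn$raw - 78.63), 0.01)
  expect_equal(average_accuracy(rep(55.5, 4))$raw, 55.5)
  expect_error(average_accuracy(c(50, 60, 70)), class = "sarcogait_invalid_input")
  expect_error(average_accuracy(c(50, 60, 70, 180)), class = "sarcogait_invalid_input")
})

# A degenerate "model" whose forward always returns class-1 logits lets the
# protocol be tested without training cost.
constant_model <- function() {
  root <- sarcogait:::new_layer("const")
  root$forward <- function(x, train = TRUE) {
    n <- dim(x)[4]
    rbind(rep(1, n), rep(0, n))
  }
  root$backward <- function(dy) dy
  structure(list(root = root, config = list(kind = "mock"), attn = NULL,
                 to_internal = NULL, c_in = 1),
            class = "sarcogait_model")
}

test_that("an always-normal classifier scores 80% on a 5/25-sarcopenia fold", {
  # 8 participants per class label mix chosen so each test fold is 1+4
  co <- tiny_cohort(4, 16)
  folds <- make_folds(co, 4, seed = 1)
  n_seq <- 3                                     # equal sequences per participant
  participant <- rep(co$participant_id, each = n_seq)
  label <- rep(co$label, each = n_seq)
  x <- array(0, dim = c(1, 2, 2, length(label)))
  ds <- list(x = x, label = label, participant = participant)
  cfg <- train_config("cnn", epochs = 1, batch_size = 8)
  ev <- train_and_eval(ds, folds, cfg, function(seed) constant_model(), seed = 1)
  expect_equal(ev$per_fold, rep(80, 4))          # 4 of 5 participants are normal
  expect_equal(ev$average, 80)
  # confusion counts: everything predicted normal
  for (cm in ev$confusion) {
    expect_equal(sum(cm[, "sarcopenia"]), 0)
    expect_equal(sum(cm), 15)
  }
})

test_that("train_and_eval is deterministic and leakage-checked", {
  set.seed(31)
  sc <- generate_cohort(cohort_spec(n_participants = 8, sarcopenia_fraction = 0.5,
                                    round_trips = 1, duration_s = 2.5, seed = 2))
  ds <- prepare_skeleton_dataset(sc, target_T = 12)
  folds <- make_folds(sc$cohort, 4, seed = 2)
  cfg <- train_config("stgcn", epochs = 2, batch_size = 4)
  builder <- function(seed) {
    build_stgcn(stgcn_config(block_channels = 4, temporal_kernel = 3,
                             temporal_strides = 1), seed = seed)
  }
  ev1 <- train_and_eval(ds, folds, cfg, builder, seed = 9)
  ev2 <- train_and_eval(ds, folds, cfg, builder, seed = 9)
  expect_identical(ev1$per_fold, ev2$per_fold)
  expect_identical(ev1$average, ev2$average)
  # a sequence assigned to an unknown participant is rejected
  bad <- ds; bad$participant[1] <- "ghost"
  expect_error(train_and_eval(bad, folds, cfg, builder), "fold")
})
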