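# The synthetic gait/pressure generator: construction symmetries,
# recoverable gait parameters, class structure, and determinism.

test_that("gait_params ties speed to stride and cadence", {
  p <- gait_params(stride_m = 1.2, cadence_spm = 120)
  expect_equal(p$speed_mps, 1.2)                 # 120 spm = 1 stride/s
  expect_silent(gait_params(stride_m = 1.2, cadence_spm = 120, speed_mps = 1.25))
  expect_error(gait_params(stride_m = 1.2, cadence_spm = 120, speed_mps = 2),
               class = "sarcogait_invalid_input")
  expect_error(gait_params(rom = 0), class = "sarcogait_invalid_input")
  expect_error(gait_params(forefoot_factor = 1.2), class = "sarcogait_invalid_input")
})

test_that("zero-noise walking is symmetric up to a half-cycle shift", {
  p <- gait_params(noise_sd = 0, asymmetry = 0, cadence_spm = 120)
  s <- simulate_walk(p, duration_s = 4, fps = 30, seed = 3)
  # cadence 120 -> cycle 1 s -> half cycle = 15 frames
  half <- 15
  T <- dim(s$coords)[1]
  la <- s$coords[, 21, ]                         # left ankle (raw index 20)
  ra <- s$coords[, 25, ]                         # right ankle (raw index 24)
  t1 <- 1:(T - half)
  expect_equal(ra[t1 + half, 2], la[t1, 2], tolerance = 1e-9)   # height matches
  dz <- ra[t1 + half, 3] - la[t1, 3]             # forward offset is constant
  expect_lt(diff(range(dz)), 1e-9)
  expect_equal(mean(dz), p$speed_mps * half / 30, tolerance = 1e-9)
})

test_that("zero-noise trunk distance equals the configured trunk length", {
  for (L in c(0.40, 0.50)) {
    p <- gait_params(trunk_m = L, noise_sd = 0)
    s25 <- select_joints(simulate_walk(p, duration_s = 2.5, seed = 1))
    expect_equal(sarcogait:::trunk_distances(s25),
                 rep(L, dim(s25$coords)[1]), tolerance = 1e-12)
  }
})

test_that("stride length is recoverable from ankle contacts within 5%", {
  p <- gait_params(stride_m = 1.1, cadence_spm = 100, noise_sd = 0, asymmetry = 0)
  s <- simulate_walk(p, duration_s = 6, fps = 30, seed = 8)
  ankle_y <- s$coords[, 21, 2]
  ankle_z <- s$coords[, 21, 3]
  T <- length(ankle_y)
  minima <- which(ankle_y[2:(T - 1)] < ankle_y[1:(T - 2)] &
                    ankle_y[2:(T - 1)] <= ankle_y[3:T]) + 1L
  # ground contacts are the deep minima (the swing phase has a shallow
  # secondary minimum well above them)
  minima <- minima[ankle_y[minima] < min(ankle_y) + 0.02]
  strides <- diff(ankle_z[minima])
  expect_gt(length(strides), 2)
  expect_lt(abs(mean(strides) - p$stride_m) / p$stride_m, 0.05)
})

test_that("walker validates inputs", {
  p <- gait_params()
  expect_error(simulate_walk(p, duration_s = 0.5), "cycle")
  expect_error(simulate_walk(p, duration_s = -1), class = "sarcogait_invalid_input")
})

test_that("forefoot factor scales forefoot mass linearly (ratio 2 check)", {
  base <- list(stride_m = 1.2, cadence_spm = 110, noise_sd = 0, stagger = 0)
  img_at <- function(ff) {
    p <- do.call(gait_params, c(base, list(forefoot_factor = ff)))
    average_pressure(synthesize_pressure(p, duration_s = 4, seed = 5))$pixels
  }
  m0 <- sum(img_at(0)); m05 <- sum(img_at(0.5)); m1 <- sum(img_at(1))
  expect_gt(m05, m0)
  expect_lt(abs((m1 - m0) / (m05 - m0) - 2), 0.02)
})

test_that("zero stagger places all same-side footprints on one lateral line", {
  p <- gait_params(stagger = 0, noise_sd = 0)
  s <- synthesize_pressure(p, duration_s = 4, seed = 2)
  img <- average_pressure(s)$pixels
  rs <- rowSums(img)
  active_rows <- which(rs > 0.01 * max(rs))      # above the Gaussian tails
  # footprints concentrate on exactly two lateral bands (left and right)
  gaps <- which(diff(active_rows) > 1)
  expect_equal(length(gaps), 1)
  expect_error(synthesize_pressure(p, duration_s = 2, grid_h = 8),
               class = "sarcogait_invalid_input")
})

test_that("averaged pressure equals average_pressure of the frames", {
  p <- gait_params()
  s <- synthesize_pressure(p, duration_s = 2.5, seed = 4)
  expect_equal(average_pressure(s)$pixels,
               apply(s$frames, c(2, 3), mean), tolerance = 1e-12)
})

test_that("generate_cohort lays out the full accounting and is deterministic", {
  spec <- cohort_spec(n_participants = 6, sarcopenia_fraction = 0.5,
                      round_trips = 2, duration_s = 2.5, seed = 77)
  sc1 <- generate_cohort(spec)
  sc2 <- generate_cohort(spec)
  expect_equal(nrow(sc1$manifest), 6 * 2 * 2)    # participants x trips x directions
  expect_identical(sc1$cohort, sc2$cohort)
  expect_identical(sc1$params, sc2$params)
  s1 <- cohort_skeleton(sc1, 5); s2 <- cohort_skeleton(sc2, 5)
  expect_identical(s1$coords, s2$coords)         # byte-identical regeneration
  p1 <- cohort_pressure(sc1, 5); p2 <- cohort_pressure(sc2, 5)
  expect_identical(p1$frames, p2$frames)
  # labels always match the intended class via the HGS draw
  expect_equal(sum(sc1$cohort$label == "sarcopenia"), 3)
})

test_that("sarcopenia priors yield slower, shorter gait than normal priors", {
  spec <- cohort_spec(n_participants = 30, sarcopenia_fraction = 0.5, seed = 12)
  sc <- generate_cohort(spec)
  stride <- sapply(sc$params, function(p) p$stride_m)
  speed <- sapply(sc$params, function(p) p$speed_mps)
  ff <- sapply(sc$params, function(p) p$forefoot_factor)
  lab <- sc$cohort$label
  expect_lt(mean(stride[lab == "sarcopenia"]), mean(stride[lab == "normal"]))
  expect_lt(mean(speed[lab == "sarcopenia"]), mean(speed[lab == "normal"]))
  expect_lt(mean(ff[lab == "sarcopenia"]), mean(ff[lab == "normal"]))
})

test_that("effect size 0 equalizes the class priors", {
  spec <- cohort_spec(n_participants = 40, sarcopenia_fraction = 0.5,
                      effect_size = 0, seed = 13)
  sc <- generate_cohort(spec)
  stride <- sapply(sc$params, function(p) p$stride_m)
  lab <- sc$cohort$label
  expect_lt(abs(mean(stride[lab == "sarcopenia"]) - mean(stride[lab == "normal"])),
            0.1)
})

test_that("a written cohort round-trips through the module readers", {
  spec <- cohort_spec(n_participants = 2, sarcopenia_fraction = 0.5,
                      round_trips = 1, duration_s = 2.5, seed = 21)
  sc <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_synthetic_cohort(sc, dir)
  co <- read_cohort_csv(file.path(dir, "cohort.csv"))
  expect_equal(co$label, sc$cohort$label)
  skel_files <- list.files(file.path(dir, "skeleton"), pattern = "\\.csv$",
                           full.names = TRUE)
  expect_length(skel_files, 4)
  back <- read_skeleton_csv(skel_files[1])
  orig <- cohort_skeleton(sc, which(sprintf("%s_%s.csv",
                                            sc$manifest$participant_id,
                                            sc$manifest$sequence_id) ==
                                      basename(skel_files[1]))[1])
  expect_equal(back$coords, orig$coords, tolerance = 1e-6)
  press_dirs <- list.dirs(file.path(dir, "pressure"), recursive = FALSE)
  expect_length(press_dirs, 4)
  ps <- read_pressure_series(press_dirs[1])
  expect_true(all(ps$frames >= 0))
})

test_that("datasets built from a cohort align labels with participants", {
  spec <- cohort_spec(n_participants = 4, sarcopenia_fraction = 0.5,
                      round_trips = 1, duration_s = 2.5, seed = 31)
  sc <- generate_cohort(spec)
  ds <- prepare_skeleton_dataset(sc, target_T = 20, branches = c("position", "velocity", "bone"))
  expect_equal(dim(ds$x), c(9, 20, 25, 8))
  lab_by_p <- sc$cohort$label[match(ds$participant, sc$cohort$participant_id)]
  expect_identical(ds$label, lab_by_p)
  dp <- prepare_pressure_dataset(sc, h = 32, w = 32)
  expect_equal(dim(dp$x), c(1, 32, 32, 8))
  expect_true(all(dp$x >= 0 & dp$x <= 1))
})
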