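# Synthetic labeled cohorts: stylized 3D gait kinematics and paired
# plantar-pressure series with the class structure the analysis assumes
# (sarcopenia gait = shorter/uneven strides, reduced joint range of motion,
# slower forward speed, reduced forefoot pressure).
#
# The walker is a sinusoidal kinematic model, not a biomechanically
# validated one; its purpose is controllable, seed-reproducible class
# structure for download-free testing of every pipeline stage.

#' Gait parameters of one walker
#'
#' Walking speed is tied to stride length and cadence at construction
#' (`speed = stride_m * cadence_spm / 120`, two steps per stride); passing
#' an inconsistent explicit speed (>10% off) is an error.
#'
#' @param stride_m Stride length (m).
#' @param cadence_spm Cadence (steps/min).
#' @param rom Range-of-motion scale in (0, 1.5].
#' @param asymmetry Left/right phase and amplitude irregularity (>= 0).
#' @param trunk_m Sacrum-to-shoulder-center trunk length (m).
#' @param noise_sd Additive joint noise standard deviation (m).
#' @param forefoot_factor Forefoot pressure multiplier in [0, 1].
#' @param stagger Lateral footprint jitter scale (>= 0).
#' @param speed_mps Optional explicit speed (must be consistent).
#' @return A `gait_params` list.
#' @export
gait_params <- function(stride_m = 1.30, cadence_spm = 110, rom = 1.0,
                        asymmetry = 0.03, trunk_m = 0.45, noise_sd = 0.005,
                        forefoot_factor = 0.95, stagger = 0.02,
                        speed_mps = NULL) {
  sg_assert(stride_m > 0 && cadence_spm > 0 && trunk_m > 0,
            "stride, cadence and trunk length must be positive")
  sg_assert(rom > 0 && rom <= 1.5, "rom must lie in (0, 1.5]")
  sg_assert(asymmetry >= 0 && stagger >= 0, "asymmetry and stagger must be >= 0")
  sg_assert(forefoot_factor >= 0 && forefoot_factor <= 1,
            "forefoot_factor must lie in [0, 1]")
  sg_assert(noise_sd >= 0, "noise_sd must be >= 0")
  derived <- stride_m * cadence_spm / 120
  if (!is.null(speed_mps)) {
    sg_assert(abs(speed_mps - derived) <= 0.1 * derived,
              "speed_mps inconsistent with stride length and cadence")
  }
  structure(list(stride_m = stride_m, cadence_spm = cadence_spm, rom = rom,
                 asymmetry = asymmetry, trunk_m = trunk_m, noise_sd = noise_sd,
                 forefoot_factor = forefoot_factor, stagger = stagger,
                 speed_mps = derived),
            class = "gait_params")
}

#' Simulate a 32-joint walking sequence
#'
#' A kinematic walker: the pelvis advances along z at the configured speed;
#' hip/knee angles follow sinusoids at the cadence frequency with amplitude
#' scaled by `rom`, the right leg phase-offset by half a cycle plus an
#' asymmetry jitter; arms counter-swing; the sacrum-to-chest distance is
#' exactly `trunk_m`. All 32 joints receive iid Gaussian noise of sd
#' `noise_sd`.
#'
#' @param params A [gait_params()].
#' @param duration_s Sequence duration (> one gait cycle).
#' @param fps Frames per second (default 30).
#' @param seed Integer seed.
#' @param direction +1 (forward along z) or -1 (return leg of a round trip).
#' @return A raw32 [skeleton_sequence()].
#' @export
simulate_walk <- function(params, duration_s = 4, fps = 30, seed = 0,
                          direction = 1) {
  stopifnot(inherits(params, "gait_params"))
  sg_assert(duration_s > 0 && fps > 0, "duration and fps must be positive")
  cycle_s <- 120 / params$cadence_spm
  sg_assert(duration_s > cycle_s, "duration must exceed one gait cycle")
  with_seed(derive_seed(seed, "walk"), {
    T <- floor(duration_s * fps)
    t <- (seq_len(T) - 1) / fps
    phi <- 2 * pi * t / cycle_s + stats::runif(1, 0, 2 * pi)
    asym_phase <- stats::rnorm(1, 0, params$asymmetry * 0.3)
    asym_amp <- stats::rnorm(1, 0, params$asymmetry * 0.2)
    L <- params$trunk_m
    thigh <- 0.42; shank <- 0.42
    hip_h <- 0.92; pelvis_hw <- 0.10; shoulder_hw <- 0.18
    uarm <- 0.30; farm <- 0.28
    co <- array(0, dim = c(T, 32, 3))
    set_j <- function(j, x, y, z) {
      co[, j + 1L, 1] <<- x; co[, j + 1L, 2] <<- y; co[, j + 1L, 3] <<- z
    }
    # pelvis and rigid spine chain
    px <- 0.02 * params$rom * sin(phi)
    py <- hip_h + 0.015 * params$rom * cos(2 * phi)
    pz <- 0.3 + params$speed_mps * t
    set_j(0, px, py, pz)                         # pelvis (sacrum)
    set_j(1, px, py + 0.50 * L, pz)              # spine navel
    set_j(2, px, py + L, pz)                     # spine chest (shoulder center)
    set_j(3, px, py + 1.15 * L, pz)              # neck
    set_j(26, px, py + 1.35 * L, pz)             # head
    set_j(27, px, py + 1.37 * L, pz + 0.10)      # nose
    set_j(28, px + 0.03, py + 1.38 * L, pz + 0.07)
    set_j(30, px - 0.03, py + 1.38 * L, pz + 0.07)
    set_j(29, px + 0.07, py + 1.36 * L, pz)
    set_j(31, px - 0.07, py + 1.36 * L, pz)
    # arms: counter-swing relative to the ipsilateral leg
    arm <- function(side, phase) {                # side +1 = left
      a <- 0.35 * params$rom * sin(phase)
      sx <- px + side * shoulder_hw; sy <- py + L + 0.02; sz <- pz
      ex <- sx; ey <- sy - uarm * cos(a); ez <- sz + uarm * sin(a)
      wa <- a + 0.30
      wx <- ex; wy <- ey - farm * cos(wa); wz <- ez + farm * sin(wa)
      list(sx = sx, sy = sy, sz = sz, ex = ex, ey = ey, ez = ez,
           wx = wx, wy = wy, wz = wz)
    }
    al <- arm(+1, phi + pi); ar <- arm(-1, phi)
    set_j(4, px + 0.05, py + L + 0.03, pz)       # clavicles
    set_j(11, px - 0.05, py + L + 0.03, pz)
    set_j(5, al$sx, al$sy, al$sz); set_j(12, ar$sx, ar$sy, ar$sz)
    set_j(6, al$ex, al$ey, al$ez); set_j(13, ar$ex, ar$ey, ar$ez)
    set_j(7, al$wx, al$wy, al$wz); set_j(14, ar$wx, ar$wy, ar$wz)
    set_j(8, al$wx, al$wy - 0.05, al$wz + 0.05)  # hands
    set_j(15, ar$wx, ar$wy - 0.05, ar$wz + 0.05)
    set_j(9, al$wx, al$wy - 0.08, al$wz + 0.09)  # hand tips
    set_j(16, ar$wx, ar$wy - 0.08, ar$wz + 0.09)
    set_j(10, al$wx - 0.03, al$wy - 0.03, al$wz + 0.04)  # thumbs
    set_j(17, ar$wx + 0.03, ar$wy - 0.03, ar$wz + 0.04)
    # legs
    leg <- function(side, phase, amp_f) {
      hx <- px + side * pelvis_hw; hy <- py - 0.02; hz <- pz
      alpha <- 0.50 * params$rom * amp_f * sin(phase)
      beta <- 0.90 * params$rom * amp_f * (1 - cos(phase)) / 2
      kx <- hx; ky <- hy - thigh * cos(alpha); kz <- hz + thigh * sin(alpha)
      gam <- alpha - beta
      ax <- kx; ay <- ky - shank * cos(gam); az <- kz + shank * sin(gam)
      list(hx = hx, hy = hy, hz = hz, kx = kx, ky = ky, kz = kz,
           ax = ax, ay = ay, az = az,
           fx = ax, fy = ay - 0.05, fz = az + 0.12)
    }
    ll <- leg(+1, phi, 1)
    lr <- leg(-1, phi + pi + asym_phase, 1 + asym_amp)
    set_j(18, ll$hx, ll$hy, ll$hz); set_j(22, lr$hx, lr$hy, lr$hz)
    set_j(19, ll$kx, ll$ky, ll$kz); set_j(23, lr$kx, lr$ky, lr$kz)
    set_j(20, ll$ax, ll$ay, ll$az); set_j(24, lr$ax, lr$ay, lr$az)
    set_j(21, ll$fx, ll$fy, ll$fz); set_j(25, lr$fx, lr$fy, lr$fz)
    if (params$noise_sd > 0) {
      co <- co + array(stats::rnorm(length(co), 0, params$noise_sd), dim = dim(co))
    }
    if (direction < 0) co[, , 3] <- 6 - co[, , 3]   # return leg of the walkway
    skeleton_sequence(co, fps = fps, joint_set = "raw32")
  })
}

#' Synthesize a plantar-pressure frame series
#'
#' Footprints are placed alternately left/right along the walkway axis at
#' half-stride spacing with lateral stagger jitter; each footprint is a heel
#' blob plus a forefoot blob (2-D Gaussians), the forefoot amplitude
#' multiplied by `forefoot_factor`. Blobs are active during stance windows
#' with a smooth loading profile; all values are >= 0.
#'
#' @param params A [gait_params()].
#' @param duration_s Series duration (s).
#' @param grid_h,grid_w Sensor grid size (default 64 x 192; the walkway runs
#'   along the 192-pixel axis, 6 m at 32 px/m).
#' @param fps Frame rate (default 30).
#' @param seed Integer seed.
#' @return A [pressure_series()].
#' @export
synthesize_pressure <- function(params, duration_s = 4, grid_h = 64,
                                grid_w = 192, fps = 30, seed = 0) {
  stopifnot(inherits(params, "gait_params"))
  sg_assert(duration_s > 0, "duration must be positive")
  walk_m <- 6
  px_per_m <- grid_w / walk_m
  # footprint half-widths ~2 sigma: heel ~4 cm, forefoot ~5.5 cm, narrow
  # enough that left and right tracks (20 cm apart) never blur together
  sigma_heel <- 0.020 * px_per_m
  sigma_fore <- 0.028 * px_per_m
  halfwin <- ceiling(4 * sigma_fore)
  if (grid_h < 2 * halfwin + 5) {
    sg_abort("grid too small for a footprint", "sarcogait_invalid_input")
  }
  with_seed(derive_seed(seed, "pressure"), {
    T <- floor(duration_s * fps)
    cycle_s <- 120 / params$cadence_spm
    stance_s <- 0.62 * cycle_s
    step_m <- params$stride_m / 2
    lat_off_m <- 0.10
    frames <- array(0, dim = c(T, grid_h, grid_w))
    k <- 0
    repeat {
      t_k <- 0.2 + k * cycle_s / 2
      along_m <- 0.3 + k * step_m
      if (t_k > duration_s || along_m > walk_m - 0.3) break
      side <- if (k %% 2 == 0) 1 else -1
      lat_m <- side * lat_off_m + stats::rnorm(1, 0, params$stagger * lat_off_m)
      row_c <- grid_h / 2 + lat_m * px_per_m
      heel_c <- (along_m - 0.05) * px_per_m
      fore_c <- (along_m + 0.10) * px_per_m
      rows <- pmax(1, floor(row_c - halfwin)):pmin(grid_h, ceiling(row_c + halfwin))
      cols <- pmax(1, floor(heel_c - halfwin)):pmin(grid_w, ceiling(fore_c + halfwin))
      rr <- matrix(rows, length(rows), length(cols))
      cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
      patch <- exp(-((rr - row_c)^2 + (cc - heel_c)^2) / (2 * sigma_heel^2)) +
        1.2 * params$forefoot_factor *
          exp(-((rr - row_c)^2 + (cc - fore_c)^2) / (2 * sigma_fore^2))
      f0 <- max(1, ceiling(t_k * fps))
      f1 <- min(T, floor((t_k + stance_s) * fps))
      if (f1 >= f0) {
        jit <- stats::runif(f1 - f0 + 1, 0.95, 1.05)
        for (f in f0:f1) {
          w <- sin(pi * (f / fps - t_k) / stance_s)
          if (w > 0) {
            frames[f, rows, cols] <- frames[f, rows, cols] + w * jit[f - f0 + 1] * patch
          }
        }
      }
      k <- k + 1
    }
    pressure_series(frames, spacing_m = 1 / px_per_m)
  })
}

#' Cohort generation spec
#'
#' Defaults mirror the study composition used as fixture defaults only:
#' 100 participants (23% male), 20% sarcopenia, 10 round trips x 2 walking
#' directions = 20 sequences per participant (100 x 10 x 2 = 2,000
#' sequences). `effect_size` scales the mean separation of the
#' sarcopenia-marker parameters (stride, cadence/speed, range of motion,
#' forefoot pressure); 0 = identical class distributions, 1 = the default
#' strong separation.
#'
#' @param n_participants,sarcopenia_fraction,male_fraction Cohort shape.
#' @param round_trips Round trips per participant (2 sequences each).
#' @param effect_size Class separation scale (>= 0).
#' @param duration_s,fps Per-sequence capture parameters.
#' @param borderline_fraction Fraction of participants whose grip strength
#'   is drawn within 0.5 kg of the diagnostic cutoff (boundary stress).
#' @param seed Master seed; everything downstream derives from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 100, sarcopenia_fraction = 0.20,
                        male_fraction = 0.23, round_trips = 10,
                        effect_size = 1, duration_s = 4, fps = 30,
                        borderline_fraction = 0.05, seed = 0) {
  sg_assert(sg_is_count(n_participants), "n_participants must be a positive integer")
  sg_assert(sarcopenia_fraction >= 0 && sarcopenia_fraction <= 1 &&
              male_fraction >= 0 && male_fraction <= 1 &&
              borderline_fraction >= 0 && borderline_fraction <= 1,
            "fractions must lie in [0, 1]")
  sg_assert(effect_size >= 0, "effect_size must be >= 0")
  structure(list(n_participants = n_participants,
                 sarcopenia_fraction = sarcopenia_fraction,
                 male_fraction = male_fraction, round_trips = round_trips,
                 effect_size = effect_size, duration_s = duration_s,
                 fps = fps, borderline_fraction = borderline_fraction,
                 seed = seed),
            class = "cohort_spec")
}

# Class priors: means for the normal class, deltas applied at effect size 1.
PRIOR_NORMAL <- list(stride = 1.30, cadence = 110, rom = 1.00,
                     forefoot = 0.95, asym = 0.03, stagger = 0.02)
PRIOR_DELTA <- list(stride = -0.45, cadence = -15, rom = -0.35,
                    forefoot = -0.40, asym = 0.12, stagger = 0.06)
PRIOR_SD <- list(stride = 0.07, cadence = 5, rom = 0.05,
                 forefoot = 0.04, trunk = 0.03)

draw_gait_params <- function(is_sarc, effect) {
  eff <- if (is_sarc) effect else 0
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  gait_params(
    stride_m = clamp(stats::rnorm(1, PRIOR_NORMAL$stride + eff * PRIOR_DELTA$stride,
                                  PRIOR_SD$stride), 0.3, 2.0),
    cadence_spm = clamp(stats::rnorm(1, PRIOR_NORMAL$cadence + eff * PRIOR_DELTA$cadence,
                                     PRIOR_SD$cadence), 50, 160),
    rom = clamp(stats::rnorm(1, PRIOR_NORMAL$rom + eff * PRIOR_DELTA$rom,
                             PRIOR_SD$rom), 0.15, 1.5),
    forefoot_factor = clamp(stats::rnorm(1, PRIOR_NORMAL$forefoot + eff * PRIOR_DELTA$forefoot,
                                         PRIOR_SD$forefoot), 0, 1),
    asymmetry = max(0, PRIOR_NORMAL$asym + eff * PRIOR_DELTA$asym),
    stagger = max(0, PRIOR_NORMAL$stagger + eff * PRIOR_DELTA$stagger),
    trunk_m = clamp(stats::rnorm(1, 0.45, PRIOR_SD$trunk), 0.35, 0.55),
    noise_sd = 0.005
  )
}

draw_hgs <- function(sex, is_sarc, borderline, thresholds = awgs_thresholds()) {
  cut <- if (sex == "male") thresholds$male else thresholds$female
  # keep a 0.06 kg margin below the cutoff so 1-decimal rounding of stored
  # values can never flip an intended sarcopenia label to normal
  if (stats::runif(1) < borderline) {
    return(if (is_sarc) cut - stats::runif(1, 0.06, 0.5) else cut + stats::runif(1, 0, 0.5))
  }
  repeat {
    v <- if (is_sarc) {
      stats::rnorm(1, cut - 6, 3)
    } else {
      stats::rnorm(1, cut + 10, 5)
    }
    if (v >= 0 && ((is_sarc && v < cut - 0.06) || (!is_sarc && v >= cut))) return(v)
  }
}

#' Generate a labeled synthetic cohort
#'
#' Draws participant metadata (sex, age, grip strength consistent with the
#' intended class under [label_awgs()]) and per-participant gait parameters
#' from class priors, then lays out one skeleton/pressure sequence pair per
#' walk in the manifest. Sequences are generated lazily and
#' deterministically from per-sequence derived seeds: the same spec always
#' yields byte-identical data.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort` with `$cohort` ([cohort_table()]),
#'   `$manifest` (one row per sequence), `$params` (per participant), and
#'   accessors [cohort_skeleton()] / [cohort_pressure()].
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  n_sarc <- round(spec$sarcopenia_fraction * n)
  with_seed(derive_seed(spec$seed, "cohort-meta"), {
    is_sarc <- c(rep(TRUE, n_sarc), rep(FALSE, n - n_sarc))
    sex <- ifelse(stats::runif(n) < spec$male_fraction, "male", "female")
    band <- sample(1:4, n, replace = TRUE, prob = c(0.18, 0.21, 0.28, 0.33))
    age <- c(30, 40, 60, 70)[band] +
      floor(stats::runif(n) * c(10, 20, 10, 16)[band])
    hgs <- numeric(n)
    params <- vector("list", n)
    for (i in seq_len(n)) {
      hgs[i] <- draw_hgs(sex[i], is_sarc[i], spec$borderline_fraction)
      params[[i]] <- draw_gait_params(is_sarc[i], spec$effect_size)
    }
  })
  ids <- sprintf("P%03d", seq_len(n))
  cohort <- cohort_table(ids, sex, age, round(hgs, 1))
  sg_assert(identical(cohort$label, ifelse(is_sarc, "sarcopenia", "normal")),
            "drawn grip strengths must reproduce the intended classes")
  n_seq <- 2 * spec$round_trips
  manifest <- data.frame(
    participant_id = rep(ids, each = n_seq),
    sequence_id = sprintf("S%02d", rep(seq_len(n_seq), times = n)),
    direction = rep(rep(c(1L, -1L), spec$round_trips), times = n),
    stringsAsFactors = FALSE
  )
  names(params) <- ids
  structure(list(spec = spec, cohort = cohort, manifest = manifest,
                 params = params),
            class = "synthetic_cohort")
}

#' Materialize one sequence of a synthetic cohort
#'
#' @param sc A [generate_cohort()] result.
#' @param i Manifest row index.
#' @return `cohort_skeleton`: a raw32 [skeleton_sequence()];
#'   `cohort_pressure`: a [pressure_series()].
#' @export
cohort_skeleton <- function(sc, i) {
  row <- sc$manifest[i, ]
  p <- sc$params[[row$participant_id]]
  seq <- simulate_walk(p, duration_s = sc$spec$duration_s, fps = sc$spec$fps,
                       seed = derive_seed(sc$spec$seed,
                                          paste("skel", row$participant_id, row$sequence_id)),
                       direction = row$direction)
  seq$participant_id <- row$participant_id
  seq$sequence_id <- row$sequence_id
  seq
}

#' @rdname cohort_skeleton
#' @export
cohort_pressure <- function(sc, i) {
  row <- sc$manifest[i, ]
  p <- sc$params[[row$participant_id]]
  s <- synthesize_pressure(p, duration_s = sc$spec$duration_s, fps = sc$spec$fps,
                           seed = derive_seed(sc$spec$seed,
                                              paste("press", row$participant_id, row$sequence_id)))
  s$participant_id <- row$participant_id
  s$sequence_id <- row$sequence_id
  s
}

#' Write a synthetic cohort to the on-disk layout
#'
#' Produces the directory structure consumed by the pipeline: `cohort.csv`,
#' `manifest.json`, one skeleton CSV (+ JSON sidecar) per sequence under
#' `skeleton/`, and per-sequence pressure frame directories under
#' `pressure/`.
#'
#' @param sc A [generate_cohort()] result.
#' @param dir Output directory.
#' @param modalities Which modalities to write.
#' @export
write_synthetic_cohort <- function(sc, dir, modalities = c("skeleton", "pressure")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(sc$cohort, file.path(dir, "cohort.csv"))
  jsonlite::write_json(sc$manifest, file.path(dir, "manifest.json"), digits = NA)
  if ("skeleton" %in% modalities) {
    dir.create(file.path(dir, "skeleton"), showWarnings = FALSE)
    for (i in seq_len(nrow(sc$manifest))) {
      row <- sc$manifest[i, ]
      write_skeleton_csv(cohort_skeleton(sc, i),
                         file.path(dir, "skeleton",
                                   sprintf("%s_%s.csv", row$participant_id, row$sequence_id)))
    }
  }
  if ("pressure" %in% modalities) {
    dir.create(file.path(dir, "pressure"), showWarnings = FALSE)
    for (i in seq_len(nrow(sc$manifest))) {
      row <- sc$manifest[i, ]
      write_pressure_series(cohort_pressure(sc, i),
                            file.path(dir, "pressure",
                                      sprintf("%s_%s", row$participant_id, row$sequence_id)))
    }
  }
  invisible(dir)
}

# ---- feature preparation ----------------------------------------------------

skeleton_features <- function(seq25_norm, branches, graph) {
  co <- seq25_norm$coords                       # (T, V, 3)
  T <- dim(co)[1]; V <- dim(co)[2]
  parts <- list()
  if ("position" %in% branches) parts$position <- aperm(co, c(3, 1, 2))
  if ("velocity" %in% branches) {
    parts$velocity <- aperm(joint_velocity(seq25_norm), c(3, 1, 2))
  }
  if ("bone" %in% branches) {
    bv <- bone_vectors(seq25_norm, graph)       # (T, E, 3)
    nodes <- array(0, dim = c(T, V, 3))
    nodes[, graph$edges[, 2] + 1L, ] <- bv      # child joint carries its bone
    parts$bone <- aperm(nodes, c(3, 1, 2))
  }
  x <- array(0, dim = c(3 * length(parts), T, V))
  for (b in seq_along(parts)) x[(3 * b - 2):(3 * b), , ] <- parts[[b]]
  x
}

#' Build the skeleton training dataset from a synthetic cohort
#'
#' Per sequence: select the 25 joints, trunk-normalize per frame, resample
#' to `target_T` frames, then assemble the enabled feature branches
#' (position / velocity / bone, 3 channels each).
#'
#' @param sc A [generate_cohort()] result.
#' @param target_T Frames after resampling (default 60).
#' @param branches Feature branches.
#' @param graph A [joint_graph()].
#' @return A dataset list: `x` (C x T x V x N), `label`, `participant`.
#' @export
prepare_skeleton_dataset <- function(sc, target_T = 60, branches = "position",
                                     graph = joint_graph()) {
  n <- nrow(sc$manifest)
  C <- 3 * length(branches)
  V <- graph$node_count
  x <- array(0, dim = c(C, target_T, V, n))
  for (i in seq_len(n)) {
    s <- select_joints(cohort_skeleton(sc, i), graph)
    s <- normalize_sequence(s)$seq
    s <- resample_sequence(s, target_T)
    x[, , , i] <- skeleton_features(s, branches, graph)
  }
  lab <- sc$cohort$label[match(sc$manifest$participant_id, sc$cohort$participant_id)]
  list(x = x, label = lab, participant = sc$manifest$participant_id,
       modality = "skeleton")
}

#' Build the pressure-image training dataset from a synthetic cohort
#'
#' Per sequence: synthesize the frame series, time-average to the 1-channel
#' image, divide by the image maximum, and bilinearly resize to `h x w`.
#'
#' @param sc A [generate_cohort()] result.
#' @param h,w Model input size (default 64 x 64).
#' @return A dataset list: `x` (1 x h x w x N), `label`, `participant`.
#' @export
prepare_pressure_dataset <- function(sc, h = 64, w = 64) {
  n <- nrow(sc$manifest)
  x <- array(0, dim = c(1, h, w, n))
  for (i in seq_len(n)) {
    img <- average_pressure(cohort_pressure(sc, i))
    img <- resize_image(normalize_pressure_image(img), h, w)
    x[1, , , i] <- img$pixels
  }
  lab <- sc$cohort$label[match(sc$manifest$participant_id, sc$cohort$participant_id)]
  list(x = x, label = lab, participant = sc$manifest$participant_id,
       modality = "pressure")
}

#' Training-batch augmentation for pressure images
#'
#' Applies [augment_pressure()] (mirror with p = 0.5, rotation drawn from
#' {-45, 0, 45} degrees) independently to each image of a (1, H, W, N)
#' batch. Intended as the `augment` hook of [fit_classifier()].
#'
#' @param batch A 1 x H x W x N array.
#' @param angles Candidate rotation angles.
#' @return The augmented batch.
#' @export
augment_pressure_batch <- function(batch, angles = c(-45, 0, 45)) {
  for (i in seq_len(dim(batch)[4])) {
    img <- augment_pressure(pressure_image(batch[1, , , i]), angles)
    batch[1, , , i] <- img$pixels
  }
  batch
}
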