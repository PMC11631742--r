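# Joint selection, trunk-distance normalization, derived features,
# resampling, and the file round trip.

test_that("select_joints is a pure projection onto the 25-joint order", {
  seq <- coded_raw32(3)
  out <- select_joints(seq)
  expect_equal(dim(out$coords), c(3, 25, 3))
  expect_identical(out$joint_set, "selected25")
  g <- joint_graph()
  # brute-force index scan: every retained value appears unchanged
  for (k in seq_len(25)) {
    expect_equal(out$coords[, k, ], seq$coords[, g$selection_map[k] + 1L, ])
  }
  expect_identical(g$node_names[1], "sacrum")
  expect_identical(g$node_names[21], "shoulder_center")
  expect_identical(g$node_names[25], "thumb_right")
  expect_error(select_joints(out), class = "sarcogait_shape_error")
})

test_that("trunk_distance matches hand-computed values and flags degenerate frames", {
  frame <- matrix(0, 25, 3)
  frame[21, ] <- c(0, 1, 0)                     # joint 20 one unit above joint 0
  expect_equal(trunk_distance(frame), 1)
  frame[1, ] <- c(1, 2, 2); frame[21, ] <- c(0, 0, 0)
  expect_equal(trunk_distance(frame), 3)        # sqrt(1 + 4 + 4)
  frame[1, ] <- frame[21, ]
  expect_error(trunk_distance(frame), class = "sarcogait_degenerate_frame")
})

test_that("normalize_sequence divides by the per-frame trunk distance", {
  co <- array(0, dim = c(2, 25, 3))
  co[, 21, 2] <- c(2, 4)                        # d = 2 then 4
  co[1, 5, ] <- c(2, 4, 4)
  co[2, 5, ] <- c(2, 4, 4)
  seq <- skeleton_sequence(co, joint_set = "selected25")
  res <- normalize_sequence(seq)
  expect_equal(res$d, c(2, 4))
  expect_equal(res$seq$coords[1, 5, ], c(1, 2, 2))
  expect_equal(res$seq$coords[2, 5, ], c(0.5, 1, 1))
})

test_that("normalization properties: unit trunk, scale invariance, idempotence", {
  set.seed(31)
  co <- array(rnorm(6 * 25 * 3), dim = c(6, 25, 3))
  seq <- skeleton_sequence(co, joint_set = "selected25")
  norm1 <- normalize_sequence(seq)$seq
  d1 <- apply(norm1$coords, 1, function(fr) trunk_distance(matrix(fr, 25, 3)))
  expect_true(all(abs(d1 - 1) < 1e-9))
  # scale invariance: c * seq normalizes to the same result
  scaled <- skeleton_sequence(co * 7.3, joint_set = "selected25")
  expect_equal(normalize_sequence(scaled)$seq$coords, norm1$coords, tolerance = 1e-12)
  # idempotence up to floating tolerance
  norm2 <- normalize_sequence(norm1)$seq
  expect_lt(max(abs(norm2$coords - norm1$coords)), 1e-9 * max(abs(norm1$coords)))
})

test_that("degenerate frames error with indices, or are dropped on request", {
  co <- array(rnorm(4 * 25 * 3), dim = c(4, 25, 3))
  co[3, 21, ] <- co[3, 1, ]                     # frame 2 (0-based) degenerate
  seq <- skeleton_sequence(co, joint_set = "selected25")
  err <- tryCatch(normalize_sequence(seq), error = identity)
  expect_s3_class(err, "sarcogait_degenerate_frame")
  expect_match(conditionMessage(err), "2")
  res <- suppressWarnings(normalize_sequence(seq, drop_degenerate = TRUE))
  expect_equal(dim(res$seq$coords)[1], 3)
})

test_that("joint_velocity uses backward differences with a zero first frame", {
  co <- array(1, dim = c(5, 25, 3))
  static <- skeleton_sequence(co, joint_set = "selected25")
  expect_true(all(joint_velocity(static) == 0))
  # linear motion: slope s per frame everywhere from frame 1 on
  s <- c(0.3, -0.2, 0.5)
  for (ax in 1:3) co[, , ax] <- outer(seq_len(5) * s[ax], rep(1, 25))
  lin <- skeleton_sequence(co, joint_set = "selected25")
  v <- joint_velocity(lin)
  expect_true(all(v[1, , ] == 0))
  for (ax in 1:3) expect_true(all(abs(v[2:5, , ax] - s[ax]) < 1e-12))
  # telescoping
  set.seed(4)
  co2 <- array(rnorm(6 * 25 * 3), dim = c(6, 25, 3))
  rnd <- skeleton_sequence(co2, joint_set = "selected25")
  v2 <- joint_velocity(rnd)
  expect_equal(apply(v2[2:6, , , drop = FALSE], c(2, 3), sum),
               co2[6, , ] - co2[1, , ], tolerance = 1e-12)
  expect_error(joint_velocity(skeleton_sequence(co2[1, , , drop = FALSE],
                                                joint_set = "selected25")))
})

test_that("bone_vectors are antisymmetric, translation invariant, unit on the trunk", {
  set.seed(5)
  g <- joint_graph()
  co <- array(rnorm(3 * 25 * 3), dim = c(3, 25, 3))
  seq <- skeleton_sequence(co, joint_set = "selected25")
  bv <- bone_vectors(seq, g)
  expect_equal(dim(bv), c(3, 24, 3))
  # translation cancels
  co_t <- sweep(co, 3, c(5, -2, 9), "+")
  bv_t <- bone_vectors(skeleton_sequence(co_t, joint_set = "selected25"), g)
  expect_equal(bv, bv_t, tolerance = 1e-12)
  # swapped parent/child flips sign
  g_rev <- joint_graph(edges = g$edges[, 2:1])
  expect_equal(bone_vectors(seq, g_rev), -bv, tolerance = 1e-12)
  # after normalization the sacrum -> spine edge chain keeps trunk length 1:
  # edges 0-1 and 1-20 sum to the trunk vector
  nseq <- normalize_sequence(seq)$seq
  nbv <- bone_vectors(nseq, g)
  trunk <- nbv[, 1, ] + nbv[, 2, ]              # 0-1 then 1-20 in edge order
  expect_equal(sqrt(rowSums(trunk^2)), rep(1, 3), tolerance = 1e-9)
  # missing joint index errors
  bad <- joint_graph(node_names = c(g$node_names, "x"),
                     edges = rbind(g$edges, c(0L, 25L)),
                     selection_map = c(g$selection_map, 0L))
  expect_error(bone_vectors(seq, bad), class = "sarcogait_shape_error")
})

test_that("resample_sequence interpolates linearly with preserved endpoints", {
  set.seed(6)
  co <- array(rnorm(7 * 25 * 3), dim = c(7, 25, 3))
  seq <- skeleton_sequence(co, joint_set = "selected25")
  expect_identical(resample_sequence(seq, 7), seq)
  const <- skeleton_sequence(array(2, dim = c(5, 25, 3)), joint_set = "selected25")
  rc <- resample_sequence(const, 11)
  expect_true(all(rc$coords == 2))
  # coordinates linear in time stay exactly on the line
  lin <- array(0, dim = c(5, 25, 3))
  for (ax in 1:3) lin[, , ax] <- outer(0:4, rep(ax, 25))
  ls <- skeleton_sequence(lin, joint_set = "selected25")
  rl <- resample_sequence(ls, 9)
  expect_equal(rl$coords[, 1, 1], seq(0, 4, length.out = 9), tolerance = 1e-12)
  expect_equal(rl$coords[1, , ], lin[1, , ])
  expect_equal(rl$coords[9, , ], lin[5, , ])
  expect_error(resample_sequence(seq, 1))
})

test_that("skeleton sequences round-trip through the CSV interface", {
  set.seed(7)
  seq <- skeleton_sequence(array(rnorm(4 * 32 * 3), dim = c(4, 32, 3)),
                           fps = 30, joint_set = "raw32",
                           participant_id = "P1", sequence_id = "S1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_skeleton_csv(seq, path)
  back <- read_skeleton_csv(path)
  expect_equal(back$coords, seq$coords, tolerance = 1e-6)
  expect_identical(back$joint_set, "raw32")
  expect_identical(back$participant_id, "P1")
  expect_equal(back$fps, 30)
})

test_that("joint graph configuration round-trips through JSON", {
  g <- joint_graph()
  path <- withr::local_tempfile(fileext = ".json")
  write_joint_graph(g, path)
  g2 <- read_joint_graph(path)
  expect_identical(g2$edges, g$edges)
  expect_identical(g2$selection_map, g$selection_map)
  expect_identical(g2$node_names, g$node_names)
})
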