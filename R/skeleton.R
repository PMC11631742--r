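# Skeleton sequences: ingestion, joint selection, per-frame trunk-length
# normalization, and the derived model-input features (velocity, bones).
#
# Coordinate convention: x = participant's left direction, y = up,
# z = camera-participant distance. A sequence is a T x J x 3 array at a
# nominal 30 fps; joint indices are 0-based everywhere in the API, matching
# the published joint numbering.

#' Construct a skeleton sequence
#'
#' @param coords Numeric T x J x 3 array (J = 32 for `raw32`, 25 for
#'   `selected25`); all values finite.
#' @param fps Frames per second (default 30).
#' @param joint_set `"raw32"` or `"selected25"`.
#' @param participant_id,sequence_id Optional identifiers.
#' @return A `skeleton_sequence` object.
#' @export
skeleton_sequence <- function(coords, fps = 30, joint_set = c("raw32", "selected25"),
                              participant_id = NA_character_,
                              sequence_id = NA_character_) {
  joint_set <- match.arg(joint_set)
  sg_assert(is.array(coords) && length(dim(coords)) == 3 && dim(coords)[3] == 3,
            "coords must be a T x J x 3 array")
  expected_j <- if (joint_set == "raw32") 32L else 25L
  if (dim(coords)[2] != expected_j) {
    sg_abort(sprintf("joint_set %s requires J = %d, got %d",
                     joint_set, expected_j, dim(coords)[2]), "sarcogait_shape_error")
  }
  sg_assert(all(is.finite(coords)), "coordinates must be finite")
  sg_assert(is.numeric(fps) && fps > 0, "fps must be positive")
  structure(list(coords = coords, fps = fps, joint_set = joint_set,
                 participant_id = participant_id, sequence_id = sequence_id),
            class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<skeleton_sequence %s: %d frames x %d joints @ %g fps (%s/%s)>\n",
              x$joint_set, d[1], d[2], x$fps, x$participant_id, x$sequence_id))
  invisible(x)
}

n_frames <- function(seq) dim(seq$coords)[1]

#' Select the 25 analysis joints from a raw 32-joint sequence
#'
#' Pure projection: retained coordinates are unchanged, output joints are in
#' the analysis order (0 = sacrum ... 24 = right thumb); T and fps preserved.
#'
#' @param seq A raw32 [skeleton_sequence()].
#' @param graph A [joint_graph()] supplying the 32 -> 25 `selection_map`.
#' @return A selected25 `skeleton_sequence`.
#' @export
select_joints <- function(seq, graph = joint_graph()) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (seq$joint_set != "raw32" || dim(seq$coords)[2] != 32) {
    sg_abort(sprintf("select_joints expects 32 joints, got %d", dim(seq$coords)[2]),
             "sarcogait_shape_error")
  }
  sg_assert(length(graph$selection_map) == graph$node_count,
            "selection_map length must equal node_count")
  out <- seq$coords[, graph$selection_map + 1L, , drop = FALSE]
  skeleton_sequence(out, fps = seq$fps, joint_set = "selected25",
                    participant_id = seq$participant_id,
                    sequence_id = seq$sequence_id)
}

#' Trunk distance of one frame
#'
#' Euclidean distance from joint 0 (sacrum) to joint 20 (shoulder center):
#' `d = sqrt((x0-x20)^2 + (y0-y20)^2 + (z0-z20)^2)`. This per-frame length is
#' the normalization denominator that removes inter-subject height variation.
#'
#' @param frame A 25 x 3 numeric matrix.
#' @param eps Degeneracy threshold: `d < eps` is a degenerate-frame error
#'   (guards against division blow-up from tracking glitches).
#' @return Positive scalar `d`.
#' @export
trunk_distance <- function(frame, eps = 1e-8) {
  sg_assert(is.matrix(frame) && nrow(frame) >= 21 && ncol(frame) == 3,
            "frame must be a J x 3 matrix with joints 0 and 20 present")
  d <- sqrt(sum((frame[1, ] - frame[21, ])^2))
  if (!is.finite(d) || d < eps) {
    sg_abort(sprintf("degenerate frame: trunk distance %.3g < eps %.3g", d, eps),
             "sarcogait_degenerate_frame")
  }
  d
}

trunk_distances <- function(seq) {
  diffs <- seq$coords[, 1, , drop = FALSE] - seq$coords[, 21, , drop = FALSE]
  sqrt(rowSums(matrix(diffs, nrow = dim(seq$coords)[1], ncol = 3)^2))
}

#' Normalize a sequence by per-frame trunk distance
#'
#' Every joint coordinate of frame t is divided by that frame's trunk
#' distance d(t) on all three axes, so the sacrum-to-shoulder-center distance
#' of every normalized frame is exactly 1 and the result is invariant to a
#' global positive rescaling of the input.
#'
#' @param seq A selected25 [skeleton_sequence()].
#' @param eps Degeneracy threshold on d.
#' @param drop_degenerate If `TRUE`, frames with `d < eps` are dropped
#'   (with a warning) instead of raising an error.
#' @return A list: `seq` (normalized sequence), `d` (per-frame distances used).
#' @export
normalize_sequence <- function(seq, eps = 1e-8, drop_degenerate = FALSE) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  sg_assert(seq$joint_set == "selected25", "normalize_sequence expects 25 joints")
  d <- trunk_distances(seq)
  bad <- !is.finite(d) | d < eps
  if (any(bad)) {
    if (!drop_degenerate) {
      sg_abort(sprintf("degenerate frames (trunk distance < %.3g) at indices: %s",
                       eps, paste(which(bad) - 1L, collapse = ", ")),
               "sarcogait_degenerate_frame")
    }
    warning(sprintf("dropping %d degenerate frame(s)", sum(bad)))
    seq$coords <- seq$coords[!bad, , , drop = FALSE]
    d <- d[!bad]
  }
  coords <- seq$coords / array(d, dim = dim(seq$coords))  # recycle along T
  out <- skeleton_sequence(coords, fps = seq$fps, joint_set = "selected25",
                           participant_id = seq$participant_id,
                           sequence_id = seq$sequence_id)
  list(seq = out, d = d)
}

#' Per-joint frame-to-frame velocity
#'
#' Backward differences in coordinate units per frame (fps deliberately not
#' folded in): `v(t, i) = coords(t, i) - coords(t-1, i)`, with `v(0, i) = 0`.
#'
#' @param seq A [skeleton_sequence()] with T >= 2.
#' @return A T x J x 3 array.
#' @export
joint_velocity <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  T <- n_frames(seq)
  sg_assert(T >= 2, "velocity requires at least 2 frames")
  v <- seq$coords
  v[2:T, , ] <- seq$coords[2:T, , , drop = FALSE] - seq$coords[1:(T - 1), , , drop = FALSE]
  v[1, , ] <- 0
  v
}

#' Bone vectors along the skeletal edges
#'
#' One vector per spatial edge per frame: child coordinate minus parent
#' coordinate, in the graph's edge order. Translation-invariant.
#'
#' @param seq A selected25 [skeleton_sequence()].
#' @param graph A [joint_graph()].
#' @return A T x n_edges x 3 array.
#' @export
bone_vectors <- function(seq, graph = joint_graph()) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  J <- dim(seq$coords)[2]
  if (any(graph$edges >= J)) {
    sg_abort("graph edge references a joint index missing from the sequence",
             "sarcogait_shape_error")
  }
  parent <- graph$edges[, 1] + 1L
  child <- graph$edges[, 2] + 1L
  seq$coords[, child, , drop = FALSE] - seq$coords[, parent, , drop = FALSE]
}

#' Resample a sequence to a fixed number of frames
#'
#' Linear interpolation along time to exactly `target_T` frames with both
#' endpoints preserved; the fps field is rescaled to the effective rate so
#' downstream duration bookkeeping stays honest.
#'
#' @param seq A [skeleton_sequence()] with T >= 2.
#' @param target_T Desired frame count (>= 2).
#' @return A `skeleton_sequence` with `target_T` frames.
#' @export
resample_sequence <- function(seq, target_T) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  T <- n_frames(seq)
  sg_assert(T >= 2, "resampling requires at least 2 frames")
  sg_assert(sg_is_count(target_T) && target_T >= 2, "target_T must be an integer >= 2")
  if (target_T == T) return(seq)
  pos <- seq.int(1, T, length.out = target_T)
  lo <- pmin(floor(pos), T - 1)
  w <- pos - lo
  co <- seq$coords
  out <- co[lo, , , drop = FALSE] * array(1 - w, dim = c(target_T, dim(co)[2], 3)) +
    co[lo + 1, , , drop = FALSE] * array(w, dim = c(target_T, dim(co)[2], 3))
  skeleton_sequence(out, fps = seq$fps * (target_T - 1) / (T - 1),
                    joint_set = seq$joint_set,
                    participant_id = seq$participant_id,
                    sequence_id = seq$sequence_id)
}

#' Read / write skeleton sequences (long-form CSV + JSON sidecar)
#'
#' Canonical on-disk format: one CSV per sequence with columns
#' `frame,joint,x,y,z` (0-based frame and joint indices) and a JSON sidecar
#' `<path>.json` holding `fps`, `joint_set`, `participant_id`, `sequence_id`.
#' Coordinates round-trip to at least 6 decimal places.
#'
#' @param path CSV file path.
#' @return `read_skeleton_csv` returns a [skeleton_sequence()].
#' @export
read_skeleton_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sg_assert(all(c("frame", "joint", "x", "y", "z") %in% names(df)),
            "skeleton CSV must have columns frame,joint,x,y,z")
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  T <- max(df$frame) + 1L
  J <- max(df$joint) + 1L
  sg_assert(nrow(df) == T * J, "skeleton CSV must contain every (frame, joint) pair")
  co <- array(NA_real_, dim = c(T, J, 3))
  idx <- cbind(df$frame + 1L, df$joint + 1L)
  co[cbind(idx, 1L)] <- df$x
  co[cbind(idx, 2L)] <- df$y
  co[cbind(idx, 3L)] <- df$z
  skeleton_sequence(co,
                    fps = meta$fps %||% 30,
                    joint_set = meta$joint_set %||% (if (J == 32) "raw32" else "selected25"),
                    participant_id = meta$participant_id %||% NA_character_,
                    sequence_id = meta$sequence_id %||% NA_character_)
}

#' @rdname read_skeleton_csv
#' @param seq A [skeleton_sequence()].
#' @param digits Decimal places written (default 7).
#' @export
write_skeleton_csv <- function(seq, path, digits = 7) {
  d <- dim(seq$coords)
  df <- data.frame(
    frame = rep(0:(d[1] - 1L), times = d[2]),
    joint = rep(0:(d[2] - 1L), each = d[1]),
    x = round(as.vector(seq$coords[, , 1]), digits),
    y = round(as.vector(seq$coords[, , 2]), digits),
    z = round(as.vector(seq$coords[, , 3]), digits)
  )
  df <- df[order(df$frame, df$joint), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fps = seq$fps, joint_set = seq$joint_set,
         participant_id = seq$participant_id, sequence_id = seq$sequence_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
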