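# Plantar-pressure series and the time-averaged 1-channel image, plus the
# training-time augmentations (horizontal mirror with p = 0.5, rotation by
# 45 degrees) and bilinear resize for model input.
#
# Images are H x W matrices, row 1 = top; the walkway axis runs along W.

#' Construct a pressure frame series
#'
#' @param frames Numeric T x H x W array of non-negative, finite pressures
#'   (arbitrary units).
#' @param spacing_m Grid spacing in meters per pixel (metadata).
#' @param participant_id,sequence_id Optional identifiers.
#' @return A `pressure_series` object.
#' @export
pressure_series <- function(frames, spacing_m = NA_real_,
                            participant_id = NA_character_,
                            sequence_id = NA_character_) {
  sg_assert(is.array(frames) && length(dim(frames)) == 3,
            "frames must be a T x H x W array")
  sg_assert(dim(frames)[1] >= 1, "series must contain at least one frame")
  sg_assert(all(is.finite(frames)), "pressures must be finite")
  if (any(frames < 0)) sg_abort("negative pressure values", "sarcogait_invalid_input")
  structure(list(frames = frames, spacing_m = spacing_m,
                 participant_id = participant_id, sequence_id = sequence_id),
            class = "pressure_series")
}

#' Construct a single-channel pressure image
#'
#' @param pixels Numeric H x W matrix of non-negative values.
#' @param label Optional class label.
#' @return A `pressure_image` object with `channel_count = 1`.
#' @export
pressure_image <- function(pixels, label = NA_character_) {
  sg_assert(is.matrix(pixels) && all(is.finite(pixels)), "pixels must be a finite matrix")
  if (any(pixels < 0)) sg_abort("negative pixel values", "sarcogait_invalid_input")
  structure(list(pixels = pixels, channel_count = 1L, label = label),
            class = "pressure_image")
}

#' Time-average a pressure series into a 1-channel image
#'
#' `pixels(h, w) = mean_t frames(t, h, w)` — the canonical average-pressure
#' representation of one walking sequence.
#'
#' @param series A [pressure_series()].
#' @return A [pressure_image()].
#' @export
average_pressure <- function(series) {
  stopifnot(inherits(series, "pressure_series"))
  d <- dim(series$frames)
  px <- colMeans(matrix(series$frames, nrow = d[1]))
  pressure_image(matrix(px, nrow = d[2], ncol = d[3]))
}

#' Horizontal mirror augmentation (p = 0.5)
#'
#' With probability 0.5 (drawn from R's RNG, so deterministic under
#' `set.seed`) returns the left-right mirror of the image, else the image
#' unchanged. Mirroring is horizontal because it maps left footprints onto
#' right ones.
#'
#' @param img A [pressure_image()].
#' @param force `NA` (random), `TRUE` (always flip), `FALSE` (never).
#' @return A [pressure_image()].
#' @export
augment_flip <- function(img, force = NA) {
  stopifnot(inherits(img, "pressure_image"))
  do_flip <- if (is.na(force)) stats::runif(1) < 0.5 else isTRUE(force)
  if (!do_flip) return(img)
  pressure_image(img$pixels[, ncol(img$pixels):1, drop = FALSE], label = img$label)
}

#' Rotate an image about its center
#'
#' Inverse-mapped bilinear interpolation about the image center; output has
#' the same H x W, out-of-frame regions are filled with 0, and values stay
#' non-negative. Multiples of 90 degrees on square images are exact lattice
#' permutations (no interpolation loss).
#'
#' @param img A [pressure_image()].
#' @param angle_deg Rotation angle in degrees (default 45, counter-clockwise).
#' @return A [pressure_image()].
#' @export
augment_rotate <- function(img, angle_deg = 45) {
  stopifnot(inherits(img, "pressure_image"))
  if (angle_deg %% 360 == 0) return(img)
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # inverse map: for each output cell, sample the input at the -angle rotation
  out_y <- rep(seq_len(h), times = w) - cy
  out_x <- rep(seq_len(w), each = h) - cx
  src_y <- cos(th) * out_y + sin(th) * out_x + cy
  src_x <- -sin(th) * out_y + cos(th) * out_x + cx
  out <- bilinear_sample(px, src_y, src_x)
  pressure_image(matrix(pmax(out, 0), h, w), label = img$label)
}

# Bilinear sampling with zero padding outside [1,h] x [1,w].
bilinear_sample <- function(px, y, x) {
  h <- nrow(px); w <- ncol(px)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  val <- function(yy, xx) {
    inside <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    v <- numeric(length(yy))
    v[inside] <- px[cbind(yy[inside], xx[inside])]
    v
  }
  v00 <- val(y0, x0); v01 <- val(y0, x0 + 1)
  v10 <- val(y0 + 1, x0); v11 <- val(y0 + 1, x0 + 1)
  v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
    v10 * fy * (1 - fx) + v11 * fy * fx
}

#' Resize a pressure image
#'
#' `method = "area"` (default) averages each output pixel over the input
#' region it covers — anti-aliased, mass-preserving up to the pixel-area
#' factor, the right choice for downscaling narrow footprints.
#' `method = "bilinear"` point-samples with endpoint alignment (used for
#' upscaling / sub-pixel geometry). Identity when the size is unchanged.
#'
#' @param img A [pressure_image()].
#' @param h,w Target size.
#' @param method `"area"` or `"bilinear"`.
#' @return A [pressure_image()].
#' @export
resize_image <- function(img, h, w, method = c("area", "bilinear")) {
  stopifnot(inherits(img, "pressure_image"))
  method <- match.arg(method)
  px <- img$pixels
  if (nrow(px) == h && ncol(px) == w) return(img)
  if (method == "area") {
    out <- box_weights(nrow(px), h) %*% px %*% t(box_weights(ncol(px), w))
    return(pressure_image(pmax(out, 0), label = img$label))
  }
  ys <- if (h == 1) (nrow(px) + 1) / 2 else seq(1, nrow(px), length.out = h)
  xs <- if (w == 1) (ncol(px) + 1) / 2 else seq(1, ncol(px), length.out = w)
  out <- bilinear_sample(px, rep(ys, times = w), rep(xs, each = h))
  pressure_image(matrix(pmax(out, 0), h, w), label = img$label)
}

# n_out x n_in row-averaging matrix: entry (i, j) is the fraction of output
# cell i's footprint covered by input cell j (rows sum to 1).
box_weights <- function(n_in, n_out) {
  wmat <- matrix(0, n_out, n_in)
  step <- n_in / n_out
  for (i in seq_len(n_out)) {
    a <- (i - 1) * step; b <- i * step
    j0 <- floor(a) + 1L; j1 <- ceiling(b)
    for (j in j0:min(j1, n_in)) {
      ov <- min(b, j) - max(a, j - 1)
      if (ov > 0) wmat[i, j] <- ov / step
    }
  }
  wmat
}

#' Training-time augmentation pipeline for a pressure image
#'
#' Applies the horizontal mirror with probability 0.5, then a rotation by an
#' angle drawn uniformly from `angles` (default {-45, 0, +45} degrees; set
#' `angles = 45` for the always-45-degree variant). Uses R's RNG; never
#' applied outside training.
#'
#' @param img A [pressure_image()].
#' @param angles Candidate rotation angles in degrees.
#' @return A [pressure_image()] of identical dimensions.
#' @export
augment_pressure <- function(img, angles = c(-45, 0, 45)) {
  img <- augment_flip(img)
  a <- if (length(angles) == 1) angles else angles[sample.int(length(angles), 1)]
  augment_rotate(img, a)
}

#' Per-image intensity normalization
#'
#' Divides by the image maximum so inputs share a [0, 1] scale; all-zero
#' images pass through unchanged.
#'
#' @param img A [pressure_image()].
#' @return A [pressure_image()].
#' @export
normalize_pressure_image <- function(img) {
  m <- max(img$pixels)
  if (m <= 0) return(img)
  pressure_image(img$pixels / m, label = img$label)
}

#' Read / write pressure data as plain text
#'
#' A series is a directory of per-frame CSVs (`frame_0000.csv`, ... each
#' H rows x W columns, no header); an image is a single CSV. A 16-bit
#' grayscale PNG copy of an image is written when the png package is
#' installed.
#'
#' @param dir Directory holding `frame_*.csv`.
#' @return `read_pressure_series` returns a [pressure_series()].
#' @export
read_pressure_series <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.csv$", full.names = TRUE))
  sg_assert(length(files) >= 1, "no frame_*.csv files found")
  mats <- lapply(files, function(f) as.matrix(utils::read.csv(f, header = FALSE)))
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  frames <- array(0, dim = c(length(mats), h, w))
  for (t in seq_along(mats)) frames[t, , ] <- mats[[t]]
  pressure_series(frames)
}

#' @rdname read_pressure_series
#' @param series A [pressure_series()].
#' @export
write_pressure_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  T <- dim(series$frames)[1]
  for (t in seq_len(T)) {
    utils::write.table(series$frames[t, , ], file.path(dir, sprintf("frame_%04d.csv", t - 1)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname read_pressure_series
#' @param img A [pressure_image()].
#' @param path CSV path; a `.png` sibling is also written if possible.
#' @export
write_pressure_image <- function(img, path) {
  utils::write.table(img$pixels, path, sep = ",", row.names = FALSE, col.names = FALSE)
  if (requireNamespace("png", quietly = TRUE)) {
    m <- max(img$pixels)
    scaled <- if (m > 0) img$pixels / m else img$pixels
    png::writePNG(scaled, sub("\\.csv$", ".png", path), dpi = NULL)
  }
  invisible(path)
}

#' @rdname read_pressure_series
#' @export
read_pressure_image <- function(path) {
  pressure_image(as.matrix(utils::read.csv(path, header = FALSE)))
}
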