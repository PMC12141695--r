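# -- small image utilities (separable Gaussian blur, 2-D median filter) ------

# replicate-padded separable Gaussian convolution
.gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m) {  # along rows (dimension 1)
    n <- nrow(m)
    padded <- rbind(m[rep(1, half), , drop = FALSE], m,
                    m[rep(n, half), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * padded[j:(j + n - 1), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(mat))))
}

# -- normalisation ------------------------------------------------------------

#' Normalise an image stack for laser drift and illumination inhomogeneity
#'
#' Works on the logarithm of the pixel intensities, where laser-power drift
#' and the static illumination profile are additive. The per-frame global
#' factor is the frame-mean log intensity (static spots contribute the same
#' offset to every frame, so they cancel from the relative drift); the
#' illumination field is the frame-averaged log image projected onto a
#' low-order 2-D polynomial surface (degree 2 by default, which represents a
#' Gaussian illumination profile exactly and is too smooth to follow
#' individual spots). Both estimates are linear projections, so applying the
#' function a second time changes nothing beyond floating-point error. The
#' overall stack mean is preserved.
#'
#' @param stack an `image_stack` or a `[frame, row, col]` array with at
#'   least 8 frames.
#' @param field_degree polynomial degree of the illumination surface
#'   (default 2).
#' @return An `image_stack` with normalised frames; the estimated
#'   illumination field (`estimated_field`) and per-frame drift factors
#'   (`estimated_drift`) are attached.
#' @export
normalize_stack <- function(stack, field_degree = 2L) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  nf <- dim(frames)[1]; nr <- dim(frames)[2]; nc <- dim(frames)[3]
  if (nf < 8) stop("normalisation needs at least 8 frames")
  for (f in seq_len(nf))
    if (all(frames[f, , ] == 0)) stop(sprintf("frame %d is all zero", f - 1))

  target_mean <- mean(frames)
  eps <- 1e-9 * max(frames)
  L <- log(pmax(frames, eps))

  # per-frame drift: frame-mean log intensity, centred
  a <- apply(L, 1, mean)
  drift_total <- exp(a - mean(a))

  # illumination: frame-averaged log image projected on a polynomial surface
  b <- apply(L, c(2, 3), mean)
  r <- (rep(seq_len(nr), nc) - (nr + 1) / 2) / nr
  c_ <- (rep(seq_len(nc), each = nr) - (nc + 1) / 2) / nc
  basis <- do.call(cbind, lapply(0:field_degree, function(i)
    sapply(0:(field_degree - i), function(j) r^i * c_^j)))
  fit <- .lm.fit(basis, as.vector(b))
  smooth_b <- as.vector(basis %*% fit$coefficients)
  field_total <- matrix(exp(smooth_b - mean(smooth_b)), nr, nc)

  for (f in seq_len(nf))
    frames[f, , ] <- frames[f, , ] / (drift_total[f] * field_total)
  frames <- frames * (target_mean / mean(frames))

  out <- if (inherits(stack, "image_stack")) stack else
    structure(list(frames = NULL, exposure_s = NA_real_, positions = NULL,
                   overlapping = NULL, drift = NULL, illumination = NULL),
              class = "image_stack")
  out$frames <- frames
  out$estimated_field <- field_total
  out$estimated_drift <- drift_total
  out
}

# -- spot detection -----------------------------------------------------------

#' Detect fluorescent spots by difference of Gaussians
#'
#' The DoG response uses `sigma_small = diameter / (2 * sqrt(2))` and
#' `sigma_large = 1.6 * sigma_small`. Local maxima above `quality_threshold`
#' are returned with sub-pixel refinement by per-axis quadratic interpolation;
#' maxima closer than `diameter` pixels to a stronger detection are
#' suppressed.
#'
#' @param frame a 2-D intensity matrix.
#' @param spot_diameter_px estimated spot diameter in pixels (default 4).
#' @param quality_threshold minimum DoG response; `NULL` uses a robust
#'   noise-calibrated default (8 robust SDs of the response).
#' @return Data frame with columns `row_px`, `col_px` (0-based, sub-pixel)
#'   and `quality`.
#' @export
detect_spots <- function(frame, spot_diameter_px = 4, quality_threshold = NULL) {
  stopifnot(is.matrix(frame))
  if (spot_diameter_px < 2) stop("spot diameter must be at least 2 px")
  s_small <- spot_diameter_px / (2 * sqrt(2))
  s_large <- 1.6 * s_small
  resp <- .gauss_blur(frame, s_small) - .gauss_blur(frame, s_large)
  if (is.null(quality_threshold))
    quality_threshold <- 8 * mad(as.vector(resp))

  n <- nrow(resp); m <- ncol(resp)
  inner_r <- 2:(n - 1); inner_c <- 2:(m - 1)
  ctr <- resp[inner_r, inner_c]
  is_max <- ctr > quality_threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (ctr >= resp[inner_r + dr, inner_c + dc])
  }
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0)
    return(data.frame(row_px = numeric(0), col_px = numeric(0),
                      quality = numeric(0)))
  rows <- hits[, 1] + 1L; cols <- hits[, 2] + 1L  # back to full-frame indices
  qual <- resp[cbind(rows, cols)]

  # non-maximum suppression at min separation = diameter (greedy by quality)
  ord <- order(-qual)
  keep <- logical(length(ord))
  kept_r <- numeric(0); kept_c <- numeric(0)
  for (i in ord) {
    if (length(kept_r) == 0 ||
        all((kept_r - rows[i])^2 + (kept_c - cols[i])^2 >= spot_diameter_px^2)) {
      keep[i] <- TRUE
      kept_r <- c(kept_r, rows[i]); kept_c <- c(kept_c, cols[i])
    }
  }
  rows <- rows[keep]; cols <- cols[keep]; qual <- qual[keep]

  # sub-pixel quadratic refinement along each axis
  refine <- function(rm1, r0, rp1) {
    den <- rm1 - 2 * r0 + rp1
    ifelse(abs(den) > .Machine$double.eps, 0.5 * (rm1 - rp1) / den, 0)
  }
  dr <- refine(resp[cbind(rows - 1, cols)], qual, resp[cbind(rows + 1, cols)])
  dc <- refine(resp[cbind(rows, cols - 1)], qual, resp[cbind(rows, cols + 1)])
  dr <- pmin(pmax(dr, -0.5), 0.5); dc <- pmin(pmax(dc, -0.5), 0.5)

  out <- data.frame(row_px = rows - 1 + dr, col_px = cols - 1 + dc,
                    quality = qual)
  out[order(-out$quality), , drop = FALSE]
}

# -- trace extraction ---------------------------------------------------------

#' Extract per-spot intensity time series from a stack
#'
#' Detections are taken on a reference frame (by default the mean of the
#' first five frames). For each spot and frame, the mean intensity over an
#' inclusive square region of interest of half-width `roi_radius_px` centred
#' on the rounded detection position is recorded. Spots whose ROI would cross
#' the image border are skipped with a message.
#'
#' @param stack an `image_stack` or `[frame, row, col]` array.
#' @param detections data frame from [detect_spots()]; `NULL` runs detection
#'   on the reference frame.
#' @param roi_radius_px ROI half-width in pixels (default 2).
#' @param reference_frames frames averaged for the reference image when
#'   `detections` is `NULL` (default first 5).
#' @param ... passed to [detect_spots()].
#' @return List with `traces` (`n_frames x n_spots` matrix), `detections`
#'   (the used subset) and `exposure_s`.
#' @export
extract_traces <- function(stack, detections = NULL, roi_radius_px = 2L,
                           reference_frames = 5L, ...) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  exposure_s <- if (inherits(stack, "image_stack")) stack$exposure_s else NA_real_
  nf <- dim(frames)[1]; nr <- dim(frames)[2]; nc <- dim(frames)[3]
  if (is.null(detections)) {
    ref <- apply(frames[seq_len(min(reference_frames, nf)), , , drop = FALSE],
                 c(2, 3), mean)
    detections <- detect_spots(ref, ...)
  }
  r <- roi_radius_px
  ctr_r <- round(detections$row_px) + 1L   # to 1-based matrix indices
  ctr_c <- round(detections$col_px) + 1L
  ok <- ctr_r - r >= 1 & ctr_r + r <= nr & ctr_c - r >= 1 & ctr_c + r <= nc
  if (any(!ok))
    message(sprintf("%d spot(s) skipped: ROI crosses the image border",
                    sum(!ok)))
  detections <- detections[ok, , drop = FALSE]
  ctr_r <- ctr_r[ok]; ctr_c <- ctr_c[ok]
  traces <- matrix(0, nf, nrow(detections))
  for (s in seq_len(nrow(detections))) {
    rs <- (ctr_r[s] - r):(ctr_r[s] + r)
    cs <- (ctr_c[s] - r):(ctr_c[s] + r)
    traces[, s] <- apply(frames[, rs, cs, drop = FALSE], 1, mean)
  }
  list(traces = traces, detections = detections, exposure_s = exposure_s)
}
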