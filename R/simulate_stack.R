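#' Render simulated traces into a synthetic TIRF image stack
#'
#' Each molecule is rendered as a symmetric 2-D Gaussian point-spread function
#' scaled by its per-frame trace value, multiplied by a per-frame global laser
#' drift factor (low-frequency sinusoid plus AR(1) noise) and by a static
#' Gaussian illumination profile centred on the field, with Poisson shot noise
#' and Gaussian read noise added.
#'
#' @param sim a `trace_sim` object from [simulate_traces()], or an
#'   `n_frames x n_molecules` intensity matrix.
#' @param dim_px image height/width in pixels, `c(rows, cols)`.
#' @param positions `n_molecules x 2` matrix of spot centres (row, col),
#'   0-based pixel coordinates with pixel centres at integers. Spots closer
#'   than `4 * psf_sigma_px` trigger a warning and are flagged.
#' @param psf_sigma_px PSF standard deviation in pixels.
#' @param drift_amplitude relative amplitude of the global laser-power drift
#'   (0 disables drift; the drift factor is `1 + drift_amplitude * s(t)` with
#'   `s` a unit-amplitude sinusoid plus AR(1) noise).
#' @param illumination_sigma_px SD of the static Gaussian illumination
#'   profile; `Inf` gives flat illumination.
#' @param shot_noise logical; add Poisson shot noise.
#' @param read_noise_sd Gaussian read noise SD (0 disables).
#' @param seed integer seed.
#' @return An object of class `image_stack`: list with `frames` (array
#'   `[frame, row, col]`), `exposure_s`, `positions` (ground truth),
#'   `overlapping` (logical per spot), `drift` (per-frame factor) and
#'   `illumination` (field matrix).
#' @export
simulate_image_stack <- function(sim, dim_px = c(64L, 64L), positions,
                                 psf_sigma_px = 1.2,
                                 drift_amplitude = 0,
                                 illumination_sigma_px = Inf,
                                 shot_noise = FALSE,
                                 read_noise_sd = 0,
                                 seed = 1L) {
  traces <- if (inherits(sim, "trace_sim")) sim$intensities else as.matrix(sim)
  exposure_s <- if (inherits(sim, "trace_sim")) sim$params$exposure_s else NA_real_
  n_frames <- nrow(traces); n_mol <- ncol(traces)
  stopifnot(nrow(positions) == n_mol, ncol(positions) == 2)
  if (any(positions[, 1] < 0 | positions[, 1] > dim_px[1] - 1 |
          positions[, 2] < 0 | positions[, 2] > dim_px[2] - 1))
    stop("spot positions must lie within the frame bounds")

  # flag spots violating the minimum separation
  overlapping <- rep(FALSE, n_mol)
  if (n_mol > 1) {
    d <- as.matrix(stats::dist(positions))
    diag(d) <- Inf
    overlapping <- apply(d < 4 * psf_sigma_px, 1, any)
    if (any(overlapping))
      warning(sprintf("%d spot(s) closer than 4*psf_sigma_px; flagged", sum(overlapping)))
  }

  set.seed(seed)
  drift <- rep(1, n_frames)
  if (drift_amplitude > 0) {
    tt <- seq_len(n_frames)
    ar <- stats::filter(rnorm(n_frames, 0, 0.3), 0.95, method = "recursive")
    s <- sin(2 * pi * tt / (n_frames / 2)) + as.numeric(ar) * 0.2
    drift <- 1 + drift_amplitude * s / max(abs(s))
  }

  rows <- 0:(dim_px[1] - 1); cols <- 0:(dim_px[2] - 1)
  illum <- matrix(1, dim_px[1], dim_px[2])
  if (is.finite(illumination_sigma_px)) {
    cr <- (dim_px[1] - 1) / 2; cc <- (dim_px[2] - 1) / 2
    illum <- exp(-outer((rows - cr)^2, (cols - cc)^2, "+") /
                   (2 * illumination_sigma_px^2))
  }

  # per-spot PSF footprints (normalised to unit peak)
  psfs <- lapply(seq_len(n_mol), function(m) {
    pr <- exp(-(rows - positions[m, 1])^2 / (2 * psf_sigma_px^2))
    pc <- exp(-(cols - positions[m, 2])^2 / (2 * psf_sigma_px^2))
    outer(pr, pc)
  })

  frames <- array(0, dim = c(n_frames, dim_px[1], dim_px[2]))
  for (f in seq_len(n_frames)) {
    img <- matrix(0, dim_px[1], dim_px[2])
    for (m in seq_len(n_mol)) img <- img + traces[f, m] * psfs[[m]]
    img <- img * drift[f] * illum
    if (shot_noise) img <- matrix(rpois(length(img), pmax(img, 0)),
                                  dim_px[1], dim_px[2])
    if (read_noise_sd > 0) img <- img + rnorm(length(img), 0, read_noise_sd)
    frames[f, , ] <- img
  }

  structure(list(frames = frames, exposure_s = exposure_s,
                 positions = positions, overlapping = overlapping,
                 drift = drift, illumination = illum),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image stack: %d frames of %d x %d px, %d ground-truth spot(s)\n",
              d[1], d[2], d[3], nrow(x$positions)))
  invisible(x)
}

#' Write an image stack as multi-page 16-bit TIFF
#'
#' Intensities are scaled into the 16-bit range by `scale` (counts per unit).
#'
#' @param stack an `image_stack` object or a `[frame, row, col]` array.
#' @param path output TIFF path.
#' @param scale divisor mapping intensities to `[0, 1]` before 16-bit
#'   quantisation; defaults to the stack maximum.
#' @export
write_stack_tiff <- function(stack, path, scale = NULL) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  if (is.null(scale)) scale <- max(frames)
  pages <- lapply(seq_len(dim(frames)[1]), function(f)
    pmin(pmax(frames[f, , ] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param exposure_s exposure time to attach on read.
#' @return `read_stack_tiff` returns an `image_stack` (without ground truth).
#' @export
read_stack_tiff <- function(path, exposure_s = NA_real_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) frames[f, , ] <- pages[[f]]
  structure(list(frames = frames, exposure_s = exposure_s,
                 positions = NULL, overlapping = NULL,
                 drift = NULL, illumination = NULL),
            class = "image_stack")
}
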