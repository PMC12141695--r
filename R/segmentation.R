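#' Segment a trace into piecewise-constant intensity levels
#'
#' Exact change-point segmentation by optimal partitioning: minimises the
#' summed squared deviation of each frame from its segment mean, scaled by a
#' robust noise variance, plus a penalty `beta` per breakpoint. The noise
#' scale is estimated as the median absolute deviation of the first
#' differences divided by sqrt(2) (differencing removes the piecewise-constant
#' signal); the default penalty `beta = 2 * log(n)` is the BIC-style cost of
#' an extra breakpoint. The dynamic program is exact and deterministic.
#'
#' @param trace numeric intensity vector.
#' @param beta breakpoint penalty; default `2 * log(length(trace))`.
#' @param min_seg_len minimum segment length in frames (default 1).
#' @param sigma robust per-frame noise SD; estimated from the trace when
#'   `NULL`.
#' @return An object of class `trace_segmentation`: list with `breakpoints`
#'   (0-based frame indices at which a new segment starts), `segments`
#'   (data frame: `start`, `end` half-open, `mean`, `sd`, `length`), the
#'   noise scale `sigma` used, and the input `trace`.
#' @examples
#' x <- c(rnorm(50, 0), rnorm(50, 8), rnorm(50, 0))
#' segment_trace(x)$breakpoints
#' @export
segment_trace <- function(trace, beta = NULL, min_seg_len = 1L, sigma = NULL) {
  x <- as.numeric(trace)
  n <- length(x)
  if (n < 2) stop("trace too short to segment")
  if (any(!is.finite(x))) stop("trace contains non-finite values")
  if (is.null(beta)) beta <- 2 * log(n)
  if (is.null(sigma)) sigma <- mad(diff(x)) / sqrt(2)
  if (sigma <= 0) sigma <- max(sd(x) * 1e-8, .Machine$double.eps)
  bp <- segment_dp_cpp(x, sigma^2, beta, as.integer(min_seg_len))
  starts <- c(0L, bp)
  ends <- c(bp, n)
  segs <- data.frame(
    start = starts, end = ends, length = ends - starts,
    mean = vapply(seq_along(starts),
                  function(k) mean(x[(starts[k] + 1):ends[k]]), 0),
    sd = vapply(seq_along(starts),
                function(k) sd(x[(starts[k] + 1):ends[k]]), 0)
  )
  segs$sd[is.na(segs$sd)] <- 0
  structure(list(breakpoints = as.integer(bp), segments = segs,
                 sigma = sigma, beta = beta, trace = x),
            class = "trace_segmentation")
}

#' @export
print.trace_segmentation <- function(x, ...) {
  cat(sprintf("Trace segmentation: %d frames, %d breakpoint(s)\n",
              length(x$trace), length(x$breakpoints)))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Background statistics from the lowest-intensity segment
#'
#' The segment with the lowest mean is taken to be the photobleached
#' background state; ties on the mean are broken in favour of the longer
#' segment. Returns the mean and SD over all frames assigned to that segment.
#'
#' Because the photobleached state occupies a sustained stretch at the end of
#' a trace, candidate segments shorter than `min_len` frames (isolated
#' low-intensity outliers, whose SD is meaningless) are ignored unless no
#' longer segment exists.
#'
#' @param segmentation a `trace_segmentation` from [segment_trace()].
#' @param min_len minimum background-segment length in frames (default 15,
#'   matching the event-calling temporal window).
#' @return List with `mu_bg`, `sigma_bg` and `segment` (its row index).
#' @export
background_stats <- function(segmentation, min_len = 15L) {
  stopifnot(inherits(segmentation, "trace_segmentation"))
  segs <- segmentation$segments
  eligible <- which(segs$length >= min_len)
  if (length(eligible) == 0) eligible <- seq_len(nrow(segs))
  # order by mean then by decreasing length so ties pick the longer segment
  k <- eligible[order(segs$mean[eligible], -segs$length[eligible])[1]]
  frames <- (segs$start[k] + 1):segs$end[k]
  vals <- segmentation$trace[frames]
  list(mu_bg = mean(vals), sigma_bg = if (length(vals) > 1) sd(vals) else 0,
       segment = k)
}
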