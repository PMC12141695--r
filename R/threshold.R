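#' Calibrate the on-state intensity threshold over a trace population
#'
#' Explores candidate multiples `k` of the background SD. For each trace the
#' background segment is located by [segment_trace()] / [background_stats()],
#' and the per-trace misdetection fraction at a candidate `k` is the fraction
#' of background-segment frames exceeding `mu_bg + k * sigma_bg`. A trace
#' "fails" at `k` when its misdetection fraction exceeds `per_trace_limit`;
#' the population misdetection fraction is the fraction of failing traces.
#' The calibration returns the smallest candidate whose population fraction
#' is at most `population_limit`, together with the full exploration table.
#'
#' @param traces list of numeric vectors, or a `frames x molecules` matrix,
#'   or a `trace_sim` object.
#' @param candidate_multipliers candidate values of `k` (default `3:15`).
#' @param per_trace_limit maximum tolerated per-trace misdetection fraction
#'   (default 0.001).
#' @param population_limit maximum tolerated fraction of failing traces
#'   (default 0.02).
#' @return An object of class `threshold_calibration`: list with `k_sigma`
#'   (the selected multiplier), `table` (k, mean per-trace fraction,
#'   population fraction), and per-trace background stats.
#' @export
calibrate_threshold <- function(traces, candidate_multipliers = 3:15,
                                per_trace_limit = 0.001,
                                population_limit = 0.02) {
  tr <- .as_trace_list(traces)
  if (length(tr) < 10) stop("calibration needs at least 10 traces")
  ks <- sort(unique(as.numeric(candidate_multipliers)))
  if (any(ks <= 0)) stop("candidate multipliers must be positive")

  n_tr <- length(tr)
  frac <- matrix(0, n_tr, length(ks))
  mu <- numeric(n_tr); sg <- numeric(n_tr)
  for (m in seq_len(n_tr)) {
    seg <- segment_trace(tr[[m]])
    bg <- background_stats(seg)
    mu[m] <- bg$mu_bg; sg[m] <- bg$sigma_bg
    segs <- seg$segments
    k_bg <- bg$segment
    vals <- seg$trace[(segs$start[k_bg] + 1):segs$end[k_bg]]
    for (j in seq_along(ks))
      frac[m, j] <- mean(vals > mu[m] + ks[j] * sg[m])
  }
  pop <- colMeans(frac > per_trace_limit)
  tab <- data.frame(k_sigma = ks,
                    mean_trace_fraction = colMeans(frac),
                    population_fraction = pop)
  ok <- which(pop <= population_limit)
  if (length(ok) == 0) {
    msg <- paste(utils::capture.output(print(tab, row.names = FALSE)),
                 collapse = "\n")
    stop("no candidate multiplier meets the misdetection limits:\n", msg)
  }
  structure(list(k_sigma = ks[min(ok)], table = tab,
                 mu_bg = mu, sigma_bg = sg,
                 per_trace_limit = per_trace_limit,
                 population_limit = population_limit),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "Threshold calibration over %d traces: selected k = %g SD above background\n",
    length(x$mu_bg), x$k_sigma))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# normalise the accepted trace containers to a list of numeric vectors
.as_trace_list <- function(traces) {
  if (inherits(traces, "trace_sim"))
    return(lapply(seq_len(ncol(traces$intensities)),
                  function(m) traces$intensities[, m]))
  if (is.matrix(traces))
    return(lapply(seq_len(ncol(traces)), function(m) traces[, m]))
  if (is.numeric(traces)) return(list(traces))
  as.list(traces)
}
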