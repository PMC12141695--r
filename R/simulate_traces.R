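#' Simulation parameters for synthetic single-molecule traces
#'
#' Bundles the acquisition and photophysics parameters of the two-state
#' blinking / irreversible-bleaching trace simulator. Defaults mirror a
#' typical single-FP TIRF acquisition: 0.06 s exposure, 1600 frames (96 s).
#'
#' @param n_molecules number of molecules (traces) to simulate.
#' @param n_frames frames per trace (default 1600).
#' @param exposure_s frame exposure time in seconds (default 0.06).
#' @param tau_bleach_s mean photobleaching time in seconds; bleach times are
#'   drawn from an exponential with this mean. `Inf` disables bleaching.
#' @param k_on_per_s off-to-on switching rate (per second).
#' @param k_off_per_s on-to-off switching rate (per second); 0 disables
#'   blinking (molecule stays on until it bleaches).
#' @param i_on on-state intensity amplitude above background (arbitrary units).
#' @param mu_bg,sigma_bg background mean and standard deviation.
#' @param sigma_on on-state noise standard deviation.
#' @param seed integer seed; identical seeds give identical output.
#'
#' @return An object of class `trace_sim_params`.
#' @export
trace_sim_params <- function(n_molecules,
                             n_frames = 1600L,
                             exposure_s = 0.06,
                             tau_bleach_s = 21.5,
                             k_on_per_s = 0.5,
                             k_off_per_s = 0.2,
                             i_on = 100,
                             mu_bg = 100,
                             sigma_bg = 5,
                             sigma_on = 10,
                             seed = 1L) {
  stopifnot(n_molecules >= 1, n_frames >= 2, exposure_s > 0)
  if (tau_bleach_s <= 0) stop("tau_bleach_s must be strictly positive")
  if (k_on_per_s < 0 || k_off_per_s < 0)
    stop("switching rates must be non-negative")
  if (sigma_bg < 0 || sigma_on < 0) stop("noise SDs must be non-negative")
  structure(list(
    n_molecules = as.integer(n_molecules), n_frames = as.integer(n_frames),
    exposure_s = exposure_s, tau_bleach_s = tau_bleach_s,
    k_on_per_s = k_on_per_s, k_off_per_s = k_off_per_s,
    i_on = i_on, mu_bg = mu_bg, sigma_bg = sigma_bg, sigma_on = sigma_on,
    seed = as.integer(seed)
  ), class = "trace_sim_params")
}

# Per-molecule RNG substreams: one draw of substream seeds from the master
# seed keeps each molecule reproducible independently of how many others are
# simulated before it.
.molecule_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate single-molecule blinking traces with irreversible photobleaching
#'
#' Each molecule bleaches at an exponential time with mean `tau_bleach_s`.
#' While unbleached it alternates between on and off states as a
#' continuous-time telegraph process (on-dwell rate `k_off_per_s`, off-dwell
#' rate `k_on_per_s`), starting in the on state at t = 0. A frame counts as
#' "on" when more than half of its exposure is spent in the on state. The
#' recorded intensity is `mu_bg` plus `i_on` for on frames, with Gaussian
#' noise of SD `sigma_on` (on frames) or `sigma_bg` (off/bleached frames).
#'
#' @param params a [trace_sim_params()] object.
#' @return An object of class `trace_sim`: a list with
#'   \describe{
#'     \item{intensities}{`n_frames x n_molecules` numeric matrix.}
#'     \item{truth}{a list with per-molecule `bleach_time_s` (continuous
#'       first-passage time), `bleach_frame` (first fully-bleached frame,
#'       0-based; equals `n_frames` when censored), `censored` (logical), and
#'       `on_intervals` (per molecule, a 2-column matrix of half-open
#'       0-based frame intervals `[start, end)`).}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' sim <- simulate_traces(trace_sim_params(5, n_frames = 200, seed = 42))
#' dim(sim$intensities)
#' @export
simulate_traces <- function(params) {
  stopifnot(inherits(params, "trace_sim_params"))
  p <- params
  seeds <- .molecule_seeds(p$seed, p$n_molecules)
  span <- p$n_frames * p$exposure_s

  intensities <- matrix(0, nrow = p$n_frames, ncol = p$n_molecules)
  bleach_time_s <- numeric(p$n_molecules)
  bleach_frame <- integer(p$n_molecules)
  censored <- logical(p$n_molecules)
  on_intervals <- vector("list", p$n_molecules)

  for (m in seq_len(p$n_molecules)) {
    set.seed(seeds[m])
    tb <- if (is.finite(p$tau_bleach_s)) rexp(1, rate = 1 / p$tau_bleach_s) else Inf
    cens <- tb >= span
    t_end <- min(tb, span)

    # telegraph switch times up to bleach (or span), starting on
    switches <- numeric(0)
    t <- 0; state_on <- TRUE
    if (p$k_off_per_s > 0 || p$k_on_per_s > 0) {
      repeat {
        rate <- if (state_on) p$k_off_per_s else p$k_on_per_s
        if (rate <= 0) break       # absorbing in current state
        t <- t + rexp(1, rate)
        if (t >= t_end) break
        switches <- c(switches, t)
        state_on <- !state_on
      }
    }

    # on-fraction of each frame: overlap of on-dwells with the frame window
    bounds <- c(0, switches, t_end)          # dwell boundaries; dwell 1 is on
    on_start <- bounds[seq(1, length(bounds) - 1, by = 2)]
    on_end <- bounds[seq(2, length(bounds), by = 2)]
    frame_lo <- (seq_len(p$n_frames) - 1) * p$exposure_s
    frame_hi <- frame_lo + p$exposure_s
    on_frac <- numeric(p$n_frames)
    for (k in seq_along(on_start)) {
      lo <- pmax(frame_lo, on_start[k]); hi <- pmin(frame_hi, on_end[k])
      ov <- pmax(0, hi - lo)
      on_frac <- on_frac + ov
    }
    on_frac <- on_frac / p$exposure_s
    frame_on <- on_frac > 0.5

    noise_sd <- ifelse(frame_on, p$sigma_on, p$sigma_bg)
    intensities[, m] <- p$mu_bg + ifelse(frame_on, p$i_on, 0) +
      rnorm(p$n_frames, 0, noise_sd)

    bleach_time_s[m] <- tb
    bleach_frame[m] <- if (cens) p$n_frames else
      as.integer(ceiling(tb / p$exposure_s))
    censored[m] <- cens
    on_intervals[[m]] <- .runs_to_intervals(frame_on)
  }

  structure(list(
    intensities = intensities,
    truth = list(bleach_time_s = bleach_time_s, bleach_frame = bleach_frame,
                 censored = censored, on_intervals = on_intervals),
    params = p
  ), class = "trace_sim")
}

# logical vector -> 2-column matrix of half-open 0-based intervals [start, end)
.runs_to_intervals <- function(on) {
  if (!any(on)) return(matrix(integer(0), ncol = 2,
                              dimnames = list(NULL, c("start", "end"))))
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' @export
print.trace_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Synthetic single-molecule traces: %d molecules x %d frames (%.2f s exposure)\n",
    p$n_molecules, p$n_frames, p$exposure_s))
  cat(sprintf("  tau_bleach = %s s, k_on = %g /s, k_off = %g /s, censored: %d\n",
              format(p$tau_bleach_s), p$k_on_per_s, p$k_off_per_s,
              sum(x$truth$censored)))
  invisible(x)
}

#' Tidy data frame of simulated traces
#'
#' @param sim a `trace_sim` object.
#' @return data frame with columns `molecule_id`, `frame` (0-based),
#'   `time_s`, `intensity`.
#' @export
traces_as_df <- function(sim) {
  stopifnot(inherits(sim, "trace_sim"))
  p <- sim$params
  data.frame(
    molecule_id = rep(seq_len(p$n_molecules), each = p$n_frames),
    frame = rep(seq_len(p$n_frames) - 1L, p$n_molecules),
    time_s = rep((seq_len(p$n_frames) - 1L) * p$exposure_s, p$n_molecules),
    intensity = as.vector(sim$intensities)
  )
}

#' Write / read tidy trace CSV
#'
#' @param sim a `trace_sim` object (or a data frame already in tidy form).
#' @param path CSV file path.
#' @export
write_traces <- function(sim, path) {
  df <- if (is.data.frame(sim)) sim else traces_as_df(sim)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @return `read_traces` returns a list of per-molecule intensity vectors with
#'   the exposure time attached as attribute `exposure_s`.
#' @export
read_traces <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("molecule_id", "frame", "time_s", "intensity") %in% names(df)))
  exposure <- if (nrow(df) >= 2) {
    t1 <- df$time_s[df$frame == 1][1]; t0 <- df$time_s[df$frame == 0][1]
    t1 - t0
  } else NA_real_
  out <- split(df$intensity[order(df$molecule_id, df$frame)],
               df$molecule_id[order(df$molecule_id, df$frame)])
  attr(out, "exposure_s") <- exposure
  out
}
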