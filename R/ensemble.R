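#' Fit a single-component exponential to a photobleaching survival curve
#'
#' The survival function `S(t) = 1 - ECDF(t)` is evaluated at each observed
#' lifetime and fitted by least squares with `S(t) = A * exp(-t / tau)`. The
#' amplitude is fixed at 1 by default (the survival curve starts at 1);
#' `free_amplitude = TRUE` frees it. The half-life is `tau * ln 2`.
#'
#' @param bleach_lifetimes numeric vector of per-molecule photobleaching
#'   lifetimes (seconds), or a list of `event_set` objects.
#' @param free_amplitude free the amplitude `A` (default fixed at 1).
#' @param include_empty include zero-lifetime molecules (traces with no
#'   called events); excluded by default.
#' @return Object of class `survival_fit` with components `tau_s`,
#'   `half_life_s`, `amplitude`, `n`, `rss`, `r_squared`, and the fitted
#'   curve (`time_s`, `survival`, `fitted`).
#' @examples
#' lt <- rexp(500, 1 / 12)
#' fit <- survival_fit(lt)
#' coef(fit)
#' @export
survival_fit <- function(bleach_lifetimes, free_amplitude = FALSE,
                         include_empty = FALSE) {
  lt <- .as_lifetimes(bleach_lifetimes)
  if (!include_empty) lt <- lt[lt > 0]
  if (length(lt) < 30) stop("survival fit needs at least 30 lifetimes")
  if (any(lt < 0)) stop("lifetimes must be non-negative")
  if (diff(range(lt)) == 0) stop("degenerate input: all lifetimes equal")

  tt <- sort(lt)
  surv <- 1 - ecdf(lt)(tt)

  tau0 <- mean(lt)
  if (free_amplitude) {
    fit <- minpack.lm::nlsLM(surv ~ A * exp(-tt / tau),
                             start = list(A = 1, tau = tau0),
                             lower = c(1e-6, 1e-9))
    A <- coef(fit)[["A"]]; tau <- coef(fit)[["tau"]]
  } else {
    fit <- minpack.lm::nlsLM(surv ~ exp(-tt / tau),
                             start = list(tau = tau0), lower = 1e-9)
    A <- 1; tau <- coef(fit)[["tau"]]
  }
  fitted_vals <- A * exp(-tt / tau)
  rss <- sum((surv - fitted_vals)^2)
  tss <- sum((surv - mean(surv))^2)
  structure(list(tau_s = tau, half_life_s = tau * log(2), amplitude = A,
                 n = length(lt), rss = rss, r_squared = 1 - rss / tss,
                 time_s = tt, survival = surv, fitted = fitted_vals),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential survival fit (n = %d): tau = %.3g s, half-life = %.3g s (R^2 = %.4f)\n",
    x$n, x$tau_s, x$half_life_s, x$r_squared))
  invisible(x)
}

#' @export
coef.survival_fit <- function(object, ...) {
  c(tau_s = object$tau_s, half_life_s = object$half_life_s,
    amplitude = object$amplitude)
}

#' @export
predict.survival_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time_s else
    if (is.list(newdata)) newdata$time_s else newdata
  object$amplitude * exp(-t / object$tau_s)
}

#' On-time distribution: histogram and log-normal fit
#'
#' Bins the cumulative on-times at `bin_width_s` (density-normalised) and
#' fits a log-normal by maximum likelihood on the unbinned values. Reports
#' both the mode `exp(mu - sigma^2)` (the peak of the fitted density) and the
#' mean `exp(mu + sigma^2 / 2)`.
#'
#' @param cumulative_on_times numeric vector of per-molecule cumulative
#'   on-times (seconds), or a list of `event_set` objects. Non-positive
#'   values are excluded (their count is reported).
#' @param bin_width_s histogram bin width in seconds (default 1.2).
#' @return Object of class `on_time_fit` with `lognormal_mu`,
#'   `lognormal_sigma`, `mode_s`, `mean_s`, `histogram` (data frame `mid`,
#'   `density`), `n`, `n_excluded`.
#' @export
on_time_distribution <- function(cumulative_on_times, bin_width_s = 1.2) {
  ot <- .as_on_times(cumulative_on_times)
  n_excl <- sum(ot <= 0)
  if (n_excl > 0)
    message(sprintf("%d non-positive on-time(s) excluded", n_excl))
  ot <- ot[ot > 0]
  if (length(ot) < 30) stop("on-time fit needs at least 30 positive values")

  fit <- MASS::fitdistr(ot, "lognormal")
  mu <- fit$estimate[["meanlog"]]; sg <- fit$estimate[["sdlog"]]

  breaks <- seq(0, max(ot) + bin_width_s, by = bin_width_s)
  h <- hist(ot, breaks = breaks, plot = FALSE)
  structure(list(lognormal_mu = mu, lognormal_sigma = sg,
                 mode_s = exp(mu - sg^2), mean_s = exp(mu + sg^2 / 2),
                 histogram = data.frame(mid = h$mids, density = h$density),
                 bin_width_s = bin_width_s,
                 n = length(ot), n_excluded = n_excl),
            class = "on_time_fit")
}

#' @export
print.on_time_fit <- function(x, ...) {
  cat(sprintf(
    "Log-normal on-time fit (n = %d): mu = %.3f, sigma = %.3f; mode = %.3g s, mean = %.3g s\n",
    x$n, x$lognormal_mu, x$lognormal_sigma, x$mode_s, x$mean_s))
  invisible(x)
}

#' @export
coef.on_time_fit <- function(object, ...) {
  c(meanlog = object$lognormal_mu, sdlog = object$lognormal_sigma,
    mode_s = object$mode_s, mean_s = object$mean_s)
}

#' Fraction of molecules fluorescing longer than a threshold
#'
#' @param bleach_lifetimes lifetimes in seconds (or list of `event_set`s).
#' @param threshold_s threshold in seconds; the fraction counts lifetimes
#'   strictly greater than it.
#' @return Numeric fraction in `[0, 1]`.
#' @export
fraction_longer_than <- function(bleach_lifetimes, threshold_s) {
  lt <- .as_lifetimes(bleach_lifetimes)
  if (length(lt) < 1) stop("need at least one lifetime")
  mean(lt > threshold_s)
}

#' Population summary of a set of event sets
#'
#' Combines the survival fit, the on-time log-normal fit and tail fractions
#' into one summary, the per-population equivalent of a photostability
#' comparison figure.
#'
#' @param event_sets list of `event_set` objects from [call_events_all()].
#' @param bin_width_s on-time histogram bin width (default 1.2 s).
#' @param thresholds_s thresholds for tail fractions (default 25 s).
#' @param include_empty include zero-lifetime traces in the survival fit.
#' @return Object of class `ensemble_summary`.
#' @export
ensemble_summary <- function(event_sets, bin_width_s = 1.2,
                             thresholds_s = 25, include_empty = FALSE) {
  lt <- .as_lifetimes(event_sets)
  surv <- survival_fit(lt, include_empty = include_empty)
  ot <- on_time_distribution(.as_on_times(event_sets), bin_width_s)
  fr <- vapply(thresholds_s, function(T)
    fraction_longer_than(lt[lt > 0 | include_empty], T), 0)
  stopifnot(isTRUE(all.equal(surv$half_life_s, surv$tau_s * log(2))))
  structure(list(n_traces = length(lt), survival = surv, on_times = ot,
                 tau_s = surv$tau_s, half_life_s = surv$half_life_s,
                 frac_longer = setNames(fr, paste0(">", thresholds_s, "s"))),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble summary over %d traces\n", x$n_traces))
  print(x$survival)
  print(x$on_times)
  cat("Tail fractions:", paste(names(x$frac_longer),
                               sprintf("%.3f", x$frac_longer)), "\n")
  invisible(x)
}

.as_lifetimes <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(x, function(e) e$bleach_lifetime_s, 0)
}

.as_on_times <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(x, function(e) e$cumulative_on_s, 0)
}
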