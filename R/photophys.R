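#' Fluorescent-protein brightness
#'
#' Brightness is the product of the molar extinction coefficient and the
#' fluorescence quantum yield, reported to one decimal place by convention.
#'
#' @param epsilon_mM_cm molar extinction coefficient (mM^-1 cm^-1).
#' @param qy fluorescence quantum yield in (0, 1].
#' @param digits reporting precision (default 1 dp); `NULL` for full
#'   precision.
#' @return Brightness in mM^-1 cm^-1.
#' @examples
#' brightness(61.4, 0.92)  # 56.5
#' @export
brightness <- function(epsilon_mM_cm, qy, digits = 1) {
  if (any(epsilon_mM_cm <= 0) || any(qy <= 0)) stop("inputs must be positive")
  if (any(qy > 1)) stop("quantum yield cannot exceed 1")
  b <- epsilon_mM_cm * qy
  if (is.null(digits)) b else round(b, digits)
}

#' Stokes shift
#'
#' @param lambda_em_nm emission maximum (nm).
#' @param lambda_max_nm excitation/absorbance maximum (nm).
#' @return Shift in nm (non-negative).
#' @examples
#' stokes_shift(511, 492)  # 19
#' @export
stokes_shift <- function(lambda_em_nm, lambda_max_nm) {
  if (any(lambda_em_nm < lambda_max_nm))
    stop("emission maximum must not precede the excitation maximum")
  lambda_em_nm - lambda_max_nm
}

#' Relative photobleaching resistance
#'
#' Ratio of half-lives relative to a reference protein (reference = 1),
#' reported to one decimal place.
#'
#' @param half_life half-life of the protein of interest.
#' @param half_life_ref half-life of the reference (same units).
#' @param digits reporting precision (default 1 dp); `NULL` for full.
#' @examples
#' relative_resistance(15.0, 8.3)  # 1.8
#' @export
relative_resistance <- function(half_life, half_life_ref, digits = 1) {
  if (any(half_life <= 0) || any(half_life_ref <= 0))
    stop("half-lives must be positive")
  r <- half_life / half_life_ref
  if (is.null(digits)) r else round(r, digits)
}

#' One-phase exponential decay fit
#'
#' Fits `F(t) = Fmin + (F0 - Fmin) * exp(-k * t)` by nonlinear least squares,
#' where `F0` is the signal at time zero and `Fmin` the plateau approached as
#' t grows (the standard one-phase decay parametrisation). Initial values:
#' `F0` from the first point, `Fmin` from the last, and `k` from a log-linear
#' regression on `signal - Fmin`. Used for photobleaching decays (in vitro
#' and in-cell) and fluorescence-lifetime decays.
#'
#' @param time_s time points (any consistent unit; reported rates are per
#'   that unit).
#' @param signal fluorescence signal.
#' @return Object of class `decay_fit` with `F0`, `Fmin`, `k`, `tau`
#'   (`1/k`), `half_life` (`ln 2 / k`), `rss` and the data.
#' @examples
#' t <- seq(0, 600, by = 5)
#' y <- 0 + (1 - 0) * exp(-t / 297)   # F0 = 1 decaying towards Fmin = 0
#' one_phase_decay_fit(t, y)$half_life  # ~206
#' @export
one_phase_decay_fit <- function(time_s, signal) {
  stopifnot(length(time_s) == length(signal))
  ok <- is.finite(time_s) & is.finite(signal)
  tt <- time_s[ok]; y <- signal[ok]   # avoid masking base::t inside nls
  if (length(tt) < 5) stop("decay fit needs at least 5 points")
  F0_0 <- y[which.min(tt)]
  Fmin_0 <- y[which.max(tt)]
  amp <- F0_0 - Fmin_0
  if (abs(amp) < 1e-12 * max(abs(y), 1) || sd(y) == 0)
    stop("signal shows no decay (k -> 0); cannot fit")
  # log-linear initial rate; guard points at/below the plateau
  z <- (y - Fmin_0) / amp
  use <- z > 1e-6
  k0 <- if (sum(use) >= 2) {
    sl <- coef(lm(log(z[use]) ~ tt[use]))[2]
    max(-sl, 1e-8)
  } else 1 / max(diff(range(tt)), 1)
  # Levenberg-Marquardt on the residuals directly; the degenerate-Jacobian
  # checks of the nls object builder reject perfectly converged noiseless
  # fits (Fmin exactly on the data), so the optimiser is used standalone
  resid_fn <- function(par) y - (par[2] + (par[1] - par[2]) * exp(-par[3] * tt))
  fit <- minpack.lm::nls.lm(
    par = c(F0 = F0_0, Fmin = Fmin_0, k = k0), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 9))
    stop("decay fit failed to converge: ", fit$message)
  cf <- fit$par
  if (cf[["k"]] <= 0) stop("fitted rate is non-positive (degenerate decay)")
  structure(list(F0 = cf[["F0"]], Fmin = cf[["Fmin"]], k = cf[["k"]],
                 tau = 1 / cf[["k"]], half_life = log(2) / cf[["k"]],
                 rss = sum(fit$fvec^2),
                 time = tt, signal = y, fitted = y - fit$fvec),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "One-phase decay: F0 = %.4g, Fmin = %.4g, k = %.4g; tau = %.4g, half-life = %.4g\n",
    x$F0, x$Fmin, x$k, x$tau, x$half_life))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...)
  c(F0 = object$F0, Fmin = object$Fmin, k = object$k)

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time else
    if (is.list(newdata)) newdata$time else newdata
  object$Fmin + (object$F0 - object$Fmin) * exp(-object$k * t)
}

#' pKa fit from a pH titration of absorbance
#'
#' Fits `A(pH) = A_min + (A_max - A_min) / (1 + 10^(n * (pKa - pH)))`, a
#' Henderson--Hasselbalch curve with a free Hill coefficient `n`
#' (initialised at 1).
#'
#' @param pH pH values spanning the transition (at least 6 points).
#' @param absorbance absorbance at the band maximum.
#' @param fix_hill fit with the Hill coefficient fixed at 1.
#' @return Object of class `pka_fit` with `pKa`, `hill_n`, `A_min`, `A_max`.
#' @export
pka_fit <- function(pH, absorbance, fix_hill = FALSE) {
  stopifnot(length(pH) == length(absorbance))
  if (length(pH) < 6) stop("pKa fit needs at least 6 pH points")
  if (sd(absorbance) < 1e-12 * max(abs(absorbance), 1))
    stop("no transition in the sampled pH range (flat absorbance)")
  A_min0 <- min(absorbance); A_max0 <- max(absorbance)
  pka0 <- pH[which.min(abs(absorbance - (A_min0 + A_max0) / 2))]
  # a decreasing titration is fitted with a negative Hill slope rather than
  # swapped plateaus, keeping the sign of n interpretable
  n0 <- if (cor(pH, absorbance) >= 0) 1 else -1
  fit <- tryCatch({
    if (fix_hill)
      minpack.lm::nlsLM(
        absorbance ~ A_min + (A_max - A_min) / (1 + 10^(pKa - pH)),
        start = list(A_min = A_min0, A_max = A_max0, pKa = pka0))
    else
      minpack.lm::nlsLM(
        absorbance ~ A_min + (A_max - A_min) / (1 + 10^(n * (pKa - pH))),
        start = list(A_min = A_min0, A_max = A_max0, pKa = pka0, n = n0))
  }, error = function(e) stop("pKa fit failed: ", conditionMessage(e)))
  cf <- coef(fit)
  structure(list(pKa = cf[["pKa"]],
                 hill_n = if (fix_hill) 1 else cf[["n"]],
                 A_min = cf[["A_min"]], A_max = cf[["A_max"]],
                 rss = sum(residuals(fit)^2), pH = pH,
                 absorbance = absorbance, fitted = fitted(fit)),
            class = "pka_fit")
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("Titration fit: pKa = %.3f, Hill n = %.3f (A: %.3g to %.3g)\n",
              x$pKa, x$hill_n, x$A_min, x$A_max))
  invisible(x)
}

#' @export
coef.pka_fit <- function(object, ...)
  c(pKa = object$pKa, hill_n = object$hill_n,
    A_min = object$A_min, A_max = object$A_max)

#' Chromophore maturation fit
#'
#' Fits `F(t) = f_max * (1 - exp(-k t))` to a fluorescence-recovery time
#' course, with `f_max` measured independently (the dark-matured end point).
#' The maturation half-time is `ln 2 / k`. Because absolute maturation
#' half-times depend on the protocol, a standardised half-time is also
#' returned: `halftime * (13.6 / reference_halftime_min)`, anchoring a
#' jointly measured sfGFP reference to its literature value of 13.6 min.
#'
#' @param time_min time in minutes.
#' @param fluorescence fluorescence signal.
#' @param f_max final (fully matured) fluorescence; must exceed 80% of the
#'   observed maximum.
#' @param reference_halftime_min measured half-time of the sfGFP reference
#'   under the same protocol (minutes); `NULL` skips standardisation.
#' @param sfgfp_literature_halftime_min literature anchor (default 13.6).
#' @return Object of class `maturation_fit` with `k`, `halftime_min`,
#'   `standardized_halftime_min`.
#' @export
maturation_fit <- function(time_min, fluorescence, f_max,
                           reference_halftime_min = NULL,
                           sfgfp_literature_halftime_min = 13.6) {
  stopifnot(length(time_min) == length(fluorescence))
  if (length(unique(time_min)) < 3)
    stop("maturation fit needs at least 3 distinct time points")
  if (f_max <= max(fluorescence) * 0.8)
    stop("f_max must exceed 80% of the observed maximum fluorescence")
  z <- 1 - fluorescence / f_max
  use <- z > 1e-6 & time_min > 0
  k0 <- if (sum(use) >= 2) max(-coef(lm(log(z[use]) ~ time_min[use]))[2], 1e-6)
        else 0.05
  fit <- minpack.lm::nlsLM(fluorescence ~ f_max * (1 - exp(-k * time_min)),
                           start = list(k = k0), lower = 1e-9)
  k <- coef(fit)[["k"]]
  if (k <= 0) stop("fitted maturation rate is non-positive")
  halftime <- log(2) / k
  standardized <- if (is.null(reference_halftime_min)) NA_real_ else
    halftime * (sfgfp_literature_halftime_min / reference_halftime_min)
  structure(list(k = k, halftime_min = halftime,
                 standardized_halftime_min = standardized,
                 rss = sum(residuals(fit)^2),
                 time = time_min, fluorescence = fluorescence,
                 fitted = fitted(fit)),
            class = "maturation_fit")
}

#' @export
print.maturation_fit <- function(x, ...) {
  cat(sprintf("Maturation fit: k = %.4g /min, half-time = %.3g min", x$k,
              x$halftime_min))
  if (!is.na(x$standardized_halftime_min))
    cat(sprintf(" (standardised: %.3g min)", x$standardized_halftime_min))
  cat("\n")
  invisible(x)
}

#' Assemble a photophysics record for one protein
#'
#' Bundles the measured spectral scalars and checks the derived-quantity
#' invariants (brightness = epsilon * QY; Stokes shift = emission -
#' excitation maximum).
#'
#' @param lambda_max_nm,lambda_em_nm excitation and emission maxima (nm).
#' @param epsilon_mM_cm molar extinction coefficient.
#' @param qy quantum yield.
#' @param pKa,hill_n titration parameters (optional).
#' @param decay a `decay_fit` (optional).
#' @param maturation a `maturation_fit` (optional).
#' @return Object of class `photophys_record`.
#' @export
photophys_record <- function(lambda_max_nm, lambda_em_nm, epsilon_mM_cm, qy,
                             pKa = NA_real_, hill_n = NA_real_,
                             decay = NULL, maturation = NULL) {
  structure(list(
    lambda_max_nm = lambda_max_nm, lambda_em_nm = lambda_em_nm,
    epsilon_mM_cm = epsilon_mM_cm, qy = qy,
    brightness_mM_cm = brightness(epsilon_mM_cm, qy),
    stokes_nm = stokes_shift(lambda_em_nm, lambda_max_nm),
    pKa = pKa, hill_n = hill_n, decay = decay, maturation = maturation
  ), class = "photophys_record")
}

#' @export
print.photophys_record <- function(x, ...) {
  cat(sprintf(
    "Photophysics: lambda_max %g nm, lambda_em %g nm, eps %.1f, QY %.2f -> brightness %.1f, Stokes %g nm\n",
    x$lambda_max_nm, x$lambda_em_nm, x$epsilon_mM_cm, x$qy,
    x$brightness_mM_cm, x$stokes_nm))
  invisible(x)
}
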