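## Time-correlation analysis: DLS cumulant and two-mode stretched-exponential
## fits, diffusion conversions, Kd regression, NSE initial-slope analysis.
##
## Measured intensity correlations are related to the field correlation by
## the Siegert relation g2 = b + a g1^2; all fit models below are written
## for g1 and squared, so the contrast a and baseline b are fitted in the
## same weighted least-squares step as the physical parameters.

#' DLS correlogram container
#'
#' @param lag Lag times in microseconds, strictly increasing.
#' @param g2 Intensity correlation values.
#' @param err Per-point standard errors (> 0), e.g. from the timewise
#'   standard deviation of repeated runs.
#' @param q Scattering vector (1/nm).
#' @param temperature Temperature (K).
#' @param solvent_viscosity Solvent viscosity (mPa s).
#' @return A \code{"correlogram"} object.
#' @export
correlogram <- function(lag, g2, err, q, temperature = 298.15,
                        solvent_viscosity = 1.095) {
  if (is.unsorted(lag, strictly = TRUE)) stop("lag times must be increasing")
  if (any(err <= 0)) stop("errors must be > 0")
  stopifnot(length(lag) == length(g2), length(g2) == length(err))
  structure(list(lag = as.numeric(lag), g2 = as.numeric(g2),
                 err = as.numeric(err), q = q, temperature = temperature,
                 solvent_viscosity = solvent_viscosity),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf(
    "correlogram: %d lags [%.3g, %.3g] us, q = %.4g 1/nm, T = %.5g K\n",
    length(x$lag), min(x$lag), max(x$lag), x$q, x$temperature))
  invisible(x)
}

#' Intermediate scattering function curve (NSE)
#'
#' @param times Correlation times in ns.
#' @param isf Normalized I(q,t)/I(q,0).
#' @param err Per-point errors (> 0).
#' @param q Scattering vector.
#' @param q_unit \code{"per_nm"} or \code{"per_angstrom"}.
#' @return An \code{"isf_curve"} object; q is stored in 1/nm.
#' @export
isf_curve <- function(times, isf, err, q, q_unit = c("per_nm",
                                                     "per_angstrom")) {
  stopifnot(length(times) == length(isf), length(isf) == length(err))
  if (any(err <= 0)) stop("errors must be > 0")
  structure(list(times = as.numeric(times), isf = as.numeric(isf),
                 err = as.numeric(err),
                 q = .q_to_per_nm(q, match.arg(q_unit))),
            class = "isf_curve")
}

#' Scattering vector from geometry
#'
#' \code{q = 4 pi n sin(theta/2) / lambda}.
#'
#' @param theta Scattering angle in degrees, in (0, 180).
#' @param wavelength Vacuum wavelength in nm.
#' @param refractive_index Solvent refractive index (default 1.33).
#' @return q in 1/nm.
#' @export
scattering_vector <- function(theta, wavelength, refractive_index = 1.33) {
  if (any(theta <= 0) || any(theta >= 180)) stop("theta must be in (0, 180)")
  4 * pi * refractive_index * sin(theta * pi / 360) / wavelength
}

#' Relaxation rate to diffusion coefficient
#'
#' \code{D = rate / q^2}. With the package conventions (rate in 1/us, q in
#' 1/nm) the result is in m^2/s; SI inputs can be declared instead.
#'
#' @param rate Relaxation rate.
#' @param q Scattering vector.
#' @param rate_unit \code{"per_us"} (default) or \code{"per_s"}.
#' @param q_unit \code{"per_nm"} (default) or \code{"per_m"}.
#' @return D in m^2/s.
#' @export
rate_to_diffusion <- function(rate, q, rate_unit = c("per_us", "per_s"),
                              q_unit = c("per_nm", "per_m")) {
  rate_unit <- match.arg(rate_unit)
  q_unit <- match.arg(q_unit)
  rate_si <- if (rate_unit == "per_us") rate * 1e6 else rate
  q_si <- if (q_unit == "per_nm") q * 1e9 else q
  rate_si / q_si^2
}

#' Stokes-Einstein radius from a diffusion coefficient
#'
#' \code{Rh = kB T / (6 pi eta D)}.
#'
#' @param D Diffusion coefficient (m^2/s).
#' @param temperature Temperature (K).
#' @param viscosity Solvent viscosity (mPa s).
#' @return Hydrodynamic radius in nm.
#' @export
stokes_einstein_radius <- function(D, temperature, viscosity) {
  stopifnot(all(D > 0), all(temperature > 0), all(viscosity > 0))
  .KB * temperature / (6 * pi * viscosity * 1e-3 * D) * 1e9
}

#' Stokes-Einstein diffusion coefficient from a radius
#'
#' Inverse of [stokes_einstein_radius()]; the two round-trip exactly.
#'
#' @param radius Hydrodynamic radius (nm).
#' @param temperature Temperature (K).
#' @param viscosity Solvent viscosity (mPa s).
#' @return D in m^2/s.
#' @export
stokes_einstein_diffusion <- function(radius, temperature, viscosity) {
  stopifnot(all(radius > 0), all(temperature > 0), all(viscosity > 0))
  .KB * temperature / (6 * pi * viscosity * 1e-3 * radius * 1e-9)
}

# 5 log-spaced initial rate guesses around a crude half-decay estimate;
# fixed, deterministic multi-start for all nonlinear correlogram fits.
.rate_guesses <- function(lag, g2) {
  y <- g2 - min(g2)
  y <- y / max(y)
  t_half <- lag[which.min(abs(y - 0.4))]
  (log(2) / t_half) * 10^seq(-1, 1, length.out = 5)
}

.wfit <- function(formula, data, start, lower, upper, weights) {
  data$.w <- weights  # nls evaluates the weights expression inside `data`
  minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                    upper = upper, weights = .w,
                    control = minpack.lm::nls.lm.control(maxiter = 200))
}

#' Second-order cumulant fit
#'
#' Error-weighted least squares of
#' \code{g2(t) = b + a exp(-t/tau0 + mu t^2 / 2)^2} over \code{t <=
#' truncation_time}. The polydispersity estimate is the normalized rate
#' spread \code{sigma* = sqrt(mu) tau0}; a negative fitted second cumulant
#' is clipped to \code{sigma* = 0} and flagged.
#'
#' @param corr A [correlogram()] with lag times in us.
#' @param truncation_time Upper fit limit (us); at least 10 points below it.
#' @return A \code{"cumulant_fit"} list: \code{contrast}, \code{baseline},
#'   \code{rate} (1/us), \code{mu} (1/us^2), \code{sigma_star},
#'   \code{truncation_time}, \code{clipped}, and the underlying \code{fit}.
#' @export
cumulant_fit <- function(corr, truncation_time) {
  stopifnot(inherits(corr, "correlogram"))
  keep <- corr$lag <= truncation_time
  if (sum(keep) < 10) stop("need >= 10 points below the truncation time")
  d <- data.frame(t = corr$lag[keep], y = corr$g2[keep], w = 1 / corr$err[keep]^2)
  best <- NULL
  for (r0 in .rate_guesses(d$t, d$y)) {
    for (s0 in c(0.05, 0.25, 0.35)) {  # sigma* starts against mu local minima
      fit <- tryCatch(
        .wfit(y ~ b + a * exp(2 * (-r * t + mu * t^2 / 2)), d,
              start = list(a = max(d$y) - 1, b = 1, r = r0,
                           mu = (s0 * r0)^2),
              lower = c(a = 1e-4, b = 0.98, r = 1e-12, mu = -Inf),
              upper = c(a = 1.3, b = 1.05, r = Inf, mu = Inf),
              weights = d$w),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || deviance(fit) < deviance(best))) best <- fit
    }
  }
  if (is.null(best)) stop("cumulant fit did not converge")
  p <- stats::coef(best)
  clipped <- p[["mu"]] < 0
  sigma_star <- if (clipped) 0 else sqrt(p[["mu"]]) / p[["r"]]
  structure(list(contrast = p[["a"]], baseline = p[["b"]], rate = p[["r"]],
                 mu = p[["mu"]], sigma_star = sigma_star,
                 truncation_time = truncation_time, clipped = clipped,
                 fit = best),
            class = "cumulant_fit")
}

#' @export
print.cumulant_fit <- function(x, ...) {
  cat(sprintf(
    "cumulant fit: rate = %.4g 1/us, sigma* = %.3f, a = %.3f, b = %.4f%s\n",
    x$rate, x$sigma_star, x$contrast, x$baseline,
    if (x$clipped) " (mu < 0 clipped)" else ""))
  invisible(x)
}

#' Truncation-time sensitivity scan
#'
#' Repeats [cumulant_fit()] for a ladder of truncation times and locates the
#' plateau: truncation times t for which \code{sigma*} varies by less than
#' \code{plateau_tol} over the scanned range \code{[t, 2t]}.
#'
#' @param corr A [correlogram()].
#' @param times At least three truncation times (us).
#' @param plateau_tol Relative variation defining the plateau (default 0.1).
#' @return Data frame with one row per truncation (\code{truncation},
#'   \code{rate}, \code{sigma_star}, \code{contrast}, \code{baseline},
#'   \code{plateau}).
#' @export
truncation_scan <- function(corr, times, plateau_tol = 0.1) {
  if (length(times) < 3) stop("need at least 3 truncation times")
  times <- sort(times)
  fits <- lapply(times, function(tt) cumulant_fit(corr, tt))
  sig <- vapply(fits, `[[`, numeric(1), "sigma_star")
  plateau <- vapply(seq_along(times), function(i) {
    in_win <- times >= times[i] & times <= 2 * times[i]
    if (sum(in_win) < 2) return(NA)
    s <- sig[in_win]
    mid <- mean(s)
    mid > 0 && (max(s) - min(s)) / mid < plateau_tol
  }, logical(1))
  data.frame(truncation = times,
             rate = vapply(fits, `[[`, numeric(1), "rate"),
             sigma_star = sig,
             contrast = vapply(fits, `[[`, numeric(1), "contrast"),
             baseline = vapply(fits, `[[`, numeric(1), "baseline"),
             plateau = plateau)
}

#' Single-exponential fit of a correlogram
#'
#' Error-weighted fit of \code{g2(t) = b + a exp(-2 t / tau1)}; the robust
#' estimator used for gradient-diffusion series.
#'
#' @param corr A [correlogram()].
#' @return List with \code{rate} (1/us), \code{tau1} (us), \code{contrast},
#'   \code{baseline}, \code{fit}.
#' @export
single_exponential_fit <- function(corr) {
  stopifnot(inherits(corr, "correlogram"))
  d <- data.frame(t = corr$lag, y = corr$g2, w = 1 / corr$err^2)
  best <- NULL
  for (r0 in .rate_guesses(d$t, d$y)) {
    fit <- tryCatch(
      .wfit(y ~ b + a * exp(-2 * r * t), d,
            start = list(a = max(d$y) - 1, b = 1, r = r0),
            lower = c(a = 1e-4, b = 0.98, r = 1e-12),
            upper = c(a = 1.3, b = 1.05, r = Inf),
            weights = d$w),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || deviance(fit) < deviance(best))) best <- fit
  }
  if (is.null(best)) stop("single-exponential fit did not converge")
  p <- stats::coef(best)
  list(rate = p[["r"]], tau1 = 1 / p[["r"]], contrast = p[["a"]],
       baseline = p[["b"]], fit = best)
}

#' Nonergodicity screen for a correlogram
#'
#' Samples at the onset of dynamical arrest show a low intercept and an
#' undefined (drifting) baseline; such correlograms must not enter the
#' ergodic fitting chain. Flags a correlogram whose single-exponential
#' intercept falls below \code{min_contrast} or whose fitted baseline sits
#' at the allowed bounds.
#'
#' @param corr A [correlogram()].
#' @param min_contrast Intercept threshold (default 0.3).
#' @return TRUE if the correlogram looks nonergodic.
#' @export
is_nonergodic <- function(corr, min_contrast = 0.3) {
  fit <- tryCatch(single_exponential_fit(corr), error = function(e) NULL)
  if (is.null(fit)) return(TRUE)
  fit$contrast < min_contrast || fit$baseline <= 0.9801 ||
    fit$baseline >= 1.0499
}

#' Gradient-diffusion concentration coefficient
#'
#' Weighted linear fit of \code{D = D0 (1 + Kd c)}; the interaction-sensitive
#' diffusion parameter Kd with a delta-method confidence interval.
#'
#' @param concentrations Concentrations (mg/mL), at least 3 distinct.
#' @param diffusivities Diffusion coefficients (m^2/s).
#' @param errors Optional standard errors on D (weights \code{1/err^2}).
#' @param level Confidence level (default 0.95).
#' @return List with \code{D0}, \code{kd} (mL/mg), \code{kd_ci}, \code{fit}.
#' @export
kd_regression <- function(concentrations, diffusivities, errors = NULL,
                          level = 0.95) {
  if (length(unique(concentrations)) < 3) {
    stop("need >= 3 distinct concentrations")
  }
  w <- if (is.null(errors)) NULL else 1 / errors^2
  fit <- stats::lm(diffusivities ~ concentrations, weights = w)
  b <- stats::coef(fit)
  d0 <- b[[1]]
  kd <- b[[2]] / d0
  # delta method for kd = b1/b0
  vc <- stats::vcov(fit)
  grad <- c(-b[[2]] / d0^2, 1 / d0)
  se <- sqrt(drop(t(grad) %*% vc %*% grad))
  zc <- stats::qt(1 - (1 - level) / 2, df = stats::df.residual(fit))
  list(D0 = d0, kd = kd, kd_ci = c(kd - zc * se, kd + zc * se), fit = fit)
}

#' Two-mode stretched-exponential fit
#'
#' Error-weighted fit of
#' \code{g2(t) = b + a (c exp(-(t/tau1)^a1) + (1-c) exp(-(t/tau2)^a2))^2}
#' with deterministic multi-start initialization from log-spaced splits of a
#' crude overall rate. The fast exponent can be pinned to 1 (it fits very
#' close to 1 for diffusive fast modes).
#'
#' @param corr A [correlogram()] spanning at least 4 decades in lag.
#' @param pin_alpha1 Fix the fast stretching exponent at 1 (default FALSE).
#' @return A \code{"two_mode_fit"} list: \code{contrast}, \code{baseline},
#'   \code{c_fast}, \code{tau1}, \code{alpha1}, \code{tau2}, \code{alpha2},
#'   \code{tau_mean} (the mean slow time from [kww_mean_time()]),
#'   \code{mode_collapse} flag, \code{fit}.
#' @export
double_stretched_fit <- function(corr, pin_alpha1 = FALSE) {
  stopifnot(inherits(corr, "correlogram"))
  if (log10(max(corr$lag) / min(corr$lag)) < 4) {
    stop("correlogram must span >= 4 decades in lag time")
  }
  d <- data.frame(t = corr$lag, y = corr$g2, w = 1 / corr$err^2)
  y <- (d$y - min(d$y)) / (max(d$y) - min(d$y))
  # scale estimates straight from the decay: the fast mode sets where the
  # normalized correlation first drops below 0.7, the slow mode where it
  # approaches the baseline; multi-start log-spaced factors around both
  t_fast <- d$t[match(TRUE, y < 0.7, nomatch = which.min(abs(y - 0.7)))]
  t_slow <- d$t[match(TRUE, y < 0.05, nomatch = length(y))]
  if (t_slow <= t_fast) t_slow <- t_fast * 30
  y_mid <- y[which.min(abs(d$t - sqrt(t_fast * t_slow)))]
  c0 <- min(max(1 - sqrt(max(y_mid, 0)), 0.05), 0.95)
  best <- NULL
  for (ks in list(c(1, 1), c(0.3, 1), c(3, 1), c(1, 0.3), c(1, 3))) {
    t1 <- t_fast * ks[1]
    t2 <- t_slow * ks[2]
    if (t2 <= t1 * 3) t2 <- t1 * 10
    st <- list(a = max(d$y) - 1, b = 1, cc = c0, lt1 = log(t1), a1 = 1,
               lt2 = log(t2), a2 = 0.7)
    lo <- c(a = 1e-4, b = 0.98, cc = 0, lt1 = log(min(d$t) / 10), a1 = 0.05,
            lt2 = log(min(d$t)), a2 = 0.05)
    hi <- c(a = 1.3, b = 1.05, cc = 1, lt1 = log(max(d$t)), a1 = 2,
            lt2 = log(max(d$t) * 100), a2 = 2)
    form <- if (pin_alpha1) {
      st$a1 <- NULL
      lo <- lo[names(lo) != "a1"]; hi <- hi[names(hi) != "a1"]
      y ~ b + a * (cc * exp(-(t / exp(lt1))) +
                     (1 - cc) * exp(-(t / exp(lt2))^a2))^2
    } else {
      y ~ b + a * (cc * exp(-(t / exp(lt1))^a1) +
                     (1 - cc) * exp(-(t / exp(lt2))^a2))^2
    }
    fit <- tryCatch(.wfit(form, d, start = st, lower = lo, upper = hi,
                          weights = d$w),
                    error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || deviance(fit) < deviance(best))) best <- fit
  }
  if (is.null(best)) stop("two-mode fit did not converge")
  p <- stats::coef(best)
  tau1 <- exp(p[["lt1"]])
  tau2 <- exp(p[["lt2"]])
  alpha1 <- if (pin_alpha1) 1 else p[["a1"]]
  collapse <- tau2 / tau1 < 3 || p[["cc"]] > 0.95 || p[["cc"]] < 0.05
  if (collapse) {
    warning("mode collapse: slow mode poorly identified ",
            "(tau2/tau1 < 3 or a vanishing amplitude fraction)")
  }
  structure(list(contrast = p[["a"]], baseline = p[["b"]],
                 c_fast = p[["cc"]], tau1 = tau1, alpha1 = alpha1,
                 tau2 = tau2, alpha2 = p[["a2"]],
                 tau_mean = kww_mean_time(tau2, p[["a2"]]),
                 mode_collapse = collapse, fit = best),
            class = "two_mode_fit")
}

#' @export
print.two_mode_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "two-mode fit: c = %.3f, tau1 = %.4g us (alpha1 = %.2f), ",
    "tau2 = %.4g us (alpha2 = %.2f), mean slow time = %.4g us\n"),
    x$c_fast, x$tau1, x$alpha1, x$tau2, x$alpha2, x$tau_mean))
  invisible(x)
}

#' Mean relaxation time of a stretched exponential
#'
#' \code{tau_bar = (tau/alpha) Gamma(1/alpha)} for \code{exp(-(t/tau)^alpha)}.
#'
#' @param tau2 Characteristic time.
#' @param alpha2 Stretching exponent (> 0).
#' @return Mean relaxation time in the units of \code{tau2}.
#' @export
kww_mean_time <- function(tau2, alpha2) {
  if (any(alpha2 <= 0)) stop("alpha2 must be > 0")
  tau2 / alpha2 * gamma(1 / alpha2)
}

#' Initial-slope diffusion from an NSE curve
#'
#' Error-weighted single-exponential fit \code{a exp(-t/tau_s)} restricted
#' to early correlation times (\code{t < t_max}, default 50 ns), giving the
#' q-dependent diffusion function \code{D(q) = 1/(tau_s q^2)}.
#'
#' @param isf An [isf_curve()] with times in ns.
#' @param t_max Fit window upper limit in ns (default 50).
#' @return List with \code{tau_s} (ns), \code{D} (m^2/s), \code{q} (1/nm),
#'   \code{fit}.
#' @export
nse_initial_slope <- function(isf, t_max = 50) {
  stopifnot(inherits(isf, "isf_curve"))
  keep <- isf$times < t_max & isf$times >= 0
  if (sum(keep) < 5) stop("need >= 5 points with t < t_max")
  d <- data.frame(t = isf$times[keep], y = isf$isf[keep],
                  w = 1 / isf$err[keep]^2)
  slope0 <- (1 - d$y[which.max(d$t)]) / max(d$t)
  fit <- .wfit(y ~ a * exp(-r * t), d,
               start = list(a = 1, r = max(slope0, 1e-6)),
               lower = c(a = 0.5, r = 1e-12), upper = c(a = 1.5, r = Inf),
               weights = d$w)
  p <- stats::coef(fit)
  tau_s <- 1 / p[["r"]]
  # rate 1/ns -> 1/s is 1e9; q 1/nm -> 1/m is 1e9
  D <- (p[["r"]] * 1e9) / (isf$q * 1e9)^2
  list(tau_s = tau_s, D = D, q = isf$q, contrast = p[["a"]], fit = fit)
}

#' Band-averaged diffusion coefficient
#'
#' Inverse-variance-weighted mean of \code{D(q)} over a q band. Preset
#' \code{"high_q"} covers 1.8-2.2 1/nm (0.18-0.22 1/angstrom), the regime of
#' short-time self-diffusion; preset \code{"cage"} should be centred on the
#' principal structure-factor peak via \code{band}.
#'
#' @param dq_curve Data frame with columns \code{q} (1/nm), \code{D}
#'   (m^2/s) and optionally \code{err}.
#' @param q_band Length-2 numeric band (1/nm) or \code{"high_q"}.
#' @return List with \code{D}, \code{se}, \code{n}.
#' @export
band_average_diffusion <- function(dq_curve, q_band = "high_q") {
  if (identical(q_band, "high_q")) q_band <- c(1.8, 2.2)
  stopifnot(length(q_band) == 2)
  keep <- dq_curve$q >= q_band[1] & dq_curve$q <= q_band[2]
  if (sum(keep) < 2) stop("need >= 2 points in the band")
  d <- dq_curve[keep, , drop = FALSE]
  w <- if (!is.null(d$err)) 1 / d$err^2 else rep(1, nrow(d))
  m <- sum(w * d$D) / sum(w)
  se <- sqrt(1 / sum(w))
  if (is.null(d$err)) se <- stats::sd(d$D) / sqrt(nrow(d))
  list(D = m, se = se, n = nrow(d))
}
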