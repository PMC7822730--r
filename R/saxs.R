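## SAXS-side analysis: Guinier radius, experimental structure factor,
## forward scattering, constrained polydisperse form-factor fitting.

#' SAXS scattering curve container
#'
#' @param q Scattering vectors, strictly increasing.
#' @param I Intensities.
#' @param err Intensity errors (> 0).
#' @param q_unit \code{"per_nm"} or \code{"per_angstrom"}; stored in 1/nm.
#' @param concentration Protein concentration (mg/mL) or NA.
#' @param label Free-text label.
#' @return A \code{"scattering_curve"} object.
#' @export
scattering_curve <- function(q, I, err, q_unit = c("per_nm", "per_angstrom"),
                             concentration = NA_real_, label = "") {
  q <- .q_to_per_nm(q, match.arg(q_unit))
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  if (any(err <= 0)) stop("errors must be > 0")
  stopifnot(length(q) == length(I), length(I) == length(err))
  structure(list(q = as.numeric(q), I = as.numeric(I), err = as.numeric(err),
                 concentration = concentration, label = label),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("scattering_curve '%s': %d points, q in [%.4g, %.4g] 1/nm%s\n",
              x$label, length(x$q), min(x$q), max(x$q),
              if (is.na(x$concentration)) "" else
                sprintf(", c = %g mg/mL", x$concentration)))
  invisible(x)
}

#' Guinier radius of gyration
#'
#' Weighted linear fit of \code{ln I} versus \code{q^2} on the low-q window,
#' iterated until the accepted window satisfies \code{q Rg <= qmax_rg};
#' \code{Rg = sqrt(-3 slope)}. Rising intensity toward the lowest q
#' (an aggregation signature) aborts the analysis.
#'
#' @param curve A [scattering_curve()] (q in 1/nm).
#' @param qmax_rg Window criterion \code{q Rg} (default 1.0).
#' @param min_points Minimum accepted window size (default 8).
#' @return List with \code{rg} (nm), \code{i0}, \code{window} (logical mask),
#'   \code{fit}.
#' @export
guinier_rg <- function(curve, qmax_rg = 1.0, min_points = 8L) {
  stopifnot(inherits(curve, "scattering_curve"))
  n0 <- min(length(curve$q), max(min_points, 10L))
  low <- seq_len(n0)
  if (any(curve$I[low] <= 0) || stats::sd(log(curve$I[low])) < 1e-12) {
    stop("no usable low-q decay; curve carries no size information")
  }
  if (stats::cor(curve$q[low]^2, log(curve$I[low])) > 0) {
    stop("intensity rises toward low q (aggregation signature)")
  }
  rg <- NA_real_
  window <- low
  for (iter in 1:20) {
    d <- data.frame(q2 = curve$q[window]^2, y = log(curve$I[window]),
                    w = (curve$I[window] / curve$err[window])^2)
    fit <- stats::lm(y ~ q2, data = d, weights = w)
    slope <- stats::coef(fit)[[2]]
    if (slope >= 0) stop("non-negative Guinier slope; no size information")
    rg_new <- sqrt(-3 * slope)
    window_new <- which(curve$q * rg_new <= qmax_rg)
    if (length(window_new) < min_points) {
      window_new <- seq_len(min_points)
    }
    if (!is.na(rg) && abs(rg_new - rg) / rg < 1e-6 &&
        identical(window_new, window)) {
      rg <- rg_new
      break
    }
    rg <- rg_new
    window <- window_new
  }
  # aggregation screens: (a) the lowest-q points must not sit
  # systematically above the fitted line (a sharp upturn); (b) a valid
  # window q Rg <= qmax_rg must exist at all -- an oversized low-q
  # component (aggregates) pushes Rg up until no measured q qualifies
  res <- stats::residuals(fit)
  head_res <- res[seq_len(min(3L, length(res)))]
  if (length(res) > 5 && mean(head_res) > 3 * stats::sd(res[-seq_len(3)])) {
    stop("low-q upturn above the Guinier line (aggregation signature)")
  }
  if (max(curve$q[window]) * rg > 1.15 * qmax_rg) {
    stop("no valid Guinier window below q Rg = ", qmax_rg,
         " (oversized or aggregating low-q component)")
  }
  list(rg = rg, i0 = exp(stats::coef(fit)[[1]]), window = window, fit = fit)
}

#' Experimental structure factor
#'
#' \code{S(q) = (I(q) / I0(q)) (c0 / cp)} with the dilute form-factor curve
#' interpolated onto the sample grid (linear in \code{log I}); errors are
#' propagated from both curves.
#'
#' @param curve Concentrated-sample [scattering_curve()].
#' @param formfactor_curve Dilute reference [scattering_curve()].
#' @param c_p Sample concentration (mg/mL); defaults to the curve metadata.
#' @param c0 Reference concentration (mg/mL); defaults to the form-factor
#'   curve metadata.
#' @return Data frame with columns \code{q}, \code{S}, \code{err} plus
#'   attributes \code{c_p}, \code{c0}.
#' @export
experimental_structure_factor <- function(curve, formfactor_curve,
                                          c_p = curve$concentration,
                                          c0 = formfactor_curve$concentration) {
  stopifnot(inherits(curve, "scattering_curve"),
            inherits(formfactor_curve, "scattering_curve"))
  if (is.na(c_p) || is.na(c0)) stop("both concentrations must be known")
  keep <- curve$q >= min(formfactor_curve$q) & curve$q <= max(formfactor_curve$q)
  q <- curve$q[keep]
  li0 <- stats::approx(formfactor_curve$q, log(formfactor_curve$I),
                       xout = q)$y
  i0 <- exp(li0)
  if (any(i0 <= 0)) stop("non-positive form-factor intensity")
  rel_e0 <- stats::approx(formfactor_curve$q,
                          formfactor_curve$err / formfactor_curve$I,
                          xout = q)$y
  s <- (curve$I[keep] / i0) * (c0 / c_p)
  err <- s * sqrt((curve$err[keep] / curve$I[keep])^2 + rel_e0^2)
  out <- data.frame(q = q, S = s, err = err)
  attr(out, "c_p") <- c_p
  attr(out, "c0") <- c0
  out
}

#' Forward scattering S(0)
#'
#' Average of the \code{n_points} lowest-q values of a structure-factor
#' curve with its standard error; a strong upturn toward low q (aggregates)
#' is flagged with a warning.
#'
#' @param sq_curve Data frame with columns \code{q}, \code{S} and optionally
#'   \code{err}.
#' @param n_points Number of lowest-q points (default 5).
#' @return List with \code{s0} and \code{se}.
#' @export
forward_scattering <- function(sq_curve, n_points = 5L) {
  if (nrow(sq_curve) < n_points) stop("fewer than n_points usable points")
  ord <- order(sq_curve$q)
  s <- sq_curve$S[ord]
  head_s <- s[seq_len(n_points)]
  if (n_points >= 3 && s[1] > 1.5 * stats::median(head_s)) {
    warning("low-q upturn: possible aggregate contribution")
  }
  list(s0 = mean(head_s), se = stats::sd(head_s) / sqrt(n_points))
}

#' Constrained polydisperse form-factor fit
#'
#' Fits a Schulz polydisperse-sphere form factor to a dilute scattering
#' curve with the number-average radius tied to an observed radius of
#' gyration at every step (via [mean_radius_from_rg()]); only the
#' polydispersity \code{sigma*}, a scalar prefactor and a constant
#' background are free. The fit range is limited to \code{q <= q_max}.
#'
#' @param curve A dilute [scattering_curve()] (no structure factor).
#' @param rg_constraint Observed intensity-averaged Rg (nm).
#' @param q_max Upper fit limit in 1/nm (default 2, i.e. 0.2 1/angstrom).
#' @return List with \code{model} (a [form_factor_model()]),
#'   \code{sigma_star}, \code{sigma_star_se}, \code{mean_radius},
#'   \code{scale}, \code{background}, \code{fit}.
#' @export
constrained_form_factor_fit <- function(curve, rg_constraint, q_max = 2) {
  stopifnot(inherits(curve, "scattering_curve"))
  keep <- curve$q <= q_max
  if (sum(keep) < 10) stop("fit range narrower than 10 points")
  d <- data.frame(q = curve$q[keep], y = curve$I[keep],
                  w = 1 / curve$err[keep]^2)
  model_i <- function(q, s, lsc, bg) {
    rbar <- mean_radius_from_rg(s, rg_constraint)
    polydisperse_form_intensity(
      form_factor_model(schulz_dist(rbar, s), exp(lsc), bg), q)
  }
  fit <- minpack.lm::nlsLM(
    y ~ model_i(q, s, lsc, bg), data = d,
    start = list(s = 0.3, lsc = log(max(d$y) / max(
      polydisperse_form_intensity(form_factor_model(
        schulz_dist(mean_radius_from_rg(0.3, rg_constraint), 0.3)), d$q))),
      bg = 0),
    lower = c(s = 0.03, lsc = -Inf, bg = 0),
    upper = c(s = 0.6, lsc = Inf, bg = Inf),
    weights = d$w,
    control = minpack.lm::nls.lm.control(maxiter = 100))
  p <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["s"]],
                 error = function(e) NA_real_)
  rbar <- mean_radius_from_rg(p[["s"]], rg_constraint)
  list(model = form_factor_model(schulz_dist(rbar, p[["s"]]),
                                 exp(p[["lsc"]]), p[["bg"]]),
       sigma_star = p[["s"]], sigma_star_se = se, mean_radius = rbar,
       scale = exp(p[["lsc"]]), background = p[["bg"]], fit = fit)
}
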