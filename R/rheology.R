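## Tracer microrheology, relative viscosity, arrest power-law fitting and
## the voluminosity estimates linking weight concentration to volume
## fraction.

#' Relative-viscosity concentration series
#'
#' @param concentrations Concentrations (mg/mL).
#' @param relative_viscosities Relative viscosities (>= 1).
#' @param errors Optional standard errors.
#' @return A \code{"viscosity_series"} object.
#' @export
viscosity_series <- function(concentrations, relative_viscosities,
                             errors = NULL) {
  stopifnot(length(concentrations) == length(relative_viscosities))
  if (any(relative_viscosities < 1)) {
    stop("relative viscosities must be >= 1")
  }
  if (is.null(errors)) errors <- rep(NA_real_, length(concentrations))
  structure(list(concentrations = as.numeric(concentrations),
                 relative_viscosities = as.numeric(relative_viscosities),
                 errors = as.numeric(errors)),
            class = "viscosity_series")
}

#' Viscosity from a tracer correlogram
#'
#' DLS microrheology: large tracers dominate the scattering, their
#' diffusion coefficient follows from a single-exponential fit and the
#' surrounding solution viscosity from Stokes-Einstein,
#' \code{eta = kB T / (6 pi R_tracer D)}. A correlogram whose
#' single-exponential residuals are far beyond the stated errors indicates
#' protein-scattering leakage (a second mode) and is flagged.
#'
#' @param corr A [correlogram()] measured on the tracer-doped sample.
#' @param tracer_radius Tracer radius in nm (default 150, i.e. 300 nm
#'   diameter beads).
#' @param leak_chisq Reduced chi-square threshold for the two-mode flag.
#' @return List with \code{eta} (mPa s), \code{D} (m^2/s), \code{rate}
#'   (1/us), \code{two_mode_flag}.
#' @export
tracer_viscosity <- function(corr, tracer_radius = 150, leak_chisq = 10) {
  stopifnot(inherits(corr, "correlogram"))
  fit <- single_exponential_fit(corr)
  chisq <- sum(stats::residuals(fit$fit)^2 / corr$err^2) /
    max(1, length(corr$lag) - 3)
  flag <- is.finite(chisq) && chisq > leak_chisq
  if (flag) {
    warning("tracer correlogram deviates from a single mode ",
            "(protein scattering leakage?)")
  }
  D <- rate_to_diffusion(fit$rate, corr$q)
  eta <- .KB * corr$temperature / (6 * pi * tracer_radius * 1e-9 * D) * 1e3
  list(eta = eta, D = D, rate = fit$rate, two_mode_flag = flag)
}

#' Relative viscosity
#'
#' \code{eta_r = eta0 / eta_s} (zero-shear sample viscosity over solvent
#' viscosity, any common unit).
#'
#' @param eta0 Zero-shear sample viscosity.
#' @param eta_s Solvent viscosity.
#' @return Dimensionless relative viscosity.
#' @export
relative_viscosity <- function(eta0, eta_s) {
  if (any(eta0 <= 0) || any(eta_s <= 0)) stop("viscosities must be > 0")
  eta0 / eta_s
}

#' Arrest power-law fit of a viscosity series
#'
#' Weighted fit of \code{log eta_r = -gamma log(1 - c/c*)} with both the
#' arrest concentration \code{c*} and the exponent \code{gamma} free; the
#' divergence is fitted in log space for stability. Normalized slow
#' relaxation times \code{tau_bar/tau0} may be supplied as
#' relative-viscosity-equivalent data. The exponent classification
#' \code{gamma < 3} (hard-sphere-like arrest, as opposed to a strongly
#' attraction-driven one) is reported as a flag.
#'
#' @param series A [viscosity_series()] with at least 5 concentrations
#'   spanning a decade in \code{eta_r}.
#' @param c_star_init Initial guess for \code{c*}; must exceed the largest
#'   concentration (default 1.2x the largest).
#' @return List with \code{c_star} (mg/mL), \code{gamma}, standard errors,
#'   \code{hard_sphere_like} flag, \code{fit}.
#' @export
arrest_powerlaw_fit <- function(series, c_star_init = NULL) {
  stopifnot(inherits(series, "viscosity_series"))
  cc <- series$concentrations
  er <- series$relative_viscosities
  if (length(cc) < 5) stop("need >= 5 concentrations")
  if (max(er) / min(er) < 10) {
    stop("series must span at least a decade in relative viscosity")
  }
  if (is.null(c_star_init)) c_star_init <- 1.2 * max(cc)
  if (c_star_init <= max(cc)) {
    stop("c* initial guess must exceed the largest concentration")
  }
  w <- if (all(is.na(series$errors))) rep(1, length(cc)) else
    (er / series$errors)^2  # sd(log eta) = err/eta
  d <- data.frame(c = cc, y = log(er), w = w)
  fit <- minpack.lm::nlsLM(
    y ~ -g * log(1 - c / cs), data = d,
    start = list(g = 2.5, cs = c_star_init),
    lower = c(g = 0.1, cs = max(cc) * 1.0001),
    upper = c(g = 10, cs = max(cc) * 10),
    weights = d$w,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    c(g = NA_real_, cs = NA_real_))
  list(c_star = p[["cs"]], gamma = p[["g"]], c_star_se = se[["cs"]],
       gamma_se = se[["g"]], hard_sphere_like = p[["g"]] < 3, fit = fit)
}

#' Relative viscosity of the arrest power law
#'
#' Forward model \code{eta_r = (1 - c/c*)^(-gamma)}; the generator/
#' prediction counterpart of [arrest_powerlaw_fit()].
#'
#' @param concentrations Concentrations (mg/mL), below \code{c_star}.
#' @param c_star Arrest concentration (mg/mL).
#' @param gamma Divergence exponent.
#' @return Relative viscosities.
#' @export
arrest_powerlaw <- function(concentrations, c_star = 360, gamma = 2.8) {
  if (any(concentrations >= c_star)) stop("concentrations must be < c*")
  (1 - concentrations / c_star)^(-gamma)
}

#' Voluminosity estimates
#'
#' Two independent routes from experiment to the effective voluminosity
#' converting mg/mL to volume fraction:
#' \enumerate{
#'   \item packing route: arrest of mildly attractive spheres occurs near
#'     random close packing, \code{nu = phi_arrest / c_arrest};
#'   \item hydrodynamic route: scale a Schulz distribution so its z-average
#'     radius \code{<R^6>/<R^5>} matches the dilute hydrodynamic radius,
#'     take the number-average sphere volume \code{V = (4 pi/3) <R^3>} and
#'     divide by the molar mass, \code{nu = V N_A / M_w}.
#' }
#' The two probe different physics (steric packing versus hydrodynamic
#' friction) and generally disagree at the 10 percent level; a chosen
#' intermediate working value is carried alongside.
#'
#' @param c_arrest Arrest concentration (mg/mL).
#' @param dist A [schulz_dist()] (only its \code{sigma_star} is used; the
#'   scale is set by \code{rh_z}).
#' @param rh_z z-averaged hydrodynamic radius (nm).
#' @param mw Molar mass (kDa).
#' @param phi_arrest Packing fraction at arrest (default 0.64, random close
#'   packing).
#' @param chosen Working value carried into downstream analysis (default
#'   1.7 mL/g).
#' @return List with \code{nu_packing}, \code{nu_hydro} (both mL/g),
#'   \code{volume_z} (nm^3), \code{mean_radius} (nm), \code{chosen}.
#' @export
voluminosity_estimates <- function(c_arrest, dist, rh_z, mw,
                                   phi_arrest = 0.64, chosen = 1.7) {
  stopifnot(c_arrest > 0, rh_z > 0, mw > 0, inherits(dist, "schulz_dist"))
  nu1 <- phi_arrest / c_arrest * 1000 # (mg/mL)^-1 -> mL/g
  rbar <- rh_z / (intensity_avg_rh(schulz_dist(1, dist$sigma_star)))
  d2 <- schulz_dist(rbar, dist$sigma_star)
  vz <- 4 * pi / 3 * schulz_moment(d2, 3) # nm^3
  # nm^3 -> mL and kDa -> g/mol: nu = V * 1e-21 * N_A / (mw * 1000)
  nu2 <- vz * 1e-21 * 6.02214076e23 / (mw * 1000)
  list(nu_packing = nu1, nu_hydro = nu2, volume_z = vz, mean_radius = rbar,
       chosen = chosen)
}
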