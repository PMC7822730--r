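## Analytic interaction and thermodynamics layer: Baxter sticky-hard-sphere
## relations, virial-coefficient ratios, Carnahan-Starling and multicomponent
## Percus-Yevick compressibility, and the monodisperse square-well S(q).

#' Interaction model of a weakly attractive protein colloid
#'
#' Bundles the sticky-hard-sphere stickiness, the equivalent square-well
#' parameters and the effective voluminosity converting weight concentration
#' to volume fraction (\code{phi = c * nu_eff}).
#'
#' @param stickiness_tau Baxter stickiness \code{tau} (> 0); values
#'   \code{> 0.25} give a non-negative normalized second virial coefficient.
#' @param well_depth Square-well depth \code{u} in kT units (>= 0).
#' @param well_width Dimensionless outer range over hard-core contact
#'   \code{lambda} (> 1); 1.25 corresponds to a well extending 0.25 contact
#'   diameters beyond contact.
#' @param voluminosity Effective voluminosity \code{nu_eff} in mL/g, or
#'   \code{NA}; when set it must exceed the dry specific volume ~0.71 mL/g.
#' @return An object of class \code{"interaction_model"}.
#' @export
interaction_model <- function(stickiness_tau = 0.774, well_depth = 0.289,
                              well_width = 1.25, voluminosity = 1.7) {
  if (stickiness_tau <= 0) stop("stickiness_tau must be > 0")
  if (well_depth < 0) stop("well_depth must be >= 0")
  if (well_width <= 1) stop("well_width must be > 1")
  if (!is.na(voluminosity) && voluminosity <= 0.71) {
    stop("voluminosity must exceed the dry specific volume ~0.71 mL/g")
  }
  structure(list(stickiness_tau = stickiness_tau, well_depth = well_depth,
                 well_width = well_width, voluminosity = voluminosity),
            class = "interaction_model")
}

#' Carnahan-Starling forward structure factor
#'
#' \code{S(0) = (1-phi)^4 / ((1+2 phi)^2 + phi^3 (phi - 4))} for monodisperse
#' hard spheres; the reduced isothermal compressibility.
#'
#' @param phi Volume fraction in \code{[0, 0.64)}.
#' @return S(0), dimensionless.
#' @export
carnahan_starling_s0 <- function(phi) {
  if (any(phi < 0) || any(phi >= 0.64)) stop("phi must be in [0, 0.64)")
  (1 - phi)^4 / ((1 + 2 * phi)^2 + phi^3 * (phi - 4))
}

#' Carnahan-Starling compressibility factor
#'
#' \code{Z = (1 + phi + phi^2 - phi^3) / (1-phi)^3}; used as the pressure
#' oracle for the hard-sphere simulation.
#'
#' @param phi Volume fraction in \code{[0, 0.64)}.
#' @return Z = p V / (N kT).
#' @export
carnahan_starling_z <- function(phi) {
  if (any(phi < 0) || any(phi >= 0.64)) stop("phi must be in [0, 0.64)")
  (1 + phi + phi^2 - phi^3) / (1 - phi)^3
}

## ---- multicomponent Percus-Yevick hard spheres (Baxter factorization) ----

# Baxter factor functions for an additive hard-sphere mixture give the
# partial direct correlation integrals in closed form. At q = 0,
#   Qhat_ij(0) = delta_ij - 2 pi sqrt(rho_i rho_j) Iq_ij,
#   Iq_ij = int_{S_ji}^{d_ij} q_ij(r) dr,
#   q_ij(r) = a_i (r^2 - d_ij^2)/2 + b_i (r - d_ij),
# with d_ij = (d_i + d_j)/2, S_ji = (d_j - d_i)/2,
#   a_i = (1 - xi3 + 3 d_i xi2) / (1 - xi3)^2,
#   b_i = -3/2 d_i^2 xi2 / (1 - xi3)^2,
#   xi_n = (pi/6) sum_i rho_i d_i^n.
# The Ashcroft-Langreth partial structure factors follow from
# S^{-1}(0) = Qhat(0)^T Qhat(0).
.py_mixture_s0_partials <- function(rho, d) {
  m <- length(rho)
  xi2 <- pi / 6 * sum(rho * d^2)
  xi3 <- pi / 6 * sum(rho * d^3)
  a <- (1 - xi3 + 3 * d * xi2) / (1 - xi3)^2
  b <- -1.5 * d^2 * xi2 / (1 - xi3)^2
  Q0 <- diag(m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      dij <- (d[i] + d[j]) / 2
      sji <- (d[j] - d[i]) / 2
      # int (r^2 - dij^2)/2 dr and int (r - dij) dr over [sji, dij]
      i1 <- (dij^3 - sji^3) / 6 - dij^2 * (dij - sji) / 2
      i2 <- (dij^2 - sji^2) / 2 - dij * (dij - sji)
      iq <- a[i] * i1 + b[i] * i2
      Q0[i, j] <- Q0[i, j] - 2 * pi * sqrt(rho[i] * rho[j]) * iq
    }
  }
  solve(crossprod(Q0))  # S_ij(0), Ashcroft-Langreth normalization
}

# BMCSL excess free-energy density of an additive hard-sphere mixture
# (the multicomponent Carnahan-Starling equation of state); reduces exactly
# to Carnahan-Starling for equal diameters.
.bmcsl_fex <- function(rho, d) {
  xi0 <- pi / 6 * sum(rho)
  xi1 <- pi / 6 * sum(rho * d)
  xi2 <- pi / 6 * sum(rho * d^2)
  xi3 <- pi / 6 * sum(rho * d^3)
  (6 / pi) * ((xi2^3 / xi3^2 - xi0) * log(1 - xi3) +
                3 * xi1 * xi2 / (1 - xi3) +
                xi2^3 / (xi3 * (1 - xi3)^2))
}

# Partial structure factors at q = 0 from the exact compressibility
# relation [S(0)^-1]_ij = sqrt(rho_i rho_j) d(beta mu_i)/d(rho_j), with the
# chemical potentials from a mixture equation of state (numerical Hessian
# of the free-energy density plus the ideal term).
.eos_mixture_s0_partials <- function(rho, d, fex = .bmcsl_fex) {
  m <- length(rho)
  h <- pmax(1e-6 * rho, 1e-10)
  hess <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in i:m) {
      rpp <- rho; rpp[i] <- rpp[i] + h[i]; rpp[j] <- rpp[j] + h[j]
      rpm <- rho; rpm[i] <- rpm[i] + h[i]; rpm[j] <- rpm[j] - h[j]
      rmp <- rho; rmp[i] <- rmp[i] - h[i]; rmp[j] <- rmp[j] + h[j]
      rmm <- rho; rmm[i] <- rmm[i] - h[i]; rmm[j] <- rmm[j] - h[j]
      hess[i, j] <- (fex(rpp, d) - fex(rpm, d) - fex(rmp, d) + fex(rmm, d)) /
        (4 * h[i] * h[j])
      hess[j, i] <- hess[i, j]
    }
  }
  binv <- diag(1 / rho) + hess              # d(beta mu_i)/d(rho_j)
  s_inv <- sqrt(outer(rho, rho)) * binv
  solve(s_inv)
}

#' Forward structure factor of polydisperse hard spheres
#'
#' Scattering-weighted zero-q limit for a discretized Schulz hard-sphere
#' mixture,
#' \code{S_M(0) = sum_ij f_i f_j sqrt(x_i x_j) S_ij(0) / sum_i x_i f_i^2}
#' with \code{f_i} proportional to particle volume at q = 0. The partial
#' structure factors come from the compressibility relation applied to the
#' BMCSL mixture equation of state (default; reduces exactly to
#' Carnahan-Starling in the monodisperse limit) or to the multicomponent
#' Percus-Yevick solution via Baxter's factor functions
#' (\code{method = "py"}). Polydispersity mildly raises S(0) above the
#' monodisperse value.
#'
#' @param phi Total volume fraction in \code{[0, 0.55]}.
#' @param dist A [schulz_dist()]; \code{sigma_star <= 0.6}.
#' @param n_species Number of equal-weight quantile species in the
#'   discretization (default 150; the volume-squared amplitude weighting
#'   emphasises the large-radius tail and needs a fine ladder).
#' @param method \code{"bmcsl"} (default) or \code{"py"}.
#' @return S(0), dimensionless.
#' @export
polydisperse_hs_s0 <- function(phi, dist, n_species = 150L,
                               method = c("bmcsl", "py")) {
  stopifnot(inherits(dist, "schulz_dist"))
  method <- match.arg(method)
  if (phi < 0 || phi > 0.55) stop("phi must be in [0, 0.55]")
  if (dist$sigma_star > 0.6) stop("sigma_star > 0.6 unsupported")
  if (phi == 0) return(1)
  if (dist$sigma_star < .SIGMA_STAR_MONO) {
    return(if (method == "py") (1 - phi)^4 / (1 + 2 * phi)^2
           else carnahan_starling_s0(phi))
  }
  r <- schulz_quantile_species(dist, n_species)
  d <- 2 * r
  x <- rep(1 / n_species, n_species)
  # number density from phi = (pi/6) rho_tot sum x_i d_i^3
  rho_tot <- phi / (pi / 6 * sum(x * d^3))
  s0 <- if (method == "py") {
    .py_mixture_s0_partials(rho_tot * x, d)
  } else {
    .eos_mixture_s0_partials(rho_tot * x, d)
  }
  f <- d^3  # volume-proportional amplitudes at q = 0
  num <- 0
  for (i in seq_len(n_species)) {
    for (j in seq_len(n_species)) {
      num <- num + f[i] * f[j] * sqrt(x[i] * x[j]) * s0[i, j]
    }
  }
  num / sum(x * f^2)
}

## ---- sticky-hard-sphere relations ----

#' Gradient-diffusion coefficient of sticky hard spheres
#'
#' Linear concentration coefficient \code{Kd = (1.454 - 1.125/tau) nu_eff}
#' of the gradient (collective) diffusion of Baxter sticky hard spheres
#' including hydrodynamic interactions; \code{tau -> Inf} recovers the pure
#' hard-sphere value 1.454 \code{nu_eff}.
#'
#' @param tau Stickiness (> 0).
#' @param nu_eff Effective voluminosity (mL/g).
#' @return Kd in mL/g.
#' @export
shs_kd <- function(tau, nu_eff) {
  if (any(tau <= 0)) stop("tau must be > 0")
  (1.454 - 1.125 / tau) * nu_eff
}

#' Stickiness at vanishing Kd
#'
#' Root of the sticky-hard-sphere gradient-diffusion relation in \code{tau}:
#' a measured \code{Kd ~ 0} pins the stickiness at \code{1.125/1.454 =
#' 0.7737}, independent of the voluminosity.
#'
#' @return The stickiness tau, dimensionless.
#' @export
solve_tau_kd_zero <- function() {
  stats::uniroot(function(tau) shs_kd(tau, 1), c(0.3, 10),
                 tol = 1e-12)$root
}

#' Normalized second virial coefficient of sticky hard spheres
#'
#' \code{B2/B2(HS) = 1 - 1/(4 tau)}; \code{B2(HS) = 4V}.
#'
#' @param tau Stickiness (> 0).
#' @return Dimensionless virial ratio.
#' @export
b2_ratio_shs <- function(tau) {
  if (any(tau <= 0)) stop("tau must be > 0")
  1 - 1 / (4 * tau)
}

#' Normalized second virial coefficient of a square-well fluid
#'
#' Closed form \code{B2/B2(HS) = 1 - (lambda^3 - 1)(exp(u) - 1)} for a well
#' of depth \code{u} (kT) reaching to \code{lambda} times contact.
#'
#' @param u Well depth in kT (>= 0).
#' @param lam Reduced outer range \code{lambda} (> 1).
#' @return Dimensionless virial ratio.
#' @export
b2_ratio_square_well <- function(u, lam) {
  if (any(u < 0)) stop("u must be >= 0")
  if (any(lam <= 1)) stop("lam must be > 1")
  1 - (lam^3 - 1) * (exp(u) - 1)
}

#' Short-time self-diffusion of sticky hard spheres
#'
#' First-order prediction \code{Ds/D0 = 1 - (1.8315 + 0.295/tau) phi}. The
#' linear theory only covers \code{phi <= 0.3}; beyond that a warning is
#' issued and the linear extrapolation returned.
#'
#' @param phi Volume fraction.
#' @param tau Stickiness (> 0).
#' @return Ds/D0, dimensionless.
#' @export
shs_self_diffusion <- function(phi, tau) {
  if (any(tau <= 0)) stop("tau must be > 0")
  if (any(phi > 0.3)) {
    warning("phi > 0.3 is outside the validity of the linear prediction")
  }
  1 - (1.8315 + 0.295 / tau) * phi
}

## ---- monodisperse structure factors ----

#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic PY solution for monodisperse hard spheres of diameter \code{d}.
#'
#' @param q_grid Scattering vectors (inverse \code{d} units).
#' @param phi Volume fraction in \code{[0, 0.55]}.
#' @param d Hard-core diameter (default 1).
#' @return S(q) at each q.
#' @export
py_structure_factor <- function(q_grid, phi, d = 1) {
  if (phi < 0 || phi > 0.55) stop("phi must be in [0, 0.55]")
  if (phi == 0) return(rep(1, length(q_grid)))
  al <- (1 + 2 * phi)^2 / (1 - phi)^4
  be <- -6 * phi * (1 + phi / 2)^2 / (1 - phi)^4
  ga <- phi * al / 2
  s <- q_grid * d
  # the beta/gamma terms lose ~all precision below x ~ 0.01 (differences of
  # O(1) terms leaving O(x^4)); switch to the q -> 0 limit there
  nc <- vapply(s, function(x) {
    if (x < 0.01) {
      return(-24 * phi * (al / 3 + be / 4 + ga / 6))
    }
    -24 * phi * (al * (sin(x) - x * cos(x)) / x^3 +
      be * (2 * x * sin(x) + (2 - x^2) * cos(x) - 2) / x^4 +
      ga * (-x^4 * cos(x) +
              4 * ((3 * x^2 - 6) * cos(x) + (x^3 - 6 * x) * sin(x) + 6)) / x^6)
  }, numeric(1))
  1 / (1 - nc)
}

#' Monodisperse square-well structure factor
#'
#' S(q) of the square-well fluid from the analytic PY hard-sphere reference
#' plus a first-order (random-phase) perturbation for the attractive well:
#' \code{1/S(q) = 1/S_PY(q) - rho c_att(q)} with
#' \code{c_att(q) = 4 pi u [ (sin qr - qr cos qr)/q^3 ]_{d}^{lam d}}.
#' \code{u = 0} recovers the PY hard-sphere curve; attraction raises the
#' low-q limit at fixed \code{phi}.
#'
#' @param q_grid Scattering vectors (inverse \code{d} units).
#' @param phi Volume fraction in \code{[0, 0.55]}.
#' @param u Well depth in kT (>= 0).
#' @param lam Reduced well range (> 1).
#' @param d Hard-core diameter (default 1).
#' @return S(q) at each q. Fails explicitly if the perturbed inverse
#'   structure factor loses positivity (closure breakdown).
#' @export
sw_structure_factor_mono <- function(q_grid, phi, u = 0.289, lam = 1.25,
                                     d = 1) {
  if (phi < 0 || phi > 0.55) stop("phi must be in [0, 0.55]")
  if (phi == 0) return(rep(1, length(q_grid)))
  s_py <- py_structure_factor(q_grid, phi, d)
  if (u == 0) return(s_py)
  rho <- 6 * phi / (pi * d^3)
  catt <- vapply(q_grid, function(q) {
    if (q * d < 0.01) {
      return(4 * pi / 3 * u * ((lam * d)^3 - d^3))
    }
    f <- function(r) (sin(q * r) - q * r * cos(q * r)) / q^3
    4 * pi * u * (f(lam * d) - f(d))
  }, numeric(1))
  inv <- 1 / s_py - rho * catt
  if (any(inv <= 0)) {
    stop("square-well perturbation breaks down (non-positive 1/S(q)); ",
         "reduce u or phi")
  }
  1 / inv
}
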