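## Synthetic-data generators with known ground truth for every input the
## analysis chain consumes. Each generator is the exact forward model of its
## analysis counterpart (Siegert-related correlograms of a Schulz ensemble,
## polydisperse sphere form factors, stretched-exponential decays, power-law
## diverging viscosity), plus multiplicative Gaussian noise with a
## lag-dependent floor emulating correlator statistics. All randomness flows
## from a single integer seed; regeneration is bit-identical.

#' Ground truth for a synthetic dataset
#'
#' @param distribution A [schulz_dist()] (radii in nm).
#' @param D0 Dilute-limit diffusion coefficient (m^2/s).
#' @param interaction An [interaction_model()].
#' @param c_star Arrest concentration (mg/mL).
#' @param gamma Viscosity divergence exponent.
#' @param noise Default relative noise level.
#' @param seed Master seed.
#' @return A \code{"ground_truth"} object.
#' @export
ground_truth <- function(distribution = schulz_dist(4.48, 0.3),
                         D0 = 3.04e-11,
                         interaction = interaction_model(),
                         c_star = 360, gamma = 2.8,
                         noise = 0.01, seed = 1L) {
  stopifnot(inherits(distribution, "schulz_dist"),
            inherits(interaction, "interaction_model"))
  structure(list(distribution = distribution, D0 = D0,
                 interaction = interaction, c_star = c_star, gamma = gamma,
                 noise = noise, seed = as.integer(seed)),
            class = "ground_truth")
}

# log-spaced lag grid covering the decay; from tau/300 to span*tau
.lag_grid <- function(tau_mean_us, n_points, span = 30) {
  exp(seq(log(tau_mean_us / 300), log(span * tau_mean_us),
          length.out = n_points))
}

# multiplicative Gaussian noise with a lag-dependent floor: the sd tracks
# the decaying signal at early lags but bottoms out at a fixed fraction of
# the contrast scale, mimicking correlator counting statistics whose
# baseline noise does not vanish with the decayed signal
.g2_noise_sd <- function(signal, contrast, noise) {
  noise * (signal + 0.3 * contrast)
}

#' Synthetic DLS correlogram of a Schulz sphere ensemble
#'
#' Forward model of dilute-solution DLS:
#' \code{g1(t) = sum_k w_k exp(-D_k q^2 t)} over a quadrature discretization
#' of the Schulz ensemble with intensity weights \code{w_k ~ P(R_k) R_k^6}
#' and Stokes-Einstein rates \code{D_k = kB T/(6 pi eta R_k)}; then
#' \code{g2 = b + a g1^2} plus multiplicative Gaussian noise. The
#' intensity-weighted mean rate equals \code{q^2 kB T/(6 pi eta Rh_z)} with
#' \code{Rh_z = <R^6>/<R^5>} by construction.
#'
#' @param dist A [schulz_dist()] (radii in nm).
#' @param q Scattering vector (1/nm).
#' @param temperature Temperature (K).
#' @param eta_s Solvent viscosity (mPa s).
#' @param n_points Number of lag points (default 150).
#' @param noise Relative noise level (>= 0).
#' @param seed Integer seed.
#' @param contrast Speckle contrast a (default 0.95).
#' @param baseline Baseline b (default 1).
#' @param lag_span Longest lag in units of the mean relaxation time.
#' @return A [correlogram()] with attribute \code{truth} (list with the
#'   mean rate, the intensity-weighted rate spread, and the z-average Rh).
#' @export
synth_dls_correlogram <- function(dist, q = 0.0229, temperature = 298.15,
                                  eta_s = 1.095, n_points = 150L,
                                  noise = 0.01, seed = 1L, contrast = 0.95,
                                  baseline = 1, lag_span = 30) {
  stopifnot(inherits(dist, "schulz_dist"), noise >= 0)
  quad <- .schulz_quadrature(dist)
  w <- quad$w * quad$r^6
  w <- w / sum(w)
  d_k <- .KB * temperature / (6 * pi * eta_s * 1e-3 * quad$r * 1e-9) # m^2/s
  rate_k <- d_k * q^2 * 1e12                                         # 1/us
  mean_rate <- sum(w * rate_k)
  rate_spread <- sqrt(sum(w * rate_k^2) / mean_rate^2 - 1)
  lag <- .lag_grid(1 / mean_rate, n_points, lag_span)
  g1 <- vapply(lag, function(tt) sum(w * exp(-rate_k * tt)), numeric(1))
  signal <- contrast * g1^2
  sd_pt <- .g2_noise_sd(signal, contrast, noise)
  g2 <- withr::with_seed(seed, baseline + signal +
                           if (noise > 0) stats::rnorm(n_points, 0, sd_pt)
                           else 0)
  err <- if (noise > 0) sd_pt else pmax(sd_pt, 1e-6)
  out <- correlogram(lag, g2, pmax(err, 1e-9), q, temperature, eta_s)
  attr(out, "truth") <- list(
    mean_rate = mean_rate, rate_spread = rate_spread,
    rh_z = intensity_avg_rh(dist), D0 = rate_to_diffusion(mean_rate, q))
  out
}

#' Synthetic two-mode stretched-exponential correlogram
#'
#' Exact forward model
#' \code{g2(t) = b + a (c exp(-(t/tau1)^a1) + (1-c) exp(-(t/tau2)^a2))^2}
#' plus multiplicative Gaussian noise.
#'
#' @param c_fast Fast-mode amplitude fraction in \code{[0, 1]}.
#' @param tau1,alpha1 Fast time (us) and exponent.
#' @param tau2,alpha2 Slow time (us) and exponent.
#' @param q Scattering vector (1/nm).
#' @param n_points Number of lag points.
#' @param noise Relative noise level.
#' @param seed Integer seed.
#' @param contrast,baseline Siegert parameters.
#' @return A [correlogram()] with attribute \code{truth}.
#' @export
synth_two_mode_correlogram <- function(c_fast, tau1, alpha1, tau2, alpha2,
                                       q = 0.022, n_points = 200L,
                                       noise = 0.01, seed = 1L,
                                       contrast = 0.95, baseline = 1) {
  stopifnot(c_fast >= 0, c_fast <= 1, tau2 > tau1, alpha1 > 0, alpha1 <= 2,
            alpha2 > 0, alpha2 <= 2)
  lag <- exp(seq(log(tau1 / 100), log(max(tau2 * 30, tau1 * 300)),
                 length.out = n_points))
  g1 <- c_fast * exp(-(lag / tau1)^alpha1) +
    (1 - c_fast) * exp(-(lag / tau2)^alpha2)
  signal <- contrast * g1^2
  sd_pt <- .g2_noise_sd(signal, contrast, noise)
  g2 <- withr::with_seed(seed, baseline + signal +
                           if (noise > 0) stats::rnorm(n_points, 0, sd_pt)
                           else 0)
  out <- correlogram(lag, g2, pmax(sd_pt, 1e-9), q)
  attr(out, "truth") <- list(c_fast = c_fast, tau1 = tau1, alpha1 = alpha1,
                             tau2 = tau2, alpha2 = alpha2,
                             tau_mean = kww_mean_time(tau2, alpha2))
  out
}

#' Synthetic SAXS curve
#'
#' \code{I(q) = scale c_p P_poly(q) S(q) + background} plus multiplicative
#' noise. \code{structure = "none"} gives the dilute form factor;
#' \code{"theory"} multiplies by the monodisperse square-well S(q) at the
#' volume-equivalent diameter; \code{"edmd"} interpolates an effective
#' structure factor measured from simulation configurations (supplied as a
#' data frame from [effective_structure_factor()] with q rescaled to 1/nm).
#'
#' @param dist A [schulz_dist()] (nm).
#' @param q_grid Scattering vectors (1/nm), increasing.
#' @param concentration Protein concentration c_p (mg/mL).
#' @param structure \code{"none"}, \code{"theory"} or \code{"edmd"}.
#' @param interaction An [interaction_model()] (used for \code{"theory"};
#'   its voluminosity maps concentration to volume fraction).
#' @param sq_curve Data frame \code{q} (1/nm), \code{S} for
#'   \code{structure = "edmd"}.
#' @param scale Intensity scale per mg/mL.
#' @param background Constant background.
#' @param noise Relative noise level.
#' @param seed Integer seed.
#' @return A [scattering_curve()] with attribute \code{truth}.
#' @export
synth_saxs_curve <- function(dist, q_grid, concentration = 11,
                             structure = c("none", "theory", "edmd"),
                             interaction = interaction_model(),
                             sq_curve = NULL, scale = 1, background = 0,
                             noise = 0.01, seed = 1L) {
  structure_kind <- match.arg(structure)
  stopifnot(inherits(dist, "schulz_dist"))
  p_poly <- polydisperse_form_intensity(
    form_factor_model(dist, 1, 0), q_grid)
  s_q <- switch(structure_kind,
    none = rep(1, length(q_grid)),
    theory = {
      phi <- concentration / 1000 * interaction$voluminosity
      d_eff <- 2 * schulz_moment(dist, 3)^(1 / 3) # volume-equivalent, nm
      sw_structure_factor_mono(q_grid, phi, interaction$well_depth,
                               interaction$well_width, d_eff)
    },
    edmd = {
      if (is.null(sq_curve)) stop("structure = 'edmd' needs sq_curve")
      stats::approx(sq_curve$q, sq_curve$S, xout = q_grid, rule = 2)$y
    })
  intensity <- scale * concentration * p_poly * s_q + background
  sd_pt <- noise * intensity
  obs <- withr::with_seed(seed, intensity +
                            if (noise > 0)
                              stats::rnorm(length(q_grid), 0, sd_pt) else 0)
  out <- scattering_curve(q_grid, obs, pmax(sd_pt, 1e-12 * max(intensity)),
                          concentration = concentration,
                          label = sprintf("synthetic (%s)", structure_kind))
  attr(out, "truth") <- list(dist = dist, structure = structure_kind,
                             s_q = s_q, scale = scale,
                             background = background)
  out
}

#' Synthetic NSE intermediate scattering functions
#'
#' \code{I(q,t)/I(q,0) = exp(-D(q) q^2 t)} for a set of scattering vectors,
#' each truncated at the spin-echo time window covering its q (the three
#' standard windows reach 91, 248 and 598 ns from high to low q). The
#' diffusion profile is constant with a configurable low-q upturn mimicking
#' rotational/internal contributions:
#' \code{D(q) = D_base (1 + upturn exp(-(q/q_c)^2))}.
#'
#' @param D_base High-q diffusion coefficient (m^2/s).
#' @param q_list Scattering vectors (1/nm), within 0.25-2.1.
#' @param upturn Relative low-q enhancement (default 0.5).
#' @param q_c Upturn decay scale (1/nm, default 0.5).
#' @param n_points Points per curve.
#' @param noise Relative noise level.
#' @param seed Integer seed.
#' @return List of [isf_curve()] objects with attribute \code{truth}
#'   (vector of true D(q)).
#' @export
synth_nse_set <- function(D_base, q_list = seq(0.3, 2.1, by = 0.2),
                          upturn = 0.5, q_c = 0.5, n_points = 25L,
                          noise = 0.005, seed = 1L) {
  d_true <- D_base * (1 + upturn * exp(-(q_list / q_c)^2))
  tau_max <- ifelse(q_list < 0.7, 598, ifelse(q_list < 1.2, 248, 91)) # ns
  curves <- vector("list", length(q_list))
  for (i in seq_along(q_list)) {
    rate_ns <- d_true[i] * (q_list[i] * 1e9)^2 * 1e-9 # 1/ns
    # quasi-log spacing of spin-echo Fourier times from 0.5 ns; pmin guards
    # the exp/log round trip at the window edge
    tt <- pmin(exp(seq(log(0.5), log(tau_max[i]), length.out = n_points)),
               tau_max[i])
    isf <- exp(-rate_ns * tt)
    sd_pt <- pmax(noise * isf, noise / 5)
    obs <- withr::with_seed(seed + i, isf + if (noise > 0)
      stats::rnorm(length(tt), 0, sd_pt) else 0)
    curves[[i]] <- isf_curve(tt, obs, pmax(sd_pt, 1e-9), q_list[i])
  }
  attr(curves, "truth") <- list(D = d_true, q = q_list, tau_max = tau_max)
  curves
}

#' Synthetic relative-viscosity series
#'
#' \code{eta_r = (1 - c/c*)^(-gamma)} with multiplicative Gaussian noise.
#'
#' @param concentrations Concentrations (mg/mL), strictly below
#'   \code{c_star}.
#' @param c_star Arrest concentration (mg/mL).
#' @param gamma Divergence exponent.
#' @param noise Relative noise level.
#' @param seed Integer seed.
#' @return A [viscosity_series()] with attribute \code{truth}.
#' @export
synth_viscosity_series <- function(concentrations, c_star = 360,
                                   gamma = 2.8, noise = 0.05, seed = 1L) {
  if (any(concentrations >= c_star)) stop("concentrations must be < c*")
  eta <- arrest_powerlaw(concentrations, c_star, gamma)
  obs <- withr::with_seed(seed, eta * (1 + if (noise > 0)
    stats::rnorm(length(eta), 0, noise) else 0))
  out <- viscosity_series(concentrations, pmax(obs, 1), noise * eta)
  attr(out, "truth") <- list(c_star = c_star, gamma = gamma)
  out
}
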