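# Independent oracles used across the suite.

# brute-force Schulz moment by adaptive quadrature of the density
schulz_moment_quadrature <- function(mean_radius, sigma_star, n) {
  cc <- 1 / sigma_star^2
  b <- mean_radius / cc
  stats::integrate(function(r) r^n * stats::dgamma(r, shape = cc, scale = b),
                   0, 20 * mean_radius, rel.tol = 1e-10)$value
}

# Perrin translational friction by the Oberbeck integral:
# Rh = 2 / int_0^inf ds / ((b^2+s) sqrt(a^2+s)), a = p b polar semi-axis
perrin_rh_numeric <- function(p, b = 1) {
  a <- p * b
  val <- stats::integrate(function(s) 1 / ((b^2 + s) * sqrt(a^2 + s)),
                          0, Inf, rel.tol = 1e-10)$value
  2 / val
}

# intensity-weighted rate spread of a Schulz ensemble under R^6 weights and
# Stokes-Einstein (1/R) rates: closed-form moment ratio
schulz_rate_spread <- function(sigma_star) {
  cc <- 1 / sigma_star^2
  sqrt((5 + cc) / (4 + cc) - 1)
}

# run a small square-well (or hard-sphere) simulation and return snapshots
run_small_sim <- function(n, phi, u, seed, sigma_star = 0,
                          n_snapshots = 100, decorrelation = 20,
                          n_species = 10) {
  radii <- if (sigma_star > 0) {
    discretize_schulz(schulz_dist(0.5, sigma_star), n_species, n, seed = seed)
  } else {
    rep(0.5, n)
  }
  spec <- square_well_spec(u, 0.25)
  box <- initialize_box(radii, phi, seed = seed)
  eq <- equilibrate(box, spec)
  snaps <- sample_configurations(eq, spec, n_samples = n_snapshots,
                                 decorrelation_events = decorrelation)
  list(box = box, snaps = snaps, spec = spec)
}
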