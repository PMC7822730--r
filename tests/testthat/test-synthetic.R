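test_that("generators are bit-identical under a fixed seed", {
  d <- schulz_dist(4.48, 0.3)
  a <- synth_dls_correlogram(d, noise = 0.02, seed = 7)
  b <- synth_dls_correlogram(d, noise = 0.02, seed = 7)
  expect_identical(a$g2, b$g2)
  expect_false(identical(
    a$g2, synth_dls_correlogram(d, noise = 0.02, seed = 8)$g2))
  v1 <- synth_viscosity_series(c(100, 200, 300), seed = 3)
  v2 <- synth_viscosity_series(c(100, 200, 300), seed = 3)
  expect_identical(v1$relative_viscosities, v2$relative_viscosities)
  s1 <- synth_saxs_curve(d, c(0.1, 0.5, 1), seed = 9)
  s2 <- synth_saxs_curve(d, c(0.1, 0.5, 1), seed = 9)
  expect_identical(s1$I, s2$I)
})

test_that("DLS generator carries the exact moment identities", {
  d <- schulz_dist(4.48, 0.3)
  corr <- synth_dls_correlogram(d, q = 0.0229, temperature = 298.15,
                                eta_s = 1.095, noise = 0, seed = 1)
  tr <- attr(corr, "truth")
  # intensity-weighted mean rate = q^2 kB T / (6 pi eta Rh_z), Rh_z from
  # the closed-form moment ratio
  rh_z <- intensity_avg_rh(d)
  d0 <- stokes_einstein_diffusion(rh_z, 298.15, 1.095)
  expect_equal(tr$mean_rate, d0 * 0.0229^2 * 1e12, tolerance = 1e-4)
  expect_equal(tr$rh_z, rh_z)
  # monodisperse truth gives mu ~ 0 through the analysis chain
  mono <- synth_dls_correlogram(schulz_dist(6.5, 0), noise = 0, seed = 1)
  cf <- cumulant_fit(mono, 1.5 / attr(mono, "truth")$mean_rate)
  expect_lt(cf$sigma_star, 0.02)
})

test_that("SAXS generator round-trips through the structure-factor ratio", {
  q <- exp(seq(log(0.06), log(2), length.out = 60))
  d <- schulz_dist(2.51, 0.475)
  ff <- synth_saxs_curve(d, q, concentration = 11, noise = 0, seed = 1)
  dense <- synth_saxs_curve(d, q, concentration = 200, structure = "theory",
                            noise = 0, seed = 1)
  sq <- experimental_structure_factor(dense, ff)
  expect_equal(sq$S, attr(dense, "truth")$s_q, tolerance = 1e-10)
  # phi -> 0 reduces to the plain form factor
  dilute <- synth_saxs_curve(d, q, concentration = 1e-6,
                             structure = "theory", noise = 0, seed = 1)
  plain <- synth_saxs_curve(d, q, concentration = 1e-6, structure = "none",
                            noise = 0, seed = 1)
  expect_equal(dilute$I, plain$I, tolerance = 1e-4)
})

test_that("NSE generator respects the echo-time windows", {
  curves <- synth_nse_set(2e-11, seed = 2)
  tr <- attr(curves, "truth")
  expect_true(all(vapply(curves, function(cv) max(cv$times), numeric(1))
                  <= 598))
  for (i in seq_along(curves)) {
    expect_lte(max(curves[[i]]$times), tr$tau_max[i])
    sl <- nse_initial_slope(curves[[i]])
    expect_equal(sl$D, tr$D[i], tolerance = 0.03)
  }
  # isf starts at ~1
  expect_equal(curves[[1]]$isf[1], 1, tolerance = 0.05)
})

test_that("viscosity generator enforces the divergence domain", {
  expect_error(synth_viscosity_series(c(100, 400), c_star = 360), "< c")
  clean <- synth_viscosity_series(c(60, 150, 250, 320), noise = 0, seed = 1)
  expect_equal(clean$relative_viscosities,
               arrest_powerlaw(c(60, 150, 250, 320), 360, 2.8))
})

test_that("ground truth serializes and regenerates identically", {
  gt <- ground_truth(seed = 12)
  path <- tempfile(fileext = ".json")
  write_ground_truth(gt, path)
  gt2 <- read_ground_truth(path)
  expect_equal(gt2$distribution$mean_radius, gt$distribution$mean_radius)
  expect_equal(gt2$interaction$stickiness_tau,
               gt$interaction$stickiness_tau)
  c1 <- synth_dls_correlogram(gt$distribution, noise = gt$noise,
                              seed = gt$seed)
  c2 <- synth_dls_correlogram(gt2$distribution, noise = gt2$noise,
                              seed = gt2$seed)
  expect_identical(c1$g2, c2$g2)
})
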