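test_that("scattering vector follows the Bragg geometry", {
  expect_equal(scattering_vector(120, 632.8, 1.33), 0.0229, tolerance = 2e-3)
  expect_equal(scattering_vector(90, 632.8, 1.33), 0.01868, tolerance = 1e-3)
  expect_equal(scattering_vector(1e-9, 632.8), 0, tolerance = 1e-10)
  expect_error(scattering_vector(0, 632.8))
  expect_error(scattering_vector(181, 632.8))
})

test_that("rate-to-diffusion conversion is unit-faithful", {
  expect_equal(rate_to_diffusion(0.01592, 0.0229), 3.04e-11,
               tolerance = 2e-3)
  expect_equal(rate_to_diffusion(1, 1, "per_s", "per_m"), 1)
  # diffusive scaling: quadrupled rate at doubled q gives the same D
  expect_equal(rate_to_diffusion(4 * 0.01592, 2 * 0.0229),
               rate_to_diffusion(0.01592, 0.0229))
})

test_that("Stokes-Einstein conversions anchor the reported radii", {
  expect_equal(stokes_einstein_radius(3.04e-11, 298.15, 1.095), 6.5,
               tolerance = 0.02)
  expect_equal(stokes_einstein_diffusion(150, 298.15, 0.89), 1.63e-12,
               tolerance = 0.01)
  # exact round trip both directions
  r <- 7.23
  expect_equal(stokes_einstein_radius(
    stokes_einstein_diffusion(r, 293, 1.2), 293, 1.2), r,
    tolerance = 1e-12)
})

test_that("cumulant fit recovers single-exponential and ensemble spreads", {
  # sigma* = 0 truth on clean data: mu ~ 0 (under noise the sqrt(mu)
  # estimator is positively biased by construction, so the clean case is
  # the meaningful zero test)
  mono <- synth_dls_correlogram(schulz_dist(6.5, 0), noise = 0, seed = 1)
  cf0 <- cumulant_fit(mono, 1.5 / attr(mono, "truth")$mean_rate)
  expect_lt(cf0$sigma_star, 0.02)
  expect_equal(cf0$rate, attr(mono, "truth")$mean_rate, tolerance = 0.01)
  # polydisperse ensemble: the oracle is the intensity-weighted rate spread
  d <- schulz_dist(4.48, 0.3)
  poly <- synth_dls_correlogram(d, noise = 0, seed = 1)
  tr <- attr(poly, "truth")
  expect_equal(tr$rate_spread, schulz_rate_spread(0.3), tolerance = 1e-3)
  cfp <- cumulant_fit(poly, 1.5 / tr$mean_rate)
  expect_equal(cfp$sigma_star, tr$rate_spread, tolerance = 0.02)
  expect_equal(cfp$rate, tr$mean_rate, tolerance = 0.01)
  # contrast rescaling leaves rate and sigma* untouched (identifiability)
  half <- synth_dls_correlogram(d, noise = 0, seed = 1, contrast = 0.45)
  cfh <- cumulant_fit(half, 1.5 / tr$mean_rate)
  expect_equal(cfh$rate, cfp$rate, tolerance = 1e-3)
  expect_equal(cfh$sigma_star, cfp$sigma_star, tolerance = 0.01)
  expect_error(cumulant_fit(poly, min(poly$lag) * 1.01), "10 points")
})

test_that("truncation scan flags plateaus on clean data only", {
  d <- schulz_dist(4.48, 0.3)
  clean <- synth_dls_correlogram(d, noise = 0, seed = 2)
  tr <- attr(clean, "truth")
  scan <- truncation_scan(clean, (1 / tr$mean_rate) * c(0.5, 0.8, 1, 1.3, 1.6, 2))
  expect_true(all(scan$plateau[!is.na(scan$plateau)]))
  expect_error(truncation_scan(clean, c(1, 2)), "3 truncation")
  # a weak slow mode inflates sigma* as the truncation window grows into
  # it, and the scan never settles into a clean plateau everywhere
  two <- synth_two_mode_correlogram(0.85, 5, 1, 2000, 0.8, noise = 0,
                                    seed = 3)
  scan2 <- truncation_scan(two, 5 * 1.8^(0:5))
  expect_gt(max(scan2$sigma_star), scan2$sigma_star[1])
  expect_true(any(!scan2$plateau, na.rm = TRUE))
})

test_that("single-exponential fit is exact on clean data, 2% under noise", {
  clean <- synth_dls_correlogram(schulz_dist(6.5, 0), noise = 0, seed = 1)
  f <- single_exponential_fit(clean)
  expect_equal(f$rate, attr(clean, "truth")$mean_rate, tolerance = 1e-6)
  expect_true(f$baseline >= 0.99 && f$baseline <= 1.02)
  rates <- vapply(1:20, function(s) {
    single_exponential_fit(
      synth_dls_correlogram(schulz_dist(6.5, 0), noise = 0.01,
                            seed = s))$rate
  }, numeric(1))
  expect_equal(mean(rates), attr(clean, "truth")$mean_rate,
               tolerance = 0.02)
})

test_that("Kd regression recovers the concentration coefficient", {
  conc <- c(2, 5, 10, 20, 35, 50)
  # constant diffusivity: Kd = 0 within confidence interval
  set.seed(4)
  d_const <- 3.04e-11 * (1 + rnorm(6, 0, 0.005))
  k0 <- kd_regression(conc, d_const)
  expect_true(k0$kd_ci[1] <= 0 && k0$kd_ci[2] >= 0)
  # synthetic Kd = -0.002 mL/mg
  kd_hat <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      dd <- 3.04e-11 * (1 - 0.002 * conc) * (1 + rnorm(6, 0, 0.005))
      kd_regression(conc, dd)$kd
    })
  }, numeric(1))
  expect_lt(abs(mean(kd_hat) - (-0.002)) / 0.002, 0.1)
  expect_error(kd_regression(c(0, 0, 0), rep(1e-11, 3)), "distinct")
})

test_that("two-mode stretched fit round-trips and flags degeneracies", {
  clean <- synth_two_mode_correlogram(0.5, 10, 1, 1e4, 0.66, noise = 0,
                                      seed = 5)
  f <- double_stretched_fit(clean)
  expect_equal(f$c_fast, 0.5, tolerance = 0.001)
  expect_equal(f$tau1, 10, tolerance = 0.01)
  expect_equal(f$alpha1, 1, tolerance = 0.005)
  expect_equal(f$tau2, 1e4, tolerance = 50)
  expect_equal(f$alpha2, 0.66, tolerance = 0.005)
  expect_false(f$mode_collapse)
  # pinning the fast exponent reproduces the same physics
  fp <- double_stretched_fit(clean, pin_alpha1 = TRUE)
  expect_equal(fp$tau2, 1e4, tolerance = 100)
  # single-mode input collapses the mode separation
  single <- synth_two_mode_correlogram(0.98, 10, 1, 40, 0.9, noise = 0.01,
                                       seed = 6)
  expect_warning(fs <- double_stretched_fit(single), "collapse")
  expect_true(fs$mode_collapse)
  expect_error(double_stretched_fit(
    synth_dls_correlogram(schulz_dist(5, 0), n_points = 20, lag_span = 2,
                          seed = 1)), "4 decades")
})

test_that("stretching exponents near the reported range are recoverable", {
  for (a2 in c(0.59, 0.75, 0.66)) {
    tm <- synth_two_mode_correlogram(0.6, 8, 1, 5e3, a2, noise = 0.01,
                                     seed = round(100 * a2))
    f <- double_stretched_fit(tm)
    expect_true(f$alpha2 >= 0.5 && f$alpha2 <= 0.8)
  }
})

test_that("KWW mean time follows (tau/alpha) Gamma(1/alpha)", {
  expect_equal(kww_mean_time(7, 1), 7)
  expect_equal(kww_mean_time(7, 0.5), 14)
  expect_equal(kww_mean_time(1, 2 / 3), 1.3293, tolerance = 1e-4)
  expect_error(kww_mean_time(1, 0))
})

test_that("NSE initial slope returns D(q) and handles mixed decays", {
  # pure exponential: exact recovery
  tt <- exp(seq(log(0.5), log(48), length.out = 30))
  q <- 0.8 # 1/nm
  d_true <- 2.5e-11
  rate <- d_true * (q * 1e9)^2 * 1e-9
  isf <- isf_curve(tt, exp(-rate * tt), rep(1e-4, 30), q)
  sl <- nse_initial_slope(isf)
  expect_equal(sl$D, d_true, tolerance = 1e-6)
  # bi-exponential: in the genuinely early-time window (rate * t << 1)
  # the slope returns the amplitude-weighted mean rate
  r1 <- 0.01; r2 <- 0.002; w1 <- 0.4
  tt2 <- exp(seq(log(0.2), log(45), length.out = 40))
  mix <- w1 * exp(-r1 * tt2) + (1 - w1) * exp(-r2 * tt2)
  isf2 <- isf_curve(tt2, mix, rep(1e-4, 40), q)
  sl2 <- nse_initial_slope(isf2, t_max = 20)
  rbar <- w1 * r1 + (1 - w1) * r2
  expect_equal(1 / sl2$tau_s, rbar, tolerance = 0.05)
  expect_error(nse_initial_slope(isf_curve(c(60, 70, 80, 90, 100),
                                           rep(0.5, 5), rep(1e-3, 5), q)),
               "t < t_max")
})

test_that("band-averaged diffusion uses inverse-variance weights", {
  flat <- data.frame(q = seq(1.8, 2.2, by = 0.1), D = rep(3e-11, 5))
  expect_equal(band_average_diffusion(flat, "high_q")$D, 3e-11)
  two <- data.frame(q = c(2, 2.1), D = c(1e-11, 2e-11), err = c(1e-12, 1e-11))
  m <- band_average_diffusion(two, c(1.9, 2.2))$D
  expect_lt(abs(m - 1e-11), abs(m - 2e-11)) # pulled to the precise point
  expect_equal(m, (1e-11 / 1e-24 + 2e-11 / 1e-22) / (1 / 1e-24 + 1 / 1e-22))
  expect_error(band_average_diffusion(flat, c(5, 6)), "band")
})

test_that("nonergodic correlograms are screened out", {
  ergodic <- synth_dls_correlogram(schulz_dist(6.5, 0), noise = 0.01,
                                   seed = 1)
  expect_false(is_nonergodic(ergodic))
  frozen <- synth_dls_correlogram(schulz_dist(6.5, 0), noise = 0.01,
                                  seed = 2, contrast = 0.1)
  expect_true(is_nonergodic(frozen))
})
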