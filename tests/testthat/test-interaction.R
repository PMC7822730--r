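test_that("Carnahan-Starling S(0) and Z match direct evaluation", {
  expect_equal(carnahan_starling_s0(0), 1)
  expect_equal(carnahan_starling_s0(0.3), 0.09760, tolerance = 1e-4)
  expect_equal(carnahan_starling_s0(0.5), 0.01754, tolerance = 1e-3)
  phi <- seq(0, 0.55, by = 0.01)
  expect_true(all(diff(carnahan_starling_s0(phi)) < 0))
  expect_error(carnahan_starling_s0(1))
  expect_equal(carnahan_starling_z(0), 1)
})

test_that("polydisperse hard-sphere S(0) has the right limits and trend", {
  expect_equal(polydisperse_hs_s0(0, schulz_dist(1, 0.3)), 1)
  # monodisperse limit reduces to Carnahan-Starling (within 2 percent)
  expect_equal(polydisperse_hs_s0(0.3, schulz_dist(1, 0.021), n_species = 60),
               carnahan_starling_s0(0.3), tolerance = 0.02)
  # polydispersity raises S(0) at every phi
  d <- schulz_dist(1, 0.3)
  for (phi in c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
    expect_gt(polydisperse_hs_s0(phi, d, n_species = 60),
              carnahan_starling_s0(phi))
  }
  # monotone decreasing in phi
  s0 <- vapply(c(0.05, 0.15, 0.25, 0.35, 0.45),
               function(p) polydisperse_hs_s0(p, d, n_species = 60),
               numeric(1))
  expect_true(all(diff(s0) < 0))
  # the Percus-Yevick route agrees with its own analytic monodisperse limit
  expect_equal(polydisperse_hs_s0(0.3, schulz_dist(1, 0.001), method = "py"),
               (1 - 0.3)^4 / (1 + 2 * 0.3)^2, tolerance = 1e-6)
  expect_error(polydisperse_hs_s0(0.3, schulz_dist(1, 0.65)))
})

test_that("sticky-hard-sphere Kd relation and its root behave", {
  expect_equal(shs_kd(0.5, 1), -0.796)
  expect_equal(shs_kd(1e9, 1), 1.454, tolerance = 1e-8)
  tau <- solve_tau_kd_zero()
  expect_equal(tau, 0.774, tolerance = 5e-4)
  expect_equal(shs_kd(tau, 1.7), 0, tolerance = 1e-10)
  # brute-force bisection oracle
  lo <- 0.3; hi <- 10
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (shs_kd(mid, 1) < 0) lo <- mid else hi <- mid
  }
  expect_equal(tau, (lo + hi) / 2, tolerance = 1e-10)
})

test_that("virial ratios follow the sticky-sphere and square-well forms", {
  tau <- solve_tau_kd_zero()
  expect_equal(b2_ratio_shs(tau), 0.677, tolerance = 5e-4)
  expect_equal(b2_ratio_shs(tau), 1 - 1.454 / (4 * 1.125), tolerance = 1e-12)
  expect_equal(b2_ratio_shs(1e12), 1, tolerance = 1e-10)
  expect_equal(b2_ratio_shs(0.25), 0)
  expect_equal(b2_ratio_square_well(0, 1.5), 1)
  expect_equal(b2_ratio_square_well(0.289, 1.25), 0.6806, tolerance = 1e-4)
  expect_equal(b2_ratio_square_well(log(2), 2^(1 / 3)), 0, tolerance = 1e-12)
})

test_that("short-time self-diffusion slope matches the stickiness", {
  expect_equal(shs_self_diffusion(0, 0.774), 1)
  slope <- (1 - shs_self_diffusion(0.1, 0.774)) / 0.1
  expect_equal(slope, 2.213, tolerance = 5e-4)
  slope_hs <- (1 - shs_self_diffusion(0.1, 1e12)) / 0.1
  expect_equal(slope_hs, 1.8315, tolerance = 1e-6)
  expect_warning(shs_self_diffusion(0.35, 0.774), "validity")
})

test_that("square-well S(q) reduces to PY and responds to attraction", {
  q <- seq(0.5, 20, by = 0.25)
  expect_equal(sw_structure_factor_mono(q, 0, 0.289, 1.25), rep(1, length(q)))
  expect_equal(sw_structure_factor_mono(q, 0.3, 0, 1.25),
               py_structure_factor(q, 0.3))
  s_py <- py_structure_factor(q, 0.3)
  # PY hard-sphere peak near q d ~ 2 pi at this density
  expect_gt(max(s_py), 1.4)
  expect_lt(max(s_py), 1.8)
  expect_equal(s_py[length(s_py)], 1, tolerance = 0.15)
  # attraction raises the q -> 0 limit at fixed phi
  for (phi in c(0.1, 0.3, 0.5)) {
    s0_hs <- sw_structure_factor_mono(1e-4, phi, 0, 1.25)
    s0_sw <- sw_structure_factor_mono(1e-4, phi, 0.289, 1.25)
    expect_gt(s0_sw, s0_hs)
  }
})

test_that("interaction model validates its physical ranges", {
  m <- interaction_model()
  expect_equal(m$stickiness_tau, 0.774)
  expect_error(interaction_model(well_width = 0.9))
  expect_error(interaction_model(voluminosity = 0.5))
})
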