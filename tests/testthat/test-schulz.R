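test_that("Schulz moments match closed form and quadrature", {
  d <- schulz_dist(1, 0.3)
  expect_equal(schulz_moment(d, 0), 1)
  expect_equal(schulz_moment(d, 1), 1)
  expect_equal(schulz_moment(d, 3), 1.28626, tolerance = 1e-4)
  # degenerate monodisperse limit
  expect_equal(schulz_moment(schulz_dist(2, 0), 4), 16)
  # agreement with adaptive quadrature of the density
  for (s in c(0.1, 0.3, 0.475)) {
    ds <- schulz_dist(1.7, s)
    for (n in 1:8) {
      expect_equal(schulz_moment(ds, n),
                   schulz_moment_quadrature(1.7, s, n),
                   tolerance = 1e-6)
    }
  }
  expect_error(schulz_moment(d, -1))
  expect_error(schulz_dist(1, 1.2))
})

test_that("Schulz density normalizes and matches moment machinery", {
  d <- schulz_dist(2.51, 0.475)
  nrm <- stats::integrate(function(r) schulz_density(d, r), 0, 20 * 2.51,
                          rel.tol = 1e-10)$value
  expect_equal(nrm, 1, tolerance = 1e-8)
})

test_that("intensity-averaged radii reproduce the reported dilute values", {
  d <- schulz_dist(2.51, 0.475)
  expect_equal(intensity_avg_rh(d), 5.35, tolerance = 0.005)
  expect_equal(intensity_avg_rg(d), 4.8, tolerance = 0.005)
  # moment-ratio definitions
  expect_equal(intensity_avg_rh(d),
               schulz_moment(d, 6) / schulz_moment(d, 5))
  expect_equal(intensity_avg_rg(d),
               sqrt(3 * schulz_moment(d, 8) / (5 * schulz_moment(d, 6))))
  expect_equal(intensity_avg_rh(schulz_dist(1, 0.3)), 1.45)
  expect_equal(intensity_avg_rg(schulz_dist(1, 0.3)), 1.227241,
               tolerance = 1e-6)
  # monodisperse limits
  expect_equal(intensity_avg_rh(schulz_dist(3, 0)), 3)
  expect_equal(intensity_avg_rg(schulz_dist(3, 0)), sqrt(3 / 5) * 3)
})

test_that("mean radius inversion from Rg is exact", {
  expect_equal(mean_radius_from_rg(0.475, 4.8), 2.51, tolerance = 0.005)
  expect_equal(mean_radius_from_rg(0, 1), sqrt(5 / 3), tolerance = 1e-10)
  # round trip at several polydispersities
  for (s in c(0, 0.1, 0.3, 0.475)) {
    rbar <- mean_radius_from_rg(s, 1.2276)
    expect_equal(intensity_avg_rg(schulz_dist(rbar, s)), 1.2276,
                 tolerance = 1e-10)
  }
  expect_error(mean_radius_from_rg(1.1, 1))
})

test_that("ellipsoid hydrodynamic radius matches the Oberbeck integral", {
  expect_equal(ellipsoid_hydro_radius(shape_model(1, 1)), 1)
  expect_equal(ellipsoid_hydro_radius(shape_model(2, 1)),
               sqrt(3) / log(2 + sqrt(3)), tolerance = 1e-10)
  expect_equal(ellipsoid_hydro_radius(shape_model(0.5, 1)),
               sqrt(0.75) / atan(sqrt(0.75) / 0.5), tolerance = 1e-10)
  for (p in c(0.3, 0.5, 0.9, 1.1, 2, 4)) {
    expect_equal(ellipsoid_hydro_radius(shape_model(p, 1)),
                 perrin_rh_numeric(p), tolerance = 1e-6)
  }
  # continuity at the sphere through the series branch
  expect_equal(ellipsoid_hydro_radius(shape_model(1 + 5e-5, 1)),
               perrin_rh_numeric(1 + 5e-5), tolerance = 1e-6)
})

test_that("ellipsoid gyration radius follows b sqrt((2+p^2)/5)", {
  expect_equal(ellipsoid_gyration_radius(shape_model(1, 1)), sqrt(3 / 5))
  expect_equal(ellipsoid_gyration_radius(shape_model(2, 1)), sqrt(6 / 5))
  expect_equal(ellipsoid_gyration_radius(shape_model(1e-6, 1)), sqrt(2 / 5),
               tolerance = 1e-6)
})

test_that("Rh/Rg map peaks at monodisperse spheres and matches anchors", {
  expect_equal(rh_rg_ratio_map(1, 0), sqrt(5 / 3), tolerance = 1e-10)
  expect_equal(rh_rg_ratio_map(1, 0.3), 1.45 / 1.227241, tolerance = 1e-5)
  expect_equal(rh_rg_ratio_map(2, 0),
               (sqrt(3) / log(2 + sqrt(3))) / sqrt(6 / 5), tolerance = 1e-10)
  # both nonsphericity and polydispersity reduce the ratio
  grid_p <- c(0.2, 0.5, 0.8, 1, 1.5, 2, 3, 5)
  grid_s <- c(0, 0.1, 0.2, 0.3, 0.45, 0.6)
  vals <- outer(grid_p, grid_s, Vectorize(rh_rg_ratio_map))
  expect_equal(max(vals), rh_rg_ratio_map(1, 0), tolerance = 1e-12)
  expect_true(all(vals[, -1] < sqrt(5 / 3)))
  expect_true(all(vals[grid_p != 1, 1] < sqrt(5 / 3)))
})

test_that("polydisperse form factor obeys sphere limits and Guinier", {
  r0 <- 2
  mono <- form_factor_model(schulz_dist(r0, 0), scale = 3, background = 0.1)
  v2 <- ((4 * pi / 3) * r0^3)^2
  expect_equal(polydisperse_form_intensity(mono, 1e-5), 3 * v2 + 0.1,
               tolerance = 1e-6)
  # first sphere form-factor null lands on the background
  expect_equal(polydisperse_form_intensity(mono, 4.493409457 / r0), 0.1,
               tolerance = 1e-6)
  expect_error(polydisperse_form_intensity(mono, numeric(0)))
  # Guinier slope of the polydisperse curve reproduces the averaged Rg
  d <- schulz_dist(2.51, 0.475)
  rg <- intensity_avg_rg(d)
  q <- seq(0.02, 0.5 / rg, length.out = 40)
  ii <- polydisperse_form_intensity(form_factor_model(d), q)
  slope <- stats::coef(stats::lm(log(ii) ~ I(q^2)))[[2]]
  expect_equal(sqrt(-3 * slope), rg, tolerance = 0.01)
})
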