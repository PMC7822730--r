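test_that("Guinier analysis recovers sphere and ensemble sizes", {
  q <- exp(seq(log(0.03), log(2), length.out = 100))
  # monodisperse sphere of radius R: Rg = sqrt(3/5) R
  mono <- synth_saxs_curve(schulz_dist(3, 0), q, noise = 0, seed = 1)
  expect_equal(guinier_rg(mono)$rg, sqrt(3 / 5) * 3, tolerance = 0.01)
  # broad Schulz ensemble at the tight-window invariant
  d <- schulz_dist(mean_radius_from_rg(0.475, 4.8), 0.475)
  poly <- synth_saxs_curve(d, q, noise = 0, seed = 2)
  expect_equal(guinier_rg(poly, qmax_rg = 0.5)$rg, 4.8, tolerance = 0.01)
  # default window keeps it within a few percent
  expect_equal(guinier_rg(poly)$rg, 4.8, tolerance = 0.04)
  # flat curve carries no size information
  flat <- scattering_curve(q, rep(2, 100), rep(0.01, 100))
  expect_error(guinier_rg(flat), "no usable")
  # a strong low-q upturn on top of a particle signal is an aggregation
  # signature
  base <- polydisperse_form_intensity(form_factor_model(schulz_dist(3, 0)),
                                      q)
  agg <- scattering_curve(q, base * (1 + 5 / (1 + (q / 0.02)^2)),
                          rep(1e-4 * base[1], 100))
  expect_error(guinier_rg(agg), "window|aggregat")
})

test_that("experimental structure factor inverts the synthetic forward model", {
  q <- exp(seq(log(0.05), log(2.5), length.out = 90))
  d <- schulz_dist(2.51, 0.475)
  inter <- interaction_model()
  ff <- synth_saxs_curve(d, q, concentration = 11, structure = "none",
                         noise = 0, seed = 1)
  dense <- synth_saxs_curve(d, q, concentration = 150, structure = "theory",
                            interaction = inter, noise = 0, seed = 2)
  s_true <- attr(dense, "truth")$s_q
  sq <- experimental_structure_factor(dense, ff)
  expect_equal(sq$S, s_true, tolerance = 1e-10)
  # the same-curve ratio is identically one
  self_sq <- experimental_structure_factor(ff, ff)
  expect_equal(self_sq$S, rep(1, nrow(self_sq)), tolerance = 1e-12)
  # with constant absolute intensity errors, the propagated S(q) error
  # blows up where the form factor is small (its minima)
  i0 <- polydisperse_form_intensity(form_factor_model(schulz_dist(2.51, 0.02)),
                                    q) + 1e-8
  abs_err <- rep(1e-5 * max(i0), length(q))
  ffn <- scattering_curve(q, i0, abs_err, concentration = 11)
  dn <- scattering_curve(q, i0 * 0.8 * 150 / 11, abs_err,
                         concentration = 150)
  sqe <- experimental_structure_factor(dn, ffn)
  i0_at <- stats::approx(q, i0, xout = sqe$q)$y
  expect_gt(stats::cor(log(sqe$err), -log(i0_at)), 0.9)
})

test_that("forward scattering averages the lowest-q points", {
  sq <- data.frame(q = 1:10 / 10, S = rep(0.3, 10))
  expect_equal(forward_scattering(sq)$s0, 0.3)
  expect_error(forward_scattering(sq, n_points = 11))
  expect_warning(
    forward_scattering(data.frame(q = 1:6 / 10,
                                  S = c(3, 0.5, 0.45, 0.44, 0.43, 0.42))),
    "upturn")
})

test_that("constrained form-factor fit recovers the polydispersity", {
  q <- exp(seq(log(0.05), log(3), length.out = 130))
  d <- schulz_dist(mean_radius_from_rg(0.475, 4.8), 0.475)
  clean <- synth_saxs_curve(d, q, concentration = 11, noise = 0,
                            seed = 1, scale = 2, background = 50)
  fit <- constrained_form_factor_fit(clean, 4.8)
  expect_equal(fit$sigma_star, 0.475, tolerance = 0.01)
  expect_equal(fit$mean_radius, 2.51, tolerance = 0.01)
  # the constraint is honored exactly by construction
  expect_equal(intensity_avg_rg(fit$model$distribution), 4.8,
               tolerance = 1e-9)
  # modest noise still identifies the width
  noisy <- synth_saxs_curve(d, q, concentration = 11, noise = 0.01,
                            seed = 5, scale = 2, background = 50)
  fitn <- constrained_form_factor_fit(noisy, 4.8)
  expect_equal(fitn$sigma_star, 0.475, tolerance = 0.03)
  expect_error(constrained_form_factor_fit(clean, 4.8, q_max = 0.06),
               "10 points")
})

test_that("synthetic S(0) falls with concentration for hard spheres", {
  q <- exp(seq(log(0.05), log(1.5), length.out = 70))
  d <- schulz_dist(2.51, 0.3)
  inter <- interaction_model(well_depth = 0, well_width = 1.25)
  ff <- synth_saxs_curve(d, q, concentration = 5, structure = "none",
                         noise = 0, seed = 1)
  s0s <- vapply(c(30, 90, 180, 270), function(cc) {
    cur <- synth_saxs_curve(d, q, concentration = cc, structure = "theory",
                            interaction = inter, noise = 0, seed = 2)
    forward_scattering(experimental_structure_factor(cur, ff))$s0
  }, numeric(1))
  expect_true(all(diff(s0s) < 0))
})
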