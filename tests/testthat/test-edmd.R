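test_that("quantile discretization reproduces the target polydispersity", {
  d <- schulz_dist(0.5, 0.3)
  r1 <- discretize_schulz(d, 10, 2000, seed = 42)
  r2 <- discretize_schulz(d, 10, 2000, seed = 42)
  expect_identical(r1, r2)
  expect_equal(length(r1), 2000L)
  expect_true(sd(r1) / mean(r1) >= 0.285 && sd(r1) / mean(r1) <= 0.30)
  # monodisperse and remainder handling
  expect_true(all(discretize_schulz(schulz_dist(1, 0), 5, 13) == 1))
  expect_equal(length(discretize_schulz(d, 10, 2003, seed = 1)), 2003L)
  # realized sigma* approaches the target from below as species increase
  for (ns in c(10, 20, 40)) {
    rr <- schulz_quantile_species(d, ns)
    s_hat <- sd(rep(rr, each = 10)) / mean(rr)
    expect_lt(abs(s_hat - 0.3) / 0.3, 0.05)
  }
})

test_that("box initialization is overlap-free at the exact volume fraction", {
  d <- schulz_dist(0.5, 0.3)
  radii <- discretize_schulz(d, 10, 200, seed = 3)
  for (phi in c(0.05, 0.5)) {
    box <- initialize_box(radii, phi, seed = 3)
    expect_equal(sum(4 * pi / 3 * radii^3) / box$box_length^3, phi,
                 tolerance = 1e-12)
    expect_identical(
      colloidcrowd:::cpp_count_overlaps(radii, box$positions,
                                        box$box_length), 0L)
    expect_equal(colSums(box$velocities), c(0, 0, 0), tolerance = 1e-10)
  }
})

test_that("hard-sphere dynamics conserve energy and momentum exactly", {
  radii <- rep(0.5, 128)
  box <- initialize_box(radii, 0.3, seed = 5)
  run <- run_edmd(box, square_well_spec(0, 0.25), 80)
  expect_lt(attr(run, "energy_drift"), 1e-10)
  expect_equal(colSums(run$velocities), c(0, 0, 0), tolerance = 1e-9)
  expect_identical(
    colloidcrowd:::cpp_count_overlaps(radii, run$positions,
                                      box$box_length), 0L)
  expect_equal(attr(run, "potential"), 0)
})

test_that("collision-virial pressure matches Carnahan-Starling", {
  radii <- rep(0.5, 500)
  box <- initialize_box(radii, 0.3, seed = 6)
  warm <- run_edmd(box, square_well_spec(0, 0.25), 100)
  run <- run_edmd(warm, square_well_spec(0, 0.25), 600)
  expect_equal(virial_pressure_z(run), carnahan_starling_z(0.3),
               tolerance = 0.03)
})

test_that("dilute square-well pressure reflects the second virial", {
  # B2*/B2(HS) from the low-density equation of state Z ~ 1 + B2 rho,
  # B2 rho = 4 phi B2*; the residual B3 contribution biases it up a few %
  radii <- rep(0.5, 400)
  box <- initialize_box(radii, 0.02, seed = 7)
  warm <- run_edmd(box, square_well_spec(0.289, 0.25), 300)
  run <- run_edmd(warm, square_well_spec(0.289, 0.25), 3000)
  b2_hat <- (virial_pressure_z(run) - 1) / (4 * 0.02)
  expect_equal(b2_hat, b2_ratio_square_well(0.289, 1.25), tolerance = 0.1)
})

test_that("a slow pair at the well edge stays bound", {
  # two particles inside the well, heading outward with radial kinetic
  # energy far below the depth: the exit attempt must bounce them back
  radii <- c(0.5, 0.5)
  pos <- rbind(c(5, 5, 5), c(6.1, 5, 5)) # separation 1.1 < 1.25 = well edge
  vel <- rbind(c(-0.05, 0, 0), c(0.05, 0, 0)) # mu vr^2/2 = 0.0025 << 0.289
  cfg <- structure(list(radii = radii, positions = pos, velocities = vel,
                        box_length = 12, phi = NA, time = 0),
                   class = "particle_config")
  out <- run_edmd(cfg, square_well_spec(0.289, 0.25), 3)
  d_after <- sqrt(sum((out$positions[1, ] - out$positions[2, ])^2))
  expect_lt(d_after, 1.25 + 1e-9)
  expect_equal(attr(out, "n_bonds"), 1)
  expect_lt(attr(out, "energy_drift"), 1e-10)
})

test_that("snapshot sampling decorrelates particle displacements", {
  radii <- rep(0.5, 128)
  box <- initialize_box(radii, 0.2, seed = 8)
  spec <- square_well_spec(0, 0.25)
  eq <- equilibrate(box, spec)
  snaps <- sample_configurations(eq, spec, n_samples = 3,
                                 decorrelation_events = 25)
  expect_length(snaps, 3)
  # a particle moves a nontrivial fraction of its diameter between samples
  disp <- sqrt(rowSums((snaps[[2]]$positions - snaps[[1]]$positions)^2))
  expect_gt(median(pmin(disp, box$box_length - disp)), 0.1)
  expect_warning(sample_configurations(box, spec, 1), "equilibrated")
})

test_that("effective structure factor limits: single particle, ideal gas", {
  one <- structure(list(radii = 0.5, positions = matrix(c(2, 2, 2), 1),
                        velocities = matrix(0, 1, 3), box_length = 6,
                        phi = NA, time = 0), class = "particle_config")
  sq1 <- effective_structure_factor(list(one), c(1.1, 2.2, 4.4))
  expect_equal(sq1$S, rep(1, nrow(sq1)), tolerance = 1e-9)
  # ideal gas: uncorrelated positions
  set.seed(9)
  gas <- lapply(1:40, function(i) {
    structure(list(radii = rep(0.5, 200),
                   positions = matrix(runif(600) * 8, 200, 3),
                   velocities = matrix(0, 200, 3), box_length = 8,
                   phi = NA, time = 0), class = "particle_config")
  })
  sqg <- effective_structure_factor(gas, seq(1, 6, by = 0.5))
  expect_equal(mean(sqg$S), 1, tolerance = 0.1)
  expect_error(effective_structure_factor(gas, 0.1), "2\\*pi/L")
})

test_that("low-q plateau estimator averages the five lowest points", {
  curve <- data.frame(q = 1:10, S = rep(0.2, 10))
  expect_equal(low_q_plateau_s0(curve)$s0, 0.2)
  expect_error(low_q_plateau_s0(data.frame(q = 1:3, S = 1:3)))
  curve2 <- data.frame(q = c(5, 1, 2, 4, 3, 6), S = c(9, 1, 2, 4, 3, 9))
  expect_equal(low_q_plateau_s0(curve2)$s0, mean(c(1, 2, 3, 4, 9)))
})

test_that("theory forward scattering agrees with simulation for a mixture", {
  d <- schulz_dist(0.5, 0.3)
  sim <- run_small_sim(1000, 0.3, 0, seed = 11, sigma_star = 0.3,
                       n_snapshots = 200, decorrelation = 20)
  L <- sim$box$box_length
  qs <- 2 * pi / L * sqrt(c(1, 2, 3, 4, 5, 6, 8, 9))
  sq <- effective_structure_factor(sim$snaps, qs)
  s0_sim <- low_q_plateau_s0(sq)$s0
  expect_equal(polydisperse_hs_s0(0.3, d), s0_sim, tolerance = 0.05)
})
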