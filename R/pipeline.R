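## Orchestration of the full analysis chain on a synthetic dataset with
## known ground truth: dilute characterization -> interaction -> crowded
## dynamics -> structure -> voluminosity. Each stage is isolated; a failing
## stage is reported and downstream stages that depend on it are skipped
## with the cause recorded.

#' Analysis configuration
#'
#' Defaults reproduce the working parameter set of the study system: a
#' weakly attractive polydisperse protein colloid with stickiness 0.774
#' (equivalently square well u = 0.289 kT, lambda = 1.25), size
#' polydispersity selectable between the DLS estimate (0.3) and the SAXS
#' fit (0.475), voluminosity 1.7 mL/g and arrest at 360 mg/mL.
#'
#' @param sigma_star Size polydispersity (default 0.3).
#' @param sigma_star_saxs Polydispersity used for the SAXS form-factor
#'   ground truth (default 0.475).
#' @param rg_nm Dilute radius of gyration constraint (nm, default 4.8).
#' @param rh_nm Dilute z-average hydrodynamic radius (nm, default 6.5).
#' @param mw_kda Average molar mass (kDa, default 180).
#' @param nu_eff Effective voluminosity (mL/g, default 1.7).
#' @param tau Stickiness (default 0.774).
#' @param u Square-well depth (kT, default 0.289).
#' @param lambda Reduced square-well range (default 1.25).
#' @param c_star Arrest concentration (mg/mL, default 360).
#' @param gamma Viscosity exponent (default 2.8).
#' @param D0 Dilute diffusion coefficient (m^2/s, default 3.04e-11).
#' @param noise Relative noise of the synthetic data (default 0.01).
#' @param seed Master seed.
#' @param n_particles Simulation size (default 256; structure-stage runs).
#' @param n_snapshots Simulation snapshots for S(q) (default 60).
#' @param run_simulation Include the simulation stage (default TRUE).
#' @return A named list of class \code{"analysis_config"}.
#' @export
analysis_config <- function(sigma_star = 0.3, sigma_star_saxs = 0.475,
                            rg_nm = 4.8, rh_nm = 6.5, mw_kda = 180,
                            nu_eff = 1.7, tau = 0.774, u = 0.289,
                            lambda = 1.25, c_star = 360, gamma = 2.8,
                            D0 = 3.04e-11, noise = 0.01, seed = 1L,
                            n_particles = 256L, n_snapshots = 60L,
                            run_simulation = TRUE) {
  structure(as.list(environment()), class = "analysis_config")
}

.stage <- function(report, name, expr) {
  out <- tryCatch(expr, error = function(e) {
    structure(list(error = conditionMessage(e)), class = "stage_error")
  })
  report$stages[[name]] <- out
  if (inherits(out, "stage_error")) {
    report$failed <- c(report$failed, name)
  }
  report
}

#' Run the full analysis chain on synthetic data
#'
#' Generates every input the analysis consumes from the configured ground
#' truth, then runs the complete chain: cumulant and truncation analysis of
#' dilute DLS; Guinier and constrained form-factor fitting of dilute SAXS
#' with the Rh/Rg shape map; Kd regression and the sticky-hard-sphere
#' chain (stickiness, virial ratio, self-diffusion slope, square-well
#' match); two-mode DLS and microrheology with the arrest power law; the
#' two voluminosity estimates; NSE band diffusion; and (optionally) the
#' square-well simulation with its effective structure factor and S(0).
#'
#' @param config An [analysis_config()].
#' @return A \code{"pipeline_report"}: list with \code{config},
#'   \code{stages} (per-stage results), \code{failed} (names of failed
#'   stages) and \code{summary} (data frame of headline quantities).
#' @export
run_full_pipeline <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  report <- list(config = config, stages = list(), failed = character(),
                 package_version = as.character(utils::packageVersion("colloidcrowd")))
  cfg <- config
  rbar_dls <- cfg$rh_nm /
    intensity_avg_rh(schulz_dist(1, cfg$sigma_star))
  dist_dls <- schulz_dist(rbar_dls, cfg$sigma_star)
  dist_saxs <- schulz_dist(mean_radius_from_rg(cfg$sigma_star_saxs, cfg$rg_nm),
                           cfg$sigma_star_saxs)
  inter <- interaction_model(cfg$tau, cfg$u, cfg$lambda, cfg$nu_eff)

  ## dilute DLS: cumulant analysis with a truncation scan
  report <- .stage(report, "dls_dilute", {
    corr <- synth_dls_correlogram(dist_dls, noise = cfg$noise,
                                  seed = cfg$seed)
    tr <- attr(corr, "truth")
    scan <- truncation_scan(corr, 1 / tr$mean_rate * c(0.5, 0.75, 1, 1.5, 2, 3))
    plateau <- scan[which(scan$plateau), , drop = FALSE]
    pick <- if (nrow(plateau) > 0) plateau[1, ] else scan[3, ]
    d0 <- rate_to_diffusion(pick$rate, corr$q)
    list(scan = scan, rate = pick$rate, sigma_star = pick$sigma_star,
         D0 = d0,
         rh_z = stokes_einstein_radius(d0, corr$temperature,
                                       corr$solvent_viscosity),
         truth = tr)
  })

  ## dilute SAXS: Guinier, constrained form-factor fit, shape-ratio map
  report <- .stage(report, "saxs_dilute", {
    q <- exp(seq(log(0.05), log(3), length.out = 120))
    curve <- synth_saxs_curve(dist_saxs, q, concentration = 11,
                              structure = "none", noise = cfg$noise,
                              seed = cfg$seed + 1)
    gn <- guinier_rg(curve)
    ff <- constrained_form_factor_fit(curve, gn$rg)
    rh_rg <- if (!inherits(report$stages$dls_dilute, "stage_error")) {
      report$stages$dls_dilute$rh_z / gn$rg
    } else NA_real_
    list(rg = gn$rg, sigma_star = ff$sigma_star,
         mean_radius = ff$mean_radius, rh_over_rg = rh_rg,
         sphere_ratio_max = rh_rg_ratio_map(1, 0))
  })

  ## interaction: Kd regression -> stickiness -> virial ratios
  report <- .stage(report, "interaction", {
    conc <- c(2, 5, 10, 20, 35, 50)
    kd_true <- shs_kd(cfg$tau, cfg$nu_eff) / 1000 # mL/mg
    dser <- vapply(seq_along(conc), function(i) {
      d_i <- cfg$D0 * (1 + kd_true * conc[i])
      withr::with_seed(cfg$seed + 10 + i,
                       d_i * (1 + stats::rnorm(1, 0, cfg$noise)))
    }, numeric(1))
    kd <- kd_regression(conc, dser, errors = cfg$noise * dser)
    tau_hat <- solve_tau_kd_zero()
    list(kd = kd$kd, kd_ci = kd$kd_ci, D0 = kd$D0,
         tau = tau_hat, b2_shs = b2_ratio_shs(tau_hat),
         b2_sw = b2_ratio_square_well(cfg$u, cfg$lambda),
         self_diffusion_slope = 1.8315 + 0.295 / round(tau_hat, 3))
  })

  ## crowded dynamics: two-mode DLS + microrheology + arrest power law
  report <- .stage(report, "crowded_dynamics", {
    conc <- c(88, 184, 280)
    alphas <- c(0.59, 0.75, 0.66)
    q <- 0.22
    tau0 <- 1 / (cfg$D0 * q^2 * 1e12) # us, dilute reference at this q
    two_mode <- lapply(seq_along(conc), function(i) {
      eta_r <- arrest_powerlaw(conc[i], cfg$c_star, cfg$gamma)
      tau_bar <- tau0 * eta_r
      # slow KWW time with the prescribed exponent and that mean time
      tau2 <- tau_bar * alphas[i] / gamma(1 / alphas[i])
      corr <- synth_two_mode_correlogram(
        0.6, tau1 = tau0, alpha1 = 1, tau2 = tau2, alpha2 = alphas[i],
        q = q, noise = cfg$noise, seed = cfg$seed + 20 + i)
      fit <- double_stretched_fit(corr)
      list(concentration = conc[i], fit = fit,
           tau_ratio = fit$tau_mean / tau0)
    })
    visc_conc <- c(50, 120, 190, 250, 300, 330, 345)
    series <- synth_viscosity_series(visc_conc, cfg$c_star, cfg$gamma,
                                     noise = 0.05, seed = cfg$seed + 30)
    arrest <- arrest_powerlaw_fit(series)
    list(two_mode = two_mode, arrest = arrest,
         tau_ratios = vapply(two_mode, `[[`, numeric(1), "tau_ratio"),
         eta_r_at_conc = arrest_powerlaw(conc, cfg$c_star, cfg$gamma))
  })

  ## voluminosity
  report <- .stage(report, "voluminosity", {
    c_arr <- if (!inherits(report$stages$crowded_dynamics, "stage_error")) {
      report$stages$crowded_dynamics$arrest$c_star
    } else cfg$c_star
    voluminosity_estimates(c_arr, schulz_dist(1, cfg$sigma_star),
                           cfg$rh_nm, cfg$mw_kda, chosen = cfg$nu_eff)
  })

  ## NSE: initial slopes and band averages
  report <- .stage(report, "nse", {
    curves <- synth_nse_set(0.6 * cfg$D0, noise = 0.005,
                            seed = cfg$seed + 40)
    slopes <- lapply(curves, nse_initial_slope)
    dq <- data.frame(q = vapply(slopes, `[[`, numeric(1), "q"),
                     D = vapply(slopes, `[[`, numeric(1), "D"))
    high_q <- band_average_diffusion(dq, "high_q")
    list(dq = dq, D_high_q = high_q$D,
         self_diffusion_check = shs_self_diffusion(0.2, cfg$tau))
  })

  ## structure: square-well simulation, effective S(q), S(0) vs theory
  if (cfg$run_simulation) {
    report <- .stage(report, "structure", {
      dist_sim <- schulz_dist(0.5, cfg$sigma_star) # mean diameter 1
      radii <- discretize_schulz(dist_sim, 10L, cfg$n_particles,
                                 seed = cfg$seed)
      box <- initialize_box(radii, 0.2, seed = cfg$seed)
      spec <- square_well_spec(cfg$u, cfg$lambda - 1)
      eq <- equilibrate(box, spec)
      snaps <- sample_configurations(eq, spec, n_samples = cfg$n_snapshots,
                                     decorrelation_events = 20)
      L <- box$box_length
      qs <- 2 * pi / L * sqrt(seq(1, 120, by = 2))
      sq <- effective_structure_factor(snaps, qs)
      s0 <- low_q_plateau_s0(sq)
      list(sq = sq, s0 = s0$s0, s0_se = s0$se,
           s0_theory_hs = polydisperse_hs_s0(0.2, dist_sim),
           s0_cs = carnahan_starling_s0(0.2))
    })
  }

  st <- report$stages
  gv <- function(stage, field) {
    if (!is.null(st[[stage]]) && !inherits(st[[stage]], "stage_error")) {
      st[[stage]][[field]]
    } else NA_real_
  }
  report$summary <- data.frame(
    quantity = c("stickiness_tau", "b2_ratio_shs", "b2_ratio_square_well",
                 "self_diffusion_slope", "sigma_star_dls", "rh_z_nm",
                 "rg_nm", "sigma_star_saxs", "c_star_mg_ml", "gamma",
                 "nu_packing_ml_g", "nu_hydro_ml_g", "nu_chosen_ml_g"),
    value = c(gv("interaction", "tau"), gv("interaction", "b2_shs"),
              gv("interaction", "b2_sw"),
              gv("interaction", "self_diffusion_slope"),
              gv("dls_dilute", "sigma_star"), gv("dls_dilute", "rh_z"),
              gv("saxs_dilute", "rg"), gv("saxs_dilute", "sigma_star"),
              if (!inherits(st$crowded_dynamics, "stage_error"))
                st$crowded_dynamics$arrest$c_star else NA_real_,
              if (!inherits(st$crowded_dynamics, "stage_error"))
                st$crowded_dynamics$arrest$gamma else NA_real_,
              gv("voluminosity", "nu_packing"),
              gv("voluminosity", "nu_hydro"),
              gv("voluminosity", "chosen")))
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Analysis chain report (seed", x$config$seed, ")\n")
  if (length(x$failed)) {
    cat("failed stages:", paste(x$failed, collapse = ", "), "\n")
  }
  print(x$summary, row.names = FALSE)
  invisible(x)
}
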