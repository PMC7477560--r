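# Time-scale and parameter calibration: the workflow that ties reduced DPD
# observables to real-unit reference statistics. The time scale tau can be
# fixed by matching particle velocities (tau = v_DPD/v_MD * r_C) or by
# matching diffusivities (tau = D_DPD * r_C^2 / D_MD); for the water model
# the two disagree by an order of magnitude unless the thermostat parameters
# (s, sigma, gamma) are tuned so that both statistics meet their targets.

#' Reference calibration targets
#'
#' The coarse-grained reference statistics of the fine-grained water system:
#' average particle speed and self-diffusivity of 4:1 molecular clouds.
#'
#' @param v_md Reference particle speed (A/ps; default 1.021).
#' @param D_md Reference diffusivity (A^2/ps; default 0.151).
#' @param reference_rdf Optional reference RDF curve (data frame r, g).
#' @return List of class `calibration_target`.
#' @export
calibration_target <- function(v_md = hg_constants()$v_md_real,
                               D_md = hg_constants()$D_md_real,
                               reference_rdf = NULL) {
  stopifnot(v_md > 0, D_md > 0)
  structure(list(v_md = v_md, D_md = D_md, reference_rdf = reference_rdf),
            class = "calibration_target")
}

#' Time scale from velocity matching
#'
#' tau = (v_DPD / v_MD) r_C, where v_DPD is the average bead speed in
#' reduced units and v_MD the reference particle speed in real units.
#'
#' @param v_dpd_reduced Average DPD bead speed (r_C/tau).
#' @param v_md_real Reference particle speed (A/ps).
#' @param r_c_real Cut-off radius in Angstrom.
#' @return tau in ps.
#' @export
#' @examples
#' timescale_from_velocity(sqrt(3), 1.021, 7.2)  # ~12.2 ps
timescale_from_velocity <- function(v_dpd_reduced, v_md_real, r_c_real) {
  args <- c(v_dpd_reduced, v_md_real, r_c_real)
  if (!all(is.finite(args)) || any(args <= 0))
    stop("all arguments must be positive")
  v_dpd_reduced / v_md_real * r_c_real
}

#' Time scale from diffusion matching
#'
#' tau = D_DPD r_C^2 / D_MD, from requiring D_DPD r_C^2 / tau = D_MD.
#'
#' @param D_dpd_reduced DPD diffusivity in reduced units (r_C^2/tau).
#' @param D_md_real Reference diffusivity (A^2/ps).
#' @param r_c_real Cut-off radius in Angstrom.
#' @return tau in ps.
#' @export
#' @examples
#' timescale_from_diffusion(0.332, 0.151, 7.2)  # ~113.98 ps
timescale_from_diffusion <- function(D_dpd_reduced, D_md_real, r_c_real) {
  args <- c(D_dpd_reduced, D_md_real, r_c_real)
  if (!all(is.finite(args)) || any(args <= 0))
    stop("all arguments must be positive")
  D_dpd_reduced * r_c_real^2 / D_md_real
}

#' Measure the calibration observables of one water simulation
#'
#' Runs a seeded pure-water DPD simulation and reports reduced diffusivity,
#' mean and RMS bead speed, and kinetic temperature.
#'
#' @param a Water-water repulsion coefficient.
#' @param gamma Friction; sigma is always derived via [fdt_sigma()].
#' @param s Dissipative weight exponent.
#' @param box_edge Cubic box edge (r_C).
#' @param seed Integer seed.
#' @param config An [integrator_config()].
#' @return List with `D`, `mean_speed`, `rms_speed`, `temperature`.
#' @export
measure_water_point <- function(a, gamma, s, box_edge = 10, seed,
                                config = integrator_config()) {
  ff <- dpd_forcefield(a, gamma = gamma, s = s)
  st <- init_water_state(box_edge, seed = seed)
  tr <- run_dpd(st, ff, config)
  vs <- velocity_stats(tr)
  list(D = diffusion_coefficient(tr)$D,
       mean_speed = vs$mean_speed, rms_speed = vs$rms_speed,
       temperature = kinetic_temperature(tr),
       trajectory = tr)
}

#' Parameter-space scan of the water model
#'
#' One seeded water simulation per grid point and seed, with sigma always
#' tied to gamma by the fluctuation-dissipation relation. Per point the scan
#' reports seed-averaged reduced diffusivity and speeds, the velocity-matched
#' time scale, and the real-unit diffusivity D_real = D_reduced r_C^2 / tau
#' that the time scale implies. Failed simulations are recorded as missing
#' and the scan continues.
#'
#' @param grid Data frame with columns `s`, `gamma`, `a`.
#' @param box_edge Cubic box edge (r_C).
#' @param seeds Integer vector of seeds (>= 1) per grid point.
#' @param config An [integrator_config()].
#' @param target A [calibration_target()].
#' @param r_c_real Cut-off radius in Angstrom.
#' @param speed `"rms"` (default) or `"mean"`: the speed statistic used for
#'   velocity matching.
#' @param verbose Print progress.
#' @return Data frame of class `scan_result`: the grid plus `sigma`, `D`,
#'   `mean_speed`, `rms_speed`, `temperature`, `tau`, `D_real`, `n_ok`.
#' @export
parameter_scan <- function(grid, box_edge = 10, seeds = 1:3,
                           config = integrator_config(),
                           target = calibration_target(),
                           r_c_real = hg_constants()$r_c_real,
                           speed = c("rms", "mean"), verbose = FALSE) {
  speed <- match.arg(speed)
  stopifnot(is.data.frame(grid), all(c("s", "gamma", "a") %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    runs <- lapply(seeds, function(sd) {
      tryCatch(measure_water_point(g$a, g$gamma, g$s, box_edge, seed = sd,
                                   config = config),
               error = function(e) NULL)
    })
    runs <- Filter(Negate(is.null), runs)
    if (verbose)
      message(sprintf("scan point s=%g gamma=%g a=%g: %d/%d runs ok",
                      g$s, g$gamma, g$a, length(runs), length(seeds)))
    if (!length(runs)) {
      return(data.frame(g, sigma = fdt_sigma(g$gamma), D = NA_real_,
                        mean_speed = NA_real_, rms_speed = NA_real_,
                        temperature = NA_real_, tau = NA_real_,
                        D_real = NA_real_, n_ok = 0L))
    }
    Dm <- mean(vapply(runs, `[[`, 0, "D"))
    ms <- mean(vapply(runs, `[[`, 0, "mean_speed"))
    rs <- mean(vapply(runs, `[[`, 0, "rms_speed"))
    tm <- mean(vapply(runs, `[[`, 0, "temperature"))
    v <- if (speed == "rms") rs else ms
    tau <- timescale_from_velocity(v, target$v_md, r_c_real)
    data.frame(g, sigma = fdt_sigma(g$gamma), D = Dm, mean_speed = ms,
               rms_speed = rs, temperature = tm, tau = tau,
               D_real = Dm * r_c_real^2 / tau, n_ok = length(runs))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Fit the water repulsion coefficient to a reference RDF
#'
#' Simulates each candidate repulsion coefficient (seed-averaged), scores it
#' by the unweighted least-squares distance between its water-water RDF and
#' the reference on the shared binning (up to `r_max`), and returns the
#' argmin with the full score table.
#'
#' @param reference_rdf Data frame with columns `r` and `g`.
#' @param candidate_a Numeric vector of candidate repulsion coefficients.
#' @param gamma,s Thermostat parameters used for all candidates.
#' @param box_edge Cubic box edge (r_C).
#' @param seeds Seeds averaged per candidate.
#' @param config An [integrator_config()].
#' @param r_max Score range (default 3 r_C).
#' @return List with `best_a`, `scores` (data frame a, objective) and
#'   `rdfs`.
#' @export
fit_repulsion_to_rdf <- function(reference_rdf, candidate_a, gamma = 4.5,
                                 s = 2, box_edge = 5, seeds = 1:3,
                                 config = integrator_config(),
                                 r_max = 3) {
  if (!length(candidate_a)) stop("empty candidate set")
  bw <- diff(reference_rdf$r[1:2])
  r_max <- min(r_max, box_edge / 2, max(reference_rdf$r) + bw / 2)
  sel_ref <- reference_rdf$r <= r_max
  curves <- list()
  objective <- vapply(candidate_a, function(a) {
    gs <- lapply(seeds, function(sd) {
      st <- init_water_state(box_edge, seed = sd)
      tr <- run_dpd(st, dpd_forcefield(a, gamma = gamma, s = s), config)
      rdf(tr, bin_width = bw, r_max = r_max)$g
    })
    g <- Reduce(`+`, gs) / length(gs)
    nb <- min(length(g), sum(sel_ref))
    g <- g[seq_len(nb)]
    curves[[as.character(a)]] <<- g
    sum((g - reference_rdf$g[which(sel_ref)[seq_len(nb)]])^2)
  }, 0)
  list(best_a = candidate_a[which.min(objective)],
       scores = data.frame(a = candidate_a, objective = objective),
       rdfs = curves)
}

#' Fit harmonic bonded parameters from reference samples
#'
#' Moment matching against the harmonic bath: rest value = sample mean,
#' stiffness k = kBT / sample variance. With `refine = TRUE` the initial
#' estimate is polished by simulating the corresponding two-bead (bond) or
#' three-bead (angle) model with the engine and iteratively rescaling k and
#' shifting the rest value until the simulated moments match the reference
#' samples — this absorbs the configurational-Jacobian bias that makes the
#' sampled distribution differ from the ideal Gaussian bath.
#'
#' @param samples Numeric vector of reference bond lengths (r_C) or angles
#'   (rad); at least 100 values.
#' @param type `"bond"` or `"angle"`.
#' @param kBT Thermal energy (default 1).
#' @param refine Polish by dimer/trimer simulation (default FALSE).
#' @param refine_iterations Refinement sweeps (default 2).
#' @param seed Seed for the refinement simulations.
#' @return List with `k`, `rest`, and (when refined) `history`.
#' @export
#' @examples
#' x <- generate_bonded_samples(3375, 0.62, n = 5000, seed = 1)
#' fit_bonded_parameters(x, "bond")
fit_bonded_parameters <- function(samples, type = c("bond", "angle"),
                                  kBT = 1, refine = FALSE,
                                  refine_iterations = 2, seed = 1) {
  type <- match.arg(type)
  if (length(samples) < 100)
    stop("need at least 100 reference samples")
  v <- var(samples)
  if (v == 0) stop("zero-variance samples cannot fix a finite stiffness")
  k <- kBT / v
  rest <- mean(samples)
  if (!refine) return(list(k = k, rest = rest))
  history <- data.frame(iteration = 0, k = k, rest = rest,
                        sim_mean = NA_real_, sim_var = NA_real_)
  for (it in seq_len(refine_iterations)) {
    sim <- .simulate_bonded_samples(k, rest, type, kBT, seed = seed + it)
    k <- k * var(sim) / v
    rest <- rest + (mean(samples) - mean(sim))
    history <- rbind(history,
                     data.frame(iteration = it, k = k, rest = rest,
                                sim_mean = mean(sim), sim_var = var(sim)))
  }
  list(k = k, rest = rest, history = history)
}

# Dimer/trimer immersed in an ideal thermostat bath: water beads with zero
# non-bonded repulsion but full friction/noise coupling. DPD forces are
# central, so an isolated oligomer's bending mode decouples from the
# pairwise thermostat at linear order; bath collisions thermalize it, and
# with no non-bonded potential the sampled geometry follows the exact bonded
# Boltzmann distribution (including the configurational Jacobian).
.simulate_bonded_samples <- function(k, rest, type, kBT = 1, seed = 1,
                                     production = 100000, save_every = 20,
                                     box_edge = 4) {
  if (type == "bond") {
    nc <- 2
    bonds <- data.frame(i = 1, j = 2, k_s = k, l0 = rest)
    angles <- NULL
  } else {
    nc <- 3
    bonds <- data.frame(i = c(1, 2), j = c(2, 3), k_s = 3375, l0 = 0.62)
    angles <- data.frame(i = 1, j = 2, k = 3, k_a = k, theta0 = rest)
  }
  n <- round(3 * box_edge^3)
  types <- c(rep("GalA", nc), rep("(H2O)4", n - nc))
  topo <- dpd_topology(types, bonds, angles,
                       chain_id = c(rep(1L, nc), rep(0L, n - nc)))
  set.seed(seed)
  pos <- matrix(runif(3 * n, 0, box_edge), n, 3)
  pos[seq_len(nc), 1] <- box_edge / 2 + (seq_len(nc) - 1) * 0.62
  pos[seq_len(nc), 2] <- box_edge / 2
  pos[seq_len(nc), 3] <- box_edge / 2
  masses <- unname(.BEAD_MASS[types])
  vel <- .maxwell_velocities(masses, kBT)
  st <- dpd_state(pos, vel, masses, types, box_edge = box_edge, seed = seed)
  # the calibrated high-friction thermostat decorrelates the stiff bonded
  # modes much faster than the conventional one, tightening the moments
  bath_ff <- dpd_forcefield(
    matrix(0, 3, 3, dimnames = list(names(.BEAD_MASS), names(.BEAD_MASS))),
    gamma = 23.53, s = 0.5, kBT = kBT)
  tr <- run_dpd(st, bath_ff,
                integrator_config(warmup = 2000, production = production,
                                  save_every = save_every),
                topology = topo)
  bd <- bonded_distributions(tr, topo)
  if (type == "bond") bd$bond_samples[[1]] else bd$angle_samples[[1]]
}

#' Time-scale calibration report
#'
#' Computes both time-scale estimators from one simulated water trajectory —
#' velocity matching and diffusion matching — and reports them with their
#' ratio. Agreement of the two (ratio near 1) indicates that both reference
#' statistics are met by the parameter set; with conventional parameters the
#' two differ by about an order of magnitude.
#'
#' @param trajectory A reduced-units water [dpd_trajectory()] with
#'   velocities.
#' @param target A [calibration_target()].
#' @param r_c_real Cut-off radius in Angstrom.
#' @param speed `"rms"` or `"mean"` speed statistic for velocity matching.
#' @return List of class `timescale_report` with `tau_velocity`,
#'   `tau_diffusion`, `ratio`, `v_dpd`, `D_dpd`, `D_real_velocity_matched`.
#' @export
calibration_report <- function(trajectory, target = calibration_target(),
                               r_c_real = hg_constants()$r_c_real,
                               speed = c("rms", "mean")) {
  speed <- match.arg(speed)
  vs <- velocity_stats(trajectory)
  v <- if (speed == "rms") vs$rms_speed else vs$mean_speed
  D <- diffusion_coefficient(trajectory)$D
  tau_v <- timescale_from_velocity(v, target$v_md, r_c_real)
  tau_d <- timescale_from_diffusion(D, target$D_md, r_c_real)
  structure(list(tau_velocity = tau_v, tau_diffusion = tau_d,
                 ratio = tau_d / tau_v, v_dpd = v, D_dpd = D,
                 D_real_velocity_matched = D * r_c_real^2 / tau_v,
                 speed_statistic = speed),
            class = "timescale_report")
}

#' @export
print.timescale_report <- function(x, ...) {
  cat("DPD time-scale calibration\n")
  cat(sprintf("  v_DPD (%s speed)        : %.4f r_C/tau\n",
              x$speed_statistic, x$v_dpd))
  cat(sprintf("  D_DPD                   : %.4f r_C^2/tau\n", x$D_dpd))
  cat(sprintf("  tau (velocity matching) : %.3f ps\n", x$tau_velocity))
  cat(sprintf("  tau (diffusion matching): %.3f ps\n", x$tau_diffusion))
  cat(sprintf("  ratio (diffusion/velocity): %.3f\n", x$ratio))
  cat(sprintf("  D in real units at the velocity-matched tau: %.4f A^2/ps\n",
              x$D_real_velocity_matched))
  invisible(x)
}
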