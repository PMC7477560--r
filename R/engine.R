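# R-facing surface of the DPD engine. Heavy loops live in src/dpd.cpp; these
# wrappers own validation, state/trajectory containers and the run protocol.

#' Simulation state
#'
#' Positions (wrapped into the periodic cube), velocities, per-bead masses
#' and types, plus the box edge and the seed driving the engine's Mersenne
#' Twister noise stream.
#'
#' @param positions N x 3 matrix of positions (r_C); wrapped on construction.
#' @param velocities N x 3 matrix of velocities (r_C/tau).
#' @param masses Per-bead masses (bead-mass units).
#' @param types Character vector of bead types.
#' @param box_edge Cubic box edge (r_C); must be at least twice the cut-off
#'   for the minimum-image convention to be valid.
#' @param seed Integer RNG seed.
#' @param cutoff Cut-off radius used for the box validity check.
#' @return Object of class `dpd_state`.
#' @export
dpd_state <- function(positions, velocities, masses, types, box_edge,
                      seed, cutoff = 1) {
  positions <- as.matrix(positions); velocities <- as.matrix(velocities)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, ncol(velocities) == 3,
            nrow(velocities) == n, length(masses) == n, length(types) == n)
  if (!all(is.finite(positions)) || !all(is.finite(velocities)))
    stop("positions and velocities must be finite")
  if (box_edge < 2 * cutoff)
    stop("box edge must be >= 2 * cutoff for minimum-image validity")
  if (any(masses <= 0)) stop("masses must be positive")
  structure(list(positions = positions %% box_edge, velocities = velocities,
                 masses = as.numeric(masses), types = types,
                 box_edge = box_edge, seed = as.integer(seed),
                 step_count = 0L),
            class = "dpd_state")
}

#' @export
print.dpd_state <- function(x, ...) {
  cat(sprintf("DPD state: %d beads in a %g^3 box, step %d, seed %d\n",
              nrow(x$positions), x$box_edge, x$step_count, x$seed))
  invisible(x)
}

#' Random water-box initial state
#'
#' Uniform random positions at the requested bead density and
#' Maxwell-Boltzmann velocities at `kBT` with zero total momentum.
#'
#' @param box_edge Cubic box edge (r_C).
#' @param density_number Beads per r_C^3 (default 3).
#' @param seed Integer seed.
#' @param kBT Thermal energy (reduced; default 1).
#' @return A [dpd_state()] of (H2O)4 beads.
#' @export
#' @examples
#' st <- init_water_state(5, seed = 1)
#' nrow(st$positions)  # 375
init_water_state <- function(box_edge, density_number = 3, seed, kBT = 1) {
  n <- round(density_number * box_edge^3)
  set.seed(seed)
  pos <- matrix(runif(3 * n, 0, box_edge), n, 3)
  masses <- rep(1, n)
  vel <- .maxwell_velocities(masses, kBT)
  dpd_state(pos, vel, masses, rep("(H2O)4", n), box_edge, seed = seed)
}

#' Integrator configuration
#'
#' Time step, velocity-prediction factor of the modified velocity-Verlet
#' scheme, cell-list refresh interval and the warm-up/production/saving
#' protocol.
#'
#' @param dt Time step (tau); default 0.001.
#' @param lambda Velocity-prediction factor (default 0.5).
#' @param cell_refresh Steps between cell-list rebuilds (default 8).
#' @param warmup Warm-up steps discarded before production (default 2000).
#' @param production Production steps (default 20000).
#' @param save_every Save a frame every this many production steps
#'   (default 200).
#' @return Object of class `integrator_config`.
#' @export
integrator_config <- function(dt = 0.001, lambda = 0.5, cell_refresh = 8,
                              warmup = 2000, production = 20000,
                              save_every = 200) {
  if (dt <= 0) stop("dt must be positive")
  if (cell_refresh < 1) stop("cell_refresh must be >= 1")
  if (save_every < 1) stop("save_every must be >= 1")
  if (warmup < 0 || production < 0)
    stop("warmup and production must be non-negative")
  structure(list(dt = dt, lambda = lambda, cell_refresh = cell_refresh,
                 warmup = as.integer(warmup),
                 production = as.integer(production),
                 save_every = as.integer(save_every)),
            class = "integrator_config")
}

#' Cell-list neighbour search
#'
#' Bins beads into cells no smaller than the cut-off and enumerates unique
#' candidate pairs from adjacent cells. With `filter = TRUE` (default) the
#' candidates are reduced to exactly the minimum-image pairs closer than the
#' cut-off; with `filter = FALSE` the raw (superset) candidate list is
#' returned, which is what the integrator re-filters at every step between
#' refreshes.
#'
#' @param positions N x 3 position matrix.
#' @param box_edge Cubic box edge; must be >= 2 * cutoff.
#' @param cutoff Pair cut-off distance.
#' @param filter Keep only pairs with minimum-image distance < cutoff.
#' @return Two-column integer matrix of bead index pairs (i < j, no
#'   duplicates, no self-pairs).
#' @export
build_cell_list <- function(positions, box_edge, cutoff = 1, filter = TRUE) {
  positions <- as.matrix(positions)
  if (box_edge < 2 * cutoff)
    stop("box edge must be >= 2 * cutoff")
  cpp_cell_pairs(positions %% box_edge, box_edge, cutoff, filter)
}

.topo_args <- function(topology) {
  if (is.null(topology)) {
    list(bond_i = integer(), bond_j = integer(), bond_ks = numeric(),
         bond_l0 = numeric(), ang_i = integer(), ang_j = integer(),
         ang_k = integer(), ang_ka = numeric(), ang_th0 = numeric())
  } else {
    list(bond_i = as.integer(topology$bonds$i),
         bond_j = as.integer(topology$bonds$j),
         bond_ks = as.numeric(topology$bonds$k_s),
         bond_l0 = as.numeric(topology$bonds$l0),
         ang_i = as.integer(topology$angles$i),
         ang_j = as.integer(topology$angles$j),
         ang_k = as.integer(topology$angles$k),
         ang_ka = as.numeric(topology$angles$k_a),
         ang_th0 = as.numeric(topology$angles$theta0))
  }
}

.type_index <- function(types, forcefield) {
  idx <- match(types, rownames(forcefield$repulsion))
  if (anyNA(idx))
    stop("state contains bead types missing from the force field: ",
         paste(unique(types[is.na(idx)]), collapse = ", "))
  as.integer(idx)
}

#' Non-bonded DPD pair forces over an explicit pair list
#'
#' Accumulates the conservative, dissipative and random contributions for
#' every listed pair inside the cut-off (pairs farther out contribute zero).
#' The symmetric per-pair noise xi is supplied by the caller, making the
#' evaluation fully deterministic; coincident beads (r = 0) contribute a zero
#' force and are counted as overlap events.
#'
#' @param state A [dpd_state()].
#' @param forcefield A [dpd_forcefield()].
#' @param pairs Two-column integer matrix of bead pairs.
#' @param dt Time step entering the random force as dt^(-1/2).
#' @param noise Numeric vector, one symmetric unit-variance draw per pair
#'   (default: standard normal draws from R's RNG).
#' @return List with `forces` (N x 3) and `n_overlap`.
#' @export
pair_forces <- function(state, forcefield, pairs, dt = 0.001,
                        noise = rnorm(nrow(pairs))) {
  stopifnot(inherits(state, "dpd_state"), inherits(forcefield, "dpd_forcefield"))
  if (length(noise) != nrow(pairs))
    stop("need one noise draw per pair")
  cpp_pair_forces(state$positions, state$velocities,
                  matrix(as.integer(pairs), ncol = 2),
                  .type_index(state$types, forcefield),
                  forcefield$repulsion, forcefield$sigma, forcefield$gamma,
                  forcefield$s, forcefield$cutoff, state$box_edge, dt,
                  as.numeric(noise))
}

#' Harmonic bonded forces
#'
#' Distance bonds pull bead pairs toward their rest length; angular bonds
#' apply the analytic gradient of the harmonic angle energy at the central
#' bead, distributed so that the net force and net torque of every term
#' vanish. Near-collinear triplets are clamped and counted as degenerate
#' events.
#'
#' @param state A [dpd_state()].
#' @param topology A [dpd_topology()].
#' @return List with `forces` (N x 3), `energy` and `n_degenerate`.
#' @export
bonded_forces <- function(state, topology) {
  stopifnot(inherits(state, "dpd_state"), inherits(topology, "dpd_topology"))
  ta <- .topo_args(topology)
  do.call(cpp_bonded_forces, c(list(pos = state$positions,
                                    box = state$box_edge), ta))
}

#' Conservative + bonded potential energy of a configuration
#'
#' @param state A [dpd_state()].
#' @param forcefield A [dpd_forcefield()].
#' @param topology Optional [dpd_topology()].
#' @return Potential energy (kBT): soft-repulsion pair energy
#'   a_ij (1 - r/r_C)^2 r_C / 2 plus harmonic bond and angle terms.
#' @export
potential_energy <- function(state, forcefield, topology = NULL) {
  ta <- .topo_args(topology)
  do.call(cpp_potential_energy,
          c(list(pos = state$positions,
                 type = .type_index(state$types, forcefield),
                 amat = forcefield$repulsion, cutoff = forcefield$cutoff,
                 box = state$box_edge), ta))
}

#' Run a DPD simulation
#'
#' Modified velocity-Verlet integration with the pairwise DPD thermostat:
#' positions advance with the current force, a predicted velocity (factor
#' `lambda`) enters the dissipative force, forces are recomputed once per
#' step and velocities corrected with the trapezoidal average. The candidate
#' cell list is rebuilt every `cell_refresh` steps and re-filtered by
#' distance at every evaluation. Warm-up frames are discarded; production
#' positions, velocities and unwrapped positions are saved every
#' `save_every` steps. The same seed reproduces the trajectory bit for bit.
#'
#' @param state Initial [dpd_state()].
#' @param forcefield A [dpd_forcefield()].
#' @param config An [integrator_config()].
#' @param topology Optional [dpd_topology()] for bonded systems.
#' @param verbose Print a one-line provenance log (seed, parameters).
#' @return A [dpd_trajectory()] carrying positions, velocities, unwrapped
#'   positions, frame metadata and the final state in
#'   `attr(, "final_state")`.
#' @export
#' @examples
#' st <- init_water_state(5, seed = 1)
#' ff <- dpd_forcefield(25, gamma = 4.5, s = 2)
#' cfg <- integrator_config(warmup = 50, production = 100, save_every = 50)
#' tr <- run_dpd(st, ff, cfg)
#' dim(tr$positions)  # 375 x 3 x 2
run_dpd <- function(state, forcefield, config = integrator_config(),
                    topology = NULL, verbose = FALSE) {
  stopifnot(inherits(state, "dpd_state"),
            inherits(forcefield, "dpd_forcefield"),
            inherits(config, "integrator_config"))
  if (!is.null(topology) && length(topology$types) != nrow(state$positions))
    stop("topology and state disagree on bead count")
  ta <- .topo_args(topology)
  if (verbose)
    message(sprintf(
      "DPD run: %d beads, box %g, dt %g, %d+%d steps, seed %d, sigma %g, gamma %g, s %g",
      nrow(state$positions), state$box_edge, config$dt, config$warmup,
      config$production, state$seed, forcefield$sigma, forcefield$gamma,
      forcefield$s))
  res <- do.call(cpp_run_dpd, c(
    list(pos0 = state$positions, vel0 = state$velocities,
         mass = state$masses, type = .type_index(state$types, forcefield),
         amat = forcefield$repulsion, sigma = forcefield$sigma,
         gamma_ = forcefield$gamma, s = forcefield$s,
         cutoff = forcefield$cutoff, box = state$box_edge,
         dt = config$dt, lambda = config$lambda,
         warmup = config$warmup, production = config$production,
         save_every = config$save_every, cell_refresh = config$cell_refresh,
         seed = state$seed), ta))
  final_state <- state
  final_state$positions <- res$final_positions
  final_state$velocities <- res$final_velocities
  final_state$step_count <- state$step_count + config$warmup +
    config$production
  traj <- dpd_trajectory(
    positions = res$positions, velocities = res$velocities,
    unwrapped = res$unwrapped, box_edge = state$box_edge,
    frame_interval = config$dt * config$save_every, units = "reduced",
    types = state$types, masses = state$masses,
    metadata = list(seed = state$seed, dt = config$dt,
                    warmup = config$warmup, production = config$production,
                    save_every = config$save_every,
                    sigma = forcefield$sigma, gamma = forcefield$gamma,
                    s = forcefield$s, n_overlap = res$n_overlap,
                    n_degenerate = res$n_degenerate))
  attr(traj, "final_state") <- final_state
  traj
}

#' Advance a state by single integration steps
#'
#' Convenience wrapper over the engine loop for stepwise inspection: runs
#' `n_steps` modified velocity-Verlet steps and returns the updated state.
#'
#' @inheritParams run_dpd
#' @param n_steps Number of steps (default 1).
#' @param dt,lambda,cell_refresh As in [integrator_config()].
#' @return The advanced [dpd_state()] with `$forces` attached.
#' @export
dpd_step <- function(state, forcefield, topology = NULL, n_steps = 1,
                     dt = 0.001, lambda = 0.5, cell_refresh = 8) {
  ta <- .topo_args(topology)
  res <- do.call(cpp_run_dpd, c(
    list(pos0 = state$positions, vel0 = state$velocities,
         mass = state$masses, type = .type_index(state$types, forcefield),
         amat = forcefield$repulsion, sigma = forcefield$sigma,
         gamma_ = forcefield$gamma, s = forcefield$s,
         cutoff = forcefield$cutoff, box = state$box_edge,
         dt = dt, lambda = lambda, warmup = 0L,
         production = as.integer(n_steps), save_every = as.integer(n_steps),
         cell_refresh = cell_refresh,
         seed = state$seed + state$step_count), ta))
  out <- state
  out$positions <- res$final_positions
  out$velocities <- res$final_velocities
  out$step_count <- state$step_count + as.integer(n_steps)
  out$forces <- res$final_forces
  out
}
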