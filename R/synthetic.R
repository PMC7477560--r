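# Synthetic fixture generators. These emulate the statistics the
# coarse-graining and calibration stages consume from fine-grained MD
# trajectories — diffusive motion with thermal velocities in a periodic box —
# without being a water model: positions follow overdamped Brownian motion
# and velocities are Maxwell-Boltzmann draws, with the ground truth recorded
# in the trajectory metadata for recovery tests.

.KB_J_PER_K <- 1.380649e-23
.SPC_WATER_MASS_KG <- 2.99151e-26   # one water molecule

#' Generate a Brownian pseudo-water trajectory
#'
#' Molecules perform independent periodic Brownian motion with per-axis
#' per-step displacement variance 2 D dt; velocities are redrawn from the
#' Maxwell-Boltzmann distribution at `temperature` each frame. The default
#' molecular diffusivity of 0.6 A^2/ps puts the diffusivity of 4:1
#' coarse-grained clouds near the 0.151 A^2/ps regime of the reference
#' system. Deterministic under `seed`; the ground truth is stored in the
#' metadata.
#'
#' @param n_molecules Number of molecules (default 967).
#' @param box_edge Periodic cubic box edge in Angstrom (default 31.036).
#' @param D Target self-diffusivity in A^2/ps (default 0.6).
#' @param temperature Temperature in K for the velocities (default 298).
#' @param mass Molecule mass in kg (default: one water molecule).
#' @param frame_interval Time between frames in ps (default 2).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return A [dpd_trajectory()] in real units (Angstrom, ps) with unwrapped
#'   coordinates and metadata `ground_truth_D`.
#' @export
#' @examples
#' tr <- generate_brownian_water(n_frames = 10, seed = 1)
#' tr$metadata$ground_truth_D
generate_brownian_water <- function(n_molecules = 967, box_edge = 31.036,
                                    D = 0.6, temperature = 298,
                                    mass = .SPC_WATER_MASS_KG,
                                    frame_interval = 2, n_frames = 100,
                                    seed) {
  stopifnot(n_molecules > 0, box_edge > 0, D >= 0, temperature > 0,
            mass > 0, frame_interval > 0, n_frames > 0)
  set.seed(seed)
  n <- n_molecules
  pos <- array(NA_real_, c(n, 3, n_frames))
  unw <- array(NA_real_, c(n, 3, n_frames))
  vel <- array(NA_real_, c(n, 3, n_frames))
  # A/ps from m/s: 1 m/s = 0.01 A/ps
  v_sd <- sqrt(.KB_J_PER_K * temperature / mass) * 0.01
  x <- matrix(runif(3 * n, 0, box_edge), n, 3)
  u <- x
  step_sd <- sqrt(2 * D * frame_interval)
  for (f in seq_len(n_frames)) {
    if (f > 1) {
      dx <- matrix(rnorm(3 * n, sd = step_sd), n, 3)
      u <- u + dx
      x <- (x + dx) %% box_edge
    }
    pos[, , f] <- x
    unw[, , f] <- u
    vel[, , f] <- matrix(rnorm(3 * n, sd = v_sd), n, 3)
  }
  dpd_trajectory(pos, velocities = vel, unwrapped = unw,
                 box_edge = box_edge, frame_interval = frame_interval,
                 units = "real", types = rep("H2O", n),
                 masses = rep(1, n),
                 metadata = list(generator = "brownian_water",
                                 ground_truth_D = D,
                                 temperature_K = temperature,
                                 mass_kg = mass, seed = seed))
}

#' Generate harmonic-bath samples for bonded-parameter fitting
#'
#' Gaussian samples with mean `rest` and variance `kBT / k` — the
#' small-oscillation statistics of a harmonic bond or angle at stiffness
#' `k`.
#'
#' @param k Stiffness (> 0), in kBT/r_C^2 (bonds) or kBT/rad^2 (angles).
#' @param rest Rest value (length in r_C or angle in rad).
#' @param kBT Thermal energy (default 1).
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Numeric vector with attributes `k`, `rest`, `kBT`.
#' @export
generate_bonded_samples <- function(k, rest, kBT = 1, n, seed) {
  stopifnot(k > 0, n >= 1, kBT > 0)
  set.seed(seed)
  out <- rnorm(n, mean = rest, sd = sqrt(kBT / k))
  attributes(out) <- list(k = k, rest = rest, kBT = kBT)
  out
}

#' Generate a simple cubic lattice frame
#'
#' `n_per_axis`^3 particles on a simple cubic lattice in a periodic box of
#' edge `spacing * n_per_axis` — an exact-geometry fixture for cell-list and
#' RDF oracles (the RDF peaks at the spacing with 6 nearest neighbours).
#'
#' @param spacing Lattice spacing (> 0).
#' @param n_per_axis Sites per axis.
#' @return A single-frame [dpd_trajectory()].
#' @export
#' @examples
#' fr <- generate_lattice(1, 3)
#' dim(fr$positions)  # 27 x 3 x 1
generate_lattice <- function(spacing, n_per_axis) {
  stopifnot(spacing > 0, n_per_axis >= 1)
  g <- (seq_len(n_per_axis) - 1) * spacing
  pos <- as.matrix(expand.grid(x = g, y = g, z = g))
  dimnames(pos) <- NULL
  arr <- array(pos, c(nrow(pos), 3, 1))
  dpd_trajectory(arr, box_edge = spacing * n_per_axis, frame_interval = 1,
                 units = "reduced",
                 metadata = list(generator = "lattice", spacing = spacing))
}
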