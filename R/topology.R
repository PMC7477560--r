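# Bead types, bonded/non-bonded parameter tables, and system builders.
# The three bead species are (H2O)4 (four water molecules), GalA (protonated
# galacturonic acid) and GalA(-) (deprotonated). Parameter values are the
# published MD-derived DPD coefficients for this system; rest lengths use the
# r_C column (1 r_C = 7.2 A) and rest angles the radian column.

.BEAD_TYPES <- c("(H2O)4", "GalA(-)", "GalA")

.BEAD_MASS <- c("(H2O)4" = 1.0, "GalA(-)" = 2.609, "GalA" = 2.623)

#' Bead types of the homogalacturonan/water model
#'
#' @return Data frame with bead type names and reduced masses (in units of
#'   the (H2O)4 bead mass).
#' @export
#' @examples
#' bead_types()
bead_types <- function() {
  data.frame(type = .BEAD_TYPES, mass = unname(.BEAD_MASS[.BEAD_TYPES]),
             stringsAsFactors = FALSE)
}

.check_type <- function(type) {
  bad <- setdiff(type, .BEAD_TYPES)
  if (length(bad))
    stop("unknown bead type(s): ", paste(bad, collapse = ", "),
         " (registered: ", paste(.BEAD_TYPES, collapse = ", "), ")")
  type
}

#' Conservative repulsion coefficients a_ij
#'
#' The MD-derived conservative force coefficients (kBT/r_C) for all pairs of
#' the three bead species. Repulsion grows with the charge of the pair:
#' GalA(-) self-repulsion (100) is the strongest, water-water (50) the
#' calibrated reference.
#'
#' @return Symmetric named 3x3 matrix.
#' @export
#' @examples
#' repulsion_table()["GalA", "GalA(-)"]  # 65
repulsion_table <- function() {
  a <- matrix(c(50.0, 75.0, 67.0,
                75.0, 100.0, 65.0,
                67.0, 65.0, 58.5), 3, 3, byrow = TRUE,
              dimnames = list(.BEAD_TYPES, .BEAD_TYPES))
  a
}

#' @rdname repulsion_table
#' @param type_a,type_b Bead type names.
#' @return `pair_repulsion()`: the scalar a_ij for one (unordered) type pair.
#' @export
pair_repulsion <- function(type_a, type_b) {
  .check_type(c(type_a, type_b))
  repulsion_table()[type_a, type_b]
}

# bonded tables keyed by sorted type sequence
.BOND_TABLE <- data.frame(
  key = c("GalA(-)|GalA(-)", "GalA(-)|GalA", "GalA|GalA"),
  k_s = c(2700.0, 2920.0, 3375.0),
  l0  = c(0.63, 0.63, 0.62),
  stringsAsFactors = FALSE
)

.bond_key <- function(a, b) {
  paste(sort(c(a, b), decreasing = TRUE, method = "radix"), collapse = "|")
}
.angle_key <- function(a, b, c) {
  outer <- sort(c(a, c), decreasing = TRUE, method = "radix")
  paste(c(outer[1], b, outer[2]), collapse = "|")
}

# angle terms keyed canonically: central type fixed, outer pair sorted
.ANGLE_TABLE <- local({
  triplets <- list(
    list(c("GalA(-)", "GalA(-)", "GalA(-)"), 17.0, 2.81),
    list(c("GalA", "GalA(-)", "GalA(-)"),    25.0, 2.79),
    list(c("GalA(-)", "GalA", "GalA(-)"),    26.0, 2.76),
    list(c("GalA", "GalA", "GalA(-)"),       32.0, 2.77),
    list(c("GalA", "GalA(-)", "GalA"),       24.0, 2.82),
    list(c("GalA", "GalA", "GalA"),          29.0, 2.83))
  data.frame(
    key = vapply(triplets, function(t) .angle_key(t[[1]][1], t[[1]][2],
                                                  t[[1]][3]), ""),
    k_a = vapply(triplets, `[[`, 0, 2),
    theta0 = vapply(triplets, `[[`, 0, 3),
    stringsAsFactors = FALSE)
})

#' Bonded-interaction parameter lookups
#'
#' Harmonic distance-bond stiffness k_S (kBT/r_C^2) with rest length l0 (r_C)
#' and angular-bond stiffness k_A (kBT/rad^2) with rest angle theta0 (rad),
#' by bead-type sequence. Lookups are invariant under reversing the sequence;
#' only combinations that occur along a homogalacturonan backbone are
#' defined.
#'
#' @param type_a,type_b,type_c Bead type names (the angle is at `type_b`).
#' @return Named list: `k_s` and `l0` for bonds; `k_a` and `theta0` for
#'   angles.
#' @export
#' @examples
#' bond_params("GalA", "GalA")              # k_s = 3375, l0 = 0.62
#' angle_params("GalA", "GalA", "GalA")     # k_a = 29, theta0 = 2.83
bond_params <- function(type_a, type_b) {
  .check_type(c(type_a, type_b))
  row <- .BOND_TABLE[.BOND_TABLE$key == .bond_key(type_a, type_b), ]
  if (nrow(row) != 1)
    stop("no distance-bond parameters for pair ", type_a, " - ", type_b)
  list(k_s = row$k_s, l0 = row$l0)
}

#' @rdname bond_params
#' @export
angle_params <- function(type_a, type_b, type_c) {
  .check_type(c(type_a, type_b, type_c))
  row <- .ANGLE_TABLE[.ANGLE_TABLE$key == .angle_key(type_a, type_b, type_c), ]
  if (nrow(row) != 1)
    stop("no angular-bond parameters for triplet ",
         type_a, " - ", type_b, " - ", type_c)
  list(k_a = row$k_a, theta0 = row$theta0)
}

.pattern_types <- function(n_units, pattern) {
  switch(pattern,
    "all-protonated"   = rep("GalA", n_units),
    "all-deprotonated" = rep("GalA(-)", n_units),
    "alternating"      = rep(c("GalA(-)", "GalA"), length.out = n_units),
    "alternating-pairs" = rep(c("GalA(-)", "GalA(-)", "GalA", "GalA"),
                              length.out = n_units),
    stop("unknown protonation pattern: ", pattern)
  )
}

#' System topology
#'
#' @param types Character vector of bead types, one per bead.
#' @param bonds Data frame with columns `i`, `j`, `k_s`, `l0` (may be empty).
#' @param angles Data frame with columns `i`, `j`, `k`, `k_a`, `theta0`
#'   (angle at `j`).
#' @param chain_id Integer chain membership per bead (0 = unbonded solvent).
#' @return Object of class `dpd_topology`.
#' @export
dpd_topology <- function(types, bonds = NULL, angles = NULL,
                         chain_id = rep(0L, length(types))) {
  .check_type(unique(types))
  n <- length(types)
  empty_bonds <- data.frame(i = integer(), j = integer(), k_s = numeric(),
                            l0 = numeric())
  empty_angles <- data.frame(i = integer(), j = integer(), k = integer(),
                             k_a = numeric(), theta0 = numeric())
  if (is.null(bonds) || nrow(bonds) == 0) bonds <- empty_bonds
  if (is.null(angles) || nrow(angles) == 0) angles <- empty_angles
  idx <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k)
  if (length(idx) && (any(idx < 1) || any(idx > n)))
    stop("bond/angle indices out of range")
  if (nrow(bonds) && any(bonds$i == bonds$j))
    stop("bonds must reference distinct beads")
  if (nrow(angles) && any(angles$i == angles$j | angles$j == angles$k |
                          angles$i == angles$k))
    stop("angles must reference three distinct beads")
  structure(list(types = types, masses = unname(.BEAD_MASS[types]),
                 bonds = bonds, angles = angles,
                 chain_id = as.integer(chain_id)),
            class = "dpd_topology")
}

#' @export
print.dpd_topology <- function(x, ...) {
  cat(sprintf("DPD topology: %d beads (%s), %d bonds, %d angles, %d chain(s)\n",
              length(x$types),
              paste(sprintf("%d %s", table(x$types)[unique(x$types)],
                            unique(x$types)), collapse = ", "),
              nrow(x$bonds), nrow(x$angles),
              length(setdiff(unique(x$chain_id), 0L))))
  invisible(x)
}

#' Build a homogalacturonan chain topology
#'
#' A linear chain of n galacturonic-acid beads joined by n-1 harmonic
#' distance bonds and n-2 angular bonds, with each term parameterized from
#' the type-dependent tables. The protonation pattern fixes the bead types:
#' all protonated, all deprotonated, strictly alternating, or alternating
#' pairs (two dissociated units next to two undissociated ones).
#'
#' @param n_units Number of galacturonic-acid units (>= 2).
#' @param pattern One of `"all-protonated"`, `"all-deprotonated"`,
#'   `"alternating"`, `"alternating-pairs"`.
#' @return A [dpd_topology()] for the chain alone (bead indices 1..n).
#' @export
#' @examples
#' ch <- build_chain(8, "all-protonated")
#' nrow(ch$bonds)   # 7
#' nrow(ch$angles)  # 6
build_chain <- function(n_units, pattern = "all-protonated") {
  if (n_units < 2) stop("a chain needs at least 2 units")
  types <- .pattern_types(n_units, pattern)
  bonds <- do.call(rbind, lapply(seq_len(n_units - 1), function(i) {
    p <- bond_params(types[i], types[i + 1])
    data.frame(i = i, j = i + 1, k_s = p$k_s, l0 = p$l0)
  }))
  angles <- NULL
  if (n_units >= 3) {
    angles <- do.call(rbind, lapply(seq_len(n_units - 2), function(i) {
      p <- angle_params(types[i], types[i + 1], types[i + 2])
      data.frame(i = i, j = i + 1, k = i + 2, k_a = p$k_a, theta0 = p$theta0)
    }))
  }
  dpd_topology(types, bonds, angles, chain_id = rep(1L, n_units))
}

#' Build a chains-in-water system
#'
#' Places `n_chains` homogalacturonan chains as seeded random walks (step l0,
#' bond angle near theta0, periodic wrapping allowed) in a cubic box and
#' fills the remaining bead budget (density_number x box volume) with water
#' beads at uniformly random positions. Soft DPD potentials tolerate initial
#' overlaps, which the warm-up resolves; no self-avoidance is enforced.
#' Velocities are Maxwell-Boltzmann at `kBT` with the centre-of-mass
#' momentum removed.
#'
#' @param n_chains Number of chains.
#' @param chain_length Galacturonic-acid units per chain.
#' @param pattern Protonation pattern, as in [build_chain()].
#' @param box_edge Cubic box edge (r_C).
#' @param density_number Beads per r_C^3 (default 3).
#' @param seed Integer seed (mandatory; the build is reproducible).
#' @param kBT Thermal energy for the initial velocities.
#' @return List with `state` (a `dpd_state`) and `topology`
#'   (a `dpd_topology`).
#' @export
#' @examples
#' sys <- build_system(1, 5, "all-protonated", box_edge = 5, seed = 1)
#' length(sys$topology$types)  # 375 beads in a 5^3 box at density 3
build_system <- function(n_chains, chain_length, pattern = "all-protonated",
                         box_edge, density_number = 3, seed, kBT = 1) {
  n_total <- round(density_number * box_edge^3)
  n_chain_beads <- n_chains * chain_length
  if (n_chain_beads > n_total)
    stop(sprintf("chain beads (%d) exceed the total bead budget (%d)",
                 n_chain_beads, n_total))
  set.seed(seed)
  types <- character(n_total)
  chain_id <- integer(n_total)
  pos <- matrix(0, n_total, 3)
  bonds <- vector("list", n_chains)
  angles <- vector("list", n_chains)
  offset <- 0L
  for (c in seq_len(n_chains)) {
    ch <- build_chain(chain_length, pattern)
    idx <- offset + seq_len(chain_length)
    types[idx] <- ch$types
    chain_id[idx] <- c
    if (nrow(ch$bonds)) {
      b <- ch$bonds; b$i <- b$i + offset; b$j <- b$j + offset
      bonds[[c]] <- b
    }
    if (nrow(ch$angles)) {
      a <- ch$angles
      a$i <- a$i + offset; a$j <- a$j + offset; a$k <- a$k + offset
      angles[[c]] <- a
    }
    pos[idx, ] <- .random_walk_chain(ch, box_edge)
    offset <- offset + chain_length
  }
  n_water <- n_total - n_chain_beads
  if (n_water > 0) {
    widx <- n_chain_beads + seq_len(n_water)
    types[widx] <- "(H2O)4"
    chain_id[widx] <- 0L
    pos[widx, ] <- matrix(runif(3 * n_water, 0, box_edge), n_water, 3)
  }
  topo <- dpd_topology(types, do.call(rbind, bonds), do.call(rbind, angles),
                       chain_id)
  vel <- .maxwell_velocities(topo$masses, kBT)
  state <- dpd_state(pos, vel, topo$masses, types, box_edge, seed = seed)
  list(state = state, topology = topo)
}

# seeded random walk with bond length l0 and interior angle near theta0
.random_walk_chain <- function(chain, box_edge) {
  n <- length(chain$types)
  pos <- matrix(0, n, 3)
  pos[1, ] <- runif(3, 0, box_edge)
  dir <- .random_unit_vector()
  l0s <- chain$bonds$l0
  pos[2, ] <- pos[1, ] + l0s[1] * dir
  if (n >= 3) {
    for (i in 3:n) {
      th0 <- chain$angles$theta0[i - 2]
      # new direction at angle (pi - theta0) from the previous one
      dir <- .deflect_direction(dir, pi - th0)
      pos[i, ] <- pos[i - 1, ] + l0s[i - 1] * dir
    }
  }
  pos %% box_edge
}

.random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# rotate `dir` by angle `alpha` about a random perpendicular axis
.deflect_direction <- function(dir, alpha) {
  perp <- rnorm(3)
  perp <- perp - sum(perp * dir) * dir
  perp <- perp / sqrt(sum(perp^2))
  cos(alpha) * dir + sin(alpha) * perp
}

.maxwell_velocities <- function(masses, kBT = 1) {
  n <- length(masses)
  vel <- matrix(rnorm(3 * n, sd = rep(sqrt(kBT / masses), 3)), n, 3)
  # remove centre-of-mass momentum
  p <- colSums(vel * masses)
  sweep(vel, 2, p / sum(masses))
}
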