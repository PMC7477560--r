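# Independent oracles used across the suite. These deliberately use naive
# loops and quadrature, not the package's code paths.

# all-pairs minimum-image neighbour search
brute_force_pairs <- function(pos, box, cutoff) {
  n <- nrow(pos)
  out <- matrix(integer(), 0, 2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      d <- d - box * round(d / box)
      if (sum(d^2) < cutoff^2) out <- rbind(out, c(i, j))
    }
  }
  out
}

pair_key <- function(m) {
  if (!nrow(m)) return(character())
  paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
}

# literal round/claim/conflict re-implementation of the equal-occupancy
# nearest-neighbour clustering (one molecule per bead per round; conflicts to
# the closest claimant, ties to the lower bead index / lower molecule id)
oracle_assign <- function(bead_pos, mol_pos, box, ratio) {
  nb <- nrow(bead_pos)
  nm <- nrow(mol_pos)
  members <- matrix(NA_integer_, nb, ratio)
  free <- rep(TRUE, nm)
  midist <- function(a, b) {
    d <- a - b
    d <- d - box * round(d / box)
    sqrt(sum(d^2))
  }
  for (round in seq_len(ratio)) {
    need <- rep(TRUE, nb)
    while (any(need)) {
      claims <- list()
      for (b in which(need)) {
        cand <- which(free)
        ds <- vapply(cand, function(m) midist(bead_pos[b, ], mol_pos[m, ]), 0)
        claims[[length(claims) + 1]] <-
          list(bead = b, mol = cand[which.min(ds)], d = min(ds))
      }
      for (mol in unique(vapply(claims, `[[`, 0L, "mol"))) {
        cl <- Filter(function(cc) cc$mol == mol, claims)
        winner <- cl[[which.min(vapply(cl, `[[`, 0, "d"))]]$bead
        members[winner, round] <- mol
        free[mol] <- FALSE
        need[winner] <- FALSE
      }
    }
  }
  list(members = members, unassigned = which(free))
}

# moments of the equilibrium distribution p(x) ~ jacobian(x) exp(-k/2 (x-x0)^2)
boltzmann_moments <- function(k, x0, jacobian, lower, upper) {
  f <- function(x) jacobian(x) * exp(-k / 2 * (x - x0)^2)
  z <- integrate(f, lower, upper)$value
  m1 <- integrate(function(x) x * f(x), lower, upper)$value / z
  m2 <- integrate(function(x) x^2 * f(x), lower, upper)$value / z
  list(mean = m1, var = m2 - m1^2)
}

ALL_TYPES <- c("(H2O)4", "GalA(-)", "GalA")

# all bead types, zero repulsion, no thermostat (pure bonded/deterministic)
zero_ff <- function() {
  dpd_forcefield(matrix(0, 3, 3, dimnames = list(ALL_TYPES, ALL_TYPES)),
                 gamma = 0, sigma = 0, s = 2)
}

# all bead types, zero repulsion, thermostat on: samples exactly the bonded
# Boltzmann distribution
zero_ff_thermo <- function(gamma = 23.53, s = 0.5) {
  dpd_forcefield(matrix(0, 3, 3, dimnames = list(ALL_TYPES, ALL_TYPES)),
                 gamma = gamma, s = s)
}

# relative-difference assertion: expect_equal() falls back to an absolute
# comparison when the target magnitude is below the tolerance, which would
# make variance checks vacuous
expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

# a bonded oligomer immersed in an ideal thermostat bath (water beads, no
# non-bonded repulsion): DPD forces are central, so bath collisions are
# needed to thermalize bending modes that decouple from the pairwise
# thermostat of an isolated oligomer
bath_state <- function(chain_pos, types_chain, box = 4, seed = 1) {
  n <- round(3 * box^3)
  nc <- nrow(chain_pos)
  types <- c(types_chain, rep("(H2O)4", n - nc))
  masses <- unname(c(2.623, 2.609, 1)[match(types, c("GalA", "GalA(-)",
                                                     "(H2O)4"))])
  set.seed(seed)
  pos <- rbind(chain_pos, matrix(runif(3 * (n - nc), 0, box), n - nc, 3))
  vel <- matrix(rnorm(3 * n, sd = rep(sqrt(1 / masses), 3)), n, 3)
  vel <- sweep(vel, 2, colSums(vel * masses) / sum(masses))
  dpd_state(pos, vel, masses, types, box, seed = seed)
}

# a short thermostatted water run shared by several engine tests
small_water_run <- function(seed = 1, a = 25, gamma = 4.5, s = 2,
                            box = 5, warmup = 2000, production = 4000,
                            save_every = 40) {
  st <- init_water_state(box, seed = seed)
  ff <- dpd_forcefield(a, gamma = gamma, s = s)
  run_dpd(st, ff, integrator_config(warmup = warmup, production = production,
                                    save_every = save_every))
}
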