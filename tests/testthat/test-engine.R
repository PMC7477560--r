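test_that("cell list equals the brute-force pair oracle", {
  set.seed(101)
  for (case in list(list(n = 300, box = 6), list(n = 120, box = 4),
                    list(n = 500, box = 8))) {
    pos <- matrix(runif(3 * case$n, 0, case$box), case$n, 3)
    got <- build_cell_list(pos, case$box, cutoff = 1)
    ref <- brute_force_pairs(pos, case$box, 1)
    expect_setequal(pair_key(got), pair_key(ref))
    # unfiltered candidates are a superset with no duplicates or self-pairs
    cand <- build_cell_list(pos, case$box, cutoff = 1, filter = FALSE)
    expect_true(all(pair_key(ref) %in% pair_key(cand)))
    expect_false(any(duplicated(pair_key(cand))))
    expect_false(any(cand[, 1] == cand[, 2]))
  }
})

test_that("cell list catches pairs straddling the periodic boundary", {
  pos <- rbind(c(0.1, 2, 2), c(3.9, 2, 2))  # distance 0.2 across the boundary
  got <- build_cell_list(pos, 4, cutoff = 1)
  expect_equal(nrow(got), 1)
  # lattice at twice the cut-off has no pairs in range
  g <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 2
  expect_equal(nrow(build_cell_list(g, 4, cutoff = 1)), 0)
  expect_error(build_cell_list(pos, 1.5, cutoff = 1), ">= 2")
})

test_that("pair forces reproduce the closed-form contributions", {
  mk_state <- function(pos, vel) {
    dpd_state(pos, vel, rep(1, 2), rep("(H2O)4", 2), 10, seed = 1)
  }
  pairs <- matrix(c(1L, 2L), 1)
  # conservative: a (1 - r), along the i<-j direction
  st <- mk_state(rbind(c(5.5, 5, 5), c(5, 5, 5)), matrix(0, 2, 3))
  f <- pair_forces(st, dpd_forcefield(50, gamma = 0, sigma = 0), pairs,
                   noise = 0)
  expect_equal(f$forces[1, ], c(25, 0, 0))
  expect_equal(f$forces[2, ], c(-25, 0, 0))
  # dissipative: -gamma w^D (v_ij . rhat), opposing head-on approach
  st <- mk_state(rbind(c(5.5, 5, 5), c(5, 5, 5)),
                 rbind(c(-1, 0, 0), c(0, 0, 0)))
  f <- pair_forces(st, dpd_forcefield(0, gamma = 4.5, sigma = 0, s = 2),
                   pairs, noise = 0)
  expect_equal(f$forces[1, 1], 4.5 * 0.25 * 1)
  # random: sigma w^R xi dt^(-1/2)
  st <- mk_state(rbind(c(5.5, 5, 5), c(5, 5, 5)), matrix(0, 2, 3))
  f <- pair_forces(st, dpd_forcefield(0, gamma = 0, sigma = 3, s = 2),
                   pairs, dt = 0.001, noise = 1)
  expect_equal(f$forces[1, 1], 3 * 0.5 * 1 / sqrt(0.001))
  # beyond the cut-off: listed pair contributes nothing
  st <- mk_state(rbind(c(7, 5, 5), c(5, 5, 5)), matrix(0, 2, 3))
  f <- pair_forces(st, dpd_forcefield(50, gamma = 4.5), pairs, noise = 1)
  expect_equal(f$forces, matrix(0, 2, 3))
  # exact overlap: zero force, logged as an overlap event
  st <- mk_state(rbind(c(5, 5, 5), c(5, 5, 5)), matrix(0, 2, 3))
  f <- pair_forces(st, dpd_forcefield(50, gamma = 4.5), pairs, noise = 1)
  expect_equal(f$forces, matrix(0, 2, 3))
  expect_equal(f$n_overlap, 1)
})

test_that("bonded forces vanish at rest geometry and match the numeric gradient", {
  topo_rest <- dpd_topology(rep("GalA", 2),
                            bonds = data.frame(i = 1, j = 2, k_s = 3375,
                                               l0 = 0.62))
  st <- dpd_state(rbind(c(2, 2, 2), c(2.62, 2, 2)), matrix(0, 2, 3),
                  rep(2.623, 2), rep("GalA", 2), 6, seed = 1)
  bf <- bonded_forces(st, topo_rest)
  expect_equal(bf$forces, matrix(0, 2, 3), tolerance = 1e-12)

  # three beads at exactly theta0: zero angle force
  th0 <- 2.83
  p3 <- rbind(c(2, 2, 2),
              c(2.62, 2, 2),
              c(2.62 + 0.62 * cos(pi - th0), 2 + 0.62 * sin(pi - th0), 2))
  topo3 <- dpd_topology(rep("GalA", 3),
                        bonds = data.frame(i = 1:2, j = 2:3, k_s = 3375,
                                           l0 = 0.62),
                        angles = data.frame(i = 1, j = 2, k = 3, k_a = 29,
                                            theta0 = th0))
  st3 <- dpd_state(p3, matrix(0, 3, 3), rep(1, 3), rep("GalA", 3), 6,
                   seed = 1)
  expect_equal(bonded_forces(st3, topo3)$forces, matrix(0, 3, 3),
               tolerance = 1e-9)

  # random geometries: force equals the central-difference energy gradient
  set.seed(21)
  for (rep in 1:5) {
    pos <- matrix(2.5 + rnorm(9, sd = 0.4), 3, 3)
    st3 <- dpd_state(pos, matrix(0, 3, 3), rep(1, 3), rep("GalA", 3), 6,
                     seed = 1)
    got <- bonded_forces(st3, topo3)$forces
    eps <- 1e-6
    num <- matrix(0, 3, 3)
    for (i in 1:3) for (d in 1:3) {
      pp <- pos; pp[i, d] <- pp[i, d] + eps
      pm <- pos; pm[i, d] <- pm[i, d] - eps
      up <- potential_energy(dpd_state(pp, matrix(0, 3, 3), rep(1, 3),
                                       rep("GalA", 3), 6, seed = 1),
                             zero_ff(), topo3)
      um <- potential_energy(dpd_state(pm, matrix(0, 3, 3), rep(1, 3),
                                       rep("GalA", 3), 6, seed = 1),
                             zero_ff(), topo3)
      num[i, d] <- -(up - um) / (2 * eps)
    }
    expect_equal(got, num, tolerance = 1e-5)
    # zero net force and zero net torque per configuration
    expect_equal(colSums(got), rep(0, 3), tolerance = 1e-10)
    torque <- colSums(t(vapply(1:3, function(i)
      c(pos[i, 2] * got[i, 3] - pos[i, 3] * got[i, 2],
        pos[i, 3] * got[i, 1] - pos[i, 1] * got[i, 3],
        pos[i, 1] * got[i, 2] - pos[i, 2] * got[i, 1]), numeric(3))))
    expect_equal(torque, rep(0, 3), tolerance = 1e-9)
  }
})

test_that("a free bead advects linearly and free velocities stay constant", {
  st <- dpd_state(matrix(c(2, 2, 2), 1), matrix(c(1, 0, 0), 1), 1,
                  "(H2O)4", 5, seed = 1)
  s2 <- dpd_step(st, zero_ff(), dt = 0.001)
  expect_equal(s2$positions[1, ], c(2.001, 2, 2))
  expect_equal(s2$velocities[1, ], c(1, 0, 0))
  # several beads, no interactions at all: velocities constant
  st <- init_water_state(5, seed = 3)
  tr <- run_dpd(st, zero_ff(),
                integrator_config(warmup = 0, production = 100,
                                  save_every = 100))
  expect_equal(tr$velocities[, , 1], st$velocities, tolerance = 1e-12)
})

test_that("deterministic bonded dimer conserves energy over 1e4 steps", {
  topo <- dpd_topology(rep("GalA", 2),
                       bonds = data.frame(i = 1, j = 2, k_s = 3375,
                                          l0 = 0.62))
  st <- dpd_state(rbind(c(2, 2, 2), c(2.70, 2, 2)),
                  rbind(c(0.3, 0.2, 0), c(-0.3, -0.2, 0.1)),
                  rep(2.623, 2), rep("GalA", 2), 6, seed = 1)
  ff <- dpd_forcefield(
    matrix(58.5, 3, 3, dimnames = list(ALL_TYPES, ALL_TYPES)),
    gamma = 0, sigma = 0, s = 2)
  tr <- run_dpd(st, ff, integrator_config(warmup = 0, production = 10000,
                                          save_every = 100),
                topology = topo)
  energies <- vapply(seq_len(n_frames(tr)), function(f) {
    sf <- dpd_state(tr$positions[, , f], tr$velocities[, , f],
                    st$masses, st$types, 6, seed = 1)
    kin <- sum(0.5 * st$masses * rowSums(tr$velocities[, , f]^2))
    potential_energy(sf, ff, topo) + kin
  }, 0)
  drift <- abs(mean(energies[91:100]) - mean(energies[1:10]))
  expect_lt(drift / mean(energies), 0.001)
})

test_that("the thermostatted run conserves momentum and samples kBT = 1", {
  tr <- small_water_run(seed = 2)
  fs <- attr(tr, "final_state")
  st <- init_water_state(5, seed = 2)
  p0 <- colSums(st$velocities * st$masses)
  pf <- colSums(fs$velocities * fs$masses)
  expect_lt(max(abs(pf - p0)), 1e-8)
  expect_equal(kinetic_temperature(tr), 1.0, tolerance = 0.03)
  # per-frame momentum stays put too
  for (f in seq_len(n_frames(tr))) {
    expect_lt(max(abs(colSums(tr$velocities[, , f]) - p0)), 1e-8)
  }
})

test_that("the calibrated thermostat also holds kBT = 1", {
  tr <- small_water_run(seed = 4, a = 50, gamma = 23.53, s = 0.5)
  expect_equal(kinetic_temperature(tr), 1.0, tolerance = 0.03)
})

test_that("runs are bit-reproducible under the same seed", {
  tr1 <- small_water_run(seed = 9, production = 800, save_every = 80)
  tr2 <- small_water_run(seed = 9, production = 800, save_every = 80)
  expect_identical(tr1$positions, tr2$positions)
  expect_identical(tr1$velocities, tr2$velocities)
  tr3 <- small_water_run(seed = 10, production = 800, save_every = 80)
  expect_false(identical(tr1$positions, tr3$positions))
})

test_that("zero-step production yields an empty but valid trajectory", {
  st <- init_water_state(5, seed = 1)
  tr <- run_dpd(st, dpd_forcefield(25, gamma = 4.5),
                integrator_config(warmup = 100, production = 0))
  expect_equal(n_frames(tr), 0)
  expect_s3_class(tr, "dpd_trajectory")
  expect_equal(tr$box_edge, 5)
})

test_that("a thermostatted harmonic dimer samples variance kBT/k_S", {
  # immersed in an ideal thermostat bath: bath collisions decorrelate the
  # stiff, underdamped bond mode that an isolated dimer samples too slowly
  st <- bath_state(rbind(c(2, 2, 2), c(2.62, 2, 2)), rep("GalA", 2),
                   box = 4, seed = 6)
  nb <- nrow(st$positions)
  topo <- dpd_topology(st$types,
                       bonds = data.frame(i = 1, j = 2, k_s = 3375,
                                          l0 = 0.62),
                       chain_id = c(rep(1L, 2), rep(0L, nb - 2)))
  tr <- run_dpd(st, zero_ff_thermo(),
                integrator_config(warmup = 2000, production = 200000,
                                  save_every = 20),
                topology = topo)
  bd <- bonded_distributions(tr, topo)
  expect_equal(bd$bonds$mean, 0.62, tolerance = 0.02)
  expect_rel(bd$bonds$variance, 1 / 3375, 0.10)
})
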