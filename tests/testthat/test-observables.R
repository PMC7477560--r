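test_that("the RDF of an ideal gas is flat and integrates to the pair count", {
  set.seed(11)
  n <- 3000; box <- 10; nf <- 20
  pos <- array(runif(3 * n * nf, 0, box), c(n, 3, nf))
  tr <- dpd_trajectory(pos, box_edge = box, frame_interval = 1)
  g <- rdf(tr, bin_width = 0.2, r_max = 4)
  expect_true(all(g$g[-1] > 0.97 & g$g[-1] < 1.03))
  # tail average within [0.9, 1.1]
  tail_bins <- g$g[g$r > 0.8 * max(g$r)]
  expect_true(mean(tail_bins) > 0.9 && mean(tail_bins) < 1.1)
  # integral consistency: sum 4 pi r^2 rho g dr ~ pairs per particle
  rho <- (n - 1) / box^3
  integral <- sum(4 * pi * g$r^2 * rho * g$g * 0.2)
  expect_equal(integral, 4 / 3 * pi * 4^3 * rho, tolerance = 0.02)
})

test_that("the lattice RDF peaks at the spacing with six nearest neighbours", {
  fr <- generate_lattice(1.0, 5)
  g <- rdf(fr, bin_width = 0.1, r_max = 2.4)
  # the first (nearest-neighbour) peak sits in the bin containing the spacing
  first_peak <- which(g$g > 0)[1]
  expect_lt(abs(g$r[first_peak] - 1.0), 0.1)
  expect_equal(g$g[first_peak], max(g$g[g$r < 1.2]))
  # neighbour count from the pair integral over the first peak
  n <- dim(fr$positions)[1]
  rho <- (n - 1) / fr$box_edge^3
  neighbours <- sum(4 * pi * g$r^2 * rho * g$g * 0.1 *
                      (g$r > 0.9 & g$r < 1.15))
  expect_equal(neighbours, 6, tolerance = 0.05)
  expect_error(rdf(fr, type_pair = c("GalA", "GalA")), "empty type selection")
  expect_error(rdf(fr, r_max = 10), "half the box")
})

test_that("diffusion estimation recovers Brownian ground truth within 5%", {
  fine <- generate_brownian_water(n_molecules = 400, box_edge = 31.036,
                                  D = 0.151, n_frames = 300, seed = 17)
  est <- diffusion_coefficient(fine)
  expect_equal(est$D, 0.151, tolerance = 0.05)
  expect_gt(est$r_squared, 0.99)
  # static particles: D = 0
  static <- generate_brownian_water(n_molecules = 50, box_edge = 10, D = 0,
                                    n_frames = 30, seed = 2)
  expect_equal(diffusion_coefficient(static)$D, 0)
})

test_that("ballistic motion is flagged by the MSD diagnostics", {
  n <- 20; nf <- 40
  v <- matrix(rnorm(3 * n, sd = 0.1), n, 3)
  pos <- array(0, c(n, 3, nf))
  for (f in seq_len(nf)) pos[, , f] <- (5 + v * f) %% 50
  unw <- array(0, c(n, 3, nf))
  for (f in seq_len(nf)) unw[, , f] <- 5 + v * f
  tr <- dpd_trajectory(pos, unwrapped = unw, box_edge = 50,
                       frame_interval = 1)
  est <- diffusion_coefficient(tr)
  expect_gt(est$ballistic_exponent, 1.8)  # MSD ~ v^2 t^2
  expect_error(diffusion_coefficient(
    dpd_trajectory(pos[, , 1:6, drop = FALSE], box_edge = 50,
                   frame_interval = 1)), "fewer than 5 lags")
})

test_that("D is stable (2%) under halving the saving rate", {
  fine <- generate_brownian_water(n_molecules = 500, box_edge = 31.036,
                                  D = 0.3, n_frames = 240, seed = 23)
  sub <- fine
  keep <- seq(1, 240, by = 2)
  sub$positions <- fine$positions[, , keep]
  sub$unwrapped <- fine$unwrapped[, , keep]
  sub$velocities <- fine$velocities[, , keep]
  sub$frame_interval <- fine$frame_interval * 2
  d1 <- diffusion_coefficient(fine)$D
  d2 <- diffusion_coefficient(sub)$D
  expect_lt(abs(d1 - d2) / d1, 0.02)
})

test_that("velocity statistics match Maxwell-Boltzmann closed forms", {
  set.seed(5)
  n <- 3000; nf <- 10
  vel <- array(rnorm(3 * n * nf), c(n, 3, nf))
  pos <- array(runif(3 * n * nf, 0, 10), c(n, 3, nf))
  tr <- dpd_trajectory(pos, velocities = vel, box_edge = 10,
                       frame_interval = 1)
  vs <- velocity_stats(tr)
  expect_equal(vs$mean_speed, sqrt(8 / pi), tolerance = 0.02)
  expect_equal(vs$rms_speed, sqrt(3), tolerance = 0.02)
  expect_equal(kinetic_temperature(tr), 1.0, tolerance = 0.02)
  # zero velocities: all statistics vanish
  tr0 <- dpd_trajectory(pos, velocities = array(0, dim(vel)), box_edge = 10,
                        frame_interval = 1)
  expect_equal(velocity_stats(tr0)$mean_speed, 0)
  expect_equal(kinetic_temperature(tr0), 0)
  # missing velocities fail loudly
  trna <- dpd_trajectory(pos, box_edge = 10, frame_interval = 1)
  expect_error(velocity_stats(trna), "no velocities")
  expect_error(kinetic_temperature(trna), "no velocities")
})

test_that("bonded distributions match the exact Boltzmann oracle", {
  # thermostatted dimer in an ideal bath: bond-length distribution
  # ~ r^2 exp(-k/2 (r-l0)^2)
  st <- bath_state(rbind(c(2, 2, 2), c(2.62, 2, 2)), rep("GalA", 2),
                   box = 4, seed = 31)
  nb2 <- nrow(st$positions)
  topo <- dpd_topology(st$types,
                       bonds = data.frame(i = 1, j = 2, k_s = 3375,
                                          l0 = 0.62),
                       chain_id = c(rep(1L, 2), rep(0L, nb2 - 2)))
  tr <- run_dpd(st, zero_ff_thermo(),
                integrator_config(warmup = 2000, production = 200000,
                                  save_every = 20), topology = topo)
  bd <- bonded_distributions(tr, topo)
  oracle <- boltzmann_moments(3375, 0.62, function(r) r^2, 0, 2)
  expect_equal(bd$bonds$mean, oracle$mean, tolerance = 0.01)
  expect_rel(bd$bonds$variance, oracle$var, 0.10)
  # the harmonic-bath approximation also holds for stiff bonds
  expect_rel(bd$bonds$variance, 1 / 3375, 0.10)

  # thermostatted trimer in an ideal bath: the angle samples the full
  # Boltzmann marginal ~ sin(theta) exp(-k/2 dtheta^2) (Jacobian included);
  # the bath is needed because central pair forces alone cannot thermalize
  # the bending mode of an isolated trimer
  th0 <- 2.83
  p3 <- rbind(c(2, 2, 2), c(2.62, 2, 2),
              c(2.62 + 0.62 * cos(pi - th0), 2 + 0.62 * sin(pi - th0), 2))
  st3 <- bath_state(p3, rep("GalA", 3), box = 4, seed = 32)
  nb <- nrow(st3$positions)
  topo3 <- dpd_topology(st3$types,
                        bonds = data.frame(i = 1:2, j = 2:3, k_s = 3375,
                                           l0 = 0.62),
                        angles = data.frame(i = 1, j = 2, k = 3, k_a = 29,
                                            theta0 = th0),
                        chain_id = c(rep(1L, 3), rep(0L, nb - 3)))
  tr3 <- run_dpd(st3, zero_ff_thermo(),
                 integrator_config(warmup = 2000, production = 200000,
                                   save_every = 20), topology = topo3)
  bd3 <- bonded_distributions(tr3, topo3)
  oracle3 <- boltzmann_moments(29, th0, sin, 0, pi)
  expect_lt(abs(bd3$angles$mean - oracle3$mean), 0.03)
  expect_rel(bd3$angles$variance, oracle3$var, 0.15)
  # the Jacobian makes the sampled moments measurably non-harmonic
  expect_lt(bd3$angles$mean, th0 - 0.05)
  expect_lt(bd3$angles$variance, 0.9 / 29)

  # frozen chain: zero-variance distributions at the exact geometry
  topof <- dpd_topology(rep("GalA", 3),
                        bonds = data.frame(i = 1:2, j = 2:3, k_s = 3375,
                                           l0 = 0.62),
                        angles = data.frame(i = 1, j = 2, k = 3, k_a = 29,
                                            theta0 = th0))
  frozen <- dpd_trajectory(array(rep(p3, 3), c(3, 3, 3)), box_edge = 5,
                           frame_interval = 1, types = rep("GalA", 3))
  bdf <- bonded_distributions(frozen, topof)
  expect_equal(bdf$bonds$variance, 0, tolerance = 1e-20)
  expect_equal(bdf$angles$mean, th0, tolerance = 1e-8)
})

test_that("chain contacts count only inter-chain pairs", {
  # two dimers: one pair of chains in contact, solvent ignored
  types <- c("GalA", "GalA", "GalA", "GalA", "(H2O)4")
  topo <- dpd_topology(types,
                       bonds = data.frame(i = c(1, 3), j = c(2, 4),
                                          k_s = 3375, l0 = 0.62),
                       chain_id = c(1L, 1L, 2L, 2L, 0L))
  pos <- rbind(c(1, 1, 1), c(1.6, 1, 1),
               c(1, 1.7, 1), c(1.6, 1.7, 1),
               c(1.2, 1.2, 1))
  tr <- dpd_trajectory(array(pos, c(5, 3, 1)), box_edge = 6,
                       frame_interval = 1, types = types)
  cc <- chain_contacts(tr, topo, contact_distance = 0.8)
  # inter-chain pairs within 0.8: (1,3), (2,4) -> 2 contacts over 4 beads
  expect_equal(cc$contacts_per_bead, 0.5)
  far <- pos; far[3:4, 2] <- 4
  trf <- dpd_trajectory(array(far, c(5, 3, 1)), box_edge = 6,
                        frame_interval = 1, types = types)
  expect_equal(chain_contacts(trf, topo, contact_distance = 0.8)$contacts_per_bead, 0)
})
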