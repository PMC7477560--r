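test_that("bead initialization picks distinct molecules and enforces the margin", {
  set.seed(3)
  mol <- matrix(runif(967 * 3, 0, 31.036), 967, 3)
  b <- cg_initialize_beads(mol, 240, 4, seed = 2)
  ids <- attr(b, "molecule_ids")
  expect_equal(nrow(b), 240)
  expect_false(any(duplicated(ids)))
  expect_equal(b, mol[ids, ], ignore_attr = TRUE)
  # 240 beads x 4 molecules leaves 7 free
  expect_equal(967 - 240 * 4, 7)
  expect_warning(cg_initialize_beads(mol[1:16, ], 4, 4, seed = 1),
                 "no free molecules")
  expect_error(cg_initialize_beads(mol[1:15, ], 4, 4, seed = 1),
               "stability margin")
})

test_that("well-separated clouds are assigned to their own beads", {
  # quasi-1D toy: two groups far apart along x
  mol <- cbind(c(0.1, 0.2, 0.3, 0.4, 9.6, 9.7, 9.8, 9.9) + 0.05,
               rep(1, 8), rep(1, 8))
  beads <- rbind(c(0.05, 1, 1), c(10.05, 1, 1))
  asg <- cg_assign_frame(beads, mol, box_edge = 20, cg_ratio = 4)
  expect_setequal(asg$members[1, ], 1:4)
  expect_setequal(asg$members[2, ], 5:8)
  expect_length(asg$unassigned, 0)
})

test_that("conflicts go to the closest claimant and ties to the lower bead", {
  # molecule 1 is the first choice of both beads, exactly equidistant
  beads <- rbind(c(4, 5, 5), c(6, 5, 5))
  mol <- rbind(c(5, 5, 5),      # equidistant from both beads (d = 1)
               c(2.5, 5, 5),    # bead 1's fallback (d = 1.5)
               c(7.5, 5, 5))    # bead 2's fallback (d = 1.5)
  asg <- cg_assign_frame(beads, mol, box_edge = 20, cg_ratio = 1)
  expect_equal(asg$members[1, 1], 1L)  # tie broken to the lower bead index
  expect_equal(asg$members[2, 1], 3L)  # loser re-searches
  # closest claimant wins a genuine conflict
  beads <- rbind(c(3.8, 5, 5), c(5.6, 5, 5))
  mol <- rbind(c(5, 5, 5),      # d = 1.2 from bead 1, d = 0.6 from bead 2
               c(2.5, 5, 5),    # d = 1.3 from bead 1
               c(7.5, 5, 5))
  asg <- cg_assign_frame(beads, mol, box_edge = 20, cg_ratio = 1)
  expect_equal(asg$members[2, 1], 1L)  # bead 2 is closer to molecule 1
  expect_equal(asg$members[1, 1], 2L)  # bead 1 re-searches and gets mol 2
})

test_that("assignment matches the literal round/conflict oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    nm <- 30; nb <- 6; ratio <- 4; box <- 5
    mol <- matrix(runif(3 * nm, 0, box), nm, 3)
    beads <- mol[sample.int(nm, nb), ]
    got <- cg_assign_frame(beads, mol, box, ratio)
    ref <- oracle_assign(beads, mol, box, ratio)
    expect_identical(got$members, ref$members)
    expect_identical(got$unassigned, ref$unassigned)
    # partition properties
    flat <- as.vector(got$members)
    expect_equal(length(unique(flat)), nb * ratio)
    expect_length(got$unassigned, nm - nb * ratio)
    expect_lte(got$n_iterations, nb * nb)
  }
  # a larger instance against the oracle
  set.seed(99)
  mol <- matrix(runif(150, 0, 4), 50, 3)
  beads <- mol[sample.int(50, 10), ]
  got <- cg_assign_frame(beads, mol, 4, 4)
  ref <- oracle_assign(beads, mol, 4, 4)
  expect_identical(got$members, ref$members)
})

test_that("bead updates take the minimum-image centre of mass", {
  # square cloud: bead moves to the centre
  mol <- rbind(c(1, 1, 2), c(1, 3, 2), c(3, 1, 2), c(3, 3, 2))
  beads <- matrix(c(1.5, 1.5, 2), 1)
  asg <- cg_assign_frame(beads, mol, box_edge = 10, cg_ratio = 4)
  up <- cg_update_positions(asg, beads, mol, 10)
  expect_equal(up[1, ], c(2, 2, 2))
  # cloud straddling the periodic boundary: centre on the short arc
  mol <- rbind(c(9.8, 5, 5), c(9.9, 5, 5), c(0.1, 5, 5), c(0.2, 5, 5))
  beads <- matrix(c(9.9, 5, 5), 1)
  asg <- cg_assign_frame(beads, mol, box_edge = 10, cg_ratio = 4)
  up <- cg_update_positions(asg, beads, mol, 10)
  expect_equal(up[1, 1], 0, tolerance = 1e-12)
  # explicit unwrapped-coordinate computation agrees
  unwrapped_mean <- mean(c(9.8, 9.9, 10.1, 10.2)) %% 10
  expect_equal(up[1, 1], unwrapped_mean)
  # single-member cloud sits on the member
  asg1 <- cg_assign_frame(matrix(c(5, 5, 5), 1), mol, 10, cg_ratio = 1)
  up1 <- cg_update_positions(asg1, matrix(c(5, 5, 5), 1), mol, 10)
  expect_equal(up1[1, ], mol[asg1$members[1, 1], ])
})

test_that("trajectory mapping is deterministic, exhaustive and continuous", {
  fine <- generate_brownian_water(n_molecules = 101, box_edge = 10, D = 0.05,
                                  n_frames = 12, frame_interval = 2,
                                  seed = 8)
  cg <- cg_map_trajectory(fine, cg_ratio = 4, seed = 4, audit = TRUE)
  expect_equal(dim(cg$positions)[1], 25)
  asg <- attr(cg, "assignments")
  for (f in seq_len(n_frames(cg))) {
    flat <- as.vector(asg[[f]]$members)
    expect_equal(length(unique(flat)), 100)  # partition, every frame
  }
  cg2 <- cg_map_trajectory(fine, cg_ratio = 4, seed = 4)
  expect_identical(cg$positions, cg2$positions)
  # static molecules: the frame-chained assignment relaxes to an exact fixed
  # point (identical partition and bead positions from one frame to the next)
  static <- generate_brownian_water(n_molecules = 60, box_edge = 8, D = 0,
                                    n_frames = 8, seed = 5)
  cgs <- cg_map_trajectory(static, cg_ratio = 4, seed = 2, audit = TRUE)
  sorted_members <- function(f)
    t(apply(attr(cgs, "assignments")[[f]]$members, 1, sort))
  expect_identical(cgs$positions[, , 7], cgs$positions[, , 8])
  expect_identical(sorted_members(7), sorted_members(8))
  # continuity: beads move no faster than molecules spread
  mol_step <- sqrt(mean((fine$unwrapped[, , 2] - fine$unwrapped[, , 1])^2) * 3)
  bead_step <- cg$positions[, , 2] - cg$positions[, , 1]
  bead_step <- bead_step - 10 * round(bead_step / 10)
  cloud_r <- max(vapply(seq_len(25), function(b) {
    d <- sweep(fine$positions[asg[[1]]$members[b, ], , 1], 2,
               cg$positions[b, , 1])
    d <- d - 10 * round(d / 10)
    sqrt(max(rowSums(d^2)))
  }, 0))
  expect_lt(mean(sqrt(rowSums(bead_step^2))), mol_step + cloud_r)
})

test_that("member-mean and displacement velocity modes both work", {
  fine <- generate_brownian_water(n_molecules = 41, box_edge = 8, D = 0.1,
                                  n_frames = 6, frame_interval = 2, seed = 3)
  cgm <- cg_map_trajectory(fine, cg_ratio = 4, seed = 1,
                           velocity_mode = "member_mean", audit = TRUE)
  asg <- attr(cgm, "assignments")
  expect_equal(cgm$velocities[1, , 3],
               colMeans(fine$velocities[asg[[3]]$members[1, ], , 3]))
  cgd <- cg_map_trajectory(fine, cg_ratio = 4, seed = 1,
                           velocity_mode = "displacement")
  step <- cgd$positions[, , 3] - cgd$positions[, , 2]
  step <- step - 8 * round(step / 8)
  expect_equal(cgd$velocities[, , 3], step / 2)
  # stripping velocities forces the displacement fallback
  bare <- fine
  bare$velocities <- NULL
  expect_error(cg_map_trajectory(bare, cg_ratio = 4, seed = 1),
               "displacement")
})
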