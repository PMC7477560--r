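# Step-wise iterative nearest-neighbour coarse-graining: maps fine-grained
# molecule trajectories onto equal-occupancy CG beads. Each frame runs
# cg_ratio rounds; in every round each bead acquires exactly one new member
# through a unique-nearest-neighbour search with conflict resolution (a
# molecule claimed by several beads goes to the closest claimant, losing
# beads search again among still-unassigned molecules). Bead positions stay
# fixed during a frame's assignment and are updated to the member centre of
# mass afterwards.

.mi_dist2 <- function(from, to, box) {
  # squared minimum-image distances, rows of `from` x rows of `to`
  d2 <- matrix(0, nrow(from), nrow(to))
  for (k in 1:3) {
    d <- outer(from[, k], to[, k], "-")
    d <- d - box * round(d / box)
    d2 <- d2 + d * d
  }
  d2
}

#' Initialize coarse-grained bead positions
#'
#' Picks `n_beads` distinct molecule positions from a frame, without
#' replacement, as the starting bead centres (for water: oxygen positions).
#' The bead count must leave at least one molecule free of any bead —
#' the stability margin of the assignment algorithm.
#'
#' @param frame_positions N x 3 matrix of molecule positions.
#' @param n_beads Number of CG beads.
#' @param cg_ratio Molecules per bead (default 4).
#' @param seed Integer seed.
#' @return `n_beads` x 3 matrix of initial bead positions, with the chosen
#'   molecule ids in `attr(, "molecule_ids")`.
#' @export
cg_initialize_beads <- function(frame_positions, n_beads, cg_ratio = 4,
                                seed) {
  frame_positions <- as.matrix(frame_positions)
  n_mol <- nrow(frame_positions)
  need <- n_beads * cg_ratio
  if (need > n_mol)
    stop(sprintf(paste0(
      "%d beads x %d molecules need %d molecules but only %d are present; ",
      "reduce n_beads so a few free molecules are left as a stability margin"),
      n_beads, cg_ratio, need, n_mol))
  if (need == n_mol)
    warning("no free molecules left; the assignment has no stability margin")
  set.seed(seed)
  ids <- sample.int(n_mol, n_beads)
  out <- frame_positions[ids, , drop = FALSE]
  attr(out, "molecule_ids") <- ids
  out
}

#' Assign molecules to beads for one frame
#'
#' Runs `cg_ratio` sequential rounds of the iterative unique-nearest-
#' neighbour search. Distances are minimum-image Euclidean distances from
#' the (fixed) bead positions; distance ties go to the lower molecule id
#' when a bead chooses, and to the lower bead index when claimants tie.
#'
#' @param bead_positions B x 3 matrix of bead positions.
#' @param frame_positions N x 3 matrix of molecule positions.
#' @param box_edge Periodic box edge.
#' @param cg_ratio Molecules per bead.
#' @return Object of class `cg_assignment`: list with `members` (B x
#'   cg_ratio matrix of molecule ids, in acquisition order), `unassigned`
#'   (ids of free molecules) and `n_iterations`.
#' @export
cg_assign_frame <- function(bead_positions, frame_positions, box_edge,
                            cg_ratio = 4) {
  bead_positions <- as.matrix(bead_positions)
  frame_positions <- as.matrix(frame_positions)
  nb <- nrow(bead_positions)
  nm <- nrow(frame_positions)
  if (nb * cg_ratio > nm)
    stop("not enough molecules for the requested beads and cg_ratio")
  members <- matrix(NA_integer_, nb, cg_ratio)
  unassigned <- rep(TRUE, nm)
  total_iter <- 0L
  for (round in seq_len(cg_ratio)) {
    active <- seq_len(nb)
    while (length(active)) {
      total_iter <- total_iter + 1L
      if (total_iter > nb * nb * cg_ratio + nb)
        stop("assignment failed to terminate; this should be impossible ",
             "with a free-molecule margin")
      uidx <- which(unassigned)
      d2 <- .mi_dist2(bead_positions[active, , drop = FALSE],
                      frame_positions[uidx, , drop = FALSE], box_edge)
      # nearest unassigned molecule per active bead (ties: lower molecule id)
      nn_local <- apply(d2, 1, which.min)
      nn_mol <- uidx[nn_local]
      nn_d2 <- d2[cbind(seq_along(active), nn_local)]
      # conflict resolution: each claimed molecule goes to its closest
      # claimant (ties: lower bead index); winners leave the round
      done <- logical(length(active))
      for (mol in unique(nn_mol)) {
        claimants <- which(nn_mol == mol)
        winner <- claimants[which.min(nn_d2[claimants])]
        members[active[winner], round] <- mol
        unassigned[mol] <- FALSE
        done[winner] <- TRUE
      }
      active <- active[!done]
    }
  }
  structure(list(members = members, unassigned = which(unassigned),
                 n_iterations = total_iter, cg_ratio = cg_ratio),
            class = "cg_assignment")
}

#' Update bead positions to member centres of mass
#'
#' Each bead moves to the centre of mass of its molecular cloud, computed
#' minimum-image-aware: members are unwrapped relative to the current bead
#' position before averaging and the result is re-wrapped into the box, so
#' clouds straddling a periodic boundary average on the short arc.
#'
#' @param assignment A [cg_assign_frame()] result.
#' @param bead_positions B x 3 matrix the assignment was built from.
#' @param frame_positions N x 3 matrix of molecule positions.
#' @param box_edge Periodic box edge.
#' @param masses Optional per-molecule masses (default: equal).
#' @return B x 3 matrix of updated bead positions.
#' @export
cg_update_positions <- function(assignment, bead_positions, frame_positions,
                                box_edge, masses = NULL) {
  stopifnot(inherits(assignment, "cg_assignment"))
  bead_positions <- as.matrix(bead_positions)
  frame_positions <- as.matrix(frame_positions)
  nb <- nrow(assignment$members)
  out <- bead_positions
  for (b in seq_len(nb)) {
    ids <- assignment$members[b, ]
    disp <- sweep(frame_positions[ids, , drop = FALSE], 2,
                  bead_positions[b, ])
    disp <- disp - box_edge * round(disp / box_edge)
    w <- if (is.null(masses)) rep(1, length(ids)) else masses[ids]
    out[b, ] <- bead_positions[b, ] + colSums(disp * w) / sum(w)
  }
  out %% box_edge
}

#' Map a fine-grained trajectory onto coarse-grained beads
#'
#' Frame 1 initializes bead positions from randomly chosen molecule
#' positions; each frame is assigned with [cg_assign_frame()] starting from
#' the previous frame's updated bead positions, then beads move to their
#' cloud centres of mass. Bead velocities are either the mean of the member
#' molecule velocities (`"member_mean"`, requires fine velocities) or the
#' bead displacement divided by the frame interval (`"displacement"`).
#'
#' @param fine_trajectory A [dpd_trajectory()] of molecule positions (and
#'   optionally velocities).
#' @param cg_ratio Molecules per bead (default 4).
#' @param n_beads Number of beads; default leaves a stability margin of at
#'   least one free molecule.
#' @param seed Integer seed for the initial bead choice.
#' @param velocity_mode `"member_mean"` or `"displacement"`.
#' @param audit Keep the per-frame assignments in
#'   `attr(, "assignments")`.
#' @param warn_cloud_radius Warn when a bead's cloud radius exceeds this;
#'   default 2 r_C (2 in reduced units, 2 x 7.2 Angstrom in real units).
#' @return A [dpd_trajectory()] of bead positions/velocities with the same
#'   box, frame interval and units as the input.
#' @export
cg_map_trajectory <- function(fine_trajectory, cg_ratio = 4, n_beads = NULL,
                              seed, velocity_mode = c("member_mean",
                                                      "displacement"),
                              audit = FALSE, warn_cloud_radius = NULL) {
  stopifnot(inherits(fine_trajectory, "dpd_trajectory"))
  velocity_mode <- match.arg(velocity_mode)
  if (is.null(warn_cloud_radius))
    warn_cloud_radius <- 2 * (if (fine_trajectory$units == "real")
      hg_constants()$r_c_real else 1)
  nf <- n_frames(fine_trajectory)
  if (nf < 1) stop("need at least one frame")
  nm <- dim(fine_trajectory$positions)[1]
  if (is.null(n_beads)) n_beads <- (nm - 1) %/% cg_ratio
  if (velocity_mode == "member_mean" && is.null(fine_trajectory$velocities))
    stop("member_mean velocities need fine-grained velocities; ",
         "use velocity_mode = \"displacement\"")
  box <- fine_trajectory$box_edge
  dt_frame <- fine_trajectory$frame_interval
  bead_pos <- cg_initialize_beads(fine_trajectory$positions[, , 1],
                                  n_beads, cg_ratio, seed)
  pos_arr <- array(NA_real_, c(n_beads, 3, nf))
  vel_arr <- array(NA_real_, c(n_beads, 3, nf))
  assignments <- if (audit) vector("list", nf)
  prev_pos <- NULL
  warned <- FALSE
  for (f in seq_len(nf)) {
    fp <- fine_trajectory$positions[, , f]
    asg <- cg_assign_frame(bead_pos, fp, box, cg_ratio)
    new_pos <- cg_update_positions(asg, bead_pos, fp, box)
    if (!warned) {
      radius <- .cloud_radius(asg, new_pos, fp, box)
      if (any(radius > warn_cloud_radius)) {
        warning(sprintf(
          "frame %d: %d bead cloud(s) exceed radius %g; assignments may be chaining across jumps",
          f, sum(radius > warn_cloud_radius), warn_cloud_radius))
        warned <- TRUE
      }
    }
    pos_arr[, , f] <- new_pos
    if (velocity_mode == "member_mean") {
      fv <- fine_trajectory$velocities[, , f]
      for (b in seq_len(n_beads))
        vel_arr[b, , f] <- colMeans(fv[asg$members[b, ], , drop = FALSE])
    } else if (f >= 2) {
      step <- new_pos - prev_pos
      step <- step - box * round(step / box)
      vel_arr[, , f] <- step / dt_frame
    }
    if (audit) assignments[[f]] <- asg
    prev_pos <- new_pos
    bead_pos <- new_pos
  }
  if (velocity_mode == "displacement" && nf >= 2)
    vel_arr[, , 1] <- vel_arr[, , 2]
  out <- dpd_trajectory(
    positions = pos_arr,
    velocities = if (nf >= 2 || velocity_mode == "member_mean") vel_arr,
    box_edge = box, frame_interval = dt_frame,
    units = fine_trajectory$units,
    types = rep("(H2O)4", n_beads),
    masses = rep(1, n_beads),
    metadata = c(fine_trajectory$metadata,
                 list(cg_ratio = cg_ratio, n_beads = n_beads,
                      cg_seed = seed, velocity_mode = velocity_mode)))
  if (audit) attr(out, "assignments") <- assignments
  out
}

.cloud_radius <- function(assignment, bead_pos, frame_positions, box) {
  vapply(seq_len(nrow(assignment$members)), function(b) {
    disp <- sweep(frame_positions[assignment$members[b, ], , drop = FALSE],
                  2, bead_pos[b, ])
    disp <- disp - box * round(disp / box)
    sqrt(max(rowSums(disp^2)))
  }, 0)
}

#' Write an assignment audit table
#'
#' @param trajectory A CG trajectory produced by [cg_map_trajectory()] with
#'   `audit = TRUE`.
#' @param path Output CSV path (columns: frame, bead, slot, molecule).
#' @return The path, invisibly.
#' @export
write_assignment_csv <- function(trajectory, path) {
  asg <- attr(trajectory, "assignments")
  if (is.null(asg)) stop("trajectory carries no assignment audit")
  rows <- do.call(rbind, lapply(seq_along(asg), function(f) {
    m <- asg[[f]]$members
    data.frame(frame = f, bead = rep(seq_len(nrow(m)), ncol(m)),
               slot = rep(seq_len(ncol(m)), each = nrow(m)),
               molecule = as.vector(m))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
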