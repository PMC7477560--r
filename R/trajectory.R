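#' Trajectory container
#'
#' Time-ordered frames of positions (and optionally velocities and unwrapped
#' positions) in a periodic cubic box, with the frame interval and unit
#' system recorded. Positions are stored as an N x 3 x F array; unwrapped
#' positions continue through periodic boundaries and feed the MSD.
#'
#' @param positions N x 3 x F array of wrapped positions.
#' @param velocities Optional N x 3 x F array of velocities.
#' @param unwrapped Optional N x 3 x F array of unwrapped positions.
#' @param box_edge Cubic box edge.
#' @param frame_interval Time between saved frames (tau or ps, per `units`).
#' @param units `"reduced"` (r_C, tau) or `"real"` (Angstrom, ps).
#' @param types Optional character vector of bead/molecule types.
#' @param masses Optional per-bead masses.
#' @param metadata Free-form provenance list (seed, parameters, ground
#'   truth).
#' @return Object of class `dpd_trajectory`.
#' @export
dpd_trajectory <- function(positions, velocities = NULL, unwrapped = NULL,
                           box_edge, frame_interval, units = "reduced",
                           types = NULL, masses = NULL, metadata = list()) {
  d <- dim(positions)
  if (length(d) != 3 || d[2] != 3)
    stop("positions must be an N x 3 x F array")
  for (arr in list(velocities, unwrapped)) {
    if (!is.null(arr) && length(arr) && !identical(dim(arr), d))
      stop("velocities/unwrapped must match the dimensions of positions")
  }
  if (!is.null(velocities) && length(velocities) == 0) velocities <- NULL
  if (!is.null(unwrapped) && length(unwrapped) == 0) unwrapped <- NULL
  if (is.null(types)) types <- rep("(H2O)4", d[1])
  if (is.null(masses)) masses <- rep(1, d[1])
  structure(list(positions = positions, velocities = velocities,
                 unwrapped = unwrapped, box_edge = box_edge,
                 frame_interval = frame_interval, units = units,
                 types = types, masses = masses, metadata = metadata),
            class = "dpd_trajectory")
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf(
    "DPD trajectory: %d particles, %d frames, box %g, frame interval %g (%s units)%s\n",
    d[1], d[3], x$box_edge, x$frame_interval, x$units,
    if (is.null(x$velocities)) ", no velocities" else ""))
  invisible(x)
}

#' @rdname dpd_trajectory
#' @param x A `dpd_trajectory`.
#' @return `n_frames()`: the number of frames.
#' @export
n_frames <- function(x) dim(x$positions)[3]

#' Extract one frame of a trajectory
#'
#' @param trajectory A [dpd_trajectory()].
#' @param i Frame index.
#' @return List with `positions`, `velocities` (or `NULL`), `box_edge`,
#'   `time`.
#' @export
get_frame <- function(trajectory, i) {
  stopifnot(i >= 1, i <= n_frames(trajectory))
  list(positions = trajectory$positions[, , i, drop = TRUE],
       velocities = if (!is.null(trajectory$velocities))
         trajectory$velocities[, , i, drop = TRUE],
       box_edge = trajectory$box_edge,
       time = i * trajectory$frame_interval)
}

#' Convert a trajectory between reduced and real units
#'
#' @param trajectory A [dpd_trajectory()].
#' @param units A [reduced_units()] object with its time unit set when the
#'   trajectory carries velocities or a frame interval.
#' @param to `"real"` or `"reduced"`.
#' @return The converted trajectory.
#' @export
convert_trajectory <- function(trajectory, units, to = c("real", "reduced")) {
  to <- match.arg(to)
  if (trajectory$units == to) return(trajectory)
  dir <- if (to == "real") "reduced_to_real" else "real_to_reduced"
  out <- trajectory
  out$positions <- convert_quantity(trajectory$positions, "length", dir, units)
  if (!is.null(trajectory$unwrapped))
    out$unwrapped <- convert_quantity(trajectory$unwrapped, "length", dir,
                                      units)
  if (!is.null(trajectory$velocities))
    out$velocities <- convert_quantity(trajectory$velocities, "velocity", dir,
                                       units)
  out$box_edge <- convert_quantity(trajectory$box_edge, "length", dir, units)
  out$frame_interval <- convert_quantity(trajectory$frame_interval, "time",
                                         dir, units)
  out$units <- to
  out
}
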