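# Trajectory statistics used as calibration targets: radial distribution
# functions, mean-squared displacement and diffusion coefficients, velocity
# statistics / kinetic temperature, and bonded-geometry distributions.

#' Radial distribution function
#'
#' Standard pair-count g(r): minimum-image distances histogrammed per frame
#' and normalized by the ideal-gas shell expectation at the partial densities
#' of the selected types, averaged over frames. For a homogeneous fluid the
#' tail approaches 1.
#'
#' @param trajectory A [dpd_trajectory()].
#' @param type_pair Character vector of length 2 selecting the particle
#'   types, or `NULL` for all particles.
#' @param bin_width Histogram bin width (trajectory length units).
#' @param r_max Histogram range; must not exceed half the box edge.
#' @return Data frame of class `rdf_curve` with columns `r` (bin centres)
#'   and `g`.
#' @export
rdf <- function(trajectory, type_pair = NULL, bin_width = 0.05,
                r_max = trajectory$box_edge / 2) {
  stopifnot(inherits(trajectory, "dpd_trajectory"))
  box <- trajectory$box_edge
  if (r_max > box / 2 + 1e-9)
    stop("r_max must not exceed half the box edge")
  if (is.null(type_pair)) type_pair <- rep(trajectory$types[1], 2)
  sel1 <- which(trajectory$types == type_pair[1])
  sel2 <- which(trajectory$types == type_pair[2])
  if (!length(sel1) || !length(sel2))
    stop("empty type selection: ", paste(type_pair, collapse = ", "))
  same <- identical(type_pair[1], type_pair[2])
  nbins <- ceiling(r_max / bin_width)
  nf <- n_frames(trajectory)
  if (nf < 1) stop("trajectory has no frames")
  counts <- numeric(nbins)
  for (f in seq_len(nf)) {
    counts <- counts + cpp_pair_dist_hist(trajectory$positions[, , f],
                                          as.integer(sel1), as.integer(sel2),
                                          same, box, bin_width, nbins)
  }
  counts <- counts / nf
  edges <- bin_width * (0:nbins)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbins + 1)]^3)
  v <- box^3
  n_pairs_ideal <- if (same) {
    length(sel1) * (length(sel1) - 1) / 2 * shell / v
  } else {
    length(sel1) * length(sel2) * shell / v
  }
  g <- counts / n_pairs_ideal
  out <- data.frame(r = (edges[-1] + edges[-(nbins + 1)]) / 2, g = g)
  attr(out, "bin_width") <- bin_width
  attr(out, "type_pair") <- type_pair
  class(out) <- c("rdf_curve", "data.frame")
  out
}

.unwrapped_coords <- function(trajectory) {
  if (!is.null(trajectory$unwrapped)) return(trajectory$unwrapped)
  # unwrap by minimum-image chaining between consecutive saved frames;
  # assumes no particle moves more than box/2 between frames
  pos <- trajectory$positions
  box <- trajectory$box_edge
  d <- dim(pos)
  unw <- pos
  if (d[3] >= 2) {
    for (f in 2:d[3]) {
      step <- pos[, , f] - pos[, , f - 1]
      step <- step - box * round(step / box)
      if (any(abs(step) > box / 2))
        stop("cannot unwrap: a particle moved more than box/2 between ",
             "saved frames; save frames more often")
      unw[, , f] <- unw[, , f - 1] + step
    }
  }
  unw
}

#' Mean-squared displacement
#'
#' MSD over all lags using every saved frame as a time origin, computed from
#' unwrapped coordinates (taken from the engine when available, otherwise
#' reconstructed by minimum-image chaining).
#'
#' @param trajectory A [dpd_trajectory()].
#' @param types Particle types to include (`NULL` = all).
#' @return Data frame of class `msd_series` with columns `lag` (time) and
#'   `msd`.
#' @export
msd <- function(trajectory, types = NULL) {
  stopifnot(inherits(trajectory, "dpd_trajectory"))
  unw <- .unwrapped_coords(trajectory)
  if (!is.null(types)) {
    sel <- trajectory$types %in% types
    if (!any(sel)) stop("empty type selection")
    unw <- unw[sel, , , drop = FALSE]
  }
  d <- dim(unw)
  nf <- d[3]
  if (nf < 2) stop("need at least 2 frames for an MSD")
  out <- numeric(nf - 1)
  for (lag in seq_len(nf - 1)) {
    disp <- unw[, , (1 + lag):nf, drop = FALSE] -
      unw[, , 1:(nf - lag), drop = FALSE]
    out[lag] <- mean(disp[, 1, ]^2 + disp[, 2, ]^2 + disp[, 3, ]^2)
  }
  res <- data.frame(lag = seq_len(nf - 1) * trajectory$frame_interval,
                    msd = out)
  class(res) <- c("msd_series", "data.frame")
  res
}

#' Self-diffusion coefficient from the MSD slope
#'
#' Least-squares fit of MSD versus lag time over a window that excludes the
#' short-time ballistic regime, D = slope / 6 in three dimensions. The fit
#' R^2 and a ballistic-regime diagnostic (log-log slope of the early MSD)
#' are reported alongside.
#'
#' @param trajectory A [dpd_trajectory()].
#' @param fit_window Fraction range of the maximum lag used for the linear
#'   fit (default 20-80%).
#' @param types Particle types to include (`NULL` = all).
#' @return List with `D`, `slope`, `intercept`, `r_squared`,
#'   `ballistic_exponent`, and the `msd` series.
#' @export
diffusion_coefficient <- function(trajectory, fit_window = c(0.2, 0.8),
                                  types = NULL) {
  m <- msd(trajectory, types = types)
  tmax <- max(m$lag)
  sel <- m$lag >= fit_window[1] * tmax & m$lag <= fit_window[2] * tmax
  if (sum(sel) < 5)
    stop("fewer than 5 lags in the fit window; save more frames")
  fit <- lm(msd ~ lag, data = m[sel, ])
  early <- m[m$lag <= 0.2 * tmax & m$msd > 0, ]
  ballistic <- if (nrow(early) >= 3) {
    unname(coef(lm(log(msd) ~ log(lag), data = early))[2])
  } else NA_real_
  list(D = unname(coef(fit)[2]) / 6,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       ballistic_exponent = ballistic,
       msd = m)
}

#' Velocity statistics and kinetic temperature
#'
#' Mean and RMS particle speed, per-component velocity variance and a speed
#' histogram; the kinetic temperature follows from equipartition,
#' T = sum(m v^2) / (3 N kB), averaged over frames.
#'
#' @param trajectory A [dpd_trajectory()] carrying velocities.
#' @param breaks Number of histogram breaks for the speed distribution.
#' @return For `velocity_stats()`: list with `mean_speed`, `rms_speed`,
#'   `component_variance` and `histogram`. For `kinetic_temperature()`: the
#'   temperature in kBT units.
#' @export
velocity_stats <- function(trajectory, breaks = 50) {
  stopifnot(inherits(trajectory, "dpd_trajectory"))
  if (is.null(trajectory$velocities))
    stop("trajectory carries no velocities")
  v <- trajectory$velocities
  speed <- sqrt(v[, 1, , drop = FALSE]^2 + v[, 2, , drop = FALSE]^2 +
                  v[, 3, , drop = FALSE]^2)
  list(mean_speed = mean(speed),
       rms_speed = sqrt(mean(speed^2)),
       component_variance = var(as.vector(v)),
       histogram = hist(speed, breaks = breaks, plot = FALSE))
}

#' @rdname velocity_stats
#' @export
kinetic_temperature <- function(trajectory) {
  stopifnot(inherits(trajectory, "dpd_trajectory"))
  if (is.null(trajectory$velocities))
    stop("trajectory carries no velocities")
  v <- trajectory$velocities
  n <- dim(v)[1]
  # |v|^2 per bead per frame
  v2 <- v[, 1, , drop = FALSE]^2 + v[, 2, , drop = FALSE]^2 +
    v[, 3, , drop = FALSE]^2
  v2 <- matrix(v2, nrow = n)
  mean(colSums(trajectory$masses * v2) / (3 * n))
}

#' Bonded-geometry distributions
#'
#' Bond-length and bond-angle samples per bonded-term type across all
#' frames, with histograms and sample moments. Angles are the interior angle
#' at the central bead, in [0, pi], from minimum-image vectors.
#'
#' @param trajectory A [dpd_trajectory()].
#' @param topology A [dpd_topology()] consistent with the trajectory.
#' @param breaks Histogram breaks.
#' @return List with data frames `bonds` and `angles` (term type, mean,
#'   variance, n) and lists `bond_samples`, `angle_samples` keyed by term
#'   type.
#' @export
bonded_distributions <- function(trajectory, topology, breaks = 50) {
  stopifnot(inherits(trajectory, "dpd_trajectory"),
            inherits(topology, "dpd_topology"))
  if (length(topology$types) != dim(trajectory$positions)[1])
    stop("topology and trajectory disagree on bead count")
  box <- trajectory$box_edge
  nf <- n_frames(trajectory)
  mi <- function(d) d - box * round(d / box)
  bond_type <- if (nrow(topology$bonds)) {
    mapply(.bond_key, topology$types[topology$bonds$i],
           topology$types[topology$bonds$j])
  } else character()
  angle_type <- if (nrow(topology$angles)) {
    mapply(.angle_key, topology$types[topology$angles$i],
           topology$types[topology$angles$j],
           topology$types[topology$angles$k])
  } else character()
  bond_samples <- list(); angle_samples <- list()
  for (f in seq_len(nf)) {
    p <- trajectory$positions[, , f]
    if (nrow(topology$bonds)) {
      dvec <- mi(p[topology$bonds$i, , drop = FALSE] -
                   p[topology$bonds$j, , drop = FALSE])
      len <- sqrt(rowSums(dvec^2))
      for (ty in unique(bond_type))
        bond_samples[[ty]] <- c(bond_samples[[ty]], len[bond_type == ty])
    }
    if (nrow(topology$angles)) {
      a <- mi(p[topology$angles$i, , drop = FALSE] -
                p[topology$angles$j, , drop = FALSE])
      b <- mi(p[topology$angles$k, , drop = FALSE] -
                p[topology$angles$j, , drop = FALSE])
      cth <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
      th <- acos(pmin(1, pmax(-1, cth)))
      for (ty in unique(angle_type))
        angle_samples[[ty]] <- c(angle_samples[[ty]], th[angle_type == ty])
    }
  }
  summarize <- function(samples) {
    if (!length(samples))
      return(data.frame(type = character(), mean = numeric(),
                        variance = numeric(), n = integer()))
    data.frame(type = names(samples),
               mean = vapply(samples, mean, 0),
               variance = vapply(samples, var, 0),
               n = vapply(samples, length, 0L), row.names = NULL)
  }
  list(bonds = summarize(bond_samples), angles = summarize(angle_samples),
       bond_samples = bond_samples, angle_samples = angle_samples,
       bond_histograms = lapply(bond_samples, hist, breaks = breaks,
                                plot = FALSE),
       angle_histograms = lapply(angle_samples, hist, breaks = breaks,
                                 plot = FALSE))
}

#' Inter-chain contact metric
#'
#' Counts bead pairs from different chains within a contact distance,
#' normalized per chain bead — a scalar that grows as dispersed chains
#' aggregate into fibres/networks.
#'
#' @param trajectory A [dpd_trajectory()].
#' @param topology A [dpd_topology()] whose `chain_id` marks chain
#'   membership (0 = solvent).
#' @param contact_distance Contact cut-off (default 1 r_C).
#' @param frames Frame indices to evaluate (default: all).
#' @return Data frame with columns `frame`, `time`, `contacts_per_bead`.
#' @export
chain_contacts <- function(trajectory, topology, contact_distance = 1,
                           frames = seq_len(n_frames(trajectory))) {
  stopifnot(inherits(trajectory, "dpd_trajectory"),
            inherits(topology, "dpd_topology"))
  chain <- topology$chain_id
  poly <- which(chain > 0)
  if (!length(poly)) stop("topology contains no chains")
  out <- data.frame(frame = frames,
                    time = frames * trajectory$frame_interval,
                    contacts_per_bead = NA_real_)
  for (k in seq_along(frames)) {
    p <- trajectory$positions[, , frames[k]]
    pairs <- build_cell_list(p[poly, , drop = FALSE], trajectory$box_edge,
                             cutoff = contact_distance, filter = TRUE)
    if (nrow(pairs)) {
      ci <- chain[poly[pairs[, 1]]]
      cj <- chain[poly[pairs[, 2]]]
      out$contacts_per_bead[k] <- sum(ci != cj) / length(poly)
    } else out$contacts_per_bead[k] <- 0
  }
  out
}
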