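# Trajectory and configuration I/O. Extended XYZ is the canonical format
# (positions + velocities, with box, step and units on the comment line);
# GRO is supported for interoperability with standard MD tooling and uses
# nm per that format's convention, converted to/from the Angstrom-based real
# units (or reduced units, recorded as such) internally.

#' Write a trajectory as extended XYZ
#'
#' One block per frame: particle count, a comment line carrying
#' `Lattice="..."`, a `Properties=` descriptor, `Time=`, `Frame=` and
#' `Units=`, then one line per particle (`type x y z [vx vy vz]`).
#'
#' @param trajectory A [dpd_trajectory()].
#' @param path Output file path.
#' @param digits Significant digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(trajectory, path, digits = 10) {
  stopifnot(inherits(trajectory, "dpd_trajectory"))
  n <- dim(trajectory$positions)[1]
  nf <- n_frames(trajectory)
  has_vel <- !is.null(trajectory$velocities)
  props <- if (has_vel) "species:S:1:pos:R:3:vel:R:3" else "species:S:1:pos:R:3"
  con <- file(path, "w")
  on.exit(close(con))
  L <- trajectory$box_edge
  for (f in seq_len(nf)) {
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=%s Time=%g Frame=%d Units=%s',
      L, L, L, props, f * trajectory$frame_interval, f, trajectory$units),
      con)
    m <- trajectory$positions[, , f]
    if (has_vel) m <- cbind(m, trajectory$velocities[, , f])
    lines <- apply(format(m, digits = digits, trim = TRUE, scientific = FALSE),
                   1, paste, collapse = " ")
    writeLines(paste(trajectory$types, lines), con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory
#'
#' @param path Input file path.
#' @return A [dpd_trajectory()]; velocities are read when the Properties
#'   descriptor declares them.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  frame_no <- 0L
  n_prev <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame_no <- frame_no + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n))
      stop("malformed particle count at line ", i, " (frame ", frame_no, ")")
    if (!is.null(n_prev) && n != n_prev)
      stop("frame ", frame_no, ": particle count changed from ", n_prev,
           " to ", n)
    n_prev <- n
    if (i + 1L + n > length(lines))
      stop("truncated file: frame ", frame_no, " promises ", n,
           " particles but the file ends at line ", length(lines))
    comment <- lines[i + 1L]
    lat <- regmatches(comment,
                      regexpr('Lattice="[^"]+"', comment))
    box <- NA_real_
    if (length(lat)) {
      nums <- as.numeric(strsplit(gsub('Lattice="|"', "", lat), "\\s+")[[1]])
      box <- nums[1]
    }
    tm <- regmatches(comment, regexpr("Time=[-0-9.eE+]+", comment))
    time <- if (length(tm)) as.numeric(sub("Time=", "", tm)) else frame_no
    un <- regmatches(comment, regexpr("Units=\\S+", comment))
    units <- if (length(un)) sub("Units=", "", un) else "real"
    has_vel <- grepl("vel:R:3", comment)
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    ncol_expect <- if (has_vel) 7L else 4L
    bad <- which(lengths(parts) < ncol_expect)
    if (length(bad))
      stop("malformed particle line ", i + 1L + bad[1], " in frame ",
           frame_no)
    types <- vapply(parts, `[[`, "", 1)
    num <- matrix(as.numeric(unlist(lapply(parts, function(p)
      p[2:ncol_expect]))), n, ncol_expect - 1L, byrow = TRUE)
    frames[[frame_no]] <- list(types = types, pos = num[, 1:3, drop = FALSE],
                               vel = if (has_vel) num[, 4:6, drop = FALSE],
                               box = box, time = time, units = units)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  nf <- length(frames)
  n <- nrow(frames[[1]]$pos)
  pos <- array(NA_real_, c(n, 3, nf))
  has_vel <- !is.null(frames[[1]]$vel)
  vel <- if (has_vel) array(NA_real_, c(n, 3, nf))
  for (f in seq_len(nf)) {
    pos[, , f] <- frames[[f]]$pos
    if (has_vel) vel[, , f] <- frames[[f]]$vel
  }
  interval <- if (nf >= 2) frames[[2]]$time - frames[[1]]$time else 1
  dpd_trajectory(pos, velocities = vel, box_edge = frames[[1]]$box,
                 frame_interval = interval, units = frames[[1]]$units,
                 types = frames[[1]]$types)
}

#' Write a trajectory in GRO format
#'
#' Coordinates are written in nm (divided by 10 from the Angstrom-based
#' real units) with velocities in nm/ps, per the format's fixed-width
#' layout. Reduced-unit trajectories should be converted to real units
#' first.
#'
#' @param trajectory A [dpd_trajectory()] in real units (Angstrom).
#' @param path Output file path.
#' @param residue_name Residue name stamped on every particle.
#' @return `path`, invisibly.
#' @export
write_gro <- function(trajectory, path, residue_name = "SOL") {
  stopifnot(inherits(trajectory, "dpd_trajectory"))
  n <- dim(trajectory$positions)[1]
  nf <- n_frames(trajectory)
  has_vel <- !is.null(trajectory$velocities)
  con <- file(path, "w")
  on.exit(close(con))
  atom <- substr(gsub("[^A-Za-z0-9]", "", trajectory$types), 1, 5)
  atom[!nzchar(atom)] <- "X"
  for (f in seq_len(nf)) {
    writeLines(sprintf("trajectory frame %d, t= %.5f", f,
                       f * trajectory$frame_interval), con)
    writeLines(sprintf("%5d", n), con)
    p <- trajectory$positions[, , f] / 10
    if (has_vel) {
      v <- trajectory$velocities[, , f] / 10
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
                         (seq_len(n) - 1) %% 99999 + 1, residue_name, atom,
                         (seq_len(n) - 1) %% 99999 + 1,
                         p[, 1], p[, 2], p[, 3], v[, 1], v[, 2], v[, 3]), con)
    } else {
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         (seq_len(n) - 1) %% 99999 + 1, residue_name, atom,
                         (seq_len(n) - 1) %% 99999 + 1,
                         p[, 1], p[, 2], p[, 3]), con)
    }
    L <- trajectory$box_edge / 10
    writeLines(sprintf("%10.5f%10.5f%10.5f", L, L, L), con)
  }
  invisible(path)
}

#' Read a GRO trajectory
#'
#' @param path Input file path.
#' @return A [dpd_trajectory()] in real units (Angstrom, ps); lengths are
#'   multiplied by 10 from the file's nm.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  frame_no <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    frame_no <- frame_no + 1L
    title <- lines[i]
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else frame_no
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n))
      stop("malformed atom count at line ", i + 1L, " (frame ", frame_no, ")")
    if (i + 2L + n > length(lines))
      stop("truncated file: frame ", frame_no, " promises ", n, " atoms")
    body <- lines[(i + 2L):(i + 1L + n)]
    pos <- matrix(NA_real_, n, 3)
    vel <- matrix(NA_real_, n, 3)
    types <- character(n)
    for (k in seq_len(n)) {
      ln <- body[k]
      if (nchar(ln) < 44)
        stop("malformed atom line ", i + 1L + k, " in frame ", frame_no)
      types[k] <- trimws(substr(ln, 11, 15))
      pos[k, ] <- as.numeric(c(substr(ln, 21, 28), substr(ln, 29, 36),
                               substr(ln, 37, 44)))
      if (nchar(ln) >= 68) {
        vel[k, ] <- as.numeric(c(substr(ln, 45, 52), substr(ln, 53, 60),
                                 substr(ln, 61, 68)))
      }
    }
    box <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]])[1]
    frames[[frame_no]] <- list(types = types, pos = pos * 10,
                               vel = if (!anyNA(vel)) vel * 10,
                               box = box * 10, time = time)
    i <- i + 3L + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  nf <- length(frames)
  n <- nrow(frames[[1]]$pos)
  pos <- array(NA_real_, c(n, 3, nf))
  has_vel <- !is.null(frames[[1]]$vel)
  vel <- if (has_vel) array(NA_real_, c(n, 3, nf))
  for (f in seq_len(nf)) {
    pos[, , f] <- frames[[f]]$pos
    if (has_vel) vel[, , f] <- frames[[f]]$vel
  }
  interval <- if (nf >= 2) frames[[2]]$time - frames[[1]]$time else 1
  dpd_trajectory(pos, velocities = vel, box_edge = frames[[1]]$box,
                 frame_interval = interval, units = "real",
                 types = frames[[1]]$types)
}

.CONFIG_KEYS <- list(
  system = c("box_edge", "density_number", "n_chains", "chain_length",
             "pattern"),
  forcefield = c("a", "gamma", "sigma", "s", "cutoff"),
  integrator = c("dt", "lambda", "cell_refresh", "warmup", "production",
                 "save_every"),
  top = c("system", "forcefield", "integrator", "seed", "output")
)

#' Read and validate a run configuration
#'
#' YAML with sections `system`, `forcefield`, `integrator`, a mandatory
#' top-level `seed`, and an optional `output` path. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), .CONFIG_KEYS$top)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$seed)) stop("configuration must set a seed")
  for (sec in c("system", "forcefield", "integrator")) {
    if (!is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), .CONFIG_KEYS[[sec]])
      if (length(bad))
        stop("unknown key(s) in ", sec, ": ", paste(bad, collapse = ", "))
    }
  }
  cfg
}

#' Run a simulation described by a configuration
#'
#' Builds the system (pure water, or chains in water when `n_chains` is
#' set), assembles the force field and integrator from the configuration
#' and runs it, echoing a provenance log.
#'
#' @param config A list from [read_run_config()] or of the same shape.
#' @param verbose Print the provenance log (default TRUE).
#' @return The [dpd_trajectory()]; written to `config$output` as extended
#'   XYZ when set.
#' @export
run_from_config <- function(config, verbose = TRUE) {
  sys <- config$system
  ffc <- config$forcefield
  itc <- config$integrator
  ff <- if (!is.null(ffc$a) && is.null(sys$n_chains)) {
    dpd_forcefield(ffc$a, gamma = ffc$gamma,
                   sigma = if (!is.null(ffc$sigma)) ffc$sigma else
                     fdt_sigma(ffc$gamma),
                   s = if (!is.null(ffc$s)) ffc$s else 2)
  } else {
    hg_forcefield(s = if (!is.null(ffc$s)) ffc$s else 0.5,
                  gamma = if (!is.null(ffc$gamma)) ffc$gamma else 23.53)
  }
  cfg_args <- itc[!vapply(itc, is.null, TRUE)]
  config_obj <- do.call(integrator_config, cfg_args)
  topology <- NULL
  if (!is.null(sys$n_chains) && sys$n_chains > 0) {
    built <- build_system(sys$n_chains, sys$chain_length,
                          if (!is.null(sys$pattern)) sys$pattern else
                            "all-protonated",
                          sys$box_edge,
                          if (!is.null(sys$density_number))
                            sys$density_number else 3,
                          seed = config$seed)
    state <- built$state
    topology <- built$topology
  } else {
    state <- init_water_state(sys$box_edge,
                              if (!is.null(sys$density_number))
                                sys$density_number else 3,
                              seed = config$seed)
  }
  tr <- run_dpd(state, ff, config_obj, topology = topology,
                verbose = verbose)
  if (!is.null(config$output)) write_xyz(tr, config$output)
  tr
}
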