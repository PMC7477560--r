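#' Physical constants and reference-system defaults
#'
#' Constants defining the reduced-unit system of the water/homogalacturonan
#' DPD model: the thermal energy at 298 K used as the energy base unit, the
#' mass of a (H2O)4 water bead used as the mass base unit, the reduced masses
#' of the protonated (GalA) and deprotonated (GalA(-)) galacturonic-acid
#' beads, and the reference fine-grained water system (967 SPC-like molecules
#' in a 31.036 Angstrom cubic box at 298 K, 4:1 coarse-graining) from which
#' the 7.2 Angstrom cut-off radius derives.
#'
#' @return Named list of constants. Lengths are in Angstrom, masses in kg,
#'   energies in Joule, times in ps, diffusivities in Angstrom^2/ps.
#' @export
#' @examples
#' hg_constants()$r_c_real
hg_constants <- function() {
  list(
    kBT_J          = 4.115e-21,   # thermal energy at 298 K [J]
    temperature_K  = 298,
    bead_mass_kg   = 11.968e-26,  # mass of one (H2O)4 bead [kg]
    mass_gala      = 2.623,       # GalA bead mass [bead masses]
    mass_gala_d    = 2.609,       # GalA(-) bead mass [bead masses]
    cg_ratio       = 4,           # water molecules per bead
    density_number = 3,           # beads per r_C^3
    n_ref_molecules = 967,        # reference water box: molecule count
    ref_box_volume = 29894,       # reference water box volume [A^3]
    ref_box_edge   = 31.036,      # reference water box edge [A]
    n_ref_beads    = 240,         # CG beads in the reference box (4 free mol.)
    r_c_real       = 7.2,         # cut-off radius [A]
    v_md_real      = 1.021,       # reference CG particle speed [A/ps]
    D_md_real      = 0.151        # reference CG diffusivity [A^2/ps]
  )
}

#' Reduced-unit system
#'
#' Defines the four base units of the reduced (dimensionless) system: length
#' (the cut-off radius r_C in Angstrom), mass (the water-bead mass in kg),
#' energy (kBT in Joule) and, optionally, time (tau in ps). Velocity and
#' diffusivity units are always derived as length/time and length^2/time and
#' never stored independently. The time unit is unknown until fixed by
#' calibration (see [timescale_from_velocity()]); conversions that need it
#' fail with an explicit error until it is set.
#'
#' @param length Angstrom per r_C (default: the 7.2 A reference cut-off).
#' @param mass kg per bead mass.
#' @param energy Joule per kBT.
#' @param time ps per tau, or `NULL` while uncalibrated.
#' @return Object of class `reduced_units`.
#' @export
#' @examples
#' u <- reduced_units(time = 12.47)
#' convert_quantity(1, "length", "reduced_to_real", u)
reduced_units <- function(length = hg_constants()$r_c_real,
                          mass = hg_constants()$bead_mass_kg,
                          energy = hg_constants()$kBT_J,
                          time = NULL) {
  for (v in list(length, mass, energy)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("unit values must be single positive numbers")
  }
  if (!is.null(time)) {
    if (!is.numeric(time) || length(time) != 1 || !is.finite(time) || time <= 0)
      stop("time unit must be a single positive number (ps per tau)")
  }
  structure(list(length = length, mass = mass, energy = energy, time = time),
            class = "reduced_units")
}

#' @export
print.reduced_units <- function(x, ...) {
  cat("Reduced-unit system:\n")
  cat(sprintf("  length : %g Angstrom per r_C\n", x$length))
  cat(sprintf("  mass   : %g kg per bead mass\n", x$mass))
  cat(sprintf("  energy : %g J per kBT\n", x$energy))
  if (is.null(x$time)) {
    cat("  time   : uncalibrated (set by time-scale calibration)\n")
  } else {
    cat(sprintf("  time   : %g ps per tau\n", x$time))
  }
  invisible(x)
}

#' Set the calibrated time unit of a reduced-unit system
#'
#' @param units A [reduced_units()] object.
#' @param tau_ps Calibrated time scale in ps per tau.
#' @return The updated `reduced_units` object.
#' @export
set_time_unit <- function(units, tau_ps) {
  stopifnot(inherits(units, "reduced_units"))
  reduced_units(units$length, units$mass, units$energy, tau_ps)
}

#' Derive the cut-off radius from a reference system
#'
#' The DPD cut-off radius doubles as the base length unit and follows from
#' the bead number density rho (beads per r_C^3), the real-space volume V of
#' the reference box, and the bead count N as r_C = (rho V / N)^(1/3). For
#' the reference water box (rho = 3, V = 29894 A^3, N = 240 beads) this gives
#' 7.2 Angstrom.
#'
#' @param density_number Beads per r_C^3 (dimensionless; conventionally 3-5).
#' @param box_volume Reference box volume in Angstrom^3.
#' @param n_beads Number of coarse-grained beads in the reference box.
#' @return Cut-off radius in Angstrom.
#' @export
#' @examples
#' derive_cutoff_radius(3, 29894, 240)  # 7.2 A
derive_cutoff_radius <- function(density_number, box_volume, n_beads) {
  args <- c(density_number, box_volume, n_beads)
  if (!all(is.finite(args)) || any(args <= 0))
    stop("density_number, box_volume and n_beads must all be positive")
  (density_number * box_volume / n_beads)^(1 / 3)
}

.unit_factor <- function(dimension, units) {
  needs_time <- dimension %in% c("time", "velocity", "diffusivity")
  if (needs_time && is.null(units$time))
    stop("uncalibrated time scale: set the time unit (tau) before converting ",
         dimension, " quantities")
  switch(dimension,
    length      = units$length,
    mass        = units$mass,
    energy      = units$energy,
    time        = units$time,
    velocity    = units$length / units$time,
    diffusivity = units$length^2 / units$time,
    stop("unknown dimension: ", dimension)
  )
}

#' Convert quantities between reduced and real units
#'
#' @param x Numeric vector of values to convert.
#' @param dimension One of `"length"`, `"mass"`, `"energy"`, `"time"`,
#'   `"velocity"`, `"diffusivity"`.
#' @param direction `"reduced_to_real"` or `"real_to_reduced"`.
#' @param units A [reduced_units()] object. Time-dependent dimensions require
#'   its time unit to be set.
#' @return Converted numeric vector. Real units are Angstrom, kg, J, ps and
#'   the derived Angstrom/ps and Angstrom^2/ps.
#' @export
#' @examples
#' u <- reduced_units(length = 7.2, time = 113.97)
#' convert_quantity(0.332, "diffusivity", "reduced_to_real", u)  # ~0.151 A^2/ps
convert_quantity <- function(x, dimension, direction = c("reduced_to_real",
                                                         "real_to_reduced"),
                             units) {
  direction <- match.arg(direction)
  stopifnot(inherits(units, "reduced_units"))
  f <- .unit_factor(dimension, units)
  if (direction == "reduced_to_real") x * f else x / f
}
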