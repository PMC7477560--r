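#' DPD weight functions
#'
#' The conservative weight is the linear ramp (1 - r/r_C) inside the cut-off
#' and zero at and beyond it. The dissipative weight generalizes the ramp
#' with an exponent s that tunes viscosity and diffusivity, and the random
#' weight is its square root, so that w_D = (w_R)^2 holds identically — the
#' condition for the pairwise thermostat to sample the canonical ensemble.
#'
#' @param r Distance(s), same units as `cutoff`.
#' @param s Dissipative weight exponent (> 0); s = 2 is the conventional
#'   choice, s = 0.5 the calibrated value for this water model.
#' @param cutoff Cut-off radius r_C (default 1, reduced units).
#' @return Dimensionless weight(s), vectorized over `r`.
#' @export
#' @examples
#' weight_conservative(0.5)          # 0.5
#' weight_dissipative(0.5, s = 0.5)  # sqrt(0.5)
weight_conservative <- function(r, cutoff = 1) {
  if (any(r < 0)) stop("distances must be non-negative")
  ifelse(r < cutoff, 1 - r / cutoff, 0)
}

#' @rdname weight_conservative
#' @export
weight_dissipative <- function(r, s, cutoff = 1) {
  if (!is.numeric(s) || length(s) != 1 || s <= 0)
    stop("weight exponent s must be a single positive number")
  if (any(r < 0)) stop("distances must be non-negative")
  ifelse(r < cutoff, (1 - r / cutoff)^s, 0)
}

#' @rdname weight_conservative
#' @export
weight_random <- function(r, s, cutoff = 1) {
  sqrt(weight_dissipative(r, s, cutoff))
}

#' Noise amplitude from the fluctuation-dissipation relation
#'
#' For the pairwise DPD thermostat the random-force amplitude is tied to the
#' friction by sigma^2 = 2 gamma kBT; any (sigma, gamma) pair violating this
#' drives the system away from temperature T.
#'
#' @param gamma Friction coefficient (>= 0).
#' @param kBT Thermal energy (default 1, reduced units).
#' @return Noise amplitude sigma = sqrt(2 gamma kBT).
#' @export
#' @examples
#' fdt_sigma(23.53)  # 6.86, the calibrated water value
#' fdt_sigma(4.5)    # 3.0, the conventional value
fdt_sigma <- function(gamma, kBT = 1) {
  if (any(gamma < 0)) stop("gamma must be non-negative")
  if (any(kBT <= 0)) stop("kBT must be positive")
  sqrt(2 * gamma * kBT)
}

#' DPD force field
#'
#' Bundles the symmetric conservative repulsion matrix a_ij (in kBT/r_C),
#' the friction gamma and noise amplitude sigma of the pairwise thermostat,
#' the dissipative weight exponent s, and the cut-off radius. By default
#' sigma is derived from gamma through the fluctuation-dissipation relation;
#' passing an inconsistent sigma explicitly marks the field as not
#' thermostat-consistent.
#'
#' @param repulsion Symmetric numeric matrix of repulsion coefficients with
#'   bead-type names as dimnames, or a single number for a one-type fluid.
#' @param gamma Friction coefficient.
#' @param sigma Noise amplitude; default `fdt_sigma(gamma, kBT)`.
#' @param s Dissipative weight exponent (> 0).
#' @param cutoff Cut-off radius (reduced units; default 1).
#' @param kBT Thermal energy used in the fluctuation-dissipation check.
#' @return Object of class `dpd_forcefield` with a `thermostat_consistent`
#'   flag.
#' @export
#' @examples
#' ff <- dpd_forcefield(25, gamma = 4.5, s = 2)    # conventional water
#' ff$sigma                                        # 3
dpd_forcefield <- function(repulsion, gamma, sigma = fdt_sigma(gamma, kBT),
                           s = 2, cutoff = 1, kBT = 1) {
  if (is.numeric(repulsion) && is.null(dim(repulsion)) &&
      length(repulsion) == 1) {
    repulsion <- matrix(repulsion, 1, 1,
                        dimnames = list("(H2O)4", "(H2O)4"))
  }
  if (!is.matrix(repulsion) || nrow(repulsion) != ncol(repulsion))
    stop("repulsion must be a square matrix (or a single number)")
  if (any(repulsion < 0)) stop("repulsion coefficients must be >= 0")
  if (max(abs(repulsion - t(repulsion))) > 1e-10)
    stop("repulsion matrix must be symmetric")
  if (is.null(rownames(repulsion)))
    dimnames(repulsion) <- list(paste0("T", seq_len(nrow(repulsion))),
                                paste0("T", seq_len(nrow(repulsion))))
  if (!is.numeric(s) || length(s) != 1 || s <= 0)
    stop("weight exponent s must be a single positive number")
  if (gamma < 0 || sigma < 0) stop("gamma and sigma must be non-negative")
  if (cutoff <= 0) stop("cutoff must be positive")
  consistent <- isTRUE(abs(sigma^2 - 2 * gamma * kBT) <=
                         1e-10 * max(1, 2 * gamma * kBT))
  structure(list(repulsion = repulsion, sigma = sigma, gamma = gamma, s = s,
                 cutoff = cutoff, kBT = kBT,
                 thermostat_consistent = consistent),
            class = "dpd_forcefield")
}

#' @export
print.dpd_forcefield <- function(x, ...) {
  cat("DPD force field\n")
  cat(sprintf("  sigma = %g, gamma = %g, s = %g, cutoff = %g r_C\n",
              x$sigma, x$gamma, x$s, x$cutoff))
  cat(sprintf("  thermostat-consistent (sigma^2 = 2 gamma kBT): %s\n",
              x$thermostat_consistent))
  cat("  repulsion a_ij [kBT/r_C]:\n")
  print(x$repulsion)
  invisible(x)
}

#' Calibrated homogalacturonan/water force field
#'
#' The full bead-type repulsion matrix for (H2O)4, GalA(-) and GalA beads
#' combined with the calibrated thermostat (s = 0.5, gamma = 23.53,
#' sigma = 6.86); see [repulsion_table()] for the pair coefficients.
#'
#' @param s Dissipative weight exponent (default 0.5, calibrated).
#' @param gamma Friction coefficient (default 23.53, calibrated).
#' @return A [dpd_forcefield()] object covering all three bead types.
#' @export
hg_forcefield <- function(s = 0.5, gamma = 23.53) {
  dpd_forcefield(repulsion_table(), gamma = gamma, s = s)
}
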