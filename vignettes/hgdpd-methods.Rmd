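---
title: "Coarse-grained DPD modelling of homogalacturonan: methods and design"
author: "hgdpd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained DPD modelling of homogalacturonan: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgdpd)
```

## The model

`hgdpd` simulates homogalacturonan — the unbranched pectic polysaccharide of
alpha-(1-4)-linked d-galacturonate units — in water at the mesoscale, using
dissipative particle dynamics (DPD). One bead stands for four water molecules
or for one galacturonic-acid residue, either protonated (GalA) or
deprotonated (GalA(-)); a 4:1 ratio is used because four waters occupy about
120 A^3, close to the ~140 A^3 of a galacturonate unit.

Beads interact pairwise inside a cut-off radius $r_C$ through three forces:

* a soft conservative repulsion
  $F^C_{ij} = a_{ij}\,\omega^C(r_{ij})\,\hat r_{ij}$ with the linear weight
  $\omega^C(r) = 1 - r/r_C$ for $r < r_C$ and 0 otherwise;
* a dissipative (friction) force
  $F^D_{ij} = -\gamma\,\omega^D(r_{ij})\,(v_{ij}\cdot\hat r_{ij})\,\hat r_{ij}$
  with the generalized weight $\omega^D(r) = (1 - r/r_C)^s$;
* a random force
  $F^R_{ij} = \sigma\,\omega^R(r_{ij})\,\xi_{ij}\,\Delta t^{-1/2}\,\hat r_{ij}$
  with $\omega^R = \sqrt{\omega^D}$ and symmetric unit-variance Gaussian
  noise $\xi_{ij}$.

The last two form a pairwise thermostat; the stationary state is canonical
at temperature $T$ exactly when $\omega^D = (\omega^R)^2$ and
$\sigma^2 = 2\gamma k_BT$ (`fdt_sigma()` enforces the latter). The exponent
$s$ reshapes the dissipative weight and is the main handle on viscosity and
diffusivity: $s = 2$ is the conventional choice, $s = 0.5$ the value this
model calibrates to. Chains add harmonic bonded terms,
$u^B = \tfrac12 k_S (r - l_0)^2$ between consecutive residues and
$u^A = \tfrac12 k_A (\theta - \theta_0)^2$ on each interior angle.

### Reduced units

All simulation quantities are dimensionless. The base units are the cut-off
radius (length), the (H2O)4 bead mass $11.968\times10^{-26}$ kg, and
$k_BT = 4.115\times10^{-21}$ J at 298 K. The printed unit "J/mol" for this
constant is dimensionally inconsistent with $\sigma^2 = 2\gamma k_BT$; it is
interpreted as Joule ($k_B \cdot 298\,$K). The cut-off follows from the
reference fine-grained system via $r_C = (\rho V / N)^{1/3}$: 967 water
molecules in a 29,894 A^3 box map to 240 beads (leaving 7 free molecules as
a clustering margin) at bead density $\rho = 3$, giving $r_C = 7.2$ A. The
GalA and GalA(-) reduced masses are shipped as the printed constants 2.623
and 2.609 rather than re-derived from molar masses, which do not reproduce
them exactly.

The time unit $\tau$ is deliberately *not* fixed a priori: it is an output
of calibration. A `reduced_units` object therefore starts without a time
unit and any time-dependent conversion fails loudly until
`set_time_unit()` is called.

## Integration and neighbour search

The equations of motion are integrated with the modified velocity-Verlet
scheme: positions advance with the current force, a predicted velocity
$\tilde v = v + \lambda\,\Delta t\, f/m$ enters the dissipative force,
forces are evaluated once per step and the velocity is corrected with the
trapezoidal average. $\lambda = 0.5$ (the canonical choice; with
$\Delta t = 0.001\,\tau$ the results are insensitive to it). The small time
step follows the observation that accurate integration of the soft
conservative potential requires MD-like steps.

Neighbour search uses cell lists with cell edge $\ge r_C$: candidate pairs
from adjacent cells are enumerated every 8 steps (the refresh interval of
the production protocol) and re-filtered by minimum-image distance at every
force evaluation. Because any pair closer than $r_C$ lies in adjacent
cells, the candidate set is a strict superset of the interacting set at all
times between refreshes — no pair can enter the cut-off undetected. The
test suite checks the filtered list against an all-pairs oracle.

Random numbers come from a Mersenne Twister generator seeded per run; the
same seed reproduces a trajectory bit for bit. One symmetric draw is made
per in-range pair per force evaluation. Exactly overlapping beads (r = 0)
contribute zero force and are counted as overlap events: soft potentials
make this recoverable, so it warns rather than aborts.

Runs follow the warm-up/production protocol: 2,000 warm-up steps are
discarded, production frames (positions and velocities, plus unwrapped
positions for the MSD) are saved every 200 steps by default.

## The coarse-graining (clustering) algorithm

To extract coarse-grained statistics from a fine-grained trajectory, water
molecules must be grouped dynamically into equal-size clouds — one per
bead. k-means does not guarantee equal occupancy, so `cg_map_trajectory()`
implements a step-wise iterative nearest-neighbour assignment:

1. Bead positions start from randomly chosen molecule (oxygen) positions in
   the first frame; later frames start from the previous frame's updated
   bead positions.
2. Each frame runs `cg_ratio` rounds. In a round, every bead searches for
   its unique nearest unassigned molecule (minimum-image distance). A
   molecule claimed by several beads goes to the closest claimant; losing
   beads search again among the remaining molecules until every bead has
   gained exactly one molecule.
3. Bead positions are updated only after all rounds finish, to the
   minimum-image-aware centre of mass of their clouds.

Distance ties go to the lower molecule id (bead choosing) and the lower
bead index (conflict between claimants); the algorithm itself does not
specify tie-breaks, and determinism is required for the oracle tests, which
compare the implementation against an independent literal re-implementation
of the round/claim/conflict rules. The bead count must leave at least one
molecule unassigned — the stability margin that guarantees every re-search
finds a molecule.

Two bead-velocity estimators are provided (`velocity_mode`): the mean of
the member molecules' velocities (default; for equal-mass water this is the
cloud's centre-of-mass velocity) and the bead displacement divided by the
frame interval. The reference statistics do not pin down which convention
"average velocity" uses; the choice moves the calibrated time scale by a
few percent, which the calibration tolerances absorb.

On static input the frame-chained assignment relaxes within a few frames to
an exact fixed point (same partition and bead positions every frame); this,
rather than immediate two-frame identity, is the guaranteed behaviour, and
is what the tests assert.

## Observables

* `rdf()` — pair-count g(r) with minimum-image distances, normalized by the
  ideal-gas shell expectation of the selected type pair, averaged over
  frames.
* `msd()` / `diffusion_coefficient()` — mean-squared displacement over all
  lags with every saved frame as a time origin, from unwrapped coordinates
  (engine-tracked, or reconstructed by minimum-image chaining under the
  assumption that nothing moves farther than half a box between frames —
  violated input is an error telling the user to save more often).
  D is the least-squares MSD slope over lags in 20–80% of the maximum lag
  (excluding the short-time ballistic regime) divided by 6. A log-log
  slope of the early MSD is reported as a ballistic-regime diagnostic.
  Window-sensitivity checks in development moved D by at most a few
  percent with no systematic trend.
* `velocity_stats()` / `kinetic_temperature()` — mean and RMS speed,
  speed histogram, and the equipartition temperature
  $T = \sum m v^2 / (3 N k_B)$ averaged over frames.
* `bonded_distributions()` — per-term-type bond-length and angle samples,
  histograms and moments.
* `chain_contacts()` — inter-chain bead pairs within a contact distance per
  chain bead; the qualitative aggregation metric.

## Calibration workflow

The time scale can be fixed two ways:

* diffusion matching: $\tau = D_{DPD}\, r_C^2 / D_{MD}$;
* velocity matching: $\tau = (v_{DPD} / v_{MD})\, r_C$.

For conventional water parameters ($s=2$, $\sigma=3$, $\gamma=4.5$,
$a=25$) the two disagree by roughly an order of magnitude — diffusion
matching gives $\tau \approx 114$ ps while the bead velocities imply
$\tau \approx 12$ ps — so a system calibrated on diffusivity alone loses
the velocity scale and vice versa. The workflow in `parameter_scan()`
therefore explores $(s, \gamma, a)$ with $\sigma$ always tied to $\gamma$
by the fluctuation–dissipation relation, reporting per grid point the
reduced diffusivity, speeds, the velocity-matched $\tau$ and the real-unit
diffusivity that $\tau$ implies. Because the RDF responds only to the
conservative force, the water repulsion is fitted first
(`fit_repulsion_to_rdf()`, unweighted least squares on the shared binning
up to 3 $r_C$); the thermostat parameters then reconcile both transport
statistics, which happens near $s = 0.5$, $\gamma = 23.53$,
$\sigma = 6.86$, $a_{ww} = 50$. `calibration_report()` always prints both
$\tau$ estimates and their ratio.

The velocity statistic used for matching defaults to the RMS speed (the
closed-form equipartition speed of a unit-mass bead is $\sqrt{3}\,
r_C/\tau$, which is what makes the velocity-matched $\tau$ essentially
parameter-independent); a mean-speed mode is available.

Bonded parameters are fitted by harmonic-bath moment matching (rest value =
sample mean, stiffness $= k_BT/\mathrm{variance}$), optionally refined by
simulating the corresponding dimer or trimer and iteratively rescaling
until the simulated moments match the reference samples. Two points of
care, both discovered by the property tests:

* The equilibrium angle distribution of a trimer is
  $\propto \sin\theta\,\exp(-\beta k_A (\theta-\theta_0)^2/2)$ on
  $[0, \pi]$. At the tabulated stiffnesses ($k_A \approx 17$–$32$ near
  $\theta_0 \approx 2.8$ rad) the Jacobian and the truncation at $\pi$
  lower the variance 20–33% below the harmonic $k_BT/k_A$ and shift the
  mean below $\theta_0$; the harmonic moment-matching estimate is
  therefore only an initial guess, and the refinement loop exists to
  absorb exactly this bias. Engine validation uses the exact Boltzmann
  moments computed by quadrature, not the harmonic approximation.
* DPD forces are central. An isolated dimer's bond length is thermostatted
  directly, but an isolated trimer's bending mode is orthogonal to every
  pairwise radial direction at linear order and equilibrates extremely
  slowly in vacuum. Refinement and validation therefore immerse the
  oligomer in an ideal thermostat bath — water beads with zero non-bonded
  repulsion but full friction/noise — which thermalizes bending while
  leaving the bonded Boltzmann marginal exact.

## Synthetic fine-grained trajectories

The coarse-graining and calibration stages are exercised end to end on
synthetic data (`generate_brownian_water()`): molecules perform independent
periodic Brownian motion (per-axis step variance $2 D \Delta t$) with
Maxwell–Boltzmann velocities redrawn each frame at 298 K, in the reference
967-molecule, 31.036 A box, saved every 2 ps. The default molecular
diffusivity of 0.6 A^2/ps puts 4:1 cloud diffusivity near the reference
0.151 A^2/ps regime. The generator embeds its ground truth in the metadata
so recovery tests are self-contained.

This fixture reproduces the *statistics the pipeline consumes* — diffusive
transport, thermal velocities, periodic geometry — and deliberately not the
structure of real water: there is no pair correlation (g(r) is flat), no
hydrogen-bond network, no momentum conservation, and velocities are
uncorrelated between frames. Tests that pass on it validate the mapping,
estimation and calibration machinery, not the fidelity of any particular
water model.

## Problem sizes and numerical choices

The standard study system is the 3,000-bead water box ($\rho = 3$,
$10^3\,r_C^3$, i.e. 72 A across) integrated at $\Delta t = 0.001\,\tau$
with 2,000 warm-up and 20,000 production steps, saved every 200 steps, and
statistics averaged over 3 seeds. These sizes are used by the acceptance
script and tests; they reproduce the reference transport numbers to within
a few percent while keeping a full calibration pass on a single CPU in
minutes. The chain-aggregation demonstration in the test suite runs 6
chains of 35 residues among ~2,000 beads for 30,000 steps and asserts
growth of the inter-chain contact metric; the production-scale
configuration (216 chains x 35 residues, 100,000 beads) is available
through `build_system()` for users who want the full-size run.

Other fixed numerical choices: forces at exactly $r = r_C$ are zero (open
interval); near-collinear angle triplets clamp $\cos\theta$ to
$[-1+\varepsilon, 1-\varepsilon]$ and are counted as degenerate events;
chain placement is a random walk with step $l_0$ and interior angle
$\theta_0$, with initial overlaps allowed (soft potentials plus warm-up
resolve them); initial velocities are Maxwell–Boltzmann with the
centre-of-mass momentum removed.

## Worked example

A desk-scale calibration check (a 5^3 box for speed):

```{r example, eval = FALSE}
st <- init_water_state(box_edge = 5, seed = 1)
ff <- dpd_forcefield(50, gamma = 23.53, s = 0.5)   # calibrated water
tr <- run_dpd(st, ff, integrator_config())
calibration_report(tr)
```

On the full 10^3 box this prints a velocity-matched time scale near 12.2 ps
against the reference speed 1.021 A/ps, and a real-unit diffusivity near
0.151 A^2/ps — the agreement of the two transport statistics that motivates
the calibrated parameter set.

## Known limitations

* Rest lengths in the distance-bond table are printed in an ambiguous
  bracketed unit in the source material; the reduced column is authoritative
  here (0.62–0.63 $r_C \approx$ 4.5 A; the alternative reading is
  dimensionally impossible for these bonds). Likewise the radian column of
  the angle table is used where the degree column disagrees in the third
  digit.
* The reduced self-diffusivity of conventional-parameter water measured by
  this engine is $\approx 0.30$ (in line with standard DPD literature for
  $s=2$, $\sigma=3$, $\gamma=4.5$, $a=25$, $\rho=3$), somewhat below the
  0.332 used as the diffusion-matching example value; the derived
  113.97 ps diffusion-matched time scale is reproduced exactly from the
  stated inputs.
* Electrostatics, pressure coupling, non-cubic boxes, esterified residues,
  rhamnogalacturonan side chains and Ca^2+ cross-linking are out of scope.
* The printed production-run step count and duration imply a time step
  different from $0.001\,\tau$; the default here remains $0.001\,\tau$.
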