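---
title: "Methods: puckering coordinates, metadynamics and catalytic-geometry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: puckering coordinates, metadynamics and catalytic-geometry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycofel)
```

glycofel implements the analysis layer of enhanced-sampling studies of
pyranose conformation and glycoside hydrolysis: puckering coordinates and
their collective variables (CVs), standard metadynamics bookkeeping and
free-energy-landscape (FEL) reconstruction, recrossing-cycle reaction
profiles, and per-frame catalytic geometry. This vignette records the models,
the conventions chosen where several are defensible, the defaults and their
units, and what the synthetic validation does and does not demonstrate.

## Ring puckering

### Model

For six ring atoms at positions $\mathbf{r}_j$ ($j = 1..6$), translated to
their geometric centre, the mean plane is defined by the normal
$\mathbf{n} \propto \mathbf{R}' \times \mathbf{R}''$ with
$\mathbf{R}' = \sum_j \mathbf{r}_j \sin\frac{2\pi(j-1)}{6}$ and
$\mathbf{R}'' = \sum_j \mathbf{r}_j \cos\frac{2\pi(j-1)}{6}$. The
out-of-plane displacements $z_j = \mathbf{r}_j \cdot \mathbf{n}$ carry all
pucker:

$$q_2 \cos\varphi_2 = \sqrt{\tfrac13}\sum_j z_j \cos\tfrac{4\pi(j-1)}{6},
\quad
q_2 \sin\varphi_2 = -\sqrt{\tfrac13}\sum_j z_j \sin\tfrac{4\pi(j-1)}{6},
\quad
q_3 = \sqrt{\tfrac16}\sum_j (-1)^{j-1} z_j,$$

with $Q = \sqrt{q_2^2 + q_3^2}$ (Å), $\theta = \operatorname{atan2}(q_2,
q_3) \in [0°, 180°]$ and $\phi = \varphi_2 \in [0°, 360°)$. The normalized
CVs are $\mathrm{cv}_i = q_i/Q$ for the Cartesian components
$(q_x, q_y, q_z) = Q(\sin\theta\cos\phi, \sin\theta\sin\phi, \cos\theta)$.

### Conventions that matter

* **Atom ordering is O5 = 1, C1 = 2, …, C5 = 6.** This is the common
  glycoscience convention and places the ⁴C₁ chair at the north pole. It is
  load-bearing: relabelling the ring cyclically by one position shifts $\phi$
  by +120° and mirrors $\theta \to 180° - \theta$, which *renames* conformers
  (a B₁,₄ becomes a ¹,⁴B) — an ambiguity that has caused real confusion in
  crystallographic refinement of anhydro-sugars. The property tests pin both
  the offset and the mirror.
* **Canonical lattice.** Chairs at $\theta \in \{0°, 180°\}$; six boats and
  six twist-boats alternating every 30° of $\phi$ on the equator; twelve
  envelopes and twelve half-chairs alternating every 30° on the
  $\theta = 54.74°$ and $125.26°$ bands ($\operatorname{atan}\sqrt2$, the
  latitude of a pure single-atom displacement). Half-chairs are placed on the
  same band as envelopes; the slight canonical split (≈51° vs ≈55°) is
  irrelevant for nearest-neighbour classification at 30° lattice spacing.
  The lattice is generated in code from pure $m=2$/$m=3$ displacement
  patterns rather than tabulated, and the suite asserts 38/38
  self-classification and the family counts 2 + 6 + 6 + 12 + 12.
* **Classification** minimises great-circle distance on the $(\theta, \phi)$
  sphere; exact ties break lexicographically by conformer name and are
  flagged.
* **Degenerate inputs.** $Q < 10^{-6}$ Å is a planar ring: angles and CVs are
  `NA` with `phi_defined = FALSE`. At the poles ($\sin\theta < 10^{-8}$),
  $\phi$ is reported as 0 with the same flag. Coincident atoms abort.
* **`ideal_ring()`** inverts the construction: a regular hexagon of
  circumradius 1.54 Å (a standard C–C bond length; only the z-displacements
  carry pucker), traversed clockwise from +z so the mean-plane normal points
  along +z, plus $z_j = \sqrt{1/3}\,q_2\cos(\phi + 120°(j-1)) +
  \sqrt{1/6}\,q_3(-1)^{j-1}$. Because these $z_j$ have no $m = 0, 1$
  component, the forward transform recovers $(Q, \theta, \phi)$ to
  floating-point accuracy — the suite sweeps 1000 random triples at 1e-6.
* **Hemisphere projection** is polar azimuthal equidistant: $r = \theta/90°$
  (north) or $(180° - \theta)/90°$ (south), $x = r\cos\phi$, $y = r\sin\phi$;
  pole to origin, equator to the unit rim. The equator belongs to both
  hemispheres; excluded states are counted.

Angles cross the API in degrees and are converted to radians at the point of
use.

## Metadynamics engine

### Bias model and schedule

Standard (non-well-tempered) metadynamics only: hills
$h\,\exp(-\sum_i (x_i - c_i)^2 / 2\sigma_i^2)$ deposited every `stride` MD
steps, with a two-level height schedule — `initial_height` for hills
1..`switch_after`, `reduced_height` afterwards. That mirrors the manual
height-reduction protocol of the simulations this package emulates (1.0
reduced to 0.5 kcal/mol after 599 hills for the puckering CVs); the schedule
switch is exact and unit-tested. Well-tempered metadynamics and reweighting
estimators are out of scope. Energies are kcal/mol throughout, with
$k_B = 0.0019872041$ kcal mol⁻¹ K⁻¹ and a default temperature of 300 K.
Puckering CVs are treated as non-periodic in $[-1, 1]$ and the reaction CV as
non-periodic — stated explicitly because HILLS dialects differ on this.

The FEL estimate is the **final-bias convention**, $F(x) = -V_\text{bias}(x)$
shifted so $\min F = 0$. Whether landscape contours should come from the
final or a time-averaged bias is not fixed by convention everywhere; the
final bias is implemented, and `fel_convergence()` exposes the difference by
tracing the basin free-energy difference against hill count — the standard
stopping diagnostic ("deposit until the difference between local minima stays
constant").

Reported deposited times use half-up rounding to two decimals, the convention
under which 909 hills × 250 steps × 0.5 fs prints as 113.63 ps.

### Toy dynamics

The Langevin sampler integrates the overdamped equation
$dx = -\nabla(V + V_\text{bias})/\gamma\,dt + \sqrt{2 k_B T\,dt/\gamma}\,\xi$
by Euler–Maruyama — the simplest scheme whose stationary distribution is
directly testable (the suite checks the harmonic-well variance against
$k_BT/k$ within 10%). The compiled loop evaluates the exact hill sum each
step, skipping hills beyond 8σ (relative error < 1e-13 of a hill height).
Friction $\gamma$ is in kcal mol⁻¹ ps Å⁻² (mobility $1/\gamma$), timestep in
fs to match the conventions of the hills bookkeeping. Trajectories that leave
10× the potential's grid bound abort with a diagnostic; stopping after a
target number of R→P→R recrossings uses dwell-filtered basin visits
(default 0.05 ps) plus a short settling tail so the closing reactant visit
registers in downstream analysis.

Analytic potentials: `double_well` ($V = B((x/a)^2 - 1)^2$, barrier $B$ at
$x = 0$, minima $\pm a$), `harmonic`, and a 2D `triwell` (three Gaussian
wells on a quartic confinement) for multi-basin exercises.

### Validation regimes and what they show

Two regimes are used deliberately:

* **Protocol emulation** (defaults: heights 1.0→0.5 after 599 hills,
  stride 250, timestep 0.5 fs, width 0.06 on the double well): barrier
  recovery through the full pipeline. Hill discretisation and the
  escape-at-threshold effect make single-recrossing barriers uncertain by
  roughly one hill height plus a few $k_BT$; the acceptance test asserts the
  exponential-averaged barrier within 1.5 kcal/mol of the analytic 5 at a
  fixed seed. This mirrors the magnitude of cycle-to-cycle spread a real
  biased-reaction study reports.
* **Near-ideal filling** (heights 0.1→0.05, width 0.15, stride 100,
  timestep 0.25 fs, friction 0.05): used for the equalization property. With
  hills much smaller than landscape features and fast diffusion, the basin
  free-energy-difference trace of a symmetric well enters and stays within a
  ±0.75 kcal/mol band over the second half of deposition, and the final
  inter-minimum difference lies within 0.5 kcal/mol of the analytic 0. The
  band scales with hill height and with the number of hills deposited per
  basin-to-basin diffusion time, which is why the property is checked in this
  regime and not under protocol-emulation hills.

## Reaction coordinate and profiles

The reaction CV is the signed distance sum over the six covalent bonds broken
(+) or formed (−) in the inverting single-displacement mechanism. It is
exactly linear in each distance (permutation-invariant, unit-tested against
naive per-term recomputation at 1e-12). Atom selectors are residue + atom
name pairs, format-agnostic across PDB and XYZ.

**Calibration protocols.** Hill widths are half the sample standard deviation
(n−1 denominator) of a CV in an unbiased run. The deposition stride is the
mean interval between the first five consecutive CV peaks; "peak" is not
sharply defined for real data, so peaks are strict three-point maxima after a
centred moving average (window 5 samples, configurable), and both the
all-peaks mean and the unsmoothed peak count are reported alongside. Neither
smoothing choice is asserted to be the original authors'. A constant series
(zero width) and series with fewer than five peaks are errors.

**Cycles and averaging.** `detect_recrossings()` segments a CV series into
maximal non-overlapping R→P→R cycles; a basin visit counts only after
0.5 ps of continuous residence by default, filtering grazing touches, and the
hill index at each recrossing completion is reported. Per-cycle profiles use
the **cumulative-hills convention** — all hills from the start of the run to
the end of the cycle — because stopping protocols report recrossings against
the cumulative deposition count; the alternative (per-cycle hill spans only)
is exposed via `cumulative = FALSE`. Profiles are combined by the Boltzmann
(exponential) average at the simulation temperature,
$f_\text{avg} = -k_BT\ln\frac1n\sum_i e^{-F_i/k_BT}$ — the standard
metadynamics convention for the term "exponential average" — then shifted to
min 0. SD and SE ($= \mathrm{SD}/\sqrt{n}$) are computed pointwise on the
*unshifted* per-cycle profiles, avoiding artificial zero variance at a shared
shifted minimum; this is one of several possible conventions and is stated as
such.

**Barriers.** $\Delta G^\ddagger$ is the maximum on the inter-basin segment
minus the reactant minimum, $\Delta G_\text{rxn}$ the product minus reactant
minimum, with the SE at the TS as the quoted uncertainty; both are invariant
under additive shifts and stable under grid refinement within one cell.
Multiple local maxima within one SD of the top trigger a multi-TS warning
listing candidates. `normalized_reaction_coordinate()` maps the CV linearly
onto $\xi \in [0,1]$ between the basin minima, falling back to time ordering
(with a warning) when more than 20% of steps run backward; empty bins are
reported as missing, never interpolated.

## Catalytic-geometry analysis

Distances and signed torsions (IUPAC convention; the flattening dihedral is
C5–O5–C1–C2 with O5 the ring oxygen) are invariant under rigid motions at
1e-9, enforced by property tests. The shared-proton analysis counts a frame
as "shared" when donor–H ≥ 1.2 Å **and** donor–acceptor ≤ 2.6 Å, and raises
the low-barrier hydrogen-bond flag when the shared fraction is ≥ 0.25 and the
mean donor–acceptor distance is within 2.6 Å. These thresholds are heuristics
consistent with shared-proton dyad geometry (donor–H ≈ 1.3 Å,
donor–acceptor ≈ 2.5 Å), configurable, and not attributed to any original
study; lowering `shared_dh_min` can only increase the shared fraction
(monotonicity is tested). Itineraries run-length-compress per-frame conformer
labels, merge runs below 2% of the trajectory into their longer neighbour
(flicker filtering) and are idempotent under re-compression.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their parameters and seed (bit-identical
reruns, asserted):

* `gen_ring_trajectory()` — rings fluctuating about canonical puckers with
  isotropic Gaussian positional noise (default 0.02 Å) and Markov switching
  between conformers; the redraw-from-occupancy chain makes the requested
  occupancy the stationary distribution.
* `gen_reaction_trajectory()` — all keyframed quantities follow
  piecewise-linear interpolation in $\xi$ through MC (0), TS (0.5) and
  P (1), with noise (default 0.03 Å, chosen to keep width estimates near
  protocol magnitudes) applied to the *distances* before a deterministic
  collinear embedding, so measured distances equal the noisy prescription
  exactly. The default keyframes anchor on the mechanism's reported geometry
  — glycosidic C1–O′ 1.5 → 2.6 Å against Ow–C1 3.5 → 2.6 Å at the TS, dyad
  proton 1.32 → 1.06 Å, C1–O5 1.41 → 1.29 Å with an 11° flattening dihedral,
  pucker ¹,⁴B → ⁴E → ¹,⁴B along the sphere geodesic — completed with
  standard bond lengths where no value is reported. Only non-positive
  prescribed distances are unrealizable for the collinear embedding; they
  abort naming the offending distance.
* `gen_dyad_ensemble()` — independent Gaussian donor–H and donor–acceptor
  marginals on collinear atoms.
* `gen_hills()` — exact height schedules with times
  `index × stride × timestep` and reflected-random-walk centers.

**Limitations.** The reaction trajectories are abstract distance carriers,
not chemically valid sugars: bond angles, excluded volume and correlations
between distances are absent, and the ring travels the pucker geodesic rather
than a dynamical path. Passing tests on these fixtures demonstrates that the
*analysis* — coordinate transforms, segmentation, averaging, classification —
is correct and self-consistent, not that any simulation protocol or level of
theory reproduces experimental energetics. Headline energetics of real
systems (a ~17 kcal/mol glycosylation barrier, a ~2 kcal/mol boat-vs-chair
preference) come from QM/MM sampling that desk-scale surrogates cannot
reproduce, and this package makes no such claim: its stochastic acceptance
checks recover the *analytic* properties of its own toy inputs.

## Problem sizes

The suite and the acceptance script run 1000-triple puckering round-trips,
1000-hill/1000-point bias oracles, toy runs of up to a few thousand hills
(hundreds of thousands of Langevin steps, compiled), reaction paths of a few
hundred frames, and dyad ensembles of 2000–10000 frames — sizes at which the
full pipeline completes in about a minute on one CPU while keeping stochastic
assertions comfortably powered.

## Interfaces

Trajectories are plain tibbles (`frame`, `residue`, `atom`, `x`, `y`, `z`,
optional `time`), readable from multi-model PDB (via bio3d) and multi-frame
XYZ; hills and CV series use PLUMED-style whitespace dialects
(`#! FIELDS` headers; `time center… sigma… height` and `time cv… [bias]`).
Result objects provide `tidy()`/`glance()` and `autoplot()` methods, so the
package composes with dplyr/ggplot2 workflows.
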