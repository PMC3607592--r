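---
title: "Free-energy landscapes of a clamshell ligand-binding domain: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy landscapes of a clamshell ligand-binding domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clamshellfe)
```

# The model

`clamshellfe` treats a bilobal receptor ligand-binding domain as a
two-state-coupled system: a conformational equilibrium of the clamshell
(closed / half-closed / open along a domain-closure coordinate) coupled
to a binding equilibrium of the ligand in the open cleft. The total
binding free energy is decomposed into two sequential substeps —
(I) opening the closed complex, (II) removing the ligand from the open
site — each estimated from biased sampling along its own reaction
coordinate, and combined by plain addition with explicit signs.

The pipeline is: **geometry** (selections, centers of mass, Kabsch
superposition) → **collective variables** (pair COM distance, projected
site distance, interdomain angle/torsion, PCA-mode projections) →
**biased sampling** (umbrella windows or staged metadynamics; in this
package produced by an overdamped Langevin integrator on analytic
potentials) → **estimators** (WHAM; hill-sum reconstruction) →
**interpretation** (minima/barriers/plateaus, three-state assignment by
reference RMSD, substep combination).

## Units and conventions

Lengths are nanometres everywhere; PDB input/output converts Angstrom
at the boundary, because all reaction-coordinate numbers in this domain
are conventionally quoted in nm. Energies are kcal/mol with
`k_B = 0.0019872041` kcal/mol/K and a default temperature of 300 K
(`kT = 0.596` kcal/mol). Angles are degrees; the interdomain torsion is
signed in (−180°, 180°] with the right-hand rule about the hinge axis.
Substep free energies are positive unbinding costs; binding free
energies are their negations, and every report prints the convention,
because the sign is the easiest thing to lose when combining substeps.

# Rigid-body PCA

Internal lobe motion is removed by substituting, per frame and per
lobe, the Kabsch-fitted rigid reference structure ("stripping"); hinge
atoms pass through. PCA is then performed on the 3N Cartesian
coordinates of the backbone atoms of both lobes plus hinge, after a
global superposition on lobe 1 that removes overall
rotation/translation. Three design points deserve explanation:

- **The reference structure.** When none is supplied, the per-lobe
  time-averaged structure (after per-lobe superposition onto the first
  frame) is used. An "optimized" reference is not uniquely defined for
  trajectory data; the time average is reproducible and unbiased
  toward any single frame.
- **Sign convention.** Eigenvectors have arbitrary sign, which breaks
  test reproducibility and plot interpretation. Mode 1 is oriented so
  its projection increases with the interdomain angle (it is the
  clamshell-opening mode); the remaining modes are oriented to make
  their largest-magnitude component positive.
- **Backbone, unweighted.** The covariance uses unweighted backbone
  coordinates, matching the RMSD conventions used for the same systems.
  Mass weighting changes eigenvalues by a near-constant factor for
  backbone-only atom sets and was left out.

A caveat the tests made explicit: because the Kabsch fit preserves
centroids, stripping does **not** change equal-mass lobe centers of
mass, so COM-based angles are identical before and after stripping.
Stripping removes internal fluctuation (per-lobe RMSF collapses), not
COM noise.

# The synthetic world

The generator module replaces an all-atom MD engine; its defaults *are*
the stated world of the package's tests, chosen once:

- **Landscapes.** Gaussian-well potentials: an asymmetric double well
  (wells at 0.53 and 1.12 nm — the closed and open coordinates — with
  planted asymmetry `delta`), and a triple well with minima at
  0.53/0.76/1.12 nm and relative depths 0/1.35/2.5 kcal/mol, emulating
  a ligand-bound landscape with closed, half-closed and open states.
  Wells are several widths apart, so the planted minima positions and
  depth differences are exact to ~1e−5, and the second well's width is
  scaled for equal curvature so the planted `delta` is at once the
  minimum-to-minimum difference, the PMF asymmetry and the basin
  free-energy difference. Because Gaussian wells flatten far from the
  minima, half-harmonic walls (500 kcal/mol/nm², 0.3 nm outside the
  outermost wells) bound the coordinate — the analogue of the finite
  window range in a real umbrella campaign. The walls are part of the
  potential and of every analytic reference the estimators are compared
  against.
- **Dynamics.** First-order (overdamped) Euler–Maruyama Langevin
  dynamics, `x ← x − (D/kT)∇U Δt + sqrt(2DΔt) ξ`, `D = kT/γ`,
  `γ = 1/ps`. Only configurational statistics matter for PMF work, and
  the overdamped chain has a known stationary distribution to converge
  to. The integrator is exact only as `Δt → 0`: the stiffest curvature
  in play (potential plus bias, `k_max`) must satisfy
  `k_max·Δt/γ ≲ 0.1`, which is why the documented examples use
  timesteps of 1e−4 to 2e−5 ps for stiff umbrella windows. Noise comes
  from R's seeded generator, so every run is bit-reproducible per seed,
  and per-window seeds derive deterministically from the base seed.
- **The toy clamshell.** Two rigid anisotropic point clouds (default
  120 atoms each — the realistic end of desk scale; a real lobe has
  ~200 backbone atoms) joined at a 30-atom hinge cluster at the origin,
  base interdomain angle 112° (closed-complex-like; 140° for apo-like
  settings). Three planted rigid-body modes: bend (rotation of lobe 2
  about the hinge normal — changes the interdomain angle one-to-one),
  twist (about the lobe-2 axis) and rock (about the lobe-1 axis), the
  latter two angle-invariant by construction. Sinusoidal schedules use
  exact Fourier frequencies over the default 200 frames, so the planted
  time courses are exactly orthogonal. Per-atom Gaussian jitter
  (default 0.01 nm) models internal motion. Ground truth (angle series,
  mode time courses, unit mode fields, displacement amplitudes) rides
  along as attributes.

  One subtlety: eigenvalue order follows *displacement* amplitude —
  angle amplitude (rad) × the lever-arm norm of the rotation field —
  not raw angle amplitude. The generator records these, and the
  acceptance test compares eigenvalue ratios against them.

What the generator does **not** emulate: solvent and friction
anisotropy, force-field detail, barrier recrossing dynamics of a real
hinge, ligand degrees of freedom, and any coupling between the lobes'
internal modes and the global ones. A green test therefore establishes
the correctness of the estimators and the geometry/PCA machinery on
data with known truth — not the accuracy of any particular force field
or sampling length on a real receptor.

# Estimators and numerical choices

**WHAM.** Log-space self-consistent iteration with gauge `f_1 = 0`,
tolerance 1e−7 kcal/mol on the offsets, at most 1e5 iterations;
half-open bins of 0.01 nm by default (≥5 bins per 0.05 nm window
spacing); out-of-range samples are counted and reported, never silently
dropped; zero-count bins become `NA`, never interpolated. Windows whose
occupied bins do not overlap anywhere form disconnected components and
are rejected by name. Since a PMF is defined up to a constant, curve
comparisons (`pmf_deviation`, batch-to-batch deviations) align the
constant by midrange (the Chebyshev-optimal shift) and restrict to
decently sampled bins.

**Convergence diagnostics.** Histogram overlap is
`Σ_j min(p_ij, p_kj)` of normalised neighbour histograms with a 0.05
red-flag threshold. Batch averaging splits every window's series into
sequential equal-count slices, solves WHAM per slice, and reports the
per-slice endpoint free energies plus the max deviation of the last two
slices; a monotone endpoint trend raises a drift flag. Endpoint free
energies are read either at a position (nearest sampled bin) or as the
mean over a declared plateau interval — the latter makes "reading a
broad plateau off the curve" reproducible, and the interval is echoed
in the output.

**Metadynamics.** Plain (not well-tempered) metadynamics with a staged
height schedule, matching the coarse-then-fine protocol
(0.5 → 0.2 → 0.05 kcal/mol hills). The integrator accumulates the bias
and its analytic gradient on a fine grid (spacing ~σ/10, multilinear
interpolation), so the per-step cost is independent of the ledger
length; hills update grid nodes within 5σ and are truncated beyond.
Default hill width: 1/5 of the CV's unbiased standard deviation from a
short pre-run (`suggest_hill_width`), a common and reproducible choice.
The surface is read off as `−V` at `t_final` and, preferably, as the
time average of `−V` over the final low-hill phase: plain metadynamics
oscillates around the true surface, and the tests showed the spatial
ripple scales like `sqrt(h)` (≈0.3 kcal/mol at h = 0.05 on a flat
landscape) — flat to well under kT, but not literally "within one hill
height"; the flatness test asserts the kT-scale bound. Basin
differences are reported both basin-integrated
(`−kT log Σ exp(−F/kT)`) and minimum-to-minimum, since published
numbers rarely say which was used; for deep narrow wells they agree.
Grids are capped at 128³ points.

**Three-state interpretation.** PMF minima are detected on a
moving-average-smoothed curve with a topographic-prominence threshold
of 0.5 kcal/mol ≈ kT — thermally meaningful features only. State
assignment is argmin over Kabsch-fit RMSDs to the closed / half-closed
/ open references; ties within 1e−6 nm are an error, never broken
arbitrarily.

# Acceptance scope

The headline free energies of the reference all-atom study come from
microsecond-scale solvated simulations and are not reproducible at desk
scale. They enter the acceptance machinery only through the exact
arithmetic the two-substep model performs on them (the
`scripts/acceptance.R` targets t1–t4); everything else is
property-based on the synthetic world: WHAM within 0.15 kcal/mol of
analytic landscapes, staged metadynamics within 0.3 kcal/mol of the
planted asymmetry and 0.5 kcal/mol of WHAM, PCA mode recovery with
|cos| > 0.95 and eigenvalue ratios within 10%, geometry within
0.5°/1°, and an end-to-end three-minimum landscape recovered at the
planted positions. The barrier of the acceptance double well (9
kcal/mol) was set by a Kramers-rate extrapolation so that an unbiased
run of the metadynamics length has ~0.02 expected spontaneous
crossings — "metadynamics crosses, unbiased does not" is then a
property of the stated world, not of a lucky seed. The optional
crystal-structure checks (closed/open pair distances of 0.54/1.30 nm)
require the real PDB entries and are out of reach offline; the
machinery to run them (`read_pdb`, `pair_com_distance` on backbone
selections) is fully tested on synthetic structures.

# Known limitations

- The Euler–Maruyama integrator needs manual timestep care for stiff
  restraints; there is no adaptive timestep.
- WHAM provides no autocorrelation correction; batch averaging is the
  convergence instrument. Sampling intervals in the documented examples
  are chosen at or above the correlation time.
- The metadynamics engine integrates in CV space directly (identity CV
  map); driving arbitrary structural CVs of the toy clamshell through
  the integrator is out of scope, though ledgers from any source can be
  analysed.
- `fes_project` and the FES analysis support up to 3 CVs; the
  integrator's grid bias is practical up to 2–3 CVs at moderate
  resolution.
- No MBAR, no 2D umbrella sampling, no well-tempered metadynamics, no
  kinetics.
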