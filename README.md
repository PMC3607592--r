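# clamshellfe

Free-energy landscapes of clamshell ligand-binding domains, from biased
sampling to binding free energies.

## The problem

The ligand-binding domain (LBD) of ionotropic glutamate receptors is a
bilobal "clamshell": two rigid lobes joined by a short flexible hinge
that close around agonists. Its conformational thermodynamics — a
closed, a half-closed and an open state along the domain-closure
coordinate — determine agonist efficacy, and the total ligand binding
free energy decomposes into two sequential substeps:

1. **Step I — opening** the initially closed receptor, with the
   reaction coordinate `xi_1` = center-of-mass distance between backbone
   atoms of one residue on each lobe (the closed form sits near
   0.5 nm, the open form near 1.3 nm);
2. **Step II — dissociation** of the ligand from the open binding site,
   with `xi_2` = the in-plane (XY-projected) COM distance between the
   ligand and a set of binding-site residues.

With substep costs `dG_I, dG_II > 0` (unbinding direction),

```
dG_total = dG_I + dG_II,        dG_bind = -dG_total
```

and when an independent metadynamics estimate of step I exists, the
combined prediction averages the two step-I estimates before adding
step II.

`clamshellfe` implements the full computational route as a tested,
reusable pipeline:

- **structio** — PDB and trajectory I/O (multi-model PDB, plain-text
  XYZ), residue selections, mass-weighted centers of mass, Kabsch
  superposition, RMSD/RMSF;
- **colvars** — the reaction coordinates and interdomain geometry
  (pair COM distance, projected site distance, hinge-vertex interdomain
  angle, interdomain torsion) evaluated over trajectories;
- **rigidpca** — rigid-body PCA: strip internal lobe motion by
  per-domain superposition, diagonalise the Cartesian covariance, and
  expose the clamshell / twisting / rocking eigenmodes as collective
  variables;
- **toysystems** — the synthetic-data generator standing in for the MD
  engine: analytic potentials (harmonic, asymmetric double well,
  three-well clamshell landscape with minima near 0.53 / 0.76 /
  1.12 nm), an overdamped Langevin integrator with umbrella and
  metadynamics biasing (compiled kernel, bit-reproducible per seed),
  and a toy two-lobe structure generator with planted bend/twist/rock
  modes;
- **wham** — umbrella-sampling estimation: shared-grid histograms, the
  WHAM self-consistency equations in log space, PMF assembly,
  histogram-overlap and sequential-batch convergence diagnostics;
- **metad** — plain (staged-height) metadynamics: Gaussian hill
  deposition on a bias grid, PLUMED-style HILLS I/O, free-energy-surface
  reconstruction with trailing time averaging, basin free-energy
  differences;
- **statemodel** — PMF feature detection (minima, barriers, plateaus),
  three-state assignment by reference RMSD, endpoint free energies, and
  the two-substep combination above;
- **cli** — `simulate` / `wham` / `metad` / `report` subcommands driven
  by JSON configs, with seed-stamped, hash-stamped manifests
  (`inst/scripts/clamshellfe`).

The WHAM estimator is, in short: with window bias
`w_i(x) = k_i (x - c_i)^2 / 2`, iterate

```
p_j  ∝  (Σ_i n_ij) / (Σ_i N_i exp[(f_i - w_i(x_j)) / kT])
f_i  =  -kT log Σ_j p_j exp[-w_i(x_j) / kT]
```

to self-consistency and set `G_j = -kT log p_j` (minimum at zero).
The metadynamics estimator deposits Gaussian hills
`h exp(-(s-c)^2 / 2σ^2)` along the trajectory and reads the surface off
as `F(s) = -V(s, t)`, time-averaged over the final low-hill phase.

## Worked example

Umbrella sampling and staged metadynamics on the same asymmetric
double-well opening landscape (planted well asymmetry 1.19 kcal/mol),
then the two-substep combination:

```r
library(clamshellfe)

dw <- double_well_potential(wells = c(0.53, 1.12), barrier = 9,
                            delta = 1.19, width = 0.1)

## step I via umbrella sampling + WHAM
lp <- langevin_params(n_steps = 4e5, seed = 42, timestep = 5e-5,
                      save_stride = 20)
windows <- generate_umbrella_dataset(dw, centers = seq(0.35, 1.30, 0.05),
                                     k = 500, lp)
pmf <- wham_pmf(windows, bin_width = 0.01)
dg_open <- endpoint_delta_g(pmf, 0.53, 1.12)

## step I via staged metadynamics (0.5 -> 0.2 -> 0.05 kcal/mol hills)
sch <- hill_schedule(heights = c(0.5, 0.2, 0.05), strides = c(1, 1, 1),
                     durations = c(300, 300, 900))
mp <- langevin_params(n_steps = 1.5e7, seed = 42, timestep = 1e-4,
                      save_stride = 100)
metad <- run_metadynamics(dw, sch, sigma = 0.05, mp)
fes <- reconstruct_fes(metad$ledger, list(lo = -0.3, hi = 2.0, n = 461),
                       average_from = 800)
dg_metad <- basin_delta_g(fes, c(1.0, 1.25), c(0.4, 0.65))$delta_g

## combine with a step-II (dissociation) estimate
combine_two_step(dg_open, 6.10, dg_metad, ligand = "toy")
```

Output (as printed by the code above):

```
Binding free energies for toy (kcal/mol)
  step I  (opening, US):       +1.27
  step I  (opening, MetaD):    +1.21
  step II (dissociation, US):  +6.10
  US total (I + II):           +7.37  => dG_bind = -7.4
  combined (mean I + II):      +7.34  => dG_bind = -7.3
  convention: substep dG are positive unbinding costs; binding free energies are their negations
```

Both estimators recover the planted 1.19 kcal/mol asymmetry (1.27 from
WHAM, 1.21 from metadynamics — each within its stated tolerance), and
the report carries the combination arithmetic with explicit signs.

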