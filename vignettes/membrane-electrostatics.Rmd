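---
title: "Membrane electrostatic potentials: models, averaging, and comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane electrostatic potentials: models, averaging, and comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memesp)
```

## Scope and model

`memesp` computes, averages, and compares 3-D electrostatic potential grids
of lipid bilayers that carry a charged phosphoinositide headgroup. The
working units are angstrom, elementary charges, and kcal/mol/e throughout;
`esp_units()` converts to kT/e and mV for display (at 296 K,
1 kT/e ≈ 0.588 kcal/mol/e, so the conventional −0.6 kcal/mol/e analysis
contour is about −1 kT/e).

### Continuum electrostatics

The potential obeys the Poisson–Boltzmann (PB) equation. The solver
(`pb_solve()`, `focus_solve()`) discretizes the *linearized* form

$$\nabla\!\cdot\!\left(\epsilon\,\nabla\phi\right) - \bar\kappa^2\,\phi
  = -4\pi k_C\,\rho,$$

with a 7-point variable-coefficient stencil on a uniform grid. Assumptions
and numerical choices:

- **Dielectric boundary.** Voxels whose centers fall inside any atom's van
  der Waals sphere take the solute dielectric (default 2); all others the
  solvent value (default 80). No reentrant/molecular-surface construction
  is attempted — the vdW surface is the model. Face dielectrics are the
  harmonic mean of the adjacent voxel values, which keeps flux continuity
  first-order accurate across the jump.
- **Screening.** $\bar\kappa^2 = \epsilon_{solv}\kappa^2$ outside the
  ion-accessible surface (vdW spheres inflated by the ion exclusion radius,
  default 2 Å) and zero inside; $\kappa$ follows from the ionic strength
  (default 0.1 mol/L) and temperature (default 296 K) via `debye_kappa()`.
- **Sources.** Point charges are spread to their eight surrounding voxel
  corners with trilinear weights, conserving total charge to machine
  precision.
- **Boundary condition.** Dirichlet values from the screened-Coulomb
  (Debye–Hückel) superposition; each atom uses exclusion radius
  `radius + ion_radius`, which makes a single-ion solve consistent with the
  finite-size-ion closed form it is tested against.
- **Solver.** Damped red–black successive over-relaxation,
  $\omega = 2/(1+\sin(\pi/\max(\mathrm{dims})))$ by default, relative
  residual tolerance $10^{-6}$. The red–black ordering makes the converged
  result independent of traversal order, and sign-flipping all charges
  flips the solution exactly.
- **Linearization.** The analyses downstream compare potentials near the
  ±0.6 kcal/mol/e contour, where $|\phi| \approx kT/e$ and the
  linearization error is small; `nonlinear = TRUE` enables a damped Picard
  iteration that replaces $\bar\kappa^2$ by
  $\bar\kappa^2\,\sinh(\phi/kT')/(\phi/kT')$ per sweep. The two modes agree
  within 2% where $|\phi| < 0.5$ kcal/mol/e in the test suite.
- **Focusing.** The standard membrane protocol solves a coarse outer grid
  (271×271×222 points, 2 Å) and interpolates its solution trilinearly onto
  the boundary of a fine inner grid (201³, 0.5 Å, centered on the probe P1
  phosphate). The tests run the same procedure at 65³ sizes, where the
  focused inner solution agrees with a direct fine solve to a mean absolute
  difference far below 0.05 kcal/mol/e in the interior half.

Convergence against the analytic single-ion solution is first-order at the
dielectric/Stern boundary and second-order in homogeneous regions; halving
the spacing from 1.0 to 0.5 Å reduces the observed error about five-fold in
the smooth region sampled by the acceptance script.

### Robust ensemble averaging: the remedian

Averaging hundreds of 201³ grids voxel-wise rules out holding all values in
memory. The remedian (Rousseeuw & Bassett 1990) keeps $k$ buffers of $b$
values per voxel: each incoming value lands in buffer 0; a full buffer
collapses to its median, which is pushed one level up. With the default
$b = 9, k = 3$, up to $9^3 = 729$ grids are summarized in 27 values per
voxel, and at exactly full capacity the result is the exact nested median
of the stream (verified against a brute-force oracle).

For a stream that does not fill the buffers (e.g. 700 < 729 grids) the
published completion rule is used: a weighted median over all buffered
entries with level-$i$ entries weighted $b^i$. This is a deliberate design
choice — the alternative of discarding partial buffers throws away up to
$b^k - b^{k-1}$ observations — and it makes `finalize_remedian()`
deterministic at any $n \ge 1$. Even-count medians use the midpoint of the
two central values.

The arithmetic mean (`mean_grid()`) is a single-pass incremental mean; the
exact median (`exact_median_grid()`) holds all grids and exists as the
reference the remedian approximates. The motivating property — spikes of
high magnitude at scattered voxels contaminate the mean but not the
remedian — is exercised by the synthetic generator's outlier model and
measured in the acceptance suite as a win rate in max-norm error over 100
seeded ensembles.

### Skin-region similarity

Two potentials are compared where a protein would feel them: the solvent
"skin", voxels whose distance to the nearest atom surface lies in
(probe, probe + skin] — defaults 2 Å probe and 3 Å skin — inside a sphere
around the P1 phosphate (10 or 14 Å in the standard analyses). Over the
masked voxels the Hodgkin similarity index and electrostatic distance are

$$SI = \frac{2\sum_i a_i b_i}{\sum_i a_i^2 + \sum_i b_i^2},\qquad
  D = \sqrt{2 - 2\,SI} \in [0, 2].$$

**Mask policy.** For all-against-all comparisons the package builds one
shared mask from a designated reference structure (the ensemble's first
member by default). A shared mask keeps $D$ a distance over one fixed voxel
set — pairwise per-snapshot masks would compare different regions pair by
pair. An explicit `mask` argument accepts any alternative (e.g. a
per-pair intersection) when that is wanted.

**Distance statistics and autocorrelation.** `distance_stats()` summarizes
the strict upper triangle. `distance_autocorrelation()` estimates the decay
of similarity with time lag from the distance matrix alone: with
$SI = 1 - D^2/2$,

$$\mathrm{ACF}(\tau) =
 \frac{\overline{SI(t, t+\tau)} - \overline{SI}_{\mathrm{all\ pairs}}}
      {1 - \overline{SI}_{\mathrm{all\ pairs}}}.$$

This estimator is 1 at lag 0 by construction, fluctuates inside the
white-noise band for exchangeable snapshots, alternates sign for a strictly
period-2 ensemble, and is undefined (error) when all snapshots are
indistinguishable. It was chosen because it needs nothing beyond the
distance matrix; it is a centered, normalized mean-similarity profile, not
the ACF of any single scalar series.

### Bulge height and headgroup geometry

`bulge_height()` operationalizes "the maximum z-height above the P1
phosphate bounded by the −0.6 kcal/mol/e contour" as the **topmost
threshold crossing** on the vertical line through P1 (optionally on all
grid columns within a lateral search radius, since a snapshot's bulge apex
can sit slightly off-axis), with linear interpolation between the
bracketing z-planes. Taking the topmost crossing rather than requiring
contiguity from the surface is a declared choice; for the smooth fields of
interest the two coincide, and the tests include a split-contour case
pinning the behavior. Heights are signed; with
`reference = "popc_plane"` they are reported relative to the mean z of
same-leaflet phosphates beyond a 15 Å lateral exclusion
(`popc_reference_z()`), so an apex below the membrane surface is negative.

Tilt angles: Θ is the angle of the P1→C4 vector to +z; Φ the angle of the
C3→C5 vector to +z, signed by the x-component of C3→C5 after rotating the
frame about z so P1→C4 lies in the xz-half-plane of positive x. That sign
rule is deterministic and z-rotation invariant; the convention in which an
in-plane vector reads 0° instead of 90° is exposed as
`geometry_spec(subtract_90 = TRUE)`, since published figure conventions
differ and the plain vector-vs-axis definition is taken as the default.

## The synthetic generator: what it emulates, what it does not

`bilayer_spec()` defaults define the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| lattice constant | 8.5 Å | hexagonal area/lipid $(\sqrt3/2)a^2 \approx 62.6$ Å², within the range reported for fluid PC bilayers |
| lipids per leaflet | 36 | smallest patch with phosphates beyond the 15 Å exclusion |
| leaflet separation | 38 Å | phosphate-to-phosphate distance of a PC bilayer |
| dipole ±1 e over 4.5 Å | — | the P⁻–N⁺ headgroup dipole of a PC lipid, oriented along z |
| probe charge | −3 e | net charge of the PtdIns(3)P headgroup |
| probe z-offset | +1.5 Å | mean P1 protrusion observed in CHARMM c36 membrane simulations |
| planted tilt (Θ, Φ) | (44.3°, −26.9°) | mean headgroup tilt from the same simulations |
| jitter σ | 1.0 Å | whole-lipid positional fluctuation per snapshot |
| outlier rate / amplitude | 0.05 / −50 kcal/mol/e on 1% of voxels | rare near-atom numerical spikes that contaminate mean grids |

Potentials come from the closed-form screened-Coulomb superposition
$\phi(r) = \sum_i q_i k_C e^{-\kappa(r_i - a)}/(\epsilon(1+\kappa a)r_i)$
(ion-exclusion factor per source atom with $a$ = ion radius), which is
linear in the charges and exact to floating precision — the independent
oracle for the PB solver and for every downstream statistic.

What the generator does **not** emulate: lipid tails, water structure,
interfacial dielectric gradients, correlated collective motions, headgroup
torsional dynamics, and counterion binding. Passing tests therefore
demonstrate that the *measurements* (averaging, similarity, bulge,
geometry) are correct and robust under controlled fluctuations — not that
MD-derived distributions are reproduced. Quantities that require real
trajectories (bulge-height distributions, Θ/Φ densities, the 0.55 ± 0.15
snapshot-distance scale) are validated property-wise (monotonicity,
parameter recovery, metric structure) rather than by value.

Two jitter scales appear in the validation suite: whole-lipid σ = 1.0 Å for
recovering the probe's z-offset, and a stiffer σ = 0.1 Å when recovering
planted tilt angles, reflecting that internal ring geometry fluctuates far
less than whole-lipid positions; with the floppier value the short C3→C5
lever arm picks up a visible acos-nonlinearity bias that says nothing about
the estimator.

## Numerical details and degenerate inputs

- Grid convention, fixed once for every module: voxel centers, 0-based
  indices, origin = center of voxel (0,0,0), x fastest in linear order.
  UHBD headers store `ox = origin − h` (the historical 1-based convention);
  both UHBD dialects store values in single precision.
- Grid coincidence checks use a $10^{-6}$ Å tolerance and name the first
  offending grid and field.
- Analytic potentials clamp voxels within $10^{-3}$ Å of a charge and
  record them in a `clamped_voxels` attribute.
- `hodgkin_index()` refuses empty masks and identically-zero pairs (the
  index is undefined); `distance_autocorrelation()` refuses zero-variance
  series; `update_remedian()` refuses streams beyond $b^k$ grids, naming
  the capacity.
- Heights return `NA` (not an error) when no voxel above P1 reaches the
  threshold — a physically meaningful "no bulge".
- All ensemble randomness funnels through one seed
  (`bilayer_spec(seed=)`, or `run_full_demo(seed=)`), and generation
  restores the caller's RNG state.

## Problem sizes

The shipped validation suite runs entirely on synthetic data at desk scale:
PB solves up to 65³ voxels, focusing with a 65³ @ 2 Å outer and 65³ @ 0.5 Å
inner grid, remedian streams of 729 small grids, similarity ensembles of
tens of snapshots, and 100-seed robustness repeats of 200-grid ensembles on
12×12×10 solvent-region grids. These sizes were chosen so each check
resolves the property it tests; the same code paths run the full 201³
protocol unchanged.

## Known limitations

- The solver is not a bit-for-bit re-implementation of any particular
  legacy PB code: convergence criteria, boundary handling, and the
  vdW-only dielectric surface may differ from grids produced by other
  tools by more than the statistical tolerances of the analyses. Published
  deposited grids are therefore consumed through the I/O layer, not
  regenerated.
- Linearized PB under-screens where $|\phi| \gg kT/e$ (near the charged
  headgroup); the nonlinear mode mitigates but retains the vdW-surface
  dielectric model.
- No periodic boundary conditions: the synthetic patch and any imported
  structure are treated as isolated, so potentials near the lateral edges
  of small patches carry finite-size effects. Analyses are restricted to
  spheres around the probe, far from the patch edge.
- The remedian depends (mildly) on stream order except at exact full
  capacity; partial-fill completion is a convention, and different
  remedian implementations may differ in the last decimals for n < b^k.
- OpenDX support covers axis-aligned uniform scalar grids only; CCP4/MRC
  maps and rotated or non-uniform grids are out of scope.
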