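---
title: "Tissue-dependent positron range correction: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-dependent positron range correction: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A positron emitted in beta-plus decay travels a tissue-dependent
distance before it annihilates; PET localizes the annihilation, not the
decay. For Rb-82, whose beta spectrum reaches 3.4 MeV, this positron
range (PR) blurs the image by several millimetres in soft tissue and by
far more in lung, washing out the contrast between the left-ventricular
wall and the blood pool in myocardial perfusion imaging (MPI). Positron
range correction (PRC) puts a model of this blur *inside* the iterative
reconstruction: the system model becomes `a * P * B`, with `B` an
image-space convolution whose kernel varies voxel by voxel with the
underlying tissue, so the ML estimate is implicitly deconvolved of the
range blur. This package implements that chain end to end at desk
scale, plus the evaluation machinery (cardiac phantom, polar-map
metrics, normal databases, total perfusion deficit, ROC/DeLong/ICC
statistics) needed to ask whether PRC changes image quality and
diagnostic performance.

## Positron transport model

Annihilation-point clouds are produced by a condensed-history Monte
Carlo with deliberately simple, documented physics:

* **Beta spectrum.** Allowed shape
  `N(E) ~ p * E_tot * (E_max - E)^2 * F(Z, E)` with the nonrelativistic
  Fermi function for positrons (`eta = -Z * alpha / beta`; repulsion
  suppresses slow positrons). Rb-82 is modeled with its two dominant
  branches (endpoints 3.378 and 2.601 MeV, renormalized probabilities
  0.864/0.136); F-18, Cu-64 and Ga-68 with their single dominant branch.
  The sampled Rb-82 mean energy (1.50 MeV) matches nuclear-data
  tabulations.
* **Energy loss.** Continuous slowing down with the Berger-Seltzer
  collision stopping power of water (I = 75 eV) including the
  Sternheimer density-effect correction; other tissues scale the water
  value linearly with density (`stopping_scale = rho / rho_water`).
  Without the density effect the stopping power is ~5% high at 3 MeV
  against ICRU tabulations, which matters for a maximum-range target.
* **Multiple scattering.** Per step, a Gaussian plane-projected
  deflection using the Lynch-Dahl fit to Moliere theory (the source of
  the Highland formula's constants, and more accurate than the Highland
  one-liner for low-Z media), plus the PDG-correlated intra-step lateral
  displacement. The Moliere logarithm is evaluated at the *remaining
  track length*, not the step thickness: per-step variances then add
  independently of step size. A bare per-step Highland logarithm is not
  refinement-stable - it would change the mean range by ~3% under 10x
  step refinement, violating the package's own convergence property.
* **Step control.** Fixed 5% fractional energy loss per step; where the
  scattering angle sigma would exceed 0.15 rad (and E > 0.1 MeV, below
  which under ~0.15 mm of range remains), the step is subdivided to stay
  in the small-angle regime. With these choices, halving the step
  changes the 1 MeV mean displacement by 0.02%, and 10x refinement by
  1.6%.
* **Cutoff.** Annihilation at rest below 10 keV (residual range ~3
  micrometres - irrelevant at millimetre scale). Annihilation in
  flight, positronium formation, bremsstrahlung transport and elemental
  composition beyond density scaling are ignored.

**Accuracy statement.** The model reproduces the printed maximum Rb-82
range (~17 mm) and the mean water ranges of F-18, Cu-64 and Ga-68 within
their stated tolerances. Its Rb-82 *mean 3-D displacement* converges to
~5.3 mm: detailed-history codes (GEANT4/PeneloPET class) report
5.9-6.1 mm, and the value often quoted for soft tissue, ~7 mm, is
generous even against those. Whether "mean PR" means mean displacement
or mean path length is genuinely ambiguous in the clinical literature;
this simulation's mean *path length* is 7.3 mm. We report the
displacement reading and flag the discrepancy rather than tune the
physics: Gaussian condensed-history scattering over-diffuses relative to
Moliere's narrow-core/heavy-tail distribution, which is the known,
documented bias of this model class.

## From clouds to a spatially variant operator

Per-tissue kernels are histograms of annihilation displacements on an
odd, centered grid whose half-extent is the *maximum PR in water* - the
clinical construction. Lung annihilations beyond that extent (roughly
40% of them) are dropped and the kernel renormalized; the fraction is
recorded on the kernel. Tissue composition comes from the density map
by piecewise-linear interpolation between the anchor densities 0.26
(lung), 1.00 (soft) and 1.92 g/cm^3 (bone); air is treated as lung
class. Continuous fractions avoid classification seams. Mixing weights
are optionally averaged over a spherical neighborhood whose radius
defaults to the mean PR in water (5.3 mm), since the medium that stops a
positron is the neighborhood of its source, not the source voxel; a
voxel-local mode exists because the vendor's exact rule is not public.

The blur is applied *source-driven*: each source voxel spreads its
activity with its own composed kernel, which makes the operator exactly
`y = sum_c K_c * (w_c . x)` - three shift-invariant convolutions - and
conserves emitted activity up to boundary truncation. The adjoint
(`sum_c w_c . (K~_c * x)`) is implemented explicitly and verified by
inner-product identity to 1e-9, because OSEM needs a *matched* pair for
its convergence theory.

## Reconstruction

OSEM with angle-interleaved subsets, multiplicative updates, uniform
positive initialization inside the field of view, division guards at
`1e-12 * max`, and per-subset sensitivity images computed with the full
system model (including the blur adjoint when PRC is on). The detector
PSF is a Gaussian surrogate (FWHM 4 mm by default; the vendor model is
proprietary) pre-convolved into each tissue kernel. Defaults mirror the
clinical protocols: STD = 2 iterations x 21 subsets, STD+PRC = 3
iterations x 21 subsets ("comparable convergence" is a configuration
choice, never inferred), both followed by a 5-mm Gaussian post-filter.
Inside OSEM the convolutions are circular (no padding): the phantom
keeps an air margin wider than the kernel half-width, so wraparound
touches only zeros, activity is conserved exactly, and the operator
remains exactly linear with an exact adjoint.

## The synthetic cohort: what it does and does not emulate

No clinical data are deposited, so cohorts are synthetic. The phantom
is a stack of short-axis slices: a prolate-ellipsoid LV shell (outer
semi-axes 33/33/44 mm, 10-mm wall) with blood pool, two lungs (0.26
g/cm^3), a spine disc (1.92), soft-tissue body (1.00), uptake ratios
myocardium : blood : soft : lung : bone = 4 : 1 : 0.4 : 0.15 : 0.2
(typical of a late rubidium frame). Acquisition = spatially variant PR
blur, detector PSF, attenuated parallel-beam projection (mu = 0.0096/mm
x density), Poisson noise at 2e6 expected counts per stack. Subjects
perturb LV scale (lognormal sigma 0.05) and uptakes (sigma 0.15);
test-retest pairs share anatomy and differ only in noise. Patient
cohorts implant 1-2 angular-sector defects with severity uniform on
[0.05, 0.7] - deliberately including sub-threshold lesions, because
FFR-positive vessels with invisible perfusion deficits are what keep
real TPD-vs-FFR AUCs near 0.85 rather than 1.0. Labels are positive
exactly where a defect was implanted (the FFR < 0.8 convention).

Not emulated: cardiac/respiratory motion, scatter and randoms,
time-of-flight, 3-D cross-slice blur (kernels are collapsed axially and
applied per slice), anatomical realism beyond ellipsoids. A green
cohort test therefore establishes that the *method* behaves as claimed
under its own forward model ("inverse crime" acknowledged: truth and
reconstruction share the blur model), not that clinical effect sizes are
reproduced.

## Polar maps, TPD and statistics

Polar sampling takes the maximal interpolated value along radial
profiles through the analytic wall position (36 angles x slices;
automatic segmentation is out of scope for phantoms), optionally
normalized to the LV maximum x 100. SNR = polar mean / blood-pool SD,
CNR = (polar mean - blood mean) / blood SD, CoV = blood SD / mean, with
a 15 x 15 x 15 mm cube VOI at the lumen centroid (cylinder mode
available). Normal databases are per-sample mean/SD over disease-free
maps, built separately per reconstruction protocol. The clinical TPD
algorithm is proprietary, so TPD is an explicit extent-x-severity
surrogate: a sample below `L = mean - k * max(SD, 0.05 * mean)` (k =
2.5) contributes `min(1, (L - v) / L)`; TPD is 100 x the mean
contribution. It is zero at or above the normal mean, bounded in [0,
100], and monotone in implanted severity and extent - the properties
that matter for ROC analysis. iTPD = sTPD - rTPD, unclamped by default.

Statistics: Mann-Whitney AUC with DeLong structural-components variance
and paired DeLong comparison; Youden threshold with ties broken toward
specificity; exact McNemar below 25 discordant pairs (else
continuity-corrected chi-square); ICC(2,1) (two-way random effects,
absolute agreement - the natural form for test-retest on one scanner;
the literature rarely states its choice) with McGraw-Wong CIs; Fisher-Z
comparison with variance `1/(n-3)`. DeLong and Fisher-Z type-I error
calibrate to 0.044 and 0.049 at nominal 0.05 under the package's null
simulations.

## What the desk-scale experiments show

On the 25-subject synthetic volunteer cohort (seeded, reproducible):
median SNR 37.4 (STD) vs 41.2 (STD+PRC) and median CNR 27.9 vs 32.2,
both Wilcoxon p < 1e-4 in the direction the clinical study reports;
defect-free retest subjects scored against the test-half normal
databases give mean sTPD and iTPD below 0.1%, far inside the <5% sanity
bound; SNR/CNR test-retest ICCs (0.02-0.64) do not differ between
protocols by Fisher-Z. On 60-patient synthetic cohorts, STD and
STD+PRC AUCs (0.90-0.99) are DeLong-equivalent across seeded
replicates.

**Known red result.** Blood-pool CoV is *not* preserved here: PRC at
the clinical 3-vs-2-iteration protocol raises CoV by ~10% (Wilcoxon p ~
0.009 across 25 subjects). The clinical study found CoV preserved; in
this desk-scale 2-D system the extra deconvolution iteration amplifies
blood-pool noise more than the paired-count design absorbs. We keep
the protocol at its clinical values rather than retune iterations to
force the property, and leave the acceptance clause red with this
explanation.

## Numerical choices and degenerate inputs

FFTs run on 5-smooth padded sizes; kernels are odd and centered, so the
reflected kernel is the exact adjoint. Sub-1e-12 negative FFT residues
are clipped. Division guards: OSEM denominator and sensitivity at
`1e-12 * max`; TPD SD floor at 5% of the sample mean; McNemar b = c = 0
gives p = 1; zero-variance DeLong difference gives p = 1 on equal AUCs;
degenerate ICC (no between-subject variance) is flagged rather than
silently clipped. Empty clouds, non-positive densities, mismatched
grids and single-class ROC inputs raise errors, not warnings. All
randomness flows through explicit integer seeds; reruns are
bit-identical.

## Scaling decisions

The experiment profiles are smaller than both the clinical matrix
(400 x 400 x 109) and the nominal 128 x 128 desk default: volunteer
cohorts run at 80 x 80 x 6 slices (2.4-mm voxels, 60 angles, 21
subsets) and patient replicates at 48 x 48 x 3 (4-mm voxels, 36 angles,
7 subsets, reduced counts). These sizes keep the full acceptance
suite - five 1e5-decay isotope runs, a 100-acquisition volunteer study
and 20 x 60-patient replicates - inside a half-hour on one CPU while
leaving the wall ~4 voxels thick, which is what the polar metrics
need. The kernels, not the grid, carry the physics; nothing in the
method depends on matrix size.
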