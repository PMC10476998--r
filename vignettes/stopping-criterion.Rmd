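---
title: "A noise-based stopping criterion for list-mode proton CT reconstruction"
author: "protonCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A noise-based stopping criterion for list-mode proton CT reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonCT)
```

## The model

List-mode proton CT measures, for each proton, a trajectory (entry and
exit positions on tracker planes) and a water-equivalent path length
(WEPL, mm).  With $x$ the vector of voxel RSP values, $b$ the vector of
measured WEPLs and $A$ the sparse matrix of chord lengths of each
proton's trajectory through each voxel, the image is a least-squares
solution of $Ax \approx b$.  Because there are far more protons than
voxels and the WEPLs carry measurement noise, $dp = Ax - b$ never
vanishes; at the unique least-squares solution the *voxel* deviation

$$ dv = V^{-1} A^{\mathsf T} dp, \qquad V = \mathrm{diag}\!\Big(\sum_p \alpha_{pv}\Big) $$

— the chord-weighted mean of $dp$ over the protons crossing each voxel —
is exactly zero, and the chord-weighted mean *calculated* WEPL of the
protons touching any voxel equals their mean *measured* WEPL.

The solver iterates $x \to x - \lambda\, dv$.  The step size is an
exact line search along $dv$, alternating between two quadratic
objectives:

* minimizing $dp\cdot dp$ after the step gives
  $\lambda = (dp \cdot A\,dv)\,/\,\lVert A\,dv\rVert^2$;
* minimizing $dv\cdot dv$ gives, with $u = V^{-1}A^{\mathsf T} A\, dv$,
  $\lambda = (dv \cdot u)\,/\,\lVert u \rVert^2$.

The alternation starts with the $dp$ objective (an arbitrary choice,
recorded in the iteration history).  Both closed forms are ordinary
exact line searches for a quadratic along a fixed direction; each step
cannot increase its own objective, though it may temporarily increase
the other — the recorded $r$ sequence is therefore not monotone
iteration by iteration.

## The stopping statistic

The standard deviation of $dp$ (over protons whose rays intersect the
grid) estimates the per-proton noise $\sigma_p$; it absorbs both the
WEPL measurement noise and the effect of trajectory uncertainty on the
calculated WEPL.  The expected per-voxel RSP precision is

$$ \sigma_v = \frac{\sigma_p}{\bar\alpha\,\sqrt{\bar N_{pv}}}, $$

with $\bar\alpha$ the mean chord length through a voxel, approximated by
the voxel edge length, and $\bar N_{pv}$ the mean number of protons per
reconstructable voxel, taken from the data.  The convergence statistic

$$ r = \frac{\mathrm{rms}(dv)}{\sigma_v} $$

is the remaining distance to the least-squares solution in units of the
expected image noise.  The solver stops at the first evaluation with
$r \le r_{\text{stop}}$; the default $r_{\text{stop}} = 0.75$ is the
midpoint of the 0.5–1 band in which reconstructed images show minimal
inter-voxel noise correlation.  $\sigma_p$ is re-estimated from the
current $dp$ at every evaluation; with realistic proton counts the
difference between divisors $N$ and $N-1$ is negligible (sample
standard deviation with mean subtraction is used).

With strictly noiseless, self-consistent data $\sigma_p \to 0$ and $r$
is undefined; the solver then stops on $\mathrm{rms}(dv) \le 10^{-12}$.
If $r$ increases for 20 consecutive evaluations the solve aborts with a
diagnostic.

## Why stop in 0.5 ≤ r ≤ 1

Early stopping leaves the image close to the smooth initial guess:
residual errors are shared across neighbouring voxels and the
autocorrelation $\rho(\delta)$ at small $\delta$ is strongly positive.
Iterating far past the noise level ($r \approx 0.2$) fits the WEPL noise;
neighbouring voxels then compensate each other under the line-integral
constraints and $\rho(1)$ turns negative — the analogue of the
ramp-filter regime of filtered back-projection.  In between, around
$r \approx 0.75$, correlations pass through zero on every axis.  Because
WET along a voxel line is a sum over many voxels, it is nearly invariant
once the image mean has converged: across $r \in \{1, 0.75, 0.5, 0.2\}$
the desk-scale acceptance runs see a spread of a few tenths of a
millimeter over a ~130 mm path.  The $r = 2$ image, reached after only
one or two iterations at this problem size, can still carry a
millimeter-scale bias in its line sums.

## Noise analysis conventions

* **ROI variance** uses divisor $N-1$ over a user-specified uniform ROI.
* **Autocorrelation**: for each axis and lag $\delta$ the mean-centered
  products are summed over all in-ROI pairs at that lag (truncating at
  the ROI edge, no wrap-around), divided by the *actual* pair count and
  by the divisor-$N$ (population) variance, so that $\rho(0) = 1$
  exactly.  A single shared ROI mean is used for both pair members.
  This differs from mixing in the divisor-$(N-1)$ variance by a factor
  $(N-1)/N$, negligible at realistic ROI sizes.  The default
  $\delta_{\max} = 10$ voxels covers the separations at which the
  correlation structure of interest lives.
* **NPS**: per axis, the measured $\rho$ scaled by the population
  variance is symmetrized to lags $-\delta_{\max}..\delta_{\max}$ and
  discrete-Fourier-transformed; the spectrum is reported on frequencies
  $k/(M h)$ ($M = 2\delta_{\max}+1$, $h$ the voxel size, units 1/mm) and
  normalized so that $\sum_k S_k\,\Delta f$ equals the variance.  The
  inverse transform reproduces the autocovariance to machine precision
  (Wiener–Khinchin round trip); sample spectra may dip slightly below
  zero where the estimated autocovariance is not positive semidefinite.
* **WET line sums** are voxel-index-based inclusive runs, RSP × voxel
  size summed along one axis.

## The synthetic-data generator

The simulator emulates a rotating-object list-mode acquisition at
simplified physics.  Study conditions (defaults):

* 90 angles × 4°; protons travel along $+z$ in the gantry frame; the
  object rotates about $+y$ (rays are rotated into the fixed object
  frame before tracing).
* Pencil-beam focal divergence with focal lengths 1935 mm (horizontal)
  and 2303 mm (vertical): rays fan out from the scanning-magnet focal
  points, so protons travel mostly in the $x$–$z$ plane with a few mrad
  of divergence into $y$.  `focalLength = Inf` gives a parallel beam.
* WEPL noise: a single Gaussian with $\sigma_{\text{WEPL}} = 3$ mm
  absorbing range straggling and detector resolution.  The noise model's
  microphysical origin does not matter for the stopping rule, only its
  existence; 3 mm is a realistic figure for a clinical-prototype range
  detector and is a free configuration parameter.
* Tracker quantization: recorded entry/exit positions snap to a 0.5 mm
  pitch; the ground-truth WEPL is integrated along the *unquantized*
  ray, so trajectory-uncertainty noise enters through the mismatch
  between the recorded chord and the true path, as in a physical
  tracker.  An optional small-angle kink at the object mid-plane
  (`scatterSigma`, mrad; default 0) emulates multiple Coulomb
  scattering in the recorded trajectory.
* One RNG child stream per angle, derived from the master seed, so
  changing the number of angles does not reshuffle other angles'
  protons, and equal seeds give bit-identical proton lists.
* For rotationally symmetric phantoms, `reassignAngles()` implements
  the standard shortcut of simulating one beam direction and randomly
  reassigning protons to rotation angles; it is only valid when the
  voxelized object is invariant under those rotations.

What the generator does **not** model: detector response and
scintillating-fiber segmentation, beam energy layers, nuclear
interactions and delta electrons, curved most-likely-path trajectories
(the trajectory model is pluggable but only straight chords are
implemented).  Passing tests on these synthetic data therefore
demonstrates the solver/stopping-rule machinery and the noise-analysis
chain under a Gaussian noise model — not detector-level fidelity.

## Numerical choices

* Voxels are half-open boxes; the compiled Siddon-style traversal drops
  chords below $10^{-6}$ mm; boundary-grazing intersections of measure
  zero contribute nothing.  Row sums of the system matrix reproduce the
  analytically clipped segment length to $10^{-9}$ mm.
* The reconstructable mask is data-driven: voxels with at least one
  proton and positive chord sum.  No object-hull detection is
  performed; off-mask voxels hold RSP 0 and are excluded from all
  statistics.  A configurable 3-sigma residual data cut for outlier
  protons exists in spirit through `ProtonList` subsetting but is off
  by default.
* The initial guess (`x0Mode = "uniform"`) is the flat image whose
  value is mean measured WEPL divided by mean geometric path length —
  the smooth start that makes semi-convergence observable; `zero` and
  user-supplied volumes are alternatives.
* $dp$ is updated incrementally ($dp \leftarrow dp - \lambda A\,dv$)
  and refreshed from $Ax - b$ every 64 iterations to cap round-off
  drift.
* `solveNormalEquations()` (sparse Cholesky on $A^{\mathsf T}A$ with one
  iterative-refinement pass) provides the direct least-squares solution
  for small systems; it is used as an independent oracle in the tests,
  never by the solver.
* Stopping is "first checked iterate with $r \le r_{\text{stop}}$",
  with no interpolation between checks.  Because one exact line-search
  step can carry $r$ well past a threshold, the *image captured at the
  stop* fluctuates around the nominal $r$.  For measuring how a
  statistic depends on $r$, `statAtR()` evaluates it on the two
  iterates bracketing the crossing and interpolates linearly in
  $\log r$; this is a measurement device and does not alter the
  stopping rule.

## Desk-scale study conditions

The acceptance studies run a scaled-down version of a clinical
uniform-cylinder scan, chosen to keep the whole suite within minutes on
one core: an 18 cm water cylinder voxelized on a 64 × 8 × 64 grid of
2 mm voxels (the grid spans 128 mm transaxially, so the cylinder is
clipped by the grid; the voxelized volume itself is the ground truth for
all WEPLs, keeping the simulated system exactly self-consistent), 2000
protons per angle at 90 angles, $\sigma_{\text{WEPL}} = 3$ mm, a central
20 × 6 × 20 ROI, and 3–8 replicate simulations per measured quantity.
Two desk-scale consequences are worth noting:

* Rotation is about $y$, so only beam divergence (and optional
  scattering) couples vertical voxel layers.  At 2 mm voxels and a few
  mrad of divergence this coupling is weak: $\rho_y$ stays near zero at
  every $r$, while the full positive-to-negative correlation swing
  appears on the $x$ and $z$ axes.  In a full-physics simulation
  multi-mrad Coulomb scattering mixes 1 mm layers strongly enough for
  the $y$ axis to participate.
* The angle-count comparison (90 × 4° vs 180 × 2° at a fixed 1.8e5
  protons) probes angular-sampling (aliasing) noise, which is resolved
  only as the iterate approaches the least-squares solution; the
  comparison is therefore made at $r = 0.2$.  At $r = 0.75$ desk-scale
  smoothing suppresses the aliasing noise and the two arms coincide.

## Limitations

* Straight-chord trajectories only; no most-likely-path model.
* Single proton block; no relaxation schedule beyond the exact line
  search; no total-variation superiorization; no GPU path.
* The per-iteration alternating line search converges in large,
  non-monotone steps near a threshold; iteration counts to reach a
  given $r$ grow roughly linearly in $-\log r$ but individual runs
  cross thresholds in jumps (hence `statAtR`).
* HDF5 containers are not supported; list-mode I/O is full-precision
  CSV.  Volumes are NIfTI or raw float32 + JSON sidecar, isotropic
  voxels only.
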