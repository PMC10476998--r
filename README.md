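# protonCT

List-mode proton CT image reconstruction with a noise-based stopping
criterion, plus the image-noise analysis that motivates it.

## The problem

Proton CT (pCT) reconstructs a 3-D map of relative stopping power (RSP)
— the quantity proton-therapy treatment planning needs — from list-mode
data: for each proton, a measured trajectory and a measured
water-equivalent path length (WEPL, in mm).  Writing the per-voxel RSP
values as a vector *x*, the WEPL measurements as *b*, and the chord
lengths of each proton's trajectory through each voxel as the sparse
matrix *A*, a pCT image is a least-squares solution of *A x ≈ b*.

Iterative solvers exhibit *semi-convergence*: starting from a smooth
guess they first approach a smooth solution, then grow noisier as the
iterate accommodates the WEPL measurement noise.  Stopping "after k
iterations" therefore yields images with arbitrary, dataset-dependent
noise and smoothing.  This package implements a principled stopping
rule.  Define

- the proton deviation vector `dp = A x − b` (mm),
- the voxel deviation vector `dv = V⁻¹ Aᵀ dp`, the chord-weighted mean
  of `dp` over the protons crossing each voxel (`V = diag(Σₚ α_pv)`),
- the iteration `x → x − λ dv`, with `λ` an exact line search that
  alternates between minimizing `dp·dp` and `dv·dv`,
- the per-proton noise `σₚ = sd(dp)` and the expected voxel precision
  `σᵥ = σₚ / (ᾱ √N̄ₚᵥ)`, with `ᾱ` the mean chord length (approximated by
  the voxel size) and `N̄ₚᵥ` the mean number of protons per voxel,
- the convergence statistic  **r = rms(dv) / σᵥ** — the remaining
  distance to the unique least-squares solution in units of the image
  noise.

Stopping when `r` falls into the band **0.5–1** (default 0.75) produces
images whose voxel-to-voxel noise correlations are minimal: stopping
earlier (`r ≈ 2`) leaves positively correlated, over-smoothed noise;
iterating to `r ≈ 0.2` (near the least-squares solution) produces
sharper but noisier images with anticorrelated neighbours, the analogue
of a ramp-filtered FBP image.  The package quantifies this with ROI
variance, per-axis voxel autocorrelation functions ρ(δ), the noise
power spectrum (via the Wiener–Khinchin relation), and WET line sums.

A synthetic list-mode simulator (voxelized phantoms, rotation about the
vertical axis, pencil-beam focal divergence, tracker-pitch quantization,
Gaussian WEPL noise, the angle-reassignment shortcut for symmetric
phantoms) makes the whole pipeline testable without scanner data.

## Worked example

```r
library(protonCT)

grid  <- voxelGrid(c(64, 8, 64), voxelSize = 2)        # mm
truth <- makePhantom(waterCylinderPhantom(), grid)      # RSP = 1 cylinder
cfg   <- simulationConfig(protonsPerAngle = 2000, nAngles = 90,
                          angleSpacing = 4, weplNoiseSigma = 3,
                          beamExtent = c(190, 16), seed = 11)
pl    <- simulateProtons(truth, cfg)

res <- reconstruct(pl, grid,
                   stop = stoppingConfig(rStop = c(2, 0.75, 0.2)))
res
#> ReconResult: 42 iterations, final r = 0.1891 (converged)
#>   snapshots at r <= 2, 0.75, 0.2

roi <- centralROI(grid, c(20, 6, 20))
for (rs in c(2, 0.75, 0.2)) {
    v  <- reconSnapshot(res, rs)
    st <- roiStats(v, roi)
    ac <- voxelAutocorrelation(v, roi, deltaMax = 5)
    cat(sprintf("r=%.2f  sd=%.4f  rho_x(1)=%+.3f\n",
                rs, sqrt(st$variance), rhoCurve(ac, "x")[2]))
}
#> r=2.00  sd=0.0018  rho_x(1)=+0.374
#> r=0.75  sd=0.0849  rho_x(1)=+0.004
#> r=0.20  sd=0.1307  rho_x(1)=-0.148
```

The three lines show the method's central behaviour: ROI noise grows as
the stop tightens (semi-convergence), while the nearest-neighbour
correlation swings from clearly positive (over-smoothed) through
approximately zero (the recommended band) to negative (least-squares
regime).  The central WET line sum changes by only ~0.2 mm between
r = 0.75 and r = 0.2 (128.38 vs 128.61 mm here), so proton range
estimates are insensitive to the exact stop once the image mean has
converged.

A command-line front end is available in `exec/pct`
(`pct simulate | reconstruct | noise | wet | run`), driven by YAML
configurations; `runPipeline()` is the equivalent R entry point.

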