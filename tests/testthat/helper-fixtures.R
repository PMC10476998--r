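# Shared fixtures, built in code.

# The worked 3-proton / 2-voxel system: proton A through voxel 1
# (chord 1), proton B through voxels 1 and 2 (chords 1, 1), proton C
# through voxel 2 (chord 1); measured WEPLs b = (1, 2.2, 1).
microSystem <- function() {
    g <- voxelGrid(c(2L, 1L, 1L), voxelSize = 1, origin = c(0, 0, 0))
    posIn <- rbind(c(0.5, 0.5, -1), c(-1, 0.5, 0.5), c(1.5, 0.5, -1))
    posOut <- rbind(c(0.5, 0.5, 2), c(3, 0.5, 0.5), c(1.5, 0.5, 2))
    pl <- protonList(posIn, posOut, wepl = c(1, 2.2, 1),
                     angleDeg = c(0, 0, 0))
    list(grid = g, protons = pl, b = c(1, 2.2, 1),
         sm = buildSystemMatrix(pl, g))
}

# Independent oracle: length of a ray segment clipped to an axis-aligned
# box, by slab intersection (no voxel traversal involved).
clippedLength <- function(p0, d, lo, hi) {
    u <- d / sqrt(sum(d^2))
    t0 <- 0; t1 <- Inf
    for (a in 1:3) {
        if (abs(u[a]) < 1e-14) {
            if (p0[a] < lo[a] || p0[a] >= hi[a]) return(0)
        } else {
            ta <- (lo[a] - p0[a]) / u[a]
            tb <- (hi[a] - p0[a]) / u[a]
            t0 <- max(t0, min(ta, tb))
            t1 <- min(t1, max(ta, tb))
        }
    }
    max(0, t1 - t0)
}

# Brute-force pair-enumeration autocorrelation oracle: loops over every
# in-ROI voxel pair at separation delta along the given axis.
bruteRho <- function(a, axis, delta) {
    d <- dim(a)
    mu <- mean(a)
    varN <- sum((a - mu)^2) / length(a)
    tot <- 0; np <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
        for (k in seq_len(d[3])) {
            idx2 <- c(i, j, k)
            idx2[axis] <- idx2[axis] + delta
            if (idx2[axis] > d[axis]) next
            tot <- tot + (a[i, j, k] - mu) *
                (a[idx2[1], idx2[2], idx2[3]] - mu)
            np <- np + 1
        }
    tot / np / varN
}

# A small noisy tomographic problem: cylinder phantom on a coarse grid.
smallTomoProblem <- function(nx = 16L, ny = 4L, nz = 16L, voxel = 4,
                             protonsPerAngle = 150L, nAngles = 36L,
                             sigma = 3, seed = 42L) {
    g <- voxelGrid(c(nx, ny, nz), voxel)
    vol <- makePhantom(waterCylinderPhantom(), g)
    cfg <- simulationConfig(protonsPerAngle, nAngles, 360 / nAngles,
                            weplNoiseSigma = sigma, trackerPitch = 0.5,
                            beamExtent = c(nx * voxel * 1.5, ny * voxel),
                            seed = seed)
    pl <- simulateProtons(vol, cfg)
    list(grid = g, truth = vol, cfg = cfg, protons = pl)
}
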