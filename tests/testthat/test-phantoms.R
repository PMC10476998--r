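test_that("phantom voxelization assigns RSP by voxel-center membership", {
    g <- voxelGrid(c(200L, 50L, 200L), voxelSize = 1)
    vol <- makePhantom(waterCylinderPhantom(), g)
    v <- rspValues(vol)
    cx <- voxelCenters(g, 1); cy <- voxelCenters(g, 2)
    cz <- voxelCenters(g, 3)
    inside <- outer(cx^2, cz^2, `+`) <= 90^2
    # a y slice through the cylinder: 1 inside, 0 outside
    mid <- v[, which.min(abs(cy)), ]
    expect_true(all(mid[inside] == 1.0))
    expect_true(all(mid[!inside] == 0.0))
    # above the 40 mm cylinder height: all background
    topIdx <- which(abs(cy) > 20)
    expect_true(all(v[, topIdx, ] == 0))

    # empty spec -> all-zero volume
    empty <- makePhantom(phantomSpec(list(), backgroundRSP = 0), g)
    expect_message(makePhantom(phantomSpec(list(), backgroundRSP = 0), g))
    expect_true(all(rspValues(empty) == 0))
})

test_that("later phantom elements override earlier ones", {
    g <- voxelGrid(c(100L, 20L, 100L), voxelSize = 2)
    spec <- phantomSpec(list(
        cylinderElement(diameter = 180, height = 40, rsp = 0.98),
        cylinderElement(center = c(40, 0, 0), diameter = 18, height = 40,
                        rsp = 1.69)))
    v <- rspValues(makePhantom(spec, g))
    atInsert <- v[which.min(abs(voxelCenters(g, 1) - 40)),
                  which.min(abs(voxelCenters(g, 2))),
                  which.min(abs(voxelCenters(g, 3)))]
    farFromInsert <- v[which.min(abs(voxelCenters(g, 1) + 40)),
                       which.min(abs(voxelCenters(g, 2))),
                       which.min(abs(voxelCenters(g, 3)))]
    expect_identical(atInsert, 1.69)
    expect_identical(farFromInsert, 0.98)
})

test_that("true WEPL is the exact line integral of RSP", {
    g <- voxelGrid(c(180L, 40L, 180L), voxelSize = 1)
    vol <- makePhantom(waterCylinderPhantom(), g)
    # diametral ray through the axis of a uniform RSP=1 cylinder
    expect_equal(trueWEPL(vol, c(0, 0, -200), c(0, 0, 1)), 180,
                 tolerance = 1e-9)
    # linearity in RSP
    half <- makePhantom(waterCylinderPhantom(rsp = 0.5), g)
    expect_equal(trueWEPL(half, c(0, 0, -200), c(0, 0, 1)), 90,
                 tolerance = 1e-9)
    # ray missing the grid entirely
    expect_identical(trueWEPL(vol, c(500, 0, -200), c(0, 0, 1)), 0)
    # zero direction rejected
    expect_error(trueWEPL(vol, c(0, 0, 0), c(0, 0, 0)), "nonzero")
})

test_that("noiseless, unquantized, parallel-beam simulation reproduces true WEPL exactly", {
    g <- voxelGrid(c(32L, 8L, 32L), voxelSize = 4)
    vol <- makePhantom(waterCylinderPhantom(), g)
    cfg <- simulationConfig(protonsPerAngle = 200, nAngles = 12,
                            angleSpacing = 30, weplNoiseSigma = 0,
                            trackerPitch = 0, beamExtent = c(120, 30),
                            focalLength = Inf, seed = 3)
    pl <- simulateProtons(vol, cfg)
    recomputed <- vapply(seq_len(nProtons(pl)), function(p)
        trueWEPL(vol, pl@posIn[p, ], pl@posOut[p, ] - pl@posIn[p, ]),
        numeric(1))
    expect_equal(recomputed, weplMeasurements(pl), tolerance = 1e-9)
})

test_that("WEPL noise has the configured Gaussian distribution", {
    g <- voxelGrid(c(32L, 8L, 32L), voxelSize = 4)
    vol <- makePhantom(waterCylinderPhantom(), g)
    cfg <- simulationConfig(protonsPerAngle = 1200, nAngles = 90,
                            angleSpacing = 4, weplNoiseSigma = 3,
                            trackerPitch = 0.5, beamExtent = c(130, 30),
                            seed = 9)
    pl <- simulateProtons(vol, cfg)
    resid <- weplMeasurements(pl) - pl@meta$trueWEPL
    n <- length(resid)
    expect_equal(length(resid), 108000L)
    # sample sd of injected noise within 1% (chi-square sampling error)
    expect_equal(sd(resid), 3, tolerance = 0.01)
    expect_lt(abs(mean(resid)), 3 * 3 / sqrt(n))
    # Kolmogorov-Smirnov against N(0, 3) on a 1e4 subsample
    ks <- suppressWarnings(
        ks.test(resid[seq_len(10000L)], "pnorm", 0, 3))
    expect_gt(ks$p.value, 0.01)
})

test_that("per-angle WEPL distributions are exchangeable for a symmetric phantom", {
    # the cylinder must lie fully inside the grid, or the square grid
    # boundary breaks the rotational symmetry this property relies on
    g <- voxelGrid(c(32L, 8L, 32L), voxelSize = 4)
    vol <- makePhantom(waterCylinderPhantom(diameter = 100), g)
    cfg <- simulationConfig(protonsPerAngle = 800, nAngles = 10,
                            angleSpacing = 36, weplNoiseSigma = 3,
                            trackerPitch = 0.5, beamExtent = c(110, 30),
                            seed = 21)
    pl <- simulateProtons(vol, cfg)
    w <- split(weplMeasurements(pl), protonAngles(pl))
    expect_length(w, 10L)
    # Kruskal-Wallis: no angle effect on the WEPL distribution
    kw <- kruskal.test(weplMeasurements(pl),
                       factor(protonAngles(pl)))
    expect_gt(kw$p.value, 0.01)
    # per-angle means agree within sampling error of the pooled mean
    m <- vapply(w, mean, numeric(1))
    se <- vapply(w, function(v) sd(v) / sqrt(length(v)), numeric(1))
    expect_true(all(abs(m - mean(weplMeasurements(pl))) < 5 * se))
})

test_that("simulation is reproducible and angle streams are independent", {
    g <- voxelGrid(c(16L, 4L, 16L), voxelSize = 8)
    vol <- makePhantom(waterCylinderPhantom(), g)
    mk <- function(seed, nAngles) {
        simulateProtons(vol, simulationConfig(
            protonsPerAngle = 50, nAngles = nAngles,
            angleSpacing = 360 / nAngles, weplNoiseSigma = 2,
            beamExtent = c(130, 30), seed = seed))
    }
    a <- mk(5, 8L); b <- mk(5, 8L)
    expect_identical(a@posIn, b@posIn)
    expect_identical(weplMeasurements(a), weplMeasurements(b))
    expect_false(identical(weplMeasurements(a),
                           weplMeasurements(mk(6, 8L))))
    # adding angles must not reshuffle earlier angles' protons
    # (same seed, same angle spacing, more angles appended)
    c8 <- simulateProtons(vol, simulationConfig(
        protonsPerAngle = 50, nAngles = 8L, angleSpacing = 10,
        weplNoiseSigma = 2, beamExtent = c(130, 30), seed = 5)) |>
        suppressWarnings()
    c12 <- simulateProtons(vol, simulationConfig(
        protonsPerAngle = 50, nAngles = 12L, angleSpacing = 10,
        weplNoiseSigma = 2, beamExtent = c(130, 30), seed = 5)) |>
        suppressWarnings()
    first8 <- seq_len(8L * 50L)
    expect_identical(weplMeasurements(c12)[first8],
                     weplMeasurements(c8))
})

test_that("incomplete angular coverage triggers a warning", {
    expect_warning(simulationConfig(10, nAngles = 10, angleSpacing = 4),
                   "360")
    expect_silent(simulationConfig(10, nAngles = 90, angleSpacing = 4))
})
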