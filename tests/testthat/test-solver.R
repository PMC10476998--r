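test_that("deviation vectors match hand arithmetic on the micro-case", {
    ms <- microSystem()
    dp <- protonDeviations(ms$sm, c(1, 1), ms$b)
    expect_equal(dp, c(0, -0.2, 0), tolerance = 1e-12)
    dv <- voxelDeviations(ms$sm, dp)
    expect_equal(dv, c(-0.1, -0.1), tolerance = 1e-12)
    # x = 0 gives dp = -b; an exact solution gives dp = 0
    expect_equal(protonDeviations(ms$sm, c(0, 0), ms$b), -ms$b)
    expect_equal(voxelDeviations(ms$sm, c(0, 0, 0)), c(0, 0))
    expect_error(protonDeviations(ms$sm, c(1, 1, 1), ms$b), "voxel")
    expect_error(protonDeviations(ms$sm, c(1, 1), c(1, 1)), "proton")
})

test_that("dv is the chord-weighted average of dp", {
    # single proton, single voxel, chord 2 mm, dp = 4 mm:
    # the weighted average of one element is that element
    g <- voxelGrid(c(1L, 1L, 1L), voxelSize = 2, origin = c(0, 0, 0))
    pl <- protonList(rbind(c(1, 1, -1)), rbind(c(1, 1, 3)),
                     wepl = 0, angleDeg = 0)
    sm <- suppressWarnings(buildSystemMatrix(pl, g))
    expect_equal(as.numeric(chordMatrix(sm)), 2, tolerance = 1e-12)
    expect_equal(voxelDeviations(sm, 4), 4, tolerance = 1e-12)
})

test_that("exact line-search step sizes match hand arithmetic and a grid search", {
    ms <- microSystem()
    dp <- protonDeviations(ms$sm, c(1, 1), ms$b)
    dv <- voxelDeviations(ms$sm, dp)
    expect_equal(optimalStepSize(ms$sm, dp, dv, "dp"), 2 / 3,
                 tolerance = 1e-12)

    # random small tomographic systems: closed form vs fine grid search
    prob <- smallTomoProblem(nx = 6L, ny = 2L, nz = 6L, voxel = 8,
                             protonsPerAngle = 60L, nAngles = 12L,
                             seed = 8L)
    sm <- suppressWarnings(buildSystemMatrix(prob$protons, prob$grid))
    b <- weplMeasurements(prob$protons)
    A <- chordMatrix(sm)
    set.seed(31)
    for (trial in 1:5) {
        x <- runif(ncol(A), 0, 2) * reconMask(sm)
        dp <- protonDeviations(sm, x, b)
        dv <- voxelDeviations(sm, dp)
        for (obj in c("dp", "dv")) {
            lamHat <- optimalStepSize(sm, dp, dv, obj)
            objFun <- function(l) {
                dpl <- protonDeviations(sm, x - l * dv, b)
                if (obj == "dp") sum(dpl^2)
                else sum(voxelDeviations(sm, dpl)^2)
            }
            lamGrid <- seq(lamHat - 0.05, lamHat + 0.05, length.out = 201)
            vals <- vapply(lamGrid, objFun, numeric(1))
            expect_equal(lamGrid[which.min(vals)], lamHat,
                         tolerance = 1e-3)
            # the closed form is a true minimizer of its own objective
            expect_lte(objFun(lamHat),
                       min(objFun(lamHat - 1e-3), objFun(lamHat + 1e-3)))
        }
    }
})

test_that("step size is zero when dp is orthogonal to A dv", {
    ms <- microSystem()
    # dv = (1, -1): A dv = (1, 0, -1); dp = (0, 1, 0) is orthogonal
    expect_equal(optimalStepSize(ms$sm, c(0, 1, 0), c(1, -1), "dp"), 0)
    expect_error(optimalStepSize(ms$sm, c(0, 1, 0), c(0, 0), "dp"),
                 "solution")
})

test_that("noise estimates follow their definitions", {
    expect_identical(protonNoiseSigma(c(5, 5, 5, 5)), 0)
    expect_equal(protonNoiseSigma(c(0, -0.2, 0)), sd(c(0, -0.2, 0)))
    expect_equal(protonNoiseSigma(c(0, -0.2, 0)), 0.1154701,
                 tolerance = 1e-6)
    set.seed(12)
    expect_equal(protonNoiseSigma(rnorm(1e5, 0, 2.5)), 2.5,
                 tolerance = 0.01)

    g1 <- voxelGrid(c(2L, 1L, 1L), voxelSize = 1, origin = c(0, 0, 0))
    expect_equal(voxelNoiseSigma(2, 400, g1), 0.1, tolerance = 1e-12)
    # sqrt law: quadrupling Npv halves sigma_v
    expect_equal(voxelNoiseSigma(2, 1600, g1),
                 voxelNoiseSigma(2, 400, g1) / 2, tolerance = 1e-12)
    expect_identical(voxelNoiseSigma(0, 400, g1), 0)
})

test_that("convergence ratio r behaves per definition", {
    expect_identical(convergenceRatio(c(0, 0, 0), 1), 0)
    expect_equal(convergenceRatio(c(0.3, 0.3), 0.3), 1, tolerance = 1e-12)
    # micro-case at x = (1,1) with sigma_v = 0.2: rms dv = 0.1 -> r = 0.5
    ms <- microSystem()
    dv <- voxelDeviations(ms$sm, protonDeviations(ms$sm, c(1, 1), ms$b))
    expect_equal(convergenceRatio(dv, 0.2), 0.5, tolerance = 1e-12)
    expect_error(convergenceRatio(dv, 0), "noiseless")
})

test_that("one dp-objective step solves the micro-case exactly", {
    ms <- microSystem()
    res <- suppressWarnings(
        reconstruct(ms$sm, b = ms$b,
                    stop = stoppingConfig(rStop = 0.01,
                                          maxIterations = 5L,
                                          x0Mode = "supplied",
                                          x0 = c(1, 1))))
    # normal equations: 2 x1 + x2 = 3.2, x1 + 2 x2 = 3.2 -> x = 16/15
    expect_equal(res@x, c(16 / 15, 16 / 15), tolerance = 1e-12)
    expect_identical(res@iterations, 1L)
    dv <- voxelDeviations(ms$sm,
                          protonDeviations(ms$sm, res@x, ms$b))
    expect_lt(sqrt(mean(dv^2)), 1e-12)
    expect_identical(reconHistory(res)$objective[1], "dp")
})

test_that("iterative solve agrees with the direct normal-equations solve", {
    prob <- smallTomoProblem(nx = 10L, ny = 2L, nz = 10L, voxel = 6,
                             protonsPerAngle = 120L, nAngles = 24L,
                             seed = 17L)
    sm <- suppressWarnings(buildSystemMatrix(prob$protons, prob$grid))
    b <- weplMeasurements(prob$protons)
    xd <- solveNormalEquations(sm, b)
    dvd <- voxelDeviations(sm, protonDeviations(sm, xd, b))
    expect_lt(sqrt(mean(dvd[reconMask(sm)]^2)), 1e-10)

    resShallow <- suppressWarnings(reconstruct(sm, b = b,
        stop = stoppingConfig(rStop = 0.01, maxIterations = 3000L)))
    res <- suppressWarnings(reconstruct(sm, b = b,
        stop = stoppingConfig(rStop = 0.001, maxIterations = 3000L)))
    expect_true(res@converged)
    h <- reconHistory(res)
    sigmaV <- h$sigmaV[nrow(h)]
    # the iterate approaches the direct solution in proportion to r
    errShallow <- max(abs(resShallow@x - xd)[reconMask(sm)])
    errDeep <- max(abs(res@x - xd)[reconMask(sm)])
    expect_lt(errDeep, errShallow)
    expect_lt(errDeep, 1e-2 * sigmaV)

    # mean-WEPL property at the solution: for every masked voxel the
    # chord-weighted mean calculated WEPL equals the measured one
    A <- chordMatrix(sm)
    calc <- as.numeric(Matrix::crossprod(A, as.numeric(A %*% xd)))
    meas <- as.numeric(Matrix::crossprod(A, b))
    s <- sm@chordSums[reconMask(sm)]
    expect_lt(max(abs((calc - meas)[reconMask(sm)] / s)), 1e-8)
})

test_that("noiseless consistent data reconstructs the truth", {
    g <- voxelGrid(c(12L, 2L, 12L), voxelSize = 6)
    vol <- makePhantom(waterCylinderPhantom(), g)
    cfg <- simulationConfig(protonsPerAngle = 400, nAngles = 24,
                            angleSpacing = 15, weplNoiseSigma = 0,
                            trackerPitch = 0, beamExtent = c(110, 12),
                            focalLength = Inf, seed = 2)
    pl <- simulateProtons(vol, cfg)
    res <- suppressWarnings(reconstruct(pl, g,
        stop = stoppingConfig(rStop = 1e-4, maxIterations = 400L)))
    err <- abs(res@x - as.numeric(rspValues(vol)))
    expect_lt(max(err[reconMask(res@system)]), 1e-3)
})

test_that("reaching a smaller r requires more iterations", {
    prob <- smallTomoProblem(seed = 23L)
    res <- suppressWarnings(reconstruct(prob$protons, prob$grid,
        stop = stoppingConfig(rStop = c(2, 1, 0.75, 0.5, 0.2),
                              maxIterations = 3000L)))
    h <- reconHistory(res)
    iters <- vapply(c(2, 1, 0.75, 0.5, 0.2),
                    function(rs) min(h$iteration[h$r <= rs]), numeric(1))
    expect_true(all(diff(iters) >= 0))
    expect_gt(iters[5], iters[3])
})

test_that("history is append-only and the final state is recorded", {
    prob <- smallTomoProblem(seed = 29L)
    res <- suppressWarnings(reconstruct(prob$protons, prob$grid,
        stop = stoppingConfig(rStop = 0.75, maxIterations = 500L)))
    h <- reconHistory(res)
    expect_true(all(diff(h$iteration) >= 0))
    expect_equal(h$r[nrow(h)], res@finalR)
    expect_true(res@converged)
    expect_lte(res@finalR, 0.75)
    # the alternation is recorded, dp objective first
    expect_identical(h$objective[1:4], c("dp", "dv", "dp", "dv"))
})
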