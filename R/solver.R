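#' Proton and voxel deviation vectors
#'
#' `protonDeviations` computes dp = A x - b, the per-proton difference
#' between the WEPL calculated from the current image and the measured
#' WEPL (mm).  `voxelDeviations` computes dv, the chord-weighted average
#' of dp over the protons touching each voxel:
#' dv_v = sum_p alpha_pv dp_p / s_v on reconstructable voxels, and 0
#' elsewhere.  dv is the iteration direction of the solver and vanishes
#' exactly at the unique least-squares solution.
#'
#' @param sm a [SystemMatrix-class].
#' @param x numeric RSP vector (one entry per voxel, R array order).
#' @param b numeric measured-WEPL vector (one entry per proton, mm).
#' @param dp numeric proton deviation vector from `protonDeviations`.
#' @return `protonDeviations`: numeric(protons), mm.
#'   `voxelDeviations`: numeric(voxels), dimensionless RSP.
#' @export
protonDeviations <- function(sm, x, b) {
    if (length(x) != ncol(sm@A))
        stop("x must have one entry per voxel (", ncol(sm@A), ")")
    if (length(b) != nrow(sm@A))
        stop("b must have one entry per proton (", nrow(sm@A), ")")
    as.numeric(sm@A %*% x) - b
}

#' @rdname protonDeviations
#' @export
voxelDeviations <- function(sm, dp) {
    if (length(dp) != nrow(sm@A))
        stop("dp must have one entry per proton")
    if (any(sm@chordSums[sm@mask] <= 0))
        stop("mask violation: zero chord sum inside the reconstructable mask")
    num <- as.numeric(Matrix::crossprod(sm@A, dp))
    dv <- numeric(length(num))
    dv[sm@mask] <- num[sm@mask] / sm@chordSums[sm@mask]
    dv
}

#' Exact line-search step size along dv
#'
#' For the update x -> x - lambda * dv, returns the lambda that exactly
#' minimizes the chosen quadratic objective after the step:
#' `objective = "dp"` minimizes dp.dp, giving
#' lambda = (dp . A dv) / ||A dv||^2; `objective = "dv"` minimizes
#' dv.dv, giving lambda = (dv . u) / ||u||^2 with u = Abar^T A dv.
#' Alternating the two objectives between iterations is the solver's
#' default strategy.
#'
#' @param sm a [SystemMatrix-class].
#' @param dp current proton deviation vector.
#' @param dv current voxel deviation vector.
#' @param objective `"dp"` or `"dv"`.
#' @param Adv optionally, the precomputed product A dv.
#' @return lambda (dimensionless).
#' @export
optimalStepSize <- function(sm, dp, dv, objective = c("dp", "dv"),
                            Adv = NULL) {
    objective <- match.arg(objective)
    if (all(dv == 0)) stop("dv is zero; already at the least-squares solution")
    if (is.null(Adv)) Adv <- as.numeric(sm@A %*% dv)
    if (objective == "dp") {
        den <- sum(Adv^2)
        if (den == 0)
            stop("stagnation: A dv = 0 although dv != 0")
        sum(dp * Adv) / den
    } else {
        u <- voxelDeviations(sm, Adv)
        den <- sum(u^2)
        if (den == 0)
            stop("stagnation: Abar^T A dv = 0 although dv != 0")
        sum(dv * u) / den
    }
}

#' Noise estimates and the convergence statistic r
#'
#' `protonNoiseSigma` estimates the average per-proton WEPL noise
#' sigma_p as the sample standard deviation (divisor N-1) of dp over
#' protons whose rays intersect the grid.  `voxelNoiseSigma` converts
#' it to the expected RSP precision of a voxel,
#' sigma_v = sigma_p / (alpha_bar * sqrt(Npv)), where alpha_bar, the
#' average chord length through a voxel, is approximated by the voxel
#' edge length, and Npv is the mean number of protons per
#' reconstructable voxel.  `convergenceRatio` forms the stopping
#' statistic r = rms(dv) / sigma_v, the remaining distance to the
#' least-squares solution in units of the expected image noise.
#'
#' @param dp proton deviation vector (mm).
#' @param missed optional logical flag of protons missing the grid,
#'   excluded from the estimate.
#' @param sigmaP per-proton WEPL noise (mm).
#' @param npv mean protons per reconstructable voxel.
#' @param grid a [VoxelGrid-class] (supplies alpha_bar = voxel size).
#' @param dv voxel deviation vector.
#' @param sigmaV voxel noise estimate; must be > 0 (with noiseless data
#'   sigma_v = 0 and r is undefined: stop on rms(dv) instead).
#' @param mask logical reconstructable-voxel mask; rms is taken over it.
#' @return sigma_p in mm; sigma_v dimensionless; r dimensionless.
#' @export
protonNoiseSigma <- function(dp, missed = NULL) {
    if (!is.null(missed)) dp <- dp[!missed]
    stats::sd(dp)
}

#' @rdname protonNoiseSigma
#' @export
voxelNoiseSigma <- function(sigmaP, npv, grid) {
    if (npv <= 0) stop("Npv must be positive")
    sigmaP / (grid@voxelSize * sqrt(npv))
}

#' @rdname protonNoiseSigma
#' @export
convergenceRatio <- function(dv, sigmaV, mask = NULL) {
    if (sigmaV <= 0)
        stop("sigma_v = 0 (noiseless regime): r is undefined; ",
             "stop on rms(dv) <= 1e-12 instead")
    if (!is.null(mask)) dv <- dv[mask]
    sqrt(mean(dv^2)) / sigmaV
}

.rmsMasked <- function(dv, mask) sqrt(mean(dv[mask]^2))

#' Least-squares iterative reconstruction with the r stopping rule
#'
#' Iterates x -> x - lambda dv from a smooth initial guess, with dv the
#' chord-weighted voxel deviation vector and lambda an exact line search
#' that alternates between minimizing dp.dp (odd iterations, starting
#' with the first) and dv.dv (even iterations).  After each iteration
#' the statistic r = rms(dv)/sigma_v is evaluated, with sigma_p
#' re-estimated from the current dp; the solver stops when r falls to
#' the smallest requested threshold or the iteration cap is reached.
#' When several thresholds are requested the image is snapshotted as r
#' first crosses each of them, so a single run yields the whole
#' semi-convergence sequence.
#'
#' With noiseless data (sigma_p = 0) r is undefined and the solver stops
#' when rms(dv) <= 1e-12.  If r increases for 20 consecutive
#' evaluations the solve aborts with a diagnostic.
#'
#' @param object a [ProtonList-class] (the system matrix is built on
#'   `grid`) or a prebuilt [SystemMatrix-class].
#' @param grid a [VoxelGrid-class] (ProtonList method).
#' @param b measured WEPL vector (SystemMatrix method).
#' @param stop a [StoppingConfig-class].
#' @param verbose log per-evaluation progress.
#' @param ... passed through.
#' @return A [ReconResult-class].
#' @export
setGeneric("reconstruct", function(object, ...)
    standardGeneric("reconstruct"))

#' @rdname reconstruct
#' @export
setMethod("reconstruct", "ProtonList",
    function(object, grid, stop = stoppingConfig(), verbose = FALSE, ...) {
        sm <- buildSystemMatrix(object, grid)
        reconstruct(sm, b = weplMeasurements(object), stop = stop,
                    verbose = verbose)
    })

#' @rdname reconstruct
#' @export
setMethod("reconstruct", "SystemMatrix",
    function(object, b, stop = stoppingConfig(), verbose = FALSE, ...) {
        sm <- object
        validObject(stop)
        nMasked <- sum(sm@mask)
        if (nrow(sm@A) < 10 * nMasked)
            warning(sprintf(
                "only %d protons for %d reconstructable voxels; the solve may be ill-posed",
                nrow(sm@A), nMasked))

        x <- .initialGuess(sm, b, stop)
        dp <- protonDeviations(sm, x, b)

        thresholds <- sort(unique(stop@rStop), decreasing = TRUE)
        rMin <- min(thresholds)
        pending <- thresholds
        snapshots <- list()
        xPrevEval <- NULL
        rPrevEval <- NA_real_

        hist <- vector("list", stop@maxIterations + 1L)
        nh <- 0L
        converged <- FALSE
        rPrev <- Inf
        rUp <- 0L
        finalR <- NA_real_
        iter <- 0L

        repeat {
            dv <- voxelDeviations(sm, dp)
            checkNow <- iter %% stop@checkEvery == 0L ||
                iter >= stop@maxIterations
            lambda <- NA_real_
            objective <- NA_character_
            if (checkNow) {
                sigmaP <- protonNoiseSigma(dp, sm@missed)
                rms <- .rmsMasked(dv, sm@mask)
                if (sigmaP > 0) {
                    sigmaV <- voxelNoiseSigma(sigmaP, sm@npv, sm@grid)
                    r <- rms / sigmaV
                } else {
                    sigmaV <- 0
                    r <- if (rms <= 1e-12) 0 else Inf
                }
                finalR <- r
                while (length(pending) && r <= pending[1]) {
                    # keep the bracketing pre-crossing state so that
                    # image statistics can be interpolated to the exact
                    # threshold (see statAtR)
                    snapshots[[format(pending[1])]] <-
                        list(x = x, r = r, xBefore = xPrevEval,
                             rBefore = rPrevEval)
                    pending <- pending[-1]
                }
                xPrevEval <- x
                rPrevEval <- r
                if (verbose)
                    message(sprintf(
                        "iter %5d  r = %.5g  rms(dv) = %.4g  sigma_p = %.4g",
                        iter, r, rms, sigmaP))
                if ((sigmaV > 0 && r <= rMin) ||
                    (sigmaV == 0 && rms <= 1e-12)) {
                    converged <- TRUE
                    nh <- nh + 1L
                    hist[[nh]] <- data.frame(iteration = iter, r = r,
                        rmsDv = rms, sigmaP = sigmaP, sigmaV = sigmaV,
                        lambda = NA_real_, objective = NA_character_)
                    break
                }
                if (r > rPrev) rUp <- rUp + 1L else rUp <- 0L
                if (rUp >= 20L)
                    stop("divergence: r increased for 20 consecutive ",
                         "evaluations (last r = ", signif(r, 6), " at ",
                         "iteration ", iter, ")")
                rPrev <- r
            }
            if (iter >= stop@maxIterations) {
                if (checkNow) {
                    nh <- nh + 1L
                    hist[[nh]] <- data.frame(iteration = iter, r = finalR,
                        rmsDv = .rmsMasked(dv, sm@mask), sigmaP = sigmaP,
                        sigmaV = sigmaV, lambda = NA_real_,
                        objective = NA_character_)
                }
                break
            }

            # alternate exact line searches, dp objective first
            objective <- if (iter %% 2L == 0L) "dp" else "dv"
            Adv <- as.numeric(sm@A %*% dv)
            lambda <- optimalStepSize(sm, dp, dv, objective, Adv = Adv)
            x <- x - lambda * dv
            dp <- dp - lambda * Adv
            iter <- iter + 1L
            # periodic refresh against incremental round-off
            if (iter %% 64L == 0L) dp <- protonDeviations(sm, x, b)

            if (checkNow) {
                nh <- nh + 1L
                hist[[nh]] <- data.frame(iteration = iter - 1L, r = finalR,
                    rmsDv = rms, sigmaP = sigmaP, sigmaV = sigmaV,
                    lambda = lambda, objective = objective)
            }
        }

        history <- do.call(rbind, hist[seq_len(nh)])
        vol <- rspVolume(array(x, dim = sm@grid@dim), sm@grid)
        new("ReconResult", volume = vol, x = x, snapshots = snapshots,
            history = history, converged = converged, finalR = finalR,
            iterations = iter, system = sm)
    })

.initialGuess <- function(sm, b, stop) {
    nv <- ncol(sm@A)
    x <- numeric(nv)
    if (stop@x0Mode == "uniform") {
        ok <- !sm@missed & sm@rowLengths > 0
        x[sm@mask] <- mean(b[ok]) / mean(sm@rowLengths[ok])
    } else if (stop@x0Mode == "supplied") {
        if (length(stop@x0) != nv)
            stop("supplied x0 must have one entry per voxel")
        x <- stop@x0
        x[!sm@mask] <- 0
    }
    x
}

#' Direct least-squares solution via the normal equations
#'
#' Solves Abar^T A x = Abar^T b (equivalently A^T A x = A^T b) on the
#' reconstructable voxels with a sparse Cholesky factorization plus one
#' step of iterative refinement.  Intended for small systems as an
#' independent check of the iterative solver; at the solution dv = 0 and
#' the chord-weighted mean calculated WEPL of the protons touching any
#' voxel equals the chord-weighted mean measured WEPL.
#'
#' @param sm a [SystemMatrix-class].
#' @param b measured WEPL vector.
#' @return numeric RSP vector over all voxels (zeros off the mask).
#' @export
solveNormalEquations <- function(sm, b) {
    Am <- sm@A[, sm@mask, drop = FALSE]
    M <- Matrix::crossprod(Am)
    rhs <- as.numeric(Matrix::crossprod(Am, b))
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)
    xm <- as.numeric(Matrix::solve(ch, rhs))
    # one refinement pass
    res <- rhs - as.numeric(M %*% xm)
    xm <- xm + as.numeric(Matrix::solve(ch, res))
    x <- numeric(ncol(sm@A))
    x[sm@mask] <- xm
    x
}
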