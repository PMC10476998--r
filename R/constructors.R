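#' @importClassesFrom Matrix Matrix dgCMatrix
NULL

#' Create a voxel grid
#'
#' @param dim integer(3): voxel counts along x, y, z.
#' @param voxelSize voxel edge length in mm (isotropic).
#' @param origin corner of the grid in mm; the default centers the grid
#'   on the object-frame origin.
#' @return A [VoxelGrid-class].
#' @examples
#' g <- voxelGrid(c(64, 8, 64), voxelSize = 2)
#' @export
voxelGrid <- function(dim, voxelSize = 1.0,
                      origin = -dim * voxelSize / 2) {
    new("VoxelGrid", dim = as.integer(dim),
        voxelSize = as.numeric(voxelSize), origin = as.numeric(origin))
}

#' Grid dimensions, voxel size and extent
#' @param grid a [VoxelGrid-class]
#' @return `gridDim`: integer(3); `voxelSize`: mm; `gridExtent`: a 3x2
#'   matrix of lower/upper bounds in mm.
#' @export
gridDim <- function(grid) grid@dim

#' @rdname gridDim
#' @export
voxelSize <- function(grid) grid@voxelSize

#' @rdname gridDim
#' @export
gridExtent <- function(grid) {
    lo <- grid@origin
    cbind(lower = lo, upper = lo + grid@dim * grid@voxelSize)
}

#' Voxel center coordinates
#'
#' @param grid a [VoxelGrid-class]
#' @param axis 1, 2 or 3 (x, y, z)
#' @return numeric vector of voxel-center coordinates (mm) along the axis.
#' @export
voxelCenters <- function(grid, axis) {
    grid@origin[axis] + (seq_len(grid@dim[axis]) - 0.5) * grid@voxelSize
}

#' Construct an RSP volume
#'
#' @param values 3-D array (or a single value, recycled) of RSP.
#' @param grid the [VoxelGrid-class].
#' @return An [RSPVolume-class].
#' @export
rspVolume <- function(values, grid) {
    if (length(values) == 1L)
        values <- array(values, dim = grid@dim)
    new("RSPVolume", values = values, grid = grid)
}

#' Extract the RSP array or grid from a volume
#' @param volume an [RSPVolume-class]
#' @return `rspValues`: the 3-D array; `rspGrid`: the [VoxelGrid-class].
#' @export
rspValues <- function(volume) volume@values

#' @rdname rspValues
#' @export
rspGrid <- function(volume) volume@grid

#' Construct a simulation configuration
#'
#' Defaults emulate a tomographic list-mode acquisition: 90 angles
#' separated by 4 degrees, 0.5 mm tracker localization, and a single
#' Gaussian WEPL noise term of 3 mm absorbing range straggling and
#' detector resolution.
#'
#' @param protonsPerAngle protons generated at each angle.
#' @param nAngles number of projection angles.
#' @param angleSpacing degrees between consecutive angles.
#' @param weplNoiseSigma Gaussian WEPL noise sigma (mm).
#' @param trackerPitch tracker position quantization (mm); 0 disables.
#' @param beamExtent lateral beam span in mm; a single horizontal span,
#'   or c(horizontal, vertical).
#' @param scatterSigma small-angle perturbation of the recorded
#'   direction (mrad); 0 disables.
#' @param focalLength horizontal and vertical focal lengths (mm) of the
#'   pencil-beam scanning geometry (defaults 1935 and 2303 mm); rays
#'   diverge from the focal points, so protons travel mostly in the
#'   x-z plane with some divergence into y.  Use `Inf` for a parallel
#'   beam.
#' @param seed master RNG seed (per-angle child streams are derived from
#'   it, so changing `nAngles` does not reshuffle other angles).
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(protonsPerAngle, nAngles = 90L,
                             angleSpacing = 4, weplNoiseSigma = 3,
                             trackerPitch = 0.5, beamExtent = 200,
                             scatterSigma = 0,
                             focalLength = c(1935, 2303), seed = 1L) {
    cfg <- new("SimulationConfig",
               protonsPerAngle = as.integer(protonsPerAngle),
               nAngles = as.integer(nAngles),
               angleSpacing = as.numeric(angleSpacing),
               weplNoiseSigma = as.numeric(weplNoiseSigma),
               trackerPitch = as.numeric(trackerPitch),
               beamExtent = as.numeric(beamExtent),
               scatterSigma = as.numeric(scatterSigma),
               focalLength = rep(as.numeric(focalLength), length.out = 2L),
               seed = as.integer(seed))
    cover <- cfg@nAngles * cfg@angleSpacing
    if (cover < 360 - 1e-9)
        warning(sprintf(
            "angles cover %.1f deg < 360 deg; tomographic sampling is incomplete",
            cover))
    cfg
}

#' Construct a ProtonList
#'
#' @param posIn,posOut n-by-3 matrices of entry/exit positions (mm,
#'   object frame).
#' @param wepl measured WEPL per proton (mm).
#' @param angleDeg projection angle per proton (degrees).
#' @param dirIn,dirOut optional n-by-3 unit direction matrices; by
#'   default the straight chord from `posIn` to `posOut`.
#' @param meta provenance list.
#' @return A [ProtonList-class].
#' @export
protonList <- function(posIn, posOut, wepl, angleDeg,
                       dirIn = NULL, dirOut = NULL, meta = list()) {
    posIn <- as.matrix(posIn); posOut <- as.matrix(posOut)
    if (is.null(dirIn)) {
        d <- posOut - posIn
        dirIn <- d / sqrt(rowSums(d^2))
    }
    if (is.null(dirOut)) dirOut <- dirIn
    new("ProtonList", posIn = posIn, posOut = posOut,
        dirIn = as.matrix(dirIn), dirOut = as.matrix(dirOut),
        wepl = as.numeric(wepl), angleDeg = as.numeric(angleDeg),
        meta = meta)
}

#' ProtonList accessors
#' @param protons a [ProtonList-class]
#' @return `nProtons`: count; `weplMeasurements`: numeric vector (mm);
#'   `protonAngles`: degrees.
#' @export
nProtons <- function(protons) length(protons@wepl)

#' @rdname nProtons
#' @export
weplMeasurements <- function(protons) protons@wepl

#' @rdname nProtons
#' @export
protonAngles <- function(protons) protons@angleDeg

#' Subset a ProtonList
#' @param x a [ProtonList-class]
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "ProtonList", function(x, i, j, ..., drop = FALSE) {
    protonList(x@posIn[i, , drop = FALSE], x@posOut[i, , drop = FALSE],
               x@wepl[i], x@angleDeg[i],
               dirIn = x@dirIn[i, , drop = FALSE],
               dirOut = x@dirOut[i, , drop = FALSE], meta = x@meta)
})

#' Construct a stopping configuration
#'
#' The default threshold r = 0.75 sits in the middle of the 0.5-1 band
#' in which reconstructed images show minimal inter-voxel noise
#' correlation.
#'
#' @param rStop threshold(s) on r; with several values the solver runs
#'   to the smallest and snapshots the image as each is crossed.
#' @param maxIterations iteration cap.
#' @param checkEvery iterations between r evaluations.
#' @param x0Mode initial guess: "uniform" (a flat image matched to the
#'   mean WEPL; the smooth start that gives semi-convergence), "zero",
#'   or "supplied".
#' @param x0 numeric vector or [RSPVolume-class] when x0Mode="supplied".
#' @return A [StoppingConfig-class].
#' @export
stoppingConfig <- function(rStop = 0.75, maxIterations = 1000L,
                           checkEvery = 1L, x0Mode = c("uniform", "zero",
                                                       "supplied"),
                           x0 = numeric(0)) {
    x0Mode <- match.arg(x0Mode)
    if (is(x0, "RSPVolume")) x0 <- as.numeric(x0@values)
    new("StoppingConfig", rStop = as.numeric(rStop),
        maxIterations = as.integer(maxIterations),
        checkEvery = as.integer(checkEvery), x0Mode = x0Mode,
        x0 = as.numeric(x0))
}

#' ReconResult accessors
#' @param result a [ReconResult-class]
#' @param rStop for `reconSnapshot`, which captured threshold to return.
#' @return `reconVolume`: the final [RSPVolume-class]; `reconHistory`:
#'   the per-evaluation data.frame; `reconSnapshot`: the
#'   [RSPVolume-class] captured when r first crossed `rStop`.
#' @export
reconVolume <- function(result) result@volume

#' @rdname reconVolume
#' @export
reconHistory <- function(result) result@history

#' @rdname reconVolume
#' @export
reconSnapshot <- function(result, rStop) {
    snap <- .getSnapshot(result, rStop)
    rspVolume(array(snap$x, dim = result@system@grid@dim),
              result@system@grid)
}

.getSnapshot <- function(result, rStop) {
    key <- format(rStop)
    if (!key %in% names(result@snapshots))
        stop("no snapshot captured at rStop = ", key)
    result@snapshots[[key]]
}

#' Evaluate an image statistic at an exact r value
#'
#' The solver checks r at discrete iterations, and a single exact
#' line-search step can carry r well past a requested threshold, so the
#' image captured at the stop fluctuates around the nominal r.  For
#' *measuring* how a statistic (ROI noise, autocorrelation, WET sums)
#' depends on r, `statAtR` evaluates `f` on the two iterates bracketing
#' the crossing and interpolates linearly in log r to the threshold.
#' The stopping rule itself is unchanged: [reconSnapshot()] still
#' returns the first checked iterate with r at or below the threshold.
#'
#' @param result a [ReconResult-class] from a run that requested `rStop`
#'   among its thresholds.
#' @param rStop the threshold to evaluate at.
#' @param f function taking an [RSPVolume-class] and returning a numeric
#'   scalar or vector.
#' @return The interpolated value(s) of `f`.
#' @export
statAtR <- function(result, rStop, f) {
    snap <- .getSnapshot(result, rStop)
    g <- result@system@grid
    after <- f(rspVolume(array(snap$x, dim = g@dim), g))
    if (is.null(snap$xBefore) || !is.finite(snap$rBefore) ||
        snap$r >= rStop)
        return(after)
    before <- f(rspVolume(array(snap$xBefore, dim = g@dim), g))
    w <- (log(snap$rBefore) - log(rStop)) /
        (log(snap$rBefore) - log(snap$r))
    (1 - w) * before + w * after
}

setMethod("show", "VoxelGrid", function(object) {
    ext <- gridExtent(object)
    cat(sprintf("VoxelGrid: %d x %d x %d voxels, %.3g mm\n",
                object@dim[1], object@dim[2], object@dim[3],
                object@voxelSize))
    cat(sprintf("  extent x: [%.1f, %.1f]  y: [%.1f, %.1f]  z: [%.1f, %.1f] mm\n",
                ext[1, 1], ext[1, 2], ext[2, 1], ext[2, 2], ext[3, 1],
                ext[3, 2]))
})

setMethod("show", "RSPVolume", function(object) {
    cat(sprintf("RSPVolume: %d x %d x %d voxels (%.3g mm), RSP range [%.4g, %.4g]\n",
                dim(object@values)[1], dim(object@values)[2],
                dim(object@values)[3], object@grid@voxelSize,
                min(object@values), max(object@values)))
})

setMethod("show", "ProtonList", function(object) {
    n <- length(object@wepl)
    cat(sprintf("ProtonList: %d protons, %d angles\n", n,
                length(unique(object@angleDeg))))
    if (n > 0)
        cat(sprintf("  WEPL [mm]: median %.1f, range [%.1f, %.1f]\n",
                    stats::median(object@wepl), min(object@wepl),
                    max(object@wepl)))
})

setMethod("show", "SystemMatrix", function(object) {
    cat(sprintf("SystemMatrix: %d protons x %d voxels, %d chords\n",
                nrow(object@A), ncol(object@A),
                length(object@A@x)))
    cat(sprintf("  reconstructable voxels: %d (%.1f%%), mean protons/voxel %.1f\n",
                sum(object@mask), 100 * mean(object@mask), object@npv))
})

setMethod("show", "ReconResult", function(object) {
    cat(sprintf("ReconResult: %d iterations, final r = %.4g (%s)\n",
                object@iterations, object@finalR,
                if (object@converged) "converged" else "not converged"))
    if (length(object@snapshots))
        cat("  snapshots at r <=", paste(names(object@snapshots),
                                         collapse = ", "), "\n")
})

setMethod("show", "AutocorrelationResult", function(object) {
    cat(sprintf("AutocorrelationResult: mean RSP %.4f, sd %.4g\n",
                object@mean, sqrt(object@variance)))
    for (ax in c("x", "y", "z")) {
        rho <- object@rho[[ax]]
        cat(sprintf("  rho_%s(0..%d): %s\n", ax, length(rho) - 1L,
                    paste(sprintf("%+.3f", rho), collapse = " ")))
    }
})
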