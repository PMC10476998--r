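#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib protonCT, .registration = TRUE
NULL

#' VoxelGrid: an isotropic 3-D voxel lattice
#'
#' Defines the reconstruction lattice.  Voxel `(i,j,k)` (0-based) occupies
#' the half-open box `[origin + i*h, origin + (i+1)*h)` along each axis,
#' where `h` is the voxel size in mm.  By convention the object rotates
#' about the +y (vertical) axis during acquisition and protons travel
#' nominally along +z in the gantry frame; all coordinates stored in
#' package objects are in the fixed object frame, in mm.
#'
#' @slot dim integer(3), voxel counts along x, y, z.
#' @slot voxelSize numeric(1), isotropic voxel edge length in mm.
#' @slot origin numeric(3), coordinates of the grid corner (mm).
#' @export
setClass("VoxelGrid",
    representation(dim = "integer", voxelSize = "numeric",
                   origin = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@dim) != 3L || any(object@dim < 1L))
            msg <- c(msg, "dim must be three voxel counts >= 1")
        if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
            msg <- c(msg, "voxelSize must be a single positive length (mm)")
        if (length(object@origin) != 3L || any(!is.finite(object@origin)))
            msg <- c(msg, "origin must be three finite coordinates (mm)")
        if (is.null(msg)) TRUE else msg
    })

#' RSPVolume: a relative-stopping-power map on a VoxelGrid
#'
#' @slot values 3-D numeric array of dimensionless RSP, dim = grid dim.
#' @slot grid the [VoxelGrid-class] the values live on.
#' @export
setClass("RSPVolume",
    representation(values = "array", grid = "VoxelGrid"),
    validity = function(object) {
        if (!identical(dim(object@values), as.integer(object@grid@dim)))
            return("values array dimensions must match the grid")
        if (any(!is.finite(object@values)))
            return("RSP values must be finite")
        TRUE
    })

#' PhantomSpec: a constructive phantom description
#'
#' A phantom is a background RSP plus an ordered list of geometric
#' elements; later elements override earlier ones where they overlap.
#' Elements are created with [cylinderElement()] (axis along y, the
#' rotation axis) and [boxElement()].
#'
#' @slot elements list of element descriptions.
#' @slot backgroundRSP numeric(1), dimensionless RSP outside all elements.
#' @export
setClass("PhantomSpec",
    representation(elements = "list", backgroundRSP = "numeric"),
    prototype(elements = list(), backgroundRSP = 0),
    validity = function(object) {
        if (length(object@backgroundRSP) != 1L || object@backgroundRSP < 0)
            return("backgroundRSP must be a single value >= 0")
        for (el in object@elements) {
            if (!is.list(el) || is.null(el$shape))
                return("each element must be a list with a 'shape' field")
            if (!el$shape %in% c("cylinder", "box"))
                return("element shape must be 'cylinder' or 'box'")
            if (is.null(el$rsp) || el$rsp < 0)
                return("element rsp must be >= 0")
        }
        TRUE
    })

#' SimulationConfig: settings for the synthetic list-mode proton simulator
#'
#' @slot protonsPerAngle integer(1), protons generated at each angle.
#' @slot nAngles integer(1), number of projection angles.
#' @slot angleSpacing numeric(1), degrees between consecutive angles.
#' @slot weplNoiseSigma numeric(1), Gaussian WEPL measurement noise (mm).
#' @slot trackerPitch numeric(1), tracker position quantization (mm);
#'   recorded entry/exit positions snap to this pitch (0 disables).
#' @slot beamExtent numeric(1 or 2), lateral beam span (mm): horizontal
#'   extent in the gantry frame and, optionally, a separate vertical span.
#' @slot scatterSigma numeric(1), small-angle perturbation of the
#'   recorded direction (mrad); 0 disables.
#' @slot focalLength numeric(2), horizontal and vertical focal lengths
#'   (mm) of the pencil-beam scanning geometry; rays diverge from the
#'   corresponding focal points.  `Inf` gives a parallel beam.
#' @slot seed integer(1), master RNG seed.
#' @export
setClass("SimulationConfig",
    representation(protonsPerAngle = "integer", nAngles = "integer",
                   angleSpacing = "numeric", weplNoiseSigma = "numeric",
                   trackerPitch = "numeric", beamExtent = "numeric",
                   scatterSigma = "numeric", focalLength = "numeric",
                   seed = "integer"),
    validity = function(object) {
        msg <- NULL
        if (object@protonsPerAngle < 1L)
            msg <- c(msg, "protonsPerAngle must be >= 1")
        if (object@nAngles < 1L) msg <- c(msg, "nAngles must be >= 1")
        if (object@angleSpacing <= 0)
            msg <- c(msg, "angleSpacing must be > 0")
        if (object@weplNoiseSigma < 0)
            msg <- c(msg, "weplNoiseSigma must be >= 0")
        if (object@trackerPitch < 0)
            msg <- c(msg, "trackerPitch must be >= 0")
        if (!length(object@beamExtent) %in% 1:2 ||
            any(object@beamExtent <= 0))
            msg <- c(msg, "beamExtent must be 1 or 2 positive spans (mm)")
        if (object@scatterSigma < 0)
            msg <- c(msg, "scatterSigma must be >= 0")
        if (length(object@focalLength) != 2L ||
            any(object@focalLength <= 0))
            msg <- c(msg, "focalLength must be two positive lengths (mm)")
        if (is.null(msg)) TRUE else msg
    })

#' ProtonList: list-mode proton data
#'
#' One row per proton: recorded (tracker-quantized) entry and exit
#' positions and unit directions in the object frame (mm), the measured
#' WEPL (mm) and the projection angle (degrees).
#'
#' @slot posIn,posOut n-by-3 matrices of recorded positions (mm).
#' @slot dirIn,dirOut n-by-3 matrices of recorded unit directions.
#' @slot wepl numeric(n), measured water-equivalent path length (mm).
#' @slot angleDeg numeric(n), projection angle (degrees).
#' @slot meta list, provenance (config echo, seed) carried along.
#' @export
setClass("ProtonList",
    representation(posIn = "matrix", posOut = "matrix",
                   dirIn = "matrix", dirOut = "matrix",
                   wepl = "numeric", angleDeg = "numeric", meta = "list"),
    prototype(meta = list()),
    validity = function(object) {
        n <- length(object@wepl)
        mats <- list(object@posIn, object@posOut, object@dirIn,
                     object@dirOut)
        for (m in mats)
            if (!is.numeric(m) || nrow(m) != n || ncol(m) != 3L)
                return("position/direction matrices must be n x 3")
        if (any(!is.finite(object@wepl)))
            return("WEPL values must be finite")
        if (length(object@angleDeg) != n)
            return("angleDeg must have one entry per proton")
        TRUE
    })

#' SystemMatrix: sparse chord lengths and per-voxel normalizers
#'
#' Row p holds the chord lengths (mm) of proton p through each voxel;
#' column v corresponds to voxel v in R array order.  `chordSums` is the
#' diagonal of V (s_v = sum_p alpha_pv), `protonCounts` the number of
#' protons touching each voxel, and `mask` flags the reconstructable
#' voxels (touched by at least one proton, positive chord sum).  `npv`
#' is the mean protons-per-voxel over the mask, used by the voxel-noise
#' estimate.
#'
#' @slot A a `dgCMatrix` of chord lengths (mm), protons x voxels.
#' @slot chordSums numeric, per-voxel chord sums s_v (mm).
#' @slot protonCounts integer, protons touching each voxel.
#' @slot npv numeric(1), mean protons per reconstructable voxel.
#' @slot mask logical, reconstructable-voxel mask.
#' @slot rowLengths numeric, each proton's geometric path through the grid.
#' @slot missed logical, protons whose rays miss the grid (empty rows).
#' @slot grid the [VoxelGrid-class].
#' @export
setClass("SystemMatrix",
    representation(A = "Matrix", chordSums = "numeric",
                   protonCounts = "integer", npv = "numeric",
                   mask = "logical", rowLengths = "numeric",
                   missed = "logical", grid = "VoxelGrid"),
    validity = function(object) {
        nv <- prod(object@grid@dim)
        if (ncol(object@A) != nv)
            return("A must have one column per voxel")
        if (length(object@chordSums) != nv || length(object@mask) != nv)
            return("per-voxel vectors must have one entry per voxel")
        if (any(object@chordSums[object@mask] <= 0))
            return("chord sums must be positive on the mask")
        TRUE
    })

#' StoppingConfig: stopping rule for the iterative solver
#'
#' @slot rStop numeric, stopping threshold(s) on the convergence
#'   statistic r; when several are given the solver runs to the smallest
#'   and snapshots the image as each is crossed.
#' @slot maxIterations integer(1).
#' @slot checkEvery integer(1), iterations between r evaluations.
#' @slot x0Mode character(1): "uniform", "zero" or "supplied".
#' @slot x0 optional numeric starting volume (used when x0Mode is
#'   "supplied").
#' @export
setClass("StoppingConfig",
    representation(rStop = "numeric", maxIterations = "integer",
                   checkEvery = "integer", x0Mode = "character",
                   x0 = "numeric"),
    prototype(rStop = 0.75, maxIterations = 1000L, checkEvery = 1L,
              x0Mode = "uniform", x0 = numeric(0)),
    validity = function(object) {
        msg <- NULL
        if (length(object@rStop) < 1L || any(object@rStop <= 0))
            msg <- c(msg, "rStop thresholds must be > 0")
        if (object@maxIterations < 1L)
            msg <- c(msg, "maxIterations must be >= 1")
        if (object@checkEvery < 1L)
            msg <- c(msg, "checkEvery must be >= 1")
        if (!object@x0Mode %in% c("uniform", "zero", "supplied"))
            msg <- c(msg, "x0Mode must be uniform, zero or supplied")
        if (is.null(msg)) TRUE else msg
    })

#' ReconResult: the solver's output and iteration history
#'
#' @slot volume the reconstructed [RSPVolume-class] at the final stop.
#' @slot x numeric, the raw RSP vector (zeros off the mask).
#' @slot snapshots named list of RSP vectors captured as r crossed each
#'   requested threshold (names are the thresholds).
#' @slot history data.frame with one row per r evaluation: iteration,
#'   r, rmsDv, sigmaP, sigmaV, lambda, objective.
#' @slot converged logical(1), whether the smallest rStop was reached.
#' @slot finalR numeric(1).
#' @slot iterations integer(1), iterations actually performed.
#' @slot system the [SystemMatrix-class] used (for downstream checks).
#' @export
setClass("ReconResult",
    representation(volume = "RSPVolume", x = "numeric",
                   snapshots = "list", history = "data.frame",
                   converged = "logical", finalR = "numeric",
                   iterations = "integer", system = "SystemMatrix"))

#' AutocorrelationResult: ROI noise structure
#'
#' Per-axis autocorrelation curves rho(delta) over a uniform ROI.
#' rho(0) is exactly 1 by construction (population-variance normalizer,
#' actual pair counts at each lag).
#'
#' @slot mean numeric(1), mean RSP over the ROI.
#' @slot variance numeric(1), divisor-(N-1) sample variance (Eq.-style
#'   ROI noise estimate).
#' @slot varianceN numeric(1), divisor-N variance (the rho normalizer).
#' @slot rho named list with numeric vectors `x`, `y`, `z`, each over
#'   delta = 0..deltaMax.
#' @slot nPairs named list of pair counts per axis and lag.
#' @slot voxelSize numeric(1), mm (for frequency axes downstream).
#' @export
setClass("AutocorrelationResult",
    representation(mean = "numeric", variance = "numeric",
                   varianceN = "numeric", rho = "list", nPairs = "list",
                   voxelSize = "numeric"))

#' NoisePowerSpectrum: per-axis NPS from the autocovariance
#'
#' Discrete Fourier transform of the symmetrized autocovariance
#' (rho * variance) per axis; frequencies in 1/mm.  The normalization is
#' such that `sum(power) * df` equals the ROI variance.
#'
#' @slot freq named list of frequency vectors (1/mm) per axis.
#' @slot power named list of power vectors (RSP^2 * mm) per axis.
#' @slot variance numeric(1), the ROI variance the spectra integrate to.
#' @slot voxelSize numeric(1), mm.
#' @export
setClass("NoisePowerSpectrum",
    representation(freq = "list", power = "list", variance = "numeric",
                   voxelSize = "numeric"))
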