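#' Define a rectangular region of interest
#'
#' Voxel-index box for noise analysis, 1-based and inclusive: the ROI
#' spans `start[a] .. start[a] + extent[a] - 1` along each axis.  Noise
#' statistics assume the ROI covers a physically uniform region.
#'
#' @param start integer(3), first voxel indices (i, j, k).
#' @param extent integer(3), voxel counts per axis (>= 1).
#' @return A plain list with class `"ROISpec"`.
#' @export
roiSpec <- function(start, extent) {
    start <- as.integer(start); extent <- as.integer(extent)
    stopifnot(length(start) == 3L, length(extent) == 3L,
              all(start >= 1L), all(extent >= 1L))
    structure(list(start = start, extent = extent), class = "ROISpec")
}

#' A centered ROI on a grid
#'
#' @param grid a [VoxelGrid-class].
#' @param extent integer(3), ROI size in voxels.
#' @return An `ROISpec` centered in the grid.
#' @export
centralROI <- function(grid, extent) {
    extent <- as.integer(extent)
    start <- pmax(1L, as.integer(floor((grid@dim - extent) / 2)) + 1L)
    roiSpec(start, extent)
}

.roiArray <- function(volume, roi) {
    d <- dim(volume@values)
    hi <- roi$start + roi$extent - 1L
    if (any(hi > d))
        stop("ROI extends beyond the grid")
    volume@values[roi$start[1]:hi[1], roi$start[2]:hi[2],
                  roi$start[3]:hi[3], drop = FALSE]
}

#' ROI mean and variance
#'
#' Mean RSP and the divisor-(N-1) sample variance over the ROI voxels —
#' the standard image-noise estimate for a uniform region.
#'
#' @param volume an [RSPVolume-class].
#' @param roi an `ROISpec` from [roiSpec()] / [centralROI()].
#' @return list with `mean`, `variance` and `n` (voxel count).
#' @export
roiStats <- function(volume, roi) {
    v <- as.numeric(.roiArray(volume, roi))
    list(mean = mean(v), variance = stats::var(v), n = length(v))
}

#' Per-axis voxel autocorrelation within a uniform ROI
#'
#' For each axis and each separation delta = 0..deltaMax, the average
#' over all in-ROI voxel pairs separated by delta along that axis of the
#' product of mean-centered RSP values, normalized so that rho(0) = 1
#' exactly: the sum is divided by the actual number of valid pairs at
#' each lag (pairs truncate at the ROI edge; no wrap-around) and by the
#' divisor-N (population) variance.  A single shared ROI mean is used
#' for both members of every pair.
#'
#' @param volume an [RSPVolume-class].
#' @param roi an `ROISpec`; its extent must exceed `deltaMax` along
#'   every axis.
#' @param deltaMax largest separation, in voxels (default 10; the
#'   correlation structure of interest lives at small separations).
#' @return An [AutocorrelationResult-class].
#' @export
voxelAutocorrelation <- function(volume, roi, deltaMax = 10L) {
    a <- .roiArray(volume, roi)
    d <- dim(a)
    deltaMax <- as.integer(deltaMax)
    if (any(d <= deltaMax))
        stop("deltaMax must be smaller than the ROI extent along each axis")
    n <- length(a)
    mu <- mean(a)
    cArr <- a - mu
    varN <- sum(cArr^2) / n
    if (varN == 0)
        stop("degenerate ROI: zero variance, correlation undefined")
    rho <- nPairs <- list()
    for (ax in 1:3) {
        rr <- numeric(deltaMax + 1L)
        np <- numeric(deltaMax + 1L)
        for (delta in 0:deltaMax) {
            i1 <- seq_len(d[ax] - delta)
            i2 <- i1 + delta
            s1 <- .slab(cArr, ax, i1)
            s2 <- .slab(cArr, ax, i2)
            np[delta + 1L] <- length(s1)
            rr[delta + 1L] <- sum(s1 * s2) / length(s1) / varN
        }
        axn <- c("x", "y", "z")[ax]
        rho[[axn]] <- rr
        nPairs[[axn]] <- np
    }
    new("AutocorrelationResult", mean = mu,
        variance = sum(cArr^2) / (n - 1), varianceN = varN, rho = rho,
        nPairs = nPairs, voxelSize = volume@grid@voxelSize)
}

.slab <- function(a, axis, idx) {
    switch(axis,
           a[idx, , , drop = FALSE],
           a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
}

#' AutocorrelationResult accessors
#' @param ac an [AutocorrelationResult-class]
#' @param axis "x", "y" or "z"
#' @return `rhoCurve`: numeric vector rho(0..deltaMax); `roiVariance`:
#'   the divisor-(N-1) ROI variance.
#' @export
rhoCurve <- function(ac, axis = c("x", "y", "z")) {
    ac@rho[[match.arg(axis)]]
}

#' @rdname rhoCurve
#' @export
roiVariance <- function(ac) ac@variance

#' Noise power spectrum from the autocorrelation function
#'
#' The autocovariance and the NPS are a Fourier-transform pair
#' (Wiener-Khinchin).  Per axis, the measured rho(0..deltaMax) is scaled
#' by the population ROI variance, symmetrized to lags
#' -deltaMax..deltaMax, and transformed with a discrete Fourier
#' transform; the spectrum is reported on frequencies k / (M h), k =
#' 0..M-1 with M = 2 deltaMax + 1 and h the voxel size, and normalized
#' so that sum(power) * df equals the ROI variance.  Sample spectra can
#' dip slightly below zero where the estimated autocovariance is not
#' positive semidefinite.
#'
#' @param ac an [AutocorrelationResult-class].
#' @return A [NoisePowerSpectrum-class].
#' @export
noisePowerSpectrum <- function(ac) {
    h <- ac@voxelSize
    freq <- power <- list()
    for (axn in c("x", "y", "z")) {
        rho <- ac@rho[[axn]]
        dmax <- length(rho) - 1L
        cov <- rho * ac@varianceN
        covCirc <- c(cov, rev(cov[-1]))          # lags 0..dmax, -dmax..-1
        M <- length(covCirc)
        power[[axn]] <- Re(stats::fft(covCirc)) * h
        freq[[axn]] <- (seq_len(M) - 1) / (M * h)
    }
    new("NoisePowerSpectrum", freq = freq, power = power,
        variance = ac@varianceN, voxelSize = h)
}

#' Invert an NPS back to the autocovariance
#'
#' The inverse discrete Fourier transform of the spectrum; used to
#' verify the Wiener-Khinchin round trip.
#'
#' @param nps a [NoisePowerSpectrum-class].
#' @param axis "x", "y" or "z".
#' @return autocovariance at lags 0..deltaMax.
#' @export
npsToAutocovariance <- function(nps, axis = c("x", "y", "z")) {
    axis <- match.arg(axis)
    p <- nps@power[[axis]] / nps@voxelSize
    M <- length(p)
    covCirc <- Re(stats::fft(p, inverse = TRUE)) / M
    covCirc[seq_len((M + 1L) / 2L)]
}

#' Water-equivalent thickness along a voxel line
#'
#' Sums RSP times voxel size over an inclusive run of voxels along one
#' axis — the discrete WET of that voxel line, as used for proton range
#' checks.  WET line sums are insensitive to the stopping threshold r
#' because smoothing redistributes RSP along the line without changing
#' its integral appreciably.
#'
#' @param volume an [RSPVolume-class].
#' @param start integer(3), first voxel (i, j, k), 1-based.
#' @param axis 1/2/3 or "x"/"y"/"z".
#' @param stopIndex last voxel index along `axis` (inclusive).
#' @return WET in mm.
#' @export
wetLineSum <- function(volume, start, axis, stopIndex) {
    if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
    start <- as.integer(start)
    run <- start[axis]:as.integer(stopIndex)
    idx <- matrix(start, nrow = length(run), ncol = 3L, byrow = TRUE)
    idx[, axis] <- run
    sum(volume@values[idx]) * volume@grid@voxelSize
}
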