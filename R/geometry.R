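#' Chord lengths of a ray through a voxel grid
#'
#' Traces a straight ray through a [VoxelGrid-class] with an incremental
#' Siddon-style traversal and returns the intersection (chord) length
#' with each traversed voxel.  Voxels are half-open boxes, so
#' boundary-grazing intersections of measure zero contribute nothing;
#' chords below 1e-6 mm are dropped.
#'
#' @param point numeric(3), a point on the ray (mm); the trace runs from
#'   this point forward along `direction`.
#' @param direction numeric(3), nonzero direction (need not be unit).
#' @param grid a [VoxelGrid-class].
#' @return data.frame with columns `index` (1-based linear voxel index,
#'   R array order) and `length` (chord, mm); zero rows if the ray
#'   misses the grid.
#' @examples
#' g <- voxelGrid(c(3, 1, 1), voxelSize = 1, origin = c(0, 0, 0))
#' traceChords(c(-1, 0.5, 0.5), c(1, 0, 0), g)  # three 1 mm chords
#' @export
traceChords <- function(point, direction, grid) {
    direction <- as.numeric(direction)
    if (sqrt(sum(direction^2)) == 0)
        stop("ray direction must be nonzero")
    res <- .cpp_trace_ray(as.numeric(point), direction, grid@dim,
                          grid@voxelSize, grid@origin)
    data.frame(index = res$index, length = res$length)
}

#' Build the sparse chord-length system matrix
#'
#' Assembles A, the protons-by-voxels sparse matrix whose entry (p, v)
#' is the chord length (mm) of proton p's recorded straight trajectory
#' through voxel v, together with the per-voxel normalizers used by the
#' solver: the chord sums s_v = sum_p alpha_pv (the diagonal of V), the
#' per-voxel proton counts, their mean Npv over the reconstructable
#' mask, and the mask itself (voxels touched by at least one proton).
#' Protons whose rays miss the grid yield empty rows and are flagged.
#'
#' @param protons a [ProtonList-class].
#' @param grid a [VoxelGrid-class].
#' @param trajectory trajectory model; only "straight" (the recorded
#'   entry-to-exit chord) is implemented.  The argument exists so that a
#'   curved most-likely-path model can be plugged in without changing
#'   the solver.
#' @return A [SystemMatrix-class].
#' @export
buildSystemMatrix <- function(protons, grid, trajectory = "straight") {
    stopifnot(is(protons, "ProtonList"), is(grid, "VoxelGrid"))
    trajectory <- match.arg(trajectory, "straight")
    n <- nProtons(protons)
    if (n == 0L) stop("proton list is empty")
    D <- protons@posOut - protons@posIn
    tr <- .cpp_trace_rays(protons@posIn, D, grid@dim, grid@voxelSize,
                          grid@origin)
    if (length(tr$i) == 0L)
        stop("all protons miss the voxel grid")
    nv <- prod(grid@dim)
    A <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                              dims = c(n, nv))
    counts <- as.integer(diff(A@p))        # protons touching each voxel
    s <- Matrix::colSums(A)
    mask <- counts >= 1L & s > 0
    new("SystemMatrix", A = A, chordSums = as.numeric(s),
        protonCounts = counts, npv = mean(counts[mask]),
        mask = mask, rowLengths = as.numeric(tr$rowLength),
        missed = tr$rowLength == 0, grid = grid)
}

#' SystemMatrix accessors
#' @param sm a [SystemMatrix-class]
#' @return `chordMatrix`: the sparse `dgCMatrix`; `reconMask`: logical
#'   per-voxel mask; `meanProtonsPerVoxel`: scalar Npv.
#' @export
chordMatrix <- function(sm) sm@A

#' @rdname chordMatrix
#' @export
reconMask <- function(sm) sm@mask

#' @rdname chordMatrix
#' @export
meanProtonsPerVoxel <- function(sm) sm@npv
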