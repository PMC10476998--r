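#' Phantom elements
#'
#' Building blocks for [phantomSpec()].  Cylinders are oriented along the
#' y axis (the rotation axis of the acquisition); boxes are axis-aligned.
#' Later elements in a spec override earlier ones where they overlap.
#'
#' @param center numeric(3), element center (mm, object frame).
#' @param diameter cylinder diameter (mm).
#' @param height cylinder height along y (mm).
#' @param size numeric(3), box edge lengths (mm).
#' @param rsp dimensionless relative stopping power of the element.
#' @return A list describing the element, for use in [phantomSpec()].
#' @export
cylinderElement <- function(center = c(0, 0, 0), diameter, height, rsp) {
    stopifnot(diameter > 0, height > 0, rsp >= 0)
    list(shape = "cylinder", center = as.numeric(center),
         diameter = as.numeric(diameter), height = as.numeric(height),
         rsp = as.numeric(rsp))
}

#' @rdname cylinderElement
#' @export
boxElement <- function(center = c(0, 0, 0), size, rsp) {
    stopifnot(all(size > 0), rsp >= 0)
    list(shape = "box", center = as.numeric(center),
         size = as.numeric(size), rsp = as.numeric(rsp))
}

#' Construct a phantom specification
#'
#' @param elements list of elements from [cylinderElement()] /
#'   [boxElement()].
#' @param backgroundRSP RSP outside all elements (default 0, air).
#' @return A [PhantomSpec-class].
#' @examples
#' # a uniform water cylinder, 18 cm diameter, 4 cm high
#' spec <- phantomSpec(list(cylinderElement(diameter = 180, height = 40,
#'                                          rsp = 1.0)))
#' @export
phantomSpec <- function(elements, backgroundRSP = 0) {
    new("PhantomSpec", elements = elements,
        backgroundRSP = as.numeric(backgroundRSP))
}

#' The uniform water cylinder phantom
#'
#' Convenience constructor for the canonical calibration object: a
#' water-equivalent cylinder (RSP 1.0) of 18 cm diameter and 4 cm
#' height, axis along y.
#'
#' @param diameter,height cylinder dimensions in mm.
#' @param rsp cylinder RSP.
#' @return A [PhantomSpec-class].
#' @export
waterCylinderPhantom <- function(diameter = 180, height = 40, rsp = 1.0) {
    phantomSpec(list(cylinderElement(diameter = diameter, height = height,
                                     rsp = rsp)))
}

#' Voxelize a phantom onto a grid
#'
#' Each voxel takes the RSP of the last element whose interior contains
#' the voxel center, or the background RSP if none does.  Elements
#' extending beyond the grid are clipped: the ground truth for any
#' downstream WEPL computation is the voxelized volume itself.
#'
#' @param spec a [PhantomSpec-class]; must contain at least one element
#'   or a positive background.
#' @param grid a [VoxelGrid-class].
#' @return An [RSPVolume-class].
#' @export
makePhantom <- function(spec, grid) {
    stopifnot(is(spec, "PhantomSpec"), is(grid, "VoxelGrid"))
    if (length(spec@elements) == 0L && spec@backgroundRSP == 0)
        message("phantom spec has no elements; returning an all-zero volume")
    cx <- voxelCenters(grid, 1)
    cy <- voxelCenters(grid, 2)
    cz <- voxelCenters(grid, 3)
    vol <- array(spec@backgroundRSP, dim = grid@dim)
    X <- array(cx, dim = grid@dim)
    Y <- array(rep(cy, each = grid@dim[1]), dim = grid@dim)
    Z <- array(rep(cz, each = grid@dim[1] * grid@dim[2]), dim = grid@dim)
    for (el in spec@elements) {
        if (el$shape == "cylinder") {
            inside <- (X - el$center[1])^2 + (Z - el$center[3])^2 <=
                (el$diameter / 2)^2 &
                abs(Y - el$center[2]) <= el$height / 2
        } else {
            inside <- abs(X - el$center[1]) <= el$size[1] / 2 &
                abs(Y - el$center[2]) <= el$size[2] / 2 &
                abs(Z - el$center[3]) <= el$size[3] / 2
        }
        vol[inside] <- el$rsp
    }
    rspVolume(vol, grid)
}

#' Ground-truth WEPL of a ray through an RSP volume
#'
#' The line integral of RSP along a straight ray: the sum over traversed
#' voxels of chord length times voxel RSP.  Returns 0 for rays that miss
#' the grid.
#'
#' @param volume an [RSPVolume-class].
#' @param point numeric(3), a point on the ray (mm); integration runs
#'   from this point forward along `direction`.
#' @param direction numeric(3), nonzero ray direction.
#' @return WEPL in mm.
#' @export
trueWEPL <- function(volume, point, direction) {
    direction <- as.numeric(direction)
    if (sqrt(sum(direction^2)) == 0)
        stop("ray direction must be nonzero")
    g <- volume@grid
    .cpp_line_integrals(matrix(as.numeric(point), 1L, 3L),
                        matrix(direction, 1L, 3L),
                        as.numeric(volume@values),
                        g@dim, g@voxelSize, g@origin)[1L]
}

# vectorized internal variant used by the simulator
.lineIntegrals <- function(volume, P0, D) {
    g <- volume@grid
    .cpp_line_integrals(P0, D, as.numeric(volume@values),
                        g@dim, g@voxelSize, g@origin)
}
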