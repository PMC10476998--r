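.protonColumns <- c("x_in", "y_in", "z_in", "dx_in", "dy_in", "dz_in",
                    "x_out", "y_out", "z_out", "dx_out", "dy_out",
                    "dz_out", "wepl_mm", "angle_deg")

#' Read and write list-mode proton data
#'
#' CSV layout with one row per proton and columns `x_in, y_in, z_in,
#' dx_in, dy_in, dz_in, x_out, y_out, z_out, dx_out, dy_out, dz_out,
#' wepl_mm, angle_deg` (mm and degrees, object-frame coordinates).
#' Values are written at full double precision, so a round trip
#' reproduces the proton list exactly for all practical purposes (>= 15
#' significant digits).
#'
#' @param protons a [ProtonList-class].
#' @param path file path; the format is chosen by extension (`.csv`).
#' @return `readProtonList` returns a [ProtonList-class].
#' @export
writeProtonList <- function(protons, path) {
    if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE))
        stop("HDF5 containers are not supported by this build; use CSV")
    df <- data.table::data.table(
        x_in = protons@posIn[, 1], y_in = protons@posIn[, 2],
        z_in = protons@posIn[, 3],
        dx_in = protons@dirIn[, 1], dy_in = protons@dirIn[, 2],
        dz_in = protons@dirIn[, 3],
        x_out = protons@posOut[, 1], y_out = protons@posOut[, 2],
        z_out = protons@posOut[, 3],
        dx_out = protons@dirOut[, 1], dy_out = protons@dirOut[, 2],
        dz_out = protons@dirOut[, 3],
        wepl_mm = protons@wepl, angle_deg = protons@angleDeg)
    data.table::fwrite(df, path)
    invisible(path)
}

#' @rdname writeProtonList
#' @export
readProtonList <- function(path) {
    if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE))
        stop("HDF5 containers are not supported by this build; use CSV")
    df <- data.table::fread(path)
    missing <- setdiff(.protonColumns, names(df))
    if (length(missing))
        stop("missing column(s): ", paste(missing, collapse = ", "))
    bad <- which(!is.finite(df$wepl_mm))
    if (length(bad))
        stop("non-finite wepl_mm at row(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
    protonList(as.matrix(df[, c("x_in", "y_in", "z_in")]),
               as.matrix(df[, c("x_out", "y_out", "z_out")]),
               df$wepl_mm, df$angle_deg,
               dirIn = as.matrix(df[, c("dx_in", "dy_in", "dz_in")]),
               dirOut = as.matrix(df[, c("dx_out", "dy_out", "dz_out")]))
}

#' Read and write RSP volumes
#'
#' Two formats, chosen by extension: NIfTI (`.nii` / `.nii.gz`, voxel
#' size in the header; stored as 32-bit float) and raw little-endian
#' 32-bit float (any other extension) with a JSON sidecar
#' `<path>.json` holding `{shape, voxel_size_mm, origin_mm}`.  Only
#' isotropic voxels are supported; anisotropic NIfTI headers are
#' rejected.
#'
#' @param volume an [RSPVolume-class].
#' @param path file path.
#' @return `readVolume` returns an [RSPVolume-class].
#' @export
writeVolume <- function(volume, path) {
    if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
        h <- volume@grid@voxelSize
        arr <- volume@values
        RNifti::pixdim(arr) <- c(h, h, h)
        RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
    } else {
        con <- file(path, "wb")
        on.exit(close(con))
        writeBin(as.numeric(volume@values), con, size = 4L,
                 endian = "little")
        jsonlite::write_json(
            list(shape = volume@grid@dim,
                 voxel_size_mm = volume@grid@voxelSize,
                 origin_mm = volume@grid@origin),
            paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
    }
    invisible(path)
}

#' @rdname writeVolume
#' @param origin grid corner (mm) to attach when reading NIfTI (the
#'   NIfTI reader keeps only the voxel size; default centers the grid).
#' @export
readVolume <- function(path, origin = NULL) {
    if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
        img <- RNifti::readNifti(path)
        pd <- RNifti::pixdim(img)[1:3]
        if (diff(range(pd)) > 1e-6 * pd[1])
            stop("anisotropic voxels are not supported (pixdim = ",
                 paste(signif(pd, 6), collapse = " x "), ")")
        d <- dim(img)
        if (is.null(origin)) origin <- -d * pd[1] / 2
        g <- voxelGrid(d, voxelSize = pd[1], origin = origin)
        rspVolume(array(as.numeric(img), dim = d), g)
    } else {
        sidecar <- paste0(path, ".json")
        if (!file.exists(sidecar))
            stop("sidecar not found: ", sidecar)
        meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        shape <- as.integer(meta$shape)
        nv <- prod(shape)
        if (file.info(path)$size != 4 * nv)
            stop("file size (", file.info(path)$size,
                 " bytes) does not match sidecar shape (expected ",
                 4 * nv, ")")
        con <- file(path, "rb")
        on.exit(close(con))
        vals <- readBin(con, "numeric", n = nv, size = 4L,
                        endian = "little")
        g <- voxelGrid(shape, voxelSize = meta$voxel_size_mm,
                       origin = as.numeric(meta$origin_mm))
        rspVolume(array(vals, dim = shape), g)
    }
}
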