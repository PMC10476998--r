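#' Validate a pipeline configuration
#'
#' A run configuration is a named list (or YAML file) with sections
#' `grid`, `phantom`, `simulation`, `stopping`, `analysis` and a
#' top-level `seed`; unknown keys anywhere are rejected.  See
#' [runPipeline()] for the keys of each section.
#'
#' @param config named list or path to a YAML file.
#' @return The validated, completed configuration (invisibly usable by
#'   [runPipeline()]).
#' @export
validateRunConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    .checkKeys(config, c("grid", "phantom", "simulation", "stopping",
                         "analysis", "seed", "output"), "top level")

    grid <- config$grid
    .checkKeys(grid, c("dim", "voxel_size_mm", "origin_mm"), "grid")
    if (is.null(grid$dim) || length(grid$dim) != 3L)
        stop("grid$dim must give three voxel counts")
    g <- voxelGrid(as.integer(grid$dim),
                   voxelSize = grid$voxel_size_mm %||% 1.0,
                   origin = grid$origin_mm %||%
                       (-as.integer(grid$dim) * (grid$voxel_size_mm %||% 1.0) / 2))

    ph <- config$phantom
    if (is.null(ph)) {
        spec <- waterCylinderPhantom()
    } else {
        .checkKeys(ph, c("background_rsp", "elements"), "phantom")
        els <- lapply(ph$elements, function(e) {
            .checkKeys(e, c("shape", "center_mm", "diameter_mm",
                            "height_mm", "size_mm", "rsp"), "phantom element")
            if (e$shape == "cylinder")
                cylinderElement(e$center_mm %||% c(0, 0, 0),
                                e$diameter_mm, e$height_mm, e$rsp)
            else boxElement(e$center_mm %||% c(0, 0, 0), e$size_mm, e$rsp)
        })
        spec <- phantomSpec(els, backgroundRSP = ph$background_rsp %||% 0)
    }

    sim <- config$simulation
    .checkKeys(sim, c("protons_per_angle", "n_angles", "angle_spacing_deg",
                      "wepl_noise_sigma_mm", "tracker_pitch_mm",
                      "beam_extent_mm", "scatter_sigma_mrad"), "simulation")
    if (is.null(sim$protons_per_angle))
        stop("simulation$protons_per_angle is required")
    seed <- config$seed %||% 1L
    simCfg <- simulationConfig(
        protonsPerAngle = sim$protons_per_angle,
        nAngles = sim$n_angles %||% 90L,
        angleSpacing = sim$angle_spacing_deg %||% 4,
        weplNoiseSigma = sim$wepl_noise_sigma_mm %||% 3,
        trackerPitch = sim$tracker_pitch_mm %||% 0.5,
        beamExtent = sim$beam_extent_mm %||% 200,
        scatterSigma = sim$scatter_sigma_mrad %||% 0,
        seed = seed)

    st <- config$stopping
    .checkKeys(st, c("r_stop", "max_iterations", "check_every", "x0"),
               "stopping")
    rStop <- st$r_stop %||% 0.75
    if (length(rStop) == 0L)
        stop("stopping$r_stop must list at least one threshold")
    stopCfg <- stoppingConfig(rStop = as.numeric(rStop),
                              maxIterations = st$max_iterations %||% 1000L,
                              checkEvery = st$check_every %||% 1L,
                              x0Mode = st$x0 %||% "uniform")

    an <- config$analysis
    .checkKeys(an, c("roi_start", "roi_extent", "delta_max"), "analysis")
    roi <- if (is.null(an$roi_extent)) centralROI(g, pmin(gridDim(g), 16L))
           else if (is.null(an$roi_start))
               centralROI(g, as.integer(an$roi_extent))
           else roiSpec(as.integer(an$roi_start), as.integer(an$roi_extent))

    list(grid = g, phantom = spec, simulation = simCfg,
         stopping = stopCfg, roi = roi,
         deltaMax = an$delta_max %||% 10L, seed = seed,
         output = config$output)
}

.checkKeys <- function(x, allowed, where) {
    if (is.null(x)) return(invisible())
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
        stop("unknown key(s) in ", where, ": ",
             paste(unknown, collapse = ", "))
    invisible()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulate - reconstruct - analyze pipeline
#'
#' Voxelizes the configured phantom, simulates a list-mode acquisition,
#' reconstructs with the r stopping rule (snapshotting every requested
#' threshold in a single solver run), and analyzes each snapshot: ROI
#' mean/variance, per-axis autocorrelation, NPS, a central WET line sum
#' along +z, and the iteration count at which the threshold was
#' reached.
#'
#' @param config a named list or YAML path (see [validateRunConfig()]).
#' @param reportPath optional path for a JSON report.
#' @param verbose log progress.
#' @return The report as a list: one entry per stopping threshold plus
#'   a `config` echo.
#' @export
runPipeline <- function(config, reportPath = NULL, verbose = FALSE) {
    cfg <- validateRunConfig(config)
    if (verbose) message("stage: phantom")
    truth <- makePhantom(cfg$phantom, cfg$grid)
    if (verbose) message("stage: simulate")
    protons <- simulateProtons(truth, cfg$simulation)
    if (verbose) message("stage: reconstruct")
    recon <- reconstruct(protons, cfg$grid, stop = cfg$stopping,
                         verbose = verbose)
    if (verbose) message("stage: analyze")

    hist <- reconHistory(recon)
    d <- gridDim(cfg$grid)
    center <- as.integer(ceiling(d / 2))
    perR <- lapply(sort(cfg$stopping@rStop, decreasing = TRUE),
                   function(rs) {
        vol <- reconSnapshot(recon, rs)
        st <- roiStats(vol, cfg$roi)
        ac <- voxelAutocorrelation(vol, cfg$roi, cfg$deltaMax)
        wet <- wetLineSum(vol, c(center[1], center[2], 1L), 3L, d[3])
        iters <- min(hist$iteration[hist$r <= rs])
        list(r_stop = rs, iterations = iters, roi_mean = st$mean,
             roi_sd = sqrt(st$variance),
             rho_x = rhoCurve(ac, "x"), rho_y = rhoCurve(ac, "y"),
             rho_z = rhoCurve(ac, "z"), wet_central_mm = wet)
    })
    names(perR) <- vapply(sort(cfg$stopping@rStop, decreasing = TRUE),
                          format, character(1))

    report <- list(
        seed = cfg$seed,
        config = list(
            grid = list(dim = gridDim(cfg$grid),
                        voxel_size_mm = voxelSize(cfg$grid)),
            protons_per_angle = cfg$simulation@protonsPerAngle,
            n_angles = cfg$simulation@nAngles,
            wepl_noise_sigma_mm = cfg$simulation@weplNoiseSigma,
            r_stop = cfg$stopping@rStop),
        results = perR)
    if (!is.null(reportPath))
        jsonlite::write_json(report, reportPath, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    invisible(report)
}
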