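#' Simulate a list-mode proton acquisition
#'
#' Generates synthetic list-mode proton data through an RSP volume at
#' simplified physics.  For each projection angle the object is rotated
#' about the +y (vertical) axis; equivalently, rays travelling along +z
#' in the gantry frame are rotated into the fixed object frame.  Each
#' proton samples a lateral position uniformly over the beam extent; its
#' ground-truth WEPL is the exact line integral of RSP along the
#' unperturbed ray, and the measured WEPL adds a single Gaussian noise
#' term absorbing range straggling and detector resolution.  Recorded
#' entry/exit positions are taken on tracker planes bracketing the
#' object and quantized to the tracker pitch, so trajectory uncertainty
#' enters through the mismatch between the recorded chord and the true
#' ray, as in a physical tracker.  An optional small-angle kink at the
#' object mid-plane emulates multiple Coulomb scattering.
#'
#' The RNG uses one child stream per angle derived from the master seed,
#' so changing the number of angles does not reshuffle the protons of
#' the remaining angles, and identical seeds give bit-identical output.
#'
#' @param volume ground-truth [RSPVolume-class].
#' @param cfg a [SimulationConfig-class].
#' @return A [ProtonList-class]; `meta` echoes the configuration and
#'   carries the per-proton ground-truth WEPL under `trueWEPL`.
#' @examples
#' grid <- voxelGrid(c(32, 4, 32), voxelSize = 4)
#' vol <- makePhantom(waterCylinderPhantom(), grid)
#' cfg <- simulationConfig(protonsPerAngle = 50, nAngles = 10,
#'                         angleSpacing = 36, beamExtent = c(180, 16),
#'                         seed = 7)
#' pl <- simulateProtons(vol, cfg)
#' @export
simulateProtons <- function(volume, cfg) {
    stopifnot(is(volume, "RSPVolume"), is(cfg, "SimulationConfig"))
    g <- volume@grid
    ext <- gridExtent(g)
    halfDiag <- sqrt(sum(((ext[, 2] - ext[, 1]) / 2)^2))
    zPlane <- max(150, halfDiag + 10)   # tracker planes at gantry z = +/- zPlane

    ex <- cfg@beamExtent[1]
    ey <- if (length(cfg@beamExtent) == 2L) cfg@beamExtent[2] else ex
    n <- cfg@protonsPerAngle
    na <- cfg@nAngles

    posIn <- posOut <- matrix(0, n * na, 3L)
    wepl <- numeric(n * na)
    weplTrue <- numeric(n * na)
    angleDeg <- numeric(n * na)

    for (a in seq_len(na) - 1L) {
        set.seed(.angleSeed(cfg@seed, a))
        theta <- a * cfg@angleSpacing * pi / 180
        ux <- stats::runif(n, -ex / 2, ex / 2)   # position at isocenter
        uy <- stats::runif(n, -ey / 2, ey / 2)

        # pencil-beam divergence: rays fan out from the focal points of
        # the scanning magnets (slope = isocenter offset / focal length)
        sx <- ux / cfg@focalLength[1]
        sy <- uy / cfg@focalLength[2]

        # true (unperturbed, unquantized) ray in the gantry frame
        pInG <- cbind(ux - sx * zPlane, uy - sy * zPlane, -zPlane)
        dG <- cbind(sx, sy, 1)

        # recorded exit position: straight, plus an optional direction
        # kink at the object mid-plane (gantry z = 0)
        exitX <- ux + sx * zPlane
        exitY <- uy + sy * zPlane
        if (cfg@scatterSigma > 0) {
            kx <- stats::rnorm(n, 0, cfg@scatterSigma * 1e-3)
            ky <- stats::rnorm(n, 0, cfg@scatterSigma * 1e-3)
            exitX <- exitX + tan(kx) * zPlane
            exitY <- exitY + tan(ky) * zPlane
        }
        pOutG <- cbind(exitX, exitY, zPlane)

        if (cfg@trackerPitch > 0) {
            q <- function(v) round(v / cfg@trackerPitch) * cfg@trackerPitch
            pInRecG <- cbind(q(pInG[, 1]), q(pInG[, 2]), pInG[, 3])
            pOutRecG <- cbind(q(pOutG[, 1]), q(pOutG[, 2]), pOutG[, 3])
        } else {
            pInRecG <- pInG
            pOutRecG <- pOutG
        }

        # rotate gantry-frame points/directions into the fixed object frame
        R <- .rotY(-theta)
        idx <- a * n + seq_len(n)
        posIn[idx, ] <- pInRecG %*% t(R)
        posOut[idx, ] <- pOutRecG %*% t(R)
        wt <- .lineIntegrals(volume, pInG %*% t(R), dG %*% t(R))
        weplTrue[idx] <- wt
        wepl[idx] <- wt + if (cfg@weplNoiseSigma > 0)
            stats::rnorm(n, 0, cfg@weplNoiseSigma) else 0
        angleDeg[idx] <- a * cfg@angleSpacing
    }

    protonList(posIn, posOut, wepl, angleDeg,
               meta = list(config = cfg, seed = cfg@seed,
                           trueWEPL = weplTrue, trackerPlane = zPlane))
}

# child seed per angle, decoupled from the number of angles
.angleSeed <- function(seed, angle) {
    as.integer((as.double(seed) * 7919 + as.double(angle) * 1000003 + 1) %%
                   2147483647)
}

# rotation about +y by phi (radians)
.rotY <- function(phi) {
    c <- cos(phi); s <- sin(phi)
    matrix(c(c, 0, s,
             0, 1, 0,
             -s, 0, c), 3L, 3L, byrow = TRUE)
}

#' Randomly reassign protons to rotation angles
#'
#' For a rotationally symmetric phantom, protons simulated at one (or a
#' few) directions can be reassigned randomly to any set of rotation
#' angles without repeating the simulation: each proton's recorded
#' trajectory is rotated about +y from its original angle to the newly
#' assigned one, while its measured WEPL is kept.  This is the standard
#' shortcut for studying how the number of angles and protons per angle
#' affect image noise at a fixed total proton count; it is only valid
#' when the imaged object is invariant under the rotations involved.
#'
#' @param protons a [ProtonList-class].
#' @param nAngles number of target angles.
#' @param angleSpacing degrees between target angles.
#' @param seed RNG seed for the random assignment.
#' @return A [ProtonList-class] with reassigned angles and rotated
#'   trajectories.
#' @export
reassignAngles <- function(protons, nAngles, angleSpacing, seed = 1L) {
    n <- nProtons(protons)
    set.seed(as.integer(seed))
    k <- sample.int(nAngles, n, replace = TRUE) - 1L
    thetaNew <- k * angleSpacing
    dTheta <- (thetaNew - protons@angleDeg) * pi / 180
    rot <- function(M) {
        c1 <- cos(dTheta); s1 <- sin(dTheta)
        # per-row rotation about +y by -dTheta (object-frame convention)
        cbind(c1 * M[, 1] - s1 * M[, 3], M[, 2],
              s1 * M[, 1] + c1 * M[, 3])
    }
    protonList(rot(protons@posIn), rot(protons@posOut),
               protons@wepl, thetaNew,
               dirIn = rot(protons@dirIn), dirOut = rot(protons@dirOut),
               meta = c(protons@meta, list(reassigned = TRUE)))
}
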