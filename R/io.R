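# File formats: multi-page TIFF for movies, an RDS container for
# calibration maps (with CSV summary export), CSV for localization tables.

#' Read a camera movie from a multi-page TIFF
#'
#' 16-bit unsigned stacks are read as raw integer ADU counts.  Float
#' stacks are assumed to follow this package's storage convention
#' (\code{\link{writeMovie}}): samples are ADU divided by 65536, so they
#' are rescaled by 65536 on read.
#'
#' @param path TIFF file path.
#' @param pixelSizeNm pixel size metadata to attach.
#' @return a \linkS4class{CameraMovie}.
#' @export
readMovie <- function(path, pixelSizeNm = 100) {
    if (!file.exists(path)) stop("no such file: ", path)
    meta <- tiff::readTIFF(path, payload = FALSE)
    if (is.list(meta) && !is.data.frame(meta)) meta <- meta[[1]]
    isFloat <- isTRUE(meta$bits.per.sample[1] == 32)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = !isFloat)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    for (i in seq_along(pages))
        if (!identical(dim(pages[[i]]), d))
            stop("inconsistent frame dimensions at frame ", i)
    vals <- unlist(pages)
    if (isFloat) vals <- vals * 65536           # float storage convention
    CameraMovie(array(as.numeric(vals), c(d, length(pages))),
                pixelSizeNm = pixelSizeNm)
}

#' Write a camera movie to a multi-page TIFF
#'
#' \code{format = "float"} stores 32-bit float samples holding ADU / 65536
#' (an exact power-of-two scaling into the TIFF writer's unit range, so
#' real-valued ADU in [0, 65536) round-trip losslessly at float32
#' precision); \code{format = "uint16"} rounds and clamps to 0..65535.
#'
#' @param movie a \linkS4class{CameraMovie}.
#' @param path output path.
#' @param format \code{"float"} or \code{"uint16"}.
#' @return the path, invisibly.
#' @export
writeMovie <- function(movie, path, format = c("float", "uint16")) {
    format <- match.arg(format)
    fr <- lapply(seq_len(nFrames(movie)), function(i) movie@frames[, , i])
    if (format == "uint16") {
        fr <- lapply(fr, function(m) pmin(pmax(round(m), 0), 65535) / 65535)
        tiff::writeTIFF(fr, path, bits.per.sample = 16L)
    } else {
        if (max(vapply(fr, max, 0)) >= 65536 ||
            min(vapply(fr, min, 0)) < 0)
            stop("float storage supports ADU in [0, 65536)")
        tiff::writeTIFF(lapply(fr, function(m) m / 65536), path,
                        bits.per.sample = 32L)
    }
    invisible(path)
}

CALIB_FORMAT_VERSION <- 1L

#' Write / read a calibration container
#'
#' The container is a single RDS file holding the per-pixel maps
#' (\code{offset}, \code{variance}, \code{gain}, \code{rqe},
#' \code{intercept}), scalar attributes (\code{meanGain}, summary
#' statistics) and a format version tag.
#'
#' @param calib a \linkS4class{CalibrationMap}.
#' @param path file path (conventionally \code{.rds}).
#' @return \code{writeCalibration}: the path, invisibly;
#'   \code{readCalibration}: a \linkS4class{CalibrationMap}.
#' @export
writeCalibration <- function(calib, path) {
    stopifnot(is(calib, "CalibrationMap"))
    saveRDS(list(format = "sCMOSrqe-calibration",
                 version = CALIB_FORMAT_VERSION,
                 offset = calib@offset, variance = calib@variance,
                 gain = calib@gain, rqe = calib@rqe,
                 intercept = calib@intercept,
                 meanGain = calib@meanGain, stats = calib@stats), path)
    invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    x <- readRDS(path)
    if (!is.list(x) || !identical(x$format, "sCMOSrqe-calibration"))
        stop("not a calibration container: ", path)
    for (f in c("offset", "variance", "gain", "rqe"))
        if (is.null(x[[f]]))
            stop("calibration container is missing dataset '", f, "'")
    if (is.null(x$meanGain)) {
        warning("container has no meanGain attribute; ",
                "recomputed from the gain map")
        x$meanGain <- mean(x$gain)
    }
    CalibrationMap(x$offset, x$variance, x$gain, x$rqe,
                   intercept = x$intercept,
                   stats = if (is.null(x$stats)) list() else x$stats)
}

#' Export calibration summary statistics as CSV
#'
#' @param calib a \linkS4class{CalibrationMap}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
exportCalibrationSummary <- function(calib, path) {
    df <- data.frame(
        statistic = c("mean_offset", "mean_variance", "mean_gain",
                      "std_gain", "std_rqe", "gain_rqe_correlation"),
        value = c(mean(calib@offset), mean(calib@variance),
                  calib@meanGain, sd(calib@gain), sd(calib@rqe),
                  cor(as.vector(calib@gain), as.vector(calib@rqe))))
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Run the simulate-identify-fit-report pipeline
#'
#' End-to-end driver over the package's stages on a synthetic or provided
#' calibration.  The resolved configuration (including the seed and
#' package version) is written as YAML next to the outputs, so a run can
#' be reproduced bit-exactly from its output directory.
#'
#' @param config list with entries \code{outDir}, \code{seed},
#'   \code{mode} ("blinking-uniform" or "constant-grid"),
#'   \code{preprocess} ("none" or "rqe"), \code{estimator} ("mle",
#'   "mle-rqe" or "wls"), \code{threshold}, \code{frameShape},
#'   \code{calibPath} (optional; a synthetic calibration is generated when
#'   absent) and any \code{\link{simulationConfig}} fields.
#' @return list with the calibration, candidate and localization tables,
#'   the counts-vs-RQE report, and the output paths; all also on disk.
#' @export
runPipeline <- function(config) {
    defaults <- list(outDir = "pipeline-out", seed = 1,
                     mode = "blinking-uniform", preprocess = "none",
                     estimator = "mle", threshold = 4,
                     frameShape = c(64, 64), calibPath = NULL)
    config <- utils::modifyList(defaults, config)
    simFields <- intersect(names(config),
                           names(formals(simulationConfig)))
    simCfg <- do.call(simulationConfig, config[simFields])
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outDir, f)

    calib <- if (!is.null(config$calibPath)) readCalibration(config$calibPath)
             else synthCalibration(config$frameShape,
                                   seed = config$seed + 101L)
    writeCalibration(calib, out("calibration.rds"))
    exportCalibrationSummary(calib, out("calibration_summary.csv"))

    sim <- simulateMovie(calib, config$mode, simCfg,
                         seed = config$seed + 202L)
    writeMovie(sim$movie, out("movie.tif"))

    cands <- identifyMovie(sim$movie, calib, config$preprocess,
                           simCfg$psfSigmaPx, config$threshold)
    write.csv(cands, out("candidates.csv"), row.names = FALSE)

    locs <- batchFit(sim$movie, calib, cands, config$estimator,
                     simCfg$psfSigmaPx)
    write.csv(locs, out("localizations.csv"), row.names = FALSE)

    report <- countsVsRQE(locs, calib, simCfg$psfSigmaPx)
    resolved <- config
    resolved$simulation <- unclass(simCfg)
    resolved$packageVersion <- as.character(packageVersion("sCMOSrqe"))
    resolved$nLocalizations <- nrow(locs)
    resolved$convergenceRate <- attr(locs, "convergenceRate")
    resolved$countsRqePearsonR <- report$pearsonR
    yaml::write_yaml(resolved[!vapply(resolved, is.matrix, TRUE)],
                     out("run_config.yaml"))
    list(calibration = calib, candidates = cands, localizations = locs,
         countsReport = report, outDir = config$outDir)
}
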