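## File formats: 16-bit multi-page TIFF movies, ThunderSTORM-compatible
## localization CSVs, YAML experiment configs and JSON metadata sidecars.

#' Write a movie stack as 16-bit multi-page TIFF
#'
#' ADU values are rounded and clipped to the 16-bit camera range.
#'
#' @param stack fov x fov x frames array (ADU).
#' @param path output file.
#' @export
writeMovieTiff <- function(stack, path) {
  if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]), function(t) {
    m <- round(stack[, , t])
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file written by [writeMovieTiff()].
#' @return fov x fov x frames array in ADU.
#' @export
readMovieTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  round(simplify2array(pages) * 65535)
}

#' Write JSON metadata sidecar
#'
#' @param x a list of metadata.
#' @param path output file.
#' @export
writeMetadataJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read JSON metadata sidecar
#'
#' @param path JSON file.
#' @return a list.
#' @export
readMetadataJson <- function(path) jsonlite::read_json(path,
                                                       simplifyVector = TRUE)

tsColumns <- c(frame = "frame", x_nm = "x [nm]", y_nm = "y [nm]",
               sigma_nm = "sigma [nm]", intensity_photon = "intensity [photon]",
               offset_photon = "offset [photon]",
               uncertainty_nm = "uncertainty [nm]")

#' Write a localization table (ThunderSTORM-compatible CSV)
#'
#' @param table localization table from [localizeFrames()].
#' @param path output CSV.
#' @export
writeLocalizations <- function(table, path) {
  out <- table[, names(tsColumns)]
  names(out) <- unname(tsColumns)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a localization CSV
#'
#' @param path CSV written by [writeLocalizations()] (or ThunderSTORM).
#' @return localization table with the package's column names.
#' @export
readLocalizations <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  idx <- match(unname(tsColumns), names(raw))
  if (anyNA(idx)) stop("unrecognized localization CSV columns in ", path)
  out <- raw[, idx]
  names(out) <- names(tsColumns)
  out
}

#' Read an experiment configuration from YAML
#'
#' A single YAML file drives the pipeline. Recognized keys (all optional
#' except \code{designs}): \code{designs} (labels in bMN(/n) nomenclature),
#' \code{dyesPerDesign}, \code{sigmaTruth} (deg), \code{ddiFrames},
#' \code{paintFrames}, \code{defocus} (nm), \code{seed}, and scalar
#' overrides under \code{optics}, \code{camera}, \code{kinetics}.
#'
#' @param path YAML file.
#' @return a validated config list with defaults filled in.
#' @export
readExperimentConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  normalizeExperimentConfig(cfg)
}

#' Fill defaults into an experiment config list
#'
#' @param cfg a (possibly partial) config list.
#' @return config list with all defaults filled in and sub-configs built.
#' @export
normalizeExperimentConfig <- function(cfg) {
  if (is.null(cfg$designs) || length(cfg$designs) == 0L)
    stop("config must list at least one design")
  defaults <- list(dyesPerDesign = 4L, sigmaTruth = 4.5, ddiFrames = 60L,
                   paintFrames = 1000L, defocus = 550, seed = 1L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg[["opticsObj"]]))
    cfg$opticsObj <- do.call(opticsConfig, as.list(cfg[["optics"]]))
  if (is.null(cfg[["cameraObj"]]))
    cfg$cameraObj <- do.call(cameraModel, as.list(cfg[["camera"]]))
  if (is.null(cfg[["kineticsObj"]]))
    cfg$kineticsObj <- do.call(kineticsParams, as.list(cfg[["kinetics"]]))
  if (is.null(cfg[["designObjs"]]))
    cfg$designObjs <- lapply(cfg$designs, parseDesign)
  cfg
}
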