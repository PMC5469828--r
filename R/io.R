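#' Read an image volume from a multi-page TIFF stack
#'
#' Pages are stacked along z (axis 1). Voxel size (µm) is taken from the
#' JSON sidecar written by [write_volume()] (`<path>.json`), else from
#' `voxel_size_override`, else reading fails. Intensities are returned as
#' non-negative floats on their original scale (the sidecar records the
#' normalization used for TIFF storage).
#'
#' @param path TIFF file path.
#' @param voxel_size_override voxel size (µm, scalar or `(z, y, x)`) used
#'   when no sidecar metadata is present.
#' @param modality overrides the sidecar modality tag.
#' @return An [lcn_volume()].
#' @export
read_volume <- function(path, voxel_size_override = NULL, modality = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("not a readable TIFF: ", path))
  if (!is.list(pages)) pages <- list(pages)
  a <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (i in seq_along(pages)) a[i, , ] <- pages[[i]]
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  scale <- meta$scale %||% 1
  a <- a * scale
  vs <- meta$voxel_size_um %||% voxel_size_override
  if (is.null(vs))
    stop("no voxel size metadata for ", path,
         " and no voxel_size_override given")
  lcn_volume(a, vs, modality %||% meta$modality %||% "THG")
}

#' Write an image volume as a multi-page TIFF with a JSON sidecar
#'
#' Integer data up to 65535 is stored losslessly as 16-bit; other data is
#' normalized by its maximum and stored as 32-bit float (exact to float32
#' precision). The sidecar `<path>.json` records voxel size (µm), modality
#' and the intensity scale.
#'
#' @param vol an [lcn_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "lcn_volume"))
  a <- vol$data
  mx <- max(a)
  integerish <- mx <= 65535 && all(a == round(a))
  if (integerish) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- if (mx > 0) mx else 1
    bits <- 32L
  }
  pages <- lapply(seq_len(dim(a)[1]), function(i) a[i, , ] / scale)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = bits))
  jsonlite::write_json(list(voxel_size_um = as.numeric(vol$voxel_size_um),
                            modality = vol$modality, scale = scale,
                            axes = "zyx", units = "micron"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# 8-bit {0, 255} mask TIFF (sidecar records voxel size)
write_mask <- function(mask, voxel_size_um, path) {
  d <- dim(mask)
  pages <- lapply(seq_len(d[1]), function(i) (mask[i, , ] != 0) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(list(voxel_size_um = as.numeric(rep_len(voxel_size_um, 3)),
                            modality = "mask", scale = 255, axes = "zyx",
                            units = "micron"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- array(FALSE, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (i in seq_along(pages)) a[i, , ] <- pages[[i]] > 0.5
  a
}

# skeleton chains as a flat edge-list table (µm coordinates)
skeleton_table <- function(skeleton) {
  if (!length(skeleton$chains))
    return(data.frame(chain = integer(), point = integer(),
                      z_um = numeric(), y_um = numeric(), x_um = numeric()))
  do.call(rbind, lapply(seq_along(skeleton$chains), function(ci) {
    ch <- skeleton$chains[[ci]]
    data.frame(chain = ci, point = seq_len(nrow(ch)),
               z_um = ch[, 1], y_um = ch[, 2], x_um = ch[, 3])
  }))
}

diameter_table <- function(diameters) {
  if (is.null(diameters) || !length(diameters$measurements))
    return(data.frame(z_um = numeric(), y_um = numeric(), x_um = numeric(),
                      dir_z = numeric(), dir_y = numeric(), dir_x = numeric(),
                      method = character(), diameter_um = numeric()))
  do.call(rbind, lapply(diameters$measurements, function(m) {
    dirv <- m$direction %||% c(NA, NA, NA)
    data.frame(z_um = m$position_um[1], y_um = m$position_um[2],
               x_um = m$position_um[3], dir_z = dirv[1], dir_y = dirv[2],
               dir_x = dirv[3], method = m$method,
               diameter_um = m$diameter_um)
  }))
}

#' Write analysis outputs to a directory
#'
#' Masks and label maps as 8-bit TIFF stacks (values 0/255), the skeleton
#' as both a TIFF stack and an edge-list text table, diameter measurements
#' as CSV, and the report as JSON plus a human-readable text summary.
#'
#' @param report an `lcn_report` from [run_pipeline()].
#' @param masks named list of logical arrays (may be empty).
#' @param skeleton an `lcn_skeleton` (or `NULL`).
#' @param outdir output directory (created if missing).
#' @param voxel_size_um voxel size for the mask sidecars.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(report, masks = list(), skeleton = NULL,
                          outdir, voxel_size_um = report$provenance$voxel_size_um %||% 0.2) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  if (file.access(outdir, 2) != 0) stop("output directory not writable: ", outdir)
  files <- character()
  for (nm in names(masks)) {
    f <- file.path(outdir, paste0(nm, ".tif"))
    write_mask(masks[[nm]], voxel_size_um, f)
    files <- c(files, f)
  }
  if (!is.null(skeleton)) {
    f <- file.path(outdir, "skeleton.tif")
    write_mask(skeleton$mask, skeleton$spacing_um, f)
    ft <- file.path(outdir, "skeleton_chains.csv")
    write.csv(skeleton_table(skeleton), ft, row.names = FALSE)
    files <- c(files, f, ft)
  }
  if (!is.null(report$diameters)) {
    f <- file.path(outdir, "diameters.csv")
    write.csv(diameter_table(report$diameters), f, row.names = FALSE)
    files <- c(files, f)
  }
  fj <- file.path(outdir, "report.json")
  jsonlite::write_json(report_to_list(report), fj, auto_unbox = TRUE,
                       digits = NA, null = "null")
  ftxt <- file.path(outdir, "report.txt")
  writeLines(utils::capture.output(print(report)), ftxt)
  invisible(c(files, fj, ftxt))
}

# serializable view of a report (numbers, strings, tables; no arrays)
report_to_list <- function(report) {
  keep <- report[setdiff(names(report), "diameters")]
  if (!is.null(report$diameters)) {
    d <- report$diameters
    keep$diameters <- list(diameter_mean_um = d$diameter_mean_um,
                           diameter_sd_um = d$diameter_sd_um,
                           n_measurements = d$n_measurements,
                           fallback_fraction = d$fallback_fraction,
                           undefined_fraction = d$undefined_fraction,
                           n_samples = d$n_samples, seed = d$seed)
  }
  keep
}

#' Reload a report written by [write_outputs()]
#'
#' @param path path to `report.json`.
#' @return The report as a plain list (class `lcn_report`).
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rep) <- "lcn_report"
  rep
}
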