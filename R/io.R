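#' Dynamic series container
#'
#' @param data 4D numeric array `(x, y, z, frame)`, nonnegative.
#' @param frame_times frame-centre times, seconds, matching the 4th
#'   dimension.
#' @param voxel_dims voxel dimensions, micrometres (length 3).
#' @return an object of class `dce_series`.
#' @export
dce_series <- function(data, frame_times, voxel_dims = c(150, 150, 625)) {
  if (length(dim(data)) != 4L) stop_invalid("'data' must be a 4D array")
  if (dim(data)[4] != length(frame_times))
    stop_invalid("frame dimension (%d) != length(frame_times) (%d)",
                 dim(data)[4], length(frame_times))
  if (min(data) < 0) stop_invalid("intensities must be nonnegative")
  structure(list(data = data, frame_times = as.numeric(frame_times),
                 voxel_dims = as.numeric(voxel_dims)),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  cat(sprintf("dce_series: %s x %d frames, voxel %s um\n",
              paste(dim(x$data)[1:3], collapse = " x "), dim(x$data)[4],
              paste(x$voxel_dims, collapse = " x ")))
  invisible(x)
}

#' Write / read a 4D DCE series as NIfTI with a JSON sidecar
#'
#' The array is stored as NIfTI (voxel dimensions in the header, in mm);
#' the frame times travel in a JSON sidecar `<path>.json` because the NIfTI
#' time axis cannot hold a non-uniform schedule faithfully. Round-trips
#' preserve the array bit-exactly.
#'
#' @param series a [dce_series()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_dce_series`: the path, invisibly. `read_dce_series`: a
#'   [dce_series()].
#' @export
write_dce_series <- function(series, path) {
  stopifnot(inherits(series, "dce_series"))
  img <- RNifti::asNifti(series$data,
                         pixdim = c(series$voxel_dims / 1000, 1))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(frame_times = series$frame_times, voxel_dims_um = series$voxel_dims),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_dce_series
#' @param path input path.
#' @param frame_times optional override; when `NULL` the sidecar
#'   `<path>.json` must exist.
#' @export
read_dce_series <- function(path, frame_times = NULL) {
  if (!file.exists(path)) stop_invalid("file '%s' not found", path)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  if (length(dim(a)) != 4L)
    stop_invalid("'%s' is %dD; a 4D dynamic series is required",
                 path, length(dim(a)))
  vd <- c(150, 150, 625)
  side <- paste0(path, ".json")
  if (is.null(frame_times)) {
    if (!file.exists(side))
      stop_invalid("no frame times: sidecar '%s' missing", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    frame_times <- as.numeric(meta$frame_times)
    if (!is.null(meta$voxel_dims_um)) vd <- as.numeric(meta$voxel_dims_um)
  } else if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$voxel_dims_um)) vd <- as.numeric(meta$voxel_dims_um)
  }
  dce_series(a, frame_times, vd)
}

#' Write / read a 3D volume (mask or parametric map) as NIfTI
#'
#' @param vol 3D numeric array.
#' @param path `.nii` / `.nii.gz` path.
#' @return the path (write) or the array (read).
#' @export
write_volume <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_invalid("file '%s' not found", path)
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Mean signal-intensity curve of a labelled region
#'
#' Arithmetic mean of the series over all voxels carrying `label`, per
#' frame — the ROI curve used for whole-placenta kinetics.
#'
#' @param series a [dce_series()] or 4D array.
#' @param rois integer label volume matching the spatial dimensions.
#' @param label label to average over.
#' @param csv optional path; when given, a CSV with columns
#'   `frame`, `time_s`, `mean_SI` is written.
#' @param frame_times required when `series` is a bare array.
#' @return a [signal_curve()].
#' @export
roi_mean_curve <- function(series, rois, label, csv = NULL,
                           frame_times = NULL) {
  if (inherits(series, "dce_series")) {
    arr <- series$data; ft <- series$frame_times
  } else {
    arr <- series; ft <- frame_times
    if (is.null(ft)) stop_invalid("'frame_times' required with a bare array")
  }
  if (!all(dim(rois) == dim(arr)[1:3]))
    stop_invalid("ROI volume does not match the series spatially")
  sel <- which(rois == label)
  if (!length(sel)) stop_invalid("label %s selects no voxels", format(label))
  flat <- matrix(arr, prod(dim(arr)[1:3]), dim(arr)[4])
  curve <- signal_curve(colMeans(flat[sel, , drop = FALSE]), ft)
  if (!is.null(csv)) {
    write.csv(data.frame(frame = seq_along(ft), time_s = ft,
                         mean_SI = curve$values),
              csv, row.names = FALSE)
  }
  curve
}

#' Write a fluorescence channel pair as TIFF
#'
#' 16-bit grayscale, one file per channel; intensities are stored as
#' `value / 65535` so integer inputs round-trip exactly.
#'
#' @param green,blue integer intensity matrices.
#' @param path_green,path_blue output paths.
#' @return invisibly the two paths.
#' @export
write_fluorescence_tiff <- function(green, blue, path_green, path_blue) {
  tiff::writeTIFF(green / 65535, path_green, bits.per.sample = 16L)
  tiff::writeTIFF(blue / 65535, path_blue, bits.per.sample = 16L)
  invisible(c(path_green, path_blue))
}

#' @rdname write_fluorescence_tiff
#' @param path a TIFF path.
#' @return `read_fluorescence_tiff`: integer intensity matrix.
#' @export
read_fluorescence_tiff <- function(path) {
  if (!file.exists(path)) stop_invalid("file '%s' not found", path)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  out <- round(m * 65535)
  storage.mode(out) <- "integer"
  out
}

#' Write a JSON provenance record next to an output file
#'
#' Records the input paths, a hash of the configuration, the package
#' version and the seed (no timestamp, so repeated runs stay
#' byte-identical).
#'
#' @param path output file whose provenance is recorded (written to
#'   `<path>.prov.json`).
#' @param inputs character vector of input paths/identifiers.
#' @param config list of configuration values.
#' @param seed integer seed used, or `NA`.
#' @return invisibly the provenance path.
#' @export
write_provenance <- function(path, inputs = character(), config = list(),
                             seed = NA_integer_) {
  tmp <- tempfile()
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  out <- paste0(path, ".prov.json")
  jsonlite::write_json(
    list(output = basename(path), inputs = inputs, config_md5 = hash,
         package = "placentaDCE",
         version = as.character(utils::packageVersion("placentaDCE")),
         seed = seed),
    out, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Export the maps of a fitted model as NIfTI volumes and a ROI CSV
#'
#' Writes one NIfTI per parametric map (plus scale and residual), the two
#' phase maps as integer volumes, T2* phase maps in milliseconds, and an
#' optional per-ROI summary CSV.
#'
#' @param fit a `dce_fit`.
#' @param dir output directory (created if needed).
#' @param rois optional integer label volume for the ROI summary.
#' @param prefix file-name prefix (default `"map"`).
#' @return invisibly the vector of written paths.
#' @export
write_fit_maps <- function(fit, dir, rois = NULL, prefix = "map") {
  stopifnot(inherits(fit, "dce_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(fit$maps)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    write_volume(fit$maps[[nm]], p)
    paths <- c(paths, p)
  }
  for (nm in grep("^r2agg", names(fit$maps), value = TRUE)) {
    t2 <- 1000 / fit$maps[[nm]]
    t2[!is.finite(t2)] <- NA_real_
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix,
                                sub("r2agg", "t2star_ms", nm)))
    write_volume(t2, p)
    paths <- c(paths, p)
  }
  for (nm in c("t_formation", "t_clearance")) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    write_volume(fit$phase_maps[[nm]], p)
    paths <- c(paths, p)
  }
  if (!is.null(rois)) {
    p <- file.path(dir, sprintf("%s_roi_summary.csv", prefix))
    write.csv(roi_summary(fit, rois), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
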