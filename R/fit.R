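#' Fit the three-compartment aggregation model to a dynamic series
#'
#' The central estimator of the package. Every masked voxel's time-course is
#' matched, by exhaustive search, against a dictionary of forward-simulated
#' curves; the entry minimising the L2 distance (after closed-form
#' amplitude fitting) supplies the voxel's six parameters. Voxels are
#' grouped by their `(t_formation, t_clearance)` phase pair and one
#' dictionary is built and cached per distinct pair; voxels whose phase
#' detection returned the never-formed sentinel are fitted against a
#' no-aggregation dictionary (aggregate rate grids collapsed to zero).
#'
#' @param series 4D numeric array `(x, y, z, frame)` or `dce_series`.
#' @param mask spatial mask of voxels to fit (`> 0` = fit).
#' @param phase_maps a [phase_maps_volume()] result (or list with integer
#'   arrays `t_formation`, `t_clearance`). When `NULL`, phases are detected
#'   from the series with default settings.
#' @param grid a [parameter_grid()]; default the `"coarse"` preset.
#' @param protocol an [acquisition_protocol()].
#' @param rel a [relaxivity()] object.
#' @param kinetics_base a [kinetic_params()] carrying the arterial
#'   concentration and initial conditions.
#' @param ... passed to [build_dictionary()] (e.g. `max_entries`).
#' @return an object of class `dce_fit` with per-voxel parametric maps.
#'   See [summary.dce_fit()], [coef.dce_fit()], [predict.dce_fit()].
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_config(shape = c(16, 16, 1)), seed = 1)
#' fit <- fit_dce(ph$series, ph$truth$zone >= 2,
#'                phase_maps = ground_truth_phase_maps(ph))
#' summary(fit)
#' }
#' @export
fit_dce <- function(series, mask, phase_maps = NULL,
                    grid = parameter_grid("coarse"),
                    protocol = acquisition_protocol(),
                    rel = relaxivity(),
                    kinetics_base = kinetic_params(0, 0), ...) {
  arr <- if (inherits(series, "dce_series")) series$data else series
  if (length(dim(arr)) != 4L) stop_invalid("'series' must be a 4D array")
  sp <- dim(arr)[1:3]
  nT <- dim(arr)[4]
  if (nT != length(protocol$frame_times))
    stop_invalid("series has %d frames but the protocol %d", nT,
                 length(protocol$frame_times))
  if (!all(dim(mask) == sp)) stop_invalid("mask does not match series shape")
  msk <- array(mask > 0, sp)
  if (is.null(phase_maps)) phase_maps <- phase_maps_volume(arr, msk)
  if (!all(dim(phase_maps$t_formation) == sp))
    stop_invalid("phase maps do not match series shape")

  flat <- matrix(arr, prod(sp), nT)
  idx <- which(msk)
  par_names <- c("k12", "k23", "v23", "r2agg_elevation", "r2agg_reduction",
                 "r2agg_recovery")
  maps <- setNames(lapply(c(par_names, "scale", "residual"),
                          function(nm) array(NA_real_, sp)),
                   c(par_names, "scale", "residual"))

  if (length(idx)) {
    tf <- phase_maps$t_formation[idx]
    tc <- phase_maps$t_clearance[idx]
    key <- paste(tf, tc, sep = "_")
    cache <- new.env(parent = emptyenv())
    for (k in unique(key)) {
      sel <- idx[key == k]
      b <- as.integer(strsplit(k, "_", fixed = TRUE)[[1L]])
      if (is.null(cache[[k]]))
        cache[[k]] <- build_dictionary(grid, protocol, rel, boundaries = b,
                                       kinetics_base = kinetics_base, ...)
      dict <- cache[[k]]
      S <- t(flat[sel, , drop = FALSE])
      zero <- colSums(S != 0) == 0L
      m <- match_curves_matrix(S, dict)
      for (nm in par_names) {
        v <- dict$params[[nm]][m$row]
        v[zero] <- NA_real_
        maps[[nm]][sel] <- v
      }
      maps$scale[sel] <- ifelse(zero, NA_real_, m$scale)
      maps$residual[sel] <- ifelse(zero, NA_real_, m$residual)
    }
  }

  structure(list(maps = maps, mask = msk, phase_maps = phase_maps,
                 grid = grid, protocol = protocol, rel = rel,
                 kinetics_base = kinetics_base, n_fitted = length(idx),
                 call = match.call()),
            class = "dce_fit")
}

#' @export
print.dce_fit <- function(x, ...) {
  cat("Three-compartment DCE aggregation model fit (dictionary matching)\n")
  cat(sprintf("  %d voxels fitted on a %s volume, %d dictionary entries\n",
              x$n_fitted, paste(dim(x$mask), collapse = " x "),
              grid_size(x$grid)))
  cat(sprintf("  median residual %.4g\n",
              stats::median(x$maps$residual[x$mask], na.rm = TRUE)))
  invisible(x)
}

#' Summarise a fitted DCE model
#'
#' Mean and standard deviation of each parametric map over the fitted
#' voxels. Aggregate rates are additionally reported as phase T2* times in
#' milliseconds (`T2* [ms] = 1000 / r2agg`).
#'
#' @param object a `dce_fit`.
#' @param ... unused.
#' @return an object of class `summary.dce_fit` (data.frame of map
#'   statistics, printed with units).
#' @export
summary.dce_fit <- function(object, ...) {
  nm <- names(object$maps)
  vals <- lapply(object$maps, function(m) m[object$mask])
  tab <- data.frame(
    map = nm,
    mean = vapply(vals, function(v) mean(v, na.rm = TRUE), 0),
    sd = vapply(vals, function(v) sd(v, na.rm = TRUE), 0),
    row.names = NULL)
  t2 <- lapply(vals[grep("^r2agg", nm)],
               function(v) 1000 / v[!is.na(v) & v > 0])
  t2tab <- data.frame(
    map = sub("r2agg", "t2star_ms", names(t2)),
    mean = vapply(t2, function(v) if (length(v)) mean(v) else NA_real_, 0),
    sd = vapply(t2, function(v) if (length(v)) sd(v) else NA_real_, 0),
    row.names = NULL)
  structure(list(table = rbind(tab, t2tab), n_fitted = object$n_fitted),
            class = "summary.dce_fit")
}

#' @export
print.summary.dce_fit <- function(x, ...) {
  cat(sprintf("dce_fit summary over %d voxels (rates s^-1, T2* ms):\n",
              x$n_fitted))
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Per-voxel parameter estimates of a fitted DCE model
#'
#' @param object a `dce_fit`.
#' @param ... unused.
#' @return data.frame with one row per fitted voxel: the voxel's linear
#'   index, the six model parameters, the amplitude `scale` and the L2
#'   `residual`.
#' @export
coef.dce_fit <- function(object, ...) {
  idx <- which(object$mask)
  out <- data.frame(voxel = idx)
  for (nm in names(object$maps)) out[[nm]] <- object$maps[[nm]][idx]
  out
}

#' Model-predicted signal curves of fitted voxels
#'
#' Re-simulates the forward model at each requested voxel's fitted
#' parameters (including its phase boundaries and amplitude), yielding the
#' dictionary curve the voxel was matched to.
#'
#' @param object a `dce_fit`.
#' @param voxels linear indices of voxels (default: all fitted voxels).
#' @param ... unused.
#' @return matrix with one row per voxel and one column per frame.
#' @export
predict.dce_fit <- function(object, voxels = which(object$mask), ...) {
  out <- matrix(NA_real_, length(voxels), length(object$protocol$frame_times))
  for (i in seq_along(voxels)) {
    v <- voxels[i]
    if (!object$mask[v] || is.na(object$maps$k12[v])) next
    kb <- object$kinetics_base
    vm <- voxel_model(
      kinetic_params(object$maps$k12[v], object$maps$k23[v], c1 = kb$c1,
                     c2_0 = kb$c2_0, c3_0 = kb$c3_0),
      aggregation_schedule(object$maps$r2agg_elevation[v],
                           object$maps$r2agg_reduction[v],
                           object$maps$r2agg_recovery[v],
                           object$phase_maps$t_formation[v],
                           object$phase_maps$t_clearance[v]),
      v23 = object$maps$v23[v], m0 = 1)
    out[i, ] <- simulate_voxel(vm, object$protocol, object$rel)$values *
      object$maps$scale[v]
  }
  out
}

#' @export
residuals.dce_fit <- function(object, ...) object$maps$residual

#' Display the parametric maps of a fitted DCE model
#'
#' @param x a `dce_fit`.
#' @param slice z-slice to display (default 1).
#' @param which map names (default the six model parameters).
#' @param ... passed to [graphics::image()].
#' @return invisibly `x`.
#' @export
plot.dce_fit <- function(x, slice = 1L,
                         which = c("k12", "k23", "v23", "r2agg_elevation",
                                   "r2agg_reduction", "r2agg_recovery"),
                         ...) {
  op <- par(mfrow = c(2, ceiling(length(which) / 2)), mar = c(1, 1, 2, 1))
  on.exit(par(op))
  for (nm in which) {
    m <- x$maps[[nm]][, , slice]
    image(m, axes = FALSE, col = hcl.colors(64, "viridis"), ...)
    title(nm)
  }
  invisible(x)
}

#' Per-ROI summary table of fitted maps
#'
#' Mean and SD of every parametric map within each labelled region.
#'
#' @param fit a `dce_fit`.
#' @param rois integer label volume matching the fit's spatial shape
#'   (0 = background).
#' @return data.frame with columns `label`, `map`, `mean`, `sd`, `n_voxels`.
#' @export
roi_summary <- function(fit, rois) {
  stopifnot(inherits(fit, "dce_fit"))
  if (!all(dim(rois) == dim(fit$mask)))
    stop_invalid("ROI labels do not match the fitted volume")
  labs <- sort(unique(rois[rois > 0 & fit$mask]))
  rows <- list()
  for (lb in labs) {
    sel <- which(rois == lb & fit$mask)
    for (nm in names(fit$maps)) {
      v <- fit$maps[[nm]][sel]
      rows[[length(rows) + 1L]] <- data.frame(
        label = lb, map = nm, mean = mean(v, na.rm = TRUE),
        sd = sd(v, na.rm = TRUE), n_voxels = length(sel))
    }
  }
  do.call(rbind, rows)
}
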