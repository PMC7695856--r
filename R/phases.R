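#' Detect aggregate formation and clearance frames in a signal curve
#'
#' The dynamic signal of a placental voxel shows three phases: elevation
#' (perfusion-driven enhancement), reduction (aggregate-induced T2*
#' attenuation) and recovery (aggregate clearance). This routine marks the
#' transition frames:
#'
#' 1. the curve is smoothed by a centred moving average (window
#'    `window`, edge-truncated);
#' 2. the formation candidate is the first frame whose smoothed value falls
#'    below `(1 - delta)` times the running maximum of the smoothed curve so
#'    far, with the following frame not exceeding that running maximum;
#' 3. the clearance candidate is the first frame after formation followed by
#'    `n_rise` consecutive smoothed increases, each by at least a relative
#'    `min_rise` (which suppresses the slow residual enhancement still
#'    present during the reduction phase);
#' 4. each candidate is refined on the raw curve within the smoothing
#'    half-window so that the reported index is the first genuinely
#'    attenuated (resp. first rising) frame, undoing the one-frame leakage
#'    the moving average introduces.
#'
#' All conditions are relative, so detection is invariant to positive
#' rescaling of the curve. Ties (equal values) count as "no change". Curves
#' whose mean lies below `floor` are reported as never-transitioning.
#'
#' @param curve a [signal_curve()] or numeric vector (>= 4 frames).
#' @param delta relative drop that declares attenuation (default 0.10).
#' @param window smoothing window, odd (default 3).
#' @param n_rise consecutive smoothed increases that declare recovery
#'   (default 2).
#' @param min_rise minimum relative size of each counted increase
#'   (default 0.02).
#' @param floor noise floor; curves with mean below it are skipped
#'   (default 0).
#' @return integer vector `c(t_formation, t_clearance)`, 1-based frame
#'   indices with sentinel `-1` when a transition never occurs.
#' @examples
#' detect_phases(signal_curve(seq(1, 2, length.out = 20),
#'                            default_frame_times()))   # c(-1, -1)
#' @export
detect_phases <- function(curve, delta = 0.10, window = 3L, n_rise = 2L,
                          min_rise = 0.02, floor = 0) {
  x <- if (inherits(curve, "signal_curve")) curve$values else as.numeric(curve)
  n <- length(x)
  if (n < 4L) stop_invalid("phase detection needs >= 4 frames (got %d)", n)
  none <- c(t_formation = -1L, t_clearance = -1L)
  if (mean(x) < floor || all(x == x[1])) return(none)

  h <- window %/% 2L
  sm <- moving_average(x, window)
  rmax <- cummax(sm)

  # --- formation: delta-drop below the running smoothed maximum
  cand <- -1L
  for (i in 2:n) {
    if (sm[i] < (1 - delta) * rmax[i - 1L] &&
        (i == n || sm[i + 1L] <= rmax[i - 1L])) { cand <- i; break }
  }
  if (cand < 0L) return(none)
  tf <- cand
  for (m in max(2L, cand - h):min(n, cand + h)) {
    if (x[m] < (1 - delta) * max(x[1:(m - 1L)])) { tf <- m; break }
  }

  # --- clearance: n_rise consecutive significant smoothed increases
  tc <- -1L
  cand2 <- -1L
  if (tf < n - n_rise + 1L) {
    for (j in tf:(n - n_rise)) {
      rises <- sm[j + seq_len(n_rise)] > sm[j + seq_len(n_rise) - 1L] * (1 + min_rise)
      if (all(rises)) { cand2 <- j + 1L; break }
    }
  }
  if (cand2 > 0L) {
    tc <- cand2
    for (m in max(tf + 1L, cand2 - h):min(n, cand2 + h + 1L)) {
      if (x[m] > x[m - 1L] * (1 + min_rise) &&
          (m == n || x[m + 1L] >= x[m])) { tc <- m; break }
    }
  }
  c(t_formation = as.integer(tf), t_clearance = as.integer(tc))
}

#' Voxel-wise phase maps over a 4D series
#'
#' Applies [detect_phases()] to every voxel selected by `mask`, producing
#' the formation and clearance frame-index maps. Unmasked voxels carry the
#' sentinel `-1`.
#'
#' @param series 4D numeric array `(x, y, z, frame)` or a `dce_series`.
#' @param mask logical/integer array matching the spatial dimensions;
#'   voxels with `mask > 0` are analysed.
#' @param ... passed to [detect_phases()].
#' @return an object of class `phase_maps`: list with integer arrays
#'   `t_formation`, `t_clearance` and the logical `mask`.
#' @export
phase_maps_volume <- function(series, mask, ...) {
  arr <- if (inherits(series, "dce_series")) series$data else series
  if (length(dim(arr)) != 4L) stop_invalid("'series' must be a 4D array")
  sp <- dim(arr)[1:3]
  if (!all(dim(mask) == sp))
    stop_invalid("mask dimensions (%s) do not match series (%s)",
                 paste(dim(mask), collapse = "x"), paste(sp, collapse = "x"))
  msk <- array(mask > 0, sp)
  tf <- array(-1L, sp); tc <- array(-1L, sp)
  idx <- which(msk)
  if (length(idx)) {
    nT <- dim(arr)[4]
    flat <- matrix(arr, prod(sp), nT)
    for (i in idx) {
      p <- detect_phases(flat[i, ], ...)
      tf[i] <- p[1L]; tc[i] <- p[2L]
    }
  }
  structure(list(t_formation = tf, t_clearance = tc, mask = msk),
            class = "phase_maps")
}

#' @export
print.phase_maps <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf(
    "phase_maps: %d analysed voxels; formation detected in %d, clearance in %d\n",
    n, sum(x$t_formation[x$mask] > 0), sum(x$t_clearance[x$mask] > 0)))
  invisible(x)
}
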