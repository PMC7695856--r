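#' Six-parameter dictionary grid
#'
#' The fitted unknowns are the exchange rates `k12` and `k23`, the C2 volume
#' fraction `v23`, and the aggregate-induced effective transverse rates of
#' the three phases. The dictionary enumerates the Cartesian product of the
#' six value lists in lexicographic order (k12 slowest, recovery rate
#' fastest). A physiological monotonicity filter
#' `r2agg_reduction > max(r2agg_elevation, r2agg_recovery)` prunes
#' combinations in which the reduction phase would not be the most
#' attenuated; disable it with `prune = FALSE`.
#'
#' The `"default"` preset brackets the fitted values reported for the
#' placenta (k12 = 0.045 +/- 0.034 s^-1, k23 = 0.059 +/- 0.035 s^-1, phase
#' T2* 63.3 / 2.7 / 13.6 ms, V23 = 0.75 +/- 0.25): 10 log-spaced k12 in
#' \[0.005, 0.20\], 10 log-spaced k23 in \[0.005, 0.25\], 5 v23 values,
#' 5 elevation rates in \[5, 80\], 17 reduction rates in \[50, 1000\] and
#' 5 recovery rates in \[10, 300\] s^-1 — 166,000 entries after pruning.
#' The `"coarse"` preset (9 x 9 x 4 x 3 x 5 x 3 before pruning, 10,368
#' entries) trades resolution for speed.
#'
#' @param preset `"default"` or `"coarse"`; individual value lists can be
#'   overridden via the named arguments.
#' @param k12,k23 exchange-rate values, s^-1.
#' @param v23 C2 volume fractions in \[0, 1\].
#' @param r2agg_elevation,r2agg_reduction,r2agg_recovery aggregate rates, s^-1.
#' @param prune apply the monotonicity filter (default TRUE).
#' @return an object of class `parameter_grid`.
#' @examples
#' g <- parameter_grid("coarse")
#' grid_size(g)
#' @export
parameter_grid <- function(preset = c("default", "coarse"),
                           k12 = NULL, k23 = NULL, v23 = NULL,
                           r2agg_elevation = NULL, r2agg_reduction = NULL,
                           r2agg_recovery = NULL, prune = TRUE) {
  preset <- match.arg(preset)
  def <- if (preset == "default") {
    list(k12 = logspace(0.005, 0.20, 10), k23 = logspace(0.005, 0.25, 10),
         v23 = c(0.125, 0.3125, 0.5, 0.6875, 0.875),
         r2agg_elevation = logspace(5, 80, 5),
         r2agg_reduction = logspace(50, 1000, 17),
         r2agg_recovery = logspace(10, 300, 5))
  } else {
    list(k12 = logspace(0.005, 0.20, 9), k23 = logspace(0.005, 0.25, 9),
         v23 = c(0.125, 0.375, 0.625, 0.875),
         r2agg_elevation = logspace(5, 80, 3),
         r2agg_reduction = logspace(50, 1000, 5),
         r2agg_recovery = logspace(10, 300, 3))
  }
  vals <- list(k12 = k12, k23 = k23, v23 = v23,
               r2agg_elevation = r2agg_elevation,
               r2agg_reduction = r2agg_reduction,
               r2agg_recovery = r2agg_recovery)
  for (nm in names(vals)) if (is.null(vals[[nm]])) vals[[nm]] <- def[[nm]]
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) < 1L || anyNA(v) || is.unsorted(v, strictly = TRUE))
      stop_invalid("grid values for '%s' must be a nonempty strictly ascending vector", nm)
    if (any(v < 0)) stop_invalid("grid values for '%s' must be >= 0", nm)
  }
  if (any(vals$v23 > 1)) stop_invalid("'v23' grid values must lie in [0, 1]")
  structure(c(vals, list(prune = isTRUE(prune))), class = "parameter_grid")
}

# aggregation-phase triples in lexicographic order, after optional pruning
agg_combos <- function(grid) {
  tab <- expand.grid(r2agg_recovery = grid$r2agg_recovery,
                     r2agg_reduction = grid$r2agg_reduction,
                     r2agg_elevation = grid$r2agg_elevation,
                     KEEP.OUT.ATTRS = FALSE)
  tab <- tab[, c("r2agg_elevation", "r2agg_reduction", "r2agg_recovery")]
  if (grid$prune) {
    keep <- tab$r2agg_reduction > pmax(tab$r2agg_elevation, tab$r2agg_recovery)
    if (!any(keep))
      stop_invalid("monotonicity filter removed every aggregation combination")
    tab <- tab[keep, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

# kinetic/volumetric triples in lexicographic order
kkv_combos <- function(grid) {
  tab <- expand.grid(v23 = grid$v23, k23 = grid$k23, k12 = grid$k12,
                     KEEP.OUT.ATTRS = FALSE)
  tab <- tab[, c("k12", "k23", "v23")]
  rownames(tab) <- NULL
  tab
}

#' Number of dictionary entries a grid generates
#'
#' @param grid a [parameter_grid()].
#' @return integer row count (after the monotonicity filter when active).
#' @export
grid_size <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  nrow(kkv_combos(grid)) * nrow(agg_combos(grid))
}

#' Full parameter table of a grid
#'
#' One row per dictionary entry, lexicographic in
#' (k12, k23, v23, r2agg_elevation, r2agg_reduction, r2agg_recovery).
#'
#' @param grid a [parameter_grid()].
#' @return data.frame with the six parameter columns.
#' @export
grid_table <- function(grid) {
  kkv <- kkv_combos(grid)
  agg <- agg_combos(grid)
  nk <- nrow(kkv); na <- nrow(agg)
  cbind(kkv[rep(seq_len(nk), each = na), , drop = FALSE],
        agg[rep(seq_len(na), times = nk), , drop = FALSE],
        row.names = NULL)
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf(
    "parameter_grid: %d x %d x %d x %d x %d x %d values (k12, k23, v23, elev, red, rec)\n  prune %s -> %d dictionary entries\n",
    length(x$k12), length(x$k23), length(x$v23), length(x$r2agg_elevation),
    length(x$r2agg_reduction), length(x$r2agg_recovery),
    if (x$prune) "on" else "off", grid_size(x)))
  invisible(x)
}
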