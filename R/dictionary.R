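#' Build the simulated-signal dictionary for one phase-boundary pair
#'
#' Simulates, with `m0 = 1`, the forward model at every grid point and
#' stores the resulting time-courses as the rows of a matrix. Signals for
#' all grid points factor into a kinetic/volumetric part (shared by all
#' aggregation triples) and a per-frame aggregate attenuation factor, so the
#' dictionary is assembled as an outer product of the two parts; rows agree
#' exactly with [simulate_voxel()].
#'
#' @param grid a [parameter_grid()].
#' @param protocol an [acquisition_protocol()].
#' @param rel a [relaxivity()] object.
#' @param boundaries integer pair `c(t_formation, t_clearance)` (1-based,
#'   sentinel -1 allowed) shared by all entries. With a sentinel formation
#'   the aggregation grids collapse to `{0}` (no aggregation); with a
#'   sentinel clearance only the recovery grid collapses.
#' @param kinetics_base a [kinetic_params()] supplying the arterial
#'   concentration and initial conditions shared by all entries.
#' @param max_entries capacity guard; grids whose pruned size exceeds it
#'   raise an error advising a coarser grid (default 1e6).
#' @return an object of class `signal_dictionary`: `entries` (rows = grid
#'   points, columns = frames), `params` (data.frame of the six parameter
#'   values per row), `boundaries`, `frame_times`, `protocol`, `rel` and the
#'   precomputed row self-products `dd`.
#' @export
build_dictionary <- function(grid, protocol, rel = relaxivity(),
                             boundaries = c(-1L, -1L),
                             kinetics_base = kinetic_params(0, 0),
                             max_entries = 1e6) {
  stopifnot(inherits(grid, "parameter_grid"),
            inherits(protocol, "acquisition_protocol"))
  tf <- as.integer(boundaries[1L]); tc <- as.integer(boundaries[2L])
  nT <- length(protocol$frame_times)
  if (tf > nT || tc > nT)
    stop_invalid("phase boundaries (%d, %d) exceed frame count %d", tf, tc, nT)
  if (tf < 0L) {
    grid <- parameter_grid(k12 = grid$k12, k23 = grid$k23, v23 = grid$v23,
                           r2agg_elevation = 0, r2agg_reduction = 0,
                           r2agg_recovery = 0, prune = FALSE)
    tc <- -1L
  } else if (tc < 0L) {
    grid <- parameter_grid(k12 = grid$k12, k23 = grid$k23, v23 = grid$v23,
                           r2agg_elevation = grid$r2agg_elevation,
                           r2agg_reduction = grid$r2agg_reduction,
                           r2agg_recovery = 0, prune = FALSE)
  }
  n_rows <- grid_size(grid)
  if (n_rows > max_entries)
    stop_invalid(paste0("dictionary would hold %d entries, above the capacity ",
                        "budget of %d; use a coarser grid"),
                 n_rows, as.integer(max_entries))

  kkv <- kkv_combos(grid)
  agg <- agg_combos(grid)

  # kinetic part: one base curve pair per (k12, k23), mixed by v23
  kk <- unique(kkv[, c("k12", "k23")])
  base <- matrix(0, nrow(kk), 2L * nT)
  for (i in seq_len(nrow(kk))) {
    kp <- kinetic_params(kk$k12[i], kk$k23[i], c1 = kinetics_base$c1,
                         c2_0 = kinetics_base$c2_0, c3_0 = kinetics_base$c3_0)
    cc <- solve_compartments(kp, protocol$frame_times)
    s2 <- spgr_signal(rel$baseline_r1 + rel$r1 * cc$c2,
                      rel$baseline_r2star + rel$r2 * cc$c2, protocol)
    s3 <- spgr_signal(rel$baseline_r1 + rel$r1 * cc$c3,
                      rel$baseline_r2star + rel$r2 * cc$c3, protocol)
    base[i, ] <- c(s2, s3)
  }
  kk_index <- match(interaction(kkv$k12, kkv$k23, drop = TRUE),
                    interaction(kk$k12, kk$k23, drop = TRUE))
  G <- kkv$v23 * base[kk_index, seq_len(nT), drop = FALSE] +
    (1 - kkv$v23) * base[kk_index, nT + seq_len(nT), drop = FALSE]

  # aggregation part: shared per-frame attenuation factor
  phase <- rep(1L, nT)                       # 1 elev, 2 red, 3 rec
  if (tf > 0L) {
    phase[seq_len(nT) >= tf] <- 2L
    if (tc > 0L) phase[seq_len(nT) >= tc] <- 3L
  }
  rates <- as.matrix(agg)[, c("r2agg_elevation", "r2agg_reduction",
                              "r2agg_recovery"), drop = FALSE]
  A <- exp(-protocol$te * rates[, phase, drop = FALSE])

  nk <- nrow(G); na <- nrow(A)
  entries <- G[rep(seq_len(nk), each = na), , drop = FALSE] *
    A[rep(seq_len(na), times = nk), , drop = FALSE]
  dimnames(entries) <- NULL
  params <- cbind(kkv[rep(seq_len(nk), each = na), , drop = FALSE],
                  agg[rep(seq_len(na), times = nk), , drop = FALSE],
                  row.names = NULL)

  structure(list(entries = entries, params = params,
                 boundaries = c(t_formation = tf, t_clearance = tc),
                 frame_times = protocol$frame_times,
                 protocol = protocol, rel = rel,
                 dd = rowSums(entries^2)),
            class = "signal_dictionary")
}

#' @export
print.signal_dictionary <- function(x, ...) {
  cat(sprintf(
    "signal_dictionary: %d entries x %d frames, boundaries (%d, %d)\n",
    nrow(x$entries), ncol(x$entries), x$boundaries[1], x$boundaries[2]))
  invisible(x)
}

#' Match one measured curve against a dictionary
#'
#' For each dictionary row `d` the per-voxel amplitude is fitted in closed
#' form as `a* = max(0, <s, d> / <d, d>)` (the proton-density scaling is a
#' nuisance parameter, making the match amplitude-invariant) and the
#' residual is `||s - a* d||_2`. The row with the minimal residual wins;
#' ties break to the lowest row index. An all-zero input cannot be matched
#' and returns a flagged sentinel.
#'
#' @param curve a [signal_curve()] or numeric vector with as many frames as
#'   the dictionary.
#' @param dict a [build_dictionary()] result.
#' @return list with `row` (index into `dict$params`), `scale`, `residual`,
#'   `params` (the winning parameter row) and `flagged`.
#' @export
match_curve <- function(curve, dict) {
  stopifnot(inherits(dict, "signal_dictionary"))
  s <- if (inherits(curve, "signal_curve")) curve$values else as.numeric(curve)
  if (length(s) != ncol(dict$entries))
    stop_invalid("curve has %d frames, dictionary %d", length(s),
                 ncol(dict$entries))
  if (all(s == 0))
    return(list(row = NA_integer_, scale = NA_real_, residual = NA_real_,
                params = NULL, flagged = TRUE))
  num <- as.vector(dict$entries %*% s)
  a <- pmax(num / dict$dd, 0)
  r2 <- pmax(sum(s^2) - 2 * a * num + a^2 * dict$dd, 0)
  best <- which.min(r2)
  list(row = best, scale = a[best], residual = sqrt(r2[best]),
       params = dict$params[best, , drop = FALSE], flagged = FALSE)
}

# vectorised matching of many curves (columns of S) against one dictionary;
# chunked so the n_entries x chunk residual matrix stays within budget
match_curves_matrix <- function(S, dict, chunk_elements = 2e7) {
  n <- nrow(dict$entries)
  m <- ncol(S)
  chunk <- max(1L, as.integer(chunk_elements %/% n))
  row <- integer(m); scl <- numeric(m); res <- numeric(m)
  ss <- colSums(S^2)
  for (start in seq(1L, m, by = chunk)) {
    j <- start:min(m, start + chunk - 1L)
    num <- dict$entries %*% S[, j, drop = FALSE]      # n x |j|
    A <- pmax(num / dict$dd, 0)
    R2 <- -2 * A * num + A^2 * dict$dd
    R2 <- sweep(R2, 2L, ss[j], "+")
    best <- max.col(-t(R2), ties.method = "first")
    row[j] <- best
    pick <- cbind(best, seq_along(j))
    scl[j] <- A[pick]
    res[j] <- sqrt(pmax(t(R2)[cbind(seq_along(j), best)], 0))
  }
  list(row = row, scale = scl, residual = res)
}
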