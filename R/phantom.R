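#' Configuration of the synthetic placental DCE phantom
#'
#' The phantom is a 4D dynamic series with known per-voxel ground truth. Its
#' in-plane geometry mimics a placental cross-section: a central canal of C1
#' (maternal blood pool) voxels surrounded by three concentric placental
#' zones — labyrinth (innermost), junctional zone, decidua (outermost).
#' Placental voxels receive kinetic, volumetric and aggregation parameters
#' sampled from truncated normals around the fitted population values
#' (k12 = 0.045 +/- 0.034 s^-1, k23 = 0.059 +/- 0.035 s^-1,
#' V23 = 0.75 +/- 0.25, phase T2* = 63.3 +/- 39.7 / 2.7 +/- 1.6 /
#' 13.6 +/- 10.0 ms), truncated at 2 SD and at the physical bounds of the
#' default fitting grid so recovery experiments are well posed. The sampler
#' additionally enforces that the reduction-phase aggregate rate exceeds the
#' elevation and recovery rates, matching the dictionary's monotonicity
#' filter. Aggregate formation propagates from the decidua inward to the
#' labyrinth and clearance back outward, implemented as frame-index offsets
#' of up to `offset_frames` around the base transition frames.
#'
#' @param shape integer 3-vector of voxel dimensions (default 48 x 48 x 4).
#' @param r_c1,r_labyrinth,r_junctional,r_decidua in-plane zone radii in
#'   voxels (defaults 4, 10, 16, 22).
#' @param c1 constant arterial concentration, mM (default 0.104).
#' @param snr signal-to-noise ratio of the Rician magnitude noise, defined
#'   as mean noise-free placental signal divided by the Gaussian sigma of
#'   the underlying channels (default 20; `Inf` disables noise).
#' @param base_formation,base_clearance base transition frames (1-based;
#'   defaults 6 and 12, i.e. attenuation from ~15 min and recovery from
#'   ~30 min of the 54-min schedule).
#' @param offset_frames maximal phase-onset offset across the placenta
#'   (default 2 frames).
#' @param means,sds named lists overriding the ground-truth sampling
#'   means/SDs (`k12`, `k23`, `v23` and `t2_elevation_ms`,
#'   `t2_reduction_ms`, `t2_recovery_ms`).
#' @param snap_grid optional [parameter_grid()]; when supplied, sampled
#'   ground-truth parameters are snapped to the nearest grid values
#'   (on-grid truth for recovery experiments).
#' @param protocol an [acquisition_protocol()].
#' @param rel a [relaxivity()] object.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(48L, 48L, 4L),
                           r_c1 = 4, r_labyrinth = 10, r_junctional = 16,
                           r_decidua = 22,
                           c1 = 0.104, snr = 20,
                           base_formation = 6L, base_clearance = 12L,
                           offset_frames = 2L,
                           means = list(), sds = list(),
                           snap_grid = NULL,
                           protocol = acquisition_protocol(),
                           rel = relaxivity()) {
  if (length(shape) != 3L || any(shape < 1))
    stop_invalid("'shape' must be three positive integers")
  if (!(r_c1 < r_labyrinth && r_labyrinth < r_junctional &&
        r_junctional < r_decidua))
    stop_invalid("zone radii must be strictly increasing")
  check_scalar(c1, "c1", lower = 0)
  if (!identical(snr, Inf)) check_scalar(snr, "snr", lower = 0, strict_lower = TRUE)
  m <- list(k12 = 0.045, k23 = 0.059, v23 = 0.75,
            t2_elevation_ms = 63.3, t2_reduction_ms = 2.7,
            t2_recovery_ms = 13.6)
  s <- list(k12 = 0.034, k23 = 0.035, v23 = 0.25,
            t2_elevation_ms = 39.7, t2_reduction_ms = 1.6,
            t2_recovery_ms = 10.0)
  m[names(means)] <- means
  s[names(sds)] <- sds
  if (any(unlist(s) < 0)) stop_invalid("sampling SDs must be >= 0")
  structure(list(shape = as.integer(shape), r_c1 = r_c1,
                 r_labyrinth = r_labyrinth, r_junctional = r_junctional,
                 r_decidua = r_decidua, c1 = c1, snr = snr,
                 base_formation = as.integer(base_formation),
                 base_clearance = as.integer(base_clearance),
                 offset_frames = as.integer(offset_frames),
                 means = m, sds = s, snap_grid = snap_grid,
                 protocol = protocol, rel = rel),
            class = "phantom_config")
}

# zone label volume: 0 background, 1 C1 canal, 2 labyrinth, 3 junctional,
# 4 decidua, by in-plane distance from the grid centre
phantom_zones <- function(cfg) {
  nx <- cfg$shape[1]; ny <- cfg$shape[2]; nz <- cfg$shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r <- sqrt(outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, "+"))
  z2 <- ifelse(r <= cfg$r_c1, 1L,
        ifelse(r <= cfg$r_labyrinth, 2L,
        ifelse(r <= cfg$r_junctional, 3L,
        ifelse(r <= cfg$r_decidua, 4L, 0L))))
  array(rep(z2, nz), cfg$shape)
}

snap_to <- function(x, values) values[pmax(1L, findInterval(x, (head(values, -1) + tail(values, -1)) / 2) + 1L)]

# sample all per-voxel ground-truth parameters (seed already set)
sample_truth <- function(cfg, idx, zones, rr) {
  n <- length(idx)
  m <- cfg$means; s <- cfg$sds
  g <- cfg$snap_grid
  k12 <- rtruncnorm1(n, m$k12, s$k12,
                     max(0.005, m$k12 - 2 * s$k12), min(0.20, m$k12 + 2 * s$k12))
  k23 <- rtruncnorm1(n, m$k23, s$k23,
                     max(0.005, m$k23 - 2 * s$k23), min(0.25, m$k23 + 2 * s$k23))
  v23 <- rtruncnorm1(n, m$v23, s$v23,
                     max(0.125, m$v23 - 2 * s$v23), min(0.875, m$v23 + 2 * s$v23))
  t2e <- rtruncnorm1(n, m$t2_elevation_ms, s$t2_elevation_ms,
                     max(1000 / 80, m$t2_elevation_ms - 2 * s$t2_elevation_ms),
                     min(1000 / 5, m$t2_elevation_ms + 2 * s$t2_elevation_ms))
  t2r <- rtruncnorm1(n, m$t2_reduction_ms, s$t2_reduction_ms,
                     max(1, m$t2_reduction_ms - 2 * s$t2_reduction_ms),
                     min(1000 / 50, m$t2_reduction_ms + 2 * s$t2_reduction_ms))
  t2c <- rtruncnorm1(n, m$t2_recovery_ms, s$t2_recovery_ms,
                     max(1000 / 300, m$t2_recovery_ms - 2 * s$t2_recovery_ms),
                     min(1000 / 10, m$t2_recovery_ms + 2 * s$t2_recovery_ms))
  re <- 1000 / t2e; rd <- 1000 / t2r; rc <- 1000 / t2c
  # physiological ordering with margin: the reduction phase is clearly the
  # most attenuated (the reported phase T2* ratio reduction:recovery is ~5x)
  rc <- pmin(rc, 0.8 * rd)
  if (!is.null(g)) {
    k12 <- snap_to(k12, g$k12); k23 <- snap_to(k23, g$k23)
    v23 <- snap_to(v23, g$v23)
    re <- snap_to(re, g$r2agg_elevation)
    rd <- snap_to(rd, g$r2agg_reduction)
    rc <- snap_to(rc, g$r2agg_recovery)
    bad <- which(rd <= 1.25 * pmax(re, rc))
    for (i in bad) {
      up <- g$r2agg_reduction[g$r2agg_reduction > 1.25 * max(re[i], rc[i])]
      if (length(up)) rd[i] <- up[1] else {
        rc[i] <- max(g$r2agg_recovery[g$r2agg_recovery < 0.8 * rd[i]])
      }
    }
  }
  # phase-onset gradient: formation earliest at the decidua (outer edge),
  # clearance earliest at the labyrinth; linear in in-plane radius
  span <- cfg$r_decidua - cfg$r_c1
  frac <- pmin(pmax((rr - cfg$r_c1) / span, 0), 1)     # 0 inner .. 1 outer
  off <- as.integer(round(cfg$offset_frames * (1 - 2 * frac)))
  tf <- cfg$base_formation + off
  tc <- cfg$base_clearance - off
  m0 <- 1000 * runif(n, 0.8, 1.2)
  list(k12 = k12, k23 = k23, v23 = v23, r2agg_elevation = re,
       r2agg_reduction = rd, r2agg_recovery = rc,
       t_formation = tf, t_clearance = tc, m0 = m0)
}

#' Generate a seeded 4D DCE phantom with known ground truth
#'
#' C1 (canal) voxels carry the constant-concentration arterial signal;
#' placental voxels are forward-simulated from sampled ground truth with a
#' three-phase aggregation schedule whose onsets propagate from the decidua
#' to the labyrinth (and back for clearance); background voxels are zero.
#' Rician magnitude noise is added at the configured SNR. Output is
#' bit-for-bit reproducible for a given `(cfg, seed)`.
#'
#' @param cfg a [phantom_config()].
#' @param seed integer RNG seed.
#' @param aggregation logical: simulate aggregate formation (default TRUE).
#' @return an object of class `dce_phantom`: list with `series` (4D array),
#'   `truth` (per-voxel ground-truth arrays incl. `zone` labels, phase maps
#'   and `m0`), `cfg` and `seed`.
#' @export
generate_phantom <- function(cfg = phantom_config(), seed = 1L,
                             aggregation = TRUE) {
  stopifnot(inherits(cfg, "phantom_config"))
  zones <- phantom_zones(cfg)
  idx <- which(zones >= 2L)
  if (!length(idx)) stop_invalid("degenerate geometry: no placental voxels")
  set.seed(as.integer(seed))
  nx <- cfg$shape[1]; ny <- cfg$shape[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rin <- sqrt(outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, "+"))
  rr <- array(rep(rin, cfg$shape[3]), cfg$shape)[idx]
  tr <- sample_truth(cfg, idx, zones, rr)
  nT <- length(cfg$protocol$frame_times)

  truth <- list(zone = zones)
  for (nm in names(tr)) {
    a <- array(if (nm %in% c("t_formation", "t_clearance")) -1L else NA_real_,
               cfg$shape)
    a[idx] <- tr[[nm]]
    truth[[nm]] <- a
  }
  if (!aggregation) {
    for (nm in c("r2agg_elevation", "r2agg_reduction", "r2agg_recovery"))
      truth[[nm]][idx] <- 0
    truth$t_formation[idx] <- -1L
    truth$t_clearance[idx] <- -1L
  }

  series <- array(0, c(cfg$shape, nT))
  flat <- matrix(0, prod(cfg$shape), nT)
  for (j in seq_along(idx)) {
    i <- idx[j]
    agg <- if (aggregation)
      aggregation_schedule(tr$r2agg_elevation[j], tr$r2agg_reduction[j],
                           tr$r2agg_recovery[j], tr$t_formation[j],
                           tr$t_clearance[j])
    else aggregation_schedule()
    vm <- voxel_model(kinetic_params(tr$k12[j], tr$k23[j], c1 = cfg$c1),
                      agg, v23 = tr$v23[j], m0 = tr$m0[j])
    flat[i, ] <- simulate_voxel(vm, cfg$protocol, cfg$rel)$values
  }
  # C1 canal: constant arterial concentration, no aggregation
  c1_idx <- which(zones == 1L)
  if (length(c1_idx)) {
    m0c <- 1000 * runif(length(c1_idx), 0.8, 1.2)
    s1 <- spgr_signal(cfg$rel$baseline_r1 + cfg$rel$r1 * cfg$c1,
                      cfg$rel$baseline_r2star + cfg$rel$r2 * cfg$c1,
                      cfg$protocol)
    flat[c1_idx, ] <- outer(m0c * s1, rep(1, nT))
    m0a <- truth$m0; m0a[c1_idx] <- m0c; truth$m0 <- m0a
  }
  if (is.finite(cfg$snr)) {
    sigma <- mean(flat[idx, ]) / cfg$snr
    noise_re <- matrix(rnorm(length(flat), 0, sigma), nrow(flat))
    noise_im <- matrix(rnorm(length(flat), 0, sigma), nrow(flat))
    flat <- sqrt((flat + noise_re)^2 + noise_im^2)
  }
  series[] <- flat
  structure(list(series = series, truth = truth, cfg = cfg,
                 seed = as.integer(seed)),
            class = "dce_phantom")
}

#' Generate the biotin-competition phantom
#'
#' Emulates the competition experiment in which excess native biotin
#' saturates the transporters before contrast injection: aggregation never
#' occurs (all aggregate rates zero, sentinel phase maps) and the uptake
#' rate `k23` is suppressed by `suppression` (default 0.3), producing a
#' lower, plateauing enhancement curve with no attenuation dip.
#'
#' @param cfg a [phantom_config()].
#' @param seed integer RNG seed.
#' @param suppression multiplicative factor on the sampled `k23`
#'   (default 0.3).
#' @return a `dce_phantom`, as [generate_phantom()].
#' @export
generate_competition_phantom <- function(cfg = phantom_config(), seed = 1L,
                                         suppression = 0.3) {
  check_scalar(suppression, "suppression", lower = 0, upper = 1)
  cfg$means$k23 <- cfg$means$k23 * suppression
  cfg$sds$k23 <- cfg$sds$k23 * suppression
  generate_phantom(cfg, seed = seed, aggregation = FALSE)
}

#' Ground-truth phase maps of a phantom
#'
#' @param phantom a `dce_phantom`.
#' @return a `phase_maps` object built from the phantom's ground truth.
#' @export
ground_truth_phase_maps <- function(phantom) {
  stopifnot(inherits(phantom, "dce_phantom"))
  structure(list(t_formation = phantom$truth$t_formation,
                 t_clearance = phantom$truth$t_clearance,
                 mask = phantom$truth$zone >= 2L),
            class = "phase_maps")
}

#' @export
print.dce_phantom <- function(x, ...) {
  cat(sprintf(
    "dce_phantom: %s voxels x %d frames, %d placental voxels, SNR %s, seed %d\n",
    paste(x$cfg$shape, collapse = " x "), dim(x$series)[4],
    sum(x$truth$zone >= 2L), format(x$cfg$snr), x$seed))
  invisible(x)
}
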