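#' Aggregation schedule of a voxel
#'
#' The contrast agent forms intravoxel aggregates whose microscopic field
#' distortions add a strong effective transverse relaxation term. The signal
#' time-course is split into three phases — elevation, reduction and recovery
#' — separated by the aggregate formation and clearance frames. Each phase
#' carries one aggregate-induced rate applied voxel-wide.
#'
#' Frame indices are 1-based; the sentinel `-1` on `t_formation` or
#' `t_clearance` means the corresponding transition never occurs.
#'
#' @param r2agg_elevation,r2agg_reduction,r2agg_recovery aggregate-induced
#'   effective transverse rates per phase, s^-1 (>= 0).
#' @param t_formation first attenuated frame (1-based) or -1.
#' @param t_clearance first recovery frame (1-based) or -1; requires a
#'   nonnegative `t_formation` and `t_formation < t_clearance`.
#' @return an object of class `aggregation_schedule`.
#' @export
aggregation_schedule <- function(r2agg_elevation = 0, r2agg_reduction = 0,
                                 r2agg_recovery = 0,
                                 t_formation = -1L, t_clearance = -1L) {
  for (nm in c("r2agg_elevation", "r2agg_reduction", "r2agg_recovery"))
    check_scalar(get(nm), nm, lower = 0)
  t_formation <- as.integer(t_formation)
  t_clearance <- as.integer(t_clearance)
  if (t_formation < -1L || t_clearance < -1L || t_formation == 0L ||
      t_clearance == 0L)
    stop_invalid("phase indices must be 1-based frame indices or the sentinel -1")
  if (t_clearance > 0L && t_formation < 0L)
    stop_invalid("'t_clearance' requires a preceding 't_formation'")
  if (t_formation > 0L && t_clearance > 0L && t_formation >= t_clearance)
    stop_invalid("'t_formation' (%d) must precede 't_clearance' (%d)",
                 t_formation, t_clearance)
  structure(list(r2agg_elevation = r2agg_elevation,
                 r2agg_reduction = r2agg_reduction,
                 r2agg_recovery = r2agg_recovery,
                 t_formation = t_formation, t_clearance = t_clearance),
            class = "aggregation_schedule")
}

# per-frame aggregate rate given a schedule (internal)
r2agg_per_frame <- function(agg, n_frames) {
  n <- seq_len(n_frames)
  out <- rep(agg$r2agg_elevation, n_frames)
  if (agg$t_formation > 0L) {
    red <- n >= agg$t_formation &
      (agg$t_clearance < 0L | n < agg$t_clearance)
    out[red] <- agg$r2agg_reduction
    if (agg$t_clearance > 0L) out[n >= agg$t_clearance] <- agg$r2agg_recovery
  }
  out
}

#' Sub-voxel model of a single DCE voxel
#'
#' Combines the exchange kinetics, the aggregation schedule, the C2 volume
#' fraction and the proton-density scaling of one voxel. `v23` is the
#' fraction of the voxel volume occupied by the maternal intravascular
#' compartment C2 (the remainder is C3); the voxel signal is the linear
#' volume-weighted sum of the two sub-compartment signals sharing one `m0`.
#'
#' @param kinetics a [kinetic_params()] object.
#' @param aggregation an [aggregation_schedule()] object.
#' @param v23 C2 volume fraction, in \[0, 1\].
#' @param m0 proton density weighted by coil sensitivity, arbitrary units (> 0).
#' @return an object of class `voxel_model`.
#' @export
voxel_model <- function(kinetics, aggregation = aggregation_schedule(),
                        v23 = 0.75, m0 = 1) {
  if (!inherits(kinetics, "kinetic_params"))
    stop_invalid("'kinetics' must be a kinetic_params object")
  if (!inherits(aggregation, "aggregation_schedule"))
    stop_invalid("'aggregation' must be an aggregation_schedule object")
  check_scalar(v23, "v23", lower = 0, upper = 1)
  check_scalar(m0, "m0", lower = 0, strict_lower = TRUE)
  structure(list(kinetics = kinetics, aggregation = aggregation,
                 v23 = v23, m0 = m0),
            class = "voxel_model")
}

#' Steady-state spoiled gradient-echo signal
#'
#' \deqn{S = M_0 \sin\theta \,
#'   \frac{1 - e^{-TR \cdot R_1}}{1 - \cos\theta \, e^{-TR \cdot R_1}}
#'   \, e^{-TE \cdot R_2^*}.}
#' The signal is bounded by `m0`, strictly increasing in `r1_total` and, for
#' `te > 0`, strictly decreasing in `r2star_total`. Vectorised over the rate
#' arguments.
#'
#' @param r1_total total longitudinal rate(s), s^-1 (>= 0).
#' @param r2star_total total effective transverse rate(s), s^-1 (>= 0).
#' @param protocol an [acquisition_protocol()].
#' @param m0 proton-density scaling (> 0).
#' @return signal in arbitrary units, same length as the rates.
#' @export
spgr_signal <- function(r1_total, r2star_total, protocol, m0 = 1) {
  check_nonneg_vector(r1_total, "r1_total")
  check_nonneg_vector(r2star_total, "r2star_total")
  check_scalar(m0, "m0", lower = 0, strict_lower = TRUE)
  e1 <- exp(-protocol$tr * r1_total)
  m0 * sin(protocol$flip_angle) * (1 - e1) /
    (1 - cos(protocol$flip_angle) * e1) *
    exp(-protocol$te * r2star_total)
}

#' Per-frame signal curve container
#'
#' @param values per-frame signal values (>= 0), arbitrary units.
#' @param frame_times frame-centre times, seconds, same length.
#' @return an object of class `signal_curve`.
#' @export
signal_curve <- function(values, frame_times) {
  if (length(values) != length(frame_times))
    stop_invalid("'values' and 'frame_times' lengths differ")
  check_nonneg_vector(values, "values")
  structure(list(values = as.numeric(values),
                 frame_times = as.numeric(frame_times)),
            class = "signal_curve")
}

#' @export
print.signal_curve <- function(x, ...) {
  cat(sprintf("signal_curve: %d frames, %.3g .. %.3g a.u.\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.signal_curve <- function(x, ..., xlab = "time [s]", ylab = "signal [a.u.]",
                              type = "b") {
  plot(x$frame_times, x$values, xlab = xlab, ylab = ylab, type = type, ...)
}

#' Forward-simulate the dynamic signal of one voxel
#'
#' For each frame the exchange concentrations are evaluated at the frame
#' centre (concentrations are taken as stepwise constant within a frame,
#' reflecting the ~3 min frame rate), converted to per-compartment relaxation
#' rates (tissue baseline plus relaxivity times concentration), and passed
#' through the spoiled-GRE equation. The aggregate term selected by the
#' frame's phase multiplies both sub-compartment signals as a shared
#' `exp(-TE * r2agg)` factor, and the voxel signal is
#' `v23 * S_C2 + (1 - v23) * S_C3`.
#'
#' @param vm a [voxel_model()].
#' @param protocol an [acquisition_protocol()].
#' @param rel a [relaxivity()] object.
#' @return a [signal_curve()].
#' @examples
#' vm <- voxel_model(kinetic_params(0.045, 0.059),
#'                   aggregation_schedule(15.8, 370, 73.5, 6L, 12L))
#' sim <- simulate_voxel(vm, acquisition_protocol(), relaxivity())
#' which.min(sim$values)   # inside the reduction window
#' @export
simulate_voxel <- function(vm, protocol, rel = relaxivity()) {
  if (!inherits(vm, "voxel_model")) stop_invalid("'vm' must be a voxel_model")
  if (!inherits(protocol, "acquisition_protocol"))
    stop_invalid("'protocol' must be an acquisition_protocol")
  nT <- length(protocol$frame_times)
  agg <- vm$aggregation
  if (agg$t_formation > nT || agg$t_clearance > nT)
    stop_invalid("phase indices exceed the protocol frame count (%d)", nT)
  cc <- solve_compartments(vm$kinetics, protocol$frame_times)
  s2 <- spgr_signal(rel$baseline_r1 + rel$r1 * cc$c2,
                    rel$baseline_r2star + rel$r2 * cc$c2, protocol, vm$m0)
  s3 <- spgr_signal(rel$baseline_r1 + rel$r1 * cc$c3,
                    rel$baseline_r2star + rel$r2 * cc$c3, protocol, vm$m0)
  fagg <- exp(-protocol$te * r2agg_per_frame(agg, nT))
  signal_curve((vm$v23 * s2 + (1 - vm$v23) * s3) * fagg, protocol$frame_times)
}
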