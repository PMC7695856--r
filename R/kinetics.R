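#' Kinetic parameters of the two-compartment exchange system
#'
#' The placenta is modelled as three sub-voxel compartments: C1, the maternal
#' arterial blood pool, held at a constant agent concentration `c1`; C2, the
#' maternal intravascular placental compartment; and C3, the trophoblast cell
#' compartment. Concentrations in C2 and C3 evolve by unidirectional exchange,
#' \deqn{\dot c_2 = k_{12}(c_1 - c_2) - k_{23}(c_2 - c_3), \qquad
#'       \dot c_3 = k_{23}(c_2 - c_3).}
#'
#' @param k12 exchange rate C1 -> C2, s^-1 (>= 0).
#' @param k23 exchange rate C2 -> C3, s^-1 (>= 0).
#' @param c1 constant arterial concentration, mM (default 0.104).
#' @param c2_0,c3_0 initial concentrations in C2 and C3, mM (default 0:
#'   the bolus arrives at t = 0 into C1 only).
#' @return an object of class `kinetic_params`.
#' @seealso [solve_compartments()]
#' @export
kinetic_params <- function(k12, k23, c1 = 0.104, c2_0 = 0, c3_0 = 0) {
  check_scalar(k12, "k12", lower = 0)
  check_scalar(k23, "k23", lower = 0)
  check_scalar(c1, "c1", lower = 0)
  check_scalar(c2_0, "c2_0", lower = 0)
  check_scalar(c3_0, "c3_0", lower = 0)
  structure(list(k12 = k12, k23 = k23, c1 = c1, c2_0 = c2_0, c3_0 = c3_0),
            class = "kinetic_params")
}

#' Closed-form concentration time-courses of the exchange system
#'
#' Solves the linear two-compartment system with constant arterial input
#' exactly, by eigen-decomposition of the system matrix
#' \eqn{A = [[-(k_{12}+k_{23}), k_{23}], [k_{23}, -k_{23}]]}. For
#' `k12, k23 > 0` both eigenvalues are real and negative and both
#' concentrations approach `c1` monotonically from zero initial conditions.
#' Rate-degenerate cases (`k12 == 0` or `k23 == 0`) use their explicit
#' single-exponential solutions.
#'
#' @param kp a [kinetic_params()] object.
#' @param times nonnegative, nondecreasing evaluation times, seconds.
#' @return an object of class `concentration_curve`: list with `times`,
#'   `c2`, `c3` (mM).
#' @examples
#' kp <- kinetic_params(k12 = 0.045, k23 = 0.059)
#' cc <- solve_compartments(kp, seq(0, 3240, by = 162))
#' all(diff(cc$c2) >= 0)   # monotone approach to c1
#' @export
solve_compartments <- function(kp, times) {
  if (!inherits(kp, "kinetic_params")) kp <- do.call(kinetic_params, kp)
  if (!is.numeric(times) || anyNA(times) || any(times < 0))
    stop_invalid("'times' must be nonnegative numbers")
  if (is.unsorted(times)) stop_invalid("'times' must be nondecreasing")
  a <- kp$k12; b <- kp$k23
  t <- as.numeric(times)
  if (a == 0 && b == 0) {
    c2 <- rep(kp$c2_0, length(t)); c3 <- rep(kp$c3_0, length(t))
  } else if (b == 0) {
    # C3 decoupled; C2 relaxes to c1 at rate k12
    c2 <- kp$c1 + (kp$c2_0 - kp$c1) * exp(-a * t)
    c3 <- rep(kp$c3_0, length(t))
  } else if (a == 0) {
    # closed pair: sum conserved, difference decays at 2*k23
    s <- kp$c2_0 + kp$c3_0; d <- kp$c2_0 - kp$c3_0
    e <- exp(-2 * b * t)
    c2 <- (s + d * e) / 2
    c3 <- (s - d * e) / 2
  } else {
    disc <- sqrt(a^2 + 4 * b^2)
    lam1 <- (-(a + 2 * b) + disc) / 2
    lam2 <- (-(a + 2 * b) - disc) / 2
    # eigenvectors (b, a + b + lambda); deviation from the fixed point (c1, c1)
    V <- matrix(c(b, a + b + lam1, b, a + b + lam2), 2, 2)
    alpha <- solve(V, c(kp$c2_0 - kp$c1, kp$c3_0 - kp$c1))
    e1 <- exp(lam1 * t); e2 <- exp(lam2 * t)
    c2 <- kp$c1 + alpha[1] * V[1, 1] * e1 + alpha[2] * V[1, 2] * e2
    c3 <- kp$c1 + alpha[1] * V[2, 1] * e1 + alpha[2] * V[2, 2] * e2
  }
  structure(list(times = t, c2 = pmax(c2, 0), c3 = pmax(c3, 0)),
            class = "concentration_curve")
}

#' Contrast-induced relaxation rates
#'
#' Linear relaxivity model: the agent adds `r1 * c` to the longitudinal and
#' `r2 * c` to the transverse relaxation rate. Tissue baseline rates are not
#' added here; they are composed in [simulate_voxel()].
#'
#' @param c concentration(s), mM (>= 0; vectorised).
#' @param rel a [relaxivity()] object.
#' @return list with `R1` and `R2` in s^-1, same length as `c`.
#' @examples
#' relaxation_rates(1, relaxivity())   # R1 = 120, R2 = 17
#' @export
relaxation_rates <- function(c, rel = relaxivity()) {
  check_nonneg_vector(c, "c")
  list(R1 = rel$r1 * c, R2 = rel$r2 * c)
}
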