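# internal validation and numeric helpers

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_invalid("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_invalid("'%s' must be >= %g (got %g)", name, lower, x)
  if (strict_upper && x >= upper)
    stop_invalid("'%s' must be < %g (got %g)", name, upper, x)
  if (!strict_upper && x > upper)
    stop_invalid("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

check_nonneg_vector <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop_invalid("'%s' must be a nonnegative numeric vector", name)
  invisible(x)
}

#' Logarithmically spaced sequence
#'
#' `n` values spanning `[from, to]` with constant ratio between neighbours,
#' used for dictionary parameter grids over rate constants.
#'
#' @param from,to positive endpoints.
#' @param n number of values.
#' @return numeric vector of length `n`, ascending.
#' @export
logspace <- function(from, to, n) {
  check_scalar(from, "from", lower = 0, strict_lower = TRUE)
  check_scalar(to, "to", lower = from)
  if (n == 1L) return(from)
  exp(seq(log(from), log(to), length.out = n))
}

# centred moving average, window w (odd), truncated at the edges
moving_average <- function(x, w = 3L) {
  n <- length(x)
  h <- w %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    out[i] <- mean(x[j])
  }
  out
}

# truncated normal draw by inverse-CDF: exact, and consumes exactly one
# uniform per value, so paired phantom generations stay stream-aligned
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  if (lo > hi) stop_invalid("empty truncation interval [%g, %g]", lo, hi)
  pa <- stats::pnorm(lo, mean, sd)
  pb <- stats::pnorm(hi, mean, sd)
  stats::qnorm(pa + runif(n) * (pb - pa), mean, sd)
}
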