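# Independent oracles used across the suite. These deliberately do not share
# code with the package internals they check.

# classic fixed-step 4th-order Runge-Kutta on the exchange ODE pair
rk4_compartments <- function(k12, k23, c1, t_end, h = 0.01,
                             y0 = c(0, 0)) {
  f <- function(y) c(k12 * (c1 - y[1]) - k23 * (y[1] - y[2]),
                     k23 * (y[1] - y[2]))
  y <- y0
  n <- round(t_end / h)
  for (i in seq_len(n)) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# brute-force double-loop dictionary matcher (no vectorisation, no shared code)
brute_force_match <- function(s, entries) {
  best_row <- NA_integer_; best_res <- Inf; best_scale <- NA_real_
  for (i in seq_len(nrow(entries))) {
    d <- entries[i, ]
    a <- sum(s * d) / sum(d * d)
    if (a < 0) a <- 0
    res <- sqrt(sum((s - a * d)^2))
    if (res < best_res) { best_res <- res; best_row <- i; best_scale <- a }
  }
  list(row = best_row, scale = best_scale, residual = best_res)
}

# rasterise filled disks onto a constant background
draw_disks <- function(dim, centers, radius, fg = 200, bg = 10) {
  img <- matrix(bg, dim[1], dim[2])
  for (i in seq_len(nrow(centers))) {
    xs <- seq_len(dim[1]); ys <- seq_len(dim[2])
    d2 <- outer((xs - centers[i, 1])^2, (ys - centers[i, 2])^2, "+")
    img[d2 <= radius^2] <- fg
  }
  img
}

# small phantom configuration shared by the volume-level tests
small_phantom_cfg <- function(...) {
  phantom_config(shape = c(24L, 24L, 2L), r_c1 = 2, r_labyrinth = 5,
                 r_junctional = 8, r_decidua = 11, ...)
}
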