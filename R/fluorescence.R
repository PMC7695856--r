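# disk rasteriser shared by the fluorescence generators
render_disks <- function(dim, centers, radii, value = 1) {
  img <- matrix(0, dim[1], dim[2])
  if (!nrow(centers)) return(img)
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]
    x0 <- centers[i, 1]; y0 <- centers[i, 2]
    xs <- max(1L, floor(x0 - r)):min(dim[1], ceiling(x0 + r))
    ys <- max(1L, floor(y0 - r)):min(dim[2], ceiling(y0 + r))
    d2 <- outer((xs - x0)^2, (ys - y0)^2, "+")
    img[xs, ys][d2 <= r^2] <- value
  }
  img
}

disk_area_px <- function(dim, center, radius) {
  xs <- max(1L, floor(center[1] - radius)):min(dim[1], ceiling(center[1] + radius))
  ys <- max(1L, floor(center[2] - radius)):min(dim[2], ceiling(center[2] + radius))
  sum(outer((xs - center[1])^2, (ys - center[2])^2, "+") <= radius^2)
}

#' Generate a two-channel fluorescence fixture with known aggregates
#'
#' Emulates a histological section imaged in two channels: blue (nuclear
#' stain; Poisson-placed nucleus disks) and green (contrast-agent
#' aggregates as disks of known geometry) over an elliptical placenta. The
#' per-phase aggregate densities mirror the relative area coverage
#' measured across the kinetic phases (elevation 1.73%, reduction 6.72%,
#' recovery 2.1% of placental area), with the reduction phase also carrying
#' larger aggregates. Aggregates are placed with a minimum separation and
#' kept disjoint from nuclei, so segmentation can recover them exactly.
#'
#' @param phase `"elevation"`, `"reduction"` or `"recovery"`; sets the
#'   target relative aggregate area and the aggregate size distribution.
#' @param seed integer RNG seed.
#' @param dim image size in pixels (default 512 x 512).
#' @param pixel_size pixel edge length, micrometres (default 2).
#' @param n_nuclei number of nucleus disks (default 300).
#' @param diameters_um optional vector of exact aggregate diameters in
#'   micrometres; overrides the phase-dependent random sizes (the phase
#'   then only labels the output).
#' @return list with `green`, `blue` (integer intensity matrices),
#'   `pixel_size`, `phase`, and `truth`: a data.frame of aggregate centres
#'   (pixels), radii (pixels) and rendered areas (um^2), plus
#'   `placenta_area_um2` of the true ellipse.
#' @export
generate_fluorescence_fixture <- function(phase = c("elevation", "reduction",
                                                    "recovery"),
                                          seed = 1L,
                                          dim = c(512L, 512L),
                                          pixel_size = 2,
                                          n_nuclei = 300L,
                                          diameters_um = NULL) {
  phase <- match.arg(phase)
  set.seed(as.integer(seed))
  target_rel <- c(elevation = 0.0173, reduction = 0.0672,
                  recovery = 0.021)[[phase]]
  mean_diam_um <- c(elevation = 20, reduction = 38, recovery = 30)[[phase]]

  cx <- dim[1] / 2; cy <- dim[2] / 2
  ax <- 0.44 * dim[1]; ay <- 0.40 * dim[2]
  xg <- matrix(seq_len(dim[1]), dim[1], dim[2])
  yg <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  inside <- ((xg - cx) / ax)^2 + ((yg - cy) / ay)^2 <= 1
  placenta_px <- sum(inside)

  in_ellipse <- function(x, y, margin) {
    ((x - cx) / (ax - margin))^2 + ((y - cy) / (ay - margin))^2 <= 1
  }

  # --- aggregates
  centers <- matrix(0, 0, 2); radii <- numeric(0)
  place <- function(r, min_gap = 3) {
    for (try in 1:400) {
      x <- runif(1, 1 + r, dim[1] - r); y <- runif(1, 1 + r, dim[2] - r)
      if (!in_ellipse(x, y, r + 2)) next
      if (nrow(centers) &&
          any(sqrt((centers[, 1] - x)^2 + (centers[, 2] - y)^2) <
              radii + r + min_gap)) next
      return(c(x, y))
    }
    NULL
  }
  if (!is.null(diameters_um)) {
    # largest first, so big disks still find room near the centre
    for (d in sort(diameters_um, decreasing = TRUE)) {
      r <- d / 2 / pixel_size
      p <- place(r)
      if (is.null(p)) stop_invalid("cannot place a %g um aggregate", d)
      centers <- rbind(centers, p); radii <- c(radii, r)
    }
  } else {
    target_px <- target_rel * placenta_px
    got <- 0
    while (got < target_px) {
      d_um <- exp(rnorm(1, log(mean_diam_um), 0.45))
      d_um <- min(max(d_um, 6), 220)
      r <- d_um / 2 / pixel_size
      p <- place(r)
      if (is.null(p)) break
      centers <- rbind(centers, p); radii <- c(radii, r)
      got <- got + pi * r^2
    }
  }
  areas_px <- vapply(seq_len(nrow(centers)), function(i)
    disk_area_px(dim, centers[i, ], radii[i]), 0)

  # --- nuclei, kept clear of aggregates
  nuc_centers <- matrix(0, 0, 2); nuc_radii <- numeric(0)
  tries <- 0L
  while (nrow(nuc_centers) < n_nuclei && tries < 40L * n_nuclei) {
    tries <- tries + 1L
    r <- runif(1, 3, 5)
    x <- runif(1, 1 + r, dim[1] - r); y <- runif(1, 1 + r, dim[2] - r)
    if (!in_ellipse(x, y, r + 2)) next
    if (nrow(centers) &&
        any(sqrt((centers[, 1] - x)^2 + (centers[, 2] - y)^2) <
            radii + r + 2)) next
    if (nrow(nuc_centers) &&
        any(sqrt((nuc_centers[, 1] - x)^2 + (nuc_centers[, 2] - y)^2) <
            nuc_radii + r + 2)) next
    nuc_centers <- rbind(nuc_centers, c(x, y)); nuc_radii <- c(nuc_radii, r)
  }

  # moderate tissue autofluorescence keeps the mean-threshold placenta
  # boundary at the 50% blur crossing, i.e. at the true ellipse edge
  green <- matrix(45L * inside, dim[1], dim[2])
  agg_mask <- render_disks(dim, centers, radii, value = 1) > 0
  green[agg_mask] <- 220L
  blue <- matrix(60L * inside, dim[1], dim[2])
  nuc_mask <- render_disks(dim, nuc_centers, nuc_radii, value = 1) > 0
  blue[nuc_mask] <- 200L
  storage.mode(green) <- "integer"; storage.mode(blue) <- "integer"

  truth <- data.frame(
    x = if (nrow(centers)) centers[, 1] else numeric(),
    y = if (nrow(centers)) centers[, 2] else numeric(),
    radius_px = radii,
    area_um2 = areas_px * pixel_size^2)
  list(green = green, blue = blue, pixel_size = pixel_size, phase = phase,
       truth = truth,
       placenta_area_um2 = placenta_px * pixel_size^2)
}
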