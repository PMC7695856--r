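#' Automatic histogram thresholding (Renyi entropy, Kapur maximum entropy, mean)
#'
#' Thresholds are computed from a 256-bin histogram of the image after
#' min-max rescaling to \[0, 255\], following the conventions of the Fiji
#' Auto-Threshold plugin (first maximising bin wins; foreground = intensity
#' strictly above the threshold bin).
#'
#' * `"renyi"` maximises the sum of the order-`alpha` Renyi entropies of the
#'   background and foreground grey-level distributions,
#'   \eqn{H_\alpha(p) = \frac{1}{1-\alpha}\log \sum_i p_i^\alpha}
#'   (default `alpha = 2`);
#' * `"maxentropy"` is the Kapur-Sahoo-Wong criterion, i.e. the Shannon
#'   limit `alpha -> 1` of the same functional;
#' * `"mean"` uses the mean grey level as the threshold.
#'
#' @param img numeric matrix of intensities (>= 0).
#' @param method one of `"renyi"`, `"maxentropy"`, `"mean"`.
#' @param alpha Renyi entropy order (ignored by the other methods).
#' @return the threshold on the rescaled 0..255 scale, or `NA` for a
#'   constant image (no threshold exists).
#' @export
auto_threshold <- function(img, method = c("renyi", "maxentropy", "mean"),
                           alpha = 2) {
  method <- match.arg(method)
  v <- as.numeric(img)
  if (!length(v) || anyNA(v)) stop_invalid("'img' must be numeric without NA")
  rng <- range(v)
  if (rng[1] == rng[2]) return(NA_real_)
  g <- pmin(pmax(round((v - rng[1]) / (rng[2] - rng[1]) * 255), 0), 255)
  h <- tabulate(g + 1L, nbins = 256L)
  p <- h / sum(h)
  if (method == "mean") return(sum((0:255) * p))

  P <- cumsum(p)
  crit <- rep(-Inf, 256L)
  for (t in 1:254) {
    Pt <- P[t + 1L]
    if (Pt <= 0 || Pt >= 1) next
    pb <- p[1:(t + 1L)] / Pt
    pf <- p[(t + 2L):256L] / (1 - Pt)
    pb <- pb[pb > 0]; pf <- pf[pf > 0]
    crit[t + 1L] <- if (method == "maxentropy") {
      -sum(pb * log(pb)) - sum(pf * log(pf))
    } else {
      (log(sum(pb^alpha)) + log(sum(pf^alpha))) / (1 - alpha)
    }
  }
  which.max(crit) - 1L                      # first maximising bin
}

# rescale to the 0..255 grey scale used by the thresholds
rescale255 <- function(img) {
  rng <- range(img)
  if (rng[1] == rng[2]) return(array(0, dim(img)))
  (img - rng[1]) / (rng[2] - rng[1]) * 255
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so components that
# touch only diagonally are merged afterwards with a union-find pass
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  m <- as.matrix(lab)
  n <- max(m)
  if (n < 2L) return(m)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(m); nc <- ncol(m)
  a <- m[-nr, -nc]; b <- m[-1, -1]          # down-right diagonal pairs
  sel <- which(a > 0 & b > 0 & a != b)
  for (s in sel) union2(a[s], b[s])
  a <- m[-1, -nc]; b <- m[-nr, -1]          # up-right diagonal pairs
  sel <- which(a > 0 & b > 0 & a != b)
  for (s in sel) union2(a[s], b[s])
  roots <- vapply(seq_len(n), find, 0L)
  relab <- match(roots, sort(unique(roots)))
  out <- m
  out[m > 0] <- relab[m[m > 0]]
  out
}

#' Segment nuclei from the nuclear-stain channel
#'
#' Pipeline: difference-of-Gaussians band-pass (sigmas `sigma_low`,
#' `sigma_high`), Renyi-entropy threshold, hole filling, then watershed on
#' the distance transform to split touching nuclei.
#'
#' @param blue 2D numeric matrix (nuclear-stain intensities).
#' @param sigma_low,sigma_high band-pass standard deviations in pixels
#'   (defaults 1 and 15).
#' @param alpha Renyi entropy order (default 2).
#' @return integer label matrix (0 = background); a constant input yields an
#'   all-zero (empty) mask.
#' @export
segment_nuclei <- function(blue, sigma_low = 1, sigma_high = 15, alpha = 2) {
  if (length(dim(blue)) != 2L || !length(blue))
    stop_invalid("'blue' must be a nonempty 2D matrix")
  if (min(blue) == max(blue)) return(array(0L, dim(blue)))
  # the Gaussian kernel (2*ceil(3*sigma)+1 wide) must fit inside the image
  sigma_high <- min(sigma_high, (min(dim(blue)) - 3) / 6)
  sigma_low <- min(sigma_low, sigma_high / 2)
  img <- EBImage::Image(blue / max(blue))
  dog <- EBImage::gblur(img, sigma = sigma_low) -
    EBImage::gblur(img, sigma = sigma_high)
  d <- rescale255(as.matrix(dog))
  thr <- auto_threshold(d, "renyi", alpha = alpha)
  if (is.na(thr)) return(array(0L, dim(blue)))
  mask <- EBImage::fillHull(EBImage::Image(round(d) > thr))
  if (sum(mask) == 0) return(array(0L, dim(blue)))
  ws <- EBImage::watershed(EBImage::distmap(mask), tolerance = 1, ext = 1)
  m <- as.matrix(ws)
  storage.mode(m) <- "integer"
  m
}

#' Segment contrast-agent aggregates from the green channel
#'
#' Kapur maximum-entropy threshold, exclusion of nucleus pixels,
#' 8-connected component labelling, removal of components below 5 square
#' micrometres, then per-aggregate morphology: area, perimeter, equivalent
#' circular diameter and a size class (`small` < 50 um diameter,
#' `medium` in \[50, 500\], `large` > 500 um; the boundary values fold into
#' `medium`).
#'
#' @param green 2D numeric matrix (aggregate-label intensities).
#' @param nuclei nucleus mask/labels from [segment_nuclei()] (or `NULL`).
#' @param pixel_size pixel edge length, micrometres.
#' @param min_area_um2 minimum retained aggregate area (default 5).
#' @return list with `labels` (integer matrix) and `table` (data.frame:
#'   `id`, `area_um2`, `perimeter_um`, `equiv_diameter_um`, `size_class`).
#' @export
segment_aggregates <- function(green, nuclei = NULL, pixel_size,
                               min_area_um2 = 5) {
  if (length(dim(green)) != 2L) stop_invalid("'green' must be a 2D matrix")
  check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  empty <- list(labels = array(0L, dim(green)),
                table = data.frame(id = integer(), area_um2 = numeric(),
                                   perimeter_um = numeric(),
                                   equiv_diameter_um = numeric(),
                                   size_class = character()))
  thr <- auto_threshold(green, "maxentropy")
  if (is.na(thr)) return(empty)
  mask <- round(rescale255(green)) > thr
  if (!is.null(nuclei)) mask[nuclei > 0] <- FALSE
  if (!any(mask)) return(empty)
  lab <- label_components8(mask)
  areas_px <- tabulate(lab[lab > 0])
  keep <- which(areas_px * pixel_size^2 >= min_area_um2)
  if (!length(keep)) return(empty)
  relab <- array(0L, dim(lab))
  relab[lab > 0] <- match(lab[lab > 0], keep, nomatch = 0L)
  feats <- EBImage::computeFeatures.shape(relab)
  area <- feats[, "s.area"] * pixel_size^2
  perim <- feats[, "s.perimeter"] * pixel_size
  eqd <- 2 * sqrt(area / pi)
  cls <- ifelse(eqd < 50, "small", ifelse(eqd > 500, "large", "medium"))
  list(labels = relab,
       table = data.frame(id = seq_along(area), area_um2 = area,
                          perimeter_um = perim, equiv_diameter_um = eqd,
                          size_class = cls, row.names = NULL))
}

#' Segment the whole placenta from the combined channels
#'
#' Each channel is min-max rescaled to 8-bit, the two are averaged, blurred
#' with a Gaussian (`sigma`), thresholded with the mean method and cleaned
#' with morphological closing (disc radius `close_radius`) and hole filling.
#'
#' @param green,blue matching 2D numeric matrices.
#' @param sigma Gaussian blur standard deviation, pixels (default 10).
#' @param close_radius closing disc radius, pixels (default 5).
#' @return logical matrix; empty for constant input.
#' @export
segment_placenta <- function(green, blue, sigma = 10, close_radius = 5) {
  if (!all(dim(green) == dim(blue)))
    stop_invalid("channel shapes differ")
  comb <- (rescale255(green) + rescale255(blue)) / 2
  if (min(comb) == max(comb)) return(array(FALSE, dim(green)))
  sm <- as.matrix(EBImage::gblur(EBImage::Image(comb / 255), sigma = sigma)) * 255
  thr <- auto_threshold(sm, "mean")
  mask <- EBImage::Image(round(rescale255(sm)) > thr)
  brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
  mask <- EBImage::fillHull(EBImage::closing(mask, brush))
  array(as.matrix(mask) > 0, dim(green))
}

#' Placenta-normalised aggregate statistics
#'
#' Totals, per-size-class breakdowns and quantities normalised by placental
#' area: the relative aggregate area is the total aggregate area divided by
#' the placenta area, and the relative count is the number of aggregates per
#' square micrometre of placenta.
#'
#' @param table aggregate table from [segment_aggregates()].
#' @param placenta placenta mask from [segment_placenta()].
#' @param pixel_size pixel edge length, micrometres.
#' @return an object of class `placenta_stats` (a list of the summary
#'   quantities).
#' @export
quantify_aggregates <- function(table, placenta, pixel_size) {
  check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  placenta_area <- sum(placenta > 0) * pixel_size^2
  if (placenta_area <= 0)
    stop_invalid("empty placenta mask: normalisation by area is undefined")
  classes <- c("small", "medium", "large")
  n_cls <- setNames(numeric(3), classes)
  a_cls <- setNames(numeric(3), classes)
  for (cl in classes) {
    sel <- table$size_class == cl
    n_cls[cl] <- sum(sel)
    a_cls[cl] <- sum(table$area_um2[sel])
  }
  total_area <- sum(table$area_um2)
  structure(list(
    n_aggregates = nrow(table),
    total_area_um2 = total_area,
    placenta_area_um2 = placenta_area,
    relative_area = total_area / placenta_area,
    relative_count_per_um2 = nrow(table) / placenta_area,
    count_by_class = n_cls,
    area_by_class_um2 = a_cls,
    relative_area_by_class = a_cls / placenta_area,
    relative_count_by_class_per_um2 = n_cls / placenta_area),
    class = "placenta_stats")
}

#' @export
print.placenta_stats <- function(x, ...) {
  cat(sprintf(
    "placenta_stats: %d aggregates, %.0f um^2 total over %.0f um^2 placenta (relative area %.4f)\n",
    x$n_aggregates, x$total_area_um2, x$placenta_area_um2, x$relative_area))
  cat("  counts by class: ",
      paste(sprintf("%s=%d", names(x$count_by_class), x$count_by_class),
            collapse = ", "), "\n")
  invisible(x)
}

#' Run the full histology quantification on a two-channel image
#'
#' Convenience wrapper: nuclei from the blue channel, aggregates from the
#' green channel with nuclei excluded, whole-placenta mask from the
#' combination, then placenta-normalised statistics.
#'
#' @param green,blue matching 2D numeric matrices.
#' @param pixel_size pixel edge length, micrometres.
#' @param ... passed to the individual segmentation steps.
#' @return list with `nuclei`, `aggregates` (labels + table), `placenta`
#'   and `stats`.
#' @export
histology_pipeline <- function(green, blue, pixel_size, ...) {
  nuc <- segment_nuclei(blue, ...)
  agg <- segment_aggregates(green, nuc, pixel_size)
  pla <- segment_placenta(green, blue)
  list(nuclei = nuc, aggregates = agg, placenta = pla,
       stats = quantify_aggregates(agg$table, pla, pixel_size))
}
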