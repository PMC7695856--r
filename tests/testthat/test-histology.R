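test_that("entropy thresholds split a spiked histogram at the expected bin", {
  # three grey levels: dark background, mid tissue, sparse bright foreground
  img <- matrix(c(rep(0, 5000), rep(90, 4000), rep(255, 300)), ncol = 100)
  thr <- auto_threshold(img, "maxentropy")
  expect_true(thr >= 90 && thr < 255)
  thr2 <- auto_threshold(img, "renyi")
  expect_true(thr2 >= 90 && thr2 < 255)
  expect_equal(auto_threshold(img, "mean"),
               mean(round(as.numeric(img))), tolerance = 1e-9)
  expect_true(is.na(auto_threshold(matrix(7, 10, 10), "maxentropy")))
})

test_that("blank and constant channels give empty segmentations", {
  z <- matrix(0, 60, 60)
  expect_equal(max(segment_nuclei(z)), 0)
  agg <- segment_aggregates(z, NULL, pixel_size = 2)
  expect_equal(nrow(agg$table), 0)
  expect_false(any(segment_placenta(z, z)))
})

test_that("separated nuclei are counted exactly and touching nuclei are split", {
  set.seed(9)
  ctr <- matrix(0, 0, 2)
  while (nrow(ctr) < 30) {
    p <- runif(2, 15, 285)
    if (nrow(ctr) && any(sqrt(colSums((t(ctr) - p)^2)) < 26)) next
    ctr <- rbind(ctr, p)
  }
  img <- draw_disks(c(300, 300), ctr, radius = 6)
  expect_equal(max(segment_nuclei(img)), 30L)
  # two disks overlapping through a thin neck are separated by the watershed
  two <- draw_disks(c(100, 100), rbind(c(38, 50), c(62, 50)), radius = 12)
  expect_equal(max(segment_nuclei(two)), 2L)
})

test_that("aggregate size classes follow the equivalent-diameter boundaries", {
  fx <- generate_fluorescence_fixture("reduction", seed = 3,
                                      dim = c(1024L, 1024L),
                                      diameters_um = c(20, 100, 600))
  res <- histology_pipeline(fx$green, fx$blue, fx$pixel_size)
  tab <- res$aggregates$table
  expect_equal(nrow(tab), 3L)
  tab <- tab[order(tab$area_um2), ]
  expect_equal(tab$size_class, c("small", "medium", "large"))
  expect_equal(tab$equiv_diameter_um, c(20, 100, 600), tolerance = 0.05)
})

test_that("sub-threshold specks are removed by the 5 um^2 area filter", {
  img <- matrix(10, 200, 200)
  img[100, 100] <- 200                      # 1 px = 4 um^2 at 2 um pixels
  img[30:40, 30:40] <- 200                  # clearly above the filter
  agg <- segment_aggregates(img, NULL, pixel_size = 2)
  expect_equal(nrow(agg$table), 1L)
  expect_gt(agg$table$area_um2[1], 100)
})

test_that("aggregate pixels honour the green mask and nucleus exclusion", {
  fx <- generate_fluorescence_fixture("reduction", seed = 17)
  nuc <- segment_nuclei(fx$blue)
  agg <- segment_aggregates(fx$green, nuc, fx$pixel_size)
  inside <- agg$labels > 0
  expect_true(all(fx$green[inside] > 45))   # strictly brighter than tissue
  expect_true(!any(nuc[inside] > 0))
  # class counts partition the table
  expect_equal(sum(agg$table$size_class %in% c("small", "medium", "large")),
               nrow(agg$table))
})

test_that("pixel-size rescaling scales areas quadratically and keeps counts", {
  fx <- generate_fluorescence_fixture("elevation", seed = 19)
  a2 <- segment_aggregates(fx$green, NULL, pixel_size = 2)
  a4 <- segment_aggregates(fx$green, NULL, pixel_size = 4)
  expect_equal(nrow(a2$table), nrow(a4$table))
  expect_equal(a4$table$area_um2, 4 * a2$table$area_um2, tolerance = 1e-12)
})

test_that("the placenta mask recovers the ellipse area and ignores global gain", {
  fx <- generate_fluorescence_fixture("elevation", seed = 23)
  m <- segment_placenta(fx$green, fx$blue)
  est <- sum(m) * fx$pixel_size^2
  expect_lt(abs(est - fx$placenta_area_um2) / fx$placenta_area_um2, 0.05)
  m2 <- segment_placenta(fx$green * 3.5, fx$blue * 3.5)
  expect_identical(m, m2)
})

test_that("placenta-normalised statistics follow their definitions", {
  tab <- data.frame(id = 1:3, area_um2 = rep(100, 3),
                    perimeter_um = rep(35, 3),
                    equiv_diameter_um = rep(11.3, 3),
                    size_class = rep("small", 3))
  placenta <- matrix(TRUE, 50, 50)          # 10,000 um^2 at 2 um pixels
  st <- quantify_aggregates(tab, placenta, pixel_size = 2)
  expect_equal(st$relative_area, 0.03)
  expect_equal(st$relative_count_per_um2, 3e-4)
  expect_equal(unname(st$count_by_class["small"]), 3)
  empty <- tab[0, ]
  st0 <- quantify_aggregates(empty, placenta, pixel_size = 2)
  expect_equal(st0$n_aggregates, 0)
  expect_equal(st0$relative_area, 0)
  expect_error(quantify_aggregates(tab, matrix(FALSE, 5, 5), 2), "empty")
})

test_that("phase fixtures reproduce the reduction > recovery > elevation ordering", {
  rel <- vapply(c("elevation", "reduction", "recovery"), function(phz) {
    f <- generate_fluorescence_fixture(phz, seed = 29)
    r <- histology_pipeline(f$green, f$blue, f$pixel_size)
    r$stats$relative_area
  }, 0)
  expect_gt(rel[["reduction"]], rel[["recovery"]])
  expect_gt(rel[["recovery"]], rel[["elevation"]])
})
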