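# Morphology features against exact shape oracles.

test_that("rasterized disk has circular geometry", {
  lab <- make_disk_label(20)
  m <- computeMorphology(lab, lab, blank_field(lab))
  expect_lt(abs(m$cell_area_um2 - pi * 400) / (pi * 400), 0.02)
  expect_equal(m$width_to_length, 1, tolerance = 0.02)
  expect_gte(m$roundness, 0.85)
})

test_that("10x40 rectangle matches exact second-moment oracle", {
  lab <- make_rect_label(10, 40)
  m <- computeMorphology(lab, lab, blank_field(lab))
  # exact discrete moments of an h x w pixel grid: var = (n^2 - 1)/12
  wl_exact <- sqrt((10^2 - 1) / (40^2 - 1))
  expect_equal(m$width_to_length, wl_exact, tolerance = 1e-9)
  expect_equal(m$width_to_length, 0.25, tolerance = 0.02)
  expect_lt(m$roundness, 0.7)
  expect_equal(m$cell_area_um2, 400)
})

test_that("disk is rounder than the equal-area rectangle", {
  disk <- make_disk_label(20)                      # ~1257 px
  rect <- make_rect_label(21, 60)                  # 1260 px
  md <- computeMorphology(disk, disk, blank_field(disk))
  mr <- computeMorphology(rect, rect, blank_field(rect))
  expect_gt(md$roundness, mr$roundness)
})

test_that("features are invariant to translation and 90-degree rotation", {
  a <- make_rect_label(10, 40, size = c(60, 80), at = c(20, 20))
  b <- make_rect_label(10, 40, size = c(60, 80), at = c(31, 27))
  c90 <- make_rect_label(40, 10, size = c(80, 60), at = c(20, 20))
  fa <- computeMorphology(a, a, blank_field(a))
  fb <- computeMorphology(b, b, blank_field(b))
  fc <- computeMorphology(c90, c90, blank_field(c90))
  for (col in c("cell_area_um2", "roundness", "width_to_length")) {
    expect_equal(fa[[col]], fb[[col]], tolerance = 1e-12)
    expect_equal(fa[[col]], fc[[col]], tolerance = 0.02)
  }
  # same holds for an anti-symmetric shape: disk quadrant
  d1 <- make_disk_label(15)
  d2 <- t(d1)
  f1 <- computeMorphology(d1, d1, blank_field(d1))
  f2 <- computeMorphology(d2, d2, blank_field(d2))
  expect_equal(f1$roundness, f2$roundness, tolerance = 0.02)
})

test_that("pixel size scales areas quadratically", {
  lab <- make_disk_label(10)
  img2 <- imageField(list(nuclear = matrix(0, nrow(lab), ncol(lab))),
                     pixelSize = 0.5)
  m1 <- computeMorphology(lab, lab, blank_field(lab))
  m2 <- computeMorphology(lab, lab, img2)
  expect_equal(m2$cell_area_um2, m1$cell_area_um2 * 0.25)
  expect_equal(m2$roundness, m1$roundness)     # dimensionless
})

test_that("tiny objects are excluded", {
  lab <- make_disk_label(20)
  lab[1:2, 1:3] <- 2L                           # 6-pixel speck
  expect_message(m <- computeMorphology(lab, lab, blank_field(lab)),
                 "excluded")
  expect_equal(m$label, 1L)
})

test_that("feature distributions: histogram, summary and shift property", {
  rec <- data.frame(nuclear_area = c(rep(200, 10), rep(600, 10)),
                    time_h = rep(c(0, 24), each = 10))
  fd <- featureDistributions(rec, "nuclear_area", bins = 10)
  expect_equal(sum(fd$histogram$count), 20)
  expect_equal(fd$summary$iqr, c(0, 0))
  # identical records give a single occupied bin per group
  expect_equal(sum(fd$histogram$count[fd$histogram$group == "0"] > 0), 1L)
  # translation equivariance of the median
  rec2 <- rec; rec2$nuclear_area <- rec2$nuclear_area + 100
  fd2 <- featureDistributions(rec2, "nuclear_area", bins = 10)
  expect_equal(fd2$summary$median, fd$summary$median + 100)
  expect_error(featureDistributions(rec, "no_such"), "unknown feature")
})

test_that("two-type mixture shows both modes at the generator means", {
  set.seed(9)
  rec <- data.frame(area = c(rnorm(300, 200, 20), rnorm(300, 600, 40)),
                    type = rep(c("a", "b"), each = 300))
  fd <- featureDistributions(rec, "area", bins = 30, by = "type")
  med <- fd$summary$median
  expect_lt(abs(med[1] - 200) / 200, 0.1)
  expect_lt(abs(med[2] - 600) / 600, 0.1)
  fd2 <- featureDistributions(rec, "area", bins = 10, by = "type",
                              feature2 = "area")
  expect_equal(sum(fd2$density2d[["a"]]), 300L)
})
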