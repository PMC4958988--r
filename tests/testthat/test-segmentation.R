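# Nuclear and cell segmentation against generator ground truth.

test_that("well-separated nuclei are each detected once", {
  out <- renderField(synthImageSpec(nCells = c(tumor = 50L),
                                    fractionDead = 0,
                                    touchingPairFraction = 0,
                                    noiseSd = 2, seed = 21))
  seg <- segmentNuclei(out$field, segmentationParams())
  expect_equal(sum(seg$records$qc_pass), 50)
  # every detection sits on a distinct true object
  m <- match_to_truth(seg, out)
  expect_false(anyNA(m$truth_id))
  expect_equal(length(unique(m$truth_id)), 50)
})

test_that("de-clumping splits touching pairs; without it they merge", {
  out <- renderField(synthImageSpec(nCells = c(a = 20L),
                                    nucleusRadiusMean = 8,
                                    nucleusRadiusSd = 0.1,
                                    touchingPairFraction = 1,
                                    fractionDead = 0, noiseSd = 1,
                                    seed = 3))
  segT <- segmentNuclei(out$field, segmentationParams())
  segF <- segmentNuclei(out$field, segmentationParams(declump = FALSE))
  nT <- sum(segT$records$qc_pass)
  expect_lte(sum(segF$records$qc_pass), 10)
  # nearly all pairs resolved (overlaps at the 1.2-radius extreme can
  # resist splitting); every detection matched within one radius
  expect_gte(nT, 18)
  expect_lte(nT, 21)
  rec <- segT$records[segT$records$qc_pass, ]
  d2 <- outer(rec$centroid_row, out$objects$row, "-")^2 +
    outer(rec$centroid_col, out$objects$col, "-")^2
  nearest <- apply(d2, 1, which.min)
  expect_true(all(sqrt(d2[cbind(seq_len(nrow(rec)), nearest)]) <=
                    out$objects$nucleus_radius_px[nearest]))
})

test_that("blank image yields zero records with a warning", {
  img <- imageField(list(nuclear = matrix(100, 64, 64)))
  expect_warning(seg <- segmentNuclei(img, segmentationParams()),
                 "blank")
  expect_equal(nrow(seg$records), 0L)
  expect_true(seg$blank)
})

test_that("missing nuclear channel is a configuration error", {
  img <- imageField(list(gfp = matrix(0, 32, 32)))
  expect_error(segmentNuclei(img, segmentationParams()), "configuration")
})

test_that("size filter and border policy set qc_pass, not removal", {
  out <- renderField(synthImageSpec(nCells = c(tumor = 30L),
                                    touchingPairFraction = 0,
                                    noiseSd = 2, seed = 22))
  seg <- segmentNuclei(out$field,
                       segmentationParams(minNuclearArea = 50,
                                          maxNuclearArea = 120))
  # tight max area: most nuclei (~r=8 -> ~200 um^2) now fail QC but stay
  expect_true(any(!seg$records$qc_pass))
  expect_true(all(seg$records$qc_reason[!seg$records$qc_pass] != ""))
  expect_true(all(seg$records$area_um2[seg$records$qc_pass] <= 120))
})

test_that("background ring is measured outside nuclei at background level", {
  out <- renderField(synthImageSpec(nCells = c(tumor = 25L),
                                    touchingPairFraction = 0,
                                    noiseSd = 0, seed = 23))
  seg <- segmentNuclei(out$field, segmentationParams())
  rec <- seg$records[seg$records$qc_pass, ]
  # dead-channel ring mean must sit at the (noiseless) background 100,
  # never contaminated by any nucleus' plateau
  expect_true(all(abs(rec$bg_dead - 100) < 1))
})

test_that("label maps and records are deterministic", {
  out <- renderField(synthImageSpec(seed = 24))
  a <- segmentNuclei(out$field, segmentationParams())
  b <- segmentNuclei(out$field, segmentationParams())
  expect_identical(a$labelMap, b$labelMap)
  expect_identical(a$records, b$records)
})

test_that("cell segmentation recovers the rasterized cell-body area", {
  out <- renderField(synthImageSpec(
    nCells = c(tumor = 1L), fieldSize = c(128L, 128L),
    nucleusRadiusMean = 8, nucleusRadiusSd = 0.01,
    cellRadiusMean = 20, cellRadiusSd = 0.01,
    fractionDead = 0, touchingPairFraction = 0, noiseSd = 2, seed = 5))
  p <- segmentationParams(cytoplasmChannel = "cyto")
  seg <- segmentNuclei(out$field, p)
  cells <- segmentCells(out$field, seg, p)
  expect_equal(nrow(cells$records), 1L)
  expect_lt(abs(cells$records$cell_area_um2 - pi * 400) / (pi * 400), 0.1)
})

test_that("adjacent cells get disjoint regions containing their seeds", {
  out <- renderField(synthImageSpec(seed = 8))
  p <- segmentationParams(cytoplasmChannel = "cyto")
  seg <- segmentNuclei(out$field, p)
  cells <- segmentCells(out$field, seg, p)
  lm <- cells$labelMap; nm <- seg$labelMap
  for (L in cells$records$label) {
    u <- unique(lm[nm == L])
    expect_identical(u, L)         # nucleus fully inside its own cell
  }
})

test_that("cell segmentation without a cytoplasm channel is refused", {
  out <- renderField(synthImageSpec(nCells = c(tumor = 5L),
                                    fieldSize = c(256L, 256L), seed = 2))
  seg <- segmentNuclei(out$field, segmentationParams())
  expect_error(segmentCells(out$field, seg, segmentationParams()),
               "configuration")
})
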