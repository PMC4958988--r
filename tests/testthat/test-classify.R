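# Fluorescence gating and the linear subpopulation classifier.

test_that("fluorescence gating handles single, ambiguous, unlabeled", {
  rec <- data.frame(mean_RFP = c(500, 50, 500, 100),
                    mean_GFP = c(50, 400, 400, 100))
  expect_identical(classifyByFluorescence(rec, c(RFP = 200, GFP = 200)),
                   c("RFP", "GFP", "ambiguous", "unlabeled"))
})

test_that("gating matches ground truth on a rendered two-label field", {
  # compact cell bodies: nucleus spacing then guarantees no neighbour's
  # fluorescence halo reaches another cell's nuclear mask
  out <- renderField(synthImageSpec(nCells = c(tumor = 25L, stroma = 25L),
                                    nucleusRadiusMean = 8,
                                    cellRadiusMean = 10,
                                    touchingPairFraction = 0,
                                    noiseSd = 2, seed = 51))
  seg <- segmentNuclei(out$field, segmentationParams())
  m <- match_to_truth(seg, out)
  ok <- !is.na(m$truth_id)
  labels <- classifyByFluorescence(m[ok, ], c(RFP = 300, GFP = 300))
  truth <- out$objects$label_channel[m$truth_id[ok]]
  expect_equal(mean(labels == truth), 1)
})

test_that("a 6-sd feature is ranked first and nearly Bayes-optimal", {
  set.seed(61)
  n <- 300
  pop <- data.frame(
    signal = c(rnorm(n, 0), rnorm(n, 6)),       # 6 sd separation
    junk1 = rnorm(2 * n), junk2 = rnorm(2 * n), junk3 = rnorm(2 * n),
    junk4 = rnorm(2 * n), junk5 = rnorm(2 * n))
  y <- rep(c("a", "b"), each = n)
  m <- trainLinearClassifier(pop, y, nTrainPerClass = 100, kFeatures = 2,
                             seed = 61)
  expect_equal(m@features[1], "signal")
  pred <- applyClassifier(m, pop)
  expect_gt(mean(pred == y), 0.99)              # Bayes error ~ 0.13%
})

test_that("identical class distributions give chance-level accuracy", {
  set.seed(62)
  pop <- data.frame(a = rnorm(600), b = rnorm(600), c = rnorm(600),
                    d = rnorm(600), e = rnorm(600))
  y <- rep(c("x", "z"), each = 300)
  m <- trainLinearClassifier(pop, y, nTrainPerClass = 150, seed = 62)
  acc <- mean(applyClassifier(m, pop) == y)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 600))
})

test_that("agrees with an independent discriminant fit on clean data", {
  pop <- synthControlPopulations(150, seed = 63)
  sp <- split_controls(pop, 100, seed = 63)
  m <- trainLinearClassifier(sp$train, sp$train$true_class,
                             seed = 63, featureCols = feature_cols(pop))
  mine <- applyClassifier(m, sp$holdout)
  ld <- MASS::lda(sp$train[, m@features], grouping = sp$train$true_class)
  ref <- as.character(predict(ld, sp$holdout[, m@features])$class)
  expect_gt(mean(mine == ref), 0.97)
})

test_that("training is seeded-deterministic and self-consistent", {
  pop <- synthControlPopulations(150, seed = 64)
  m1 <- trainLinearClassifier(pop, pop$true_class, seed = 5,
                              featureCols = feature_cols(pop))
  m2 <- trainLinearClassifier(pop, pop$true_class, seed = 5,
                              featureCols = feature_cols(pop))
  expect_identical(m1@coefficients, m2@coefficients)
  # a record at a class centroid classifies to that class
  cent <- as.data.frame(t(colMeans(
    pop[pop$true_class == "tumor_dead", m1@features])))
  expect_identical(applyClassifier(m1, cent), "tumor_dead")
})

test_that("classification is invariant to affine feature rescaling", {
  pop <- synthControlPopulations(150, seed = 65)
  fc <- feature_cols(pop)
  m1 <- trainLinearClassifier(pop, pop$true_class, seed = 65,
                              featureCols = fc)
  pop2 <- pop
  pop2$rfp_mean <- pop2$rfp_mean * 1000 + 5      # arbitrary affine map
  m2 <- trainLinearClassifier(pop2, pop2$true_class, seed = 65,
                              featureCols = fc)
  expect_identical(applyClassifier(m1, pop), applyClassifier(m2, pop2))
})

test_that("degenerate and undersized training inputs error or warn", {
  pop <- synthControlPopulations(120, seed = 66)
  expect_error(trainLinearClassifier(pop, pop$true_class,
                                     nTrainPerClass = 500),
               "training error")
  pop$flat <- 1
  expect_warning(m <- trainLinearClassifier(pop, pop$true_class,
                                            seed = 66,
                                            featureCols = feature_cols(pop)),
                 "zero-variance")
  expect_false("flat" %in% m@features)
})

test_that("concordance: identity, disjoint, permutation symmetry", {
  a <- c("t", "f", "t", "f")
  expect_equal(concordance(a, a)$fraction, 1)
  expect_equal(concordance(a, c("x", "x", "x", "x"))$fraction, 0)
  set.seed(67)
  b <- sample(c("t", "f"), 4, replace = TRUE)
  p <- sample(4)
  expect_equal(concordance(a[p], b[p])$fraction,
               concordance(a, b)$fraction)
  expect_error(concordance(a, a[1:3]), "equal length")
  # confusion table totals
  cc <- concordance(a, c("t", "t", "f", "f"))
  expect_equal(sum(cc$confusion), 4)
})

test_that("JSON round trip reproduces the model bit-for-bit", {
  pop <- synthControlPopulations(120, seed = 68)
  m <- trainLinearClassifier(pop, pop$true_class, seed = 68,
                             featureCols = feature_cols(pop))
  path <- tempfile(fileext = ".json")
  writeClassifierModel(m, path)
  m2 <- readClassifierModel(path)
  expect_equal(m2@coefficients, m@coefficients)
  expect_identical(applyClassifier(m2, pop), applyClassifier(m, pop))
})
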