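# Synthetic image generator: ground truth, determinism, invariants.

test_that("empty spec renders blank images at background level", {
  spec <- synthImageSpec(nCells = c(tumor = 0L), noiseSd = 3,
                         backgroundLevel = 100, seed = 1)
  out <- renderField(spec)
  expect_equal(nrow(out$objects), 0L)
  for (ch in channelNames(out$field)) {
    x <- getChannel(out$field, ch)
    expect_equal(mean(x), 100, tolerance = 0.01)
    expect_equal(sd(x), 3, tolerance = 0.05)
  }
  expect_true(all(out$nucleusMap == 0L))
})

test_that("well-separated live cells give one component each, noiseless", {
  spec <- synthImageSpec(nCells = c(tumor = 50L), fractionDead = 0,
                         touchingPairFraction = 0, noiseSd = 0, seed = 2)
  out <- renderField(spec)
  expect_equal(nrow(out$objects), 50L)
  x <- getChannel(out$field, "nuclear")
  comp <- EBImage::bwlabel(x > 100 + 450)   # half the plateau amplitude
  expect_equal(max(comp), 50)
})

test_that("dead flags reproduce an independent replay of the seeded draw", {
  n <- 100L; fd <- 0.2; seed <- 77L
  spec <- synthImageSpec(nCells = c(tumor = n), fieldSize = c(768L, 768L),
                         fractionDead = fd, touchingPairFraction = 0,
                         seed = seed)
  out <- renderField(spec)
  # replay the generator's RNG prelude: type shuffle, two radius draws,
  # then the binomial alive draw
  set.seed(seed)
  type <- sample(rep("tumor", n))
  nr <- pmax(3, rnorm(n, spec@nucleusRadiusMean[type],
                      spec@nucleusRadiusSd[type]))
  pmax(nr + 2, rnorm(n, spec@cellRadiusMean[type],
                     spec@cellRadiusSd[type]))
  alive <- rbinom(n, 1L, 1 - fd) == 1L
  expect_identical(out$objects$alive, alive)
  expect_equal(sum(!out$objects$alive), sum(!alive))
})

test_that("identical spec and seed give bit-identical output", {
  spec <- synthImageSpec(nCells = c(tumor = 20L), seed = 9)
  a <- renderField(spec)
  b <- renderField(spec)
  expect_identical(a$objects, b$objects)
  expect_identical(a$nucleusMap, b$nucleusMap)
  for (ch in channelNames(a$field))
    expect_identical(getChannel(a$field, ch), getChannel(b$field, ch))
})

test_that("dead nuclei carry the dead-stain plateau over their mask", {
  spec <- synthImageSpec(nCells = c(tumor = 40L), fractionDead = 0.5,
                         noiseSd = 0, seed = 5)
  out <- renderField(spec)
  dch <- getChannel(out$field, "dead")
  for (i in out$objects$id) {
    m <- mean(dch[out$nucleusMap == i])
    lvl <- if (out$objects$alive[i]) spec@deadStainLiveLevel
           else spec@deadStainDeadLevel
    expect_gte(m, lvl - 1e-9)
  }
})

test_that("ground-truth dead fraction converges to fractionDead", {
  # pooled over 10 independent fields of 250 cells (n = 2500)
  fd <- 0.2
  dead <- vapply(1:10, function(s) {
    out <- renderField(synthImageSpec(
      nCells = c(tumor = 250L), fieldSize = c(1024L, 1024L),
      nucleusRadiusMean = 6, cellRadiusMean = 10,
      fractionDead = fd, seed = 100 + s))
    sum(!out$objects$alive)
  }, numeric(1))
  n <- 2500
  phat <- sum(dead) / n
  se <- sqrt(fd * (1 - fd) / n)
  expect_lt(abs(phat - fd), 3 * se)
})

test_that("overfull field raises a placement error", {
  spec <- synthImageSpec(nCells = c(tumor = 60L), fieldSize = c(96L, 96L),
                         seed = 3)
  expect_error(renderField(spec), "placement")
})

test_that("spec validity rejects inconsistent stain levels and fractions", {
  expect_error(synthImageSpec(deadStainLiveLevel = 200,
                              deadStainDeadLevel = 150),
               "exceed")
  expect_error(synthImageSpec(fractionDead = 1.5), "fractionDead")
})
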