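# Rate decomposition: log-linear growth fit, accumulated-death
# inversion, b = r + d identity, exponentiality diagnostics.

test_that("exact doubling series gives r = ln2/24 with perfect fit", {
  ts <- wellTimeSeries(c(0, 24, 48), live = c(1000, 2000, 4000))
  fit <- fitNetGrowthRate(ts)
  expect_equal(fit$r, log(2) / 24, tolerance = 1e-12)
  expect_equal(fit$N0Fit, 1000, tolerance = 1e-9)
  expect_equal(fit$rSquared, 1)
})

test_that("flat series gives r = 0 and a flagged zero R-squared", {
  ts <- wellTimeSeries(c(0, 24, 48), live = c(500, 500, 500))
  fit <- fitNetGrowthRate(ts)
  expect_equal(fit$r, 0)
  expect_equal(fit$rSquared, 0)
  expect_true("flat_series" %in% fit$flags)
})

test_that("zero live counts are excluded with a warning", {
  ts <- wellTimeSeries(c(0, 24, 48, 72), live = c(1000, 500, 0, 0),
                       flags = "extinct")
  expect_warning(fit <- fitNetGrowthRate(ts), "zero live")
  expect_equal(fit$nPoints, 2L)
  expect_error(suppressWarnings(
    fitNetGrowthRate(wellTimeSeries(c(0, 24), live = c(100, 0)))),
    "at least 2")
})

test_that("death-rate closed form inverts its own forward model", {
  # forward: D(T) from the hazard integral; backward: d recovered
  r <- 0.03; N0 <- 1000; TT <- 72; d <- 0.01
  DT <- d * N0 * (exp(r * TT) - 1) / r
  ts <- wellTimeSeries(c(0, TT), live = c(N0, N0 * exp(r * TT)),
                       deadCum = c(0, DT))
  expect_equal(estimateDeathRate(ts, r, N0), d, tolerance = 1e-12)
  # r -> 0 limit
  ts0 <- wellTimeSeries(c(0, 72), live = c(1000, 1000),
                        deadCum = c(0, 720))
  expect_equal(estimateDeathRate(ts0, 0, 1000), 0.01, tolerance = 1e-12)
  # no deaths
  ts1 <- wellTimeSeries(c(0, 72), live = c(1000, 2000), deadCum = c(0, 0))
  expect_equal(estimateDeathRate(ts1, 0.01, 1000), 0)
})

test_that("birth rate is the exact sum identity, with negative flagged", {
  expect_equal(birthRate(0.03, 0.01), 0.04)
  expect_equal(birthRate(-0.02, 0.05), 0.03)
  expect_warning(b <- birthRate(-0.05, 0.01), "negative")
  expect_equal(b, -0.04)
})

test_that("rates are recovered from simulated trajectories", {
  b <- 0.04; d <- 0.01
  reps <- lapply(1:50, function(i)
    simulateBirthDeath(birthDeathParams(b, d, 2000), seed = 2000 + i))
  est <- estimateRates(reps)
  expect_lt(abs(growthRate(est) - (b - d)), 0.005)
  expect_lt(abs(deathRate(est) - d), 0.005)
  expect_identical(birthRate(est), growthRate(est) + deathRate(est))
  expect_true(est@exponentialOk)
})

test_that("scaling all counts leaves r, d, b unchanged and scales N0", {
  ts <- simulateBirthDeath(birthDeathParams(0.05, 0.02, 1000), seed = 7)
  k <- 13
  ts2 <- wellTimeSeries(ts@data$time_h, live = k * ts@data$live,
                        deadCum = k * ts@data$dead_cum)
  e1 <- suppressWarnings(estimateRates(ts))
  e2 <- suppressWarnings(estimateRates(ts2))
  expect_equal(growthRate(e2), growthRate(e1), tolerance = 1e-12)
  expect_equal(deathRate(e2), deathRate(e1), tolerance = 1e-12)
  expect_equal(e2@N0Fit, k * e1@N0Fit, tolerance = 1e-9)
})

test_that("exponentiality check flags saturating growth, passes clean", {
  t <- seq(0, 96, by = 8)
  K <- 5000; N0 <- 500; r <- 0.06
  logistic <- K / (1 + (K / N0 - 1) * exp(-r * t))
  expect_false(checkExponentiality(
    wellTimeSeries(t, live = round(logistic)))$ok)
  expect_true(checkExponentiality(
    wellTimeSeries(t, live = round(1000 * exp(0.03 * t))))$ok)
  two <- checkExponentiality(wellTimeSeries(c(0, 24),
                                            live = c(100, 210)))
  expect_true(two$ok)
  expect_true("insufficient_points" %in% two$flags)
})

test_that("rate grid keeps every condition and the b = r + d identity", {
  conds <- expand.grid(drug = c(0, 1), o2 = c(21, 0.1),
                       glc = c(4.5, 1))
  series <- lapply(seq_len(nrow(conds)), function(i) {
    cond <- condition(drugConc = conds$drug[i], oxygenPct = conds$o2[i],
                      glucose = conds$glc[i])
    lapply(1:3, function(k)
      simulateBirthDeath(birthDeathParams(0.04, 0.01, 2000),
                         seed = 100 * i + k, condition = cond,
                         replicateId = paste0("r", k)))
  })
  names(series) <- vapply(series, function(s) s[[1]]@condition@label, "")
  grid <- rateGrid(series)
  expect_equal(nrow(grid), 8L)
  expect_identical(grid$b, grid$r + grid$d)
  # identical inputs give identical estimates
  g2 <- rateGrid(series)
  expect_identical(grid, g2)
  # matrix pivot carries the r values
  m <- rateMatrix(grid, "drug_conc", "oxygen_pct")
  expect_equal(dim(m), c(2L, 2L))
  expect_false(anyNA(m))
})

test_that("a drug that lowers birth rate shows monotone fitted r", {
  doses <- c(0, 0.1, 1, 10)
  bs <- c(0.05, 0.04, 0.03, 0.02)     # cytostatic dose response
  series <- lapply(seq_along(doses), function(i)
    lapply(1:10, function(k)
      simulateBirthDeath(birthDeathParams(bs[i], 0.005, 3000),
                         seed = 7000 + 10 * i + k,
                         condition = condition(drugConc = doses[i]))))
  names(series) <- paste0("dose", doses)
  grid <- rateGrid(series)
  expect_true(all(diff(grid$r[order(doses)]) < 0))
})

test_that("failed fits are retained as rows with a reason", {
  good <- simulateBirthDeath(birthDeathParams(0.04, 0.01, 1000), seed = 1)
  bad <- wellTimeSeries(c(0, 24), live = c(5, 0),
                        condition = condition(label = "dead_well"))
  grid <- suppressWarnings(rateGrid(list(ok = good, broken = bad)))
  expect_equal(nrow(grid), 2L)
  expect_true(is.na(grid$r[grid$condition == "broken"]))
  expect_match(grid$flags[grid$condition == "broken"], "fit_failed")
})
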