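# Birth/death rate decomposition from live/dead count time series.
#
# Model: live counts grow exponentially, N(t) = N0 * exp(r t); dead
# cells accumulate under a constant per-capita death hazard d, so
# E[D(T)] = d * N0 * (exp(rT) - 1) / r. The net growth rate r comes
# from OLS on ln(live) vs time (replicates pooled into one
# regression), d from inverting the accumulated-death expectation, and
# the birth rate is the identity b = r + d.

.series_points <- function(series) {
  if (is(series, "WellTimeSeries")) series <- list(series)
  stopifnot(all(vapply(series, is, logical(1), "WellTimeSeries")))
  series
}

#' Fit the net growth rate by log-linear regression
#'
#' Ordinary least squares of \code{ln(live)} on time, pooling all
#' points of all supplied replicate series into a single regression
#' (correct weighting under unbalanced replication). Zero live counts
#' cannot be log-transformed; they are excluded with a warning and
#' flagged.
#'
#' @param series a \linkS4class{WellTimeSeries} or list of replicate
#'   series under one condition.
#' @return list: \code{r} (slope, 1/hour), \code{N0Fit} (exp of the
#'   intercept), \code{rSquared}, \code{nPoints}, \code{flags}.
#' @examples
#' ts <- wellTimeSeries(c(0, 24, 48), live = c(1000, 2000, 4000))
#' fitNetGrowthRate(ts)$r     # log(2)/24
#' @export
fitNetGrowthRate <- function(series) {
  series <- .series_points(series)
  pts <- do.call(rbind, lapply(series, function(s)
    aggregate(live ~ time_h, data = s@data, FUN = sum)))
  flags <- character()
  zero <- pts$live <= 0
  if (any(zero)) {
    warning(sum(zero), " zero live count(s) excluded from log-linear fit")
    flags <- c(flags, "zero_counts_excluded")
    pts <- pts[!zero, , drop = FALSE]
  }
  if (nrow(pts) < 2L || length(unique(pts$time_h)) < 2L)
    stop("estimation error: need at least 2 time points with live > 0")
  fit <- lm(log(live) ~ time_h, data = pts)
  r2 <- suppressWarnings(summary(fit)$r.squared)   # noiseless fits are fine
  if (sd(log(pts$live)) == 0) {    # flat series: zero total variance,
    r2 <- 0                        # R-squared undefined -> 0 + flag
    flags <- c(flags, "flat_series")
  } else if (!is.finite(r2)) {
    r2 <- 0
    flags <- c(flags, "degenerate_fit")
  }
  # mean residual per distinct time: systematic lack of fit (curvature)
  # is a function of time, so replicate scatter is averaged out first
  resid_t <- tapply(stats::residuals(fit), pts$time_h, mean)
  resid_t <- resid_t[order(as.numeric(names(resid_t)))]
  list(r = unname(coef(fit)[2]), N0Fit = unname(exp(coef(fit)[1])),
       rSquared = r2, nPoints = nrow(pts),
       nTimes = length(resid_t), flags = flags,
       residualsByTime = as.numeric(resid_t))
}

#' Estimate the death rate from accumulated deaths
#'
#' Under a constant per-capita death hazard and exponential live growth
#' the expected cumulative deaths by time T are
#' \code{D(T) = d * N0 * (exp(rT) - 1) / r}; inverting gives
#' \code{d = D(T) * r / (N0 * (exp(rT) - 1))}. In the r -> 0 limit
#' (|r| < 1e-9) this reduces to \code{d = D(T) / (N0 * T)}. With
#' replicate series the per-replicate estimates are averaged. D(T) = 0
#' gives d = 0; d is clipped at zero.
#'
#' @param series a \linkS4class{WellTimeSeries} or list of replicates.
#' @param r net growth rate from \code{\link{fitNetGrowthRate}} (1/hour).
#' @param N0 fitted initial live count.
#' @return death rate d (1/hour), >= 0.
#' @examples
#' DT <- 0.01 * 1000 * (exp(0.03 * 72) - 1) / 0.03
#' ts <- wellTimeSeries(c(0, 72), live = c(1000, 1000 * exp(0.03 * 72)),
#'                      deadCum = c(0, DT))
#' estimateDeathRate(ts, r = 0.03, N0 = 1000)   # 0.01
#' @export
estimateDeathRate <- function(series, r, N0) {
  series <- .series_points(series)
  d_hat <- vapply(series, function(s) {
    dat <- aggregate(dead_cum ~ time_h, data = s@data, FUN = sum)
    TT <- max(dat$time_h)
    if (TT <= 0) stop("estimation error: final time T must be > 0")
    DT <- dat$dead_cum[which.max(dat$time_h)]
    if (DT <= 0) return(0)
    if (abs(r) < 1e-9) DT / (N0 * TT)
    else DT * r / (N0 * (exp(r * TT) - 1))
  }, numeric(1))
  max(0, mean(d_hat))
}

# Wald-Wolfowitz runs test on residual signs; one-sided p for too few
# runs (a systematic sign pattern). Normal approximation.
.runs_pvalue <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0) return(0)   # all one sign: maximal pattern
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(1)
  pnorm((runs - mu) / sqrt(v))
}

#' Check whether a series is consistent with exponential growth
#'
#' Seeding density matters: too few or too many cells and growth
#' becomes sub-exponential, invalidating the log-linear fit. The check
#' passes when the fit's R-squared reaches the floor and, with at
#' least 8 distinct time points, the per-time mean residual signs show
#' no systematic pattern (one-sided runs test for too few runs at
#' level alpha; averaging replicates first isolates lack of fit from
#' replicate scatter).
#' Series with fewer than 3 points cannot be falsified and pass with
#' an \code{"insufficient_points"} flag.
#'
#' @param series a \linkS4class{WellTimeSeries} or list of replicates.
#' @param r2Floor minimum R-squared (default 0.95).
#' @param alpha runs-test level (default 0.05).
#' @return list: \code{ok} logical, \code{rSquared}, \code{runsP},
#'   \code{flags}.
#' @export
checkExponentiality <- function(series, r2Floor = 0.95, alpha = 0.05) {
  fit <- suppressWarnings(fitNetGrowthRate(series))
  flags <- fit$flags
  if (fit$nPoints <= 2L) {
    return(list(ok = TRUE, rSquared = fit$rSquared, runsP = NA_real_,
                flags = c(flags, "insufficient_points")))
  }
  ok <- fit$rSquared >= r2Floor
  runsP <- NA_real_
  if (fit$nTimes >= 8L) {
    runsP <- .runs_pvalue(fit$residualsByTime)
    if (is.finite(runsP) && runsP < alpha) {
      ok <- FALSE
      flags <- c(flags, "residual_sign_pattern")
    }
  }
  if (!ok && fit$rSquared < r2Floor) flags <- c(flags, "low_r_squared")
  list(ok = ok, rSquared = fit$rSquared, runsP = runsP, flags = flags)
}

#' Full rate decomposition for one condition
#'
#' Runs the log-linear growth fit, the accumulated-death inversion and
#' the b = r + d identity, plus the exponentiality diagnostic, and
#' returns everything as a \linkS4class{RateEstimate}. N0 in the
#' death-rate formula is the fitted intercept, not the measured t = 0
#' count, which reduces sensitivity to seeding noise.
#'
#' @param series a \linkS4class{WellTimeSeries} or list of replicates
#'   under one condition.
#' @param r2Floor,alpha passed to \code{\link{checkExponentiality}}.
#' @return A \linkS4class{RateEstimate}.
#' @examples
#' ts <- simulateBirthDeath(birthDeathParams(0.04, 0.01, 2000), seed = 1)
#' estimateRates(ts)
#' @export
estimateRates <- function(series, r2Floor = 0.95, alpha = 0.05) {
  fit <- fitNetGrowthRate(series)
  d <- estimateDeathRate(series, fit$r, fit$N0Fit)
  b <- fit$r + d
  flags <- fit$flags
  if (b < 0) flags <- c(flags, "negative_birth_rate")
  ex <- checkExponentiality(series, r2Floor = r2Floor, alpha = alpha)
  new("RateEstimate", r = fit$r, d = d, b = b, N0Fit = fit$N0Fit,
      rSquared = fit$rSquared, exponentialOk = ex$ok,
      flags = unique(c(flags, ex$flags)))
}

#' Rate decomposition over a grid of conditions
#'
#' Applies \code{\link{estimateRates}} to each condition's replicate
#' series and assembles the long-format table behind a net-growth-rate
#' heatmap: one row per condition with r, d, b (1/hour), the fitted
#' N0, fit diagnostics and flags. A condition whose fit fails is
#' retained with missing values and the failure reason.
#'
#' @param seriesByCondition named list; each element is a
#'   \linkS4class{WellTimeSeries} or list of replicate series. Names
#'   are condition labels (taken from the series' conditions when
#'   unnamed).
#' @param ... passed to \code{\link{estimateRates}}.
#' @return data.frame, one row per condition: condition fields,
#'   \code{n_series}, \code{r}, \code{d}, \code{b}, \code{N0_fit},
#'   \code{r_squared}, \code{exponential_ok}, \code{flags}.
#' @export
rateGrid <- function(seriesByCondition, ...) {
  rows <- lapply(seq_along(seriesByCondition), function(i) {
    sl <- seriesByCondition[[i]]
    if (is(sl, "WellTimeSeries")) sl <- list(sl)
    cond <- sl[[1]]@condition
    lbl <- names(seriesByCondition)[i]
    if (is.null(lbl) || !nzchar(lbl)) lbl <- cond@label
    base <- data.frame(condition = lbl, drug_conc = cond@drugConc,
                       oxygen_pct = cond@oxygenPct,
                       glucose_g_per_L = cond@glucose,
                       coculture = cond@coculture,
                       n_series = length(sl), stringsAsFactors = FALSE)
    est <- tryCatch(suppressWarnings(estimateRates(sl, ...)),
                    error = function(e) e)
    if (inherits(est, "error")) {
      cbind(base, data.frame(r = NA_real_, d = NA_real_, b = NA_real_,
                             N0_fit = NA_real_, r_squared = NA_real_,
                             exponential_ok = NA,
                             flags = paste("fit_failed:",
                                           conditionMessage(est))))
    } else {
      cbind(base, data.frame(r = est@r, d = est@d, b = est@b,
                             N0_fit = est@N0Fit, r_squared = est@rSquared,
                             exponential_ok = est@exponentialOk,
                             flags = paste(est@flags, collapse = ";")))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pivot a rate grid into a heatmap-ready matrix
#'
#' @param grid output of \code{\link{rateGrid}}.
#' @param rowVar,colVar condition columns spanning the matrix axes.
#' @param value which estimate to pivot (default \code{"r"}, the net
#'   growth rate).
#' @return numeric matrix with sorted unique \code{rowVar} values as
#'   rows and \code{colVar} values as columns.
#' @export
rateMatrix <- function(grid, rowVar = "drug_conc", colVar = "oxygen_pct",
                       value = "r") {
  rv <- sort(unique(grid[[rowVar]]))
  cv <- sort(unique(grid[[colVar]]))
  m <- matrix(NA_real_, length(rv), length(cv),
              dimnames = list(as.character(rv), as.character(cv)))
  for (i in seq_len(nrow(grid)))
    m[as.character(grid[[rowVar]][i]),
      as.character(grid[[colVar]][i])] <- grid[[value]][i]
  m
}
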