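# Exact stochastic simulation of cell population growth and synthetic
# per-cell feature tables for classifier training.

#' Simulate a linear birth-death process exactly
#'
#' Event-driven (Gillespie) simulation of a population with constant
#' per-capita birth rate b and death rate d, observed at the given
#' sample times. This realizes exactly the model assumed by the rate
#' decomposition: exponential expected growth at r = b - d and a
#' constant death hazard per live cell. Extinction before the last
#' sample time is not an error; the series continues at zero and the
#' result is flagged \code{"extinct"}.
#'
#' @param p a \linkS4class{BirthDeathParams}.
#' @param seed integer RNG seed.
#' @param condition a \linkS4class{Condition} attached to the series.
#' @param replicateId replicate identifier.
#' @param subpopulation subpopulation name.
#' @return A \linkS4class{WellTimeSeries}; the data carry an extra
#'   \code{births_cum} column so that the conservation identity
#'   births - deaths = N(t) - N0 can be audited per trajectory.
#' @examples
#' ts <- simulateBirthDeath(birthDeathParams(0.04, 0.01, 500), seed = 1)
#' liveCounts(ts)
#' @export
simulateBirthDeath <- function(p, seed, condition = hcsquant::condition(),
                               replicateId = "r1", subpopulation = "all") {
  stopifnot(is(p, "BirthDeathParams"))
  validObject(p)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  m <- gillespie_bd(p@b, p@d, p@N0, p@sampleTimes)
  flags <- if (m[nrow(m), "live"] == 0) "extinct" else character()
  d <- data.frame(time_h = m[, "time"], subpopulation = subpopulation,
                  live = m[, "live"], dead_cum = m[, "dead_cum"],
                  births_cum = m[, "births_cum"])
  new("WellTimeSeries", condition = condition, replicateId = replicateId,
      data = d, flags = flags)
}

#' Generate synthetic pure control populations for classification
#'
#' Draws per-cell feature records for the four-way classification task
#' (two fluorescent labels crossed with live/dead), emulating pure
#' control wells: each class has Gaussian intensity and morphology
#' distributions, with the class-informative intensity channels (RFP,
#' GFP, dead-stain nuclear/background ratio) separated between classes
#' by \code{intensitySepSd} standard deviations. A handful of
#' uninformative noise features is included so that feature selection
#' has something to reject.
#'
#' @param nPerClass cells drawn per class.
#' @param seed integer RNG seed.
#' @param intensitySepSd between-class separation of the informative
#'   intensity features, in units of their within-class sd (default 4:
#'   labeled vs unlabeled populations differ by several-fold intensity).
#' @param classes class names; defaults to the 2 labels x live/dead grid.
#' @return data.frame with feature columns and a \code{true_class}
#'   column.
#' @examples
#' head(synthControlPopulations(50, seed = 1))
#' @export
synthControlPopulations <- function(nPerClass = 200, seed = 1L,
                                    intensitySepSd = 4,
                                    classes = c("tumor_live", "tumor_dead",
                                                "stroma_live",
                                                "stroma_dead")) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- nPerClass
  is_tumor <- grepl("tumor", classes)
  is_dead <- grepl("dead", classes)
  one_class <- function(k) {
    tum <- is_tumor[k]; dead <- is_dead[k]
    # intensity channels: "on" level sits intensitySepSd sds above "off"
    rfp_sd <- 80; gfp_sd <- 80; ratio_sd <- 0.1
    data.frame(
      true_class = classes[k],
      rfp_mean = rnorm(n, 100 + if (tum) intensitySepSd * rfp_sd else 0,
                       rfp_sd),
      gfp_mean = rnorm(n, 100 + if (!tum) intensitySepSd * gfp_sd else 0,
                       gfp_sd),
      dead_ratio = rnorm(n, 1.0 + if (dead) intensitySepSd * ratio_sd else 0,
                         ratio_sd),
      nuclear_area = rnorm(n, if (dead) 120 else 180, 30),
      cell_area = rnorm(n, if (tum) 800 else 1250, 180),
      roundness = pmin(1, rnorm(n, if (tum) 0.85 else 0.70, 0.06)),
      width_to_length = pmin(1, rnorm(n, if (tum) 0.88 else 0.62, 0.09)),
      nuclear_mean = rnorm(n, 1000, 100),
      noise_a = rnorm(n), noise_b = rnorm(n), noise_c = rnorm(n),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(classes), one_class))
  rownames(out) <- NULL
  out
}
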