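#' Microenvironmental condition of a well
#'
#' One combination of the perturbations applied to a well: drug
#' concentration, oxygen tension, glucose level and whether the well is
#' a co-culture. Conditions index the rows of the rate grid.
#'
#' @slot drugConc drug concentration, micromolar.
#' @slot oxygenPct oxygen tension, percent.
#' @slot glucose glucose, g/L.
#' @slot coculture logical, co-culture well.
#' @slot label free-text condition label (unique within a layout).
#' @exportClass Condition
setClass("Condition",
  representation(drugConc = "numeric", oxygenPct = "numeric",
                 glucose = "numeric", coculture = "logical",
                 label = "character"),
  prototype(drugConc = 0, oxygenPct = 21, glucose = 4.5,
            coculture = FALSE, label = "control"))

setValidity("Condition", function(object) {
  msg <- character()
  for (s in c("drugConc", "oxygenPct", "glucose")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0)
      msg <- c(msg, sprintf("'%s' must be a single non-negative number", s))
  }
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "'label' must be a non-empty string")
  if (length(msg)) msg else TRUE
})

#' Construct a Condition
#'
#' @param drugConc drug concentration (uM).
#' @param oxygenPct oxygen tension (percent); 21 is normoxia.
#' @param glucose glucose (g/L); 4.5 is standard high-glucose medium.
#' @param coculture logical co-culture flag.
#' @param label condition label; autogenerated from the fields if missing.
#' @return A \linkS4class{Condition}.
#' @examples
#' condition(drugConc = 1, oxygenPct = 0.1)
#' @export
condition <- function(drugConc = 0, oxygenPct = 21, glucose = 4.5,
                      coculture = FALSE, label = NULL) {
  if (is.null(label))
    label <- sprintf("drug%g_O2%g_glc%g_%s", drugConc, oxygenPct, glucose,
                     if (coculture) "cocx" else "mono")
  new("Condition", drugConc = drugConc, oxygenPct = oxygenPct,
      glucose = glucose, coculture = coculture, label = label)
}

#' A registered multi-channel image field
#'
#' One field of view from one well at one time point: a named list of
#' per-channel 2D intensity matrices (arbitrary units) sharing one pixel
#' grid, plus the physical pixel size. Channel roles (nuclear stain,
#' dead-cell stain, fluorescent labels, cytoplasm tracker) are carried
#' by the channel names and mapped in the segmentation/viability
#' parameter objects.
#'
#' @slot channels named list of numeric matrices, identical dimensions.
#' @slot pixelSize physical pixel size, micrometres per pixel.
#' @slot well well identifier, e.g. \code{"B03"}.
#' @slot field field identifier within the well.
#' @slot timeH acquisition time, hours from assay start.
#' @exportClass ImageField
setClass("ImageField",
  representation(channels = "list", pixelSize = "numeric",
                 well = "character", field = "character",
                 timeH = "numeric"),
  prototype(pixelSize = 1, well = "A01", field = "f1", timeH = 0))

setValidity("ImageField", function(object) {
  ch <- object@channels
  if (!length(ch)) return("at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named")
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("each channel must be a numeric matrix")
  dims <- vapply(ch, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all channels must share the same dimensions")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  TRUE
})

#' Construct an ImageField
#'
#' @param channels named list of same-sized numeric matrices.
#' @param pixelSize micrometres per pixel.
#' @param well,field identifiers.
#' @param timeH time point in hours.
#' @return An \linkS4class{ImageField}.
#' @export
imageField <- function(channels, pixelSize = 1, well = "A01",
                       field = "f1", timeH = 0) {
  new("ImageField", channels = channels, pixelSize = pixelSize,
      well = well, field = field, timeH = timeH)
}

#' Specification of a synthetic image field
#'
#' Parameters of the ground-truthed image generator: how many cells of
#' each type to render, nuclear and cell-body size distributions, the
#' fraction of each type rendered dead (elevated dead-stain signal),
#' stain levels, noise, and the fraction of cells placed as touching
#' pairs to exercise de-clumping.
#'
#' @slot fieldSize integer (rows, cols) in pixels.
#' @slot nCells named integer vector, cells per type.
#' @slot nucleusRadiusMean,nucleusRadiusSd per-type nuclear radius (px).
#' @slot cellRadiusMean,cellRadiusSd per-type cell-body radius (px).
#' @slot fractionDead per-type fraction rendered dead, in [0, 1].
#' @slot deadStainLiveLevel,deadStainDeadLevel dead-channel plateau
#'   intensity (a.u.) of live vs dead nuclei; dead must exceed live.
#' @slot backgroundLevel image background intensity (a.u.).
#' @slot noiseSd additive Gaussian noise standard deviation (a.u.).
#' @slot labelChannelByType named character, type to fluorescence
#'   channel (entries may be NA for unlabeled types).
#' @slot touchingPairFraction fraction of cells placed in touching
#'   pairs (centre distance 1.2-1.6 nuclear radii), in [0, 1].
#' @slot pixelSize micrometres per pixel.
#' @slot seed integer RNG seed; all randomness in rendering flows from it.
#' @exportClass SynthImageSpec
setClass("SynthImageSpec",
  representation(fieldSize = "integer", nCells = "integer",
                 nucleusRadiusMean = "numeric", nucleusRadiusSd = "numeric",
                 cellRadiusMean = "numeric", cellRadiusSd = "numeric",
                 fractionDead = "numeric",
                 deadStainLiveLevel = "numeric",
                 deadStainDeadLevel = "numeric",
                 backgroundLevel = "numeric", noiseSd = "numeric",
                 labelChannelByType = "character",
                 touchingPairFraction = "numeric",
                 pixelSize = "numeric", seed = "integer"))

setValidity("SynthImageSpec", function(object) {
  msg <- character()
  if (length(object@fieldSize) != 2L || any(object@fieldSize < 16L))
    msg <- c(msg, "fieldSize must be two integers >= 16")
  if (any(object@nCells < 0L)) msg <- c(msg, "cell counts must be >= 0")
  types <- names(object@nCells)
  if (is.null(types) || any(!nzchar(types)))
    msg <- c(msg, "nCells must be named by cell type")
  per_type <- c("nucleusRadiusMean", "nucleusRadiusSd", "cellRadiusMean",
                "cellRadiusSd", "fractionDead")
  for (s in per_type)
    if (length(slot(object, s)) != length(object@nCells))
      msg <- c(msg, sprintf("'%s' must have one value per type", s))
  if (any(object@nucleusRadiusMean <= 0) || any(object@cellRadiusMean <= 0))
    msg <- c(msg, "radii must be positive")
  if (any(object@fractionDead < 0 | object@fractionDead > 1))
    msg <- c(msg, "fractionDead must lie in [0, 1]")
  if (object@deadStainDeadLevel <= object@deadStainLiveLevel)
    msg <- c(msg, "deadStainDeadLevel must exceed deadStainLiveLevel")
  if (object@touchingPairFraction < 0 || object@touchingPairFraction > 1)
    msg <- c(msg, "touchingPairFraction must lie in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Parameters of a linear birth-death process
#'
#' Per-capita birth and death rates (1/hour, constant), initial live
#' population and the observation times for the exact stochastic
#' simulator. The death hazard is constant per live cell per unit time;
#' the expected live population is N0 * exp((b - d) * t).
#'
#' @slot b per-capita birth rate, 1/hour, >= 0.
#' @slot d per-capita death rate, 1/hour, >= 0.
#' @slot N0 initial live cell count, >= 1.
#' @slot sampleTimes observation times in hours, strictly increasing,
#'   starting at 0.
#' @exportClass BirthDeathParams
setClass("BirthDeathParams",
  representation(b = "numeric", d = "numeric", N0 = "numeric",
                 sampleTimes = "numeric"))

setValidity("BirthDeathParams", function(object) {
  msg <- character()
  if (!is.finite(object@b) || object@b < 0)
    msg <- c(msg, "b must be finite and >= 0")
  if (!is.finite(object@d) || object@d < 0)
    msg <- c(msg, "d must be finite and >= 0")
  if (object@N0 < 1) msg <- c(msg, "N0 must be >= 1")
  st <- object@sampleTimes
  if (length(st) < 1L || st[1] != 0 || any(diff(st) <= 0))
    msg <- c(msg, "sampleTimes must be strictly increasing, starting at 0")
  if (length(msg)) msg else TRUE
})

#' Construct BirthDeathParams
#'
#' @param b,d per-capita birth and death rates (1/hour).
#' @param N0 initial live population.
#' @param sampleTimes observation times (hours), starting at 0.
#' @return A \linkS4class{BirthDeathParams}.
#' @examples
#' birthDeathParams(b = 0.04, d = 0.01, N0 = 2000)
#' @export
birthDeathParams <- function(b, d, N0, sampleTimes = c(0, 24, 48, 72)) {
  new("BirthDeathParams", b = b, d = d, N0 = N0, sampleTimes = sampleTimes)
}

#' Live/dead count time series from one well
#'
#' Counts of live cells and cumulative dead cells per subpopulation at
#' each sampled time point, under one microenvironmental condition.
#' Dead counts are cumulative: endpoint staining marks all accumulated
#' dead cells still adherent.
#'
#' @slot condition the \linkS4class{Condition} applied to the well.
#' @slot replicateId replicate identifier.
#' @slot data data.frame with columns \code{time_h},
#'   \code{subpopulation}, \code{live}, \code{dead_cum}.
#' @slot flags character vector of QC/processing flags (e.g.
#'   \code{"extinct"} when the live population hit zero).
#' @exportClass WellTimeSeries
setClass("WellTimeSeries",
  representation(condition = "Condition", replicateId = "character",
                 data = "data.frame", flags = "character"),
  prototype(replicateId = "r1", flags = character()))

setValidity("WellTimeSeries", function(object) {
  d <- object@data
  need <- c("time_h", "subpopulation", "live", "dead_cum")
  if (!all(need %in% names(d)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (any(d$live < 0) || any(d$dead_cum < 0))
    return("counts must be >= 0")
  for (sp in unique(d$subpopulation)) {
    di <- d[d$subpopulation == sp, ]
    if (is.unsorted(di$time_h, strictly = TRUE))
      return("time_h must be strictly increasing within a subpopulation")
    if (di$time_h[1] < 0) return("times must start at >= 0")
    if (any(diff(di$dead_cum) < 0))
      return("dead_cum must be non-decreasing in time")
  }
  TRUE
})

#' Construct a WellTimeSeries
#'
#' @param times sample times (hours).
#' @param live live counts at each time.
#' @param deadCum cumulative dead counts at each time.
#' @param condition a \linkS4class{Condition}.
#' @param subpopulation subpopulation name (scalar, recycled).
#' @param replicateId replicate identifier.
#' @param flags character flags.
#' @return A \linkS4class{WellTimeSeries}.
#' @examples
#' wellTimeSeries(c(0, 24, 48), live = c(1000, 2000, 4000),
#'                deadCum = c(0, 10, 30))
#' @export
wellTimeSeries <- function(times, live, deadCum = rep(0, length(times)),
                           condition = hcsquant::condition(),
                           subpopulation = "all", replicateId = "r1",
                           flags = character()) {
  new("WellTimeSeries", condition = condition, replicateId = replicateId,
      data = data.frame(time_h = times, subpopulation = subpopulation,
                        live = live, dead_cum = deadCum),
      flags = flags)
}

#' Birth/death/net-growth rate estimate for one condition
#'
#' The decomposition of a live/dead count time series: net growth rate r
#' from a log-linear fit of live counts, death rate d from accumulated
#' deaths under a constant per-capita death hazard, and birth rate
#' b = r + d (an exact identity in every estimate).
#'
#' @slot r net growth rate, 1/hour.
#' @slot d death rate, 1/hour, >= 0.
#' @slot b birth rate, 1/hour; always exactly \code{r + d}.
#' @slot N0Fit fitted initial live count (exp of the fit intercept).
#' @slot rSquared coefficient of determination of the log-linear fit.
#' @slot exponentialOk logical; TRUE when the series is consistent with
#'   exponential growth (R-squared floor plus residual runs test).
#' @slot flags character diagnostics.
#' @exportClass RateEstimate
setClass("RateEstimate",
  representation(r = "numeric", d = "numeric", b = "numeric",
                 N0Fit = "numeric", rSquared = "numeric",
                 exponentialOk = "logical", flags = "character"),
  prototype(flags = character(), exponentialOk = NA))

setValidity("RateEstimate", function(object) {
  msg <- character()
  if (!identical(object@b, object@r + object@d))
    msg <- c(msg, "b must equal r + d exactly")
  if (!is.na(object@d) && object@d < 0) msg <- c(msg, "d must be >= 0")
  if (!is.na(object@rSquared) &&
      (object@rSquared < 0 || object@rSquared > 1))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' A trained linear subpopulation classifier
#'
#' Multiclass linear discriminant fitted by least squares on
#' standardized, separability-selected features. Stores everything
#' needed to reproduce a classification bit-for-bit: class names,
#' selected features, per-feature standardization, per-class linear
#' coefficients, the training seed, and training/control accuracies.
#'
#' @slot classNames class labels, in tie-break priority order.
#' @slot features selected feature names (columns of the record table).
#' @slot center,scaleSd per-feature standardization mean and sd.
#' @slot coefficients (k+1) x nclass matrix; first row is the intercept.
#' @slot trainingAccuracy fraction correct on the training subsample.
#' @slot controlAccuracy fraction correct on held-out pure controls
#'   (NA until evaluated).
#' @slot seed RNG seed used to draw the training subsample.
#' @exportClass ClassifierModel
setClass("ClassifierModel",
  representation(classNames = "character", features = "character",
                 center = "numeric", scaleSd = "numeric",
                 coefficients = "matrix", trainingAccuracy = "numeric",
                 controlAccuracy = "numeric", seed = "integer"),
  prototype(controlAccuracy = NA_real_))

setValidity("ClassifierModel", function(object) {
  k <- length(object@features)
  if (length(object@center) != k || length(object@scaleSd) != k)
    return("center/scaleSd must match the selected features")
  if (nrow(object@coefficients) != k + 1L ||
      ncol(object@coefficients) != length(object@classNames))
    return("coefficients must be (k+1) x nclass")
  if (!is.na(object@trainingAccuracy) &&
      (object@trainingAccuracy < 0 || object@trainingAccuracy > 1))
    return("trainingAccuracy must lie in [0, 1]")
  TRUE
})
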