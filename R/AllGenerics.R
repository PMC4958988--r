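#' @name accessors
#' @title Accessors for hcsquant classes
#' @description Small accessor generics for the package's S4 containers.
#' @param x an hcsquant object.
#' @param ... unused.
#' @param name channel name (for \code{getChannel}).
NULL

#' @rdname accessors
#' @return \code{channelNames}: character vector of channel names.
#' @export
setGeneric("channelNames", function(x, ...) standardGeneric("channelNames"))

#' @rdname accessors
#' @return \code{getChannel}: the named channel's intensity matrix.
#' @export
setGeneric("getChannel", function(x, name, ...) standardGeneric("getChannel"))

#' @rdname accessors
#' @return \code{pixelSize}: micrometres per pixel.
#' @export
setGeneric("pixelSize", function(x, ...) standardGeneric("pixelSize"))

#' @rdname accessors
#' @return \code{sampleTimes}: numeric vector of time points (hours).
#' @export
setGeneric("sampleTimes", function(x, ...) standardGeneric("sampleTimes"))

#' @rdname accessors
#' @return \code{liveCounts}, \code{deadCounts}: named numeric counts.
#' @export
setGeneric("liveCounts", function(x, ...) standardGeneric("liveCounts"))

#' @rdname accessors
#' @export
setGeneric("deadCounts", function(x, ...) standardGeneric("deadCounts"))

#' @rdname accessors
#' @return \code{growthRate}, \code{deathRate}: the fitted rates (1/hour).
#' @export
setGeneric("growthRate", function(x, ...) standardGeneric("growthRate"))

#' @rdname accessors
#' @export
setGeneric("deathRate", function(x, ...) standardGeneric("deathRate"))

#' Birth rate: accessor and identity
#'
#' For a \linkS4class{RateEstimate}, returns the stored birth rate.
#' For numerics, combines a net growth rate and a death rate into the
#' birth rate via the identity \code{b = r + d}. A negative result is
#' biologically impossible under the model and is flagged with a
#' warning (it signals a model violation, e.g. death of non-dividing
#' cells misattributed).
#'
#' @param x a \linkS4class{RateEstimate}, or the net growth rate r (1/hour).
#' @param d death rate (1/hour), for the numeric method.
#' @param ... unused.
#' @return Birth rate b (1/hour).
#' @examples
#' birthRate(0.03, 0.01)   # 0.04
#' birthRate(-0.02, 0.05)  # 0.03
#' @export
setGeneric("birthRate", function(x, d, ...) standardGeneric("birthRate"))

# ---- methods -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("channelNames", "ImageField", function(x, ...) names(x@channels))

#' @rdname accessors
#' @export
setMethod("getChannel", "ImageField", function(x, name, ...) {
  if (!name %in% names(x@channels))
    stop("no such channel: '", name, "' (have: ",
         paste(names(x@channels), collapse = ", "), ")")
  x@channels[[name]]
})

#' @rdname accessors
#' @export
setMethod("pixelSize", "ImageField", function(x, ...) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("sampleTimes", "WellTimeSeries", function(x, ...)
  sort(unique(x@data$time_h)))

#' @rdname accessors
#' @export
setMethod("liveCounts", "WellTimeSeries", function(x, ...) {
  d <- x@data
  ta <- tapply(d$live, d$time_h, sum)
  setNames(as.numeric(ta), names(ta))
})

#' @rdname accessors
#' @export
setMethod("deadCounts", "WellTimeSeries", function(x, ...) {
  d <- x@data
  ta <- tapply(d$dead_cum, d$time_h, sum)
  setNames(as.numeric(ta), names(ta))
})

#' @rdname accessors
#' @export
setMethod("growthRate", "RateEstimate", function(x, ...) x@r)

#' @rdname accessors
#' @export
setMethod("deathRate", "RateEstimate", function(x, ...) x@d)

#' @rdname birthRate
#' @export
setMethod("birthRate", signature(x = "RateEstimate", d = "missing"),
  function(x, d, ...) x@b)

#' @rdname birthRate
#' @export
setMethod("birthRate", signature(x = "numeric", d = "numeric"),
  function(x, d, ...) {
    b <- x + d
    if (any(is.finite(b) & b < 0))
      warning("negative birth rate: model violation flagged")
    b
  })

# ---- show ----------------------------------------------------------------

setMethod("show", "ImageField", function(object) {
  dm <- dim(object@channels[[1]])
  cat(sprintf("ImageField well=%s field=%s t=%gh | %dx%d px (%g um/px)\n",
              object@well, object@field, object@timeH, dm[1], dm[2],
              object@pixelSize))
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
})

setMethod("show", "WellTimeSeries", function(object) {
  d <- object@data
  cat(sprintf("WellTimeSeries [%s, rep %s] %d time points, %d subpopulation(s)\n",
              object@condition@label, object@replicateId,
              length(unique(d$time_h)), length(unique(d$subpopulation))))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf("RateEstimate: r=%.5f d=%.5f b=%.5f (1/h), N0=%.1f, R2=%.4f\n",
              object@r, object@d, object@b, object@N0Fit, object@rSquared))
  cat(sprintf("  exponential_ok=%s%s\n", object@exponentialOk,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ", "), "]")
              else ""))
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf("ClassifierModel: %d classes (%s)\n",
              length(object@classNames),
              paste(object@classNames, collapse = ", ")))
  cat("  features:", paste(object@features, collapse = ", "), "\n")
  cat(sprintf("  training accuracy %.3f | control accuracy %s\n",
              object@trainingAccuracy,
              ifelse(is.na(object@controlAccuracy), "NA",
                     sprintf("%.3f", object@controlAccuracy))))
})

setMethod("show", "Condition", function(object) {
  cat(sprintf("Condition '%s': drug %g uM, O2 %g%%, glucose %g g/L, %s\n",
              object@label, object@drugConc, object@oxygenPct,
              object@glucose,
              if (object@coculture) "co-culture" else "monoculture"))
})

setMethod("show", "SynthImageSpec", function(object) {
  cat(sprintf("SynthImageSpec %dx%d px, seed %d\n",
              object@fieldSize[1], object@fieldSize[2], object@seed))
  cat("  cells:", paste(sprintf("%s=%d", names(object@nCells),
                                object@nCells), collapse = ", "), "\n")
})
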