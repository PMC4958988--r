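# Live/dead classification from dead-cell stain intensity.
#
# Two rules: an absolute nuclear-intensity threshold (suited to
# propidium iodide), or the nuclear-to-background intensity ratio with
# a strict > 1.2 default cut (suited to far-red stains such as
# TO-PRO-3 or DRAQ7, where the local background annulus normalizes
# illumination). Both comparisons are strict: a cell sitting exactly at
# the boundary is called live.

#' Viability-call parameters
#'
#' @slot method \code{"absolute_threshold"} or \code{"background_ratio"}.
#' @slot deadChannel dead-cell stain channel name.
#' @slot intensityThreshold absolute nuclear mean cut (a.u.), strict.
#' @slot ratioThreshold nuclear/background ratio cut (dimensionless,
#'   default 1.2), strict.
#' @slot statistic nuclear intensity statistic, \code{"mean"} (default)
#'   or \code{"sum"} (total nuclear intensity; absolute method only).
#' @exportClass ViabilityParams
setClass("ViabilityParams",
  representation(method = "character", deadChannel = "character",
                 intensityThreshold = "numeric",
                 ratioThreshold = "numeric", statistic = "character"))

setValidity("ViabilityParams", function(object) {
  msg <- character()
  if (!object@method %in% c("absolute_threshold", "background_ratio"))
    msg <- c(msg, "method must be absolute_threshold or background_ratio")
  if (object@method == "absolute_threshold" &&
      (!is.finite(object@intensityThreshold) ||
       object@intensityThreshold <= 0))
    msg <- c(msg, "intensityThreshold must be > 0")
  if (!is.finite(object@ratioThreshold) || object@ratioThreshold <= 0)
    msg <- c(msg, "ratioThreshold must be > 0")
  if (!object@statistic %in% c("mean", "sum"))
    msg <- c(msg, "statistic must be 'mean' or 'sum'")
  if (length(msg)) msg else TRUE
})

#' Construct viability parameters
#'
#' @param method \code{"background_ratio"} (default) or
#'   \code{"absolute_threshold"}.
#' @param deadChannel dead-stain channel name.
#' @param intensityThreshold absolute cut (a.u.), for the absolute method.
#' @param ratioThreshold ratio cut, default 1.2.
#' @param statistic \code{"mean"} or \code{"sum"} nuclear intensity.
#' @return A \linkS4class{ViabilityParams}.
#' @examples
#' viabilityParams()                             # ratio > 1.2 rule
#' viabilityParams("absolute_threshold", intensityThreshold = 150)
#' @export
viabilityParams <- function(method = c("background_ratio",
                                       "absolute_threshold"),
                            deadChannel = "dead",
                            intensityThreshold = NA_real_,
                            ratioThreshold = 1.2,
                            statistic = "mean") {
  new("ViabilityParams", method = match.arg(method),
      deadChannel = deadChannel,
      intensityThreshold = intensityThreshold,
      ratioThreshold = ratioThreshold, statistic = statistic)
}

#' Call each nucleus live or dead
#'
#' Absolute method: dead iff the nuclear dead-stain statistic strictly
#' exceeds \code{intensityThreshold}. Ratio method: dead iff nuclear
#' mean / background-ring mean strictly exceeds \code{ratioThreshold}
#' (default 1.2); a ratio of exactly 1.2 is live. Records whose
#' background-ring mean is missing or non-positive cannot be ratioed
#' and are returned as \code{NA} (unclassifiable, excluded from both
#' counts).
#'
#' @param records nucleus record table from \code{\link{segmentNuclei}}.
#' @param p a \linkS4class{ViabilityParams}.
#' @return logical vector aligned with \code{records}: TRUE = dead,
#'   FALSE = live, NA = unclassifiable.
#' @examples
#' rec <- data.frame(mean_dead = c(130, 120), bg_dead = c(100, 100),
#'                   qc_pass = TRUE)
#' callDead(rec, viabilityParams())   # TRUE (1.3), FALSE (exactly 1.2)
#' @export
callDead <- function(records, p = viabilityParams()) {
  stopifnot(is(p, "ViabilityParams"))
  validObject(p)
  mcol <- paste0("mean_", p@deadChannel)
  if (!mcol %in% names(records))
    stop("records lack the dead-channel mean column '", mcol, "'")
  nuc <- records[[mcol]]
  if (p@statistic == "sum") {
    if (!"area_px" %in% names(records))
      stop("statistic = 'sum' needs an 'area_px' column")
    nuc <- nuc * records$area_px
  }
  if (p@method == "absolute_threshold") {
    return(nuc > p@intensityThreshold)
  }
  bcol <- paste0("bg_", p@deadChannel)
  if (!bcol %in% names(records))
    stop("ratio method needs the background-ring column '", bcol, "'")
  bg <- records[[bcol]]
  out <- nuc / bg > p@ratioThreshold
  out[!is.finite(bg) | bg <= 0] <- NA
  out
}

#' Count live and dead cells in a field
#'
#' Dead is the number of TRUE calls among qc-passing records; live is
#' the remaining qc-passing, classifiable records (total minus dead
#' minus unclassifiable). Records failing segmentation QC never enter
#' either count.
#'
#' @param records nucleus record table (with \code{qc_pass}).
#' @param calls logical vector from \code{\link{callDead}}, aligned
#'   with \code{records}.
#' @return named integer vector \code{c(live, dead, unclassifiable)};
#'   \code{live + dead + unclassifiable} equals the number of
#'   qc-passing records.
#' @examples
#' rec <- data.frame(qc_pass = rep(TRUE, 5))
#' countLiveDead(rec, c(TRUE, FALSE, FALSE, NA, FALSE))
#' @export
countLiveDead <- function(records, calls) {
  if (nrow(records) != length(calls))
    stop("calls must align with records")
  ok <- records$qc_pass
  calls <- calls[ok]
  dead <- sum(calls, na.rm = TRUE)
  unclass <- sum(is.na(calls))
  live <- sum(ok) - dead - unclass
  c(live = as.integer(live), dead = as.integer(dead),
    unclassifiable = as.integer(unclass))
}
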