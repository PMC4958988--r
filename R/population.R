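# Subpopulation composition over time and condition.

#' Build a composition table from per-cell labels and vital calls
#'
#' Aggregates per-cell subpopulation labels and live/dead calls into
#' absolute counts and fractions per (time, condition, subpopulation,
#' vital state), pooling fields and replicate wells (per-well rows are
#' retained alongside the pooled rows). Fractions are over all
#' subpopulation x vital-state cells within a (time, condition)
#' stratum and sum to one.
#'
#' @param perCell data.frame with one row per cell: \code{well},
#'   \code{time_h}, \code{subpopulation}, \code{vital}
#'   (\code{"live"}/\code{"dead"}).
#' @param layout plate-layout data.frame mapping \code{well} to a
#'   \code{condition} column (see \code{\link{readPlateLayout}}).
#' @return list: \code{pooled} (data.frame time_h, condition,
#'   subpopulation, vital, count, fraction), \code{perWell} (same plus
#'   well). Empty strata keep count 0 and fraction NA (flagged).
#' @examples
#' pc <- data.frame(well = "A01", time_h = 0,
#'                  subpopulation = rep(c("tumor", "stroma"), c(54, 46)),
#'                  vital = "live")
#' lay <- data.frame(well = "A01", condition = "control")
#' buildComposition(pc, lay)$pooled
#' @export
buildComposition <- function(perCell, layout) {
  need <- c("well", "time_h", "subpopulation", "vital")
  if (!all(need %in% names(perCell)))
    stop("perCell must have columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(perCell$well), layout$well)
  if (length(unknown))
    stop("well(s) not in layout: ", paste(unknown, collapse = ", "))
  perCell$condition <- layout$condition[match(perCell$well, layout$well)]
  cnt <- function(df, keys) {
    agg <- aggregate(list(count = rep(1L, nrow(df))), df[keys], length)
    strat <- setdiff(keys, c("subpopulation", "vital"))
    tot <- aggregate(list(total = agg$count), agg[strat], sum)
    agg <- merge(agg, tot, by = strat)
    agg$fraction <- ifelse(agg$total > 0, agg$count / agg$total, NA_real_)
    agg$total <- NULL
    agg[do.call(order, agg[keys]), , drop = FALSE]
  }
  pooled <- cnt(perCell, c("time_h", "condition", "subpopulation", "vital"))
  perWell <- cnt(perCell, c("time_h", "condition", "well",
                            "subpopulation", "vital"))
  rownames(pooled) <- rownames(perWell) <- NULL
  list(pooled = pooled, perWell = perWell)
}

#' Scale dissociated-spheroid counts to whole-spheroid totals
#'
#' Dissociated spheroids are plated as an aliquot of the cell
#' suspension (by default 25 ul of 200 ul, dilution factor 8), so a
#' whole-spheroid estimate is the measured count times the dilution
#' factor. Both raw and scaled counts are reported.
#'
#' @param counts data.frame with a \code{count} column (one row per
#'   spheroid/well), or a numeric vector of measured counts.
#' @param dilutionFactor aliquot dilution factor (default 8 = 200/25).
#' @return data.frame with \code{count_measured} and
#'   \code{count_scaled}.
#' @examples
#' spheroidCounts(c(500, 800))        # scaled: 4000, 6400
#' @export
spheroidCounts <- function(counts, dilutionFactor = 8) {
  if (dilutionFactor <= 0) stop("dilutionFactor must be > 0")
  if (is.numeric(counts)) counts <- data.frame(count = counts)
  out <- counts
  out$count_measured <- out$count
  out$count_scaled <- out$count * dilutionFactor
  out$count <- NULL
  out
}
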