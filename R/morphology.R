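# Single-cell morphology features.
#
# Area is pixel count times pixelSize^2; roundness is the compactness
# statistic 4*pi*A/P^2 with the perimeter measured along the
# 8-connected boundary chain (diagonal steps weighted sqrt(2), which
# reduces rasterization bias); width-to-length is the minor/major axis
# ratio of the second-moment ellipse. Note that compactness formulas
# differ between analysis platforms, so absolute roundness values are
# comparable only within this package.

# second-moment ellipse axis ratio (minor/major) per label
.axis_ratio <- function(lab, nlab) {
  idx <- which(lab > 0)
  if (!length(idx)) return(numeric(nlab))
  L <- lab[idx]
  nr <- nrow(lab)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  f <- factor(L, levels = seq_len(nlab))
  n <- tabulate(L, nlab)
  my <- as.vector(rowsum(as.numeric(rows), f)) / pmax(n, 1)
  mx <- as.vector(rowsum(as.numeric(cols), f)) / pmax(n, 1)
  dy <- rows - my[L]; dx <- cols - mx[L]
  syy <- as.vector(rowsum(dy * dy, f)) / pmax(n, 1)
  sxx <- as.vector(rowsum(dx * dx, f)) / pmax(n, 1)
  sxy <- as.vector(rowsum(dx * dy, f)) / pmax(n, 1)
  tr <- sxx + syy
  det <- sxx * syy - sxy^2
  disc <- sqrt(pmax(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  ratio <- sqrt(pmax(0, l2) / pmax(l1, .Machine$double.eps))
  ratio[n == 0] <- NA_real_
  pmin(1, ratio)
}

#' Compute single-cell morphology features
#'
#' Measures every segmented cell: cell and nuclear area (um^2),
#' roundness 4*pi*A/P^2 of the cell outline, width-to-length ratio of
#' the cell's second-moment ellipse, and per-channel mean intensities
#' over the cell region. Objects smaller than \code{minAreaPx} pixels
#' are excluded (poor segmentation); cells flagged by segmentation QC
#' are carried through with \code{qc_pass = FALSE}.
#'
#' @param cellLabelMap integer cell label matrix (from
#'   \code{\link{segmentCells}} or ground truth); labels key nuclei.
#' @param nucleiLabelMap integer nucleus label matrix on the same grid.
#' @param img the \linkS4class{ImageField} measured.
#' @param minAreaPx minimum object size in pixels (default 8).
#' @param qc optional data.frame with \code{label} and \code{qc_pass}
#'   from cell segmentation, merged into the output.
#' @return data.frame, one row per cell: \code{label},
#'   \code{cell_area_um2}, \code{nuclear_area_um2}, \code{roundness},
#'   \code{width_to_length}, \code{perimeter_px}, per-channel
#'   \code{mean_<channel>}, \code{qc_pass}.
#' @export
computeMorphology <- function(cellLabelMap, nucleiLabelMap, img,
                              minAreaPx = 8L, qc = NULL) {
  stopifnot(is(img, "ImageField"))
  lab <- cellLabelMap
  storage.mode(lab) <- "integer"
  nlab <- max(lab, 0L)
  if (nlab == 0L) {
    return(data.frame(label = integer(), cell_area_um2 = numeric(),
                      nuclear_area_um2 = numeric(), roundness = numeric(),
                      width_to_length = numeric(), perimeter_px = numeric(),
                      qc_pass = logical()))
  }
  ps2 <- pixelSize(img)^2
  area_px <- tabulate(lab[lab > 0L], nlab)
  nuc_px <- tabulate(nucleiLabelMap[nucleiLabelMap > 0L], nlab)
  per <- chain_perimeter(lab, nlab)
  ratio <- .axis_ratio(lab, nlab)
  roundness <- 4 * pi * area_px / pmax(per, .Machine$double.eps)^2
  mns <- .channel_means(lab, img@channels, nlab)
  rec <- data.frame(label = seq_len(nlab),
                    cell_area_um2 = area_px * ps2,
                    nuclear_area_um2 = nuc_px * ps2,
                    roundness = roundness,
                    width_to_length = ratio,
                    perimeter_px = per, stringsAsFactors = FALSE)
  for (nm in names(mns)) rec[[nm]] <- mns[[nm]]
  rec$qc_pass <- TRUE
  if (!is.null(qc)) {
    bad <- qc$label[!qc$qc_pass]
    rec$qc_pass[rec$label %in% bad] <- FALSE
    rec <- rec[rec$label %in% qc$label, , drop = FALSE]
  }
  small <- area_px[rec$label] < minAreaPx
  if (any(small)) {
    message(sum(small), " object(s) below ", minAreaPx,
            " px excluded from morphology")
    rec <- rec[!small, , drop = FALSE]
  }
  rec <- rec[area_px[rec$label] > 0, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Distributions of a morphology feature over time (or any grouping)
#'
#' Histograms one feature per group with shared break points, plus
#' summary statistics (n, median, IQR), for tracking population
#' morphology over time or condition. Optionally exports a 2D binned
#' density of two features (e.g. cell area versus roundness).
#'
#' @param records per-cell feature table (rows = cells), containing
#'   \code{feature} and the \code{by} column.
#' @param feature feature column to histogram.
#' @param bins number of bins (breaks shared across groups).
#' @param by grouping column (default \code{"time_h"}); when missing
#'   from the table a single group is used.
#' @param feature2 optional second feature; when given, returns a 2D
#'   binned count table of \code{feature} x \code{feature2} per group.
#' @return list: \code{histogram} (data.frame group, bin_mid, count),
#'   \code{summary} (data.frame group, n, median, iqr, q25, q75).
#' @export
featureDistributions <- function(records, feature, bins = 30,
                                 by = "time_h", feature2 = NULL) {
  if (!feature %in% names(records))
    stop("configuration error: unknown feature '", feature, "'")
  if (!is.null(feature2) && !feature2 %in% names(records))
    stop("configuration error: unknown feature '", feature2, "'")
  if (!nrow(records)) stop("need at least one record")
  grp <- if (by %in% names(records)) records[[by]] else rep("all",
                                                            nrow(records))
  x <- records[[feature]]
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  mids <- (head(breaks, -1) + breaks[-1]) / 2
  hist_rows <- lapply(split(x, grp), function(xi) {
    ct <- tabulate(pmin(bins, pmax(1, findInterval(xi, breaks,
                                                   rightmost.closed = TRUE))),
                   bins)
    data.frame(bin_mid = mids, count = ct)
  })
  hist_df <- do.call(rbind, Map(function(g, d)
    cbind(group = g, d), names(hist_rows), hist_rows))
  rownames(hist_df) <- NULL
  summ <- do.call(rbind, lapply(split(x, grp), function(xi) {
    q <- quantile(xi, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(xi), median = q[2], iqr = q[3] - q[1],
               q25 = q[1], q75 = q[3])
  }))
  summ <- cbind(group = rownames(summ), summ)
  rownames(summ) <- NULL
  out <- list(histogram = hist_df, summary = summ)
  if (!is.null(feature2)) {
    y <- records[[feature2]]
    rng2 <- range(y, finite = TRUE)
    if (diff(rng2) == 0) rng2 <- rng2 + c(-0.5, 0.5)
    br2 <- seq(rng2[1], rng2[2], length.out = bins + 1)
    ix <- pmin(bins, pmax(1, findInterval(x, breaks, rightmost.closed = TRUE)))
    iy <- pmin(bins, pmax(1, findInterval(y, br2, rightmost.closed = TRUE)))
    out$density2d <- lapply(split(seq_along(x), grp), function(ii) {
      m <- matrix(0L, bins, bins)
      for (k in ii) m[ix[k], iy[k]] <- m[ix[k], iy[k]] + 1L
      dimnames(m) <- list(signif(mids, 6),
                          signif((head(br2, -1) + br2[-1]) / 2, 6))
      m
    })
  }
  out
}
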