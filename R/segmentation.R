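# Nuclear and whole-cell segmentation.
#
# Foreground by Otsu threshold on the blurred nuclear channel (with a
# fixed-threshold override), de-clumping by distance-transform
# watershed, whole-cell regions by seeded propagation on the cytoplasm
# tracker channel. Per-object records carry per-channel nuclear mean
# intensities and a background-ring mean measured in an annulus
# offset - halfwidth .. offset + halfwidth pixels outside the nucleus,
# excluding pixels of any nucleus.

#' Segmentation parameters
#'
#' @slot nuclearChannel channel used for nuclear segmentation.
#' @slot minNuclearArea,maxNuclearArea nuclear size filter, um^2;
#'   objects outside the window get \code{qc_pass = FALSE}.
#' @slot declump split touching nuclei by distance-transform watershed.
#' @slot cytoplasmChannel channel for whole-cell segmentation (NA when
#'   cells are not segmented).
#' @slot backgroundRingOffsetPx centre offset of the background annulus
#'   outside the nuclear boundary, px (default 30; the assay reads this
#'   as a per-cell-type offset in 15-45).
#' @slot backgroundRingHalfwidthPx half-width of the annulus, px.
#' @slot blurSigma Gaussian blur applied before thresholding, px.
#' @slot thresholdOverride fixed foreground threshold (a.u.) replacing
#'   Otsu when finite.
#' @slot watershedTolerance minimum distance-map depth separating two
#'   seeds during de-clumping, px.
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(nuclearChannel = "character",
                 minNuclearArea = "numeric", maxNuclearArea = "numeric",
                 declump = "logical", cytoplasmChannel = "character",
                 backgroundRingOffsetPx = "integer",
                 backgroundRingHalfwidthPx = "integer",
                 blurSigma = "numeric", thresholdOverride = "numeric",
                 watershedTolerance = "numeric"))

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (!(object@minNuclearArea > 0 &&
        object@minNuclearArea < object@maxNuclearArea))
    msg <- c(msg, "need 0 < minNuclearArea < maxNuclearArea")
  if (object@backgroundRingOffsetPx <= 0)
    msg <- c(msg, "backgroundRingOffsetPx must be > 0")
  if (object@backgroundRingHalfwidthPx < 0 ||
      object@backgroundRingHalfwidthPx >= object@backgroundRingOffsetPx)
    msg <- c(msg, "ring halfwidth must be in [0, offset)")
  if (length(msg)) msg else TRUE
})

#' Construct segmentation parameters
#'
#' @param nuclearChannel name of the nuclear-stain channel.
#' @param minNuclearArea,maxNuclearArea nuclear size window (um^2).
#' @param declump logical; split touching nuclei.
#' @param cytoplasmChannel cytoplasm-tracker channel name, or NA.
#' @param backgroundRingOffsetPx,backgroundRingHalfwidthPx background
#'   annulus geometry (px).
#' @param blurSigma pre-threshold Gaussian blur (px).
#' @param thresholdOverride fixed threshold (a.u.); NA uses Otsu.
#' @param watershedTolerance de-clumping watershed tolerance (px).
#' @return A \linkS4class{SegmentationParams}.
#' @export
segmentationParams <- function(nuclearChannel = "nuclear",
                               minNuclearArea = 50,
                               maxNuclearArea = 2000,
                               declump = TRUE,
                               cytoplasmChannel = NA_character_,
                               backgroundRingOffsetPx = 30L,
                               backgroundRingHalfwidthPx = 15L,
                               blurSigma = 1,
                               thresholdOverride = NA_real_,
                               watershedTolerance = 0.25) {
  new("SegmentationParams", nuclearChannel = nuclearChannel,
      minNuclearArea = minNuclearArea, maxNuclearArea = maxNuclearArea,
      declump = declump, cytoplasmChannel = cytoplasmChannel,
      backgroundRingOffsetPx = as.integer(backgroundRingOffsetPx),
      backgroundRingHalfwidthPx = as.integer(backgroundRingHalfwidthPx),
      blurSigma = blurSigma, thresholdOverride = thresholdOverride,
      watershedTolerance = watershedTolerance)
}

# per-label pixel statistics from a label matrix
.label_stats <- function(lab) {
  nlab <- max(lab)
  idx <- which(lab > 0)
  L <- lab[idx]
  nr <- nrow(lab); nc <- ncol(lab)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  area <- tabulate(L, nlab)
  keep <- area > 0
  f <- factor(L, levels = seq_len(nlab))
  cy <- as.vector(rowsum(as.numeric(rows), f)) / pmax(area, 1L)
  cx <- as.vector(rowsum(as.numeric(cols), f)) / pmax(area, 1L)
  border <- as.vector(rowsum(as.numeric(rows == 1L | rows == nr |
                                        cols == 1L | cols == nc), f)) > 0
  list(nlab = nlab, area_px = area, cy = cy, cx = cx, border = border,
       present = keep)
}

.channel_means <- function(lab, channels, nlab) {
  idx <- which(lab > 0)
  f <- factor(lab[idx], levels = seq_len(nlab))
  area <- tabulate(lab[idx], nlab)
  out <- lapply(channels, function(ch)
    as.vector(rowsum(ch[idx], f)) / pmax(area, 1L))
  names(out) <- paste0("mean_", names(channels))
  out
}

# annulus mean outside one nucleus, excluding all nuclear pixels
.background_ring_means <- function(lab, channels, nlab, offset, halfw) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- offset + halfw + 2L
  out <- matrix(NA_real_, nlab, length(channels),
                dimnames = list(NULL, paste0("bg_", names(channels))))
  st <- .label_stats(lab)
  for (L in seq_len(nlab)) {
    if (st$area_px[L] == 0) next
    rad <- sqrt(st$area_px[L] / pi)
    r0 <- max(1L, floor(st$cy[L] - rad - pad))
    r1 <- min(nr, ceiling(st$cy[L] + rad + pad))
    c0 <- max(1L, floor(st$cx[L] - rad - pad))
    c1 <- min(nc, ceiling(st$cx[L] + rad + pad))
    sub <- lab[r0:r1, c0:c1]
    objm <- sub == L
    if (!any(objm)) next
    dist <- EBImage::distmap(1 - objm)
    ring <- dist >= (offset - halfw) & dist <= (offset + halfw) & sub == 0L
    if (!any(ring)) next
    for (j in seq_along(channels))
      out[L, j] <- mean(channels[[j]][r0:r1, c0:c1][ring])
  }
  out
}

#' Segment nuclei from the nuclear-stain channel
#'
#' Thresholds the blurred nuclear channel (Otsu by default), labels
#' connected components, optionally splits touching clumps with a
#' distance-transform watershed, and measures every object: centroid,
#' area, per-channel nuclear mean intensity and per-channel background
#' annulus mean. Objects outside the nuclear size window or touching
#' the field border are retained in the table with
#' \code{qc_pass = FALSE} and excluded from counts downstream.
#'
#' @param img an \linkS4class{ImageField}.
#' @param p a \linkS4class{SegmentationParams}.
#' @return list with \code{labelMap} (integer matrix; 0 = background)
#'   and \code{records} (data.frame, one row per object: \code{label},
#'   \code{centroid_row}, \code{centroid_col}, \code{area_px},
#'   \code{area_um2}, \code{mean_<channel>}, \code{bg_<channel>},
#'   \code{qc_pass}, \code{qc_reason}), plus a \code{blank} flag set
#'   when the image carried no usable foreground.
#' @export
segmentNuclei <- function(img, p = segmentationParams()) {
  stopifnot(is(img, "ImageField"), is(p, "SegmentationParams"))
  validObject(p)
  if (!p@nuclearChannel %in% channelNames(img))
    stop("configuration error: nuclear channel '", p@nuclearChannel,
         "' not present in image field")
  x <- getChannel(img, p@nuclearChannel)
  xb <- as.matrix(EBImage::gblur(x, sigma = p@blurSigma))
  rng <- range(xb)
  blank <- FALSE
  if (diff(rng) < .Machine$double.eps^0.5) {
    warning("blank or saturated nuclear channel; no objects segmented")
    blank <- TRUE
    mask <- matrix(FALSE, nrow(x), ncol(x))
  } else if (is.finite(p@thresholdOverride)) {
    mask <- xb > p@thresholdOverride
  } else {
    xn <- (xb - rng[1]) / diff(rng)
    mask <- xn > EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  }
  if (!any(mask)) {
    lab <- matrix(0L, nrow(x), ncol(x))
    rec <- .empty_nucleus_records(channelNames(img))
    return(list(labelMap = lab, records = rec, blank = TRUE))
  }
  if (p@declump) {
    # sub-pixel distance transform: the watershed runs on a 2x
    # nearest-neighbour upsampled mask, halving discretization bumps in
    # the distance map so shallow saddles between touching nuclei are
    # still detected; tolerance is stated in original pixels
    up <- 2L
    m2 <- mask[rep(seq_len(nrow(mask)), each = up),
               rep(seq_len(ncol(mask)), each = up)]
    ws <- EBImage::watershed(EBImage::distmap(m2),
                             tolerance = up * p@watershedTolerance,
                             ext = up)
    lab <- EBImage::imageData(ws)[seq(1, nrow(m2), up),
                                  seq(1, ncol(m2), up)]
  } else {
    lab <- EBImage::imageData(EBImage::bwlabel(mask))
  }
  storage.mode(lab) <- "integer"
  st <- .label_stats(lab)
  nlab <- st$nlab
  ps2 <- pixelSize(img)^2
  area_um2 <- st$area_px * ps2
  qc_reason <- rep("", nlab)
  qc_reason[area_um2 < p@minNuclearArea] <- "too_small"
  qc_reason[area_um2 > p@maxNuclearArea] <- "too_large"
  qc_reason[st$border] <- "border"
  mns <- .channel_means(lab, img@channels, nlab)
  bgs <- .background_ring_means(lab, img@channels, nlab,
                                p@backgroundRingOffsetPx,
                                p@backgroundRingHalfwidthPx)
  rec <- data.frame(label = seq_len(nlab),
                    centroid_row = st$cy, centroid_col = st$cx,
                    area_px = st$area_px, area_um2 = area_um2,
                    stringsAsFactors = FALSE)
  for (nm in names(mns)) rec[[nm]] <- mns[[nm]]
  for (nm in colnames(bgs)) rec[[nm]] <- bgs[, nm]
  rec$qc_pass <- qc_reason == ""
  rec$qc_reason <- qc_reason
  rec <- rec[st$present, , drop = FALSE]
  rownames(rec) <- NULL
  list(labelMap = lab, records = rec, blank = blank)
}

.empty_nucleus_records <- function(chn) {
  rec <- data.frame(label = integer(), centroid_row = numeric(),
                    centroid_col = numeric(), area_px = integer(),
                    area_um2 = numeric(), stringsAsFactors = FALSE)
  for (nm in c(paste0("mean_", chn), paste0("bg_", chn)))
    rec[[nm]] <- numeric()
  rec$qc_pass <- logical()
  rec$qc_reason <- character()
  rec
}

#' Segment whole cells around nuclear seeds
#'
#' Grows one cell region per qc-passing nucleus by seeded propagation
#' over the cytoplasm-tracker channel, confined to above-background
#' cytoplasm signal (the nucleus itself is always part of its cell).
#' Cells touching the field border, without surrounding cytoplasm
#' signal, or with implausible geometry are flagged
#' \code{qc_pass = FALSE}.
#'
#' @param img an \linkS4class{ImageField}.
#' @param nuclei the result of \code{\link{segmentNuclei}} (or a
#'   compatible list with \code{labelMap} and \code{records}).
#' @param p a \linkS4class{SegmentationParams} with
#'   \code{cytoplasmChannel} set.
#' @return list with \code{labelMap} (cell labels, keyed by nucleus
#'   label) and \code{records} (data.frame: \code{label},
#'   \code{cell_area_px}, \code{cell_area_um2}, \code{qc_pass},
#'   \code{qc_reason}).
#' @export
segmentCells <- function(img, nuclei, p) {
  stopifnot(is(img, "ImageField"), is(p, "SegmentationParams"))
  if (is.na(p@cytoplasmChannel))
    stop("configuration error: no cytoplasm channel configured")
  if (!p@cytoplasmChannel %in% channelNames(img))
    stop("configuration error: cytoplasm channel '", p@cytoplasmChannel,
         "' not present in image field")
  nucLab <- nuclei$labelMap
  nrec <- nuclei$records
  seeds <- nucLab
  drop <- nrec$label[!nrec$qc_pass]
  seeds[seeds %in% drop] <- 0L
  cyto <- getChannel(img, p@cytoplasmChannel)
  cb <- as.matrix(EBImage::gblur(cyto, sigma = p@blurSigma))
  rng <- range(cb)
  cmask <- if (diff(rng) < .Machine$double.eps^0.5)
    matrix(FALSE, nrow(cb), ncol(cb))
  else {
    cn <- (cb - rng[1]) / diff(rng)
    cn > EBImage::otsu(EBImage::Image(cn), range = c(0, 1))
  }
  cmask <- cmask | seeds > 0L
  cellLab <- EBImage::imageData(EBImage::propagate(EBImage::Image(cb),
                                                   seeds = seeds,
                                                   mask = cmask))
  storage.mode(cellLab) <- "integer"
  nlab <- max(nucLab)
  st <- .label_stats(cellLab)
  nuc_area <- tabulate(nucLab[nucLab > 0L], nlab)
  keep <- nrec$label[nrec$qc_pass]
  ps2 <- pixelSize(img)^2
  cell_area <- st$area_px
  qc_reason <- rep("", st$nlab)
  qc_reason[st$border] <- "border"
  no_cyto <- cell_area <= nuc_area[seq_len(st$nlab)] * 1.02
  qc_reason[no_cyto & qc_reason == ""] <- "no_cytoplasm"
  implaus <- cell_area > 40 * pmax(nuc_area[seq_len(st$nlab)], 1)
  qc_reason[implaus & qc_reason == ""] <- "poor_segmentation"
  rec <- data.frame(label = seq_len(st$nlab),
                    cell_area_px = cell_area,
                    cell_area_um2 = cell_area * ps2,
                    qc_pass = qc_reason == "",
                    qc_reason = qc_reason, stringsAsFactors = FALSE)
  rec <- rec[rec$label %in% keep & st$present, , drop = FALSE]
  rownames(rec) <- NULL
  list(labelMap = cellLab, records = rec)
}
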