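# Ground-truthed synthetic image fields.
#
# Cells are rendered as anti-aliased ellipses (nuclei) inside circular
# cell bodies on a flat background, with additive Gaussian noise as a
# stand-in for shot noise. A configurable fraction of cells is placed
# as touching pairs (centre distance 1.2-1.6 nuclear radii) to force
# the de-clumping path in segmentation. Dead cells carry an elevated
# dead-stain plateau over their exact nuclear mask so that the
# nuclear-mean postcondition holds before noise.

#' Construct a synthetic image specification
#'
#' Defaults describe a typical non-confluent two-population co-culture
#' field: a smaller, rounder "tumor" type labeled in the RFP channel
#' and a larger "stroma" type labeled in GFP, at about 30\% cell-body
#' coverage, with a 1.2x dead/live stain contrast well above the
#' live-level baseline.
#'
#' @param fieldSize image size in pixels (rows, cols).
#' @param nCells named integer vector of cells per type.
#' @param nucleusRadiusMean,nucleusRadiusSd per-type nuclear radius (px).
#' @param cellRadiusMean,cellRadiusSd per-type cell-body radius (px).
#' @param fractionDead per-type fraction rendered dead.
#' @param deadStainLiveLevel,deadStainDeadLevel dead-channel nuclear
#'   plateau for live and dead cells (a.u.).
#' @param backgroundLevel image background (a.u.).
#' @param noiseSd additive Gaussian noise sd (a.u.).
#' @param labelChannelByType named map from type to fluorescence channel.
#' @param touchingPairFraction fraction of cells placed in touching pairs.
#' @param pixelSize micrometres per pixel.
#' @param seed RNG seed; rendering is bit-reproducible given spec + seed.
#' @return A \linkS4class{SynthImageSpec}.
#' @examples
#' spec <- synthImageSpec(nCells = c(tumor = 30), seed = 7)
#' @export
synthImageSpec <- function(fieldSize = c(512L, 512L),
                           nCells = c(tumor = 50L, stroma = 25L),
                           nucleusRadiusMean = NULL,
                           nucleusRadiusSd = NULL,
                           cellRadiusMean = NULL,
                           cellRadiusSd = NULL,
                           fractionDead = NULL,
                           deadStainLiveLevel = 110,
                           deadStainDeadLevel = 200,
                           backgroundLevel = 100,
                           noiseSd = 5,
                           labelChannelByType = NULL,
                           touchingPairFraction = 0.1,
                           pixelSize = 1,
                           seed = 1L) {
  nt <- length(nCells)
  types <- names(nCells)
  rep_t <- function(x, def) {
    if (is.null(x)) x <- def
    if (length(x) == 1L) x <- rep(x, nt)
    stats::setNames(x, types)
  }
  # default sizes: first type small/round, later types progressively larger
  def_nr <- 8 + 2 * (seq_len(nt) - 1L)
  def_cr <- 16 + 4 * (seq_len(nt) - 1L)
  if (is.null(labelChannelByType)) {
    def_ch <- c("RFP", "GFP", "CH3", "CH4")[seq_len(nt)]
    labelChannelByType <- stats::setNames(def_ch, types)
  }
  new("SynthImageSpec",
      fieldSize = as.integer(fieldSize),
      nCells = stats::setNames(as.integer(nCells), types),
      nucleusRadiusMean = rep_t(nucleusRadiusMean, def_nr),
      nucleusRadiusSd = rep_t(nucleusRadiusSd, 0.15 * def_nr),
      cellRadiusMean = rep_t(cellRadiusMean, def_cr),
      cellRadiusSd = rep_t(cellRadiusSd, 0.1 * def_cr),
      fractionDead = rep_t(fractionDead, 0.2),
      deadStainLiveLevel = deadStainLiveLevel,
      deadStainDeadLevel = deadStainDeadLevel,
      backgroundLevel = backgroundLevel,
      noiseSd = noiseSd,
      labelChannelByType = labelChannelByType,
      touchingPairFraction = touchingPairFraction,
      pixelSize = pixelSize,
      seed = as.integer(seed))
}

# anti-aliased coverage of a rotated ellipse over a pixel grid crop;
# returns list(rows, cols, cov) restricted to the bounding box
.ellipse_coverage <- function(center, r, axisRatio, theta, fieldSize) {
  a <- r / sqrt(axisRatio)          # semi-major
  b <- r * sqrt(axisRatio)          # semi-minor; area = pi r^2 preserved
  ext <- ceiling(a) + 2L
  r0 <- max(1L, floor(center[1] - ext)); r1 <- min(fieldSize[1], ceiling(center[1] + ext))
  c0 <- max(1L, floor(center[2] - ext)); c1 <- min(fieldSize[2], ceiling(center[2] + ext))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  dy <- outer(rows - center[1], rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - center[2])
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  dn <- sqrt((u / a)^2 + (v / b)^2)
  cov <- pmin(1, pmax(0, 0.5 + (1 - dn) * b))
  list(rows = rows, cols = cols, cov = cov, dn = dn)
}

#' Render a synthetic image field with ground truth
#'
#' Produces one intensity matrix per channel (nuclear stain, dead-cell
#' stain, one fluorescence channel per labeled type, and a cytoplasm
#' tracker) together with the exact ground truth: per-object centroid,
#' type, alive flag, true sizes, and pixel-level nucleus/cell label
#' maps (touching-pair pixels are assigned to the nearer generating
#' centre). Identical spec and seed give bit-identical output.
#'
#' @param spec a \linkS4class{SynthImageSpec}.
#' @return A list with elements \code{field} (\linkS4class{ImageField}),
#'   \code{objects} (ground-truth data.frame, one row per rendered
#'   object), \code{nucleusMap} and \code{cellMap} (integer label
#'   matrices keyed by object id).
#' @examples
#' out <- renderField(synthImageSpec(nCells = c(tumor = 10), seed = 3))
#' nrow(out$objects)
#' @export
renderField <- function(spec) {
  stopifnot(is(spec, "SynthImageSpec"))
  validObject(spec)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec@seed)

  fs <- spec@fieldSize
  types <- names(spec@nCells)
  n <- sum(spec@nCells)
  bg <- spec@backgroundLevel

  label_channels <- unique(spec@labelChannelByType[
    !is.na(spec@labelChannelByType)])
  ch_names <- c("nuclear", "dead", label_channels, "cyto")
  blank <- matrix(0, fs[1], fs[2])
  channels <- stats::setNames(replicate(length(ch_names), blank,
                                        simplify = FALSE), ch_names)
  nucMap <- matrix(0L, fs[1], fs[2])
  cellMap <- matrix(0L, fs[1], fs[2])

  obj <- NULL
  if (n > 0) {
    type <- rep(types, spec@nCells)
    type <- sample(type)           # interleave types for pairing
    nr <- pmax(3, rnorm(n, spec@nucleusRadiusMean[type],
                        spec@nucleusRadiusSd[type]))
    cr <- pmax(nr + 2, rnorm(n, spec@cellRadiusMean[type],
                             spec@cellRadiusSd[type]))
    alive <- rbinom(n, 1L, 1 - spec@fractionDead[type]) == 1L
    axisRatio <- runif(n, 0.8, 1)
    theta <- runif(n, 0, pi)
    nPairs <- floor(spec@touchingPairFraction * n / 2)
    pair_id <- rep(NA_integer_, n)
    if (nPairs > 0) pair_id[seq_len(2 * nPairs)] <- rep(seq_len(nPairs),
                                                        each = 2)
    cy <- cx <- rep(NA_real_, n)
    maxAttempts <- 400L
    for (i in seq_len(n)) {
      margin <- cr[i] + 1
      placed <- FALSE
      partner <- if (!is.na(pair_id[i]) && i %% 2 == 0L) i - 1L else NA
      for (att in seq_len(maxAttempts)) {
        if (!is.na(partner)) {
          dist <- runif(1, 1.2, 1.6) * (nr[i] + nr[partner]) / 2
          phi <- runif(1, 0, 2 * pi)
          y <- cy[partner] + dist * sin(phi)
          x <- cx[partner] + dist * cos(phi)
          if (y < margin || y > fs[1] - margin ||
              x < margin || x > fs[2] - margin) next
          others <- setdiff(which(!is.na(cy)), partner)
        } else {
          y <- runif(1, margin, fs[1] - margin)
          x <- runif(1, margin, fs[2] - margin)
          others <- which(!is.na(cy))
        }
        if (length(others)) {
          dd <- sqrt((cy[others] - y)^2 + (cx[others] - x)^2)
          if (any(dd < nr[others] + nr[i] + 4)) next
        }
        cy[i] <- y; cx[i] <- x; placed <- TRUE
        break
      }
      if (!placed)
        stop("placement error: field too small for the requested cell ",
             "count at this density")
    }

    bestDn <- matrix(Inf, fs[1], fs[2])
    bestDc <- matrix(Inf, fs[1], fs[2])
    nucAmp <- 900; labelAmp <- 400; cytoAmp <- 200
    for (i in seq_len(n)) {
      e <- .ellipse_coverage(c(cy[i], cx[i]), nr[i], axisRatio[i],
                             theta[i], fs)
      channels$nuclear[e$rows, e$cols] <-
        pmax(channels$nuclear[e$rows, e$cols], nucAmp * e$cov)
      inmask <- e$cov >= 0.5
      closer <- inmask & e$dn < bestDn[e$rows, e$cols]
      sub <- nucMap[e$rows, e$cols]; sub[closer] <- i
      nucMap[e$rows, e$cols] <- sub
      bd <- bestDn[e$rows, e$cols]; bd[closer] <- e$dn[closer]
      bestDn[e$rows, e$cols] <- bd

      cb <- .ellipse_coverage(c(cy[i], cx[i]), cr[i], 1, 0, fs)
      channels$cyto[cb$rows, cb$cols] <-
        pmax(channels$cyto[cb$rows, cb$cols], cytoAmp * cb$cov)
      lab_ch <- spec@labelChannelByType[type[i]]
      if (!is.na(lab_ch))
        channels[[lab_ch]][cb$rows, cb$cols] <-
          pmax(channels[[lab_ch]][cb$rows, cb$cols], labelAmp * cb$cov)
      cin <- cb$cov >= 0.5
      ccl <- cin & cb$dn < bestDc[cb$rows, cb$cols]
      sub <- cellMap[cb$rows, cb$cols]; sub[ccl] <- i
      cellMap[cb$rows, cb$cols] <- sub
      bd <- bestDc[cb$rows, cb$cols]; bd[ccl] <- cb$dn[ccl]
      bestDc[cb$rows, cb$cols] <- bd
    }
    # dead-stain channel: exact plateau over the owned nuclear mask so
    # the nuclear mean equals the specified level before noise
    deadLevel <- ifelse(alive, spec@deadStainLiveLevel,
                        spec@deadStainDeadLevel)
    channels$dead[nucMap > 0] <- (deadLevel - bg)[nucMap[nucMap > 0]]

    obj <- data.frame(
      id = seq_len(n), type = type, row = cy, col = cx, alive = alive,
      nucleus_radius_px = nr, cell_radius_px = cr,
      axis_ratio = axisRatio, theta = theta,
      pair_id = pair_id,
      label_channel = unname(spec@labelChannelByType[type]),
      nuclear_area_px = as.vector(table(factor(nucMap[nucMap > 0],
                                               levels = seq_len(n)))),
      cell_area_px = as.vector(table(factor(cellMap[cellMap > 0],
                                            levels = seq_len(n)))),
      stringsAsFactors = FALSE)
  } else {
    obj <- data.frame(id = integer(), type = character(), row = numeric(),
                      col = numeric(), alive = logical(),
                      nucleus_radius_px = numeric(),
                      cell_radius_px = numeric(), axis_ratio = numeric(),
                      theta = numeric(), pair_id = integer(),
                      label_channel = character(),
                      nuclear_area_px = numeric(),
                      cell_area_px = numeric(), stringsAsFactors = FALSE)
  }

  # smooth the segmentation channels a little (optics-like softening),
  # add flat background and Gaussian noise everywhere
  for (nm in c("nuclear", "cyto"))
    channels[[nm]] <- as.matrix(EBImage::gblur(channels[[nm]], sigma = 1))
  npx <- prod(fs)
  for (nm in ch_names) {
    channels[[nm]] <- channels[[nm]] + bg
    if (spec@noiseSd > 0)
      channels[[nm]] <- channels[[nm]] +
        matrix(rnorm(npx, 0, spec@noiseSd), fs[1], fs[2])
    channels[[nm]][channels[[nm]] < 0] <- 0
  }

  list(field = imageField(channels, pixelSize = spec@pixelSize),
       objects = obj, nucleusMap = nucMap, cellMap = cellMap)
}
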