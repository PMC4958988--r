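# Standard-format readers/writers and pipeline orchestration.
#
# Image convention: one single-channel TIFF per channel, named
# {well}_{field}_t{hours}_{channel}.tif (a pluggable parser accepts
# other schemes). CSV dialect: UTF-8, comma, header row, '.' decimal;
# every CSV written by a pipeline run carries a one-line run manifest
# as a '#' comment (config hash, seed, package version), which the
# readers skip.

.manifest_line <- function(seed = NA, configHash = NA) {
  sprintf("# hcsquant manifest: version=%s seed=%s config=%s date=%s",
          as.character(packageVersion("hcsquant")), seed, configHash,
          format(Sys.Date()))
}

#' Write / read a CSV with a run-manifest comment line
#'
#' @param x data.frame to write.
#' @param path file path.
#' @param seed,configHash recorded in the manifest line.
#' @return \code{readManifestCSV}: the data.frame (manifest skipped).
#' @export
writeManifestCSV <- function(x, path, seed = NA, configHash = NA) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.manifest_line(seed, configHash), con)
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifestCSV
#' @export
readManifestCSV <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write an image field as per-channel TIFFs
#'
#' One 32-bit float single-channel TIFF per channel, named
#' \code{{well}_{field}_t{hours}_{channel}.tif}.
#'
#' @param img an \linkS4class{ImageField}.
#' @param dir output directory (created if needed).
#' @param scale intensities are divided by \code{scale} before writing
#'   (TIFF stores [0,1] floats); the same scale must be used to read.
#' @return character vector of file paths, invisibly.
#' @export
writeImageField <- function(img, dir, scale = 65535) {
  stopifnot(is(img, "ImageField"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(channelNames(img), function(ch) {
    p <- file.path(dir, sprintf("%s_%s_t%g_%s.tif", img@well, img@field,
                                img@timeH, ch))
    m <- getChannel(img, ch) / scale
    m[m < 0] <- 0
    m[m > 1] <- 1
    tiff::writeTIFF(m, p, bits.per.sample = 32L)
    p
  }, character(1))
  invisible(paths)
}

#' Parse an image file name into well/field/time/channel
#'
#' Default parser for the \code{{well}_{field}_t{hours}_{channel}.tif}
#' convention; supply a custom function of the same shape for other
#' schemes.
#'
#' @param filename file name (without directory).
#' @return list with \code{well}, \code{field}, \code{timeH},
#'   \code{channel}, or NULL when the name does not match.
#' @export
parseImageFilename <- function(filename) {
  m <- regmatches(filename,
                  regexec("^([^_]+)_([^_]+)_t([0-9.]+)_(.+)\\.tiff?$",
                          filename))[[1]]
  if (length(m) != 5L) return(NULL)
  list(well = m[2], field = m[3], timeH = as.numeric(m[4]), channel = m[5])
}

#' Read an image field from per-channel TIFFs
#'
#' @param dir directory holding the channel TIFFs.
#' @param well,field,timeH identifiers selecting the field.
#' @param pixelSize micrometres per pixel of the acquisition.
#' @param scale intensity scale used at write time.
#' @param parser filename parser (see \code{\link{parseImageFilename}}).
#' @return An \linkS4class{ImageField}.
#' @export
readImageField <- function(dir, well, field, timeH, pixelSize = 1,
                           scale = 65535, parser = parseImageFilename) {
  files <- list.files(dir, pattern = "\\.tiff?$")
  channels <- list()
  for (f in files) {
    info <- parser(f)
    if (is.null(info)) next
    if (info$well == well && info$field == field && info$timeH == timeH)
      channels[[info$channel]] <-
        tiff::readTIFF(file.path(dir, f)) * scale
  }
  if (!length(channels))
    stop("no channel TIFFs found for ", well, "/", field, " t=", timeH,
         " in ", dir)
  imageField(channels, pixelSize = pixelSize, well = well, field = field,
             timeH = timeH)
}

#' Read and validate a plate layout
#'
#' The layout CSV maps wells to conditions; columns: \code{well},
#' \code{condition} (label), and optionally \code{drug_conc},
#' \code{oxygen_pct}, \code{glucose_g_per_L}, \code{coculture},
#' \code{cell_types}, \code{seeding_density}, \code{replicate}.
#' Wells must be unique and numeric condition fields non-negative.
#'
#' @param path layout CSV path.
#' @return validated data.frame.
#' @export
readPlateLayout <- function(path) {
  lay <- readManifestCSV(path)
  if (!all(c("well", "condition") %in% names(lay)))
    stop("validation error: layout needs 'well' and 'condition' columns")
  if (anyDuplicated(lay$well))
    stop("validation error: duplicate wells in layout")
  for (cc in intersect(c("drug_conc", "oxygen_pct", "glucose_g_per_L",
                         "seeding_density"), names(lay)))
    if (any(lay[[cc]] < 0, na.rm = TRUE))
      stop("validation error: negative values in layout column ", cc)
  lay
}

#' Assemble WellTimeSeries objects from a counts table
#'
#' @param counts data.frame with columns \code{well}, \code{time_h},
#'   \code{live}, \code{dead_cum} and optionally \code{subpopulation}.
#' @param layout plate layout (see \code{\link{readPlateLayout}}).
#' @param enforceMonotoneDead force \code{dead_cum} non-decreasing by
#'   running maximum (off by default; endpoint-plate dead counts are
#'   already cumulative).
#' @return named list of \linkS4class{WellTimeSeries}, one per well.
#' @export
countsToSeries <- function(counts, layout, enforceMonotoneDead = FALSE) {
  need <- c("well", "time_h", "live", "dead_cum")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  if (!"subpopulation" %in% names(counts)) counts$subpopulation <- "all"
  out <- lapply(split(counts, counts$well), function(cw) {
    cw <- cw[order(cw$subpopulation, cw$time_h), , drop = FALSE]
    if (enforceMonotoneDead)
      cw$dead_cum <- ave(cw$dead_cum, cw$subpopulation, FUN = cummax)
    w <- cw$well[1]
    li <- layout[layout$well == w, , drop = FALSE]
    cond <- if (nrow(li)) {
      condition(
        drugConc = if ("drug_conc" %in% names(li)) li$drug_conc[1] else 0,
        oxygenPct = if ("oxygen_pct" %in% names(li)) li$oxygen_pct[1] else 21,
        glucose = if ("glucose_g_per_L" %in% names(li))
          li$glucose_g_per_L[1] else 4.5,
        coculture = if ("coculture" %in% names(li))
          isTRUE(li$coculture[1]) else FALSE,
        label = li$condition[1])
    } else stop("well ", w, " not found in layout")
    rep_id <- if ("replicate" %in% names(li)) as.character(li$replicate[1])
              else w
    new("WellTimeSeries", condition = cond, replicateId = rep_id,
        data = data.frame(time_h = cw$time_h,
                          subpopulation = cw$subpopulation,
                          live = cw$live, dead_cum = cw$dead_cum),
        flags = character())
  })
  out
}

#' Fit the rate grid from a counts CSV and a plate layout
#'
#' The counts-CSV entry point of the pipeline: reads per-well live and
#' cumulative dead counts, groups wells into conditions via the
#' layout (replicate wells pooled into one regression), and returns
#' the per-condition rate decomposition table.
#'
#' @param countsPath counts CSV (\code{well}, \code{time_h},
#'   \code{live}, \code{dead_cum}).
#' @param layoutPath plate-layout CSV.
#' @param out optional output CSV path for the rate table.
#' @param ... passed to \code{\link{rateGrid}}.
#' @return the rate grid data.frame (invisibly when written).
#' @export
fitRatesFromCSV <- function(countsPath, layoutPath, out = NULL, ...) {
  counts <- readManifestCSV(countsPath)
  layout <- readPlateLayout(layoutPath)
  series <- countsToSeries(counts, layout)
  byCond <- split(series,
                  vapply(series, function(s) s@condition@label,
                         character(1)))
  grid <- rateGrid(byCond, ...)
  if (!is.null(out)) {
    writeManifestCSV(grid, out)
    return(invisible(grid))
  }
  grid
}

#' Run the full pipeline on a directory of images or a counts CSV
#'
#' Executes the stages segment -> viability -> morphology -> classify
#' -> composition -> rates in order, skipping stages whose inputs are
#' not configured (e.g. no dead channel: viability refused with a
#' warning; fewer than two time points: rates skipped). All outputs
#' are CSVs under \code{config$outDir}, each carrying a run manifest;
#' reruns with identical inputs are byte-identical apart from the
#' manifest date.
#'
#' @param config a list (or path to a YAML/JSON file) with entries:
#'   \code{imageDir} or \code{countsCsv}; \code{layoutCsv};
#'   \code{outDir}; \code{pixelSize}; \code{channels} (named list:
#'   \code{nuclear}, \code{dead}, \code{cyto}, \code{labels} =
#'   character vector); optional \code{labelThresholds} (named);
#'   optional \code{seed}; optional \code{stages} (subset to run).
#' @return named list of the produced tables.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$outDir)) stop("validation error: config needs outDir")
  if (is.null(config$layoutCsv))
    stop("validation error: config needs layoutCsv")
  if (is.null(config$imageDir) && is.null(config$countsCsv))
    stop("validation error: config needs imageDir or countsCsv")
  layout <- readPlateLayout(config$layoutCsv)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) NA else config$seed
  cfgHash <- substr(.hash_config(config), 1, 12)
  stages <- config$stages
  out <- list()

  if (!is.null(config$imageDir)) {
    fields <- .discover_fields(config$imageDir)
    if (!nrow(fields)) stop("no images found in ", config$imageDir)
    ch <- config$channels
    segP <- segmentationParams(
      nuclearChannel = if (is.null(ch$nuclear)) "nuclear" else ch$nuclear,
      cytoplasmChannel = if (is.null(ch$cyto)) NA_character_ else ch$cyto)
    can_viab <- !is.null(ch$dead)
    if (!can_viab)
      warning("no dead channel configured: viability stage skipped")
    perCell <- NULL
    counts <- NULL
    for (i in seq_len(nrow(fields))) {
      fi <- fields[i, ]
      img <- readImageField(config$imageDir, fi$well, fi$field, fi$timeH,
                            pixelSize = config$pixelSize %||% 1)
      seg <- segmentNuclei(img, segP)
      calls <- if (can_viab)
        callDead(seg$records, viabilityParams(deadChannel = ch$dead))
      else rep(NA, nrow(seg$records))
      cl <- if (can_viab) countLiveDead(seg$records, calls)
            else c(live = sum(seg$records$qc_pass), dead = 0L,
                   unclassifiable = 0L)
      counts <- rbind(counts,
                      data.frame(well = fi$well, field = fi$field,
                                 time_h = fi$timeH, live = cl["live"],
                                 dead = cl["dead"],
                                 unclassifiable = cl["unclassifiable"]))
      morph <- if (!is.na(segP@cytoplasmChannel)) {
        cells <- segmentCells(img, seg, segP)
        computeMorphology(cells$labelMap, seg$labelMap, img,
                          qc = cells$records)
      } else {
        computeMorphology(seg$labelMap, seg$labelMap, img,
                          qc = seg$records[, c("label", "qc_pass")])
      }
      if (nrow(morph)) {
        morph$well <- fi$well; morph$field <- fi$field
        morph$time_h <- fi$timeH
        keep <- seg$records$label[seg$records$qc_pass]
        dead_by_label <- setNames(calls, seg$records$label)
        morph$vital <- ifelse(is.na(dead_by_label[as.character(morph$label)]),
                              NA, ifelse(dead_by_label[as.character(morph$label)],
                                         "dead", "live"))
        morph <- morph[morph$label %in% keep, , drop = FALSE]
        perCell <- rbind(perCell, morph)
      }
    }
    out$counts <- counts
    writeManifestCSV(counts, file.path(config$outDir, "counts.csv"),
                     seed, cfgHash)
    out$perCell <- perCell
    writeManifestCSV(perCell, file.path(config$outDir, "cells.csv"),
                     seed, cfgHash)
    # subpopulation labels by fluorescence gating, when configured
    if (!is.null(config$labelThresholds) && !is.null(perCell)) {
      thr <- unlist(config$labelThresholds)
      perCell$subpopulation <- classifyByFluorescence(perCell, thr)
      comp <- buildComposition(
        perCell[!is.na(perCell$vital),
                c("well", "time_h", "subpopulation", "vital")], layout)
      out$composition <- comp$pooled
      writeManifestCSV(comp$pooled,
                       file.path(config$outDir, "composition.csv"),
                       seed, cfgHash)
    }
    counts$dead_cum <- counts$dead   # endpoint plates: already cumulative
    rates_in <- counts
  } else {
    rates_in <- readManifestCSV(config$countsCsv)
    out$counts <- rates_in
  }

  if (is.null(stages) || "rates" %in% stages) {
    enough <- length(unique(rates_in$time_h)) >= 2L
    if (!enough) {
      warning("fewer than 2 time points: rates stage skipped")
    } else {
      series <- countsToSeries(rates_in, layout)
      byCond <- split(series, vapply(series, function(s)
        s@condition@label, character(1)))
      out$rates <- rateGrid(byCond)
      writeManifestCSV(out$rates, file.path(config$outDir, "rates.csv"),
                       seed, cfgHash)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.hash_config <- function(config) {
  config$outDir <- NULL
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(s), tf)
  unname(tools::md5sum(tf))
}

.discover_fields <- function(dir, parser = parseImageFilename) {
  files <- list.files(dir, pattern = "\\.tiff?$")
  rows <- lapply(files, parser)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(well = character(), field = character(),
                      timeH = numeric()))
  df <- unique(do.call(rbind, lapply(rows, function(r)
    data.frame(well = r$well, field = r$field, timeH = r$timeH,
               stringsAsFactors = FALSE))))
  df[order(df$well, df$field, df$timeH), , drop = FALSE]
}
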