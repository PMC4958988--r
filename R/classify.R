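# Subpopulation classification: fluorescence gating and a supervised
# least-squares linear discriminant on standardized, separability-
# selected features.

#' Classify cells by fluorescence intensity thresholds
#'
#' A cell is assigned to the channel whose mean intensity exceeds its
#' threshold. Cells exceeding more than one channel's threshold are
#' \code{"ambiguous"}; cells exceeding none are \code{"unlabeled"}.
#'
#' @param records per-cell table with \code{mean_<channel>} columns.
#' @param channelThresholds named numeric vector, channel name to
#'   intensity threshold (a.u.).
#' @return character vector of labels aligned with \code{records}.
#' @examples
#' rec <- data.frame(mean_RFP = c(500, 50, 500), mean_GFP = c(50, 400, 400))
#' classifyByFluorescence(rec, c(RFP = 200, GFP = 200))
#' @export
classifyByFluorescence <- function(records, channelThresholds) {
  chn <- names(channelThresholds)
  cols <- paste0("mean_", chn)
  miss <- cols[!cols %in% names(records)]
  if (length(miss))
    stop("records lack channel column(s): ", paste(miss, collapse = ", "))
  above <- vapply(seq_along(chn), function(j)
    records[[cols[j]]] > channelThresholds[j], logical(nrow(records)))
  if (is.null(dim(above))) above <- matrix(above, nrow = nrow(records))
  nAbove <- rowSums(above)
  out <- rep("unlabeled", nrow(records))
  one <- nAbove == 1L
  out[one] <- chn[apply(above[one, , drop = FALSE], 1, which)]
  out[nAbove > 1L] <- "ambiguous"
  out
}

# standardized mean difference of a feature between two classes
.smd <- function(x, g1, g2) {
  s <- sqrt((sd(x[g1])^2 + sd(x[g2])^2) / 2)
  if (!is.finite(s) || s == 0) return(0)
  abs(mean(x[g1]) - mean(x[g2])) / s
}

#' Train a linear subpopulation classifier
#'
#' From a labeled per-cell feature table: draws a fixed-size training
#' subsample per class (seeded, reproducible), ranks candidate numeric
#' features by between-class separability (absolute standardized mean
#' difference; for more than two classes, the maximum over class
#' pairs), keeps the top \code{kFeatures}, standardizes them, and fits
#' a multiclass linear discriminant by least squares on class
#' indicators. Zero-variance features are dropped with a warning.
#'
#' @param records per-cell feature table.
#' @param trueLabels class label per record.
#' @param nTrainPerClass training cells drawn per class (default 100).
#' @param kFeatures number of features to select (default 5).
#' @param seed RNG seed for the training subsample.
#' @param featureCols candidate feature columns; defaults to all
#'   numeric columns.
#' @return A \linkS4class{ClassifierModel}.
#' @examples
#' pop <- synthControlPopulations(150, seed = 2)
#' m <- trainLinearClassifier(pop[-1], pop$true_class, seed = 2)
#' m
#' @export
trainLinearClassifier <- function(records, trueLabels,
                                  nTrainPerClass = 100L, kFeatures = 5L,
                                  seed = 1L, featureCols = NULL) {
  stopifnot(nrow(records) == length(trueLabels))
  classes <- sort(unique(trueLabels))
  if (length(classes) < 2L) stop("need at least two classes")
  tab <- table(trueLabels)
  if (any(tab < nTrainPerClass))
    stop("training error: fewer than ", nTrainPerClass,
         " labeled cells for class(es): ",
         paste(names(tab)[tab < nTrainPerClass], collapse = ", "))
  if (is.null(featureCols))
    featureCols <- names(records)[vapply(records, is.numeric, logical(1))]
  if (length(featureCols) < kFeatures)
    stop("need at least ", kFeatures, " numeric feature columns")

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  idx <- unlist(lapply(classes, function(cl)
    sample(which(trueLabels == cl), nTrainPerClass)))
  X <- records[idx, featureCols, drop = FALSE]
  y <- trueLabels[idx]

  # drop degenerate features, rank the rest by max pairwise SMD
  sds <- vapply(X, sd, numeric(1))
  if (any(!is.finite(sds) | sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(featureCols[!is.finite(sds) | sds == 0], collapse = ", "))
    featureCols <- featureCols[is.finite(sds) & sds > 0]
    X <- X[, featureCols, drop = FALSE]
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  sep <- vapply(featureCols, function(fc) {
    max(vapply(pairs, function(pr)
      .smd(X[[fc]], y == pr[1], y == pr[2]), numeric(1)))
  }, numeric(1))
  selected <- names(sort(sep, decreasing = TRUE))[seq_len(kFeatures)]

  Xs <- as.matrix(X[, selected, drop = FALSE])
  ctr <- colMeans(Xs)
  scl <- apply(Xs, 2, sd)
  Z <- sweep(sweep(Xs, 2, ctr), 2, scl, "/")
  Yind <- outer(y, classes, "==") * 1
  Zd <- cbind(1, Z)
  B <- solve(crossprod(Zd), crossprod(Zd, Yind))
  dimnames(B) <- list(c("(intercept)", selected), classes)
  pred <- classes[max.col(Zd %*% B, ties.method = "first")]
  model <- new("ClassifierModel", classNames = classes,
               features = selected,
               center = setNames(ctr, selected),
               scaleSd = setNames(scl, selected),
               coefficients = B,
               trainingAccuracy = mean(pred == y),
               controlAccuracy = NA_real_, seed = as.integer(seed))
  validObject(model)
  model
}

#' Apply a trained linear classifier
#'
#' Standardizes the model's selected features with the stored training
#' moments, computes linear scores and assigns each cell to the
#' argmax class. Ties break in class-name order (first listed wins)
#' and are reported via a message.
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param records per-cell feature table containing the model's
#'   selected features.
#' @return character vector of class labels.
#' @export
applyClassifier <- function(model, records) {
  stopifnot(is(model, "ClassifierModel"))
  miss <- model@features[!model@features %in% names(records)]
  if (length(miss))
    stop("application error: missing feature column(s): ",
         paste(miss, collapse = ", "))
  X <- as.matrix(records[, model@features, drop = FALSE])
  Z <- sweep(sweep(X, 2, model@center), 2, model@scaleSd, "/")
  scores <- cbind(1, Z) %*% model@coefficients
  top <- apply(scores, 1, max)
  nties <- sum(rowSums(scores == top) > 1L)
  if (nties > 0)
    message(nties, " tie(s) broken in class order")
  model@classNames[max.col(scores, ties.method = "first")]
}

#' Evaluate a classifier on held-out pure control populations
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param records held-out control feature table.
#' @param trueLabels true class per record.
#' @return the model with \code{controlAccuracy} filled in.
#' @export
evaluateOnControls <- function(model, records, trueLabels) {
  pred <- applyClassifier(model, records)
  model@controlAccuracy <- mean(pred == trueLabels)
  model
}

#' Agreement between two label assignments
#'
#' Fraction of exact agreements over cells classified by both (used
#' e.g. to compare morphology-based against fluorescence-based
#' classification), plus the full confusion matrix.
#'
#' @param labelsA,labelsB equal-length label vectors; NA marks a cell
#'   not classified by that method.
#' @return list: \code{fraction} agreement, \code{n} cells compared,
#'   \code{confusion} contingency table (A in rows, B in columns).
#' @examples
#' concordance(c("t", "f", "t"), c("t", "f", "f"))$fraction  # 2/3
#' @export
concordance <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    stop("label vectors must have equal length")
  keep <- !is.na(labelsA) & !is.na(labelsB)
  a <- labelsA[keep]; b <- labelsB[keep]
  list(fraction = if (length(a)) mean(a == b) else NA_real_,
       n = length(a),
       confusion = table(A = a, B = b))
}

#' Serialize / restore a classifier model as JSON
#'
#' The document captures everything needed for bit-reproducible
#' application: class names, selected features, standardization
#' moments, coefficients, seed and accuracies.
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param path output / input JSON file.
#' @return \code{writeClassifierModel}: the path, invisibly.
#'   \code{readClassifierModel}: the restored model.
#' @export
writeClassifierModel <- function(model, path) {
  stopifnot(is(model, "ClassifierModel"))
  doc <- list(format = "hcsquant-classifier", version = 1L,
              class_names = model@classNames, features = model@features,
              center = as.list(model@center),
              scale_sd = as.list(model@scaleSd),
              coefficients = apply(model@coefficients, 2, identity,
                                   simplify = FALSE),
              training_accuracy = model@trainingAccuracy,
              control_accuracy = model@controlAccuracy,
              seed = model@seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeClassifierModel
#' @export
readClassifierModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(doc$format, "hcsquant-classifier"))
  k <- length(doc$features)
  B <- do.call(cbind, lapply(doc$coefficients, unlist))
  rownames(B) <- c("(intercept)", doc$features)
  new("ClassifierModel", classNames = doc$class_names,
      features = doc$features,
      center = unlist(doc$center)[doc$features],
      scaleSd = unlist(doc$scale_sd)[doc$features],
      coefficients = B,
      trainingAccuracy = as.numeric(doc$training_accuracy),
      controlAccuracy = if (is.null(doc$control_accuracy)) NA_real_
                        else suppressWarnings(as.numeric(doc$control_accuracy)),
      seed = as.integer(doc$seed))
}
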