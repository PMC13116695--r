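#' Train the species classifier
#'
#' Linear-kernel support vector machine (one-vs-one voting as provided
#' by [e1071::svm()]) over dosage vectors.  Unit regularization cost;
#' features are used unscaled (dosages already live in \[0, 1\]).  The
#' variant order is recorded in the model and enforced at prediction.
#'
#' @param x samples x variants numeric matrix, or a
#'   [DosageMatrix-class] (columns become samples).
#' @param labels per-sample species labels (>= 2 classes, >= 1 sample
#'   each); defaults to the species labels carried by a DosageMatrix.
#' @param cost SVM regularization cost (default 1).
#' @param seed integer seed (the linear fit is deterministic; kept for
#'   interface uniformity).
#' @return an object of class `diagClassifier`.
#' @export
trainClassifier <- function(x, labels = NULL, cost = 1, seed = 1L) {
  if (methods::is(x, "DosageMatrix")) {
    labels <- labels %||% speciesLabels(x)
    x <- t(dosage(x))
  }
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("training requires at least two classes")
  if (any(table(labels) < 1L)) stop("every class needs at least one sample")
  x[is.na(x)] <- 0.5
  fit <- withSeed(seed, e1071::svm(x, labels, kernel = "linear",
                                   cost = cost, scale = FALSE))
  structure(list(fit = fit, features = colnames(x),
                 levels = levels(labels), cost = cost),
            class = "diagClassifier")
}

#' @export
predict.diagClassifier <- function(object, newdata, ...) {
  if (methods::is(newdata, "DosageMatrix")) newdata <- t(dosage(newdata))
  newdata <- as.matrix(newdata)
  if (!is.null(object$features)) {
    if (is.null(colnames(newdata)) &&
        ncol(newdata) == length(object$features))
      colnames(newdata) <- object$features
    miss <- setdiff(object$features, colnames(newdata))
    if (length(miss))
      stop(sprintf("newdata lacks %d of %d training features",
                   length(miss), length(object$features)))
    newdata <- newdata[, object$features, drop = FALSE]
  }
  newdata[is.na(newdata)] <- 0.5
  stats::predict(object$fit, newdata, decision.values = TRUE, ...)
}

#' Evaluate the classifier on pure and mixed samples
#'
#' Reports per-sample predictions and decision scores; aggregate
#' accuracy over pure samples; and, for mixtures, whether the predicted
#' class equals the majority parent (either parent is accepted at a
#' 50-50 mix), with a per-proportion breakdown.
#'
#' @param model a `diagClassifier`.
#' @param samples a [DosageMatrix-class] carrying `parent_a`,
#'   `parent_b`, `proportion` column metadata (as produced by
#'   [simulatePure()] / [simulateMixtures()]), or a plain matrix plus
#'   `truth` labels.
#' @param truth optional per-sample true labels for plain matrices.
#' @return list of class `ClassifierReport`: `predictions` (data.frame),
#'   `accuracy_pure`, `mixture_majority_rate`, `by_proportion`.
#' @export
evaluateClassifier <- function(model, samples, truth = NULL) {
  if (methods::is(samples, "DosageMatrix")) {
    cd <- as.data.frame(SummarizedExperiment::colData(samples))
    x <- t(dosage(samples))
  } else {
    x <- as.matrix(samples)
    cd <- data.frame(parent_a = truth %||% rep(NA_character_, nrow(x)),
                     parent_b = NA_character_,
                     proportion = 1, row.names = rownames(x))
  }
  if (!nrow(x))
    return(structure(list(predictions = data.frame(), accuracy_pure = NA_real_,
                          mixture_majority_rate = NA_real_,
                          by_proportion = data.frame()),
                     class = "ClassifierReport"))
  pred <- predict(model, x)
  dv <- attr(pred, "decision.values")
  isPure <- is.na(cd$parent_b) | cd$proportion %in% c(0, 1)
  majority <- ifelse(isPure, cd$parent_a,
              ifelse(cd$proportion > 0.5, cd$parent_a,
              ifelse(cd$proportion < 0.5, cd$parent_b, NA_character_)))
  correct <- ifelse(!is.na(majority), as.character(pred) == majority,
                    as.character(pred) == cd$parent_a |
                    as.character(pred) == cd$parent_b)
  predictions <- data.frame(sample = rownames(x),
                            predicted = as.character(pred),
                            parent_a = cd$parent_a, parent_b = cd$parent_b,
                            proportion = cd$proportion,
                            correct = correct)
  if (!is.null(dv)) predictions <- cbind(predictions, as.data.frame(dv))
  byProp <- if (any(!isPure)) {
    agg <- stats::aggregate(correct ~ proportion,
                            data = predictions[!isPure, ], FUN = mean)
    names(agg)[2] <- "majority_rate"
    agg
  } else data.frame()
  structure(list(
    predictions = predictions,
    accuracy_pure = if (any(isPure)) mean(correct[isPure]) else NA_real_,
    mixture_majority_rate = if (any(!isPure)) mean(correct[!isPure])
                            else NA_real_,
    by_proportion = byProp), class = "ClassifierReport")
}

#' Project new samples into a fitted PCA space
#'
#' Centers and scales `newdata` with the training statistics stored in
#' the [PCAResult-class], imputes missing values to the training column
#' mean, and multiplies into the loading basis.  Projecting a training
#' sample reproduces its score; a noiseless 50-50 mixture projects to
#' the midpoint of its parents.
#'
#' @param pca a [PCAResult-class].
#' @param newdata samples x variants matrix or [DosageMatrix-class];
#'   must cover the PCA's variant set.
#' @return samples x components score matrix.
#' @export
projectSamples <- function(pca, newdata) {
  if (methods::is(newdata, "DosageMatrix")) newdata <- t(dosage(newdata))
  newdata <- as.matrix(newdata)
  feats <- rownames(pcaLoadings(pca))
  if (is.null(colnames(newdata)) && ncol(newdata) == length(feats))
    colnames(newdata) <- feats
  miss <- setdiff(feats, colnames(newdata))
  if (length(miss))
    stop(sprintf("newdata lacks %d PCA variants", length(miss)))
  x <- newdata[, feats, drop = FALSE]
  if (any(rowSums(!is.na(x)) == 0L))
    stop("sample with all values missing cannot be projected")
  xs <- sweep(sweep(x, 2L, pca@center, "-"), 2L, pca@scale, "/")
  xs[is.na(xs)] <- 0
  xs %*% pcaLoadings(pca)
}
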