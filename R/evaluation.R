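## One-vs-rest evaluation suite: confusion matrix, per-class metric set,
## rank-sum ROC AUC, macro ("Overall") summaries and cross-validation
## aggregation.

#' Multi-class confusion matrix
#'
#' Counts of samples with true class i predicted as class j; rows are
#' truth, columns are predictions.
#'
#' @param truth,predicted equal-length label vectors over `classes`.
#' @param classes ordered class names (default [gradeLevels()]).
#' @return K x K integer matrix with `truth`/`predicted` dimnames.
#' @export
#' @examples
#' confusionTable(c("Normal", "Moderate"), c("Normal", "Intensive"))
confusionTable <- function(truth, predicted, classes = gradeLevels()) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  m <- table(factor(truth, levels = classes),
             factor(predicted, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Row-percent view of a confusion matrix
#'
#' @param m confusion count matrix (rows = truth).
#' @return Matrix of row percentages (each row sums to 100 when the row
#'   has any samples).
#' @export
rowPercent <- function(m) {
  rs <- rowSums(m)
  out <- 100 * sweep(m, 1L, pmax(rs, 1L), "/")
  out[rs == 0L, ] <- NA_real_
  out
}

#' Confusion counts from a row-percent matrix under equal class sizes
#'
#' Reconstructs absolute counts from a row-normalized percentage
#' confusion matrix (the form results tables are often printed in),
#' assuming every true class holds `nPerClass` samples.
#'
#' @param pct K x K matrix of row percentages.
#' @param nPerClass samples per true class.
#' @return K x K count matrix.
#' @export
#' @examples
#' pct <- matrix(c(92.5, 2.5, 5, 5, 87.5, 7.5, 2.5, 10, 87.5),
#'               3, 3, byrow = TRUE)
#' confusionFromRowPercent(pct, 40)
confusionFromRowPercent <- function(pct, nPerClass) {
  counts <- pct / 100 * nPerClass
  if (max(abs(counts - round(counts))) > 1e-6)
    stop("percentages are not consistent with integer counts at this class size")
  round(counts)
}

#' One-vs-rest counts for a class
#'
#' Collapses all other classes into a single negative class:
#' TP is the diagonal cell, FN the rest of the row, FP the rest of the
#' column, and TN everything else; the four counts partition the grand
#' total.
#'
#' @param m confusion count matrix (rows = truth).
#' @param class class name or index.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
ovrCounts <- function(m, class) {
  if (is.character(class)) class <- match(class, rownames(m))
  if (is.na(class) || class < 1L || class > nrow(m))
    stop("unknown class")
  tp <- m[class, class]
  fn <- sum(m[class, ]) - tp
  fp <- sum(m[, class]) - tp
  tn <- sum(m) - tp - fn - fp
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

.safeRatio <- function(num, den, metric, flags) {
  if (den <= 0) {
    flags$zero <- c(flags$zero, metric)
    return(list(value = 0, flags = flags))
  }
  list(value = num / den, flags = flags)
}

#' Per-class one-vs-rest metrics
#'
#' For every class, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' precision `TP/(TP+FP)`, one-vs-rest accuracy `(TP+TN)/(TP+TN+FP+FN)`
#' and F-measure, the harmonic mean `2*P*R/(P+R)`. A zero denominator
#' yields 0 with a warning (small folds can leave a predicted class
#' empty).
#'
#' @param m confusion count matrix (rows = truth).
#' @return data.frame (one row per class) of proportions in \[0, 1\].
#' @export
#' @examples
#' m <- confusionTable(rep(gradeLevels(), each = 2),
#'                     rep(gradeLevels(), times = 2))
#' classMetrics(m)
classMetrics <- function(m) {
  classes <- rownames(m)
  flags <- new.env()
  flags$zero <- character()
  rows <- lapply(classes, function(cl) {
    ct <- ovrCounts(m, cl)
    sens <- .safeRatio(ct["TP"], ct["TP"] + ct["FN"],
                       paste0(cl, ":sensitivity"), flags)$value
    spec <- .safeRatio(ct["TN"], ct["TN"] + ct["FP"],
                       paste0(cl, ":specificity"), flags)$value
    prec <- .safeRatio(ct["TP"], ct["TP"] + ct["FP"],
                       paste0(cl, ":precision"), flags)$value
    acc <- .safeRatio(ct["TP"] + ct["TN"], sum(ct),
                      paste0(cl, ":accuracy"), flags)$value
    f <- fMeasure(prec, sens)
    data.frame(sensitivity = unname(sens), specificity = unname(spec),
               precision = unname(prec), accuracy = unname(acc),
               fMeasure = f)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- classes
  if (length(flags$zero))
    warning("zero denominator, metric set to 0: ",
            paste(flags$zero, collapse = ", "))
  out
}

#' F-measure (harmonic mean of precision and sensitivity)
#'
#' @param precision,sensitivity proportions in \[0, 1\] (vectorized).
#' @return `2 * P * R / (P + R)`, 0 when both are 0.
#' @export
#' @examples
#' fMeasure(0.90, 0.925)
fMeasure <- function(precision, sensitivity) {
  ifelse(precision + sensitivity > 0,
         2 * precision * sensitivity / (precision + sensitivity), 0)
}

#' One-vs-rest ROC AUC by the rank-sum (Mann-Whitney) statistic
#'
#' The probability that a randomly chosen positive sample receives a
#' higher score for the class than a randomly chosen negative one, with
#' midrank handling of ties: `AUC = (Rpos - n1(n1+1)/2) / (n1 * n0)`
#' where `Rpos` is the rank sum of positive scores.
#'
#' @param probabilities n x K matrix of class probabilities (rows sum
#'   to 1), or a numeric vector of scores for `class`.
#' @param truth length-n label vector.
#' @param class class name (or index into the probability columns).
#' @return AUC in \[0, 1\]; `NA` with a warning if the class is absent
#'   from the truth or no negatives exist.
#' @export
#' @examples
#' p <- matrix(c(.9, .05, .05, .2, .6, .2), 2, byrow = TRUE,
#'             dimnames = list(NULL, gradeLevels()))
#' rocAucOvr(p, c("Normal", "Moderate"), "Normal")
rocAucOvr <- function(probabilities, truth, class) {
  truth <- as.character(truth)
  if (is.matrix(probabilities)) {
    if (any(abs(rowSums(probabilities) - 1) > 1e-6))
      stop("probability rows must sum to 1")
    col <- if (is.character(class)) match(class, colnames(probabilities))
           else class
    if (is.na(col)) stop("unknown class")
    scores <- probabilities[, col]
    clName <- if (is.character(class)) class else colnames(probabilities)[col]
  } else {
    scores <- probabilities
    clName <- class
  }
  pos <- truth == clName
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    warning("class ", clName, " absent from truth (or no negatives); AUC undefined")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro ("Overall") summary of per-class metrics
#'
#' Unweighted arithmetic mean of each metric across classes.
#'
#' @param perClass data.frame of per-class metrics (classes in rows).
#' @return Named numeric vector of column means.
#' @export
#' @examples
#' macroSummary(data.frame(precision = c(.90, .85, .88)))
macroSummary <- function(perClass) {
  colMeans(as.matrix(perClass))
}

#' Full evaluation report from predictions
#'
#' Builds the confusion matrix, the per-class one-vs-rest metric suite
#' (plus AUC when probabilities are given) and the macro summary row.
#'
#' @param truth,predicted label vectors.
#' @param probabilities optional n x K probability matrix for AUC.
#' @param classes ordered class names.
#' @return An [EvaluationReport-class].
#' @export
evaluationReport <- function(truth, predicted, probabilities = NULL,
                             classes = gradeLevels()) {
  m <- confusionTable(truth, predicted, classes)
  perClass <- classMetrics(m)
  if (!is.null(probabilities)) {
    if (is.null(colnames(probabilities)))
      colnames(probabilities) <- classes
    perClass$auc <- vapply(classes, function(cl)
      suppressWarnings(rocAucOvr(probabilities, truth, cl)), numeric(1L))
  }
  new("EvaluationReport", confusion = m, perClass = perClass,
      overall = macroSummary(perClass))
}

#' Aggregate per-fold evaluation reports (mean and sd)
#'
#' Summarizes k-fold cross-validation: for every metric, the across-fold
#' mean and sample standard deviation per class, plus an `Overall` row
#' holding the mean of the per-class means (equivalently the across-fold
#' summary of each fold's macro value).
#'
#' @param reports list of >= 2 [EvaluationReport-class] objects.
#' @return List of data.frames `mean` and `sd` (rows: classes then
#'   `Overall`; columns: metrics).
#' @export
cvAggregate <- function(reports) {
  if (length(reports) < 2L)
    stop("need at least 2 folds to aggregate")
  per <- lapply(reports, function(r) as.matrix(r@perClass))
  classes <- rownames(per[[1L]])
  metrics <- colnames(per[[1L]])
  arr <- simplify2array(per)  # classes x metrics x folds
  mMean <- apply(arr, c(1L, 2L), mean)
  mSd <- apply(arr, c(1L, 2L), stats::sd)
  macro <- t(apply(arr, 3L, colMeans))  # folds x metrics
  mMean <- rbind(mMean, Overall = colMeans(mMean))
  mSd <- rbind(mSd, Overall = apply(macro, 2L, stats::sd))
  list(mean = as.data.frame(mMean), sd = as.data.frame(mSd))
}
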