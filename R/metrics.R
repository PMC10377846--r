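#' Metric suite from a pooled binary confusion matrix
#'
#' Computes the seven evaluation metrics used throughout the pipeline plus
#' the raw counts. Note that the "AUC" column convention of the clinical
#' comparison tables is balanced accuracy, `(TPR + TNR) / 2`, not a ROC
#' integral; a rank-based ROC AUC is available separately as [roc_auc()].
#' Ratios with a zero denominator are reported as 0 and recorded in the
#' `undefined` field.
#'
#' @param tp,fp,tn,fn non-negative confusion counts (positive = apnea by the
#'   package convention; see [cross_validate()]'s `positive_label`)
#' @return an object of class `metrics_report`: a list with `tp`, `fp`, `tn`,
#'   `fn`, `accuracy`, `tpr`, `tnr`, `auc`, `precision`, `f_score`, `g_mean`
#'   and `undefined` (names of zero-denominator metrics)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("confusion counts sum to zero", call. = FALSE)
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  tpr <- safe(tp, tp + fn, "tpr")
  tnr <- safe(tn, tn + fp, "tnr")
  precision <- safe(tp, tp + fp, "precision")
  f_score <- safe(2 * precision * tpr, precision + tpr, "f_score")
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / total,
    tpr = tpr, tnr = tnr,
    auc = (tpr + tnr) / 2,
    precision = precision,
    f_score = f_score,
    g_mean = sqrt(tpr * tnr),
    undefined = undefined
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  vals <- unlist(x[c("accuracy", "tpr", "tnr", "auc", "precision",
                     "f_score", "g_mean")])
  print(round(vals, 4))
  if (length(x$undefined))
    cat("undefined (reported as 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a metrics report to a named numeric vector
#' @param report a `metrics_report`
#' @return named numeric vector of the seven metrics
#' @export
metrics_vector <- function(report) {
  unlist(report[c("accuracy", "tpr", "tnr", "auc", "precision",
                  "f_score", "g_mean")])
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney estimate of the probability that a positive row scores above
#' a negative one (ties count half). Provided as the conventional ROC AUC,
#' distinct from the balanced-accuracy "AUC" column of [confusion_metrics()].
#'
#' @param scores numeric score per row, larger meaning more positive
#' @param labels 0/1 labels
#' @return AUC in `[0,1]`
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) stop("both classes required", call. = FALSE)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Friedman-style mean rank across metric columns
#'
#' Within each metric column, classifiers are ranked (descending when larger
#' is better) with average ranks on ties; a classifier's mean rank is the
#' average of its per-metric ranks. Lower means consistently better.
#'
#' @param metric_matrix numeric matrix, classifiers in rows, metrics in
#'   columns, no missing cells
#' @param higher_is_better direction of every column (default `TRUE`)
#' @return named numeric vector of per-classifier mean ranks
#' @export
mean_rank <- function(metric_matrix, higher_is_better = TRUE) {
  m <- as.matrix(metric_matrix)
  if (anyNA(m)) stop("metric matrix must have no missing cells", call. = FALSE)
  sgn <- if (higher_is_better) -1 else 1
  ranks <- apply(m, 2, function(col) rank(sgn * col, ties.method = "average"))
  ranks <- matrix(ranks, nrow = nrow(m))
  stats::setNames(rowMeans(ranks), rownames(m))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on the paired differences `a - b`. Zero differences are
#' removed; absolute differences are ranked with average ranks on ties and
#' the statistic is the sum of ranks of positive differences. The null
#' distribution is enumerated exactly over all sign patterns for n <= 15,
#' and approximated by a tie-corrected, continuity-corrected normal above
#' that. If every difference is zero the result is degenerate with p = 1.
#'
#' @param a,b equal-length paired numeric vectors; at least 5 nonzero
#'   differences are required for a non-degenerate test
#' @param method `"auto"` (exact up to n = 15, approximate beyond), or force
#'   `"exact"` / `"approximate"` — the latter mainly to cross-check the two
#'   branches against each other
#' @return list with `statistic` (positive-rank sum), `p_value`, `n` (nonzero
#'   pairs), `method` (`"exact"`, `"approximate"` or `"degenerate"`) and
#'   `degenerate` flag
#' @export
wilcoxon_signed_rank <- function(a, b,
                                 method = c("auto", "exact", "approximate")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("paired samples differ in length", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(statistic = 0, p_value = 1, n = 0L,
                method = "degenerate", degenerate = TRUE))
  if (length(d) < 5)
    stop("need at least 5 nonzero differences", call. = FALSE)
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (method == "auto") method <- if (n <= 15) "exact" else "approximate"
  if (method == "exact") {
    if (n > 20) stop("exact enumeration is guarded to n <= 20", call. = FALSE)
    bits <- vapply(0:(2^n - 1),
                   function(i) as.integer(intToBits(i))[seq_len(n)],
                   integer(n))
    Wall <- drop(r %*% bits)
    p <- min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(W - mu) * 0.5
    z <- (W - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = W, p_value = p, n = n, method = method, degenerate = FALSE)
}
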