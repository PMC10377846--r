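#' Cross-validation configuration
#'
#' @param K number of folds (default 10)
#' @param stratified preserve class proportions across folds (default `TRUE`)
#' @param seed integer seed for the fold assignment
#' @return an object of class `cv_config`
#' @export
cv_config <- function(K = 10L, stratified = TRUE, seed = 1L) {
  stopifnot(K >= 2)
  structure(list(K = as.integer(K), stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Assign rows to cross-validation folds
#'
#' Stratified assignment shuffles each class separately and deals rows to
#' folds cyclically, keeping class proportions as even as integer counts
#' allow. Deterministic given the config seed.
#'
#' @param labels 0/1 label vector
#' @param cv a [cv_config()]
#' @return integer vector of fold ids in `1..K`, one per row
#' @export
make_folds <- function(labels, cv = cv_config()) {
  n <- length(labels)
  if (cv$K > n) stop("more folds than rows", call. = FALSE)
  with_seed(cv$seed, {
    folds <- integer(n)
    if (cv$stratified) {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        folds[idx] <- rep_len(seq_len(cv$K), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(cv$K), n)
    }
    folds
  })
}

#' Cross-validated evaluation of a classifier
#'
#' Partitions the rows into K folds (stratified by default), collects the
#' out-of-fold predictions, pools them into a single confusion matrix and
#' returns its [confusion_metrics()]. With `positive_label = 1` (default) the
#' apnea class is treated as positive; set 0 for the opposite convention.
#'
#' @param table a [labeled_table()] with no missing cells
#' @param classifier a classifier spec with a [predict_labels()] method
#' @param cv a [cv_config()]; stratified folding requires each class to have
#'   at least K members
#' @param positive_label which label counts as positive in the report
#' @return a `metrics_report` with attribute `"folds"` (the fold assignment)
#'   and attribute `"error_rate"`
#' @export
cross_validate <- function(table, classifier, cv = cv_config(),
                           positive_label = 1L) {
  stopifnot(inherits(table, "labeled_table"))
  if (anyNA(table$data)) stop("table has missing cells; preprocess first", call. = FALSE)
  y <- table$labels
  if (cv$stratified && any(table(y) < cv$K))
    stop("stratified CV needs >= K members per class", call. = FALSE)
  folds <- make_folds(y, cv)
  pred <- integer(length(y))
  for (f in seq_len(cv$K)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (length(unique(y[tr])) < 2)
      warning("training fold ", f, " contains a single class")
    pred[te] <- predict_labels(classifier,
                               subset_table(table, rows = tr),
                               as_feature_matrix(table)[te, , drop = FALSE])
  }
  pos <- as.integer(positive_label)
  rep_ <- confusion_metrics(
    tp = sum(pred == pos & y == pos),
    fp = sum(pred == pos & y != pos),
    tn = sum(pred != pos & y != pos),
    fn = sum(pred != pos & y == pos)
  )
  attr(rep_, "folds") <- folds
  attr(rep_, "error_rate") <- mean(pred != y)
  rep_
}
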