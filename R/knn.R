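#' k-nearest-neighbour classifier specification
#'
#' Mirrors the configuration surface of the standard clinical-ML presets:
#' neighbour count, one of six distance metrics, a distance-weighting rule for
#' the vote, and optional z-score standardization using training statistics.
#'
#' @param n_neighbors number of neighbours (>= 1)
#' @param distance one of `"euclidean"`, `"cityblock"`, `"cosine"`,
#'   `"correlation"` (1 - Pearson), `"spearman"` (1 - Spearman rank
#'   correlation across features), `"hamming"` (mismatch fraction)
#' @param weighting `"equal"`, `"inverse"` (1/d) or `"squared_inverse"`
#'   (1/d^2); exact matches (zero distance) dominate the weighted vote
#' @param standardize z-score columns with training mean/sd before computing
#'   distances; zero-variance training columns are ignored with a warning
#' @return an object of class `knn_spec`
#' @export
knn_spec <- function(n_neighbors = 5L,
                     distance = c("euclidean", "cityblock", "cosine",
                                  "correlation", "spearman", "hamming"),
                     weighting = c("equal", "inverse", "squared_inverse"),
                     standardize = FALSE) {
  distance <- match.arg(distance)
  weighting <- match.arg(weighting)
  stopifnot(n_neighbors >= 1)
  structure(list(n_neighbors = as.integer(n_neighbors), distance = distance,
                 weighting = weighting, standardize = isTRUE(standardize)),
            class = c("knn_spec", "classifier_spec"))
}

# Pairwise distances between the rows of A (queries) and B (references).
pairwise_distances <- function(A, B, distance) {
  switch(distance,
    euclidean = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      sqrt(pmax(d2, 0))
    },
    cityblock = {
      D <- matrix(0, nrow(A), nrow(B))
      for (j in seq_len(ncol(A)))
        D <- D + abs(outer(A[, j], B[, j], "-"))
      D
    },
    hamming = {
      D <- matrix(0, nrow(A), nrow(B))
      for (j in seq_len(ncol(A)))
        D <- D + (outer(A[, j], B[, j], "!=") * 1)
      D / ncol(A)
    },
    cosine = 1 - row_cosine(A, B),
    correlation = 1 - row_cosine(sweep_rows(A), sweep_rows(B)),
    spearman = {
      rA <- t(apply(A, 1, rank)); rB <- t(apply(B, 1, rank))
      1 - row_cosine(sweep_rows(rA), sweep_rows(rB))
    },
    stop("unknown distance: ", distance, call. = FALSE)
  )
}

sweep_rows <- function(M) M - rowMeans(M)

# Cosine similarity between rows; zero-norm rows get similarity 0.
row_cosine <- function(A, B) {
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  na[na == 0] <- Inf; nb[nb == 0] <- Inf
  tcrossprod(A, B) / outer(na, nb)
}

# Weighted vote over the k nearest labels. Zero-distance neighbours dominate
# non-equal weightings; a tied vote falls back to the training majority class
# (label 0 when training classes are equally frequent).
knn_vote <- function(nb_labels, nb_dists, weighting, majority) {
  if (weighting != "equal" && any(nb_dists == 0)) {
    nb_labels <- nb_labels[nb_dists == 0]
    w <- rep(1, length(nb_labels))
  } else {
    w <- switch(weighting,
      equal = rep(1, length(nb_dists)),
      inverse = 1 / nb_dists,
      squared_inverse = 1 / nb_dists^2)
    w[!is.finite(w)] <- max(w[is.finite(w)], 1) # guard equal-weight inf
  }
  w1 <- sum(w[nb_labels == 1L]); w0 <- sum(w[nb_labels == 0L])
  if (w1 > w0) 1L else if (w0 > w1) 0L else majority
}

# Standardize train/test with training statistics; drop zero-variance columns.
standardize_pair <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  keep <- sd > 0
  if (!all(keep))
    warning("ignoring ", sum(!keep), " zero-variance column(s) during standardization")
  if (!any(keep)) stop("no informative columns after standardization", call. = FALSE)
  list(tr = scale(Xtr[, keep, drop = FALSE], mu[keep], sd[keep]),
       te = scale(Xte[, keep, drop = FALSE], mu[keep], sd[keep]))
}

#' Predict labels with weighted kNN
#'
#' @param train a [labeled_table()] of training rows
#' @param test test rows: a matrix, data.frame or [labeled_table()] with the
#'   same feature columns
#' @param spec a [knn_spec()]
#' @return integer vector of predicted 0/1 labels
#' @export
knn_predict <- function(train, test, spec = knn_spec()) {
  stopifnot(inherits(train, "labeled_table"), inherits(spec, "knn_spec"))
  Xtr <- as_feature_matrix(train)
  Xte <- if (inherits(test, "labeled_table")) as_feature_matrix(test)
         else as.matrix(test)
  if (ncol(Xte) != ncol(Xtr)) stop("feature mismatch", call. = FALSE)
  if (spec$n_neighbors > nrow(Xtr))
    stop("k exceeds the number of training rows", call. = FALSE)
  predict_knn_matrix(Xtr, train$labels, Xte, spec)
}

predict_knn_matrix <- function(Xtr, ytr, Xte, spec) {
  if (spec$standardize) {
    st <- standardize_pair(Xtr, Xte)
    Xtr <- st$tr; Xte <- st$te
  }
  if (spec$distance %in% c("correlation", "spearman") && ncol(Xtr) >= 2) {
    const <- apply(Xtr, 2, function(c) length(unique(c)) == 1)
    if (any(const) && !all(const)) {
      warning("ignoring ", sum(const),
              " zero-variance column(s) under ", spec$distance, " distance")
      Xtr <- Xtr[, !const, drop = FALSE]; Xte <- Xte[, !const, drop = FALSE]
    }
  }
  D <- pairwise_distances(Xte, Xtr, spec$distance)
  k <- spec$n_neighbors
  n1 <- sum(ytr == 1L); n0 <- sum(ytr == 0L)
  majority <- if (n1 > n0) 1L else 0L
  vapply(seq_len(nrow(D)), function(i) {
    o <- order(D[i, ])[seq_len(k)] # stable order: boundary ties by row index
    knn_vote(ytr[o], D[i, o], spec$weighting, majority)
  }, integer(1))
}

#' Dispatch prediction for a classifier specification
#'
#' Internal seam used by [cross_validate()] and the wrapper fitness: every
#' classifier spec implements a method that fits on `train` and labels `test`.
#'
#' @param spec a classifier specification ([knn_spec()], [subspace_spec()], ...)
#' @param train a [labeled_table()]
#' @param test test rows (matrix or [labeled_table()])
#' @return integer vector of 0/1 predictions
#' @export
predict_labels <- function(spec, train, test) UseMethod("predict_labels")

#' @export
predict_labels.knn_spec <- function(spec, train, test) {
  knn_predict(train, test, spec)
}
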