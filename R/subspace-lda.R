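#' Random-subspace discriminant ensemble specification
#'
#' An ensemble of linear discriminants, each trained on an independently
#' sampled feature subset, with class posteriors averaged across learners.
#' The defaults (30 learners, subspace dimension 16) match the conventional
#' subspace-discriminant preset.
#'
#' @param n_learners number of base discriminants (>= 1)
#' @param subspace_dim features sampled per learner (without replacement);
#'   must not exceed the table's feature count
#' @param seed integer seed fixing the subspace draws
#' @return an object of class `subspace_spec`
#' @export
subspace_spec <- function(n_learners = 30L, subspace_dim = 16L, seed = 1L) {
  stopifnot(n_learners >= 1, subspace_dim >= 1)
  structure(list(n_learners = as.integer(n_learners),
                 subspace_dim = as.integer(subspace_dim),
                 seed = as.integer(seed)),
            class = c("subspace_spec", "classifier_spec"))
}

# Two-class linear discriminant with pooled covariance; adds a small ridge
# when the pooled scatter is numerically singular.
lda_fit <- function(X, y) {
  X0 <- X[y == 0L, , drop = FALSE]; X1 <- X[y == 1L, , drop = FALSE]
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  n0 <- nrow(X0); n1 <- nrow(X1)
  pool <- if (n0 > 1) (n0 - 1) * stats::cov(X0) else 0
  pool <- pool + if (n1 > 1) (n1 - 1) * stats::cov(X1) else 0
  S <- pool / max(n0 + n1 - 2, 1)
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e) {
    ridge <- diag(mean(diag(S)) * 1e-6 + 1e-10, ncol(S))
    solve(S + ridge, mu1 - mu0)
  })
  b <- -0.5 * sum((mu1 + mu0) * w) + log(n1 / n0)
  list(w = w, b = b)
}

lda_posterior <- function(fit, X) stats::plogis(drop(X %*% fit$w) + fit$b)

#' Predict with a random-subspace discriminant ensemble
#'
#' Trains `n_learners` linear discriminants on seeded feature subsets of size
#' `subspace_dim` and averages their class-1 posteriors; rows with an average
#' posterior of at least 0.5 are labeled 1. Deterministic given the spec seed.
#'
#' @param train a [labeled_table()]
#' @param test test rows (matrix, data.frame or [labeled_table()])
#' @param spec a [subspace_spec()]
#' @return integer vector of predicted 0/1 labels
#' @export
subspace_discriminant_predict <- function(train, test, spec = subspace_spec()) {
  stopifnot(inherits(train, "labeled_table"), inherits(spec, "subspace_spec"))
  Xtr <- as_feature_matrix(train)
  Xte <- if (inherits(test, "labeled_table")) as_feature_matrix(test)
         else as.matrix(test)
  if (spec$subspace_dim > ncol(Xtr))
    stop("subspace_dim exceeds the feature count", call. = FALSE)
  y <- train$labels
  if (length(unique(y)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  post <- with_seed(spec$seed, {
    acc <- numeric(nrow(Xte))
    for (l in seq_len(spec$n_learners)) {
      feat <- sample.int(ncol(Xtr), spec$subspace_dim)
      fit <- lda_fit(Xtr[, feat, drop = FALSE], y)
      acc <- acc + lda_posterior(fit, Xte[, feat, drop = FALSE])
    }
    acc / spec$n_learners
  })
  as.integer(post >= 0.5)
}

#' @export
predict_labels.subspace_spec <- function(spec, train, test) {
  subspace_discriminant_predict(train, test, spec)
}
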