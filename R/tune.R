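#' Default kNN hyperparameter grid
#'
#' The search space spanned by the clinical presets: neighbour counts from 1
#' to roughly half the sample size (log-spaced), all six distances, the three
#' weighting rules and both standardization settings.
#'
#' @param n_rows training sample size used to cap the neighbour counts
#' @return list of candidate values per [knn_spec()] field
#' @export
knn_grid <- function(n_rows = 100L) {
  ks <- unique(pmin(c(1L, 2L, 4L, 6L, 10L, 14L, 16L, 22L, 32L),
                    max(1L, n_rows %/% 2)))
  list(n_neighbors = ks,
       distance = c("euclidean", "cityblock", "cosine", "correlation",
                    "spearman", "hamming"),
       weighting = c("equal", "inverse", "squared_inverse"),
       standardize = c(TRUE, FALSE))
}

#' Seeded grid / random search over kNN hyperparameters
#'
#' Evaluates candidate configurations by cross-validated accuracy under a
#' shared fold assignment. When the budget covers the full grid the search is
#' exhaustive; otherwise `budget` configurations are sampled without
#' replacement using the seed. Ties are broken toward fewer neighbours, then
#' by grid order.
#'
#' @param table a preprocessed [labeled_table()]
#' @param grid list of candidate values per field, as in [knn_grid()]
#' @param budget maximum number of configurations evaluated (>= 1)
#' @param cv a [cv_config()] shared by every candidate
#' @param seed integer seed for subsampling the grid
#' @return the winning [knn_spec()], with attributes `"accuracy"` and
#'   `"n_evaluated"`
#' @export
tune_knn <- function(table, grid = knn_grid(nrow(table$data)), budget = 50L,
                     cv = cv_config(), seed = 1L) {
  stopifnot(budget >= 1)
  if (!length(grid) || !all(lengths(grid) > 0))
    stop("empty search space", call. = FALSE)
  full <- expand.grid(grid, stringsAsFactors = FALSE)
  full <- full[full$n_neighbors <= nrow(table$data), , drop = FALSE]
  if (!nrow(full)) stop("empty search space after filtering", call. = FALSE)
  rows <- if (budget >= nrow(full)) seq_len(nrow(full))
          else with_seed(seed, sort(sample.int(nrow(full), budget)))
  best <- NULL
  for (r in rows) {
    cand <- full[r, ]
    spec <- knn_spec(cand$n_neighbors, cand$distance, cand$weighting,
                     cand$standardize)
    acc <- suppressWarnings(cross_validate(table, spec, cv)$accuracy)
    if (is.null(best) || acc > best$acc ||
        (acc == best$acc && spec$n_neighbors < best$spec$n_neighbors)) {
      best <- list(spec = spec, acc = acc)
    }
  }
  out <- best$spec
  attr(out, "accuracy") <- best$acc
  attr(out, "n_evaluated") <- length(rows)
  out
}
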