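#' Swarm configuration for binary PSO
#'
#' The motivating study fixes the transfer-function family and the fitness
#' weights but not the swarm constants; the defaults here are the standard
#' BPSO conventions: 10 particles, 100 iterations, inertia decayed linearly
#' from 0.9 to 0.4, acceleration coefficients c1 = c2 = 2, velocities clamped
#' to plus/minus 6.
#'
#' @param n_particles swarm size (>= 2)
#' @param n_iterations iteration budget
#' @param inertia scalar, or length-2 `(start, end)` for a linear schedule
#' @param c1,c2 cognitive and social acceleration coefficients (>= 0)
#' @param velocity_clamp symmetric velocity bound (> 0)
#' @param tf_id transfer function, `"S1"` to `"S4"` (see [transfer_value()])
#' @param polarity `"standard"` sets a bit to 1 with probability S(v), the
#'   convention of the binary-PSO transfer-function literature;
#'   `"as_printed"` applies the inverted published rule (bit 0 when
#'   `rand < S(v)`), retained for comparison
#' @param seed integer run seed
#' @return an object of class `swarm_config`
#' @export
swarm_config <- function(n_particles = 10L, n_iterations = 100L,
                         inertia = c(0.9, 0.4), c1 = 2, c2 = 2,
                         velocity_clamp = 6,
                         tf_id = c("S1", "S2", "S3", "S4"),
                         polarity = c("standard", "as_printed"),
                         seed = 1L) {
  tf_id <- match.arg(tf_id)
  polarity <- match.arg(polarity)
  stopifnot(n_particles >= 2, n_iterations >= 1, c1 >= 0, c2 >= 0,
            velocity_clamp > 0, length(inertia) %in% c(1, 2))
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 inertia = inertia, c1 = c1, c2 = c2,
                 velocity_clamp = velocity_clamp,
                 tf_id = tf_id, polarity = polarity, seed = as.integer(seed)),
            class = "swarm_config")
}

#' Fitness weights of the wrapper objective
#'
#' The wrapper fitness is `alpha * er + beta * F / N`, where `er` is the
#' cross-validated misclassification rate on the selected columns, `F` the
#' number of selected features and `N` the total; lower is better. The
#' conventional weights 0.99/0.01 make accuracy dominate with a mild
#' parsimony pressure.
#'
#' @param alpha weight of the error-rate term
#' @param beta weight of the feature-fraction term; `alpha + beta` must be 1
#' @return an object of class `fitness_weights`
#' @export
fitness_weights <- function(alpha = 0.99, beta = 0.01) {
  stopifnot(alpha >= 0, beta >= 0, abs(alpha + beta - 1) < 1e-8)
  structure(list(alpha = alpha, beta = beta), class = "fitness_weights")
}

#' Combine an error rate and a subset size into the wrapper fitness
#'
#' @param er misclassification rate in `[0,1]`
#' @param n_selected number of selected features `F`
#' @param n_features total number of features `N`
#' @param weights a [fitness_weights()]
#' @return `alpha * er + beta * F/N`, in `[0,1]`
#' @export
fitness_score <- function(er, n_selected, n_features,
                          weights = fitness_weights()) {
  stopifnot(er >= 0, er <= 1, n_selected >= 0, n_features >= 1,
            n_selected <= n_features)
  weights$alpha * er + weights$beta * n_selected / n_features
}

#' One velocity update step
#'
#' Per dimension: `v' = w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with
#' fresh uniform `r1`, `r2` in (0,1) per dimension (drawn from the current
#' RNG stream unless supplied), clamped to the configured bound.
#'
#' @param v current velocity vector
#' @param x current 0/1 position
#' @param pbest,gbest personal and global best 0/1 positions
#' @param config a [swarm_config()]
#' @param inertia_now inertia weight to use; defaults to the schedule start
#' @param r1,r2 optional uniform draws (for reproducing single steps)
#' @return updated velocity vector
#' @export
update_velocity <- function(v, x, pbest, gbest, config = swarm_config(),
                            inertia_now = config$inertia[1],
                            r1 = NULL, r2 = NULL) {
  n <- length(v)
  stopifnot(length(x) == n, length(pbest) == n, length(gbest) == n)
  if (is.null(r1)) r1 <- stats::runif(n)
  if (is.null(r2)) r2 <- stats::runif(n)
  out <- inertia_now * v +
    config$c1 * r1 * (pbest - x) +
    config$c2 * r2 * (gbest - x)
  pmin(pmax(out, -config$velocity_clamp), config$velocity_clamp)
}

#' Binary position update through a transfer function
#'
#' Each bit is redrawn against the transfer probability of its velocity.
#' Under `"standard"` polarity the bit becomes 1 when `rand < S(v)`; under
#' `"as_printed"` the inverse rule applies (the two produce complementary
#' bits on the same random stream).
#'
#' @param velocity numeric velocity vector
#' @param tf_id transfer function id (see [transfer_value()])
#' @param polarity `"standard"` or `"as_printed"`
#' @param rand optional uniform draws, one per dimension
#' @return integer 0/1 position vector
#' @export
update_position_binary <- function(velocity, tf_id = "S1",
                                   polarity = c("standard", "as_printed"),
                                   rand = NULL) {
  polarity <- match.arg(polarity)
  if (is.null(rand)) rand <- stats::runif(length(velocity))
  s <- transfer_value(tf_id, velocity)
  below <- rand < s
  if (polarity == "standard") as.integer(below) else as.integer(!below)
}

# ---- fitness machinery -----------------------------------------------------

# Build a memoised per-mask fitness evaluator. For plain (unstandardized)
# kNN under an additive metric, per-feature distance contributions are
# precomputed once so each mask costs one matrix sum plus the fold loop.
make_fitness_fn <- function(table, classifier, weights, cv) {
  X <- as_feature_matrix(table)
  y <- table$labels
  N <- ncol(X)
  folds <- make_folds(y, cv)
  memo <- new.env(parent = emptyenv())
  fast <- inherits(classifier, "knn_spec") && !classifier$standardize &&
    classifier$distance %in% c("euclidean", "cityblock", "hamming")
  per_feature <- NULL
  if (fast) {
    per_feature <- lapply(seq_len(N), function(j) {
      dif <- outer(X[, j], X[, j], "-")
      switch(classifier$distance,
             euclidean = dif^2,
             cityblock = abs(dif),
             hamming = (dif != 0) * 1)
    })
  }
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  majority <- if (n1 > n0) 1L else 0L
  k <- if (fast) classifier$n_neighbors else NULL

  eval_fast <- function(sel) {
    D <- Reduce(`+`, per_feature[sel])
    if (classifier$distance == "euclidean") D <- sqrt(pmax(D, 0))
    if (classifier$distance == "hamming") D <- D / length(sel)
    wrong <- 0L
    for (f in unique(folds)) {
      te <- which(folds == f); tr <- which(folds != f)
      kk <- min(k, length(tr))
      for (i in te) {
        d <- D[tr, i]
        o <- order(d)[seq_len(kk)]
        p <- knn_vote(y[tr][o], d[o], classifier$weighting, majority)
        if (p != y[i]) wrong <- wrong + 1L
      }
    }
    wrong / length(y)
  }

  eval_generic <- function(sel) {
    sub <- subset_table(table, cols = sel)
    wrong <- 0L
    for (f in unique(folds)) {
      te <- which(folds == f); tr <- which(folds != f)
      p <- predict_labels(classifier, subset_table(sub, rows = tr),
                          as_feature_matrix(sub)[te, , drop = FALSE])
      wrong <- wrong + sum(p != y[te])
    }
    wrong / length(y)
  }

  function(mask) {
    mask <- as.integer(mask)
    if (sum(mask) == 0L)
      return(list(fitness = 1.0, error_rate = 1.0, n_selected = 0L))
    key <- mask_key(mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    sel <- which(mask == 1L)
    er <- if (fast) eval_fast(sel) else eval_generic(sel)
    out <- list(fitness = fitness_score(er, length(sel), N, weights),
                error_rate = er, n_selected = length(sel))
    memo[[key]] <- out
    out
  }
}

#' Wrapper fitness of one feature subset
#'
#' Cross-validated misclassification rate of the classifier restricted to the
#' selected columns, combined with the subset-size penalty by
#' [fitness_score()]. The empty mask is fixed at the worst fitness 1.0
#' without invoking the classifier.
#'
#' @param mask 0/1 vector, one entry per feature
#' @param table a preprocessed [labeled_table()]
#' @param classifier classifier spec used inside the wrapper
#' @param weights a [fitness_weights()]
#' @param cv a [cv_config()]; the fold assignment is fixed by its seed
#' @return list with `fitness`, `error_rate`, `n_selected`
#' @export
subset_fitness <- function(mask, table, classifier = knn_spec(),
                           weights = fitness_weights(), cv = cv_config()) {
  if (length(mask) != n_features(table))
    stop("mask length must equal the feature count", call. = FALSE)
  make_fitness_fn(table, classifier, weights, cv)(mask)
}

# incumbent-keeping comparison: strictly better fitness wins; equal fitness
# prefers fewer features, then the lexicographically smaller mask
mask_improves <- function(fit_new, mask_new, fit_old, mask_old) {
  if (fit_new < fit_old) return(TRUE)
  if (fit_new > fit_old) return(FALSE)
  f_new <- sum(mask_new); f_old <- sum(mask_old)
  if (f_new != f_old) return(f_new < f_old)
  mask_key(mask_new) < mask_key(mask_old)
}

#' Fold seed used inside a BPSO run
#'
#' The wrapper fitness holds its cross-validation folds fixed within a run so
#' fitness is deterministic; the fold seed is derived from the run seed by
#' this function. Exposed so external oracles can evaluate subsets under the
#' identical folds.
#'
#' @param run_seed the swarm seed
#' @return integer fold seed
#' @export
bpso_fold_seed <- function(run_seed) derive_seed(run_seed, 2L)

#' Binary-PSO wrapper feature selection
#'
#' Positions are initialized uniformly at random and velocities at zero; each
#' iteration applies [update_velocity()], [update_position_binary()], fitness
#' evaluation and pbest/gbest replacement. Fitness is the wrapper objective of
#' [subset_fitness()] with folds fixed per run ([bpso_fold_seed()]).
#' Deterministic given the swarm seed.
#'
#' @param table a preprocessed [labeled_table()] (no missing cells, both
#'   classes present)
#' @param swarm a [swarm_config()]
#' @param classifier classifier spec scored inside the fitness
#' @param weights a [fitness_weights()]
#' @param cv a [cv_config()]; its seed is replaced by the run-derived fold
#'   seed
#' @return an object of class `fs_result`: `gbest` (named 0/1 vector),
#'   `fitness`, `accuracy` (1 - error rate of the best subset), `n_selected`,
#'   `trace` (best-so-far fitness, initial population first, one entry per
#'   iteration after), `seed`, `tf_id`, `polarity`
#' @export
run_bpso <- function(table, swarm = swarm_config(), classifier = knn_spec(),
                     weights = fitness_weights(), cv = cv_config()) {
  stopifnot(inherits(table, "labeled_table"), inherits(swarm, "swarm_config"))
  if (anyNA(table$data)) stop("table has missing cells; preprocess first", call. = FALSE)
  if (length(unique(table$labels)) < 2)
    stop("degenerate table: a class is absent", call. = FALSE)
  N <- n_features(table)
  cv$seed <- bpso_fold_seed(swarm$seed)
  fit_fn <- make_fitness_fn(table, classifier, weights, cv)
  w_sched <- if (length(swarm$inertia) == 2)
    seq(swarm$inertia[1], swarm$inertia[2], length.out = swarm$n_iterations)
  else rep(swarm$inertia, swarm$n_iterations)

  with_seed(swarm$seed, {
    P <- swarm$n_particles
    pos <- matrix(as.integer(stats::runif(P * N) < 0.5), nrow = P)
    vel <- matrix(0, nrow = P, ncol = N)
    evals <- lapply(seq_len(P), function(i) fit_fn(pos[i, ]))
    pbest <- pos
    pbest_fit <- vapply(evals, `[[`, numeric(1), "fitness")
    g <- 1L
    for (i in seq_len(P))
      if (mask_improves(pbest_fit[i], pbest[i, ], pbest_fit[g], pbest[g, ])) g <- i
    gbest <- pbest[g, ]
    gbest_fit <- pbest_fit[g]
    gbest_eval <- evals[[g]]
    trace <- numeric(swarm$n_iterations + 1)
    trace[1] <- gbest_fit

    for (m in seq_len(swarm$n_iterations)) {
      for (i in seq_len(P)) {
        vel[i, ] <- update_velocity(vel[i, ], pos[i, ], pbest[i, ], gbest,
                                    swarm, inertia_now = w_sched[m])
        pos[i, ] <- update_position_binary(vel[i, ], swarm$tf_id, swarm$polarity)
        ev <- fit_fn(pos[i, ])
        if (mask_improves(ev$fitness, pos[i, ], pbest_fit[i], pbest[i, ])) {
          pbest[i, ] <- pos[i, ]
          pbest_fit[i] <- ev$fitness
          if (mask_improves(ev$fitness, pos[i, ], gbest_fit, gbest)) {
            gbest <- pos[i, ]
            gbest_fit <- ev$fitness
            gbest_eval <- ev
          }
        }
      }
      trace[m + 1] <- gbest_fit
    }
    structure(list(
      gbest = stats::setNames(gbest, feature_names(table)),
      fitness = gbest_fit,
      accuracy = 1 - gbest_eval$error_rate,
      n_selected = sum(gbest),
      trace = trace,
      seed = swarm$seed,
      tf_id = swarm$tf_id,
      polarity = swarm$polarity
    ), class = "fs_result")
  })
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf(
    "<fs_result> %d/%d features, fitness %.4f, accuracy %.4f (tf %s, seed %d)\n",
    x$n_selected, length(x$gbest), x$fitness, x$accuracy, x$tf_id, x$seed))
  invisible(x)
}

#' Exhaustive feature-subset oracle
#'
#' Evaluates the wrapper fitness of every nonempty subset under identical CV
#' folds and returns the minimizer; ties prefer fewer features, then the
#' lexicographically smallest mask. Guarded to N <= 12 features (2^N - 1
#' evaluations); intended as a validation oracle for [run_bpso()], whose
#' result can never beat it.
#'
#' @inheritParams run_bpso
#' @param cv a [cv_config()]; use `cv_config(seed = bpso_fold_seed(s))` to
#'   share folds with a BPSO run seeded `s`
#' @return list with `mask` (named 0/1 vector), `fitness`, `error_rate`,
#'   `n_selected`
#' @export
exhaustive_best_subset <- function(table, classifier = knn_spec(),
                                   weights = fitness_weights(),
                                   cv = cv_config()) {
  N <- n_features(table)
  if (N > 12) stop("exhaustive search is guarded to N <= 12 features", call. = FALSE)
  fit_fn <- make_fitness_fn(table, classifier, weights, cv)
  best <- NULL
  for (code in seq_len(2^N - 1)) {
    mask <- as.integer(intToBits(code))[seq_len(N)]
    ev <- fit_fn(mask)
    if (is.null(best) ||
        mask_improves(ev$fitness, mask, best$fitness, best$mask)) {
      best <- list(mask = mask, fitness = ev$fitness,
                   error_rate = ev$error_rate, n_selected = ev$n_selected)
    }
  }
  best$mask <- stats::setNames(best$mask, feature_names(table))
  best
}

#' Serialize a feature-selection result
#'
#' Writes three artifacts under a common prefix: `<prefix>_mask.csv` (a
#' one-row 0/1 table, one column per feature), `<prefix>_summary.json`
#' (fitness, accuracy, subset size, seed, transfer function) and
#' `<prefix>_trace.csv` (best-so-far fitness per iteration, for convergence
#' plots).
#'
#' @param result an `fs_result` from [run_bpso()]
#' @param prefix path prefix for the three files
#' @return character vector of the written paths, invisibly
#' @export
write_fs_result <- function(result, prefix) {
  stopifnot(inherits(result, "fs_result"))
  mask_path <- paste0(prefix, "_mask.csv")
  utils::write.csv(as.data.frame(t(result$gbest)), mask_path, row.names = FALSE)
  json_path <- paste0(prefix, "_summary.json")
  jsonlite::write_json(
    list(fitness = result$fitness, accuracy = result$accuracy,
         n_selected = result$n_selected, seed = result$seed,
         tf_id = result$tf_id, polarity = result$polarity),
    json_path, auto_unbox = TRUE, digits = NA)
  trace_path <- paste0(prefix, "_trace.csv")
  utils::write.csv(
    data.frame(iteration = seq_along(result$trace) - 1L,
               best_fitness = result$trace),
    trace_path, row.names = FALSE)
  invisible(c(mask_path, json_path, trace_path))
}
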