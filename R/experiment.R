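#' Per-feature selection frequency over repeated runs
#'
#' Counts, for each feature of the common universe, how many masks select it.
#' Masks may be named vectors over different (grouped) schemas; features
#' absent from a mask's universe simply contribute nothing.
#'
#' @param masks list of 0/1 vectors; named vectors are aligned by name,
#'   unnamed ones must share a common length and order
#' @return named integer vector of selection counts over the feature union
#' @export
selection_frequency <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1)
  named <- vapply(masks, function(m) !is.null(names(m)), logical(1))
  if (all(named)) {
    universe <- unique(unlist(lapply(masks, names)))
    counts <- stats::setNames(integer(length(universe)), universe)
    for (m in masks) counts[names(m)] <- counts[names(m)] + as.integer(m)
  } else {
    len <- unique(lengths(masks))
    if (length(len) != 1)
      stop("unnamed masks must share a common length", call. = FALSE)
    counts <- Reduce(`+`, lapply(masks, as.integer))
    names(counts) <- paste0("f", seq_len(len))
  }
  counts
}

#' Feature-reduction and accuracy-improvement accounting
#'
#' Summarizes a before/after feature-selection comparison the way the study
#' tables do: reduction is the percentage of features removed; improvement is
#' the absolute accuracy difference expressed in percentage points.
#'
#' @param acc_before,acc_after accuracies in `[0,1]`
#' @param n_before,n_after feature counts, `n_after <= n_before`
#' @return list with `feature_reduction_pct` and `accuracy_improvement_pp`
#' @seealso [relative_accuracy_change()] for the relative-change variant
#' @export
improvement_summary <- function(acc_before, n_before, acc_after, n_after) {
  if (n_before <= 0) stop("n_before must be positive", call. = FALSE)
  if (n_after > n_before) stop("n_after exceeds n_before", call. = FALSE)
  stop_if_not_proportion(acc_before, "acc_before")
  stop_if_not_proportion(acc_after, "acc_after")
  list(feature_reduction_pct = 100 * (n_before - n_after) / n_before,
       accuracy_improvement_pp = 100 * (acc_after - acc_before))
}

#' Relative accuracy change in percent
#'
#' `100 * (acc_after - acc_before) / acc_before` — deliberately named apart
#' from the absolute percentage-point convention of [improvement_summary()].
#'
#' @param acc_before,acc_after accuracies in `[0,1]`, `acc_before > 0`
#' @return relative change in percent
#' @export
relative_accuracy_change <- function(acc_before, acc_after) {
  if (acc_before <= 0) stop("acc_before must be positive", call. = FALSE)
  100 * (acc_after - acc_before) / acc_before
}

#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs: the data source, which
#' demographic groupings to run, the classifier roster for the comparison
#' stage, the swarm/fitness/CV settings for feature selection, the number of
#' independent FS runs, and the master seed every random draw derives from.
#'
#' @param data either a [generator_config()] (synthetic source) or a path to
#'   a CSV written by [write_labeled_table()]
#' @param schema a [schema_spec()] for synthetic sources
#' @param groups character subset of `c("none", "race", "sex", "age")`
#' @param classifiers named list of classifier specs compared per group
#' @param fs_classifier classifier spec used inside the wrapper fitness
#' @param swarm a [swarm_config()] (its seed is overridden per run)
#' @param runs number of independent FS repetitions per group
#' @param weights a [fitness_weights()]
#' @param cv a [cv_config()]
#' @param out_dir directory for the report bundle
#' @param seed master seed
#' @return an object of class `experiment_config`
#' @export
experiment_config <- function(data = generator_config(),
                              schema = default_schema(),
                              groups = c("none", "race", "sex", "age"),
                              classifiers = list(
                                knn = knn_spec(10L, "euclidean", "equal", TRUE),
                                wknn = knn_spec(10L, "euclidean", "squared_inverse", TRUE),
                                ensemble = subspace_spec()),
                              fs_classifier = knn_spec(5L),
                              swarm = swarm_config(),
                              runs = 10L,
                              weights = fitness_weights(),
                              cv = cv_config(),
                              out_dir = tempfile("apneafs_report_"),
                              seed = 1L) {
  stopifnot(runs >= 1,
            all(groups %in% c("none", "race", "sex", "age")),
            length(classifiers) >= 1, !is.null(names(classifiers)))
  structure(list(data = data, schema = schema, groups = groups,
                 classifiers = classifiers, fs_classifier = fs_classifier,
                 swarm = swarm, runs = as.integer(runs), weights = weights,
                 cv = cv, out_dir = out_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

load_experiment_data <- function(config) {
  if (inherits(config$data, "generator_config")) {
    gen <- config$data
    gen$seed <- derive_seed(config$seed, 10L)
    generate_dataset(config$schema, gen)
  } else if (is.character(config$data)) {
    if (!file.exists(config$data))
      stop("unreadable data source: ", config$data, call. = FALSE)
    read_labeled_table(config$data)
  } else stop("unsupported data source", call. = FALSE)
}

#' Run the full grouped feature-selection study
#'
#' End-to-end orchestration: load or generate the data; preprocess
#' (sparse-column removal, imputation, min-max normalization); for each
#' requested grouping, compare the classifier roster under shared CV folds
#' (metrics plus mean ranks), run `runs` seeded BPSO repetitions, and
#' summarize best/average accuracy, the best mask, per-feature selection
#' frequencies and the reduction/improvement accounting against the
#' all-features baseline. All randomness derives from the master seed; a
#' manifest records the seeds and group sizes. Report tables are written
#' under `out_dir`.
#'
#' @param config an [experiment_config()]
#' @return the report bundle, invisibly: a list with one entry per group
#'   (`metrics`, `mean_ranks`, `fs_runs`, `best`, `selection_counts`,
#'   `improvement`) plus `manifest`
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- load_experiment_data(config)
  table <- drop_sparse(table)
  table <- impute(table)

  # grouping precedes normalization: the age threshold is in years, and each
  # group is min-max rescaled on its own support
  group_tables <- list()
  for (g in config$groups) {
    if (g == "none") {
      group_tables[["all"]] <- table
    } else {
      sp <- group_spec(g)
      if (!(if (is.character(sp$column)) sp$column %in% names(table$data)
            else sp$column <= ncol(table$data)))
        stop("invalid group column for variable: ", g, call. = FALSE)
      group_tables <- c(group_tables, split_groups(table, sp))
    }
  }
  norms <- lapply(group_tables, min_max_normalize)
  group_tables <- lapply(norms, `[[`, "table")
  if ("all" %in% names(norms))
    write_normalization_params(norms$all$params,
                               file.path(config$out_dir, "normalization.json"))

  bundle <- list()
  manifest <- list(seed = config$seed, runs = config$runs,
                   n_samples = nrow(table$data),
                   group_sizes = lapply(group_tables, function(t) nrow(t$data)))
  gi <- 0L
  for (gname in names(group_tables)) {
    gi <- gi + 1L
    gt <- group_tables[[gname]]
    cvg <- config$cv
    cvg$seed <- derive_seed(config$seed, 100L + gi)

    metrics <- t(vapply(config$classifiers, function(spec)
      metrics_vector(suppressWarnings(cross_validate(gt, spec, cvg))),
      numeric(7)))
    ranks <- if (nrow(metrics) > 1) mean_rank(metrics) else
      stats::setNames(1, rownames(metrics))

    run_seeds <- vapply(seq_len(config$runs),
                        function(r) derive_seed(config$seed, 1000L * gi + r),
                        integer(1))
    fs_runs <- lapply(run_seeds, function(s) {
      sw <- config$swarm
      sw$seed <- s
      run_bpso(gt, sw, config$fs_classifier, config$weights, config$cv)
    })
    fits <- vapply(fs_runs, `[[`, numeric(1), "fitness")
    accs <- vapply(fs_runs, `[[`, numeric(1), "accuracy")
    best_i <- which.min(fits)
    best <- fs_runs[[best_i]]

    baseline <- suppressWarnings(cross_validate(gt, config$fs_classifier, cvg))
    improvement <- improvement_summary(baseline$accuracy, n_features(gt),
                                       best$accuracy, best$n_selected)

    masks <- lapply(fs_runs, `[[`, "gbest")
    counts <- selection_frequency(masks)

    safe <- gsub("[^A-Za-z0-9_.<=>-]", "_", gname)
    mt <- data.frame(classifier = rownames(metrics), metrics,
                     mean_rank = ranks, check.names = FALSE)
    utils::write.csv(mt, file.path(config$out_dir,
                                   paste0("metrics_", safe, ".csv")),
                     row.names = FALSE)
    mm <- do.call(rbind, lapply(masks, function(m) as.integer(m)))
    colnames(mm) <- names(masks[[1]])
    utils::write.csv(cbind(data.frame(run = seq_len(config$runs),
                                      seed = run_seeds, fitness = fits,
                                      accuracy = accs), mm),
                     file.path(config$out_dir, paste0("fs_runs_", safe, ".csv")),
                     row.names = FALSE)
    write_fs_result(best, file.path(config$out_dir, paste0("best_", safe)))

    bundle[[gname]] <- list(
      metrics = metrics, mean_ranks = ranks, fs_runs = fs_runs,
      best = best,
      accuracy_mean = mean(accs), accuracy_sd = stats::sd(accs),
      selection_counts = counts,
      baseline_accuracy = baseline$accuracy,
      improvement = improvement)
    manifest$fs_seeds[[gname]] <- run_seeds
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bundle$manifest <- manifest
  invisible(bundle)
}
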