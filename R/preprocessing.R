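#' Remove sparsely observed columns and rows
#'
#' Columns whose missing fraction strictly exceeds `threshold` are removed
#' first; then rows whose missing fraction over the remaining columns strictly
#' exceeds `threshold` are removed. A column with exactly the threshold's
#' missing fraction is retained. Labels are exempt from the rule (they are
#' never missing) and follow the retained rows.
#'
#' @param table a [labeled_table()]
#' @param threshold maximum tolerated missing fraction, in `(0,1]`; default 0.5
#' @return a [labeled_table()]
#' @export
drop_sparse <- function(table, threshold = 0.5) {
  stopifnot(inherits(table, "labeled_table"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("`threshold` must lie in (0,1]", call. = FALSE)
  miss <- is.na(as_feature_matrix(table))
  keep_col <- colMeans(miss) <= threshold
  if (!any(keep_col))
    stop("every column exceeds the missingness threshold; table unusable",
         call. = FALSE)
  miss <- miss[, keep_col, drop = FALSE]
  keep_row <- rowMeans(miss) <= threshold
  subset_table(table, rows = which(keep_row), cols = which(keep_col))
}

#' Impute missing cells with column mean or mode
#'
#' Numeric columns receive the mean of their observed values; nominal columns
#' receive the most frequent observed level (ties broken by level order).
#' Observed cells are untouched and the output has no missing feature cells.
#'
#' @param table a [labeled_table()]
#' @return a [labeled_table()] with zero missing cells
#' @export
impute <- function(table) {
  stopifnot(inherits(table, "labeled_table"))
  data <- table$data
  for (j in seq_along(data)) {
    col <- data[[j]]
    nas <- is.na(col)
    if (!any(nas)) next
    if (all(nas))
      stop("column `", names(data)[j],
           "` is fully missing; drop it before imputing", call. = FALSE)
    if (is.factor(col)) {
      col[nas] <- col_mode(col)
    } else {
      col[nas] <- mean(col, na.rm = TRUE)
    }
    data[[j]] <- col
  }
  labeled_table(data, table$labels, table$types)
}

#' Min-max normalization of numeric columns
#'
#' Every numeric column is rescaled to `[0,1]` by `(x - min) / (max - min)`
#' using the column's own extremes; nominal columns are untouched. A
#' degenerate column (max equal to min) maps to 0 everywhere, keeping the
#' range contract where the formula is undefined. The returned parameters can
#' be replayed onto new rows with [apply_normalization()].
#'
#' @param table a [labeled_table()] with no missing numeric cells
#' @return list with elements `table` (normalized [labeled_table()]) and
#'   `params` (a `normalization_params` object storing per-column min/max)
#' @export
min_max_normalize <- function(table) {
  stopifnot(inherits(table, "labeled_table"))
  num <- names(table$types)[table$types == "numeric"]
  if (anyNA(table$data[num]))
    stop("impute before normalizing: numeric cells are missing", call. = FALSE)
  mins <- vapply(table$data[num], min, numeric(1))
  maxs <- vapply(table$data[num], max, numeric(1))
  params <- structure(list(columns = num, min = mins, max = maxs),
                      class = "normalization_params")
  list(table = apply_normalization(table, params), params = params)
}

#' Apply stored min-max parameters to a table
#'
#' @param table a [labeled_table()] containing the parameterized columns
#' @param params a `normalization_params` object from [min_max_normalize()]
#' @return a [labeled_table()]
#' @export
apply_normalization <- function(table, params) {
  stopifnot(inherits(params, "normalization_params"))
  data <- table$data
  for (nm in params$columns) {
    if (!nm %in% names(data)) stop("column `", nm, "` absent", call. = FALSE)
    span <- params$max[[nm]] - params$min[[nm]]
    data[[nm]] <- if (span == 0) rep(0, nrow(data))
                  else (data[[nm]] - params$min[[nm]]) / span
  }
  labeled_table(data, table$labels, table$types)
}

#' Serialize / read normalization parameters
#'
#' @param params a `normalization_params` object
#' @param path destination JSON file
#' @return `path` invisibly (writer); a `normalization_params` (reader)
#' @export
write_normalization_params <- function(params, path) {
  stopifnot(inherits(params, "normalization_params"))
  jsonlite::write_json(
    list(columns = params$columns, min = as.list(params$min),
         max = as.list(params$max)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_normalization_params
#' @export
read_normalization_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(columns = x$columns,
                 min = unlist(x$min)[x$columns],
                 max = unlist(x$max)[x$columns]),
            class = "normalization_params")
}

.epworth_bands <- data.frame(
  lo = c(0, 6, 11, 13, 16),
  hi = c(5, 10, 12, 15, 24),
  label = c("lower normal daytime sleepiness",
            "higher normal daytime sleepiness",
            "mild daytime sleepiness",
            "moderate daytime sleepiness",
            "significant daytime sleepiness"),
  stringsAsFactors = FALSE
)

#' Epworth sleepiness scale band
#'
#' Maps an Epworth score (0-24) to its clinical band: 0-5 lower normal,
#' 6-10 higher normal, 11-12 mild, 13-15 moderate, 16-24 significant daytime
#' sleepiness.
#'
#' @param score integer score(s) between 0 and 24
#' @return character vector of band labels
#' @export
epworth_category <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 24) ||
      any(score != floor(score)))
    stop("Epworth scores must be whole numbers in [0,24]", call. = FALSE)
  idx <- findInterval(score, .epworth_bands$lo)
  .epworth_bands$label[idx]
}

#' Demographic grouping specification
#'
#' @param group_variable one of `"race"`, `"sex"`, `"age"`
#' @param column the column name or index holding the variable; defaults to
#'   the conventional schema positions `f1`/`f3`/`f2`
#' @param age_threshold split point in years for age grouping (default 50,
#'   inclusive on the lower side)
#' @param drop_group_column whether each group table drops the grouping
#'   column; defaults to `TRUE` for race and sex (a 31-feature table yields
#'   30-feature groups) and `FALSE` for age
#' @return an object of class `group_spec`
#' @export
group_spec <- function(group_variable, column = NULL, age_threshold = 50,
                       drop_group_column = NULL) {
  if (!group_variable %in% c("race", "sex", "age"))
    stop("unknown group variable: ", group_variable, call. = FALSE)
  if (is.null(column))
    column <- switch(group_variable, race = "f1", age = "f2", sex = "f3")
  if (is.null(drop_group_column))
    drop_group_column <- group_variable != "age"
  structure(list(group_variable = group_variable, column = column,
                 age_threshold = age_threshold,
                 drop_group_column = drop_group_column),
            class = "group_spec")
}

#' Partition a table into demographic groups
#'
#' Race and sex grouping split on the column's levels and, by default, remove
#' the now-constant grouping column from each output. Age grouping splits at
#' the threshold (`age <= t` versus `age > t`) and keeps the age column.
#' Group sizes always sum to the input row count.
#'
#' @param table a [labeled_table()]
#' @param spec a [group_spec()]
#' @return named list of [labeled_table()] objects
#' @export
split_groups <- function(table, spec) {
  stopifnot(inherits(table, "labeled_table"), inherits(spec, "group_spec"))
  col <- spec$column
  if (is.character(col)) {
    if (!col %in% names(table$data))
      stop("group column `", col, "` not found", call. = FALSE)
    col <- match(col, names(table$data))
  }
  v <- table$data[[col]]
  if (spec$group_variable == "age") {
    if (!is.numeric(v)) stop("age column must be numeric", call. = FALSE)
    key <- ifelse(v <= spec$age_threshold,
                  paste0("age<=", spec$age_threshold),
                  paste0("age>", spec$age_threshold))
  } else {
    key <- as.character(v)
  }
  keep_cols <- seq_len(ncol(table$data))
  if (spec$drop_group_column) keep_cols <- setdiff(keep_cols, col)
  groups <- lapply(split(seq_along(key), key), function(rows)
    subset_table(table, rows = rows, cols = keep_cols))
  groups
}
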