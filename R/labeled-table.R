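#' Labeled clinical feature table
#'
#' The central data container of the package: a rectangular table of mixed
#' numeric and nominal features with a binary outcome vector. Nominal columns
#' are stored as factors, numeric columns as doubles; missing cells are `NA`.
#' Labels are 0/1 integers (1 = apnea) and may never be missing.
#'
#' @param data data.frame of features; columns must be numeric or factor.
#'   Character columns are converted to factors.
#' @param labels binary vector (0/1 or logical) with one entry per row of
#'   `data`; no missing values allowed.
#' @param types optional named character vector, `"numeric"` or `"nominal"`
#'   per column; inferred from the column classes when omitted.
#' @return An object of class `labeled_table`.
#' @export
labeled_table <- function(data, labels, types = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (j in seq_along(data)) {
    if (is.character(data[[j]])) data[[j]] <- factor(data[[j]])
    if (is.logical(data[[j]])) data[[j]] <- factor(data[[j]])
    if (is.integer(data[[j]])) data[[j]] <- as.double(data[[j]])
  }
  inferred <- vapply(data, function(col) {
    if (is.factor(col)) "nominal" else if (is.numeric(col)) "numeric"
    else stop("unsupported column type: ", class(col)[1], call. = FALSE)
  }, character(1))
  if (is.null(types)) {
    types <- inferred
  } else {
    types <- types[names(data)]
    if (any(is.na(types)) || !all(types %in% c("numeric", "nominal")))
      stop("`types` must name every column as numeric or nominal", call. = FALSE)
    mism <- types == "nominal" & inferred == "numeric"
    for (j in which(mism)) data[[j]] <- factor(data[[j]])
  }
  if (is.logical(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (length(labels) != nrow(data))
    stop("labels length must equal row count", call. = FALSE)
  if (anyNA(labels))
    stop("labels must not contain missing values", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  structure(
    list(data = data, labels = labels, types = stats::setNames(types, names(data))),
    class = "labeled_table"
  )
}

#' @export
print.labeled_table <- function(x, ...) {
  cat(sprintf(
    "<labeled_table> %d samples x %d features (%d numeric, %d nominal); %d positive / %d negative; %d missing cells\n",
    nrow(x$data), ncol(x$data),
    sum(x$types == "numeric"), sum(x$types == "nominal"),
    sum(x$labels == 1L), sum(x$labels == 0L),
    sum(is.na(x$data))
  ))
  invisible(x)
}

#' @export
dim.labeled_table <- function(x) dim(x$data)

#' Feature names of a labeled table
#' @param table a [labeled_table()]
#' @return character vector of column names
#' @export
feature_names <- function(table) names(table$data)

#' Number of features
#' @param table a [labeled_table()]
#' @return integer feature count
#' @export
n_features <- function(table) ncol(table$data)

#' Subset rows and/or feature columns of a labeled table
#'
#' Labels follow the row subset; types follow the column subset.
#'
#' @param table a [labeled_table()]
#' @param rows row indices (default all)
#' @param cols column indices or names (default all)
#' @return a [labeled_table()]
#' @export
subset_table <- function(table, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(table$data))
  if (is.null(cols)) cols <- seq_len(ncol(table$data))
  labeled_table(
    table$data[rows, cols, drop = FALSE],
    table$labels[rows],
    table$types[cols]
  )
}

#' Numeric matrix view of a labeled table
#'
#' Factors are replaced by their integer level codes; used by distance-based
#' classifiers. Missing cells propagate as `NA`.
#'
#' @param table a [labeled_table()]
#' @return numeric matrix, one column per feature
#' @export
as_feature_matrix <- function(table) {
  cols <- lapply(table$data, function(col) {
    if (is.factor(col)) as.double(col) else col
  })
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  m
}

#' Write a labeled table as CSV plus a sidecar metadata file
#'
#' The CSV has one header row, one sample per row, an empty cell for each
#' missing value and a final `label` column in 0/1. The sidecar (JSON) records
#' per-column types, nominal level sets and, optionally, a planted-feature
#' mask so that generated benchmarks are self-describing.
#'
#' @param table a [labeled_table()]
#' @param path CSV destination
#' @param meta_path sidecar destination; default `<path>.meta.json`
#' @param planted_mask optional 0/1 vector stored alongside the types
#' @return `path`, invisibly
#' @export
write_labeled_table <- function(table, path,
                                meta_path = paste0(path, ".meta.json"),
                                planted_mask = NULL) {
  out <- table$data
  for (j in seq_along(out)) if (is.factor(out[[j]])) out[[j]] <- as.character(out[[j]])
  out$label <- table$labels
  utils::write.csv(out, path, row.names = FALSE, na = "")
  levels_list <- lapply(table$data, function(col) if (is.factor(col)) levels(col) else NULL)
  meta <- list(
    types = as.list(table$types),
    nominal_levels = levels_list[!vapply(levels_list, is.null, logical(1))]
  )
  if (!is.null(planted_mask)) meta$planted_mask <- as.integer(planted_mask)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a labeled table written by [write_labeled_table()]
#'
#' @param path CSV file
#' @param meta_path sidecar metadata file; default `<path>.meta.json`. When the
#'   sidecar is absent, column types are inferred (character columns nominal).
#' @return a [labeled_table()]
#' @export
read_labeled_table <- function(path, meta_path = paste0(path, ".meta.json")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         check.names = FALSE)
  if (!"label" %in% names(raw)) stop("CSV lacks a `label` column", call. = FALSE)
  labels <- raw$label
  raw$label <- NULL
  types <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    types <- unlist(meta$types)
    for (nm in names(meta$nominal_levels)) {
      if (nm %in% names(raw))
        raw[[nm]] <- factor(raw[[nm]], levels = meta$nominal_levels[[nm]])
    }
  }
  labeled_table(raw, labels, types = types)
}
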