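# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; stays within 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 1009) %% 2147483629)
}

# Column mode for factors: most frequent level, ties broken by level order.
col_mode <- function(col) {
  tab <- table(col)
  names(tab)[which.max(tab)]
}

mask_key <- function(mask) paste(as.integer(mask), collapse = "")

stop_if_not_proportion <- function(x, name, open_right = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) stop(sprintf("`%s` must be a proportion in [0,%s", name,
                        if (open_right) "1)" else "1]"), call. = FALSE)
  invisible(x)
}
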