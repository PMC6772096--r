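# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed from a master seed and a stream label, so that
# adding one table to a simulation never perturbs the draws of another.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master_seed, label) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 97L)
  as.integer((as.numeric(master_seed) * 2654435761 + h) %% 2147483647)
}

# Schema validation for tabular inputs: errors name the table and the
# offending column so pipeline failures are traceable to a file.
check_columns <- function(df, required, table_name) {
  if (!is.data.frame(df)) {
    stop(sprintf("'%s' must be a data frame", table_name), call. = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("table '%s' is missing column(s): %s",
                 table_name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop(sprintf("table '%s' has no rows", table_name), call. = FALSE)
  }
  invisible(df)
}

# Named-vector lookup with a clear error for unknown keys.
lookup <- function(keys, table, what) {
  idx <- match(keys, names(table))
  if (anyNA(idx)) {
    stop(sprintf("unknown %s: %s", what,
                 paste(unique(keys[is.na(idx)]), collapse = ", ")), call. = FALSE)
  }
  unname(table[idx])
}
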