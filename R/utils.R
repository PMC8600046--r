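# internal helpers shared across modules

# Canonical form for an unordered protein pair: uppercase, sorted, "A|B".
pair_key <- function(a, b) {
  a <- norm_symbol(a)
  b <- norm_symbol(b)
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# HGNC-style symbol normalisation: trim + uppercase. Curated lists mix cases.
norm_symbol <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(!nzchar(x) | is.na(x))) {
    abort("protein symbols must be non-empty strings", class = "peroxnet_bad_symbol")
  }
  x
}

stop_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(
      sprintf("%s is missing required column(s): %s", what, paste(miss, collapse = ", ")),
      class = "peroxnet_bad_input"
    )
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
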