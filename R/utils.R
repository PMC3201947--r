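`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic text rendering of numbers for report files: "." decimal,
# scientific notation below 1e-4, fixed significant digits.
fmt_num <- function(x) {
  out <- rep("NA", length(x))
  ok <- !is.na(x)
  small <- ok & x != 0 & abs(x) < 1e-4
  out[ok & !small] <- sprintf("%.10g", x[ok & !small])
  out[small] <- sprintf("%.9e", x[small])
  out
}

# Write a data.frame as TSV with deterministic number formatting.
# List columns are comma-joined.
write_tsv_report <- function(df, path) {
  df <- as.data.frame(df)
  for (i in seq_along(df)) {
    if (is.list(df[[i]])) {
      df[[i]] <- vapply(df[[i]], function(v) paste(v, collapse = ","), character(1))
    } else if (is.numeric(df[[i]]) && !is.integer(df[[i]])) {
      df[[i]] <- fmt_num(df[[i]])
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
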