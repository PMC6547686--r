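# internal validation helpers ------------------------------------------------

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(min), format(max), format(x)))
  }
  if (integer && x != trunc(x)) {
    abort(sprintf("`%s` must be an integer, got %s.", name, format(x)))
  }
  invisible(x)
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` is missing column(s): %s.", name,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Sequences arrive as T- or U-alphabet strings; everything internal is DNA.
# Errors name the offending entry so a bad FASTA record is findable.
normalize_sequences <- function(sequences, what = "sequences") {
  if (is.data.frame(sequences)) {
    assert_columns(sequences, c("transcript_id", "sequence"), what)
    out <- toupper(sequences$sequence)
    names(out) <- sequences$transcript_id
  } else {
    out <- toupper(as.character(sequences))
    if (is.null(names(out))) {
      names(out) <- paste0("seq", seq_along(out))
    }
  }
  out <- gsub("U", "T", out, fixed = TRUE)
  bad <- grepl("[^ACGT]", out)
  if (any(bad)) {
    abort(sprintf(
      "%s contain characters outside {A,C,G,T,U}: %s",
      what, paste(head(names(out)[bad], 5L), collapse = ", ")
    ))
  }
  out
}

# Interval overlap in nt for 0-based half-open intervals.
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Parse a comma-separated offsets string ("", "3,7") into an integer vector.
parse_offsets <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) integer(0) else as.integer(strsplit(s, ",")[[1]])
  })
}

format_offsets <- function(offsets) {
  vapply(offsets, function(o) paste(o, collapse = ","), character(1))
}

# Ensure a reads tibble carries conversion offsets as a list-column.
reads_with_offsets <- function(reads) {
  assert_columns(reads, c("transcript_id", "start", "end",
                          "conversion_offsets"), "reads")
  if (is.character(reads$conversion_offsets)) {
    reads$conversion_offsets <- parse_offsets(reads$conversion_offsets)
  }
  reads
}
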