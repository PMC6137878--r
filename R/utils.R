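# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals. Percentages in reports are
# rendered this way so that e.g. 3 carriers of 96 prints as 3.13, not the
# 3.12 that banker's rounding would give. The 1e-9 guard absorbs binary
# representation error in values like 72.5949999... that are exact halves in
# decimal.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Read a TSV with a mandatory header; keeps strings as characters and never
# interprets "NA"-like gene symbols (there is none in practice, but symbols
# such as "T" would otherwise be at risk of type coercion).
read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "", na.strings = NULL)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

# Parse "true"/"false" (any case, also TRUE/FALSE/1/0) from config tables.
parse_logical <- function(x, what = "logical", line = NULL) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    loc <- if (is.null(line)) bad else line[bad]
    stop("cannot parse ", what, " value '", x[is.na(out)][1],
         "' (line ", loc, ")", call. = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
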