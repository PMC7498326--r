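# Internal helpers shared across modules.

# Stop with a classed condition so callers/tests can match on error class.
md_abort <- function(msg, class) {
  rlang::abort(msg, class = paste0("magdistill_", class))
}

# Coerce a character vector of numbers, erroring with 1-based line numbers
# (offset accounts for a header line) when a field does not parse.
parse_numeric_field <- function(x, field, line_offset = 1L) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "")
  if (length(bad) > 0) {
    md_abort(
      sprintf(
        "Unparseable %s %s at line %d",
        field, dQuote(x[bad[1]]), bad[1] + line_offset
      ),
      "row_error"
    )
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
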