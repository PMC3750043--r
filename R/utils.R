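# Internal helpers shared across modules.

mh_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mixhill_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' Logarithmically spaced sequence
#'
#' @param from,to positive endpoints (inclusive).
#' @param length.out number of points.
#' @return numeric vector spaced evenly on the log10 axis.
#' @export
lseq <- function(from, to, length.out) {
  stopifnot(from > 0, to > 0, length.out >= 2)
  10^seq(log10(from), log10(to), length.out = length.out)
}

# Column check with a named error message.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    mh_stop(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      "mixhill_parse_error"
    )
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
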