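# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# typed errors so callers and tests can distinguish validation from I/O faults
abort <- function(msg, class = "descope_error", ...) {
  stop(errorCondition(msg, ..., class = c(class, "descope_error", "error")))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
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

# Shortest decimal representation that round-trips to the identical double.
# %.15g is tried first for readability; fall back to %.17g which is always exact.
format_full <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- "NA"
  ok <- !is.na(x)
  if (any(ok)) {
    s15 <- sprintf("%.15g", x[ok])
    exact <- as.numeric(s15) == x[ok]
    s15[!exact] <- sprintf("%.17g", x[ok][!exact])
    out[ok] <- s15
  }
  out
}

# Missing markers accepted on input ("" / NA / NaN, case-insensitive).
is_missing_marker <- function(x) {
  x <- trimws(x)
  is.na(x) | x == "" | tolower(x) %in% c("na", "nan")
}

parse_numeric <- function(x, column) {
  out <- rep(NA_real_, length(x))
  keep <- !is_missing_marker(x)
  if (any(keep)) {
    val <- suppressWarnings(as.numeric(x[keep]))
    bad <- is.na(val)
    if (any(bad)) {
      rows <- which(keep)[bad]
      abort(sprintf("column '%s': non-numeric values at rows %s (e.g. '%s')",
                    column, paste(utils::head(rows, 5L), collapse = ", "),
                    x[keep][bad][1L]),
            class = "descope_parse_error")
    }
    out[keep] <- val
  }
  out
}
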