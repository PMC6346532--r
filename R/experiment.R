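#' Construct a DE experiment
#'
#' An experiment is one differential-expression result table (one row per
#' gene) together with its data dictionary and display metadata. Gene
#' identity and order are given by the `EnsemblID` column; all declared
#' dimensions must be present and, for numeric dimensions, numeric (with `NA`
#' as the explicit missing marker). Any `pValue` values present must lie in
#' [0, 1].
#'
#' @param id unique experiment identifier.
#' @param data data frame holding at least every dictionary dimension.
#' @param dictionary a [data_dictionary()].
#' @param title human-readable title.
#' @param visibility `"public"` or `"private"`.
#' @param icon icon label used by front-ends (metadata only; public
#'   experiments conventionally get `"box"`).
#' @return An object of class `de_experiment` with fields `id`, `title`,
#'   `visibility`, `icon`, `data`, `dictionary`.
#' @export
new_experiment <- function(id, data, dictionary, title = id,
                           visibility = c("private", "public"), icon = "box") {
  if (!is_string(id)) abort("experiment id must be a non-empty string",
                            class = "descope_validation_error")
  visibility <- match.arg(visibility)
  stopifnot(inherits(dictionary, "de_dictionary"), is.data.frame(data))

  missing_cols <- setdiff(dictionary$name, names(data))
  if (length(missing_cols))
    abort(sprintf("experiment '%s': missing dimension column(s): %s",
                  id, paste(missing_cols, collapse = ", ")),
          class = "descope_validation_error")
  # the dictionary is authoritative: undeclared columns are dropped
  data <- data[, dictionary$name, drop = FALSE]
  rownames(data) <- NULL

  ids <- as.character(data$EnsemblID)
  if (nrow(data) > 0L && (any(is.na(ids)) || any(!nzchar(ids))))
    abort(sprintf("experiment '%s': empty or missing EnsemblID values", id),
          class = "descope_validation_error")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    abort(sprintf("experiment '%s': duplicate EnsemblID(s): %s",
                  id, paste(utils::head(dup, 10L), collapse = ", ")),
          class = "descope_validation_error")
  data$EnsemblID <- ids

  for (dim in dictionary$name[dictionary$kind == "numeric"]) {
    if (!is.numeric(data[[dim]])) {
      if (is.logical(data[[dim]]) && all(is.na(data[[dim]])))
        data[[dim]] <- as.numeric(data[[dim]])
      else
        abort(sprintf("experiment '%s': dimension '%s' is declared numeric but is not",
                      id, dim), class = "descope_validation_error")
    }
  }
  for (dim in dictionary$name[dictionary$kind == "categorical"])
    data[[dim]] <- as.character(data[[dim]])

  if ("pValue" %in% names(data)) {
    p <- data$pValue
    bad <- which(!is.na(p) & (p < 0 | p > 1))
    if (length(bad))
      abort(sprintf("experiment '%s': pValue outside [0,1] at row(s) %s",
                    id, paste(utils::head(bad, 10L), collapse = ", ")),
            class = "descope_validation_error")
  }

  structure(list(id = id, title = title, visibility = visibility, icon = icon,
                 data = data, dictionary = dictionary),
            class = "de_experiment")
}

#' Gene identifiers of an experiment
#' @param experiment a `de_experiment`.
#' @return Character vector of EnsemblIDs in table order.
#' @export
genes <- function(experiment) {
  stopifnot(inherits(experiment, "de_experiment"))
  experiment$data$EnsemblID
}

#' @export
print.de_experiment <- function(x, ...) {
  cat(sprintf("<de_experiment> %s ('%s', %s, icon=%s)\n  %d genes x %d dimensions: %s\n",
              x$id, x$title, x$visibility, x$icon, nrow(x$data),
              nrow(x$dictionary), paste(x$dictionary$name, collapse = ", ")))
  invisible(x)
}

# column of a declared dimension, with kind check ("any" skips the check)
dimension_values <- function(experiment, dim, kind = "any") {
  k <- dimension_kind(experiment$dictionary, dim)
  if (kind != "any" && k != kind)
    abort(sprintf("dimension '%s' is %s, not %s", dim, k, kind),
          class = "descope_validation_error")
  experiment$data[[dim]]
}
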