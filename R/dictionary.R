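#' Data dictionaries
#'
#' A data dictionary declares the dimensions (columns) of a DE result table
#' and their semantic kinds. It is authoritative: no type inference is ever
#' performed on the tables themselves. Exactly one dimension must have kind
#' `"identifier"` and it must be named `EnsemblID` — the key that makes
#' experiments joinable with annotation tables and comparable across the
#' collection.
#'
#' @param dimensions data frame with columns `name`, `kind`
#'   (`numeric`/`categorical`/`identifier`) and optionally `description`.
#' @return An object of class `de_dictionary`: the validated dimension table.
#' @examples
#' data_dictionary(data.frame(
#'   name = c("EnsemblID", "foldChange", "pValue"),
#'   kind = c("identifier", "numeric", "numeric")))
#' @export
data_dictionary <- function(dimensions) {
  if (!is.data.frame(dimensions) || !all(c("name", "kind") %in% names(dimensions)))
    abort("dimensions must be a data frame with columns 'name' and 'kind'",
          class = "descope_validation_error")
  d <- data.frame(name = as.character(dimensions$name),
                  kind = as.character(dimensions$kind),
                  description = if ("description" %in% names(dimensions))
                    as.character(dimensions$description) else "",
                  stringsAsFactors = FALSE)
  validate_dictionary(d)
  structure(d, class = c("de_dictionary", "data.frame"))
}

validate_dictionary <- function(d) {
  if (nrow(d) == 0L)
    abort("dictionary declares no dimensions", class = "descope_validation_error")
  if (any(is.na(d$name)) || any(!nzchar(d$name)))
    abort("dimension names must be non-empty", class = "descope_validation_error")
  dup <- unique(d$name[duplicated(d$name)])
  if (length(dup))
    abort(sprintf("duplicate dimension name(s): %s", paste(dup, collapse = ", ")),
          class = "descope_validation_error")
  bad <- setdiff(unique(d$kind), c("numeric", "categorical", "identifier"))
  if (length(bad))
    abort(sprintf("unknown dimension kind(s): %s", paste(bad, collapse = ", ")),
          class = "descope_validation_error")
  ids <- d$name[d$kind == "identifier"]
  if (length(ids) != 1L || ids != "EnsemblID")
    abort(paste("a dictionary must declare exactly one identifier dimension",
                "and it must be named 'EnsemblID'"),
          class = "descope_validation_error")
  invisible(d)
}

#' Read a data dictionary from JSON
#'
#' The document must contain a top-level `dimensions` array of objects with
#' fields `name`, `kind` and optionally `description`. Unknown top-level
#' fields are preserved verbatim in the `"extra"` attribute of the result.
#'
#' @param path path to a JSON file.
#' @return A `de_dictionary`.
#' @export
read_data_dictionary <- function(path) {
  if (!file.exists(path))
    abort(sprintf("dictionary file not found: %s", path), class = "descope_io_error")
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) abort(sprintf("malformed JSON in '%s': %s", path,
                                      conditionMessage(e)),
                              class = "descope_parse_error"))
  if (!is.list(doc) || is.null(doc$dimensions))
    abort(sprintf("'%s' has no top-level 'dimensions' array", path),
          class = "descope_validation_error")
  dims <- as.data.frame(doc$dimensions, stringsAsFactors = FALSE)
  dict <- data_dictionary(dims)
  extra <- doc[setdiff(names(doc), "dimensions")]
  if (length(extra)) attr(dict, "extra") <- extra
  dict
}

#' Write a data dictionary to JSON
#'
#' Inverse of [read_data_dictionary()]; preserved unknown fields are written
#' back alongside `dimensions`.
#'
#' @param dictionary a `de_dictionary`.
#' @param path output path.
#' @export
write_data_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "de_dictionary"))
  doc <- c(list(dimensions = as.data.frame(unclass(dictionary),
                                           stringsAsFactors = FALSE)),
           attr(dictionary, "extra"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Canonical dictionary for generated DE tables
#'
#' EnsemblID, geneName, baseMean, foldChange, pValue, pAdj — the dimension
#' names used throughout the synthetic-data generator and the examples.
#' @return A `de_dictionary`.
#' @export
default_dictionary <- function() {
  data_dictionary(data.frame(
    name = c("EnsemblID", "geneName", "baseMean", "foldChange", "pValue", "pAdj"),
    kind = c("identifier", "categorical", rep("numeric", 4L)),
    description = c("Ensembl gene identifier", "gene symbol",
                    "mean normalized expression", "log2 fold change",
                    "raw p-value", "BH-adjusted p-value")))
}

dimension_kind <- function(dictionary, dim) {
  i <- match(dim, dictionary$name)
  if (is.na(i))
    abort(sprintf("unknown dimension '%s'", dim), class = "descope_validation_error")
  dictionary$kind[i]
}
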