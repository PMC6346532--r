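#' Read a DE result table
#'
#' Reads a delimited text table (one gene per row) against a data dictionary.
#' The delimiter is auto-detected from the header line (tab preferred, comma
#' fallback). Every dictionary dimension must appear in the header; columns
#' not declared in the dictionary are ignored. Missing numeric values may be
#' written as an empty field, `NA` or `NaN` (case-insensitive). Row order is
#' preserved.
#'
#' @param path path to a TSV/CSV file with a header row.
#' @param dictionary a [data_dictionary()] describing the columns.
#' @param id experiment id; defaults to the file name without extension.
#' @param title,visibility,icon experiment metadata, see [new_experiment()].
#' @return A `de_experiment`.
#' @export
read_de_table <- function(path, dictionary, id = NULL, title = NULL,
                          visibility = "private", icon = "box") {
  if (!file.exists(path))
    abort(sprintf("DE table not found: %s", path), class = "descope_io_error")
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    abort(sprintf("'%s' is empty", path), class = "descope_parse_error")
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", na.strings = NULL,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(dictionary$name, names(raw))
  if (length(missing_cols))
    abort(sprintf("'%s' lacks declared column(s): %s",
                  path, paste(missing_cols, collapse = ", ")),
          class = "descope_validation_error")
  data <- raw[, dictionary$name, drop = FALSE]
  for (i in seq_len(nrow(dictionary))) {
    dim <- dictionary$name[i]
    data[[dim]] <- switch(dictionary$kind[i],
      numeric     = parse_numeric(data[[dim]], dim),
      categorical = ifelse(is_missing_marker(data[[dim]]), NA_character_, data[[dim]]),
      identifier  = data[[dim]])
  }
  id <- id %||% sub("\\.[^.]*$", "", basename(path))
  new_experiment(id, data, dictionary, title = title %||% id,
                 visibility = visibility, icon = icon)
}

#' Write a DE result table
#'
#' Writes the experiment's declared dimensions as delimited text. Numeric
#' values are written with full precision so that [read_de_table()] inverts
#' the write exactly; missing values are written as `NA`.
#'
#' @param experiment a `de_experiment`.
#' @param path output path.
#' @param sep field separator, tab by default.
#' @export
write_de_table <- function(experiment, path, sep = "\t") {
  stopifnot(inherits(experiment, "de_experiment"))
  dict <- experiment$dictionary
  cols <- lapply(seq_len(nrow(dict)), function(i) {
    v <- experiment$data[[dict$name[i]]]
    if (dict$kind[i] == "numeric") format_full(v)
    else ifelse(is.na(v), "NA", as.character(v))
  })
  lines <- c(paste(dict$name, collapse = sep),
             if (nrow(experiment$data) > 0L) do.call(paste, c(cols, sep = sep)))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) abort(sprintf("cannot write '%s': %s", path,
                                                   conditionMessage(e)),
                                           class = "descope_io_error"))
  invisible(path)
}

#' Read a gene annotation table
#'
#' A local, flat replacement for on-line gene-metadata services: a TSV keyed
#' by `EnsemblID` with one row per gene and arbitrarily many attribute
#' columns (gene symbol, biotype, ...).
#'
#' @param path TSV path with header; must contain an `EnsemblID` column.
#' @return A data frame keyed by `EnsemblID` (class `de_annotation`).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path))
    abort(sprintf("annotation table not found: %s", path), class = "descope_io_error")
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", na.strings = NULL,
                           stringsAsFactors = FALSE)
  if (!"EnsemblID" %in% names(tab))
    abort(sprintf("'%s' lacks the EnsemblID key column", path),
          class = "descope_validation_error")
  dup <- unique(tab$EnsemblID[duplicated(tab$EnsemblID)])
  if (length(dup))
    abort(sprintf("annotation has duplicate key(s): %s",
                  paste(utils::head(dup, 10L), collapse = ", ")),
          class = "descope_validation_error")
  structure(tab, class = c("de_annotation", "data.frame"))
}

#' Join annotation columns onto an experiment
#'
#' Adds the requested annotation columns as new dimensions, matched by
#' `EnsemblID`. Genes absent from the annotation get missing values. Gene
#' order, gene count and existing dimensions are never changed.
#'
#' @param experiment a `de_experiment`.
#' @param annotation a data frame keyed by `EnsemblID`
#'   (e.g. from [read_annotation_table()]).
#' @param columns character vector of annotation columns to attach; numeric
#'   columns become numeric dimensions, all others categorical.
#' @return A new `de_experiment` with the extra dimensions.
#' @export
join_annotations <- function(experiment, annotation, columns) {
  stopifnot(inherits(experiment, "de_experiment"), is.data.frame(annotation))
  if (!"EnsemblID" %in% names(annotation))
    abort("annotation must be keyed by EnsemblID", class = "descope_validation_error")
  if (length(columns) == 0L) return(experiment)
  absent <- setdiff(columns, names(annotation))
  if (length(absent))
    abort(sprintf("annotation column(s) not found: %s", paste(absent, collapse = ", ")),
          class = "descope_validation_error")
  clash <- intersect(columns, experiment$dictionary$name)
  if (length(clash))
    abort(sprintf("column(s) already exist as dimensions: %s",
                  paste(clash, collapse = ", ")),
          class = "descope_validation_error")

  idx <- match(genes(experiment), annotation$EnsemblID)
  data <- experiment$data
  new_dims <- experiment$dictionary
  for (col in columns) {
    v <- annotation[[col]][idx]
    numeric_col <- is.numeric(annotation[[col]])
    data[[col]] <- if (numeric_col) as.numeric(v) else as.character(v)
    new_dims <- rbind(new_dims,
                      data.frame(name = col,
                                 kind = if (numeric_col) "numeric" else "categorical",
                                 description = "joined annotation",
                                 stringsAsFactors = FALSE))
  }
  new_experiment(experiment$id, data, data_dictionary(new_dims),
                 title = experiment$title, visibility = experiment$visibility,
                 icon = experiment$icon)
}
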