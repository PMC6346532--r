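#' Write a collection to a directory
#'
#' Layout: `manifest.json` (experiment ids in order, focus, context) plus one
#' subdirectory per experiment holding `table.tsv`, `dictionary.json` and
#' `metadata.json` (id, title, visibility, icon).
#'
#' @param collection a `de_collection`.
#' @param dir output directory (created if needed).
#' @export
write_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "de_collection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (e in collection$experiments) {
    sub <- file.path(dir, e$id)
    dir.create(sub, showWarnings = FALSE)
    write_de_table(e, file.path(sub, "table.tsv"))
    write_data_dictionary(e$dictionary, file.path(sub, "dictionary.json"))
    jsonlite::write_json(list(id = e$id, title = e$title,
                              visibility = e$visibility, icon = e$icon),
                         file.path(sub, "metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  jsonlite::write_json(list(experiments = names(collection$experiments),
                            focus = collection$focus_id,
                            context = collection$context_ids),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Read a collection from a directory
#'
#' Inverse of [write_collection()].
#'
#' @param dir collection directory containing `manifest.json`.
#' @return A `de_collection`.
#' @export
read_collection <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path))
    abort(sprintf("no manifest.json in '%s'", dir), class = "descope_io_error")
  manifest <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE)
  exps <- lapply(manifest$experiments, function(id) {
    sub <- file.path(dir, id)
    meta <- jsonlite::fromJSON(file.path(sub, "metadata.json"))
    dict <- read_data_dictionary(file.path(sub, "dictionary.json"))
    read_de_table(file.path(sub, "table.tsv"), dict, id = meta$id,
                  title = meta$title, visibility = meta$visibility,
                  icon = meta$icon)
  })
  coll <- build_collection(exps)
  if (!is.null(manifest$focus) && length(manifest$focus))
    coll <- set_focus(coll, manifest$focus)
  if (!is.null(manifest$context) && length(manifest$context))
    coll <- set_context(coll, manifest$context)
  coll
}

#' Register one DE table into a collection directory
#'
#' Validates the table against its dictionary and writes it as a new
#' experiment subdirectory, updating (or creating) the manifest.
#'
#' @param table_path DE table path.
#' @param dict_path data-dictionary JSON path.
#' @param dir collection directory.
#' @param id,title,visibility,icon experiment metadata; id defaults to the
#'   table file name.
#' @return The experiment id, invisibly.
#' @export
import_experiment <- function(table_path, dict_path, dir, id = NULL,
                              title = NULL, visibility = "private",
                              icon = "box") {
  dict <- read_data_dictionary(dict_path)
  exp <- read_de_table(table_path, dict, id = id, title = title,
                       visibility = visibility, icon = icon)
  manifest_path <- file.path(dir, "manifest.json")
  coll <- if (file.exists(manifest_path)) {
    existing <- read_collection(dir)
    if (exp$id %in% names(existing$experiments))
      abort(sprintf("experiment '%s' already registered", exp$id),
            class = "descope_validation_error")
    existing$experiments <- c(existing$experiments,
                              stats::setNames(list(exp), exp$id))
    existing
  } else build_collection(list(exp))
  write_collection(coll, dir)
  invisible(exp$id)
}
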