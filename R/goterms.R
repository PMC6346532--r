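#' Build a GO annotation store
#'
#' A local gene-ontology annotation: term metadata plus term-to-gene
#' membership, with the inverse gene-to-terms index kept in sync.
#'
#' @param terms data frame with columns `term_id`, `term_name`,
#'   `term_definition`, or `NULL` to derive minimal metadata from
#'   `term_genes`.
#' @param term_genes named list: term_id -> character vector of gene IDs
#'   (non-empty, deduplicated).
#' @return An object of class `go_annotation` with fields `terms` (data
#'   frame, including `size`), `term_genes` and `gene_index` (named list:
#'   gene -> sorted term ids).
#' @export
go_annotation <- function(terms = NULL, term_genes) {
  if (!is.list(term_genes) || is.null(names(term_genes)) ||
      any(!nzchar(names(term_genes))))
    abort("term_genes must be a named list of gene-ID vectors",
          class = "descope_validation_error")
  term_genes <- lapply(term_genes, function(g) unique(as.character(g)))
  if (any(lengths(term_genes) == 0L))
    abort("every term must annotate at least one gene",
          class = "descope_validation_error")
  if (is.null(terms))
    terms <- data.frame(term_id = names(term_genes),
                        term_name = names(term_genes),
                        term_definition = "", stringsAsFactors = FALSE)
  terms <- terms[match(names(term_genes), terms$term_id), , drop = FALSE]
  if (anyNA(terms$term_id))
    abort("terms table must describe every term in term_genes",
          class = "descope_validation_error")
  terms$size <- lengths(term_genes)
  rownames(terms) <- NULL

  pairs_gene <- unlist(term_genes, use.names = FALSE)
  pairs_term <- rep(names(term_genes), lengths(term_genes))
  gene_index <- split(pairs_term, pairs_gene)
  gene_index <- lapply(gene_index, sort)

  structure(list(terms = terms, term_genes = term_genes,
                 gene_index = gene_index),
            class = "go_annotation")
}

#' @export
print.go_annotation <- function(x, ...) {
  cat(sprintf("<go_annotation> %d terms, %d genes, %d gene-term pairs\n",
              nrow(x$terms), length(x$gene_index),
              sum(lengths(x$term_genes))))
  invisible(x)
}

#' Load a GO annotation table
#'
#' Two plain-text formats are accepted: a flat TSV with header columns
#' `term_id`, `term_name`, `term_definition`, `gene_id` (one gene-term pair
#' per row), or GAF 2.x (comment lines starting with `!`; the DB object
#' symbol and the GO ID columns are used, qualifiers are ignored). Duplicate
#' (term, gene) pairs are deduplicated.
#'
#' @param path annotation file.
#' @param format `"auto"` (GAF when the file starts with `!` or ends in
#'   `.gaf`), `"tsv"` or `"gaf"`.
#' @return A `go_annotation`.
#' @export
load_go_annotation <- function(path, format = c("auto", "tsv", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path))
    abort(sprintf("annotation file not found: %s", path), class = "descope_io_error")
  first <- readLines(path, n = 1L)
  if (format == "auto")
    format <- if (grepl("\\.gaf$", path) ||
                  (length(first) && startsWith(first, "!"))) "gaf" else "tsv"
  if (format == "gaf") return(load_gaf(path))

  lines <- readLines(path)
  if (length(lines) < 1L)
    abort(sprintf("'%s' is empty", path), class = "descope_parse_error")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("term_id", "term_name", "term_definition", "gene_id")
  if (!all(need %in% header))
    abort(sprintf("'%s' lacks column(s): %s", path,
                  paste(setdiff(need, header), collapse = ", ")),
          class = "descope_validation_error")
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  if (length(bad))
    abort(sprintf("malformed row(s) in '%s' at line(s) %s", path,
                  paste(utils::head(bad + 1L, 10L), collapse = ", ")),
          class = "descope_parse_error")
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- header
  empty <- which(!nzchar(tab$term_id) | !nzchar(tab$gene_id))
  if (length(empty))
    abort(sprintf("empty term_id/gene_id in '%s' at line(s) %s", path,
                  paste(utils::head(empty + 1L, 10L), collapse = ", ")),
          class = "descope_parse_error")

  term_genes <- lapply(split(tab$gene_id, tab$term_id), unique)
  meta <- tab[!duplicated(tab$term_id),
              c("term_id", "term_name", "term_definition")]
  meta <- meta[match(names(term_genes), meta$term_id), ]
  go_annotation(meta, term_genes)
}

load_gaf <- function(path) {
  lines <- grep("^!", readLines(path), invert = TRUE, value = TRUE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    abort(sprintf("no annotation rows in '%s'", path), class = "descope_parse_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 5L)
  if (length(bad))
    abort(sprintf("GAF rows with fewer than 5 columns at line(s) %s",
                  paste(utils::head(bad, 10L), collapse = ", ")),
          class = "descope_parse_error")
  gene <- vapply(fields, function(f) if (nzchar(f[3L])) f[3L] else f[2L],
                 character(1))
  term <- vapply(fields, `[[`, character(1), 5L)
  go_annotation(NULL, lapply(split(gene, term), unique))
}

go_term_url <- function(term_id) {
  if (length(term_id) == 0L) return(character(0))
  paste0("http://amigo.geneontology.org/amigo/term/", term_id)
}

resolve_selection <- function(selection) {
  ids <- if (inherits(selection, "selection_state")) selection$selected
         else as.character(selection)
  unique(ids)
}

#' Scan GO terms covered by a selection
#'
#' Finds every term containing at least one selected gene and scores it by
#' coverage: the percentage of the *term's* genes that are selected. The
#' list is sorted by coverage descending, with ties broken by term size
#' ascending and then term id. Because the denominator is the term size,
#' the metric favours small terms; the `min_size`/`max_size` bounds exist to
#' counter that.
#'
#' @param annotation a `go_annotation`.
#' @param selection a `selection_state` or character vector of gene IDs
#'   (non-empty). Duplicates are ignored: the score depends only on the set.
#' @param min_size,max_size term-size bounds, `1 <= min_size <= max_size`.
#' @param experiment,color_dim optional: when given, a `mean_value` column
#'   reports the mean of `color_dim` over each term's selected genes present
#'   in the experiment.
#' @return Data frame of class `go_term_scores` with columns `term_id`,
#'   `term_name`, `term_size`, `n_selected`, `coverage_pct`, `url` (and
#'   `mean_value`), sorted.
#' @export
scan_terms <- function(annotation, selection, min_size = 1L, max_size = Inf,
                       experiment = NULL, color_dim = NULL) {
  stopifnot(inherits(annotation, "go_annotation"))
  sel <- resolve_selection(selection)
  if (length(sel) == 0L)
    abort("selection is empty", class = "descope_validation_error")
  if (min_size < 1L || min_size > max_size)
    abort("need 1 <= min_size <= max_size", class = "descope_validation_error")

  hits <- unlist(annotation$gene_index[intersect(sel, names(annotation$gene_index))],
                 use.names = FALSE)
  if (length(hits) == 0L) n_sel <- integer(0) else {
    counts <- table(hits)
    n_sel <- as.integer(counts)
    names(n_sel) <- names(counts)
  }
  term_ids <- names(n_sel) %||% character(0)
  size <- annotation$terms$size[match(term_ids, annotation$terms$term_id)]
  keep <- size >= min_size & size <= max_size
  term_ids <- term_ids[keep]; size <- size[keep]; n_sel <- n_sel[keep]

  out <- data.frame(term_id = term_ids,
                    term_name = annotation$terms$term_name[
                      match(term_ids, annotation$terms$term_id)],
                    term_size = as.integer(size),
                    n_selected = as.integer(n_sel),
                    coverage_pct = 100 * as.integer(n_sel) / as.integer(size),
                    stringsAsFactors = FALSE)
  out$url <- go_term_url(out$term_id)
  if (!is.null(experiment) && !is.null(color_dim)) {
    vals <- dimension_values(experiment, color_dim, "numeric")
    names(vals) <- genes(experiment)
    out$mean_value <- vapply(out$term_id, function(t) {
      g <- intersect(annotation$term_genes[[t]], sel)
      v <- vals[intersect(g, names(vals))]
      if (length(v)) mean(v, na.rm = TRUE) else NA_real_
    }, numeric(1))
  }
  out <- out[order(-out$coverage_pct, out$term_size, out$term_id), ]
  rownames(out) <- NULL
  class(out) <- c("go_term_scores", "data.frame")
  out
}

#' Build the GO plot model for one term
#'
#' The GO plot draws one small rectangle per gene, coloured by a numeric
#' dimension (usually fold change) through the blue-white-red diverging
#' scale. Entries are the term's selected genes (or the whole term with
#' `all_genes = TRUE`), ordered by value descending; genes the experiment
#' does not measure get the missing colour and no value. The plot width is
#' the entry count, reported also as a fraction of `width_reference` so a
#' panel of terms can share a common scale (see [go_plot_models()]).
#'
#' @param annotation a `go_annotation`.
#' @param term_id term to plot.
#' @param experiment the experiment providing gene values.
#' @param selection a `selection_state` or gene-ID vector; ignored when
#'   `all_genes = TRUE`.
#' @param color_dim numeric dimension mapped to colour.
#' @param limits length-2 colour limits; default symmetric about 0 at the
#'   maximum absolute displayed value (so white = 0 for fold changes).
#' @param all_genes show all genes of the term, not only selected ones?
#' @param width_reference width (entry count) of the widest term in the
#'   panel; defaults to this term's own width.
#' @return An object of class `go_plot_model`: list with `term_id`,
#'   `entries` (data frame `gene`, `value`, `r`, `g`, `b`, `color`,
#'   `missing`), `width_units`, `width_fraction`, `limits`, `color_dim`,
#'   `url`.
#' @export
go_plot_data <- function(annotation, term_id, experiment, selection = NULL,
                         color_dim = "foldChange", limits = NULL,
                         all_genes = FALSE, width_reference = NULL) {
  stopifnot(inherits(annotation, "go_annotation"),
            inherits(experiment, "de_experiment"))
  term_genes <- annotation$term_genes[[term_id]]
  if (is.null(term_genes))
    abort(sprintf("unknown GO term '%s'", term_id), class = "descope_validation_error")
  vals_all <- dimension_values(experiment, color_dim, "numeric")
  names(vals_all) <- genes(experiment)

  show <- if (isTRUE(all_genes)) term_genes
          else intersect(term_genes, resolve_selection(selection))
  value <- unname(vals_all[match(show, names(vals_all))])
  missing <- !(show %in% names(vals_all)) | is.na(value)
  ord <- order(-value, show, na.last = TRUE)
  show <- show[ord]; value <- value[ord]; missing <- missing[ord]

  if (is.null(limits)) {
    m <- suppressWarnings(max(abs(value[!missing])))
    if (!is.finite(m) || m == 0) m <- 1
    limits <- c(-m, m)
  }
  rgb <- diverging_color(ifelse(missing, NA_real_, value),
                         low = limits[1], high = limits[2])
  entries <- data.frame(gene = show, value = value, rgb,
                        color = rgb_to_hex(rgb), missing = missing,
                        stringsAsFactors = FALSE)
  width_units <- nrow(entries)
  ref <- width_reference %||% width_units
  structure(list(term_id = term_id, entries = entries,
                 width_units = width_units,
                 width_fraction = if (ref > 0) width_units / ref else 0,
                 limits = limits, color_dim = color_dim,
                 url = go_term_url(term_id)),
            class = "go_plot_model")
}

#' GO plot models for a panel of terms
#'
#' Builds [go_plot_data()] for several terms with a shared width scale: the
#' widest term gets `width_fraction` exactly 1 and every other width is
#' proportional.
#'
#' @inheritParams go_plot_data
#' @param term_ids character vector of term ids.
#' @return Named list of `go_plot_model` objects.
#' @export
go_plot_models <- function(annotation, term_ids, experiment, selection = NULL,
                           color_dim = "foldChange", limits = NULL,
                           all_genes = FALSE) {
  widths <- vapply(term_ids, function(t) {
    g <- annotation$term_genes[[t]]
    if (is.null(g))
      abort(sprintf("unknown GO term '%s'", t), class = "descope_validation_error")
    if (isTRUE(all_genes)) length(g)
    else length(intersect(g, resolve_selection(selection)))
  }, numeric(1))
  ref <- max(widths, 0)
  models <- lapply(term_ids, function(t)
    go_plot_data(annotation, t, experiment, selection = selection,
                 color_dim = color_dim, limits = limits,
                 all_genes = all_genes,
                 width_reference = if (ref > 0) ref else NULL))
  stats::setNames(models, term_ids)
}
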