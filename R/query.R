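#' Filter clauses
#'
#' One cumulative filter condition on a dimension, mirroring the two-part
#' table-header filter of a spreadsheet-style DE table: an operator and an
#' operand. Numeric dimensions support `<`, `>` and `=` (exact equality);
#' categorical dimensions (and the identifier) support only `=`, which is a
#' case-insensitive substring match. A gene with a missing value on the
#' clause's dimension fails the clause.
#'
#' @param dimension dimension name.
#' @param op one of `"lt"`, `"gt"`, `"eq"` (or the symbols `<`, `>`, `=`).
#' @param operand number, or string for categorical matching.
#' @return A `filter_clause`.
#' @export
filter_clause <- function(dimension, op, operand) {
  op <- switch(as.character(op), "<" = "lt", ">" = "gt", "=" = "eq",
               lt = "lt", gt = "gt", eq = "eq",
               abort(sprintf("unknown operator '%s' (use <, > or =)", op),
                     class = "descope_validation_error"))
  if (!is_string(dimension))
    abort("clause dimension must be a non-empty string", class = "descope_validation_error")
  if (length(operand) != 1L || is.na(operand))
    abort("clause operand must be a single non-missing value",
          class = "descope_validation_error")
  structure(list(dimension = dimension, op = op, operand = operand),
            class = "filter_clause")
}

#' Parse a clause from its mini-grammar
#'
#' Grammar: `dim(<|>|=)value`, e.g. `"pValue<0.005"` or `"geneName=Soat"`.
#' The first occurrence of `<`, `>` or `=` splits dimension from operand;
#' surrounding whitespace is trimmed.
#'
#' @param text clause string.
#' @return A `filter_clause`.
#' @export
parse_clause <- function(text) {
  m <- regexpr("[<>=]", text)
  if (m < 0L)
    abort(sprintf("cannot parse clause '%s': no <, > or = operator", text),
          class = "descope_parse_error")
  dimension <- trimws(substr(text, 1L, m - 1L))
  operand <- trimws(substr(text, m + 1L, nchar(text)))
  filter_clause(dimension, substr(text, m, m), operand)
}

# logical mask of genes passing one clause (or lying inside one brush rect)
clause_mask <- function(experiment, clause) {
  if (inherits(clause, "brush_rect")) return(brush_mask(experiment, clause))
  kind <- dimension_kind(experiment$dictionary, clause$dimension)
  v <- experiment$data[[clause$dimension]]
  if (kind == "numeric") {
    o <- suppressWarnings(as.numeric(clause$operand))
    if (is.na(o))
      abort(sprintf("operand '%s' is not numeric (dimension '%s')",
                    clause$operand, clause$dimension),
            class = "descope_validation_error")
    ok <- !is.na(v)
    switch(clause$op,
           lt = ok & v < o,
           gt = ok & v > o,
           eq = ok & v == o)
  } else {
    if (clause$op != "eq")
      abort(sprintf("dimension '%s' is %s: only '=' is supported",
                    clause$dimension, kind),
            class = "descope_validation_error")
    v <- as.character(v)
    !is.na(v) & grepl(tolower(as.character(clause$operand)), tolower(v),
                      fixed = TRUE)
  }
}

new_selection_state <- function(experiment, clauses, selected,
                                highlighted = NULL, view = NULL) {
  structure(list(experiment_id = experiment$id,
                 universe = genes(experiment),
                 clauses = clauses,
                 selected = selected,
                 highlighted = highlighted,
                 view = view),
            class = "selection_state")
}

#' @export
print.selection_state <- function(x, ...) {
  cat(sprintf("<selection_state> %d/%d genes of '%s' (%d clause(s)%s)\n",
              length(x$selected), length(x$universe), x$experiment_id,
              length(x$clauses),
              if (is.null(x$highlighted)) "" else paste0(", highlight ", x$highlighted)))
  invisible(x)
}

#' Apply a chain of filter clauses
#'
#' Evaluates the conjunctive (AND) clause chain against a focus experiment:
#' a gene is selected iff it satisfies every clause. The result does not
#' depend on clause order, and adding a clause can only shrink the
#' selection. An empty chain selects all genes.
#'
#' @param experiment the focus `de_experiment`.
#' @param clauses list of [filter_clause()] / [brush_rect()] objects (a
#'   single clause may be passed bare).
#' @param selection optional existing `selection_state` whose clauses are
#'   extended.
#' @return A `selection_state` with the selected gene IDs in table order.
#' @export
apply_filters <- function(experiment, clauses = list(), selection = NULL) {
  stopifnot(inherits(experiment, "de_experiment"))
  if (inherits(clauses, "filter_clause") || inherits(clauses, "brush_rect"))
    clauses <- list(clauses)
  if (!is.null(selection)) clauses <- c(selection$clauses, clauses)
  mask <- rep(TRUE, nrow(experiment$data))
  for (cl in clauses) mask <- mask & clause_mask(experiment, cl)
  new_selection_state(experiment, clauses, genes(experiment)[mask],
                      highlighted = selection$highlighted %||% NULL,
                      view = selection$view %||% NULL)
}

#' Brush rectangles
#'
#' A rectangular selection spanned in a scatter plot, expressed in
#' *transformed* axis space. The rectangle carries its own dimensions and
#' transforms so it stays evaluable independent of later view changes.
#' Boundaries are closed: points exactly on the edge are selected. Genes
#' whose values fall outside the transform domain (e.g. p = 0 under
#' `-log10`) are never selected by a brush.
#'
#' @param x_dim,y_dim numeric dimension names.
#' @param x_range,y_range length-2 numeric intervals (min, max) in
#'   transformed space; must be finite.
#' @param transform_x,transform_y axis transform names, see
#'   [transform_values()].
#' @return A `brush_rect`.
#' @export
brush_rect <- function(x_dim, y_dim, x_range, y_range,
                       transform_x = "linear", transform_y = "linear") {
  check_transform(transform_x); check_transform(transform_y)
  for (r in list(x_range, y_range)) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2])
      abort("brush ranges must be finite (min, max) intervals",
            class = "descope_validation_error")
  }
  structure(list(x_dim = x_dim, y_dim = y_dim,
                 transform_x = transform_x, transform_y = transform_y,
                 x_range = as.numeric(x_range), y_range = as.numeric(y_range)),
            class = "brush_rect")
}

brush_mask <- function(experiment, rect) {
  tx <- transform_values(dimension_values(experiment, rect$x_dim, "numeric"),
                         rect$transform_x)
  ty <- transform_values(dimension_values(experiment, rect$y_dim, "numeric"),
                         rect$transform_y)
  tx$in_domain & ty$in_domain &
    !is.na(tx$values) & !is.na(ty$values) &
    tx$values >= rect$x_range[1] & tx$values <= rect$x_range[2] &
    ty$values >= rect$y_range[1] & ty$values <= rect$y_range[2]
}

#' Brush genes in a plot
#'
#' Selects the genes whose transformed coordinates lie inside the closed
#' rectangle. With `zoom = TRUE` (the main-plot default) the view range
#' shrinks to the rectangle so the selection can be refined; with
#' `zoom = FALSE` (small-multiples behaviour) only the selection changes.
#'
#' @param experiment the focus `de_experiment`.
#' @param view the current `view_state`; its axes must match the rectangle.
#' @param rect a [brush_rect()].
#' @param zoom zoom the view into the rectangle?
#' @param selection optional existing `selection_state` to extend (AND).
#' @return A `selection_state`; its `view` field holds the (possibly zoomed)
#'   view.
#' @export
apply_brush <- function(experiment, view, rect, zoom = TRUE, selection = NULL) {
  stopifnot(inherits(experiment, "de_experiment"), inherits(view, "view_state"),
            inherits(rect, "brush_rect"))
  if (!identical(rect$x_dim, view$x_dim) || !identical(rect$y_dim, view$y_dim))
    abort(sprintf("brush axes (%s, %s) do not match view axes (%s, %s)",
                  rect$x_dim, rect$y_dim, view$x_dim, view$y_dim),
          class = "descope_validation_error")
  if (zoom && view$zoom_locked)
    abort("zooming is disabled for this view", class = "descope_validation_error")
  out <- apply_filters(experiment, list(rect), selection = selection)
  if (zoom) {
    view$x_range <- rect$x_range
    view$y_range <- rect$y_range
  }
  out$view <- view
  out
}

#' Link a selection to another experiment
#'
#' Brushing-and-linking: the gene set selected in the focus experiment,
#' restricted to the genes another experiment actually measures. Genes
#' absent there are silently dropped.
#'
#' @param selection a `selection_state` (or character vector of gene IDs).
#' @param other_experiment a `de_experiment`.
#' @return Character vector of shared selected gene IDs.
#' @export
link_selection <- function(selection, other_experiment) {
  ids <- if (inherits(selection, "selection_state")) selection$selected
         else as.character(selection)
  ids[ids %in% genes(other_experiment)]
}

#' Highlight a single gene
#'
#' Mouse-over semantics: mark one gene of the focus experiment as
#' highlighted without touching the selection. The highlight travels to
#' every linked view that contains the gene.
#'
#' @param selection a `selection_state`.
#' @param gene_id gene to highlight; must belong to the focus experiment.
#' @return The updated `selection_state`.
#' @export
highlight_gene <- function(selection, gene_id) {
  stopifnot(inherits(selection, "selection_state"))
  if (!is_string(gene_id) || !gene_id %in% selection$universe)
    abort(sprintf("gene '%s' is not in the focus experiment", gene_id),
          class = "descope_validation_error")
  selection$highlighted <- gene_id
  selection
}

#' @rdname highlight_gene
#' @export
clear_highlight <- function(selection) {
  stopifnot(inherits(selection, "selection_state"))
  selection["highlighted"] <- list(NULL)
  selection
}
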