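#' Build an experiment collection
#'
#' A collection holds many experiments (public and private), an optional
#' focus experiment — the one under detailed scrutiny — and an ordered list
#' of context experiments shown alongside it. Iteration order is insertion
#' order and is deterministic.
#'
#' @param experiments non-empty list of `de_experiment` objects with unique ids.
#' @return An object of class `de_collection` with fields `experiments`
#'   (named list), `focus_id` (or `NULL`) and `context_ids`.
#' @export
build_collection <- function(experiments) {
  if (!is.list(experiments) || length(experiments) == 0L)
    abort("a collection needs at least one experiment", class = "descope_validation_error")
  if (!all(vapply(experiments, inherits, logical(1), "de_experiment")))
    abort("all elements must be de_experiment objects", class = "descope_validation_error")
  ids <- vapply(experiments, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    abort(sprintf("duplicate experiment id(s): %s", paste(dup, collapse = ", ")),
          class = "descope_validation_error")
  names(experiments) <- ids
  structure(list(experiments = experiments, focus_id = NULL,
                 context_ids = character(0)),
            class = "de_collection")
}

#' @export
print.de_collection <- function(x, ...) {
  cat(sprintf("<de_collection> %d experiments; focus: %s; context: %s\n",
              length(x$experiments), x$focus_id %||% "<none>",
              if (length(x$context_ids)) paste(x$context_ids, collapse = ", ")
              else "<none>"))
  invisible(x)
}

check_member <- function(collection, id) {
  if (!is_string(id) || !id %in% names(collection$experiments))
    abort(sprintf("no experiment '%s' in collection", id),
          class = "descope_validation_error")
}

#' Set the focus experiment
#'
#' Making another experiment the focus moves the current focus to the end of
#' the context list, mirroring the click-to-switch interaction of linked
#' small multiples. Setting the current focus again is a no-op. For
#' responsive comparison a maximum of 4 context experiments is recommended,
#' though nothing enforces that cap.
#'
#' @param collection a `de_collection`.
#' @param id id of the experiment to focus.
#' @return The updated collection.
#' @export
set_focus <- function(collection, id) {
  stopifnot(inherits(collection, "de_collection"))
  check_member(collection, id)
  if (identical(collection$focus_id, id)) return(collection)
  collection$context_ids <- setdiff(collection$context_ids, id)
  if (!is.null(collection$focus_id))
    collection$context_ids <- c(collection$context_ids, collection$focus_id)
  collection$focus_id <- id
  collection
}

#' Set the context experiments
#'
#' @param collection a `de_collection`.
#' @param ids ordered, duplicate-free experiment ids; must not contain the
#'   current focus.
#' @return The updated collection.
#' @export
set_context <- function(collection, ids) {
  stopifnot(inherits(collection, "de_collection"))
  for (id in ids) check_member(collection, id)
  if (anyDuplicated(ids))
    abort("context ids must be duplicate-free", class = "descope_validation_error")
  if (!is.null(collection$focus_id) && collection$focus_id %in% ids)
    abort("the focus experiment cannot also be a context experiment",
          class = "descope_validation_error")
  collection$context_ids <- as.character(ids)
  collection
}

#' Assemble the cross-experiment p-value matrix
#'
#' Stacks the `pValue` dimension of every experiment into an experiments ×
#' genes matrix over the union of all gene IDs (first-seen order). A gene
#' absent from an experiment is imputed with p = 1.0 — treated as maximally
#' non-significant — and flagged in `imputed_mask`. When `gene_subset` is
#' given the universe is intersected with it (union order preserved).
#'
#' @param collection a `de_collection`; every experiment must declare a
#'   numeric `pValue` dimension.
#' @param gene_subset optional character vector restricting the gene universe.
#' @param transform optional function applied to the assembled values (an
#'   experimentation hook; the default is to use raw p-values).
#' @return An object of class `pvalue_matrix`: list with `values` (numeric
#'   matrix, dimnames = experiment ids × gene ids) and `imputed_mask`
#'   (logical matrix of the same shape).
#' @export
assemble_pvalue_matrix <- function(collection, gene_subset = NULL, transform = NULL) {
  stopifnot(inherits(collection, "de_collection"))
  exps <- collection$experiments
  for (e in exps) {
    has_p <- "pValue" %in% e$dictionary$name &&
      dimension_kind(e$dictionary, "pValue") == "numeric"
    if (!has_p)
      abort(sprintf("experiment '%s' has no numeric pValue dimension", e$id),
            class = "descope_validation_error")
  }
  universe <- unique(unlist(lapply(exps, genes), use.names = FALSE))
  if (!is.null(gene_subset))
    universe <- universe[universe %in% gene_subset]
  if (length(universe) == 0L)
    abort("empty gene universe", class = "descope_validation_error")

  values <- matrix(1.0, nrow = length(exps), ncol = length(universe),
                   dimnames = list(names(exps), universe))
  imputed <- matrix(TRUE, nrow = length(exps), ncol = length(universe),
                    dimnames = list(names(exps), universe))
  for (i in seq_along(exps)) {
    idx <- match(genes(exps[[i]]), universe)
    keep <- !is.na(idx)
    values[i, idx[keep]] <- exps[[i]]$data$pValue[keep]
    imputed[i, idx[keep]] <- FALSE
  }
  # a present-but-missing pValue is treated like an absent gene
  na_cells <- is.na(values)
  if (any(na_cells)) {
    values[na_cells] <- 1.0
    imputed[na_cells] <- TRUE
  }
  if (!is.null(transform)) values <- transform(values)
  structure(list(values = values, imputed_mask = imputed),
            class = "pvalue_matrix")
}

#' @export
print.pvalue_matrix <- function(x, ...) {
  cat(sprintf("<pvalue_matrix> %d experiments x %d genes (%d imputed cells)\n",
              nrow(x$values), ncol(x$values), sum(x$imputed_mask)))
  invisible(x)
}
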