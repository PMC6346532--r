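#' Compute the experiment-similarity overview
#'
#' Projects experiments onto the first principal components of the
#' experiments × genes p-value matrix: experiments are the observations,
#' genes the variables. Columns are mean-centered but not scaled (p-values
#' already share the [0, 1] scale; unit-variance scaling would amplify
#' near-constant genes). Experiments with similar significance profiles land
#' close together. For small matrices (`min(dim) <= exact_threshold`) an
#' exact SVD is used; larger ones go through the seeded
#' [randomized_svd()]. Component signs are fixed so that the
#' largest-magnitude gene loading of each component is positive, and scores
#' are computed as the centered matrix times the loadings — so experiments
#' with identical p-value rows receive bit-identical coordinates.
#'
#' @param matrix a `pvalue_matrix` (from [assemble_pvalue_matrix()]) or a
#'   plain numeric matrix with experiment rownames; at least 2 experiments
#'   and 2 genes.
#' @param n_components number of components to report (default 2).
#' @param seed integer seed for the randomized decomposition.
#' @param exact_threshold use the exact decomposition when the smaller matrix
#'   dimension is at most this (default 25).
#' @return An `overview_coords` data frame with columns `id`, `pc1`, `pc2`,
#'   ... and attributes `explained_variance`, `n_genes_used`, `seed`.
#' @export
compute_overview <- function(matrix, n_components = 2L, seed = 1L,
                             exact_threshold = 25L) {
  x <- if (inherits(matrix, "pvalue_matrix")) matrix$values else matrix
  if (!is.matrix(x) || !is.numeric(x))
    abort("matrix must be numeric", class = "descope_validation_error")
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) abort("need at least 2 experiments", class = "descope_validation_error")
  if (p < 2L) abort("need at least 2 genes", class = "descope_validation_error")
  if (anyNA(x)) abort("matrix contains NA values", class = "descope_validation_error")

  xc <- sweep(x, 2L, colMeans(x), "-")
  total_ss <- sum(xc^2)
  if (total_ss == 0)
    abort("no variance: all experiments have identical p-value profiles",
          class = "descope_validation_error")

  n_components <- as.integer(n_components)
  k <- min(n_components, n - 1L, p)
  if (min(n, p) <= exact_threshold) {
    s <- svd(xc, nu = 0L, nv = k)
    v <- s$v[, seq_len(k), drop = FALSE]
    d <- s$d[seq_len(k)]
  } else {
    s <- randomized_svd(xc, k = k, seed = seed)
    v <- s$v
    d <- s$d
  }
  for (j in seq_len(k)) {
    m <- which.max(abs(v[, j]))
    if (v[m, j] < 0) v[, j] <- -v[, j]
  }
  scores <- xc %*% v
  # experiments with identical p-value profiles must get bit-identical
  # coordinates; BLAS summation order can differ by row position, so map
  # duplicate rows onto their first occurrence's scores
  key <- vapply(seq_len(n), function(i) paste(x[i, ], collapse = "\r"),
                character(1))
  scores <- scores[match(key, key), , drop = FALSE]
  if (k < n_components) {                       # rank-deficient: pad with zeros
    scores <- cbind(scores, matrix(0, n, n_components - k))
    d <- c(d, rep(0, n_components - k))
  }
  ev <- d[seq_len(n_components)]^2 / total_ss

  ids <- rownames(x) %||% paste0("experiment", seq_len(n))
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (j in seq_len(n_components)) out[[paste0("pc", j)]] <- scores[, j]
  structure(out, class = c("overview_coords", "data.frame"),
            explained_variance = ev, n_genes_used = p, seed = as.integer(seed))
}

#' Recompute the overview on a gene selection
#'
#' Restricts the p-value matrix to the selected genes and recomputes the
#' similarity map, so the overview reflects only the genes the user cares
#' about. Equivalent to composing [assemble_pvalue_matrix()] with
#' [compute_overview()].
#'
#' @param collection a `de_collection`.
#' @param selection a `selection_state` or character vector of gene IDs.
#' @param seed seed passed to [compute_overview()].
#' @param n_components see [compute_overview()].
#' @return An `overview_coords` data frame; its `n_genes_used` attribute is
#'   the size of the restricted universe.
#' @export
recompute_on_selection <- function(collection, selection, seed = 1L,
                                   n_components = 2L) {
  ids <- if (inherits(selection, "selection_state")) selection$selected
         else as.character(selection)
  if (length(ids) == 0L)
    abort("selection is empty", class = "descope_validation_error")
  m <- assemble_pvalue_matrix(collection, gene_subset = ids)
  compute_overview(m, n_components = n_components, seed = seed)
}

#' Experiments nearest to the focus on the overview
#'
#' Euclidean distance in the (pc1, pc2) plane, ascending; ties broken by id
#' lexicographically; the focus itself is excluded. `k` larger than the
#' number of other experiments is clamped.
#'
#' @param coords an `overview_coords` data frame.
#' @param focus_id id of the focus experiment.
#' @param k number of neighbours requested.
#' @return Data frame with columns `id` and `distance`, sorted.
#' @export
nearest_experiments <- function(coords, focus_id, k = 5L) {
  stopifnot(is.data.frame(coords))
  if (k < 1L) abort("k must be >= 1", class = "descope_validation_error")
  i <- match(focus_id, coords$id)
  if (is.na(i))
    abort(sprintf("no experiment '%s' in coordinates", focus_id),
          class = "descope_validation_error")
  d <- sqrt((coords$pc1 - coords$pc1[i])^2 + (coords$pc2 - coords$pc2[i])^2)
  others <- setdiff(seq_len(nrow(coords)), i)
  ord <- others[order(d[others], coords$id[others])]
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(id = coords$id[ord], distance = d[ord], stringsAsFactors = FALSE)
}
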