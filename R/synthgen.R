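#' Synthetic-collection configuration
#'
#' Describes a synthetic set of DE experiments with planted structure:
#' `n_clusters` groups of `experiments_per_cluster` experiments that share a
#' cluster-specific signature gene set (fraction `signature_fraction` of the
#' universe) whose fold changes are drawn around +/- `effect_size`, plus
#' `n_null_experiments` with no signal and Uniform(0,1) p-values. p-values
#' of cluster experiments come from a two-sided normal tail of the
#' standardized fold change, `z = (foldChange / noise_sd) * sqrt(pseudo_n)`
#' with `pseudo_n = 6`, mimicking a small-replicate DE test — so
#' experiments of the same cluster share their small-p genes. Each
#' experiment additionally drops a random `missing_fraction` of genes to
#' exercise union-plus-imputation code paths. The GO side plants
#' `enriched_term_fraction` of `n_terms` terms that draw at least 80% of
#' their genes from one cluster's signature.
#'
#' @param n_genes gene-universe size.
#' @param n_clusters,experiments_per_cluster,n_null_experiments collection layout.
#' @param effect_size mean absolute signature fold change (log2 units).
#' @param signature_fraction fraction of genes in each cluster signature.
#' @param noise_sd fold-change noise standard deviation.
#' @param missing_fraction fraction of genes dropped per experiment.
#' @param n_terms,term_size_range,enriched_term_fraction GO annotation layout.
#' @param pseudo_n pseudo sample size of the implied DE test.
#' @param seed integer seed fixing every draw.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_genes = 2000L, n_clusters = 3L,
                         experiments_per_cluster = 5L,
                         n_null_experiments = 3L, effect_size = 1.0,
                         signature_fraction = 0.1, noise_sd = 0.5,
                         missing_fraction = 0.02, n_terms = 50L,
                         term_size_range = c(10L, 50L),
                         enriched_term_fraction = 0.2, pseudo_n = 6,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_clusters = as.integer(n_clusters),
              experiments_per_cluster = as.integer(experiments_per_cluster),
              n_null_experiments = as.integer(n_null_experiments),
              effect_size = effect_size, signature_fraction = signature_fraction,
              noise_sd = noise_sd, missing_fraction = missing_fraction,
              n_terms = as.integer(n_terms),
              term_size_range = as.integer(term_size_range),
              enriched_term_fraction = enriched_term_fraction,
              pseudo_n = pseudo_n, seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 10L || n_clusters < 1L || experiments_per_cluster < 1L ||
        n_null_experiments < 0L || n_terms < 1L)
      abort("counts must be positive (n_genes >= 10)", class = "descope_validation_error")
    if (signature_fraction <= 0 || signature_fraction >= 1 ||
        enriched_term_fraction <= 0 || enriched_term_fraction >= 1 ||
        missing_fraction < 0 || missing_fraction >= 1)
      abort("fractions must lie in (0, 1)", class = "descope_validation_error")
    if (effect_size <= 0 || noise_sd <= 0 || pseudo_n <= 0)
      abort("effect_size, noise_sd and pseudo_n must be positive",
            class = "descope_validation_error")
    if (floor(signature_fraction * n_genes) < 1L)
      abort("signature_fraction * n_genes must be at least 1",
            class = "descope_validation_error")
    if (length(term_size_range) != 2L || term_size_range[1] < 1L ||
        term_size_range[1] > term_size_range[2] ||
        term_size_range[2] > n_genes)
      abort("term_size_range must satisfy 1 <= min <= max <= n_genes",
            class = "descope_validation_error")
  })
  structure(cfg, class = "synth_config")
}

synth_gene_ids <- function(n) sprintf("ENSG%011d", seq_len(n))

#' Generate a synthetic experiment collection
#'
#' Draws the collection described by a [synth_config()]: per cluster a fixed
#' signature (gene set plus per-gene effect direction), per experiment noisy
#' fold changes around that signature, p-values from the standardized
#' two-sided normal tail, BH-adjusted p-values, log-normal `baseMean` and a
#' `geneName` label. Null experiments carry pure-noise fold changes and
#' Uniform(0,1) p-values. Everything is a deterministic function of the
#' seed.
#'
#' @param config a `synth_config`.
#' @return List with `collection` (a `de_collection`, no focus set) and
#'   `truth`: cluster label per experiment (`NA` for nulls), the per-cluster
#'   `signatures` (gene ids, named by signed effect), and the seed.
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    universe <- synth_gene_ids(n)
    gene_names <- sprintf("Gene%04d", seq_len(n))
    n_sig <- max(1L, floor(config$signature_fraction * n))

    signatures <- lapply(seq_len(config$n_clusters), function(k) {
      idx <- sample.int(n, n_sig)
      list(genes = universe[idx], index = idx,
           sign = sample(c(-1, 1), n_sig, replace = TRUE))
    })
    names(signatures) <- paste0("cluster", seq_len(config$n_clusters))

    experiments <- list()
    labels <- character(0)
    mk_table <- function(fc, p) {
      base_mean <- stats::rlnorm(n, meanlog = log(500), sdlog = 1.5)
      keep <- rep(TRUE, n)
      n_drop <- floor(config$missing_fraction * n)
      if (n_drop > 0L) keep[sample.int(n, n_drop)] <- FALSE
      data.frame(EnsemblID = universe, geneName = gene_names,
                 baseMean = base_mean, foldChange = fc, pValue = p,
                 pAdj = stats::p.adjust(p, method = "BH"),
                 stringsAsFactors = FALSE)[keep, , drop = FALSE]
    }
    dict <- default_dictionary()

    # the observed fold change estimates the true effect with standard error
    # noise_sd / sqrt(pseudo_n); z = fc / se is the implied Wald statistic,
    # N(0, 1) for non-signature genes so their p-values are Uniform(0, 1)
    se <- config$noise_sd / sqrt(config$pseudo_n)
    for (k in seq_len(config$n_clusters)) {
      sig <- signatures[[k]]
      for (j in seq_len(config$experiments_per_cluster)) {
        fc <- stats::rnorm(n, 0, se)
        fc[sig$index] <- stats::rnorm(n_sig, sig$sign * config$effect_size, se)
        z <- fc / se
        p <- pmin(2 * stats::pnorm(-abs(z)), 1)
        id <- sprintf("cluster%d_rep%d", k, j)
        experiments[[id]] <- new_experiment(
          id, mk_table(fc, p), dict,
          title = sprintf("Synthetic cluster %d replicate %d", k, j),
          visibility = "public", icon = "box")
        labels[id] <- names(signatures)[k]
      }
    }
    for (j in seq_len(config$n_null_experiments)) {
      fc <- stats::rnorm(n, 0, se)
      p <- 2 * stats::pnorm(-abs(fc / se))   # z ~ N(0,1): Uniform(0,1) p-values
      id <- sprintf("null%d", j)
      experiments[[id]] <- new_experiment(
        id, mk_table(fc, p), dict,
        title = sprintf("Synthetic null experiment %d", j),
        visibility = "private", icon = letters[(j - 1L) %% 26L + 1L])
      labels[id] <- NA_character_
    }

    list(collection = build_collection(unname(experiments)),
         truth = list(cluster = labels, signatures = signatures,
                      seed = config$seed))
  })
}

#' Invert the comparison direction of an experiment
#'
#' Models the same contrast run the other way around (condition A vs B
#' instead of B vs A): every fold change flips sign while p-values,
#' baseMean and the gene set are untouched. Because the similarity map is
#' computed on p-values only, an experiment and its inverted twin land on
#' identical overview coordinates — while every GO plot shows the mirrored
#' regulation pattern.
#'
#' @param experiment a `de_experiment` with `foldChange` and `pValue`.
#' @param suffix id/title suffix for the twin.
#' @return The inverted `de_experiment`.
#' @export
invert_experiment <- function(experiment, suffix = "_inv") {
  stopifnot(inherits(experiment, "de_experiment"))
  for (d in c("foldChange", "pValue"))
    if (!d %in% experiment$dictionary$name)
      abort(sprintf("experiment '%s' lacks dimension '%s'", experiment$id, d),
            class = "descope_validation_error")
  data <- experiment$data
  data$foldChange <- -data$foldChange
  new_experiment(paste0(experiment$id, suffix), data, experiment$dictionary,
                 title = paste0(experiment$title, " (opposite direction)"),
                 visibility = experiment$visibility, icon = experiment$icon)
}

#' Generate a synthetic GO annotation with planted enrichment
#'
#' Plants `enriched_term_fraction` of the terms on the clusters (round
#' robin): an enriched term draws at least 80% of its genes from the
#' matching cluster's signature and the rest from the background; all other
#' terms sample uniformly from the whole universe. Term sizes are uniform
#' in `term_size_range`.
#'
#' @param config a `synth_config`.
#' @param truth the `truth` component returned by [generate_collection()]
#'   (provides the cluster signatures).
#' @return List with `annotation` (a `go_annotation`) and `term_cluster`
#'   (named character vector: term id -> enriched cluster label, `NA` for
#'   background terms).
#' @export
generate_go_annotation <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(truth$signatures))
    abort("truth must carry the cluster signatures", class = "descope_validation_error")
  with_seed(config$seed + 1L, {
    universe <- synth_gene_ids(config$n_genes)
    n_enriched <- max(1L, round(config$enriched_term_fraction * config$n_terms))
    clusters <- names(truth$signatures)
    term_ids <- sprintf("GO:%07d", seq_len(config$n_terms))

    term_cluster <- rep(NA_character_, config$n_terms)
    term_cluster[seq_len(n_enriched)] <-
      clusters[(seq_len(n_enriched) - 1L) %% length(clusters) + 1L]

    term_genes <- vector("list", config$n_terms)
    sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                    config$n_terms, replace = TRUE)
    for (i in seq_len(config$n_terms)) {
      size <- sizes[i]
      if (is.na(term_cluster[i])) {
        term_genes[[i]] <- sample(universe, size)
      } else {
        sig <- truth$signatures[[term_cluster[i]]]$genes
        n_from_sig <- min(length(sig), ceiling(stats::runif(1, 0.8, 1) * size))
        rest <- setdiff(universe, sig)
        term_genes[[i]] <- c(sample(sig, n_from_sig),
                             sample(rest, size - n_from_sig))
      }
    }
    names(term_genes) <- term_ids
    meta <- data.frame(
      term_id = term_ids,
      term_name = ifelse(is.na(term_cluster),
                         sprintf("synthetic background process %d", seq_along(term_ids)),
                         sprintf("synthetic %s process %d", term_cluster,
                                 seq_along(term_ids))),
      term_definition = "synthetic gene set", stringsAsFactors = FALSE)
    list(annotation = go_annotation(meta, term_genes),
         term_cluster = stats::setNames(term_cluster, term_ids))
  })
}

#' Write a GO annotation as flat TSV
#'
#' One gene-term pair per row, readable by [load_go_annotation()].
#'
#' @param annotation a `go_annotation`.
#' @param path output path.
#' @export
write_go_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "go_annotation"))
  meta <- annotation$terms
  rows <- unlist(lapply(seq_len(nrow(meta)), function(i) {
    g <- annotation$term_genes[[meta$term_id[i]]]
    paste(meta$term_id[i], meta$term_name[i], meta$term_definition[i], g,
          sep = "\t")
  }))
  writeLines(c("term_id\tterm_name\tterm_definition\tgene_id", rows), path)
  invisible(path)
}
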