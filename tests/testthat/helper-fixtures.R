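# fixture builders and independent oracles shared across test files

tiny_dictionary <- function() {
  data_dictionary(data.frame(
    name = c("EnsemblID", "geneName", "baseMean", "foldChange", "pValue"),
    kind = c("identifier", "categorical", "numeric", "numeric", "numeric")))
}

tiny_experiment <- function(id = "exp1", p = c(0.001, 0.004, 0.005, 0.5),
                            fc = NULL, visibility = "private") {
  n <- length(p)
  fc <- fc %||% seq(-1, 1, length.out = n)
  new_experiment(id, data.frame(
    EnsemblID = sprintf("ENSG%011d", seq_len(n)),
    geneName = sprintf("Gene%d", seq_len(n)),
    baseMean = 100 * seq_len(n),
    foldChange = fc,
    pValue = p), tiny_dictionary(), visibility = visibility)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_experiment <- function(id, n = 50, genes = NULL, na_frac = 0) {
  genes <- genes %||% sprintf("ENSG%011d", sample.int(10 * n, n))
  d <- data.frame(EnsemblID = genes,
                  geneName = sample(c(sprintf("Sym%d", 1:20), "Soat1"), n, TRUE),
                  baseMean = rlnorm(n, 5, 1),
                  foldChange = rnorm(n),
                  pValue = runif(n))
  if (na_frac > 0)
    for (col in c("baseMean", "foldChange", "pValue")) {
      hit <- runif(n) < na_frac
      d[[col]][hit] <- NA
    }
  new_experiment(id, d, tiny_dictionary())
}

# exact PCA oracle: centered SVD scores with the same sign convention
exact_pca_scores <- function(x, k = 2) {
  xc <- sweep(x, 2, colMeans(x), "-")
  s <- svd(xc, nu = 0, nv = k)
  v <- s$v
  for (j in seq_len(k)) {
    m <- which.max(abs(v[, j]))
    if (v[m, j] < 0) v[, j] <- -v[, j]
  }
  xc %*% v
}

# per-component sign alignment before comparing two score matrices
align_signs <- function(a, b) {
  for (j in seq_len(ncol(a)))
    if (sum(a[, j] * b[, j]) < 0) a[, j] <- -a[, j]
  a
}

# structured random p-value matrix: planted similarity clusters + uniform noise
random_pvalue_matrix <- function(n_exp, n_genes, n_clusters = 3) {
  p <- matrix(runif(n_exp * n_genes), n_exp, n_genes,
              dimnames = list(sprintf("e%02d", seq_len(n_exp)),
                              sprintf("g%05d", seq_len(n_genes))))
  sig_size <- max(2L, round(0.1 * n_genes))
  members <- split(seq_len(n_exp),
                   rep_len(seq_len(n_clusters), n_exp))
  for (k in seq_len(n_clusters)) {
    sig <- sample.int(n_genes, sig_size)
    for (i in members[[k]]) p[i, sig] <- runif(sig_size, 0, 1e-4)
  }
  p
}

# linear-scan filter oracle: evaluates a clause chain gene by gene
oracle_filter <- function(experiment, clauses) {
  d <- experiment$data
  dict <- experiment$dictionary
  pass <- vapply(seq_len(nrow(d)), function(i) {
    for (cl in clauses) {
      v <- d[[cl$dimension]][i]
      kind <- dict$kind[match(cl$dimension, dict$name)]
      if (is.na(v)) return(FALSE)
      ok <- if (kind == "numeric") {
        o <- as.numeric(cl$operand)
        switch(cl$op, lt = v < o, gt = v > o, eq = v == o)
      } else {
        cl$op == "eq" && grepl(tolower(cl$operand), tolower(v), fixed = TRUE)
      }
      if (!ok) return(FALSE)
    }
    TRUE
  }, logical(1))
  d$EnsemblID[pass]
}

# brute-force nearest-centre oracle over an exhaustive candidate lattice
oracle_hex_assign <- function(x, y, x0, y0, r) {
  dx <- 1.5 * r; dy <- sqrt(3) * r
  qs <- seq(floor(min(x - x0) / dx) - 2, ceiling(max(x - x0) / dx) + 2)
  ps <- seq(floor(min(y - y0) / dy) - 2, ceiling(max(y - y0) / dy) + 2)
  grid <- expand.grid(q = qs, p = ps)
  cx <- x0 + dx * grid$q
  cy <- y0 + dy * grid$p + (grid$q %% 2) * dy / 2
  t(vapply(seq_along(x), function(i) {
    d2 <- (x[i] - cx)^2 + (y[i] - cy)^2
    best <- which(d2 <= min(d2) + 1e-12 * r^2)
    best <- best[order(grid$q[best], grid$p[best])][1]
    c(q = grid$q[best], p = grid$p[best])
  }, numeric(2)))
}

# brute-force GO scan oracle: per-term intersection, filter, sort
oracle_scan <- function(annotation, selection, min_size, max_size) {
  sel <- unique(selection)
  rows <- lapply(names(annotation$term_genes), function(t) {
    g <- annotation$term_genes[[t]]
    n_sel <- length(intersect(g, sel))
    if (n_sel < 1 || length(g) < min_size || length(g) > max_size) return(NULL)
    data.frame(term_id = t, term_size = length(g), n_selected = n_sel,
               coverage_pct = 100 * n_sel / length(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out <- out[order(-out$coverage_pct, out$term_size, out$term_id), ]
  rownames(out) <- NULL
  out
}

random_go_annotation <- function(n_terms = 20, n_genes = 100) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  tg <- lapply(seq_len(n_terms), function(i)
    sample(genes, sample(2:20, 1)))
  names(tg) <- sprintf("GO:%07d", seq_len(n_terms))
  go_annotation(NULL, tg)
}
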