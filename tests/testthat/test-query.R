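test_that("the p-value filter uses strict comparison at the boundary", {
  e <- tiny_experiment("f", p = c(0.001, 0.004, 0.005, 0.5))
  sel <- apply_filters(e, parse_clause("pValue<0.005"))
  expect_equal(sel$selected, genes(e)[1:2])   # 0.005 itself excluded
})

test_that("clause semantics: empty chain, eq, categorical containment, missing", {
  e <- tiny_experiment("f")
  expect_equal(apply_filters(e, list())$selected, genes(e))

  expect_equal(apply_filters(e, filter_clause("baseMean", "=", 200))$selected,
               genes(e)[2])
  # categorical "=" is case-insensitive substring containment
  expect_equal(apply_filters(e, filter_clause("geneName", "=", "gene1"))$selected,
               genes(e)[1])
  expect_error(apply_filters(e, filter_clause("geneName", "<", "x")),
               "only '='", class = "descope_validation_error")
  expect_error(apply_filters(e, filter_clause("nope", "<", 1)),
               "nope", class = "descope_validation_error")

  # a missing value fails every clause on that dimension, including eq
  d <- e$data; d$pValue[1] <- NA
  e2 <- new_experiment("f2", d, e$dictionary)
  expect_false(genes(e2)[1] %in%
                 apply_filters(e2, filter_clause("pValue", "<", 0.9))$selected)
  expect_false(genes(e2)[1] %in%
                 apply_filters(e2, filter_clause("pValue", "=", 0.001))$selected)
})

test_that("filter engine matches the linear-scan oracle on random chains", {
  set.seed(121)
  dims <- c("baseMean", "foldChange", "pValue", "geneName")
  for (trial in 1:50) {
    e <- random_experiment("r", n = 100, na_frac = 0.1)
    clauses <- lapply(seq_len(sample(1:4, 1)), function(i) {
      dim <- sample(dims, 1)
      if (dim == "geneName") filter_clause(dim, "eq", sample(c("sym", "Soat1", "1"), 1))
      else filter_clause(dim, sample(c("lt", "gt", "eq"), 1),
                         round(runif(1, -1, 1), 2))
    })
    got <- apply_filters(e, clauses)$selected
    expect_identical(got, oracle_filter(e, clauses))
    # commutativity and AND-monotonicity
    expect_identical(apply_filters(e, rev(clauses))$selected, got)
    expect_true(all(got %in% apply_filters(e, clauses[-1])$selected))
  }
})

test_that("brushing selects closed-rectangle containment in transformed space", {
  e <- tiny_experiment("b", p = c(0.001, 0.01, 0.1, 1))
  v <- default_view(e)   # volcano: x foldChange linear, y -log10 pValue
  rect <- brush_rect("foldChange", "pValue", x_range = c(-2, 2),
                     y_range = c(1, 3), transform_y = "-log10")
  sel <- apply_brush(e, v, rect)
  # -log10 p: 3, 2, 1, 0 — the closed [1, 3] interval keeps the first three
  expect_equal(sel$selected, genes(e)[1:3])
  expect_equal(sel$view$x_range, c(-2, 2))    # default zooms into the rect
  sel2 <- apply_brush(e, v, rect, zoom = FALSE)
  expect_equal(sel2$view$x_range, v$x_range)

  wrong <- brush_rect("baseMean", "pValue", c(0, 1), c(0, 1))
  expect_error(apply_brush(e, v, wrong), "do not match",
               class = "descope_validation_error")
})

test_that("brush matches point-in-box oracle; out-of-domain genes never selected", {
  set.seed(131)
  for (trial in 1:20) {
    n <- 100
    d <- data.frame(EnsemblID = sprintf("g%03d", 1:n),
                    geneName = "x", baseMean = rlnorm(n),
                    foldChange = rnorm(n),
                    pValue = c(0, runif(n - 1)))   # p = 0 is out of -log10 domain
    e <- new_experiment("bb", d, tiny_dictionary())
    v <- default_view(e)
    rect <- brush_rect("foldChange", "pValue",
                       x_range = sort(rnorm(2)), y_range = sort(runif(2, 0, 3)),
                       transform_y = "-log10")
    got <- apply_brush(e, v, rect, zoom = FALSE)$selected
    ref <- d$EnsemblID[d$pValue > 0 &
                         d$foldChange >= rect$x_range[1] &
                         d$foldChange <= rect$x_range[2] &
                         -log10(d$pValue) >= rect$y_range[1] &
                         -log10(d$pValue) <= rect$y_range[2]]
    expect_identical(got, ref)
    expect_false("g001" %in% got)
  }
})

test_that("filter-then-brush equals brush-then-filter", {
  set.seed(141)
  e <- random_experiment("fb", n = 200)
  v <- default_view(e)
  cl <- filter_clause("foldChange", "gt", 0)
  rect <- brush_rect("foldChange", "pValue", c(-1, 2), c(0.5, 3),
                     transform_y = "-log10")
  a <- apply_brush(e, v, rect, zoom = FALSE,
                   selection = apply_filters(e, cl))$selected
  b <- apply_filters(e, cl,
                     selection = apply_brush(e, v, rect, zoom = FALSE))$selected
  expect_identical(a, b)
})

test_that("link_selection intersects with the other experiment's universe", {
  set.seed(151)
  shared <- sprintf("ENSG%011d", 1:30)
  a <- random_experiment("a", n = 30, genes = shared)
  b <- random_experiment("b", n = 20, genes = shared[11:30])
  none <- random_experiment("c", n = 10,
                            genes = sprintf("ENSGX%010d", 1:10))
  sel <- apply_filters(a, list())
  expect_identical(link_selection(sel, a), genes(a))
  expect_identical(link_selection(sel, b), shared[11:30])
  expect_identical(link_selection(sel, none), character(0))
  expect_identical(link_selection(sel, b),
                   intersect(sel$selected, genes(b)))
})

test_that("highlighting is membership-checked, reversible, selection-neutral", {
  e <- tiny_experiment("h")
  sel <- apply_filters(e, filter_clause("pValue", "<", 0.01))
  h <- highlight_gene(sel, genes(e)[1])
  expect_equal(h$highlighted, genes(e)[1])
  expect_identical(h$selected, sel$selected)
  expect_identical(clear_highlight(h), sel)
  expect_error(highlight_gene(sel, "ENSGnope"), "not in the focus",
               class = "descope_validation_error")

  # propagation: context with the gene sees the highlight, one without does not
  ctx_with <- tiny_experiment("cw")
  ctx_without <- new_experiment("co", {
    d <- tiny_experiment("tmp")$data; d$EnsemblID <- paste0("X", d$EnsemblID); d
  }, tiny_dictionary())
  sm1 <- small_multiple_view(ctx_with, default_view(e), h)
  sm2 <- small_multiple_view(ctx_without, default_view(e), h)
  expect_equal(sm1$highlighted, genes(e)[1])
  expect_null(sm2$highlighted)
})
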