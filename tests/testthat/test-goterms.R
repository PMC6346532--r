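test_that("annotation loading builds an exact inverse index and dedups", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term_id\tterm_name\tterm_definition\tgene_id",
               "GO:1\tproc A\tdef A\tg1",
               "GO:1\tproc A\tdef A\tg2",
               "GO:1\tproc A\tdef A\tg2",     # duplicate pair
               "GO:2\tproc B\tdef B\tg2",
               "GO:2\tproc B\tdef B\tg3"), path)
  ann <- load_go_annotation(path)
  expect_equal(ann$terms$size, c(2L, 2L))
  expect_equal(ann$term_genes[["GO:1"]], c("g1", "g2"))
  expect_equal(ann$gene_index[["g2"]], c("GO:1", "GO:2"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term_id\tterm_name\tterm_definition\tgene_id",
               "GO:1\tA\td\tg1", "GO:2\tonly three fields"), bad)
  expect_error(load_go_annotation(bad), "line", class = "descope_parse_error")
})

test_that("gene index inverts term membership on random annotations", {
  set.seed(191)
  for (trial in 1:10) {
    ann <- random_go_annotation()
    # brute-force rebuild of the inverse index
    ref <- list()
    for (t in names(ann$term_genes))
      for (g in ann$term_genes[[t]]) ref[[g]] <- c(ref[[g]], t)
    ref <- lapply(ref, sort)
    expect_identical(ann$gene_index[sort(names(ann$gene_index))],
                     ref[sort(names(ref))])
  }
})

test_that("GAF input yields the same gene-term pairs as flat TSV", {
  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.2",
               "DB\tDB1\tSoat1\t\tGO:0000001\tREF\tIEA",
               "DB\tDB2\tAbca1\t\tGO:0000001\tREF\tIEA",
               "DB\tDB2\tAbca1\tNOT\tGO:0000002\tREF\tIEA"), gaf)
  ann <- load_go_annotation(gaf)
  expect_equal(sort(ann$term_genes[["GO:0000001"]]), c("Abca1", "Soat1"))
  expect_equal(ann$term_genes[["GO:0000002"]], "Abca1")
})

test_that("scan_terms ranks full-coverage terms first and applies size bounds", {
  tg <- list("GO:A" = sprintf("g%d", 1:10),
             "GO:B" = sprintf("g%d", 1:3),
             "GO:C" = sprintf("g%d", 8:20))
  ann <- go_annotation(NULL, tg)
  sel <- sprintf("g%d", 1:10)
  sc <- scan_terms(ann, sel)
  expect_equal(sc$term_id[1:2], c("GO:B", "GO:A"))   # both 100%, smaller first
  expect_equal(sc$coverage_pct[1:2], c(100, 100))
  # a size-3 term is excluded by min_size = 5
  sc5 <- scan_terms(ann, sel, min_size = 5)
  expect_false("GO:B" %in% sc5$term_id)
  sc_max <- scan_terms(ann, sel, max_size = 10)
  expect_false("GO:C" %in% sc_max$term_id)
  expect_error(scan_terms(ann, character(0)), "empty",
               class = "descope_validation_error")
})

test_that("scan_terms matches the brute-force oracle on random inputs", {
  set.seed(201)
  for (trial in 1:30) {
    ann <- random_go_annotation()
    sel <- sample(sprintf("g%04d", 1:100), sample(5:40, 1))
    bounds <- sort(sample(1:20, 2))
    got <- scan_terms(ann, sel, min_size = bounds[1], max_size = bounds[2])
    ref <- oracle_scan(ann, sel, bounds[1], bounds[2])
    if (is.null(ref)) expect_equal(nrow(got), 0L)
    else expect_identical(as.data.frame(got)[, names(ref)], ref)
    # invariance to selection representation (duplicates, order)
    got2 <- scan_terms(ann, sample(rep(sel, 2)), bounds[1], bounds[2])
    expect_identical(got2, got)
  }
})

test_that("coverage favours small terms: nested terms never rank worse", {
  set.seed(211)
  genes <- sprintf("g%04d", 1:100)
  for (trial in 1:20) {
    inner <- sample(genes, 10)
    outer <- unique(c(inner, sample(genes, 20)))
    sel <- unique(c(sample(inner, 5), sample(genes, 10)))
    ann <- go_annotation(NULL, list("GO:inner" = inner, "GO:outer" = outer))
    sc <- scan_terms(ann, sel)
    if (all(c("GO:inner", "GO:outer") %in% sc$term_id)) {
      ci <- sc$coverage_pct[sc$term_id == "GO:inner"]
      co <- sc$coverage_pct[sc$term_id == "GO:outer"]
      ni <- sc$n_selected[sc$term_id == "GO:inner"]
      no <- sc$n_selected[sc$term_id == "GO:outer"]
      if (ni == no) {
        expect_gte(ci, co)
        expect_lte(match("GO:inner", sc$term_id), match("GO:outer", sc$term_id))
      }
    }
  }
})

test_that("GO plot entries are value-ordered, colour-anchored and width-scaled", {
  e <- tiny_experiment("g", p = rep(0.01, 4), fc = c(2, -2, 0, 1))
  ann <- go_annotation(NULL, list(
    "GO:X" = genes(e)[1:3],
    "GO:Y" = c(genes(e)[1:2], "ENSGabsent"),
    "GO:Z" = genes(e)[3]))
  sel <- genes(e)

  pm <- go_plot_data(ann, "GO:X", e, sel, limits = c(-2, 2))
  expect_equal(pm$entries$gene, genes(e)[c(1, 3, 2)])   # fc 2, 0, -2
  expect_equal(unname(unlist(pm$entries[1, c("r", "g", "b")])), c(255L, 0L, 0L))
  expect_equal(unname(unlist(pm$entries[2, c("r", "g", "b")])), c(255L, 255L, 255L))
  expect_equal(unname(unlist(pm$entries[3, c("r", "g", "b")])), c(0L, 0L, 255L))

  # genes all at the white point (fc = 0 = mid) give an all-white plot
  mid <- go_plot_data(ann, "GO:Z", e, sel, limits = c(-2, 2))
  expect_true(all(mid$entries$value == 0))
  expect_equal(unname(unlist(mid$entries[1, c("r", "g", "b")])),
               c(255L, 255L, 255L))
  # default limits are symmetric about 0 (all-zero entries fall back to 1)
  mid_auto <- go_plot_data(ann, "GO:Z", e, sel)
  expect_equal(mid_auto$limits, c(-1, 1))

  # a gene missing from the experiment gets the missing colour, no value
  pmy <- go_plot_data(ann, "GO:Y", e, sel, all_genes = TRUE, limits = c(-2, 2))
  miss <- pmy$entries[pmy$entries$missing, ]
  expect_equal(miss$gene, "ENSGabsent")
  expect_true(is.na(miss$value))
  expect_equal(miss$color, "#c8c8c8")

  # empty selection intersection gives an empty model
  none <- go_plot_data(ann, "GO:Z", e, selection = genes(e)[1:2])
  expect_equal(none$width_units, 0L)
  expect_equal(nrow(none$entries), 0L)
  expect_error(go_plot_data(ann, "GO:nope", e, sel), "unknown",
               class = "descope_validation_error")

  # shared width scale: widest term exactly 1, others proportional
  models <- go_plot_models(ann, c("GO:X", "GO:Z"), e, sel, limits = c(-2, 2))
  expect_equal(models[["GO:X"]]$width_fraction, 1)
  expect_equal(models[["GO:Z"]]$width_fraction, 1 / 3)
})
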