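test_that("axis transforms mask out-of-domain values and negate correctly", {
  t <- transform_values(c(0.01, 1, 0, -2, NA), "-log10")
  expect_equal(t$values[1], 2)
  expect_equal(t$values[2], 0)
  expect_equal(t$in_domain, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(is.na(t$values[!t$in_domain])))

  x <- c(-3.5, 0, 4)
  expect_equal(transform_values(x, "linear")$values, x)
  expect_equal(transform_values(x, "-linear")$values, -x)
  expect_equal(transform_values(4, "log2")$values, 2)
  expect_equal(transform_values(4, "-sqrt")$values, -2)
  expect_equal(transform_values(0, "sqrt")$in_domain, TRUE)  # sqrt domain is x >= 0
  expect_error(transform_values(1, "cubert"), "unknown",
               class = "descope_validation_error")

  # mask bookkeeping equals a per-element oracle on random input
  set.seed(161)
  v <- c(rnorm(200), rep(0, 5), NA, Inf)
  for (tr in c("linear", "-linear", "log2", "-log2", "log10", "-log10",
               "sqrt", "-sqrt")) {
    t <- transform_values(v, tr)
    base <- sub("^-", "", tr)
    ref <- is.finite(v) & switch(base, linear = TRUE, sqrt = v >= 0, v > 0)
    expect_identical(t$in_domain, ref)
    expect_equal(sum(t$in_domain) + sum(!t$in_domain), length(v))
  }
})

test_that("hexbin conserves counts and assigns nearest centres", {
  g1 <- hexbin(data.frame(x = 1, y = 2), radius = 0.5)
  expect_equal(nrow(g1$centers), 1L)
  expect_equal(g1$centers$count, 1L)
  expect_equal(nrow(hexbin(data.frame(x = numeric(0), y = numeric(0)), 1)$centers), 0L)
  expect_error(hexbin(data.frame(x = 1, y = 1), -1), "positive",
               class = "descope_validation_error")

  set.seed(171)
  for (trial in 1:10) {
    n <- 300
    pts <- data.frame(x = runif(n, -5, 5), y = rnorm(n), id = sprintf("p%03d", 1:n))
    r <- runif(1, 0.2, 1.5)
    g <- hexbin(pts, r)
    expect_equal(sum(g$centers$count), n)
    expect_true(all(g$centers$count > 0))
    ref <- oracle_hex_assign(pts$x, pts$y, min(pts$x), min(pts$y), r)
    expect_equal(g$centers$q[g$assignment], unname(ref[, "q"]))
    expect_equal(g$centers$p[g$assignment], unname(ref[, "p"]))
  }
})

test_that("render_mode applies the strict below-threshold rule", {
  expect_equal(render_mode(4999), "dots")
  expect_equal(render_mode(5000), "hex")
  expect_equal(render_mode(50000, force_dots = TRUE), "dots")
  expect_equal(render_mode(50000, any_selection_active = TRUE), "dots")
  expect_equal(render_mode(100, dot_threshold = 50), "hex")
  expect_error(render_mode(-1), "non-negative", class = "descope_validation_error")
})

test_that("axis swap walks dimensions as a two-click state machine", {
  e <- tiny_experiment("v")
  v <- default_view(e)
  expect_equal(c(v$x_dim, v$y_dim), c("foldChange", "pValue"))
  expect_equal(v$transform_y, "-log10")

  v2 <- swap_axis(v, "baseMean")
  expect_equal(c(v2$x_dim, v2$y_dim), c("baseMean", "foldChange"))
  expect_equal(v2$transform_x, "linear")     # never used before -> linear
  expect_equal(v2$transform_y, "linear")     # foldChange keeps its transform

  expect_identical(swap_axis(v, "foldChange"), v)     # current x: no-op
  expect_error(swap_axis(v, "geneName"), "categorical",
               class = "descope_validation_error")

  # involution: swapping y then the old x restores the original pair
  v3 <- swap_axis(swap_axis(v, "pValue"), "foldChange")
  expect_equal(c(v3$x_dim, v3$y_dim), c(v$x_dim, v$y_dim))
  expect_equal(v3$transform_y, v$transform_y)

  # two successive clicks A then B -> x = B, y = A
  v4 <- swap_axis(swap_axis(v, "baseMean"), "pValue")
  expect_equal(c(v4$x_dim, v4$y_dim), c("pValue", "baseMean"))
})

test_that("transforms persist per dimension across swaps", {
  e <- tiny_experiment("v")
  v <- set_transform(swap_axis(default_view(e), "baseMean"), "x", "log10")
  # baseMean remembered as log10 when it comes back to an axis later
  v <- swap_axis(v, "pValue")      # x=pValue, y=baseMean(log10)
  expect_equal(v$transform_y, "log10")
  expect_equal(v$transform_x, "-log10")  # pValue remembered from the volcano
})

test_that("diverging colours anchor exactly and interpolate monotonically", {
  expect_equal(unname(diverging_color(0, -2, high = 2)[1, ]), c(255L, 255L, 255L))
  expect_equal(unname(diverging_color(-5, -2, high = 2)[1, ]), c(0L, 0L, 255L))
  expect_equal(unname(diverging_color(7, -2, high = 2)[1, ]), c(255L, 0L, 0L))
  expect_error(diverging_color(0, 2, high = -2), "low < high",
               class = "descope_validation_error")
  expect_error(diverging_color(0, -1, mid = 5, high = 1), "mid",
               class = "descope_validation_error")

  sweep <- seq(-2, 2, length.out = 101)
  m <- diverging_color(sweep, -2, high = 2)
  expect_true(all(diff(m[, "r"]) >= 0))
  expect_true(all(diff(m[, "b"]) <= 0))
  # per-point interpolation oracle
  for (i in seq_along(sweep)) {
    v <- sweep[i]
    ref <- if (v <= 0) c(round(255 * (v + 2) / 2), round(255 * (v + 2) / 2), 255)
           else c(255, round(255 * (1 - v / 2)), round(255 * (1 - v / 2)))
    expect_equal(unname(m[i, ]), as.integer(ref))
  }
})

test_that("small multiples copy focus axes and full range, never zoomed", {
  set.seed(181)
  shared <- sprintf("ENSG%011d", 1:40)
  focus <- random_experiment("f", n = 40, genes = shared)
  ctx <- random_experiment("c", n = 30, genes = shared[1:30])
  fv <- default_view(focus)
  fv$x_range <- c(-0.1, 0.1)   # focus plot has zoomed in

  sel <- apply_filters(focus, filter_clause("foldChange", "gt", 0))
  sm <- small_multiple_view(ctx, fv, sel)
  expect_equal(sm$view$x_dim, fv$x_dim)
  expect_equal(sm$view$transform_y, fv$transform_y)
  expect_equal(sm$view$x_range, fv$full_x_range)   # not the zoomed range
  expect_true(sm$view$zoom_locked)
  expect_identical(sm$highlight, link_selection(sel, ctx))
  expect_error(apply_brush(ctx, sm$view,
                           brush_rect(fv$x_dim, fv$y_dim, c(0, 1), c(0, 1),
                                      transform_y = fv$transform_y)),
               "disabled", class = "descope_validation_error")

  expect_identical(small_multiple_view(ctx, fv, NULL)$highlight, character(0))
  dict <- data_dictionary(data.frame(name = c("EnsemblID", "stat"),
                                     kind = c("identifier", "numeric")))
  bare <- new_experiment("bare", data.frame(EnsemblID = "g", stat = 1), dict)
  expect_error(small_multiple_view(bare, fv), "foldChange",
               class = "descope_validation_error")
})

test_that("hexbin_view drops out-of-domain genes and defaults radius to range/30", {
  e <- tiny_experiment("hv", p = c(0, 0.01, 0.1, 1))   # p = 0 dropped by -log10
  v <- default_view(e)
  g <- hexbin_view(e, v)
  expect_equal(length(g$assignment), 3L)
  expect_equal(sum(g$centers$count), 3L)
  expect_equal(g$radius, diff(v$x_range) / 30)
  expect_setequal(names(g$assignment), genes(e)[2:4])
})
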