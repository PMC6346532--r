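#' Axis transforms
#'
#' The eight scatter-plot axis transforms: `linear`, `-linear`, `log2`,
#' `-log2`, `log10`, `-log10`, `sqrt`, `-sqrt`. A leading `-` negates the
#' base transform (so the volcano plot's y-axis is `-log10` of the p-value).
#' Values outside a transform's domain (x <= 0 for logs, x < 0 for square
#' roots, and non-finite input for all) are masked out — dropped from plots
#' and from brush eligibility — never clipped.
#'
#' @param values numeric vector.
#' @param transform transform name.
#' @return List with `values` (transformed, `NA` where masked) and
#'   `in_domain` (logical mask).
#' @examples
#' transform_values(c(0.01, 1, 0), "-log10")  # 0 is out of domain
#' @export
transform_values <- function(values, transform) {
  check_transform(transform)
  values <- as.numeric(values)
  neg <- startsWith(transform, "-")
  base <- sub("^-", "", transform)
  in_domain <- is.finite(values) & switch(base,
    linear = TRUE,
    log2   = values > 0,
    log10  = values > 0,
    sqrt   = values >= 0)
  out <- rep(NA_real_, length(values))
  v <- values[in_domain]
  out[in_domain] <- switch(base,
    linear = v, log2 = log2(v), log10 = log10(v), sqrt = sqrt(v))
  if (neg) out <- -out
  list(values = out, in_domain = in_domain)
}

axis_transforms <- c("linear", "-linear", "log2", "-log2",
                     "log10", "-log10", "sqrt", "-sqrt")

check_transform <- function(transform) {
  if (!is_string(transform) || !transform %in% axis_transforms)
    abort(sprintf("unknown axis transform '%s' (use one of: %s)",
                  paste(transform, collapse = ","),
                  paste(axis_transforms, collapse = ", ")),
          class = "descope_validation_error")
  invisible(transform)
}

#' Choose the rendering mode for a plot
#'
#' Genes are drawn as individual dots when the user forces dots, when a
#' selection made in another view must be shown in context, or when the
#' number of genes to render is strictly below the dot threshold; otherwise
#' the view falls back to hexagonal binning to avoid over-plotting.
#'
#' @param n_to_render number of genes the view would draw (>= 0).
#' @param any_selection_active is a selection active in any linked view?
#' @param force_dots user override from the plot options.
#' @param dot_threshold the cut-off (default 5000).
#' @return `"dots"` or `"hex"`.
#' @examples
#' render_mode(4999)  # "dots"
#' render_mode(5000)  # "hex"
#' @export
render_mode <- function(n_to_render, any_selection_active = FALSE,
                        force_dots = FALSE, dot_threshold = 5000L) {
  if (!is.numeric(n_to_render) || length(n_to_render) != 1L || n_to_render < 0)
    abort("n_to_render must be a single non-negative number",
          class = "descope_validation_error")
  if (isTRUE(force_dots) || isTRUE(any_selection_active) ||
      n_to_render < dot_threshold) "dots" else "hex"
}

#' Diverging blue-white-red colour mapping
#'
#' Piecewise-linear interpolation from blue (0,0,255) at `low` through white
#' (255,255,255) at `mid` to red (255,0,0) at `high`; values outside
#' [`low`, `high`] are clamped. Used for the GO plot's gene rectangles,
#' where fold change maps naturally with `mid = 0`.
#'
#' @param value numeric vector.
#' @param low,high colour-scale limits, `low < high`.
#' @param mid the white point; defaults to the interval midpoint.
#' @return Integer matrix with columns `r`, `g`, `b` in 0..255.
#' @export
diverging_color <- function(value, low, mid = (low + high) / 2, high) {
  if (!is.finite(low) || !is.finite(high) || low >= high)
    abort("colour limits must satisfy low < high", class = "descope_validation_error")
  if (!is.finite(mid) || mid < low || mid > high)
    abort("mid must lie inside [low, high]", class = "descope_validation_error")
  v <- pmin(pmax(as.numeric(value), low), high)
  n <- length(v)
  rgb <- matrix(255L, n, 3L, dimnames = list(NULL, c("r", "g", "b")))
  lo <- !is.na(v) & v <= mid
  hi <- !is.na(v) & v > mid
  f_lo <- if (mid > low) (v[lo] - low) / (mid - low) else rep(1, sum(lo))
  rgb[lo, "r"] <- rgb[lo, "g"] <- as.integer(round(255 * f_lo))
  f_hi <- if (high > mid) (v[hi] - mid) / (high - mid) else rep(1, sum(hi))
  rgb[hi, "g"] <- rgb[hi, "b"] <- as.integer(round(255 * (1 - f_hi)))
  rgb[is.na(v), ] <- NA_integer_
  rgb
}

#' @describeIn diverging_color RGB matrix rows as `#rrggbb` hex strings
#'   (`NA` rows give `missing_color`).
#' @param rgb integer matrix with columns r, g, b.
#' @param missing_color hex string used for `NA` rows.
#' @export
rgb_to_hex <- function(rgb, missing_color = "#c8c8c8") {
  out <- rep(missing_color, nrow(rgb))
  ok <- stats::complete.cases(rgb)
  out[ok] <- grDevices::rgb(rgb[ok, 1], rgb[ok, 2], rgb[ok, 3], maxColorValue = 255)
  out
}
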