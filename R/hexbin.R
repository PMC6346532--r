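#' Hexagonal binning of plot points
#'
#' Aggregates transformed 2-D points onto a flat-top hexagonal lattice
#' anchored at the data range's lower-left corner: lattice column `q` sits at
#' `xmin + 1.5 * r * q`, row `p` at `ymin + sqrt(3) * r * p`, with odd
#' columns shifted up by half a row. Each point is assigned to its nearest
#' hex centre (ties broken towards the smaller column, then row). Hexes
#' containing no point are omitted, so the per-hex counts always sum to the
#' number of points binned.
#'
#' @param points data frame or matrix with columns `x` and `y` (already
#'   transformed, in-domain coordinates); an optional `id` column names the
#'   assignment.
#' @param radius hexagon radius (centre to vertex) in plot-space units; > 0.
#' @return An object of class `hexbin_grid`: list with `centers` (data frame
#'   `q`, `p`, `cx`, `cy`, `count`), `assignment` (integer index into
#'   `centers` per point, named by point ids when given), `radius`,
#'   `orientation = "flat-top"`.
#' @export
hexbin <- function(points, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    abort("radius must be a single positive number", class = "descope_validation_error")
  points <- as.data.frame(points)
  empty <- structure(list(centers = data.frame(q = integer(0), p = integer(0),
                                               cx = numeric(0), cy = numeric(0),
                                               count = integer(0)),
                          assignment = integer(0), radius = radius,
                          orientation = "flat-top"),
                     class = "hexbin_grid")
  if (nrow(points) == 0L) return(empty)
  if (!all(c("x", "y") %in% names(points)))
    abort("points must have columns 'x' and 'y'", class = "descope_validation_error")
  x <- as.numeric(points$x); y <- as.numeric(points$y)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    abort("points must be finite (mask out-of-domain values before binning)",
          class = "descope_validation_error")

  key <- hex_assign(x, y, min(x), min(y), radius)
  uniq <- unique(key[order(key$q, key$p), , drop = FALSE])
  idx <- match(paste(key$q, key$p), paste(uniq$q, uniq$p))
  dy <- sqrt(3) * radius
  centers <- data.frame(q = uniq$q, p = uniq$p,
                        cx = min(x) + 1.5 * radius * uniq$q,
                        cy = min(y) + dy * uniq$p + (uniq$q %% 2) * dy / 2,
                        count = as.integer(tabulate(idx, nbins = nrow(uniq))))
  rownames(centers) <- NULL
  if (!is.null(points$id)) names(idx) <- as.character(points$id)
  structure(list(centers = centers, assignment = idx, radius = radius,
                 orientation = "flat-top"),
            class = "hexbin_grid")
}

# nearest lattice centre for each point, searching the 3x3 candidate
# neighbourhood around the point's fractional lattice coordinates
hex_assign <- function(x, y, x0, y0, r) {
  dx <- 1.5 * r
  dy <- sqrt(3) * r
  q0 <- (x - x0) / dx
  n <- length(x)
  best_q <- integer(n); best_p <- integer(n); best_d <- rep(Inf, n)
  for (qq in -1L:1L) {
    q <- as.integer(floor(q0)) + qq
    off <- (q %% 2L) * dy / 2
    p0 <- (y - y0 - off) / dy
    for (pp in -1L:1L) {
      p <- as.integer(floor(p0)) + pp
      d2 <- (x - (x0 + dx * q))^2 + (y - (y0 + dy * p + off))^2
      better <- d2 < best_d - 1e-12 * r^2 |
        (abs(d2 - best_d) <= 1e-12 * r^2 &
           (q < best_q | (q == best_q & p < best_p)))
      best_q[better] <- q[better]
      best_p[better] <- p[better]
      best_d[better] <- d2[better]
    }
  }
  data.frame(q = best_q, p = best_p)
}

#' @export
print.hexbin_grid <- function(x, ...) {
  cat(sprintf("<hexbin_grid> %d hexes, %d points, radius %g (%s)\n",
              nrow(x$centers), length(x$assignment), x$radius, x$orientation))
  invisible(x)
}

#' Hex-bin the genes of a view
#'
#' Convenience wrapper: transforms the view's axis dimensions, drops
#' out-of-domain genes and genes outside the current view range, and bins
#' the rest. The default radius is 1/30 of the view's x-range, giving about
#' 30 hex columns.
#'
#' @param experiment a `de_experiment`.
#' @param view a `view_state` for that experiment.
#' @param radius hex radius; `NULL` for the default.
#' @return A `hexbin_grid`; its assignment is named by gene IDs.
#' @export
hexbin_view <- function(experiment, view, radius = NULL) {
  stopifnot(inherits(view, "view_state"))
  tx <- transform_values(dimension_values(experiment, view$x_dim, "numeric"),
                         view$transform_x)
  ty <- transform_values(dimension_values(experiment, view$y_dim, "numeric"),
                         view$transform_y)
  ok <- tx$in_domain & ty$in_domain
  if (!anyNA(view$x_range) && !anyNA(view$y_range))
    ok <- ok & !is.na(tx$values) & !is.na(ty$values) &
      tx$values >= view$x_range[1] & tx$values <= view$x_range[2] &
      ty$values >= view$y_range[1] & ty$values <= view$y_range[2]
  pts <- data.frame(x = tx$values[ok], y = ty$values[ok],
                    id = genes(experiment)[ok])
  if (is.null(radius)) {
    width <- diff(view$x_range)
    radius <- if (is.finite(width) && width > 0) width / 30 else 1
  }
  hexbin(pts, radius)
}
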