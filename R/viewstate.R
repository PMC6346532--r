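#' Scatter-plot view state
#'
#' The model behind the focus experiment's main scatter plot: which numeric
#' dimensions sit on the axes, their transforms, the current and full data
#' ranges (in transformed space), and the dot-rendering override. The
#' default view is the volcano plot: `-log10(pValue)` against linear
#' `foldChange`. The view keeps its experiment so axis interactions can
#' recompute ranges.
#'
#' @param experiment the focus `de_experiment`.
#' @param x_dim,y_dim numeric dimension names.
#' @param transform_x,transform_y axis transforms, see [transform_values()].
#' @param force_dots always render genes as dots?
#' @return An object of class `view_state`.
#' @export
view_state <- function(experiment, x_dim = "foldChange", y_dim = "pValue",
                       transform_x = "linear", transform_y = "-log10",
                       force_dots = FALSE) {
  stopifnot(inherits(experiment, "de_experiment"))
  for (d in c(x_dim, y_dim)) dimension_values(experiment, d, "numeric")
  check_transform(transform_x); check_transform(transform_y)
  v <- structure(list(experiment = experiment,
                      x_dim = x_dim, y_dim = y_dim,
                      transform_x = transform_x, transform_y = transform_y,
                      x_range = NULL, y_range = NULL,
                      full_x_range = NULL, full_y_range = NULL,
                      force_dots = isTRUE(force_dots),
                      zoom_locked = FALSE,
                      last_transform = stats::setNames(
                        list(transform_x, transform_y), c(x_dim, y_dim))),
                 class = "view_state")
  refresh_ranges(v)
}

axis_full_range <- function(experiment, dim, transform) {
  t <- transform_values(dimension_values(experiment, dim, "numeric"), transform)
  if (!any(t$in_domain)) return(c(NA_real_, NA_real_))
  range(t$values[t$in_domain])
}

refresh_ranges <- function(view) {
  view$full_x_range <- axis_full_range(view$experiment, view$x_dim, view$transform_x)
  view$full_y_range <- axis_full_range(view$experiment, view$y_dim, view$transform_y)
  view$x_range <- view$full_x_range
  view$y_range <- view$full_y_range
  view
}

#' @rdname view_state
#' @export
default_view <- function(experiment) view_state(experiment)

#' @export
print.view_state <- function(x, ...) {
  cat(sprintf("<view_state> '%s': x = %s (%s), y = %s (%s)%s\n",
              x$experiment$id, x$x_dim, x$transform_x, x$y_dim, x$transform_y,
              if (x$zoom_locked) " [zoom locked]" else ""))
  invisible(x)
}

#' Put a dimension on the x-axis
#'
#' The table-header click interaction: the clicked dimension becomes the
#' x-axis and the current x-axis moves to the y-axis, so two clicks walk any
#' dimension pair onto the plot. Each axis takes the transform last used for
#' its dimension (linear if never used). Clicking the current x-axis is a
#' no-op. Ranges reset to the full data range of the new axes.
#'
#' @param view a `view_state`.
#' @param clicked_dim a numeric dimension of the view's experiment.
#' @return The updated `view_state`.
#' @export
swap_axis <- function(view, clicked_dim) {
  stopifnot(inherits(view, "view_state"))
  dimension_values(view$experiment, clicked_dim, "numeric")
  if (identical(clicked_dim, view$x_dim)) return(view)
  view$y_dim <- view$x_dim
  view$transform_y <- view$last_transform[[view$y_dim]] %||% "linear"
  view$x_dim <- clicked_dim
  view$transform_x <- view$last_transform[[clicked_dim]] %||% "linear"
  view$last_transform[[view$x_dim]] <- view$transform_x
  view$last_transform[[view$y_dim]] <- view$transform_y
  refresh_ranges(view)
}

#' Change the transform of one axis
#'
#' @param view a `view_state`.
#' @param axis `"x"` or `"y"`.
#' @param transform new transform name.
#' @return The updated `view_state` (ranges reset to the new full range).
#' @export
set_transform <- function(view, axis = c("x", "y"), transform) {
  stopifnot(inherits(view, "view_state"))
  axis <- match.arg(axis)
  check_transform(transform)
  if (axis == "x") view$transform_x <- transform else view$transform_y <- transform
  view$last_transform[[if (axis == "x") view$x_dim else view$y_dim]] <- transform
  refresh_ranges(view)
}

#' Build a small-multiple view of a context experiment
#'
#' Small multiples share the focus plot's axes, transforms and *full* ranges
#' so the eye can compare panels directly; they never zoom into a selected
#' area. The focus selection is linked in as a highlight set, restricted to
#' the genes the context experiment measures, and a highlighted gene travels
#' along when present.
#'
#' @param context_experiment a `de_experiment`; must have the focus view's
#'   dimensions.
#' @param focus_view the focus experiment's `view_state`.
#' @param selection optional `selection_state` from the focus experiment.
#' @return List of class `small_multiple` with fields `view` (zoom-locked
#'   `view_state` on the context experiment, ranges copied from the focus
#'   view's full ranges), `highlight` (linked gene IDs) and `highlighted`
#'   (single linked gene or `NULL`).
#' @export
small_multiple_view <- function(context_experiment, focus_view, selection = NULL) {
  stopifnot(inherits(context_experiment, "de_experiment"),
            inherits(focus_view, "view_state"))
  for (d in c(focus_view$x_dim, focus_view$y_dim))
    if (!d %in% context_experiment$dictionary$name)
      abort(sprintf("context experiment '%s' lacks dimension '%s'",
                    context_experiment$id, d),
            class = "descope_validation_error")
  view <- view_state(context_experiment,
                     x_dim = focus_view$x_dim, y_dim = focus_view$y_dim,
                     transform_x = focus_view$transform_x,
                     transform_y = focus_view$transform_y,
                     force_dots = focus_view$force_dots)
  view$x_range <- focus_view$full_x_range
  view$y_range <- focus_view$full_y_range
  view$zoom_locked <- TRUE
  highlight <- if (is.null(selection)) character(0)
               else link_selection(selection, context_experiment)
  highlighted <- selection$highlighted %||% NULL
  if (!is.null(highlighted) && !highlighted %in% genes(context_experiment))
    highlighted <- NULL
  structure(list(view = view, highlight = highlight, highlighted = highlighted),
            class = "small_multiple")
}
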