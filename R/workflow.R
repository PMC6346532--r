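#' Session configuration
#'
#' Bundles the knobs shared by every workflow step. Values are resolved with
#' flag > config file > default precedence by the command-line wrapper;
#' programmatic callers just pass arguments.
#'
#' @param collection_dir collection directory (see [write_collection()]).
#' @param seed integer seed used by every stochastic step.
#' @param hex_radius hex radius or `"auto"` (x-range / 30).
#' @param dot_threshold dot-rendering threshold (default 5000).
#' @param go_min_size,go_max_size GO term-size bounds.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return A `session_config` list.
#' @export
session_config <- function(collection_dir = NULL, seed = 1L,
                           hex_radius = "auto", dot_threshold = 5000L,
                           go_min_size = 1L, go_max_size = Inf,
                           log_level = "info") {
  structure(list(collection_dir = collection_dir, seed = as.integer(seed),
                 hex_radius = hex_radius,
                 dot_threshold = as.integer(dot_threshold),
                 go_min_size = as.integer(go_min_size),
                 go_max_size = go_max_size, log_level = log_level),
            class = "session_config")
}

workflow_log <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message(sprintf(...))
}

#' Run a scripted analysis session
#'
#' The non-interactive mirror of an interactive session: an ordered list of
#' steps is executed against a collection, each step reading the state the
#' previous ones left (current collection, current selection) and writing
#' its artifact into `out_dir`. A session log (`session.json`) records every
#' step, clause and the seed, so a recorded session replays to byte-identical
#' outputs.
#'
#' Steps are lists with a `cmd` field:
#' \describe{
#'   \item{`synth`}{generate a synthetic collection into the session
#'     (`config` may override [synth_config()] fields); writes it to
#'     `collection/` plus `go_annotation.tsv` and `truth.json`.}
#'   \item{`focus`}{`id`: set the focus experiment.}
#'   \item{`overview`}{PCA overview of the current collection (restricted to
#'     the current selection when `on_selection = TRUE`); writes `coords.tsv`.}
#'   \item{`query`}{`where`: character vector of clause strings applied to
#'     the focus experiment; writes `ids.txt`.}
#'   \item{`plot`}{hex-bin model of the focus experiment's current view
#'     (`x`, `y`, `tx`, `ty` optional); writes `plot.json`.}
#'   \item{`go`}{scan terms for the current selection against `annotation`
#'     (path, or the session's synthetic annotation); writes `terms.tsv`.}
#' }
#'
#' @param config a [session_config()]; its `collection_dir` (when set) is
#'   loaded before the first step.
#' @param script list of step lists; an empty script is a no-op success.
#' @param out_dir artifact directory, created if needed.
#' @return Invisibly, a list with the final `collection`, `selection` and
#'   the paths of all written artifacts. Any step error aborts with the
#'   failing step named.
#' @export
run_workflow <- function(config, script = list(), out_dir = ".") {
  stopifnot(inherits(config, "session_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  state$collection <- if (!is.null(config$collection_dir))
    read_collection(config$collection_dir) else NULL
  state$selection <- NULL
  state$annotation <- NULL
  state$artifacts <- character(0)

  for (i in seq_along(script)) {
    step <- script[[i]]
    cmd <- step$cmd %||% "?"
    workflow_log(config, "[%d/%d] %s", i, length(script), cmd)
    tryCatch(
      run_step(cmd, step, state, config, out_dir),
      error = function(e) abort(
        sprintf("workflow step %d ('%s') failed: %s", i, cmd,
                conditionMessage(e)),
        class = "descope_workflow_error"))
  }
  log_path <- file.path(out_dir, "session.json")
  jsonlite::write_json(list(seed = config$seed, steps = script),
                       log_path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(list(collection = state$collection, selection = state$selection,
                 artifacts = c(state$artifacts, log_path)))
}

need_collection <- function(state) {
  if (is.null(state$collection))
    abort("no collection loaded (run synth or set collection_dir first)",
          class = "descope_validation_error")
  state$collection
}

focus_experiment <- function(state) {
  coll <- need_collection(state)
  if (is.null(coll$focus_id))
    abort("no focus experiment set", class = "descope_validation_error")
  coll$experiments[[coll$focus_id]]
}

run_step <- function(cmd, step, state, config, out_dir) {
  switch(cmd,
    synth = {
      cfg <- do.call(synth_config,
                     c(step$config %||% list(),
                       if (is.null(step$config$seed)) list(seed = config$seed)))
      gen <- generate_collection(cfg)
      go <- generate_go_annotation(cfg, gen$truth)
      state$collection <- gen$collection
      state$annotation <- go$annotation
      coll_dir <- file.path(out_dir, "collection")
      write_collection(gen$collection, coll_dir)
      write_go_annotation(go$annotation, file.path(out_dir, "go_annotation.tsv"))
      jsonlite::write_json(
        list(cluster = as.list(gen$truth$cluster),
             signatures = lapply(gen$truth$signatures, function(s)
               list(genes = s$genes, sign = s$sign)),
             term_cluster = as.list(go$term_cluster)),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
        null = "null")
      state$artifacts <- c(state$artifacts, coll_dir,
                           file.path(out_dir, c("go_annotation.tsv", "truth.json")))
    },
    focus = {
      state$collection <- set_focus(need_collection(state), step$id)
    },
    overview = {
      coll <- need_collection(state)
      coords <- if (isTRUE(step$on_selection)) {
        if (is.null(state$selection))
          abort("overview on_selection requires a previous query",
                class = "descope_validation_error")
        recompute_on_selection(coll, state$selection, seed = config$seed)
      } else compute_overview(assemble_pvalue_matrix(coll), seed = config$seed)
      tab <- as.data.frame(coords)
      tab$visibility <- vapply(coll$experiments[tab$id], `[[`, character(1),
                               "visibility")
      tab$icon <- vapply(coll$experiments[tab$id], `[[`, character(1), "icon")
      path <- file.path(out_dir, step$out %||% "coords.tsv")
      num <- vapply(tab, is.numeric, logical(1))
      tab[num] <- lapply(tab[num], format_full)
      utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
      state$artifacts <- c(state$artifacts, path)
    },
    query = {
      exp <- focus_experiment(state)
      clauses <- lapply(step$where %||% character(0), parse_clause)
      state$selection <- apply_filters(exp, clauses)
      path <- file.path(out_dir, step$out %||% "ids.txt")
      writeLines(state$selection$selected, path)
      state$artifacts <- c(state$artifacts, path)
    },
    plot = {
      exp <- focus_experiment(state)
      view <- view_state(exp,
                         x_dim = step$x %||% "foldChange",
                         y_dim = step$y %||% "pValue",
                         transform_x = step$tx %||% "linear",
                         transform_y = step$ty %||% "-log10")
      radius <- if (identical(config$hex_radius, "auto")) NULL
                else as.numeric(config$hex_radius)
      grid <- hexbin_view(exp, view, radius = radius)
      mode <- render_mode(length(grid$assignment),
                          any_selection_active = !is.null(state$selection) &&
                            length(state$selection$selected) <
                              length(state$selection$universe),
                          force_dots = isTRUE(step$force_dots),
                          dot_threshold = config$dot_threshold)
      path <- file.path(out_dir, step$out %||% "plot.json")
      jsonlite::write_json(
        list(experiment = exp$id, x = view$x_dim, y = view$y_dim,
             transform_x = view$transform_x, transform_y = view$transform_y,
             mode = mode, radius = grid$radius, orientation = grid$orientation,
             centers = grid$centers,
             assignment = stats::setNames(as.list(grid$assignment),
                                          names(grid$assignment))),
        path, auto_unbox = TRUE, digits = NA)
      state$artifacts <- c(state$artifacts, path)
    },
    go = {
      if (!is.null(step$annotation))
        state$annotation <- load_go_annotation(step$annotation)
      if (is.null(state$annotation))
        abort("no GO annotation available (synth it or pass annotation=)",
              class = "descope_validation_error")
      if (is.null(state$selection))
        abort("go scan requires a previous query", class = "descope_validation_error")
      scores <- scan_terms(state$annotation, state$selection,
                           min_size = step$min %||% config$go_min_size,
                           max_size = step$max %||% config$go_max_size,
                           experiment = if (!is.null(step$color))
                             focus_experiment(state) else NULL,
                           color_dim = step$color)
      path <- file.path(out_dir, step$out %||% "terms.tsv")
      num <- vapply(scores, is.numeric, logical(1))
      out <- as.data.frame(scores)
      out[num] <- lapply(out[num], format_full)
      utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
      state$artifacts <- c(state$artifacts, path)
    },
    abort(sprintf("unknown workflow step '%s'", cmd),
          class = "descope_validation_error")
  )
  invisible(NULL)
}

#' Replay a recorded session
#'
#' Re-runs the steps stored in a `session.json` written by [run_workflow()].
#' With the same collection inputs this reproduces every artifact
#' byte-for-byte.
#'
#' @param log_path path to a session log.
#' @param config a [session_config()]; its seed is overridden by the
#'   recorded one.
#' @param out_dir where to write the replayed artifacts.
#' @return See [run_workflow()].
#' @export
replay_session <- function(log_path, config = session_config(), out_dir = ".") {
  log <- jsonlite::fromJSON(log_path, simplifyVector = FALSE)
  config$seed <- as.integer(log$seed)
  run_workflow(config, log$steps, out_dir = out_dir)
}
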