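#' Directory-based plugin discovery
#'
#' Extensions are installed by dropping an `.R` file into one of four
#' subdirectories of a plugins directory: `graphing/`, `transformations/`,
#' `io/` and `analysis/`. Each file is sourced in an isolated environment and
#' must define a list named `plugin` honouring the contract of its category:
#'
#' * `transformations`: fields `name`, `forward`, `inverse`, optional `params`
#'   — usable anywhere a built-in transform is, via [get_transform()].
#' * `io`: fields `name`, `extensions` (character vector), `read(path)` and
#'   `write(ds, path)`.
#' * `analysis`: fields `name`, `run(ws, node_id, params)` returning a
#'   clustering id.
#' * `graphing`: fields `name`, `applicability` (`"dataset"`, `"clustering"`
#'   or `"both"`), `render(ws, item_id, channels, path)`.
#'
#' A plugin that fails to load (syntax error, missing fields) is skipped and
#' recorded in the registry's error report; it never aborts discovery or
#' affects other plugins.
#'
#' @name plugin-system
NULL

plugin_categories <- c("graphing", "transformations", "io", "analysis")

validate_plugin <- function(p, category) {
  if (!is.list(p) || is.null(p$name) || !nzchar(p$name))
    return("plugin must be a list with a non-empty 'name'")
  need <- switch(category,
    transformations = c("forward", "inverse"),
    io = c("extensions", "read", "write"),
    analysis = "run",
    graphing = c("applicability", "render")
  )
  missing <- need[!vapply(need, function(f) !is.null(p[[f]]), logical(1))]
  if (length(missing))
    return(sprintf("missing required field(s): %s",
                   paste(missing, collapse = ", ")))
  if (category == "graphing" &&
      !p$applicability %in% c("dataset", "clustering", "both"))
    return(sprintf("invalid applicability '%s'", p$applicability))
  NULL
}

#' Discover plugins under a directory
#'
#' Scans `graphing/`, `transformations/`, `io/` and `analysis/` beneath
#' `plugins_dir` for `.R` files, loading each candidate in isolation.
#'
#' @param plugins_dir path to the plugins directory (may be empty or lack
#'   some category subdirectories).
#' @return An object of class `cyto_plugin_registry`: per-category named
#'   lists of plugin specs, plus an `errors` data.frame (file, message) for
#'   candidates that failed to load.
#' @export
discover_plugins <- function(plugins_dir) {
  if (!dir.exists(plugins_dir))
    cyto_io_error(sprintf("plugins directory not found: %s", plugins_dir))
  registry <- stats::setNames(
    lapply(plugin_categories, function(x) list()), plugin_categories)
  errors <- data.frame(file = character(0), message = character(0))
  for (category in plugin_categories) {
    dir <- file.path(plugins_dir, category)
    if (!dir.exists(dir)) next
    files <- sort(list.files(dir, pattern = "\\.[Rr]$", full.names = TRUE))
    for (f in files) {
      env <- new.env(parent = getNamespace("cytopop"))
      result <- tryCatch({
        sys.source(f, envir = env)
        p <- get0("plugin", envir = env, inherits = FALSE)
        if (is.null(p)) stop("file does not define a 'plugin' list")
        problem <- validate_plugin(p, category)
        if (!is.null(problem)) stop(problem)
        p
      }, error = function(e) e)
      if (inherits(result, "error")) {
        errors <- rbind(errors, data.frame(
          file = f, message = conditionMessage(result)))
        next
      }
      if (!is.null(registry[[category]][[result$name]])) {
        errors <- rbind(errors, data.frame(
          file = f,
          message = sprintf("duplicate plugin name '%s' in category '%s'",
                            result$name, category)))
        next
      }
      result$category <- category
      result$source_path <- f
      registry[[category]][[result$name]] <- result
    }
  }
  structure(list(plugins = registry, errors = errors),
            class = "cyto_plugin_registry")
}

#' @export
print.cyto_plugin_registry <- function(x, ...) {
  for (category in plugin_categories) {
    names <- names(x$plugins[[category]])
    cat(sprintf("%-16s %s\n", paste0(category, ":"),
                if (length(names)) paste(names, collapse = ", ") else "(none)"))
  }
  if (nrow(x$errors))
    cat(sprintf("%d plugin(s) failed to load\n", nrow(x$errors)))
  invisible(x)
}

#' Resolve a plugin by category and name
#'
#' @param registry a registry from [discover_plugins()].
#' @param category one of `"graphing"`, `"transformations"`, `"io"`,
#'   `"analysis"`.
#' @param name plugin name.
#' @return The plugin spec (a list).
#' @export
plugin_resolve <- function(registry, category, name) {
  stopifnot(inherits(registry, "cyto_plugin_registry"))
  if (!category %in% plugin_categories)
    cyto_key_error(sprintf("unknown plugin category '%s'", category))
  p <- registry$plugins[[category]][[name]]
  if (is.null(p))
    cyto_key_error(sprintf("no plugin '%s' in category '%s'", name, category))
  p
}

#' Graphing plugins applicable to an item kind
#'
#' Graphing plugins declare whether they apply to datasets, to clusterings,
#' or to both; a scatterplot typically declares both while a histogram is
#' dataset-only. This is what a front end would use to build an item's menu.
#'
#' @param registry a registry from [discover_plugins()].
#' @param kind `"dataset"` or `"clustering"`.
#' @return Character vector of applicable graphing plugin names.
#' @export
applicable_graphing <- function(registry, kind) {
  stopifnot(inherits(registry, "cyto_plugin_registry"))
  if (!kind %in% c("dataset", "clustering"))
    cyto_value_error(sprintf("unknown item kind '%s'", kind))
  plugins <- registry$plugins$graphing
  names(plugins)[vapply(plugins, function(p)
    p$applicability %in% c(kind, "both"), logical(1))]
}
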