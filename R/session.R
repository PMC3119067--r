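#' Session persistence
#'
#' The entire analysis state is saved as two files sharing a path stem:
#' `<stem>.find`, a JSON document holding all qualitative information (the
#' dataset tree, labels, channel names, exclusions, keywords, clustering
#' parameters and display orders, figure groups) plus an index of the numeric
#' arrays; and `<stem>.bin`, a flat binary store concatenating those arrays —
#' event matrices as little-endian float64 (column-major) and cluster
#' assignments as little-endian int32. Fixed endianness makes bundles
#' portable across machines; the JSON carries a format version.
#'
#' @name session-persistence
NULL

SESSION_FORMAT_VERSION <- "1.0"

#' Save a workspace to a two-file session bundle
#'
#' Both files are written to temporary paths and renamed into place, so an
#' existing bundle at the same stem is replaced atomically.
#'
#' @param ws a workspace.
#' @param stem path stem; `<stem>.find` and `<stem>.bin` are written.
#' @return A list describing the bundle (paths, version, array index),
#'   invisibly.
#' @export
save_session <- function(ws, stem) {
  meta_path <- paste0(stem, ".find")
  bin_path <- paste0(stem, ".bin")

  arrays <- list()   # id -> list(values, what, size)
  index <- list()
  offset <- 0L
  add_array <- function(id, values, what) {
    size <- if (what == "double") 8L else 4L
    index[[id]] <<- list(offset = offset, length = length(values),
                         dtype = what)
    arrays[[id]] <<- list(values = values, what = what, size = size)
    offset <<- offset + length(values) * size
  }

  # deterministic order: nodes in creation order, then clusterings
  node_ids <- names(ws$nodes)
  for (id in node_ids)
    add_array(paste0("events:", id), as.vector(ws$nodes[[id]]$data$events),
              "double")
  cl_ids <- names(ws$clusterings)
  for (id in cl_ids)
    add_array(paste0("assignment:", id),
              as.integer(ws$clusterings[[id]]$assignment), "integer")

  nodes_meta <- lapply(ws$nodes, function(n) list(
    id = n$id, label = n$label,
    channels = as.list(n$data$channels),
    n_events = nrow(n$data$events),
    keywords = as.list(n$data$keywords),
    excluded = as.list(n$excluded),
    parent = n$parent,
    children = as.list(n$children),
    clusterings = as.list(n$clusterings),
    annotations = n$annotations,
    events_array = paste0("events:", n$id)
  ))
  cl_meta <- lapply(ws$clusterings, function(cl) list(
    id = cl$id, dataset_id = cl$dataset_id, k = cl$k,
    algorithm = cl$algorithm, params = cl$params,
    transform = cl$transform, transform_params = cl$transform_params,
    channels = as.list(cl$channels),
    display_order = as.list(cl$display_order),
    assignment_array = paste0("assignment:", cl$id)
  ))
  # canonicalize figure groups so repeated save cycles serialize identically
  fg <- lapply(ws$figure_groups, function(specs) lapply(specs, function(s) {
    s$channels <- as.numeric(unlist(s$channels))
    s
  }))
  meta <- list(
    version = SESSION_FORMAT_VERSION,
    counter = as.list(ws$counter),
    nodes = nodes_meta,
    clusterings = cl_meta,
    figure_groups = fg,
    palette = cluster_palette(12),
    arrays = index
  )

  dir <- dirname(meta_path)
  tmp_meta <- tempfile("session", tmpdir = dir, fileext = ".find")
  tmp_bin <- tempfile("session", tmpdir = dir, fileext = ".bin")
  ok <- tryCatch({
    jsonlite::write_json(meta, tmp_meta, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    con <- file(tmp_bin, "wb")
    for (a in arrays) {
      if (a$what == "double")
        writeBin(as.double(a$values), con, size = 8L, endian = "little")
      else
        writeBin(as.integer(a$values), con, size = 4L, endian = "little")
    }
    close(con)
    TRUE
  }, error = function(e) {
    unlink(c(tmp_meta, tmp_bin))
    cyto_io_error(conditionMessage(e))
  })
  file.rename(tmp_meta, meta_path)
  file.rename(tmp_bin, bin_path)
  invisible(list(metadata_path = meta_path, binary_path = bin_path,
                 version = SESSION_FORMAT_VERSION, index = index))
}

read_indexed_array <- function(raw, entry) {
  size <- if (entry$dtype == "double") 8L else 4L
  end <- entry$offset + entry$length * size
  if (end > length(raw))
    cyto_corrupt_bundle_error(sprintf(
      "binary store truncated: array needs bytes up to %d, file has %d",
      end, length(raw)))
  bytes <- raw[(entry$offset + 1):end]
  if (entry$dtype == "double")
    readBin(bytes, "double", n = entry$length, size = 8L, endian = "little")
  else
    readBin(bytes, "integer", n = entry$length, size = 4L, endian = "little")
}

#' Load a session bundle into a fresh workspace
#'
#' @param stem path stem used in [save_session()].
#' @return A [cyto_workspace()] with the saved tree, clusterings and figure
#'   groups restored; numeric arrays are reproduced bitwise.
#' @export
load_session <- function(stem) {
  meta_path <- paste0(stem, ".find")
  bin_path <- paste0(stem, ".bin")
  if (!file.exists(meta_path))
    cyto_bundle_error(sprintf("metadata file missing: %s", meta_path))
  if (!file.exists(bin_path))
    cyto_bundle_error(sprintf("binary store missing: %s", bin_path))
  meta <- tryCatch(
    jsonlite::read_json(meta_path),
    error = function(e) cyto_corrupt_bundle_error(conditionMessage(e)))
  if (is.null(meta$version))
    cyto_corrupt_bundle_error("metadata has no format version")
  if (!identical(meta$version, SESSION_FORMAT_VERSION))
    cyto_version_error(sprintf(
      "unsupported session format version '%s' (supported: %s)",
      meta$version, SESSION_FORMAT_VERSION))
  raw <- readBin(bin_path, "raw", n = file.size(bin_path))

  get_entry <- function(array_id) {
    entry <- meta$arrays[[array_id]]
    if (is.null(entry))
      cyto_corrupt_bundle_error(sprintf(
        "metadata references absent array '%s'", array_id))
    entry
  }

  ws <- cyto_workspace()
  for (nm in meta$nodes) {
    entry <- get_entry(nm$events_array)
    channels <- unlist(nm$channels)
    n_events <- nm$n_events
    if (entry$length != n_events * length(channels))
      cyto_corrupt_bundle_error(sprintf(
        "array '%s' length %d does not match %d x %d",
        nm$events_array, entry$length, n_events, length(channels)))
    events <- matrix(read_indexed_array(raw, entry),
                     nrow = n_events, ncol = length(channels))
    kw <- vapply(nm$keywords, as.character, character(1))
    ws$nodes[[nm$id]] <- list(
      id = nm$id, label = nm$label,
      data = fcs_dataset(events, channels, keywords = kw),
      excluded = as.integer(unlist(nm$excluded)),
      parent = nm$parent,
      children = as.character(unlist(nm$children)),
      clusterings = as.character(unlist(nm$clusterings)),
      annotations = nm$annotations
    )
  }
  for (cm in meta$clusterings) {
    entry <- get_entry(cm$assignment_array)
    ws$clusterings[[cm$id]] <- list(
      id = cm$id, dataset_id = cm$dataset_id,
      assignment = read_indexed_array(raw, entry),
      k = as.integer(cm$k), algorithm = cm$algorithm,
      params = cm$params,
      transform = cm$transform,
      transform_params = cm$transform_params,
      channels = as.character(unlist(cm$channels)),
      display_order = as.integer(unlist(cm$display_order))
    )
  }
  ws$figure_groups <- meta$figure_groups %||% list()
  counter <- unlist(meta$counter)
  ws$counter <- c(ds = as.integer(counter[["ds"]]),
                  cl = as.integer(counter[["cl"]]))
  ws
}
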