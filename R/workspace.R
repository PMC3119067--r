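#' Analysis workspace
#'
#' A workspace holds the hierarchical analysis state: loaded datasets, the
#' child datasets isolated from them, the clusterings attached to each, and
#' named figure groups. Datasets form a tree — a child dataset created by
#' [extract_clusters()] hangs beneath the dataset it was isolated from.
#' The workspace is an environment, so the `ws_*` functions mutate it in
#' place and return ids (or the requested object) invisibly where natural.
#'
#' @return An object of class `cyto_workspace`.
#' @export
cyto_workspace <- function() {
  ws <- new.env(parent = emptyenv())
  ws$nodes <- list()        # id -> dataset node
  ws$clusterings <- list()  # id -> clustering
  ws$figure_groups <- list()
  ws$counter <- c(ds = 0L, cl = 0L)
  class(ws) <- "cyto_workspace"
  ws
}

#' @export
print.cyto_workspace <- function(x, ...) {
  cat(sprintf("<cyto_workspace> %d dataset(s), %d clustering(s), %d figure group(s)\n",
              length(x$nodes), length(x$clusterings), length(x$figure_groups)))
  roots <- names(x$nodes)[vapply(x$nodes, function(n) is.null(n$parent), logical(1))]
  print_tree <- function(id, indent) {
    n <- x$nodes[[id]]
    cat(sprintf("%s%s [%s] %d x %d\n", strrep("  ", indent), n$label, id,
                nrow(n$data$events), length(n$data$channels)))
    for (cl in n$clusterings)
      cat(sprintf("%s* clustering %s (k = %d)\n", strrep("  ", indent + 1),
                  cl, x$clusterings[[cl]]$k))
    for (ch in n$children) print_tree(ch, indent + 1)
  }
  for (r in roots) print_tree(r, 1)
  invisible(x)
}

next_id <- function(ws, kind) {
  ws$counter[kind] <- ws$counter[kind] + 1L
  sprintf("%s%d", kind, ws$counter[kind])
}

#' Add a dataset to a workspace
#'
#' @param ws a [cyto_workspace()].
#' @param data an [fcs_dataset].
#' @param label display label; defaults to a generated one.
#' @param parent id of the parent node, or `NULL` for a root dataset.
#' @return The id of the new node.
#' @export
ws_add_dataset <- function(ws, data, label = NULL, parent = NULL) {
  stopifnot(inherits(ws, "cyto_workspace"), inherits(data, "fcs_dataset"))
  if (!is.null(parent) && is.null(ws$nodes[[parent]]))
    cyto_key_error(sprintf("unknown parent node '%s'", parent))
  id <- next_id(ws, "ds")
  if (is.null(label)) label <- id
  ws$nodes[[id]] <- list(
    id = id, label = label, data = data,
    excluded = integer(0), parent = parent,
    children = character(0), clusterings = character(0),
    annotations = list()
  )
  if (!is.null(parent))
    ws$nodes[[parent]]$children <- c(ws$nodes[[parent]]$children, id)
  id
}

#' Fetch a dataset node by id
#' @param ws a workspace.
#' @param id node id.
#' @return The node (a list).
#' @export
ws_node <- function(ws, id) {
  n <- ws$nodes[[id]]
  if (is.null(n)) cyto_key_error(sprintf("unknown dataset node '%s'", id))
  n
}

ws_clustering <- function(ws, id) {
  cl <- ws$clusterings[[id]]
  if (is.null(cl)) cyto_key_error(sprintf("unknown clustering '%s'", id))
  cl
}

#' Delete a node and its entire subtree
#'
#' Removes the node, all descendant nodes, and every clustering attached to
#' any of them, so no dangling ids remain.
#'
#' @param ws a workspace.
#' @param id node id.
#' @export
ws_delete_node <- function(ws, id) {
  node <- ws_node(ws, id)
  for (ch in node$children) ws_delete_node(ws, ch)
  for (cl in node$clusterings) ws$clusterings[[cl]] <- NULL
  if (!is.null(node$parent) && !is.null(ws$nodes[[node$parent]])) {
    p <- ws$nodes[[node$parent]]
    p$children <- setdiff(p$children, id)
    ws$nodes[[node$parent]] <- p
  }
  ws$nodes[[id]] <- NULL
  invisible(ws)
}

# ---------------------------------------------------------------------------
# Column management and previews

#' Preview the first rows of a dataset
#'
#' @param ws a workspace.
#' @param id node id.
#' @param n_rows number of rows to show (default 10); fewer if the dataset is
#'   smaller.
#' @return A numeric matrix of `min(n_rows, events)` rows with channel names
#'   as column names, values unmodified and in file order.
#' @export
ws_preview <- function(ws, id, n_rows = 10L) {
  if (n_rows < 1) cyto_value_error("n_rows must be positive")
  node <- ws_node(ws, id)
  k <- min(n_rows, nrow(node$data$events))
  node$data$events[seq_len(k), , drop = FALSE]
}

#' Rename a channel
#'
#' Only the label changes; event data, exclusions and clusterings are
#' untouched.
#'
#' @param ws a workspace.
#' @param id node id.
#' @param index channel index (1-based).
#' @param new_name replacement name.
#' @export
rename_channel <- function(ws, id, index, new_name) {
  node <- ws_node(ws, id)
  n_chan <- length(node$data$channels)
  if (index < 1 || index > n_chan) cyto_value_error("channel index out of range")
  if (!nzchar(new_name)) cyto_value_error("channel name must be non-empty")
  proposed <- node$data$channels
  proposed[index] <- new_name
  if (anyDuplicated(proposed))
    cyto_name_clash_error(sprintf("channel name '%s' already in use", new_name))
  node$data$channels <- proposed
  colnames(node$data$events) <- proposed
  ws$nodes[[id]] <- node
  invisible(ws)
}

#' Reorder the channels of a dataset
#'
#' @param ws a workspace.
#' @param id node id.
#' @param permutation a permutation of `1:n_channels`; column `j` of the
#'   result is column `permutation[j]` of the original.
#' @export
reorder_channels <- function(ws, id, permutation) {
  node <- ws_node(ws, id)
  n_chan <- length(node$data$channels)
  if (length(permutation) != n_chan || !setequal(permutation, seq_len(n_chan)))
    cyto_value_error("argument is not a permutation of the channel indices")
  permutation <- as.integer(permutation)
  excluded_names <- node$data$channels[node$excluded]
  node$data$events <- node$data$events[, permutation, drop = FALSE]
  node$data$channels <- node$data$channels[permutation]
  colnames(node$data$events) <- node$data$channels
  node$excluded <- which(node$data$channels %in% excluded_names)
  ws$nodes[[id]] <- node
  invisible(ws)
}

#' Exclude channels from automated analysis
#'
#' Excluded channels (for example a Time ramp) are ignored by clustering and
#' summaries but remain available for plotting and export. At least one
#' channel must stay included.
#'
#' @param ws a workspace.
#' @param id node id.
#' @param indices integer channel indices to exclude (may be empty).
#' @export
set_excluded_channels <- function(ws, id, indices) {
  node <- ws_node(ws, id)
  indices <- unique(as.integer(indices))
  n_chan <- length(node$data$channels)
  if (length(indices) && (min(indices) < 1 || max(indices) > n_chan))
    cyto_value_error("excluded channel index out of range")
  if (length(indices) >= n_chan)
    cyto_value_error("at least one channel must remain included in analysis")
  node$excluded <- sort(indices)
  ws$nodes[[id]] <- node
  invisible(ws)
}

#' Analysis channel indices of a node (those not excluded)
#' @param ws a workspace.
#' @param id node id.
#' @return Integer vector of included channel indices.
#' @export
analysis_channels <- function(ws, id) {
  node <- ws_node(ws, id)
  setdiff(seq_along(node$data$channels), node$excluded)
}

#' Analysis event matrix of a node
#'
#' The event matrix restricted to the channels included in analysis, in raw
#' (untransformed) units.
#'
#' @param ws a workspace.
#' @param id node id.
#' @return Numeric matrix.
#' @export
analysis_matrix <- function(ws, id) {
  node <- ws_node(ws, id)
  node$data$events[, analysis_channels(ws, id), drop = FALSE]
}

#' Enumerate all unordered channel pairs
#'
#' The number of distinct 2-D views needed to cover an `n`-channel dataset is
#' `choose(n, 2)`: 190 plots for 20 channels, 4950 for 100 — the combinatorial
#' burden that motivates automated population discovery.
#'
#' @param n_channels number of channels (at least 2).
#' @return A `choose(n, 2) x 2` integer matrix of 1-based index pairs in
#'   lexicographic order.
#' @export
enumerate_channel_pairs <- function(n_channels) {
  if (is.na(n_channels) || n_channels < 2)
    cyto_value_error("at least two channels are required")
  t(utils::combn(as.integer(n_channels), 2L))
}

# ---------------------------------------------------------------------------
# Cluster isolation and summaries

#' Isolate clusters into a new child dataset
#'
#' Copies the events assigned to any of the selected clusters into a new
#' dataset attached as a child of the clustered dataset, preserving the
#' original row order. The child is a full independent dataset (all channels,
#' copied data) and can itself be transformed, clustered and exported.
#'
#' @param ws a workspace.
#' @param clustering_id id of the clustering to select from.
#' @param cluster_ids non-empty vector of cluster indices (1-based).
#' @param label label for the child node.
#' @return The id of the new child node.
#' @export
extract_clusters <- function(ws, clustering_id, cluster_ids, label = NULL) {
  cl <- ws_clustering(ws, clustering_id)
  if (length(cluster_ids) == 0) cyto_value_error("no clusters selected")
  cluster_ids <- unique(as.integer(cluster_ids))
  unknown <- setdiff(cluster_ids, seq_len(cl$k))
  if (length(unknown))
    cyto_key_error(sprintf("unknown cluster id(s): %s",
                           paste(unknown, collapse = ", ")))
  parent <- ws_node(ws, cl$dataset_id)
  keep <- which(cl$assignment %in% cluster_ids)
  child_data <- fcs_dataset(parent$data$events[keep, , drop = FALSE],
                            parent$data$channels, parent$data$keywords)
  if (is.null(label))
    label <- sprintf("%s clusters %s", parent$label,
                     paste(sort(cluster_ids), collapse = "+"))
  child <- ws_add_dataset(ws, child_data, label = label, parent = parent$id)
  ws$nodes[[child]]$excluded <- parent$excluded
  child
}

#' Per-cluster summary statistics
#'
#' Counts, percentages and the per-channel mean/standard deviation "shape" of
#' each cluster, computed on the analysis channels in the transformed space
#' the clustering was run in (the same shapes drive merging and matching).
#'
#' @param ws a workspace.
#' @param clustering_id clustering id.
#' @return A list with `table` (data.frame of cluster, count, percentage) and
#'   `shapes` (list of per-cluster mean/sd vectors, see [cluster_shapes()]).
#' @export
cluster_summary <- function(ws, clustering_id) {
  cl <- ws_clustering(ws, clustering_id)
  counts <- tabulate(cl$assignment, nbins = cl$k)
  X <- clustering_space_matrix(ws, cl)
  list(
    table = data.frame(
      cluster = seq_len(cl$k),
      count = counts,
      percentage = 100 * counts / length(cl$assignment)
    ),
    shapes = cluster_shapes(X, cl$assignment, k = cl$k)
  )
}

# Reconstruct the transformed analysis matrix a clustering was computed on.
clustering_space_matrix <- function(ws, cl) {
  node <- ws_node(ws, cl$dataset_id)
  idx <- match(cl$channels, node$data$channels)
  if (anyNA(idx))
    cyto_key_error(sprintf("clustering channels missing from dataset: %s",
                           paste(cl$channels[is.na(idx)], collapse = ", ")))
  X <- node$data$events[, idx, drop = FALSE]
  tr <- get_transform(cl$transform, cl$transform_params)
  apply_transform_matrix(X, tr)
}

# ---------------------------------------------------------------------------
# Figure groups (named plot groupings; metadata only)

#' Create or replace a named figure group
#'
#' A figure group is a named collection of plot specifications (node id, plot
#' kind, channel pair, options) that can be re-rendered as a multi-panel
#' figure. It carries no interactive state.
#'
#' @param ws a workspace.
#' @param name group name.
#' @param plot_specs list of lists with fields `node`, `kind`, `channels`, and
#'   optional `options`.
#' @export
ws_set_figure_group <- function(ws, name, plot_specs) {
  for (spec in plot_specs) {
    if (is.null(spec$node) ||
        (is.null(ws$nodes[[spec$node]]) && is.null(ws$clusterings[[spec$node]])))
      cyto_key_error(sprintf("figure group references unknown item '%s'",
                             if (is.null(spec$node)) "<missing>" else spec$node))
  }
  ws$figure_groups[[name]] <- plot_specs
  invisible(ws)
}
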