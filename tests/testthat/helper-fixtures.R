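# Shared fixture builders. Everything is generated in code at test time.

random_dataset <- function(n = 20, c = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fcs_dataset(matrix(stats::runif(n * c, 0, 1e4), n, c),
              paste0("CH", seq_len(c)))
}

# workspace with one generated mixture dataset, Time excluded
mixture_workspace <- function(n_events = 500, k = 3, n_channels = 4,
                              seed = 11, separation = 8) {
  spec <- mixture_spec(n_events, k = k, n_channels = n_channels,
                       separation = separation, seed = seed)
  gen <- generate_mixture(spec)
  ws <- cyto_workspace()
  id <- ws_add_dataset(ws, gen$dataset, label = "mixture")
  set_excluded_channels(ws, id, which(gen$dataset$channels == "Time"))
  list(ws = ws, id = id, labels = gen$labels, spec = spec)
}

# register a clustering built directly from an assignment vector
install_clustering <- function(ws, node_id, assignment,
                               transform = "linear") {
  node <- ws_node(ws, node_id)
  cl_id <- sprintf("cl%d", length(ws$clusterings) + 1L)
  chans <- analysis_channels(ws, node_id)
  ws$clusterings[[cl_id]] <- list(
    id = cl_id, dataset_id = node_id,
    assignment = as.integer(assignment), k = max(assignment),
    algorithm = "fixed", params = list(),
    transform = transform, transform_params = list(),
    channels = node$data$channels[chans],
    display_order = seq_len(max(assignment))
  )
  ws$nodes[[node_id]]$clusterings <- c(node$clusterings, cl_id)
  cl_id
}

# exhaustive minimum-cost assignment for small square matrices
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    total <- sum(cost[cbind(seq_len(n), p)])
    if (total < best_cost) { best_cost <- total; best <- p }
  }
  list(assignment = best, cost = best_cost)
}

# write a transformations plugin file implementing arcsinh
write_arcsinh_plugin <- function(dir) {
  path <- file.path(dir, "transformations", "arcsinh.R")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(c(
    "plugin <- list(",
    "  name = \"arcsinh\",",
    "  params = list(cofactor = 5),",
    "  forward = function(x) asinh(x / 5),",
    "  inverse = function(y) sinh(y) * 5",
    ")"
  ), path)
  path
}

write_broken_plugin <- function(dir) {
  path <- file.path(dir, "transformations", "broken.R")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines("plugin <- list(name = 'broken', forward = function(x x)", path)
  path
}
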