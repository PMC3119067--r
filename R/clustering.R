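#' Automated population discovery
#'
#' The discovery pipeline follows the classic over-clustering strategy for
#' cytometry data: log-transform the analysis channels, place a high number
#' of deterministic initial centers, run standard k-means, then iteratively
#' merge the most similar pair of clusters — judged by a statistical shape
#' comparison of their per-channel means relative to their spreads — until
#' the user's target number of populations remains. The pipeline contains no
#' random draw, so repeated runs on identical input are bitwise identical.
#'
#' @name population-discovery
NULL

#' Deterministic maximin seeding
#'
#' Chooses `n_seeds` data points as initial cluster centers without
#' randomness: the first center is the point farthest from the grand
#' centroid; each subsequent center is the point maximizing the distance to
#' its nearest already-chosen center. Ties break to the lowest row index, so
#' the output is identical across runs.
#'
#' @param X numeric matrix (events x channels).
#' @param n_seeds number of centers; at most the number of distinct rows.
#' @return A list with `centers` (matrix of chosen rows) and `indices`.
#' @export
seed_centers <- function(X, n_seeds) {
  X <- as.matrix(X)
  n_distinct <- sum(!duplicated(X))
  if (n_seeds < 1) cyto_value_error("n_seeds must be at least 1")
  if (n_seeds > n_distinct)
    cyto_value_error(sprintf(
      "n_seeds (%d) exceeds the number of distinct rows (%d)",
      n_seeds, n_distinct))
  centroid <- colMeans(X)
  # squared distances preserve the argmax and avoid n_seeds sqrt passes
  d2 <- rowSums(sweep(X, 2, centroid)^2)
  chosen <- integer(n_seeds)
  chosen[1] <- which.max(d2)           # which.max: first index on ties
  mind <- rowSums(sweep(X, 2, X[chosen[1], ])^2)
  for (i in seq_len(n_seeds - 1L)) {
    chosen[i + 1L] <- which.max(mind)
    di <- rowSums(sweep(X, 2, X[chosen[i + 1L], ])^2)
    mind <- pmin(mind, di)
  }
  list(centers = X[chosen, , drop = FALSE], indices = chosen)
}

#' Lloyd k-means from given centers
#'
#' Standard Lloyd iterations with Euclidean distance from a fixed set of
#' starting centers: assign each event to its nearest center (ties to the
#' lowest center index), recompute centers as cluster means, and repeat until
#' the maximum center movement falls below `tol` or `max_iter` iterations.
#' A center that loses all its events is dropped, so the returned number of
#' clusters can be smaller than the number of seeds.
#'
#' @param X numeric matrix (events x channels), non-empty.
#' @param centers initial center matrix (one row per center).
#' @param max_iter iteration cap (default 100).
#' @param tol convergence threshold on the maximum center movement
#'   (default 1e-6).
#' @return List with `assignment` (1-based cluster index per event),
#'   `centers` (final centers), `k`, and `iterations`.
#' @export
kmeans_lloyd <- function(X, centers, max_iter = 100L, tol = 1e-6) {
  X <- as.matrix(X)
  centers <- as.matrix(centers)
  if (nrow(X) == 0) cyto_value_error("empty event matrix")
  if (nrow(centers) == 0) cyto_value_error("at least one center is required")
  assignment <- integer(nrow(X))
  for (iter in seq_len(max_iter)) {
    D <- center_dist2(X, centers)
    assignment <- max.col(-D, ties.method = "first")
    counts <- tabulate(assignment, nbins = nrow(centers))
    keep <- which(counts > 0)
    dropped <- length(keep) < nrow(centers)
    if (dropped) {
      assignment <- match(assignment, keep)
      centers <- centers[keep, , drop = FALSE]
    }
    new_centers <- cluster_means(X, assignment, nrow(centers))
    movement <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (!dropped && movement < tol) break
  }
  list(assignment = assignment, centers = centers,
       k = nrow(centers), iterations = iter)
}

# squared Euclidean distances, events x centers
center_dist2 <- function(X, centers) {
  cross <- X %*% t(centers)
  x2 <- rowSums(X^2)
  c2 <- rowSums(centers^2)
  d2 <- outer(x2, c2, "+") - 2 * cross
  pmax(d2, 0)
}

cluster_means <- function(X, assignment, k) {
  M <- matrix(0, nrow = k, ncol = ncol(X))
  for (j in seq_len(k))
    M[j, ] <- colMeans(X[assignment == j, , drop = FALSE])
  M
}

#' Per-cluster shape statistics
#'
#' The "shape" of a cluster is its per-channel mean and standard deviation
#' in the space the clustering was run in. Standard deviations are floored at
#' `sd_floor` so singleton or degenerate clusters never divide by zero in
#' [shape_distance()].
#'
#' @param X numeric matrix the assignment refers to.
#' @param assignment 1-based cluster index per row of `X`.
#' @param k number of clusters (defaults to `max(assignment)`).
#' @param sd_floor lower bound on each standard deviation.
#' @return A list of `k` shapes, each with `mean`, `sd` and `count`.
#' @export
cluster_shapes <- function(X, assignment, k = max(assignment),
                           sd_floor = 1e-6) {
  X <- as.matrix(X)
  lapply(seq_len(k), function(j) {
    rows <- X[assignment == j, , drop = FALSE]
    s <- if (nrow(rows) > 1) apply(rows, 2, stats::sd) else rep(0, ncol(rows))
    list(mean = colMeans(rows), sd = pmax(s, sd_floor), count = nrow(rows))
  })
}

#' Shape distance between two clusters
#'
#' A symmetric, diagonal-covariance Mahalanobis-type distance between cluster
#' shapes: `D(a, b) = sqrt(sum_d (mu_ad - mu_bd)^2 / (sd_ad^2 + sd_bd^2))`.
#' Zero for identical shapes; used both for merging over-clustered k-means
#' output and for matching clusters across runs.
#'
#' @param a,b shapes as returned by [cluster_shapes()] (lists with `mean` and
#'   `sd` vectors of equal length).
#' @return Nonnegative scalar.
#' @export
shape_distance <- function(a, b) {
  if (length(a$mean) != length(b$mean))
    cyto_value_error("shapes have different channel counts")
  sqrt(sum((a$mean - b$mean)^2 / (a$sd^2 + b$sd^2)))
}

#' Merge clusters down to a target count
#'
#' Repeatedly merges the pair of clusters with the smallest
#' [shape_distance()], recomputing shapes after every merge, until `target_k`
#' clusters remain. Ties break to the lexicographically smallest index pair.
#' The final clusters are renumbered 1..`target_k` by descending size so that
#' cluster 1 is always the largest population.
#'
#' @param assignment 1-based cluster index per event.
#' @param X matrix the assignment refers to (in the clustering space).
#' @param target_k desired number of clusters, between 1 and the current
#'   count.
#' @return The merged, compacted assignment vector.
#' @export
merge_to_target <- function(assignment, X, target_k) {
  assignment <- compact_labels(assignment)
  k <- max(assignment)
  if (target_k < 1) cyto_value_error("target_k must be at least 1")
  if (target_k > k)
    cyto_value_error(sprintf(
      "target_k (%d) exceeds the current cluster count (%d)", target_k, k))
  while (k > target_k) {
    shapes <- cluster_shapes(X, assignment, k)
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        d <- shape_distance(shapes[[i]], shapes[[j]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    assignment[assignment == best[2]] <- best[1]
    assignment <- compact_labels(assignment)
    k <- k - 1L
  }
  relabel_by_size(assignment, target_k)
}

# renumber labels to 1..k preserving first-appearance order of the label ids
compact_labels <- function(assignment) {
  match(assignment, sort(unique(assignment)))
}

# renumber so cluster 1 is the largest; ties keep the current label order
relabel_by_size <- function(assignment, k = max(assignment)) {
  counts <- tabulate(assignment, nbins = k)
  new_of_old <- integer(k)
  new_of_old[order(-counts, seq_len(k))] <- seq_len(k)
  new_of_old[assignment]
}

#' Discover populations in a dataset
#'
#' Runs the full pipeline on a dataset's analysis channels: transform
#' (log10 by default), deterministic maximin over-seeding with
#' `n_seeds = 10 * target_k` centers (capped at a tenth of the event count),
#' Lloyd k-means, then shape-based merging down to `target_k`. The resulting
#' clustering is registered on the node and returned.
#'
#' @param ws a workspace.
#' @param id dataset node id.
#' @param target_k target number of populations (>= 1).
#' @param n_seeds number of initial centers; `NULL` for the default above.
#' @param transform transform name applied to all included analysis channels
#'   before clustering (`"log"`, `"linear"`, `"hyperlog"`).
#' @param transform_params parameters for the transform.
#' @return The id of the new clustering.
#' @export
discover_populations <- function(ws, id, target_k, n_seeds = NULL,
                                 transform = "log",
                                 transform_params = list()) {
  node <- ws_node(ws, id)
  if (target_k < 1) cyto_value_error("target_k must be at least 1")
  tr <- get_transform(transform, transform_params)
  chan_idx <- analysis_channels(ws, id)
  X <- apply_transform_matrix(node$data$events[, chan_idx, drop = FALSE], tr)
  n <- nrow(X)
  n_distinct <- sum(!duplicated(X))
  if (n_distinct < target_k)
    cyto_value_error(sprintf(
      "dataset has only %d distinct analysis rows; target_k = %d",
      n_distinct, target_k))
  if (is.null(n_seeds)) {
    n_seeds <- min(10L * as.integer(target_k), n %/% 10L)
    n_seeds <- max(n_seeds, as.integer(target_k))
    n_seeds <- min(n_seeds, n_distinct)
  }
  if (n_seeds < target_k)
    cyto_value_error("n_seeds must be at least target_k")

  seeds <- seed_centers(X, n_seeds)
  km <- kmeans_lloyd(X, seeds$centers)
  if (km$k < target_k)
    cyto_value_error(sprintf(
      "k-means retained only %d clusters; target_k = %d", km$k, target_k))
  assignment <- merge_to_target(km$assignment, X, target_k)

  cl_id <- next_id(ws, "cl")
  ws$clusterings[[cl_id]] <- list(
    id = cl_id, dataset_id = id,
    assignment = as.integer(assignment), k = as.integer(target_k),
    algorithm = "overseeded-kmeans-shape-merge",
    params = list(target_k = as.integer(target_k),
                  n_seeds = as.integer(n_seeds)),
    transform = tr$name, transform_params = tr$params,
    channels = node$data$channels[chan_idx],
    display_order = seq_len(as.integer(target_k))
  )
  ws$nodes[[id]]$clusterings <- c(node$clusterings, cl_id)
  cl_id
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same events:
#' 1 for identical partitions, about 0 for independent ones. Used to score
#' recovery of known ground-truth populations.
#'
#' @param a,b label vectors of equal length.
#' @return Scalar in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) cyto_value_error("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
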