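#' Cross-run cluster matching
#'
#' Clustering algorithms do not return populations in a stable order, so the
#' "same" population can receive a different color in every run. Matching
#' compares the cluster shapes of a target clustering against a reference
#' clustering and reassigns the target's display (color) order so that the
#' most similar populations share a color, leaving the assignment vector
#' itself untouched.
#'
#' @name cluster-matching
NULL

#' Pairwise shape-distance matrix between two clusterings
#'
#' Entry `(i, j)` is the [shape_distance()] between cluster `i` of the
#' reference and cluster `j` of the target. Both clusterings must have been
#' computed over the same channel set and transform, otherwise the shapes are
#' not comparable.
#'
#' @param ws a workspace.
#' @param ref_id,target_id clustering ids.
#' @return A `k_ref x k_target` matrix of nonnegative distances.
#' @export
similarity_matrix <- function(ws, ref_id, target_id) {
  ref <- ws_clustering(ws, ref_id)
  target <- ws_clustering(ws, target_id)
  if (!identical(ref$channels, target$channels) ||
      !identical(ref$transform, target$transform))
    cyto_value_error("clusterings were computed over different channels or transforms")
  sh_r <- cluster_shapes(clustering_space_matrix(ws, ref), ref$assignment, ref$k)
  sh_t <- cluster_shapes(clustering_space_matrix(ws, target), target$assignment, target$k)
  D <- matrix(0, nrow = ref$k, ncol = target$k)
  for (i in seq_len(ref$k))
    for (j in seq_len(target$k))
      D[i, j] <- shape_distance(sh_r[[i]], sh_t[[j]])
  D
}

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the linear assignment problem for a square cost matrix by the
#' shortest-augmenting-path formulation in O(n^3). Deterministic and exact.
#'
#' @param cost square numeric cost matrix.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (n != ncol(cost)) cyto_value_error("cost matrix must be square")
  if (n == 0) return(integer(0))
  # potentials u, v and column -> row matching p; index 1 is a virtual column
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n) + 1L) if (p[j] > 0L) assignment[p[j]] <- j - 1L
  assignment
}

#' Match a clustering to a reference and reassign its display order
#'
#' Finds the one-to-one pairing of reference and target clusters minimizing
#' the total shape distance (optimal assignment, not greedy, so the result is
#' independent of cluster numbering). Each matched target cluster adopts the
#' display position — hence the color — of its reference partner; unmatched
#' target clusters are appended after them in their original relative order.
#' Only the target's `display_order` changes; assignments are untouched.
#'
#' @param ws a workspace.
#' @param target_id clustering to recolor.
#' @param ref_id reference clustering.
#' @return A list with `pairs` (data.frame of `ref`, `target`, `distance`),
#'   `unmatched` (target cluster indices without a reference partner), and
#'   `display_order` (the target's new display order), invisibly applied to
#'   the workspace.
#' @export
reorder_to_reference <- function(ws, target_id, ref_id) {
  ref <- ws_clustering(ws, ref_id)
  target <- ws_clustering(ws, target_id)
  D <- similarity_matrix(ws, ref_id, target_id)
  kr <- nrow(D); kt <- ncol(D)
  n <- max(kr, kt)
  # pad to square with zero cost: dummies absorb the surplus side and add a
  # constant, so minimizing the padded total minimizes the real matched total
  C <- matrix(0, n, n)
  C[seq_len(kr), seq_len(kt)] <- D
  a <- solve_assignment(C)

  pairs <- data.frame(ref = integer(0), target = integer(0),
                      distance = numeric(0))
  raw_slot <- rep(NA_real_, kt)
  for (i in seq_len(kr)) {
    j <- a[i]
    if (j <= kt) {
      pairs <- rbind(pairs, data.frame(ref = i, target = j,
                                       distance = D[i, j]))
      raw_slot[j] <- ref$display_order[i]
    }
  }
  unmatched <- which(is.na(raw_slot))
  # novel clusters take the first unused slots, in original relative order
  raw_slot[unmatched] <- max(ref$display_order, 0) +
    seq_along(unmatched) / (length(unmatched) + 1)
  display_order <- as.integer(rank(raw_slot, ties.method = "first"))

  target$display_order <- display_order
  ws$clusterings[[target_id]] <- target
  list(pairs = pairs[order(pairs$ref), , drop = FALSE],
       unmatched = unmatched, display_order = display_order)
}

#' Display color palette
#'
#' A fixed 12-color palette cycled by display position, so cluster colors are
#' reproducible across sessions and exported figures.
#'
#' @param n number of colors required.
#' @return Character vector of `n` hex colors.
#' @export
cluster_palette <- function(n) {
  base <- c("#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD", "#8C564B",
            "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF", "#AEC7E8", "#FFBB78")
  rep_len(base, n)
}
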