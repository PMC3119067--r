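test_that("preview returns the first ten rows, fewer when the data are small", {
  ws <- cyto_workspace()
  big <- ws_add_dataset(ws, random_dataset(100, 4, seed = 1))
  small <- ws_add_dataset(ws, random_dataset(3, 2, seed = 2))
  p <- ws_preview(ws, big)
  expect_equal(nrow(p), 10L)
  expect_identical(p, ws_node(ws, big)$data$events[1:10, ])
  expect_equal(nrow(ws_preview(ws, small)), 3L)
  expect_error(ws_preview(ws, big, 0), class = "cytopop_value_error")
})

test_that("renaming updates the header without touching data", {
  ws <- cyto_workspace()
  id <- ws_add_dataset(ws, fcs_dataset(matrix(1:6, 3, 2), c("FSC-A", "SSC-A")))
  before <- ws_node(ws, id)$data$events
  rename_channel(ws, id, 1, "FSC")
  expect_identical(ws_node(ws, id)$data$channels, c("FSC", "SSC-A"))
  expect_equal(unname(ws_node(ws, id)$data$events), unname(before))
  expect_identical(colnames(ws_preview(ws, id)), c("FSC", "SSC-A"))
  expect_error(rename_channel(ws, id, 2, "FSC"),
               class = "cytopop_name_clash_error")
  expect_error(rename_channel(ws, id, 5, "X"), class = "cytopop_value_error")
})

test_that("reordering is an involution and rejects non-permutations", {
  ws <- cyto_workspace()
  id <- ws_add_dataset(ws, random_dataset(10, 2, seed = 3))
  original <- ws_node(ws, id)$data
  reorder_channels(ws, id, c(2, 1))
  expect_identical(ws_node(ws, id)$data$channels, rev(original$channels))
  expect_equal(ws_node(ws, id)$data$events[, 1], original$events[, 2],
               ignore_attr = TRUE)
  reorder_channels(ws, id, c(2, 1))
  expect_identical(ws_node(ws, id)$data$events, original$events)
  expect_error(reorder_channels(ws, id, c(1, 1)),
               class = "cytopop_value_error")
})

test_that("reordering remaps the exclusion mask by channel name", {
  ws <- cyto_workspace()
  id <- ws_add_dataset(ws, fcs_dataset(matrix(1:12, 3, 4),
                                       c("FSC", "SSC", "FL1", "Time")))
  set_excluded_channels(ws, id, 4)
  reorder_channels(ws, id, c(4, 1, 2, 3))
  expect_identical(ws_node(ws, id)$data$channels[1], "Time")
  expect_equal(ws_node(ws, id)$excluded, 1L)
  expect_identical(colnames(analysis_matrix(ws, id)), c("FSC", "SSC", "FL1"))
})

test_that("channel exclusion shrinks the analysis matrix but not the data", {
  ws <- cyto_workspace()
  id <- ws_add_dataset(ws, fcs_dataset(matrix(runif(25), 5, 5),
                                       c("FSC", "SSC", "FL1", "FL2", "Time")))
  set_excluded_channels(ws, id, 5)
  expect_equal(ncol(analysis_matrix(ws, id)), 4L)
  expect_equal(ncol(ws_node(ws, id)$data$events), 5L)
  set_excluded_channels(ws, id, integer(0))
  expect_equal(analysis_matrix(ws, id), ws_node(ws, id)$data$events)
  expect_error(set_excluded_channels(ws, id, 1:5),
               class = "cytopop_value_error")
})

test_that("channel-pair enumeration matches brute force", {
  pairs20 <- enumerate_channel_pairs(20)
  expect_equal(nrow(pairs20), 190L)
  expect_identical(enumerate_channel_pairs(2), cbind(1L, 2L))
  # brute-force double loop oracle
  brute <- function(n) {
    out <- NULL
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      out <- rbind(out, c(i, j))
    out
  }
  for (n in c(3, 7, 12)) {
    expect_equal(unname(enumerate_channel_pairs(n)), brute(n))
  }
  expect_equal(nrow(enumerate_channel_pairs(100)), 4950L)
  expect_error(enumerate_channel_pairs(1), class = "cytopop_value_error")
})

test_that("cluster extraction preserves order, counts and partitions", {
  mw <- mixture_workspace(300, k = 3, seed = 21)
  cl <- discover_populations(mw$ws, mw$id, target_k = 3)
  assign <- mw$ws$clusterings[[cl]]$assignment
  parent_events <- ws_node(mw$ws, mw$id)$data$events

  all_child <- extract_clusters(mw$ws, cl, 1:3)
  expect_identical(ws_node(mw$ws, all_child)$data$events, parent_events)

  c1 <- extract_clusters(mw$ws, cl, 1)
  expect_equal(nrow(ws_node(mw$ws, c1)$data$events), sum(assign == 1))
  expect_identical(ws_node(mw$ws, c1)$data$events,
                   parent_events[assign == 1, , drop = FALSE])

  # complementary selections partition the parent
  c23 <- extract_clusters(mw$ws, cl, 2:3)
  combined <- rbind(ws_node(mw$ws, c1)$data$events,
                    ws_node(mw$ws, c23)$data$events)
  expect_equal(nrow(combined), nrow(parent_events))
  expect_equal(sort(combined[, 1]), sort(parent_events[, 1]))

  expect_equal(ws_node(mw$ws, mw$id)$children, c(all_child, c1, c23))
  expect_error(extract_clusters(mw$ws, cl, integer(0)),
               class = "cytopop_value_error")
  expect_error(extract_clusters(mw$ws, cl, 9), class = "cytopop_key_error")
})

test_that("cluster summaries tally the assignment vector", {
  ws <- cyto_workspace()
  id <- ws_add_dataset(ws, random_dataset(100, 3, seed = 4))
  assignment <- rep(c(1L, 2L), c(25, 75))
  cl <- install_clustering(ws, id, assignment)
  s <- cluster_summary(ws, cl)
  expect_equal(s$table$count, c(25, 75))
  expect_equal(s$table$percentage, c(25, 75))
  expect_equal(sum(s$table$percentage), 100)

  one <- install_clustering(ws, id, rep(1L, 100))
  expect_equal(cluster_summary(ws, one)$table$percentage, 100)

  # brute-force tally oracle on a random assignment
  set.seed(8)
  a <- sample(1:4, 100, replace = TRUE)
  cl2 <- install_clustering(ws, id, a)
  tally <- vapply(1:4, function(j) sum(a == j), integer(1))
  expect_equal(cluster_summary(ws, cl2)$table$count, tally)
})

test_that("deleting a node removes its subtree and clusterings", {
  mw <- mixture_workspace(200, k = 2, seed = 31)
  cl <- discover_populations(mw$ws, mw$id, target_k = 2)
  child <- extract_clusters(mw$ws, cl, 1)
  grandchild <- ws_add_dataset(mw$ws, random_dataset(5, 4, seed = 6),
                               parent = child)
  ws_delete_node(mw$ws, mw$id)
  expect_length(mw$ws$nodes, 0)
  expect_length(mw$ws$clusterings, 0)
  expect_error(ws_node(mw$ws, grandchild), class = "cytopop_key_error")
})

test_that("figure groups validate their references", {
  ws <- cyto_workspace()
  id <- ws_add_dataset(ws, random_dataset(5, 2, seed = 7))
  ws_set_figure_group(ws, "overview",
                      list(list(node = id, kind = "scatter",
                                channels = c(1, 2))))
  expect_named(ws$figure_groups, "overview")
  expect_error(
    ws_set_figure_group(ws, "bad", list(list(node = "nope", kind = "scatter"))),
    class = "cytopop_key_error")
})
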