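#' Render a figure to file
#'
#' Headless figure export for the four built-in 2-D views: scatterplots,
#' histograms, heatmaps (2-D binned density), and side-by-side boxplots of
#' all channels included in analysis. Output formats: PNG, PDF, PostScript,
#' EPS and SVG. When `item_id` names a clustering, a scatterplot colors
#' events by the clustering's display order through the fixed palette
#' ([cluster_palette()]); histograms, heatmaps and boxplots describe raw
#' datasets only and raise an applicability error for clustering items.
#'
#' @param ws a workspace.
#' @param item_id a dataset node id or a clustering id.
#' @param kind `"scatter"`, `"histogram"`, `"heatmap"` or `"boxplot"`.
#' @param channels length-2 vector of channel indices (scatter/heatmap), a
#'   single index (histogram), or ignored (boxplot).
#' @param path output file path.
#' @param format `"png"`, `"pdf"`, `"ps"`, `"eps"` or `"svg"`; `NULL` infers
#'   it from the path extension.
#' @param transform optional transform name applied to the plotted channels
#'   for display.
#' @param width,height device size in inches (pixels at 96 dpi for PNG).
#' @return `path`, invisibly.
#' @export
export_plot <- function(ws, item_id, kind, channels = c(1L, 2L), path,
                        format = NULL, transform = "linear",
                        width = 6, height = 5) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("png", "pdf", "ps", "eps", "svg"))
    cyto_value_error(sprintf("unsupported figure format '%s'", format))
  if (!kind %in% c("scatter", "histogram", "heatmap", "boxplot"))
    cyto_value_error(sprintf("unknown plot kind '%s'", kind))

  is_clustering <- !is.null(ws$clusterings[[item_id]])
  if (is_clustering && kind != "scatter")
    cyto_applicability_error(sprintf(
      "plot kind '%s' applies to datasets only, not clusterings", kind))

  if (is_clustering) {
    cl <- ws_clustering(ws, item_id)
    node <- ws_node(ws, cl$dataset_id)
    colors <- cluster_palette(cl$k)[cl$display_order][cl$assignment]
  } else {
    node <- ws_node(ws, item_id)
    colors <- "#1F77B4"
  }
  tr <- get_transform(transform)
  n_chan <- length(node$data$channels)
  if (kind %in% c("scatter", "heatmap") &&
      (length(channels) != 2 || any(channels < 1) || any(channels > n_chan)))
    cyto_value_error("scatter/heatmap need two valid channel indices")
  if (kind == "histogram" &&
      (length(channels) < 1 || channels[1] < 1 || channels[1] > n_chan))
    cyto_value_error("histogram needs one valid channel index")

  open_device(path, format, width, height)
  on.exit(grDevices.dev_off_safe(), add = TRUE)
  ev <- node$data$events
  ch <- node$data$channels
  if (kind == "scatter") {
    x <- tr$forward(ev[, channels[1]]); y <- tr$forward(ev[, channels[2]])
    graphics::plot(x, y, pch = 16, cex = 0.4, col = colors,
                   xlab = ch[channels[1]], ylab = ch[channels[2]],
                   main = node$label)
  } else if (kind == "histogram") {
    graphics::hist(tr$forward(ev[, channels[1]]), breaks = 50,
                   col = "#1F77B4", border = NA,
                   xlab = ch[channels[1]], main = node$label)
  } else if (kind == "heatmap") {
    x <- tr$forward(ev[, channels[1]]); y <- tr$forward(ev[, channels[2]])
    nb <- 64L
    xb <- seq(min(x), max(x), length.out = nb + 1L)
    yb <- seq(min(y), max(y), length.out = nb + 1L)
    counts <- table(cut(x, xb, include.lowest = TRUE),
                    cut(y, yb, include.lowest = TRUE))
    graphics::image(xb, yb, log1p(unclass(counts)),
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = ch[channels[1]], ylab = ch[channels[2]],
                    main = node$label)
  } else {
    idx <- analysis_channels(ws, node$id)
    graphics::boxplot(lapply(idx, function(j) tr$forward(ev[, j])),
                      names = ch[idx], las = 2, col = "#AEC7E8",
                      main = node$label)
  }
  invisible(path)
}

open_device <- function(path, format, width, height) {
  switch(format,
    png = grDevices::png(path, width = width * 96, height = height * 96,
                         res = 96),
    pdf = grDevices::pdf(path, width = width, height = height),
    ps = grDevices::postscript(path, width = width, height = height,
                               paper = "special", horizontal = FALSE),
    eps = grDevices::postscript(path, width = width, height = height,
                                paper = "special", horizontal = FALSE,
                                onefile = FALSE),
    svg = grDevices::svg(path, width = width, height = height)
  )
}

grDevices.dev_off_safe <- function() {
  if (grDevices::dev.cur() > 1) grDevices::dev.off()
}

#' Render a grid of panels to one figure file
#'
#' Composes several plot specifications (as stored in a figure group) into a
#' single multi-panel figure, filling a grid with a fixed number of columns
#' (default 2).
#'
#' @param ws a workspace.
#' @param plot_specs list of lists with `node`, `kind`, `channels` and
#'   optional `transform`.
#' @param path output path.
#' @param format figure format as in [export_plot()].
#' @param ncol number of grid columns.
#' @return `path`, invisibly.
#' @export
export_plot_grid <- function(ws, plot_specs, path, format = NULL, ncol = 2L) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% c("png", "pdf", "ps", "eps", "svg"))
    cyto_value_error(sprintf("unsupported figure format '%s'", format))
  n <- length(plot_specs)
  if (n == 0) cyto_value_error("no plot specifications given")
  nrow <- ceiling(n / ncol)
  open_device(path, format, width = 5 * ncol, height = 4 * nrow)
  on.exit(grDevices.dev_off_safe(), add = TRUE)
  graphics::par(mfrow = c(nrow, ncol))
  for (spec in plot_specs) {
    draw_panel(ws, spec$node, spec$kind %||% "scatter",
               as.integer(unlist(spec$channels %||% c(1L, 2L))),
               spec$transform %||% "linear")
  }
  invisible(path)
}

# panel drawing on the current device (shared by export_plot_grid)
draw_panel <- function(ws, item_id, kind, channels, transform) {
  is_clustering <- !is.null(ws$clusterings[[item_id]])
  if (is_clustering && kind != "scatter")
    cyto_applicability_error(sprintf(
      "plot kind '%s' applies to datasets only, not clusterings", kind))
  if (is_clustering) {
    cl <- ws_clustering(ws, item_id)
    node <- ws_node(ws, cl$dataset_id)
    colors <- cluster_palette(cl$k)[cl$display_order][cl$assignment]
  } else {
    node <- ws_node(ws, item_id)
    colors <- "#1F77B4"
  }
  tr <- get_transform(transform)
  ev <- node$data$events; ch <- node$data$channels
  if (kind == "scatter") {
    graphics::plot(tr$forward(ev[, channels[1]]), tr$forward(ev[, channels[2]]),
                   pch = 16, cex = 0.4, col = colors,
                   xlab = ch[channels[1]], ylab = ch[channels[2]],
                   main = node$label)
  } else if (kind == "histogram") {
    graphics::hist(tr$forward(ev[, channels[1]]), breaks = 50,
                   col = "#1F77B4", border = NA,
                   xlab = ch[channels[1]], main = node$label)
  } else {
    cyto_value_error(sprintf("plot kind '%s' not supported in grids", kind))
  }
}
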