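#' Data transforms
#'
#' Fluorescence intensities span several decades and are routinely viewed and
#' clustered in a compressed space. A transform here is a named, parameterized
#' strictly increasing map with a forward and an inverse function. Built-ins:
#'
#' * `linear` — identity.
#' * `log` — `y = log10(max(x, 1))`; values at or below 1 are clamped to 0.
#'   This is the transform applied before automated population discovery.
#' * `hyperlog` — linear near zero, logarithmic at large magnitude, defined
#'   through the root function `EH(y) = 10^(y d / r) + b (y d / r) - 1` for
#'   `y >= 0` and its odd extension for `y < 0`. The forward (display)
#'   transform inverts `EH` numerically by bisection.
#'
#' @param name transform name (`"linear"`, `"log"`, `"hyperlog"`, or the name
#'   of a registered transformation plugin).
#' @param params named list of parameters (hyperlog: `b` linear coefficient,
#'   `d` decades, `r` top of scale).
#' @param registry optional plugin registry from [discover_plugins()]; its
#'   `transformations` category is searched after the built-ins.
#' @return An object of class `cyto_transform` with elements `name`, `params`,
#'   `forward` and `inverse` (both vectorized numeric maps).
#' @export
get_transform <- function(name, params = list(), registry = NULL) {
  if (name == "linear") {
    return(new_transform("linear", list(), identity, identity))
  }
  if (name == "log") {
    return(new_transform(
      "log", list(),
      forward = function(x) log10(pmax(x, 1)),
      inverse = function(y) 10^y
    ))
  }
  if (name == "hyperlog") {
    p <- utils::modifyList(list(b = 100, d = 4, r = 262144), params)
    return(hyperlog_transform(b = p$b, d = p$d, r = p$r))
  }
  if (!is.null(registry)) {
    spec <- tryCatch(plugin_resolve(registry, "transformations", name),
                     cytopop_key_error = function(e) NULL)
    if (!is.null(spec))
      return(new_transform(name, spec$params %||% list(),
                           spec$forward, spec$inverse))
  }
  cyto_key_error(sprintf("unknown transform '%s'", name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_transform <- function(name, params, forward, inverse) {
  structure(list(name = name, params = params,
                 forward = forward, inverse = inverse),
            class = "cyto_transform")
}

#' @export
print.cyto_transform <- function(x, ...) {
  p <- if (length(x$params))
    paste0("(", paste(names(x$params), unlist(x$params), sep = " = ",
                      collapse = ", "), ")")
  else ""
  cat(sprintf("<cyto_transform> %s%s\n", x$name, p))
  invisible(x)
}

#' Clamped log10 transform
#'
#' `y = log10(max(x, 1))`: values at or below 1 map to 0. The clamp floor is
#' a constant (not the data minimum) so the transform is deterministic and
#' independent of the dataset.
#'
#' @param values numeric vector or matrix.
#' @return Transformed values, same shape.
#' @export
log_transform <- function(values) log10(pmax(values, 1))

#' Hyperlog root function EH
#'
#' Evaluates `EH(y) = 10^(y d / r) + b (y d / r) - 1` for `y >= 0` and
#' `-EH(-y)` for `y < 0`: an odd, strictly increasing map from display
#' coordinates back to raw intensity. `EH(0) = 0`.
#'
#' @param y numeric vector of display-space values.
#' @param b linear coefficient (> 0); larger `b` widens the linear region.
#' @param d number of decades covered (> 0).
#' @param r top-of-scale display value (> 0).
#' @return Raw-intensity values, same length as `y`.
#' @export
hyperlog_root <- function(y, b = 100, d = 4, r = 262144) {
  if (b <= 0 || d <= 0 || r <= 0)
    cyto_value_error("hyperlog parameters b, d, r must be positive")
  eh <- function(z) 10^(z * d / r) + b * (z * d / r) - 1
  sign(y) * eh(abs(y))
}

#' Hyperlog forward (display) transform
#'
#' Inverts [hyperlog_root()] numerically: for each `x`, finds the `y` in
#' `[-r, r]` with `EH(y) = x` by bisection (absolute tolerance 1e-10, at most
#' 200 iterations — robust at interactive scale).
#'
#' @inheritParams hyperlog_root
#' @param x numeric vector of raw-intensity values; must lie within
#'   `[-EH(r), EH(r)]`.
#' @return Display-space values, same length as `x`.
#' @export
hyperlog_forward <- function(x, b = 100, d = 4, r = 262144) {
  if (b <= 0 || d <= 0 || r <= 0)
    cyto_value_error("hyperlog parameters b, d, r must be positive")
  vapply(x, function(xi) {
    lo <- -r; hi <- r
    flo <- hyperlog_root(lo, b, d, r) - xi
    fhi <- hyperlog_root(hi, b, d, r) - xi
    if (flo == 0) return(lo)
    if (fhi == 0) return(hi)
    if (flo * fhi > 0)
      cyto_convergence_error(sprintf(
        "value %g outside the invertible range [-EH(r), EH(r)]", xi))
    for (i in seq_len(200)) {
      mid <- (lo + hi) / 2
      fmid <- hyperlog_root(mid, b, d, r) - xi
      if (fmid == 0 || (hi - lo) / 2 < 1e-10) return(mid)
      if (flo * fmid < 0) hi <- mid else { lo <- mid; flo <- fmid }
    }
    (lo + hi) / 2
  }, numeric(1))
}

hyperlog_transform <- function(b = 100, d = 4, r = 262144) {
  new_transform(
    "hyperlog", list(b = b, d = d, r = r),
    forward = function(x) hyperlog_forward(x, b, d, r),
    inverse = function(y) hyperlog_root(y, b, d, r)
  )
}

# Apply a transform to selected columns of a plain matrix.
apply_transform_matrix <- function(X, transform, channels = NULL) {
  stopifnot(inherits(transform, "cyto_transform"))
  if (is.null(channels)) channels <- seq_len(ncol(X))
  Y <- X
  for (j in channels) Y[, j] <- transform$forward(X[, j])
  Y
}

#' Apply a transform to a dataset's analysis channels
#'
#' Returns the transformed analysis matrix; the raw event data on the node
#' are retained untouched, so transforms are always recomputable and I/O
#' stays lossless.
#'
#' @param ws a workspace.
#' @param id dataset node id.
#' @param transform a `cyto_transform` or a transform name resolved via
#'   [get_transform()].
#' @param channels indices *within the analysis matrix* to transform;
#'   `NULL` transforms every included channel. Untouched channels pass
#'   through unchanged.
#' @param params,registry passed to [get_transform()] when `transform` is a
#'   name.
#' @return Transformed analysis matrix.
#' @export
apply_transform <- function(ws, id, transform, channels = NULL,
                            params = list(), registry = NULL) {
  if (is.character(transform))
    transform <- get_transform(transform, params, registry)
  X <- analysis_matrix(ws, id)
  if (!is.null(channels) &&
      (length(channels) == 0 || min(channels) < 1 || max(channels) > ncol(X)))
    cyto_value_error("channel index out of range for the analysis matrix")
  apply_transform_matrix(X, transform, channels)
}
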