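#' Synthetic cytometry mixtures
#'
#' Generates multichannel event data with known cluster structure for tests
#' and demonstrations: a scatter pair (FSC, SSC) drawn from per-component
#' normal distributions, fluorescence channels drawn from per-component
#' lognormal distributions (the heavy right tails typical of fluorescence
#' intensities), and an optional monotone Time ramp to exercise channel
#' exclusion. Ground-truth component labels are returned alongside the
#' events. Generation is fully deterministic given the spec's seed.
#'
#' @name synthetic-data
NULL

#' Specify a synthetic mixture
#'
#' Component locations are given on the latent scale: raw units for the
#' scatter channels, log10 units for the fluorescence channels (an event's
#' fluorescence value is `10^z` with `z` normal). The pairwise separation
#' between two components is the Mahalanobis-like distance
#' `sqrt(sum_c (mu_ic - mu_jc)^2 / (0.5 (sd_ic^2 + sd_jc^2)))` over those
#' latent parameters, in SD units; every pair must meet `separation`.
#'
#' @param n_events number of events.
#' @param k number of components.
#' @param n_channels number of measurement channels (>= 2: FSC, SSC, then
#'   fluorescence channels FL1, FL2, ...).
#' @param weights mixing weights (default equal), nonnegative, summing to 1.
#' @param means optional `k x n_channels` matrix of latent component means;
#'   `NULL` places components at random until `separation` is met.
#' @param sds optional `k x n_channels` matrix of latent SDs.
#' @param separation minimum pairwise component separation in SD units
#'   (default 8, a well-separated regime).
#' @param include_time append a monotone "Time" ramp channel (default TRUE).
#' @param seed integer seed driving all randomness.
#' @return An object of class `cyto_mixture_spec`.
#' @export
mixture_spec <- function(n_events, k, n_channels = 4, weights = NULL,
                         means = NULL, sds = NULL, separation = 8,
                         include_time = TRUE, seed = 1L) {
  if (n_channels < 2) cyto_value_error("need at least FSC and SSC channels")
  if (k < 1) cyto_value_error("k must be at least 1")
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-12)
    cyto_value_error("weights must be k nonnegative values summing to 1")

  n_fluor <- n_channels - 2L
  channels <- c("FSC", "SSC",
                if (n_fluor > 0) paste0("FL", seq_len(n_fluor)))
  if (is.null(sds)) {
    # scatter SDs in raw units; fluorescence SDs in log10 (decade) units
    sds <- cbind(matrix(6000, k, 2),
                 matrix(0.06, k, n_fluor))
  }
  if (is.null(means)) {
    means <- with_seed(seed + 1L, place_components(k, n_fluor, sds, separation))
  }
  means <- as.matrix(means); sds <- as.matrix(sds)
  if (!all(dim(means) == c(k, n_channels)) ||
      !all(dim(sds) == c(k, n_channels)))
    cyto_value_error("means and sds must be k x n_channels matrices")
  if (any(sds <= 0)) cyto_value_error("all SDs must be positive")
  achieved <- min_pairwise_separation(means, sds)
  if (k > 1 && achieved < separation)
    cyto_generation_error(sprintf(
      "achieved separation %.2f below the declared minimum %.2f",
      achieved, separation))
  structure(list(
    n_events = as.integer(n_events), k = as.integer(k),
    n_channels = as.integer(n_channels), channels = channels,
    weights = weights, means = means, sds = sds,
    separation = separation, achieved_separation = achieved,
    include_time = include_time, seed = as.integer(seed)
  ), class = "cyto_mixture_spec")
}

# run expr under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

min_pairwise_separation <- function(means, sds) {
  k <- nrow(means)
  if (k < 2) return(Inf)
  best <- Inf
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      d <- sqrt(sum((means[i, ] - means[j, ])^2 /
                      (0.5 * (sds[i, ]^2 + sds[j, ]^2))))
      best <- min(best, d)
    }
  }
  best
}

# rejection placement: draw component locations until the separation holds
place_components <- function(k, n_fluor, sds, separation) {
  for (attempt in seq_len(100)) {
    scatter <- matrix(stats::runif(k * 2, 0.2 * 262144, 0.8 * 262144), k, 2)
    fluor <- if (n_fluor > 0)
      matrix(stats::runif(k * n_fluor, 1.2, 4.6), k, n_fluor)
    else matrix(0, k, 0)
    means <- cbind(scatter, fluor)
    if (min_pairwise_separation(means, sds) >= separation) return(means)
  }
  cyto_generation_error(sprintf(
    "could not place %d components at separation %.1f in 100 attempts",
    k, separation))
}

#' Generate a synthetic dataset with ground-truth labels
#'
#' @param spec a [mixture_spec()].
#' @return A list with `dataset` (an [fcs_dataset]) and `labels` (integer
#'   component index per event, 1-based).
#' @export
generate_mixture <- function(spec) {
  stopifnot(inherits(spec, "cyto_mixture_spec"))
  with_seed(spec$seed, {
    labels <- sample.int(spec$k, spec$n_events, replace = TRUE,
                         prob = spec$weights)
    n_chan <- spec$n_channels
    events <- matrix(0, spec$n_events, n_chan)
    for (c in seq_len(n_chan)) {
      z <- stats::rnorm(spec$n_events,
                        mean = spec$means[labels, c],
                        sd = spec$sds[labels, c])
      events[, c] <- if (c <= 2) pmax(z, 0) else 10^z
    }
    channels <- spec$channels
    if (spec$include_time) {
      events <- cbind(events, seq(0, by = 0.01, length.out = spec$n_events))
      channels <- c(channels, "Time")
    }
    list(dataset = fcs_dataset(events, channels), labels = labels)
  })
}

#' Write a synthetic mixture as on-disk fixtures
#'
#' Serializes one generated mixture as a valid FCS 3.0 file, an equivalent
#' CSV event table, and a plain-text ground-truth label column (one label per
#' row, aligned with the event rows).
#'
#' @param spec a [mixture_spec()].
#' @param dir output directory (created if needed).
#' @param name base file name (default "mixture").
#' @return Named list of the three paths (`fcs`, `csv`, `labels`).
#' @export
write_fixture <- function(spec, dir, name = "mixture") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- generate_mixture(spec)
  paths <- list(
    fcs = file.path(dir, paste0(name, ".fcs")),
    csv = file.path(dir, paste0(name, ".csv")),
    labels = file.path(dir, paste0(name, "-labels.txt"))
  )
  write_fcs(gen$dataset, paths$fcs, datatype = "D")
  write_events_csv(gen$dataset, paths$csv)
  writeLines(as.character(gen$labels), paths$labels)
  paths
}
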