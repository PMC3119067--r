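---
title: "Automated population discovery in multicolor flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated population discovery in multicolor flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytopop)
```

## The problem

A flow cytometer records, for every cell (event) that crosses its laser
interrogation point, a vector of light intensities: forward scatter (FSC,
roughly cell size), side scatter (SSC, granularity), and one fluorescence
value per dye. Classical analysis isolates populations by *manual gating*:
drawing regions on two-dimensional plots, one channel pair at a time. The
number of distinct channel pairs grows as $\binom{N}{2}$, so a 20-color
experiment needs 190 plots and a 100-channel mass-cytometry run close to
5,000 — and no stack of axis-aligned 2-D gates can, in general, separate
populations whose boundaries are not aligned with the measured axes.

`cytopop` is a headless toolkit for this setting: it reads standard FCS 3.0
and CSV event files, discovers populations automatically in the full
N-dimensional space, keeps every derived object (child datasets, clusterings,
figures) in a reproducible workspace tree, and persists the whole analysis as
a portable two-file bundle.

## The discovery algorithm

`discover_populations()` implements an over-clustering strategy with
shape-based merging. Given a target number of populations $K$:

1. **Transform.** All channels included in analysis are passed through a
   clamped log transform, $y = \log_{10}\max(x, 1)$. Fluorescence
   intensities are approximately log-normally distributed within a
   population, so clusters become compact and roughly spherical in log
   space. The transform is a parameter (`transform = "log"`), and the clamp
   floor is the constant 1 rather than a data quantile so the map never
   depends on the dataset.

2. **Over-seed.** $m = 10K$ initial centers (capped at a tenth of the event
   count) are placed *deterministically* by maximin/farthest-point
   traversal: the first seed is the event farthest from the grand centroid;
   each next seed is the event farthest from its nearest chosen seed, ties
   always resolving to the lowest row index. Deterministic seeding is what
   makes the whole pipeline bitwise reproducible — there is no random draw
   anywhere downstream.

3. **k-means.** Standard Lloyd iterations (Euclidean distance, centers
   recomputed as cluster means) run until the largest center movement falls
   below $10^{-6}$ or 100 iterations. A center that loses all its events is
   dropped. Over-seeding means each true population is typically covered by
   several small k-means clusters; the burden of getting $K$ right is moved
   to the merge step.

4. **Shape-based merging.** Each cluster's *shape* is its per-channel mean
   $\mu$ and standard deviation $\sigma$ in transformed space. The distance
   between two shapes is a symmetric, diagonal-covariance Mahalanobis-type
   statistic
   $$D(a,b) \;=\; \sqrt{\sum_{d}\frac{(\mu_{ad}-\mu_{bd})^2}
   {\sigma_{ad}^2+\sigma_{bd}^2}},$$
   which counts mean separation in units of the clusters' own spread, so a
   wide and a narrow cluster at the same location merge readily while two
   tight clusters a fixed distance apart do not. The closest pair is merged,
   shapes are recomputed, and the step repeats until $K$ clusters remain.
   Ties break to the lexicographically smallest index pair. Finally clusters
   are renumbered by descending size, so cluster 1 is always the largest
   population and colors are stable under resampling.

Standard deviations are floored at $10^{-6}$ (transformed units) so that
singleton clusters — which have no empirical spread — never divide by zero.

## Matching clusterings across runs

Even a deterministic pipeline numbers clusters differently across *related*
datasets (or different targets), which scrambles colors in side-by-side
figures. `reorder_to_reference()` computes the full matrix of shape
distances between a reference and a target clustering and solves the optimal
one-to-one assignment (a Hungarian shortest-augmenting-path solver, exact in
$O(k^3)$) rather than greedy nearest-first matching: the optimal assignment
is deterministic and independent of cluster numbering, whereas greedy
matching can cascade a single early mistake. Matched target clusters adopt
their reference partner's display position; novel clusters are appended in
their original relative order. Only the display (color) order changes — the
assignment vector is never touched.

## Transforms

Besides `linear` and `log`, the package ships a hyperlog transform: linear
near zero (where log is undefined or wildly magnified and compensated data
can be negative) and logarithmic at large magnitude. It is defined through
its root function
$$EH(y) = 10^{y d / r} + b\,\tfrac{y d}{r} - 1 \quad (y \ge 0),
\qquad EH(-y) = -EH(y),$$
with defaults $b = 100$ (width of the linear region), $d = 4$ decades and
$r = 262{,}144$ ($2^{18}$, a common full-scale value). The forward display
transform inverts $EH$ by bisection on $[-r, r]$ to $10^{-10}$ absolute in
at most 200 iterations — robustness was preferred over speed, since the
transform is applied at interactive scale. Values outside
$[-EH(r), EH(r)]$ raise a convergence error rather than extrapolating.

Whether a pipeline should log-transform *all* analysis channels or only the
fluorescence ones is genuinely open (scatter channels are often displayed
linearly); the default transforms every included channel, and excluding
scatter channels from transformation is achieved by passing explicit channel
indices to `apply_transform()`.

## File formats and the data model

The FCS 3.0 reader supports list mode (`$MODE L`) with `$DATATYPE` `I`
(uniform `$PnB` of 8/16/32 bits), `F` and `D`, byte orders `1,2,3,4` and
`4,3,2,1`, delimiter escaping in the TEXT segment, and the
`$BEGINDATA`/`$ENDDATA` fallback when the header offsets overflow their
8-character fields. Two deliberate choices keep I/O lossless: `$PnE`
amplification is *not* applied at read time (scaling belongs to the
transform layer), and `write_fcs()` defaults to float64 so that
`read_fcs(write_fcs(ds))` is bitwise exact; files read as float32 keep their
`$DATATYPE` and round-trip bitwise as float32. Mixed per-parameter integer
widths are rejected rather than guessed. All indices are 1-based, following
R convention.

Datasets live in a workspace tree. Channels can be renamed, reordered
(exclusion masks follow by name) and excluded from analysis — a Time ramp is
the canonical exclusion. `extract_clusters()` copies the events of selected
clusters into an independent child dataset rather than a view: a child can
be re-transformed, re-clustered and exported without any aliasing back to
its parent.

Sessions persist as `<stem>.find` (JSON metadata: tree structure, channel
names, keywords, clustering parameters, display orders, figure groups, and
an offset index) plus `<stem>.bin` (a flat little-endian binary store:
events as float64, assignments as int32). Fixed endianness makes bundles
machine-portable; the format is versioned and both files are written to
temporaries and renamed into place, so overwrites are atomic.

## The synthetic-data generator

Tests and demonstrations run on generated mixtures (`mixture_spec()`,
`generate_mixture()`): scatter channels are per-component normal,
fluorescence channels per-component lognormal (location and scale given in
log10 units), and a monotone Time ramp is appended by default. Component
locations are placed by rejection sampling until every pair meets the
declared minimum separation, measured as
$\sqrt{\sum_c (\mu_{ic}-\mu_{jc})^2 / \tfrac12(\sigma_{ic}^2+\sigma_{jc}^2)}$
on the latent (normal / log-normal log-scale) parameters; 100 failed
attempts raise an error rather than silently relaxing the requirement.
Defaults are chosen to be cytometry-realistic: fluorescence log-means in
1.2–4.6 decades with 0.06-decade spread, scatter means in the middle 60% of
a $2^{18}$ scale with SD 6,000, equal weights, and a separation of 8 SD —
a well-separated regime in which recovery should be essentially perfect,
which is what the recovery checks assert (adjusted Rand index $\ge 0.99$
at the true $K$ for $K \in \{2,\dots,5\}$, $n = 2000$).

What the generator does *not* emulate is important for interpreting green
tests: real data carry spectral spillover between channels, debris and
doublets, rain between populations, and populations of very unequal size
and overlapping shape. Passing the recovery checks shows the pipeline is
correct on its stated model, not that it will resolve heavily overlapping
populations in real experiments — for those, the target $K$, the transform,
and channel exclusion remain scientific choices.

## Plugins and the command line

Four plugin categories mirror the extension points of the analysis flow:
`transformations` (forward/inverse pairs usable wherever built-ins are),
`io` (readers/writers for additional formats), `analysis` (population
discovery algorithms), and `graphing` (renderers declaring applicability to
datasets, clusterings, or both — a front end uses that declaration to build
item menus). Installation is by convention: drop an `.R` file defining a
`plugin` list into the matching subdirectory. Each candidate is sourced in
an isolated environment; a broken file is reported and skipped without
affecting other plugins or core state.

The CLI (`cyto_main()`, wrapped by the installed `inst/cli/cytopop` script)
is a thin veneer: every subcommand calls the corresponding library function,
so CLI behavior and library behavior cannot drift apart, and tests invoke
both. Figures export to PNG, PDF, PostScript, EPS and SVG; multi-panel
figures are composed on a fixed-column grid (default 2).

## Numerical and design notes

* Distances are computed as squared Euclidean throughout seeding and
  k-means (monotone in the true distance, cheaper, and immune to `sqrt`
  rounding at ties); assignments break ties to the lowest index.
* `merge_to_target()` recomputes all shapes after every merge rather than
  updating incrementally — quadratic in the seed count, but the seed count
  is small (tens) and the simple form is immune to drift.
* The Hungarian solver pads rectangular problems to square with a constant
  column: the constant cancels in the minimization, so the matched-pair
  total is exactly optimal for the rectangular problem.
* Test and check problem sizes (up to 2,000 events, 5 components, 50-seed
  over-clustering) were chosen so the full suite exercises every path in
  seconds at desk scale; the algorithms themselves are vectorized and run
  comfortably at $10^5$–$10^6$ events.

## Known limitations

* No compensation/spillover handling (`$SPILLOVER` is preserved as an
  opaque keyword but not applied).
* FCS 2.0 and 3.1 dialects, correlated-histogram mode, and the ANALYSIS
  segment are out of scope; integer data must use a uniform bit width.
* The shape statistic is a diagonal-covariance approximation; strongly
  correlated, elongated populations can merge or match imperfectly. The
  statistic is isolated in `shape_distance()` as the single point to swap
  for a full-covariance variant.
* Logicle/arcsinh transforms are left to transformation plugins (the test
  suite ships an arcsinh plugin as the worked example).
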