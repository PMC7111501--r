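---
title: "Building clustered heat maps with chmforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building clustered heat maps with chmforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chmforge)
```

## What this package does

A clustered heat map (CHM) is the workhorse graphic of genome-scale profiling:
a numeric matrix whose rows and columns have been reordered by agglomerative
hierarchical clustering, drawn as a color grid with flanking dendrograms and
annotation ("covariate") bars. Producing a good one is rarely linear — the
matrix is thresholded, log-transformed, centered and filtered, clustering
options are revisited, colors and breakpoints are adjusted — and the final
figure is only trustworthy if that whole path can be reproduced.

chmforge implements this workflow as a scriptable pipeline with provenance as
a first-class object: every option that affects any output byte is recorded in
a creation log, and `replay()` rebuilds a byte-identical archive from the
original input plus that log.

## The data model

`labeled_matrix` keeps the numeric grid together with ordered row and column
label vectors. Labels live outside the matrix `dimnames` deliberately:
uploaded matrices routinely carry duplicated sample columns, and the pipeline
must be able to represent them before `dedupe_labels()` repairs them. Cells
are either finite doubles or missing (`NA`). Tokens that fail to parse as
numbers fall into two classes: the recognized missing vocabulary (`""`, `NA`,
`NaN`, `null`, case-insensitive) and everything else, which also becomes
missing but is counted separately as *invalid* so `summarize_matrix()` can
report data-quality problems.

`matrix_session` preserves the untouched original next to the working copy and
an ordered transform history. Undo is implemented literally as "restore the
original and re-apply a prefix of the history", which makes
`working == replay(original, history)` an invariant rather than a convention,
and makes the history the natural serialization of the matrix state.

## Transform semantics

The transform vocabulary is small and each choice has a reason:

* **Threshold** (`threshold_na`): "below the cutoff" means *strictly* less
  than; a value equal to the cutoff survives. This matters at noise floors
  like `1e-5`, where instrument output frequently sits exactly at the floor.
* **Log** (`log_transform`): non-positive cells become missing rather than
  raising an error. A hard error here would be hostile in an iterative
  workflow; the expectation is that a later missing-data filter removes rows
  the log ruined, and the summary flags make the damage visible.
* **Mean centering**: per-vector means are computed over non-missing cells
  only; an all-missing vector passes through. After the step every vector's
  non-missing mean is zero to within 1e-12 (a property the tests enforce).
* **Missing-data filter**: a vector's missing percentage is computed against
  the *full* axis length, not the observed count, and removal requires the
  percentage to *strictly exceed* the limit — a row at exactly 50% missing
  survives a 50% filter.
* **Standard-deviation filter**: sample SD with denominator `n - 1` over
  non-missing cells; a vector with fewer than two observations has SD defined
  as 0 so it sorts last. Ties at the keep boundary go to the earlier vector,
  and survivors keep their original relative order, so the filter is fully
  deterministic.
* **Correlation**: Pearson over pairwise-complete observations; a
  zero-variance pair gives a missing cell with a warning rather than an
  error, consistent with the forgiving flow above.
* **Histogram**: 10 equal-width bins spanning the observed range by default;
  all-equal data collapses to a single bin so the count conservation
  invariant (bin counts sum to non-missing cells) always holds.

Each step serializes to one text line (`action<TAB>key=value;...`) with
round-trip numeric formatting, so a parsed history replays cell-for-cell
identically — this line format is also the transform payload of the creation
log.

## Clustering

`distance_matrix()` supports euclidean, manhattan and correlation
(`1 - r`) metrics. Missing values are handled by pairwise-complete positions
with proportional rescaling: for a pair sharing `k` of `m` positions the
partial sum is scaled by `m/k` before the final root (the same convention as
classical `dist()`). A pair sharing no positions is an error — there is no
defensible distance to invent.

`cluster_axis()` performs agglomerative clustering with ward, complete,
average or single linkage. "ward" uses ward.D2 semantics — the
squared-distance Lance–Williams update applied to unsquared Euclidean input —
which is the convention of the R clustering ecosystem this tool family grew
out of. The merge table uses the standard convention (negative entries are
leaves, positive entries earlier merges). The test suite checks merge heights
and partitions against a naive O(n³) re-implementation of the agglomeration
written directly from the update formulas.

Leaf ordering is made deterministic by a single rule: at every internal node
the child subtree containing the smallest original index is drawn on the
left. No optimal-leaf-ordering (seriation) is attempted; the ordering is a
convention, not an optimization, and determinism is the property we need for
reproducible archives. Axis ordering can also be `original` (identity) or
`random`; random orders take an explicit seed, run under a locally scoped RNG
(the caller's RNG state is untouched), and the seed is recorded in the log so
a "randomized" map is still exactly replayable.

The clustering stage enforces a size gate: rows + columns must not exceed
5,000 (configurable), e.g. 1,000 samples by 4,000 genes. The intent is that
larger uploads are reduced by the filters first; `summarize_matrix()` flags a
matrix that is still over the gate.

`cut_top_branches(d, k)` removes the `k - 1` highest merges and labels the
resulting subtrees `"Cluster 1" .. "Cluster k"` in order of first appearance
along the leaf order, i.e. left to right on the drawn map — so cluster
numbering matches what a reader sees. The result is an ordinary discrete
covariate. Cutting at `k` then `k + 1` always refines the partition.

## Covariates and palettes

Covariate files are two-column text (label, value; tab or comma). Discrete
and continuous kinds are the user's declaration, not an inference — except
for covariates embedded in the uploaded matrix, where an all-numeric
row/column is *proposed* as continuous and the flag can be overridden. For
continuous covariates a header line is auto-detected as a first line whose
second field is not a number; for discrete covariates no such rule exists
(any string is a valid category), but a header label that does not match any
matrix label drops out through the restriction rule anyway. Entries whose
labels are not in the matrix are dropped with a warning; matrix labels absent
from the file are missing and render in a dedicated missing color (white by
default) that is never used for a real category.

Default discrete colors cycle a palette in order of first appearance along
the axis; the bundled default is the 8-color Okabe–Ito colorblind-safe
palette, and palettes live in a small local JSON store. Continuous covariates
default to a two-point ramp spanning the observed min..max (a degenerate
constant covariate widens its span by 1 to keep breakpoints strictly
increasing).

## Color maps and formatting

A `color_map` is a strictly increasing breakpoint vector with one color per
breakpoint: values at a breakpoint take exactly that color, values between
breakpoints interpolate linearly per RGB channel, values outside clamp to the
end colors, and missing cells take the map's missing color (`#CCCCCC` for the
body by default — distinct from the white used in covariate bars and gap
strips). The default body map pins the working matrix's 5th percentile,
median and 95th percentile to blue–white–red; percentile pinning keeps the
visible dynamic range stable under outliers. Gaps partition the display order
into blocks separated by blank strips of a fixed 2-cell width; they change
layout only, never values or order.

## The archive and determinism

`write_ngchm()` serializes a finished build as a zip archive anchored by a
`heatmapProperties.json` options document (versioned schema, currently
`"1.0"`): the complete option set, both axis permutations, dendrogram merge
tables/heights/leaf orders, covariate metadata and the file manifest.
Alongside it sit the working matrix in display order (tab-delimited), one
Newick file per clustered axis, one payload file per covariate bar, and the
canonical creation log. Dendrograms are stored twice on purpose: Newick for
interoperability with tree tooling, and the merge table in the properties
document so reading the archive back is lossless without a Newick parser.

Determinism choices, because byte-identity is a stated contract:

* archive entries are written in sorted name order with all timestamps forced
  to a fixed epoch (2020-01-01 UTC);
* doubles in the properties document are printed with 17 significant digits,
  so every double survives the text round trip bit-exactly;
* the matrix payload uses shortest-round-trip decimal formatting (15
  significant digits, widened to 17 where needed);
* the embedded creation log is the canonical, timestamp-free form. Wall-clock
  timestamps live only in session logs outside the archive; if they were
  embedded, two otherwise identical builds could never be byte-identical and
  replay could never reproduce the original file.

`read_ngchm()` reconstructs the build state (the pre-transform original is
deliberately not part of the archive; the original input plus the log is the
reconstruction path) and preserves unknown extra entries opaquely, so
archives annotated by other tools survive a read/write cycle.

## Rendering

`render_pdf()` produces three pages: summary (whole matrix with dendrograms,
covariate bars, gaps and top-item callouts), detail (an explicit zoom window,
defaulting to the top-left 50×50 display cells — the interactive zoom of a
GUI replaced by a parameter), and a final legends/metadata page. All cell
colors come from an intermediate raster whose entries are exactly
`map_color()` of the ordered working matrix; tests assert on that raster, not
on PDF bytes, since PDF containers embed creation timestamps. Labels are
truncated with an ellipsis beyond a configurable character budget; compact
dendrogram display square-roots the heights to keep deep trees readable in a
fixed-depth panel.

## The synthetic data generator

`simulate_expression_matrix()` generates what the pipeline is pointed at in
practice: positive log-normal values (baseline `exp(1.5 + N(0, 1))`, a bulk
expression-like dynamic range), planted row/column cluster blocks produced by
a `delta = 2` log-scale mean shift, 5% missing cells, 1% sub-noise-floor
values (below `1e-5`, so the threshold transform has real work), and
optionally duplicated column labels. The companion `simulate_covariates()`
and `write_fixture_files()` materialize matching covariate files and can
inject invalid tokens into the written matrix text.

The default 2,000 × 100 shape mirrors the documented use case (genes by
samples, reduced to the 500 most variable rows). What the generator does
*not* emulate: batch effects, heavy-tailed outliers, count-specific
mean–variance relationships, or within-cluster correlation structure beyond
the block mean shifts. Passing tests therefore demonstrate the pipeline's
mechanics (filters, ordering, serialization, replay) and cluster recovery
under clean separation — they are not a claim about clustering performance on
messy real cohorts.

## Problem sizes and tolerances in the tests

The suite exercises the documented sizes directly: the six-step cleanup runs
on a full 2,000 × 100 matrix; the size gate is checked at 1,000 × 4,000
(accept) and 4,501 × 500 (reject); oracle-equivalence runs 100 random
matrices with up to 20 leaves across all 12 linkage × metric combinations at
a 1e-9 height tolerance; replay and round-trip checks run on complete builds
with clustered and seeded-random axes. Mean-centering is verified to 1e-12,
distances to 1e-10 against per-pair formula oracles. These sizes keep the
whole suite under half a minute while still covering every contract at its
stated scale.

## Known limitations

* The archive schema is this package's own versioned design. The container
  (zip around a properties document) follows the NG-CHM convention, but
  bit-compatibility with the production NG-CHM viewer's internal tile format is out
  of scope.
* Label link-out types are carried as free-text tags, never resolved.
* Only Pearson correlation is offered where correlation appears; the
  linkage/metric menu is fixed to the four linkages and three metrics above.
* Undo history is linear (a prefix replay), matching the builder model — there
  is no branching history.
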