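---
title: "Methods: rank-based coexpression analysis along the maize leaf gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based coexpression analysis along the maize leaf gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafcoex)
```

## The problem and the data

The growing maize leaf is a spatial time course: its base holds dividing
cells, its tip fully differentiated ones, so four zones sampled along leaf
three — basal, transitional, maturing, mature — order a developmental
gradient from youngest to oldest tissue. `leafcoex` analyses RPKM expression
profiles over these four ordered zones to ask which genes move together
along the gradient, with a focus on the maize aquaporin families (PIP1/PIP2,
TIP, NIP, SIP) and the transmembrane solute transporters (GO:0055085) whose
coordinated expression with an aquaporin suggests a functional link.

The package ships two plain-text fixtures: the published table of the 24
aquaporin isoforms with detectable expression along the gradient
(`table1_matrix()`, digit-for-digit, with below-detection cells stored as 0
plus an explicit flag), and a 33-symbol aquaporin catalogue
(`aquaporin_catalogue()`). The two isoforms ZmPIP1;3 and ZmPIP1;4 are
indistinguishable at the gene-model level (one model, GRMZM2G392975, two
symbols): the expression fixture keeps both printed rows, and
`collapse_duplicates()` merges them — refusing, rather than averaging, rows
that share an id but disagree in value.

## Profiling calls

* **Detection** — a gene is detected when its maximum RPKM over the zones
  reaches `min_detect`. The default is 1.0 RPKM, the conventional floor for
  calling a transcript present in bulk RNA-Seq; on the packaged table every
  printed isoform clears it (row maxima are all ≥ 1.72), reproducing the 24
  detected isoforms with subfamily tallies PIP = 11, TIP = 8, NIP = 5.
* **Stage-silenced calls** — `classify_stage_specific()` flags the zones in
  which a detected gene falls below `low_threshold` (default 1.0 RPKM).
  Note a terminology trap inherited from the field: a gene "specifically
  expressed in" a stage here means *low or undetected in that stage*, the
  inverse of the phrase's usual reading. The implementation follows that
  definition verbatim and the reporting vocabulary ("flagged", "low") keeps
  it unambiguous. No single threshold reproduces every stage-specific list
  in the source material, so the classifier is parameterised and reports
  rather than hard-codes.
* **Fold changes** — plain ratios of RPKM between two zones, with a
  pseudocount defaulting to 0 because the published ratios are plain
  divisions; a zero denominator yields a flagged infinity rather than an
  error.
* **Peak zones** — per-gene argmax over the gradient; ties break toward the
  younger zone and are recorded.

## The rank-based network

For every gene pair the Pearson product-moment correlation of their
profiles is computed (`stats::cor`). A profile that is flat along the
gradient has no defined correlation; such entries are marked undefined
(`NA`), excluded from ranking, and never form edges — they are not zero and
not an error. Each gene then ranks all other genes by descending
correlation. Two genes are connected iff

1. their correlation strictly exceeds `min_cc` (default 0.95), and
2. at least one of them is within the other's `max_rank` most-correlated
   neighbours (default 50).

The defaults are the published settings: a stringent correlation floor to
connect only strongly mutually coexpressed genes, with a permissive rank cap.
The rank condition is read as an OR across the two directions (the defining
sentence is asymmetric — "one gene is within the max_rank most correlated
genes of the other"); a `both_directions` mode is available, and at the
default parameters on the 23-gene aquaporin matrix the choice is inert
because the rank condition is vacuous below 50 neighbours. Ranking sorts the
raw pairwise correlations; no averaged similarity score is interposed. With
`min_cc = 0.95`, negative correlations can never contribute edges and no
absolute-value mode is offered.

**Numerical choices.** Before ranking, correlations are quantized to 12
decimals, so that values which are mathematically tied (two exact scaled
copies of a profile both have correlation 1 with a third, but floating-point
evaluation may split them in the last bit) cannot be reordered by rounding
noise; remaining ties break by ascending gene id. This makes the ranking —
and therefore the network — fully deterministic and independent of the
evaluation order of the correlation sums. The edge threshold itself uses the
unquantized correlation.

With only four zones per profile, a Pearson correlation rests on n = 4
points: it is the study's own regime, but a fragile one — single-zone noise
moves correlations a lot, and |r| > 0.95 arises by chance between unrelated
profiles at a non-negligible rate. The simulator (below) deliberately keeps
this regime so that tests see the method as it is actually used; `n_zones`
is nonetheless parameterised.

## Modules

A module is a connected component of the thresholded network with at least
`min_module_size` (default 2) members; smaller components are reported as
leftovers, never dropped. The source analysis does not name its partitioning
method; at a 0.95 correlation floor, connected components are the minimal
faithful reading, and an average-linkage hierarchical alternative
(`hclust_modules()`, cut at *k* groups on 1 − cc distance) is provided for
exploration. Modules are labelled by the strict majority of their members'
peak zones: `early` (basal/transitional), `late` (maturing/mature), or
`mixed`. On the packaged table the pipeline yields exactly two multi-gene
modules, one early and one late — the two anti-regulated aquaporin groups —
plus a handful of unassigned genes; the published 14 + 9 memberships are
emitted for comparison but are not asserted anywhere, since they depend on
an unstated partitioning method and possibly on non-aquaporin genes present
in the original genome-wide graph.

## Associations

`associate()` evaluates every query × target pair (aquaporins ×
transporters) against exactly the network edge criteria, with correlations
and neighbour ranks computed over the *full* supplied matrix — a pair's rank
reflects its genome-wide neighbourhood, not a two-gene toy problem. "Same
expression pattern" is operationalised as "would be an edge", with no
additional filter, and a passing pair is provably symmetric with the network
built on the same matrix (tested). `shared_target_report()` inverts the
table to expose transporters matched by several aquaporins at once.

## The synthetic-data generator

`synthetic_spec()` / `simulate_expression()` emulate the statistical
structure the analysis assumes, with ground-truth labels for every gene:

* two anti-correlated prototype profiles over the 4 ordered zones — early:
  monotone decreasing; late: monotone increasing — log-spaced over 2–1000,
  matching the orders-of-magnitude span of real RPKM;
* module blocks of 14 and 9 genes (the sizes of the two published aquaporin
  modules);
* 5 "transporter" genes tied to each prototype (the typical multiplicity of
  the published association tables);
* 50 uncorrelated background genes;
* multiplicative log-normal noise per cell, `2^N(0, noise_sd)` with
  `noise_sd = 0.05` by default — RPKM is positive and log-normal noise keeps
  it so while being scale-free across the profile's magnitude range; module
  genes also get a gene-specific positive log-normal scale, which leaves
  Pearson correlation untouched.

These defaults were chosen once to mirror the study's conditions and are
not tuned: at `noise_sd = 0` every within-prototype pair has correlation
exactly 1 and the whole pipeline is exactly recoverable (modules = planted
blocks, associations = planted ties, no tolerance needed); at the default
noise, recovery is scored as the adjusted Rand index between recovered
component membership and planted block over the module genes, and stays at
or near 1. The ARI is evaluated over the planted module genes because, at
n = 4 zones, independent background genes occasionally exceed the 0.95 floor
by chance and form small spurious components — real behaviour of the method
that should be visible, but not a module-recovery failure; a background
gene essentially cannot bridge the two blocks, as they are anti-correlated.

What the generator does **not** emulate: count-level sampling noise (RPKM
is simulated directly, not derived from reads), zone-to-zone correlation of
noise, library-size effects, or maize genome annotation. Passing recovery
tests therefore shows the inference machinery is correct under the model's
own assumptions, not that the biological findings are robust to everything
real data can do.

`perturb_gene()` rewrites one gene's profile to achieve a chosen
correlation with a reference gene by exact construction (the target times
the centred unit reference plus the complementary weight of an orthogonal
unit noise vector, then an affine map into a positive RPKM range). The
realized correlation equals the target to floating-point precision — the
construction is exact rather than rejection-calibrated — and is still
verified within ±0.02; it is used to probe edge behaviour on either side of
the 0.95 floor.

## Pipeline, reproducibility, problem sizes

`run_pipeline()` chains profiling → duplicate collapse → network →
modules → associations, writes every output atomically (temp file + rename,
so failed runs leave no partial files), and drops a JSON manifest with the
configuration, package version and input checksums beside the outputs;
re-running the same configuration reproduces byte-identical outputs. A thin
command-line front-end over the same functions ships at
`inst/cli/leafcoex.R`.

Test and validation problem sizes are deliberately small, matching the
scale of the scientific question: the fixture network has 23 nodes; the
oracle-equivalence property runs 200 random instances of up to 12 genes
against an independent brute-force implementation; module-recovery runs 20
simulated datasets of 83 genes. Each completes in seconds.

## Known limitations

* Pearson correlation on 4 points is intrinsically noisy; edges near the
  0.95 floor should be read with that in mind (use `perturb_gene()` to see
  how sharply membership flips at the floor).
* No statistical significance is attached to edges — the method thresholds,
  it does not test; p-values/FDR on correlations are out of scope, as are
  weighted (soft-threshold) networks and modularity-optimising partitions.
* Raw-read processing is out of scope: the package starts from an RPKM
  table.
* The transporter catalogue of the original genome-wide analysis is not
  redistributed here; the association machinery accepts any catalogue in
  the documented format.
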