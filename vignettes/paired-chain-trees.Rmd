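---
title: "Building B cell lineage trees from paired heavy and light chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building B cell lineage trees from paired heavy and light chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Background

During an immune response, B cells proliferate and accumulate somatic
hypermutations (SHM) in the variable regions of their B cell receptor (BCR)
genes, forming clones: lineages of related cells descended from a common
naive ancestor. Phylogenetic trees built from BCR sequences reconstruct
this diversification and are used to study affinity maturation, antibody
evolution, and clonal dynamics.

A BCR is a heterodimer of a heavy chain (IGH) and a light chain (IGK or
IGL). Bulk repertoire sequencing observes heavy chains only, so lineage
trees have traditionally been built from heavy chains alone. Single-cell
V(D)J sequencing recovers the native heavy/light pairing, which brings two
complications and one opportunity:

* cells in one heavy-chain clone may carry distinct light-chain
  rearrangements (different V/J genes), and must be split into subgroups
  before a single alignment makes sense;
* real datasets mix paired cells with cells (or bulk reads) whose light
  chain is missing, so the combined alignment has large blocks of missing
  data;
* the light chain mutates at roughly half the heavy-chain rate, so forcing
  both chains onto a single set of branch lengths misestimates them.

`bcrtrees` implements a complete pipeline for this setting: light-chain
subgroup resolution, heavy+light concatenation with explicit missing-data
handling, germline-rooted tree building under maximum parsimony and two
maximum-likelihood models, tree comparison and support metrics, and a
paired SHM simulator used to validate the estimators.

## Pipeline

### Input and clone preparation

Input is an AIRR Rearrangement TSV (`read_airr()`), with one row per
rearrangement carrying IMGT-gapped `sequence_alignment` and
`germline_alignment` columns, `locus`, V/J calls, `junction_length`, and a
`clone_id` from upstream clonal clustering. `cell_id` links the heavy and
light rows of one cell; rows without it are treated as bulk heavy-chain
reads. Validation rejects malformed rows individually and keeps the rest.

`resolve_light_chains()` splits each heavy-chain clone into subgroups of
cells whose light chains share a V gene, J gene, and junction length
(allele suffixes are ignored). Subgroups are merged greedily, largest
first, when their gene sets are compatible. Cells without a light chain
are then assigned to the subgroup whose light-chain consensus is nearest
by Hamming distance, with fully ambiguous positions skipped and ties going
to the larger subgroup.

`format_clone()` builds one alignment per clone subgroup: heavy and light
chains are concatenated in that order; a cell missing its light chain gets
an `N` run the length of the light-chain alignment. `N`, `.` and `-` are
all treated as fully ambiguous states everywhere downstream. The clone
germline is the per-position consensus of the member germlines (ties
become `N`), and it is included as a zero-distance outgroup tip that roots
every tree. Identical tips (up to ambiguity) are collapsed, with the
merged tip keeping the determinate character wherever any member had one;
`make_heavy_only()` derives the matched heavy-only alignment over the same
tip set for paired-versus-heavy comparisons.

### Tree building

Three estimators share the germline-rooted, NNI-based search:

* **Maximum parsimony** (`parsimony_search()`): Fitch counting over the
  concatenated alignment with ambiguity-aware state sets; branch lengths
  are minimum-change counts per site from a final Sankoff-style pass.
* **Single-partition ML** (`ml_search(mode = "single")`): one GTR model
  over the whole concatenation, Felsenstein pruning with per-partition
  site-pattern compression, exact per-branch optimization by coordinate
  ascent, and optional estimation of the GTR exchangeabilities and
  empirical base frequencies.
* **Scaled multi-partition ML** (`ml_search(mode = "scaled")`): separate
  heavy and light partitions sharing one topology. The heavy partition
  scalar is pinned to 1; the light partition evolves along each branch `t`
  as `c * t`, with the scalar `c` estimated by maximum likelihood. If
  every light-chain position is ambiguous the scalar is unidentifiable and
  is fixed at 1 with a warning.

Scaled-mode branch lengths are reported on the whole-alignment scale: the
raw heavy-unit length is multiplied by `(Lh + c * Ll) / (Lh + Ll)`, where
`Lh` and `Ll` are the partition widths. This makes the reported tree
length an expected substitutions-per-site average over the concatenation,
directly comparable with the single-partition model and with simulated
truth, and is what removes the missing-light-chain bias discussed below.

GTR transition probabilities come from the symmetrized eigendecomposition
of the rate matrix (computed once per model, then shared across all branch
lengths in a batched matrix product), with the matrix normalized to one
expected substitution per site at stationarity.

### Evaluation

`rf_cluster_distance()` compares germline-rooted topologies by the
symmetric difference of their nontrivial clade sets, after collapsing
internal branches shorter than a threshold (default 0.001
substitutions/site) into polytomies so that effectively unresolved splits
are not scored. `codon_bootstrap()` resamples codon columns within each
partition (keeping heavy and light widths fixed) and reports per-clade
support counts. `divergence()` and `percent_length_error()` give
germline-to-tip path lengths and signed tree-length errors.

### Simulator

The simulator provides ground truth for all of the above. Mutations are
applied as discrete events under a 5-mer targeting model: the builtin
model elevates mutability 3.5x at WRC/GYW hotspots and reduces it 0.4x at
SYC/GRS coldspots, with uniform substitutions; published 5-mer tables can
be loaded from TSV (`read_targeting_model()`). Contexts are recomputed
after every event, so hotspots can be created and destroyed as a lineage
evolves. Within one branch every event hits a distinct position, so each
branch's event count is fully observable in its endpoint sequences;
repeated hits and back mutations arise only across branches of a lineage.

`simulate_clone()` draws a random rooted topology with the germline at the
root, applies Poisson(`branch_mean_events`) heavy-chain events per branch
and Poisson(`branch_mean_events * rate_ratio`) light-chain events
(defaults 4 and 0.5), and records the realized per-branch event counts,
which give the true tree in events per site. `mask_light_chains()` removes
the light chains of a chosen fraction of cells while always keeping at
least one paired cell per clone. `simulate_triplet()` is a minimal
two-tips-plus-germline design with fixed per-branch event counts, used to
isolate per-branch biases. All simulated data can be exported as AIRR TSV
so the full pipeline is exercised through its public input format.

## The missing-light-chain experiment

The central quantitative behaviour the package is built around: when most
cells lack a light chain, the concatenated alignment is mostly `N` in the
light partition. Under a single-partition model, each branch length is
effectively set by the heavy chain alone, but it is interpreted as a
per-site rate over the whole concatenation — so with the light chain
mutating at half the heavy rate, tree lengths are overestimated by
roughly `(Lh + Ll) / (Lh + rate_ratio * Ll) - 1` (about 25% at the default
lengths of 360 and 330 nt) when nearly all light chains are missing.

The scaled model absorbs this: the light scalar is estimated from whatever
paired cells remain, and the reporting scale `(Lh + c * Ll) / (Lh + Ll)`
re-weights branch lengths so that the mean tree-length error stays near
zero at every missingness level.

```{r, eval = FALSE}
library(bcrtrees)

sim <- simulate_clone(n_tips = 20, branch_mean_events = 4, rate_ratio = 0.5,
                      seed = 1)
masked <- mask_light_chains(sim, fraction = 0.95, seed = 2)
aln <- clone_sim_alignment(masked)

single <- ml_search(aln, mode = "single", seed = 3)
scaled <- ml_search(aln, mode = "scaled", seed = 3)

c(true = tree_length(sim$tree),
  single = single$tree_length,
  scaled = scaled$tree_length,
  light_scalar = scaled$light_scalar)
```

`run_benchmark()` runs this design over many clones, masking fractions,
methods, and paired/heavy-only modes, and `run_triplet_benchmark()` does
the per-branch version. Both are reproducible from a single seed.

## Study design and problem sizes

The package's validation studies (in `tests/testthat/` and
`scripts/acceptance.R`) use clones of 20 cells with Poisson(4) heavy-chain
events per branch and a light/heavy rate ratio of 0.5 — enough signal per
branch that topology is mostly recoverable while branch-length noise
remains realistic. Tree-length bias studies use 24-150 clones per
condition; per-branch triplet studies use 200 replicates. At 95% masking a
20-cell clone keeps a single paired cell, so the light scalar is estimated
from roughly a dozen light-chain events; its sampling noise (typically a
12% tree-length standard deviation per clone) is averaged over clones,
which is why the mean-error studies use clone counts in the hundreds.

## Limitations

* The topology generator is neutral (uniform coalescent-style joins);
  selection-driven tree shapes are out of scope.
* The builtin targeting model is a stylized hot/coldspot scheme, not a
  fitted 5-mer table; use `read_targeting_model()` for empirical tables.
* Clonal clustering is assumed done upstream; `clone_id` is taken as
  given.
* Indels are not modelled: gap characters are treated as missing data, not
  as events.
* The scalar applies to the whole light partition; per-site rate variation
  (e.g. gamma-distributed rates) is not implemented.
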