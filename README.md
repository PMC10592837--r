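# bcrtrees

Phylogenetic trees from paired heavy and light chain B cell receptor
(BCR) sequences.

Single-cell V(D)J sequencing recovers the native pairing of a B cell's
heavy and light chains, but real datasets mix paired cells with cells and
bulk reads whose light chain is missing, and the light chain mutates at
roughly half the heavy-chain rate. `bcrtrees` builds germline-rooted B
cell lineage trees from such data:

* **AIRR I/O** — reads and writes AIRR Rearrangement TSV, with row-level
  validation, Newick and FASTA export.
* **Clone preparation** — resolves light-chain subgroups within heavy
  clones (shared light V gene, J gene, and junction length; allele
  suffixes ignored), assigns light-less cells to the nearest subgroup
  consensus, concatenates heavy+light alignments with missing light
  chains as `N` runs, builds consensus clone germlines, and collapses
  duplicate tips.
* **Tree building** — maximum parsimony (Fitch/Sankoff), single-partition
  GTR maximum likelihood (Felsenstein pruning, NNI search), and a scaled
  multi-partition GTR model in which light-chain branch lengths differ
  from heavy-chain branch lengths by a maximum-likelihood scalar.
* **Evaluation** — Robinson–Foulds cluster distance with short-branch
  collapsing, codon-resampling bootstrap, divergence, tree-length error.
* **Simulation** — a paired somatic-hypermutation simulator with 5-mer
  hot/coldspot targeting, Poisson event counts per branch, light-chain
  masking, and a benchmark harness; simulated data round-trips through
  the AIRR format so the whole pipeline is exercised end to end.

A command-line interface (`exec/bcrtrees`) exposes the pipeline as
`resolve`, `build`, `rf`, `bootstrap`, `simulate`, and `benchmark`
subcommands.

## Worked example

Simulate a 10-cell clone (heavy chains at Poisson(4) mutation events per
branch, light chains at half that rate), mask the light chains of half
the cells, run the alignment through the standard clone-preparation
pipeline, and fit the scaled two-partition model:

```r
library(bcrtrees)

sim <- simulate_clone(n_tips = 10, branch_mean_events = 4, rate_ratio = 0.5,
                      seed = 7)
masked <- mask_light_chains(sim, fraction = 0.5, seed = 8)
aln <- clone_sim_alignment(masked)
print(aln)
#> clone_alignment sim1_1: 10 tips, heavy [0,360), light [360,690)

fit <- ml_search(aln, mode = "scaled", seed = 9)
print(fit)
#> bcr_fit [ml-scaled]: 11 tips, tree length 0.17034, lnL -1640.9131, light scalar 0.640

rf_cluster_distance(fit$tree, sim$tree)
#> RF cluster distance 1 (unique: 0 + 1; collapse < 0.001)
```

The estimated light scalar is close to the simulated rate ratio of 0.5,
and the fitted topology differs from the true tree by a single cluster
(a short true branch the data cannot resolve). Comparing tree lengths
against a single-partition fit of the same alignment:

```r
single <- ml_search(aln, mode = "single", seed = 9)
round(c(true = tree_length(sim$tree),
        `ml-scaled` = fit$tree_length,
        `ml-single` = single$tree_length,
        light_scalar = fit$light_scalar), 4)
#>         true    ml-scaled    ml-single light_scalar
#>       0.1638       0.1703       0.1776       0.6397
```

The single-partition model overestimates the tree length because the
masked light chains contribute uninformative sites that it must average
over at the heavy-chain rate; the effect grows with the masked fraction
(about +25% when 95% of cells are unpaired) and is what the scaled model
is designed to remove. See the vignette
(`vignettes/paired-chain-trees.Rmd`) for the model details and the full
experiment.

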