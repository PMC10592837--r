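# Tree comparison and support metrics: RF cluster distance with
# short-branch collapsing, codon-resampling bootstrap, divergence, and
# percent tree-length error.

#' Collapse short internal branches into polytomies
#'
#' Contracts every internal branch strictly shorter than `threshold`,
#' creating polytomies. Tip branches are never contracted. Default
#' thresholds are 0.001 (mutations per nucleotide) or 0.003 (mutations per
#' codon), selected by the `units` flag when `threshold` is NULL.
#'
#' @param tree A rooted `phylo` tree.
#' @param threshold Collapse threshold; branches with length < threshold go.
#' @param units `"nucleotide"` or `"codon"`; sets the default threshold.
#' @return The collapsed `phylo` tree.
#' @export
collapse_short_branches <- function(tree, threshold = NULL,
                                    units = c("nucleotide", "codon")) {
  units <- match.arg(units)
  if (is.null(threshold)) threshold <- if (units == "nucleotide") 0.001 else 0.003
  if (threshold < 0) stop("negative collapse threshold", call. = FALSE)
  if (threshold == 0) return(tree)
  nt <- length(tree$tip.label)
  repeat {
    internal_child <- tree$edge[, 2] > nt
    short <- which(internal_child & tree$edge.length < threshold)
    if (length(short) == 0) break
    e <- short[1]
    v <- tree$edge[e, 2]
    u <- tree$edge[e, 1]
    # Reattach v's children to u, drop v.
    keep <- tree$edge[, 2] != v
    edge <- tree$edge[keep, , drop = FALSE]
    len <- tree$edge.length[keep]
    edge[edge[, 1] == v, 1] <- u
    # Renumber nodes above v down by one.
    edge[edge > v] <- edge[edge > v] - 1L
    tree$edge <- edge
    tree$edge.length <- len
    tree$Nnode <- tree$Nnode - 1L
  }
  normalize_phylo(tree)
}

# Rooted cluster set of a tree: for each internal edge, the tip-label set
# on the side away from the germline tip. Singleton tips and the trivial
# all-non-germline-tips cluster are excluded. Returns character keys.
#' @noRd
clade_clusters <- function(tree, germline_label = "Germline") {
  ti <- tree_info(tree)
  nt <- ti$ntip
  labs <- tree$tip.label
  g <- match(germline_label, labs)
  if (is.na(g)) stop("germline tip '", germline_label, "' not found", call. = FALSE)
  # Tip sets below each node.
  below <- vector("list", max(ti$edge))
  for (i in seq_len(nt)) below[[i]] <- i
  for (v in ti$post_internal) {
    below[[v]] <- sort(unlist(below[ti$children[[v]]]))
  }
  all_tips <- seq_len(nt)
  out <- character(0)
  for (v in seq_len(max(ti$edge))) {
    if (v <= nt || v == ti$root) next
    cl <- below[[v]]
    if (g %in% cl) cl <- setdiff(all_tips, cl)
    cl <- setdiff(cl, g)
    if (length(cl) < 2 || length(cl) >= nt - 1) next
    out <- c(out, paste(sort(labs[cl]), collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds cluster distance
#'
#' Collapses branches shorter than `threshold` in both trees, maps each
#' tree to the set of rooted subclades (tip-label sets of internal nodes,
#' rooted on the germline tip; singleton tips and the trivial all-tips
#' cluster excluded), and counts the clusters unique to each tree. Trees
#' need not be strictly binary.
#'
#' @param tree1,tree2 Rooted `phylo` trees over the same tip label set
#'   (including the germline).
#' @param threshold Collapse threshold (default 0.001, nucleotide units).
#' @param germline_label Tip label of the germline.
#' @return An `rf_cluster` list: `distance`, `clusters_unique_to_tree1`,
#'   `clusters_unique_to_tree2`, `collapse_threshold`.
#' @export
rf_cluster_distance <- function(tree1, tree2, threshold = 0.001,
                                germline_label = "Germline") {
  if (!setequal(tree1$tip.label, tree2$tip.label)) {
    stop("tip sets differ: only in tree1 [",
         paste(setdiff(tree1$tip.label, tree2$tip.label), collapse = ","),
         "], only in tree2 [",
         paste(setdiff(tree2$tip.label, tree1$tip.label), collapse = ","), "]",
         call. = FALSE)
  }
  c1 <- clade_clusters(collapse_short_branches(tree1, threshold), germline_label)
  c2 <- clade_clusters(collapse_short_branches(tree2, threshold), germline_label)
  u1 <- length(setdiff(c1, c2))
  u2 <- length(setdiff(c2, c1))
  structure(list(distance = u1 + u2,
                 clusters_unique_to_tree1 = u1,
                 clusters_unique_to_tree2 = u2,
                 collapse_threshold = threshold), class = "rf_cluster")
}

#' @export
print.rf_cluster <- function(x, ...) {
  cat(sprintf("RF cluster distance %d (unique: %d + %d; collapse < %g)\n",
              x$distance, x$clusters_unique_to_tree1,
              x$clusters_unique_to_tree2, x$collapse_threshold))
  invisible(x)
}

#' Codon-resampling bootstrap
#'
#' Builds `n` replicate alignments by sampling codon columns (nucleotide
#' triplets) with replacement, preserving each sampled codon's partition
#' label (partitions are trimmed to whole codons first; trailing remainder
#' sites are dropped with a warning). The support of each internal branch
#' of the full tree is the number of replicate trees containing the same
#' tip-set cluster after same-threshold collapsing.
#'
#' @param aln A `clone_alignment`.
#' @param build A function `(clone_alignment) -> bcr_fit or phylo` building
#'   a tree.
#' @param n Number of replicates (default 100).
#' @param seed Seed for the resampling.
#' @param collapse_threshold Collapse threshold applied before cluster
#'   extraction.
#' @param germline_label Tip label of the germline.
#' @return A `bootstrap_summary` list: `support` (named integer vector
#'   keyed by tip-set), `mean_support`, `n_replicates`, and the full tree.
#' @export
codon_bootstrap <- function(aln, build, n = 100, seed = NULL,
                            collapse_threshold = 0.001,
                            germline_label = "Germline") {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  full <- build(aln)
  full_tree <- if (inherits(full, "bcr_fit")) full$tree else full
  full_clusters <- clade_clusters(
    collapse_short_branches(full_tree, collapse_threshold), germline_label)
  support <- stats::setNames(rep(0L, length(full_clusters)), full_clusters)

  ivs <- list(heavy = aln$heavy_interval, light = aln$light_interval)
  codons <- list()
  for (nm in names(ivs)) {
    iv <- ivs[[nm]]
    len <- iv[2] - iv[1]
    ncod <- len %/% 3
    if (len %% 3 != 0) {
      warning(sprintf("%s partition length %d not divisible by 3; dropping %d trailing site(s)",
                      nm, len, len %% 3))
    }
    if (ncod > 0) {
      starts <- iv[1] + 3 * (seq_len(ncod) - 1)
      codons <- c(codons, lapply(starts, function(s) list(part = nm, start = s)))
    }
  }
  ncod_all <- length(codons)
  tipnames <- names(aln$tip_sequences)

  resample_aln <- function() {
    pick <- sample.int(ncod_all, ncod_all, replace = TRUE)
    parts <- vapply(codons[pick], function(x) x$part, character(1))
    pick <- pick[order(match(parts, c("heavy", "light")))]
    cols <- unlist(lapply(codons[pick], function(x) x$start + 1:3))
    nh <- 3 * sum(vapply(codons[pick], function(x) x$part, character(1)) == "heavy")
    tips <- vapply(aln$tip_sequences, function(s) {
      chars_to_seq(seq_to_chars(s)[cols])
    }, character(1))
    names(tips) <- tipnames
    out <- aln
    out$tip_sequences <- tips
    out$germline <- chars_to_seq(seq_to_chars(aln$germline)[cols])
    out$heavy_interval <- c(0L, nh)
    out$light_interval <- c(nh, length(cols))
    out
  }

  with_seed_opt(seed, {
    for (r in seq_len(n)) {
      rep_aln <- resample_aln()
      fit <- build(rep_aln)
      rep_tree <- if (inherits(fit, "bcr_fit")) fit$tree else fit
      rep_clusters <- clade_clusters(
        collapse_short_branches(rep_tree, collapse_threshold), germline_label)
      hit <- full_clusters %in% rep_clusters
      support[hit] <- support[hit] + 1L
    }
  })
  structure(list(support = support,
                 mean_support = if (length(support) > 0) mean(support) else NA_real_,
                 n_replicates = n,
                 full_tree = full_tree), class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("codon bootstrap: %d replicates, %d internal branches, mean support %.1f\n",
              x$n_replicates, length(x$support), x$mean_support))
  invisible(x)
}

#' Divergence of a tip from the germline
#'
#' Sum of branch lengths along the unique path from the germline tip to the
#' given tip.
#'
#' @param tree A `phylo` tree containing the germline tip.
#' @param tip Tip label (or index).
#' @param germline_label Tip label of the germline.
#' @return Path length (0 for the germline tip itself).
#' @export
divergence <- function(tree, tip, germline_label = "Germline") {
  ti <- tree_info(tree)
  labs <- tree$tip.label
  a <- if (is.character(tip)) match(tip, labs) else as.integer(tip)
  g <- match(germline_label, labs)
  if (is.na(a) || is.na(g)) stop("tip not found in tree", call. = FALSE)
  path_to_root <- function(v) {
    out <- v
    while (v != ti$root) {
      v <- ti$parent[v]
      out <- c(out, v)
    }
    out
  }
  pa <- path_to_root(a)
  pg <- path_to_root(g)
  common <- intersect(pa, pg)
  mrca <- common[1]
  seg <- c(pa[seq_len(which(pa == mrca) - 1)], pg[seq_len(which(pg == mrca) - 1)])
  sum(tree$edge.length[ti$edge_of[seg]])
}

#' Percent tree-length error
#'
#' `(true - estimated) / true`: positive values are underestimates,
#' negative values overestimates.
#'
#' @param true_len True tree length (> 0).
#' @param est_len Estimated tree length.
#' @return The signed fractional error.
#' @export
percent_length_error <- function(true_len, est_len) {
  if (any(true_len <= 0)) stop("true length must be positive", call. = FALSE)
  (true_len - est_len) / true_len
}
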