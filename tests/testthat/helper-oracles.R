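# Shared test fixtures and brute-force oracles. The oracles enumerate
# ancestral state assignments directly and are deliberately independent of
# the pruning / Sankoff implementations they check.

NUC4 <- c("A", "C", "G", "T")

# Minimal clone_alignment constructor for hand-built sequences.
test_aln <- function(tips, germline, Lh = nchar(germline),
                     id = "test_1") {
  L <- nchar(germline)
  structure(list(
    clone_subgroup_id = id,
    tip_sequences = tips,
    germline = germline,
    heavy_interval = c(0L, as.integer(Lh)),
    light_interval = c(as.integer(Lh), as.integer(L)),
    collapse_map = as.list(stats::setNames(names(tips), names(tips))),
    light_present = stats::setNames(rep(Lh < L, length(tips)), names(tips))
  ), class = "clone_alignment")
}

tree_from_text <- function(nwk) read_newick(nwk, text = TRUE)

# One AIRR rearrangement row.
airr_row <- function(sequence_id, cell_id, locus, seq, germ,
                     v_call = if (locus == "IGH") "IGHV1-1*01" else "IGKV1-39*01",
                     j_call = if (locus == "IGH") "IGHJ4*01" else "IGKJ2*01",
                     junction_length = 33L, clone_id = "clone1") {
  tibble::tibble(sequence_id = sequence_id, cell_id = cell_id, locus = locus,
                 v_call = v_call, j_call = j_call,
                 junction_length = junction_length,
                 sequence_alignment = seq, germline_alignment = germ,
                 clone_id = clone_id)
}

# Allowed encoded states of one character (N/gap -> all four).
allowed_states <- function(ch) {
  i <- match(ch, NUC4)
  if (is.na(i)) 1:4 else i
}

# Brute-force partitioned log-likelihood: sum over every joint state
# assignment of all nodes, site by site. Exponential; only for tiny trees.
brute_force_loglik <- function(tree, aln, scheme, germline_label = "Germline") {
  ti <- bcrtrees:::tree_info(tree)
  nt <- ti$ntip
  nnode <- max(ti$edge)
  seqs <- c(aln$tip_sequences,
            stats::setNames(aln$germline, germline_label))
  tipchars <- lapply(tree$tip.label, function(lb) strsplit(seqs[[lb]], "")[[1]])
  total <- 0
  for (k in seq_along(scheme$partitions)) {
    part <- scheme$partitions[[k]]
    iv <- part$interval
    Pmats <- lapply(seq_len(nrow(ti$edge)), function(e) {
      transition_matrix(part$model, tree$edge.length[e] * part$scalar)
    })
    for (site in seq.int(iv[1] + 1L, iv[2])) {
      sets <- vector("list", nnode)
      for (i in seq_len(nt)) sets[[i]] <- allowed_states(tipchars[[i]][site])
      for (v in (nt + 1):nnode) sets[[v]] <- 1:4
      grid <- expand.grid(sets, KEEP.OUT.ATTRS = FALSE)
      lik <- 0
      for (r in seq_len(nrow(grid))) {
        s <- as.integer(grid[r, ])
        p <- part$model$pi[s[ti$root]]
        for (e in seq_len(nrow(ti$edge))) {
          p <- p * Pmats[[e]][s[ti$edge[e, 1]], s[ti$edge[e, 2]]]
        }
        lik <- lik + p
      }
      total <- total + log(lik)
    }
  }
  total
}

# Brute-force minimum-changes parsimony score by exhaustive enumeration of
# ancestral (and ambiguous-tip) states.
brute_force_parsimony <- function(tree, aln, germline_label = "Germline") {
  ti <- bcrtrees:::tree_info(tree)
  nt <- ti$ntip
  nnode <- max(ti$edge)
  seqs <- c(aln$tip_sequences,
            stats::setNames(aln$germline, germline_label))
  tipchars <- lapply(tree$tip.label, function(lb) strsplit(seqs[[lb]], "")[[1]])
  L <- nchar(aln$germline)
  total <- 0
  for (site in seq_len(L)) {
    sets <- vector("list", nnode)
    for (i in seq_len(nt)) sets[[i]] <- allowed_states(tipchars[[i]][site])
    for (v in (nt + 1):nnode) sets[[v]] <- 1:4
    grid <- expand.grid(sets, KEEP.OUT.ATTRS = FALSE)
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      s <- as.integer(grid[r, ])
      ch <- sum(s[ti$edge[, 1]] != s[ti$edge[, 2]])
      if (ch < best) best <- ch
    }
    total <- total + best
  }
  total
}

# Random nucleotide string, optionally salted with ambiguous characters.
random_seq <- function(L, n_ambig = 0) {
  x <- sample(NUC4, L, replace = TRUE)
  if (n_ambig > 0) {
    pos <- sample.int(L, n_ambig)
    x[pos] <- sample(c("N", ".", "-"), n_ambig, replace = TRUE)
  }
  paste(x, collapse = "")
}
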