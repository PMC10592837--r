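# Paired heavy/light somatic hypermutation simulator: 5-mer hot/cold-spot
# targeting, triplet benchmarks, clone-scale simulation with Poisson
# mutation counts per branch (light means scaled by rate_ratio), and
# light-chain dropout masking.

#' Built-in 5-mer targeting model
#'
#' A simplified somatic hypermutation targeting model: mutability is
#' elevated at classic WRC/GYW hotspot contexts (the mutated base is the C
#' of WRC or the G of GYW; W = A/T, R = A/G, Y = C/T), reduced at SYC/GRS
#' coldspots (S = C/G), and uniform elsewhere. Substitutions are uniform
#' over the three non-identity bases. Contexts containing N or gaps fall
#' back to uniform mutability. Published 5-mer tables (e.g. S5F-style) can
#' be supplied instead via [read_targeting_model()].
#'
#' @param hot Mutability multiplier at hotspots (default 3.5).
#' @param cold Multiplier at coldspots (default 0.4).
#' @return A `targeting_model` object.
#' @export
targeting_model <- function(hot = 3.5, cold = 0.4) {
  stopifnot(hot > 0, cold > 0)
  structure(list(type = "builtin", hot = hot, cold = cold, table = NULL),
            class = "targeting_model")
}

#' Read a 5-mer targeting model from TSV
#'
#' Expects columns `fivemer`, `mutability`, and `p_a`, `p_c`, `p_g`, `p_t`
#' (substitution distribution for the center base; the identity entry must
#' be 0 and rows must sum to 1).
#'
#' @param path TSV path.
#' @return A `targeting_model` object backed by the table.
#' @export
read_targeting_model <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    fivemer = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  need <- c("fivemer", "mutability", "p_a", "p_c", "p_g", "p_t")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("targeting table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tab$fivemer <- toupper(tab$fivemer)
  probs <- as.matrix(tab[, c("p_a", "p_c", "p_g", "p_t")])
  ctr <- match(substr(tab$fivemer, 3, 3), NUC)
  for (i in seq_len(nrow(tab))) {
    if (!is.na(ctr[i]) && probs[i, ctr[i]] != 0) {
      stop("substitution distribution has non-zero identity entry for ",
           tab$fivemer[i], call. = FALSE)
    }
  }
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("substitution rows must sum to 1", call. = FALSE)
  }
  if (any(tab$mutability <= 0)) stop("mutability must be positive", call. = FALSE)
  mut <- stats::setNames(tab$mutability, tab$fivemer)
  structure(list(type = "table", hot = NA, cold = NA,
                 table = list(mutability = mut, probs = probs,
                              fivemer = tab$fivemer)),
            class = "targeting_model")
}

#' @export
print.targeting_model <- function(x, ...) {
  if (x$type == "builtin") {
    cat(sprintf("targeting_model (builtin): hot %.2f, cold %.2f\n", x$hot, x$cold))
  } else {
    cat(sprintf("targeting_model (table): %d 5-mers\n",
                length(x$table$mutability)))
  }
  invisible(x)
}

# Relative mutability of position i given its 5-mer context (character
# vector form); uniform fallback for contexts touching N/gap or sequence
# ends.
#' @noRd
context_mutability <- function(chars, i, model) {
  L <- length(chars)
  if (i < 3 || i > L - 2) return(1)
  ctx <- chars[(i - 2):(i + 2)]
  if (any(!(ctx %in% NUC))) return(1)
  if (model$type == "table") {
    m <- model$table$mutability[paste(ctx, collapse = "")]
    return(if (is.na(m)) 1 else unname(m))
  }
  W <- c("A", "T"); R <- c("A", "G"); Y <- c("C", "T"); S <- c("C", "G")
  ctr <- ctx[3]
  if (ctr == "C" && ctx[2] %in% R && ctx[1] %in% W) return(model$hot)   # WRC
  if (ctr == "G" && ctx[4] %in% Y && ctx[5] %in% W) return(model$hot)   # GYW
  if (ctr == "C" && ctx[2] %in% Y && ctx[1] %in% S) return(model$cold)  # SYC
  if (ctr == "G" && ctx[4] %in% R && ctx[5] %in% S) return(model$cold)  # GRS
  1
}

#' @noRd
draw_substitution <- function(chars, i, model) {
  from <- chars[i]
  if (model$type == "table" && i >= 3 && i <= length(chars) - 2) {
    ctx <- chars[(i - 2):(i + 2)]
    if (all(ctx %in% NUC)) {
      key <- paste(ctx, collapse = "")
      row <- match(key, model$table$fivemer)
      if (!is.na(row)) {
        return(sample(NUC, 1, prob = model$table$probs[row, ]))
      }
    }
  }
  sample(setdiff(NUC, from), 1)
}

#' Apply targeted point mutations to a sequence
#'
#' Applies `n_events` sequential mutation events. At each event a position
#' is drawn with probability proportional to its current 5-mer context
#' mutability (contexts are recomputed after every event, so hotspots can
#' appear and disappear as the sequence evolves), then a substitution is
#' drawn from the context's distribution. Each position is mutated at most
#' once per call, so every event is observable and the Hamming distance to
#' the input equals `n_events`; repeated hits and back mutations can still
#' arise along multi-branch lineages, where each branch is a separate
#' call. Positions holding N or gaps are never mutated.
#'
#' @param seq Nucleotide string (length >= 5).
#' @param n_events Number of mutation events (>= 0); at most the number of
#'   mutable positions.
#' @param model A [targeting_model()].
#' @param seed Optional seed.
#' @return A list with `sequence` (mutated string) and `events` (tibble:
#'   `pos` 1-based, `from`, `to`).
#' @export
apply_targeted_mutations <- function(seq, n_events, model = targeting_model(),
                                     seed = NULL) {
  stopifnot(n_events >= 0)
  chars <- seq_to_chars(seq)
  L <- length(chars)
  mutable <- chars %in% NUC
  if (n_events > 0 && !any(mutable)) {
    stop("no mutable positions (all N/gap)", call. = FALSE)
  }
  if (n_events > sum(mutable)) {
    stop("n_events (", n_events, ") exceeds the ", sum(mutable),
         " mutable positions", call. = FALSE)
  }
  pos <- integer(n_events); from <- character(n_events); to <- character(n_events)
  with_seed_opt(seed, {
    w <- numeric(L)
    for (i in seq_len(L)) {
      w[i] <- if (mutable[i]) context_mutability(chars, i, model) else 0
    }
    for (ev in seq_len(n_events)) {
      i <- sample.int(L, 1, prob = w)
      newb <- draw_substitution(chars, i, model)
      pos[ev] <- i; from[ev] <- chars[i]; to[ev] <- newb
      chars[i] <- newb
      # A position receives at most one event per call, so every event is
      # an observable point difference from the input sequence.
      mutable[i] <- FALSE
      lo <- max(1, i - 2); hi <- min(L, i + 2)
      for (j in lo:hi) {
        w[j] <- if (mutable[j]) context_mutability(chars, j, model) else 0
      }
    }
  })
  list(sequence = chars_to_seq(chars),
       events = tibble::tibble(pos = pos, from = from, to = to))
}

#' Synthetic naive germline pair
#'
#' Draws a synthetic heavy/light germline pair with uniform base
#' composition; a stand-in for empirical naive-cell starting pairs
#' (lengths default to typical IMGT-gapped V(D)J spans).
#'
#' @param len_h,len_l Heavy and light lengths in nt.
#' @param seed Optional seed.
#' @return List with `heavy` and `light` strings.
#' @export
simulate_germline_pair <- function(len_h = 360, len_l = 330, seed = NULL) {
  with_seed_opt(seed, {
    list(heavy = chars_to_seq(sample(NUC, len_h, replace = TRUE)),
         light = chars_to_seq(sample(NUC, len_l, replace = TRUE)))
  })
}

#' Simulate a 3-taxa triplet
#'
#' Germline, one internal node and two tips; per branch, exactly `m_h`
#' heavy and `m_l` light mutation events are applied (heavy and light with
#' their own targeting models). The `SC+bulk` variant of the alignment
#' removes tip B's light chain.
#'
#' @param germ Optional germline pair (list with `heavy`, `light`);
#'   defaults to [simulate_germline_pair()].
#' @param m_h,m_l Heavy and light mutation events per branch (defaults 25
#'   and 12).
#' @param model_h,model_l Targeting models.
#' @param seed Optional seed.
#' @return A `triplet_sim`: germline/tip sequences, per-branch event
#'   counts, and the true per-branch length `(m_h+m_l)/(Lh+Ll)` in
#'   events/site.
#' @export
simulate_triplet <- function(germ = NULL, m_h = 25, m_l = 12,
                             model_h = targeting_model(),
                             model_l = targeting_model(), seed = NULL) {
  with_seed_opt(seed, {
    if (is.null(germ)) germ <- simulate_germline_pair()
    Lh <- nchar(germ$heavy); Ll <- nchar(germ$light)
    mut <- function(h, l) {
      list(heavy = apply_targeted_mutations(h, m_h, model_h)$sequence,
           light = apply_targeted_mutations(l, m_l, model_l)$sequence)
    }
    internal <- mut(germ$heavy, germ$light)
    tipA <- mut(internal$heavy, internal$light)
    tipB <- mut(internal$heavy, internal$light)
    structure(list(
      germ = germ, internal = internal, tipA = tipA, tipB = tipB,
      m_h = m_h, m_l = m_l, len_h = Lh, len_l = Ll,
      true_branch_length = (m_h + m_l) / (Lh + Ll),
      true_branch_length_heavy = m_h / Lh
    ), class = "triplet_sim")
  })
}

#' Clone alignment of a simulated triplet
#'
#' @param sim A `triplet_sim`.
#' @param variant `"SC"` (both tips keep their light chain) or `"SC+bulk"`
#'   (tip B's light chain replaced by an N run).
#' @param heavy_only Restrict to the heavy chain (matched tips).
#' @return A `clone_alignment` with tips `A` and `B`.
#' @export
triplet_alignment <- function(sim, variant = c("SC", "SC+bulk"),
                              heavy_only = FALSE) {
  variant <- match.arg(variant)
  Ll <- sim$len_l
  lightB <- if (variant == "SC+bulk") strrep("N", Ll) else sim$tipB$light
  tips <- c(A = paste0(sim$tipA$heavy, sim$tipA$light),
            B = paste0(sim$tipB$heavy, lightB))
  aln <- structure(list(
    clone_subgroup_id = "triplet_1",
    tip_sequences = tips,
    germline = paste0(sim$germ$heavy, sim$germ$light),
    heavy_interval = c(0L, sim$len_h),
    light_interval = c(sim$len_h, sim$len_h + Ll),
    collapse_map = list(A = "A", B = "B"),
    light_present = c(A = TRUE, B = variant == "SC")
  ), class = "clone_alignment")
  if (heavy_only) make_heavy_only(aln) else aln
}

# Random rooted topology by uniform coalescent-style joins; germline tip
# attached at the root with a zero-length branch. Returns a phylo skeleton
# whose edge order is used to index per-branch event counts.
#' @noRd
random_topology <- function(n_tips, germline_label = "Germline") {
  tip_labels <- c(paste0("cell", seq_len(n_tips)), germline_label)
  nt <- n_tips + 1L
  # Build with temporary ids: tips 1..nt; internals allocated upward.
  nxt <- nt
  parent <- integer(0); child <- integer(0)
  active <- seq_len(n_tips)
  while (length(active) > 1) {
    pick <- sample(length(active), 2)
    nxt <- nxt + 1L
    parent <- c(parent, nxt, nxt)
    child <- c(child, active[pick])
    active <- c(active[-pick], nxt)
  }
  root <- nxt + 1L
  parent <- c(parent, root, root)
  child <- c(child, active, nt)  # last lineage + germline tip
  tr <- list(edge = cbind(parent, child), edge.length = numeric(length(parent)),
             tip.label = tip_labels, Nnode = root - nt)
  class(tr) <- "phylo"
  tr
}

#' Simulate a clone under paired SHM
#'
#' Draws a random rooted topology (uniform coalescent-style joins) with the
#' germline at the root; on each branch the heavy mutation event count is
#' Poisson(`branch_mean_events`) and the light count
#' Poisson(`branch_mean_events * rate_ratio`). Sequences are evolved
#' root-to-tip with 5-mer targeted substitutions; only tips are retained as
#' observed cells. The returned true tree carries branch lengths in
#' events/site over the concatenated alignment.
#'
#' @param n_tips Number of cells (>= 2).
#' @param branch_mean_events Mean heavy-chain mutation events per branch.
#' @param rate_ratio Light/heavy event-rate ratio (default 0.5).
#' @param germ Optional germline pair; defaults to a synthetic pair.
#' @param model_h,model_l Targeting models.
#' @param seed Optional seed.
#' @param germline_label Germline tip label.
#' @return A `clone_sim`: `tree` (true tree, events/site), `tree_heavy`
#'   (heavy-only true lengths), `heavy`/`light` named tip sequences,
#'   `events` per-edge counts, `germ`, `masked` (empty), and parameters.
#' @export
simulate_clone <- function(n_tips, branch_mean_events = 4, rate_ratio = 0.5,
                           germ = NULL, model_h = targeting_model(),
                           model_l = targeting_model(), seed = NULL,
                           germline_label = "Germline") {
  stopifnot(n_tips >= 2)
  with_seed_opt(seed, {
    if (is.null(germ)) germ <- simulate_germline_pair()
    Lh <- nchar(germ$heavy); Ll <- nchar(germ$light)
    tr <- random_topology(n_tips, germline_label)
    ti <- tree_info(tr)
    nedge <- nrow(tr$edge)
    germ_tip <- match(germline_label, tr$tip.label)
    h_events <- rpois(nedge, branch_mean_events)
    l_events <- rpois(nedge, branch_mean_events * rate_ratio)
    # Germline pendant branch carries no events (the root IS the germline).
    ge <- ti$edge_of[germ_tip]
    h_events[ge] <- 0L
    l_events[ge] <- 0L

    heavy <- character(max(ti$edge)); light <- character(max(ti$edge))
    heavy[ti$root] <- germ$heavy; light[ti$root] <- germ$light
    # Preorder walk mutating down each branch.
    walk <- function(u) {
      for (v in ti$children[[u]]) {
        e <- ti$edge_of[v]
        heavy[v] <<- apply_targeted_mutations(heavy[u], h_events[e], model_h)$sequence
        light[v] <<- apply_targeted_mutations(light[u], l_events[e], model_l)$sequence
        if (v > ti$ntip) walk(v)
      }
    }
    walk(ti$root)

    tree <- tr
    tree$edge.length <- (h_events + l_events) / (Lh + Ll)
    tree <- normalize_phylo(tree)
    tree_heavy <- tr
    tree_heavy$edge.length <- h_events / Lh
    tree_heavy <- normalize_phylo(tree_heavy)

    cells <- setdiff(tr$tip.label, germline_label)
    idx <- match(cells, tr$tip.label)
    structure(list(
      tree = tree, tree_heavy = tree_heavy,
      heavy = stats::setNames(heavy[idx], cells),
      light = stats::setNames(light[idx], cells),
      germ = germ,
      events = tibble::tibble(parent = tr$edge[, 1], child = tr$edge[, 2],
                              heavy = h_events, light = l_events),
      masked = character(0),
      params = list(n_tips = n_tips, branch_mean_events = branch_mean_events,
                    rate_ratio = rate_ratio, len_h = Lh, len_l = Ll),
      germline_label = germline_label,
      seed = seed
    ), class = "clone_sim")
  })
}

#' Mask light chains of simulated cells
#'
#' Randomly removes light chains so each clone's masked share is as close
#' as possible to `fraction` while every clone keeps at least one cell with
#' a paired light chain.
#'
#' @param sims A `clone_sim` or list of them.
#' @param fraction Fraction of cells to mask, in `[0, 1)`.
#' @param seed Optional seed.
#' @return Input with the `masked` field set to the masked cell names.
#' @export
mask_light_chains <- function(sims, fraction, seed = NULL) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)", call. = FALSE)
  single <- inherits(sims, "clone_sim")
  if (single) sims <- list(sims)
  out <- with_seed_opt(seed, {
    lapply(sims, function(sim) {
      cells <- names(sim$heavy)
      paired <- setdiff(cells, sim$masked)
      k <- min(round(fraction * length(cells)), length(paired) - 1L)
      if (k > 0) {
        sim$masked <- union(sim$masked, sample(paired, k))
      }
      sim
    })
  })
  if (single) out[[1]] else out
}

#' Export a simulated clone as AIRR rearrangement records
#'
#' One heavy-chain row per cell plus one light-chain row per unmasked cell,
#' with synthetic V/J calls, so the full clone-preparation pipeline can be
#' exercised through its public input format.
#'
#' @param sim A `clone_sim`.
#' @param clone_id Clone identifier for the records.
#' @param cell_prefix Prefix prepended to every cell (and sequence) id.
#'   Needed when records from several simulated clones are combined into
#'   one table, since each clone reuses the same cell names.
#' @return A rearrangement tibble (see [read_airr()]).
#' @export
clone_sim_airr <- function(sim, clone_id = "sim1", cell_prefix = "") {
  cells <- names(sim$heavy)
  rows <- list()
  for (orig in cells) {
    cell <- paste0(cell_prefix, orig)
    rows[[length(rows) + 1]] <- tibble::tibble(
      sequence_id = paste0(cell, "_IGH"), cell_id = cell, locus = "IGH",
      v_call = "IGHV1-1*01", j_call = "IGHJ4*01", junction_length = 33L,
      sequence_alignment = sim$heavy[[orig]],
      germline_alignment = sim$germ$heavy, clone_id = clone_id)
    if (!(orig %in% sim$masked)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sequence_id = paste0(cell, "_IGK"), cell_id = cell, locus = "IGK",
        v_call = "IGKV1-1*01", j_call = "IGKJ2*01", junction_length = 33L,
        sequence_alignment = sim$light[[orig]],
        germline_alignment = sim$germ$light, clone_id = clone_id)
    }
  }
  dplyr::bind_rows(rows)
}

#' Clone alignment of a simulated clone
#'
#' Runs the simulated records through the standard pipeline
#' ([group_cells()], [resolve_light_chains()], [format_clone()]).
#'
#' @param sim A `clone_sim`.
#' @param clone_id Clone identifier.
#' @param collapse Collapse duplicate tips (default TRUE).
#' @return A `clone_alignment`.
#' @export
clone_sim_alignment <- function(sim, clone_id = "sim1", collapse = TRUE) {
  records <- clone_sim_airr(sim, clone_id)
  grouped <- group_cells(records)
  resolved <- resolve_light_chains(grouped$bundles)
  format_clone(resolved$bundles,
               clone_subgroup_id = paste0(clone_id, "_1"),
               germline_heavy = sim$germ$heavy,
               germline_light = sim$germ$light,
               collapse = collapse)
}
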