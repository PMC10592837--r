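# Maximum parsimony machinery: exact minimum-change scoring (unordered
# states, Sankoff dynamic programming with unit costs, valid for
# polytomies) and branch lengths as expected per-edge change counts
# averaged uniformly over all most-parsimonious reconstructions (MPRs).
# N and gaps are treated as the full ambiguity set {A,C,G,T}.

BIGCOST <- 1e9

# Pattern-compress a clone alignment over its full length for parsimony.
#' @noRd
make_parsimony_data <- function(aln, germline_label = "Germline") {
  seqs <- c(aln$tip_sequences, stats::setNames(aln$germline, germline_label))
  enc <- lapply(seqs, encode_nuc)
  S <- do.call(rbind, enc)
  key <- apply(S, 2, function(col) paste(ifelse(is.na(col), 0L, col), collapse = ","))
  uk <- unique(key)
  idx <- match(uk, key)
  w <- as.numeric(table(factor(key, levels = uk)))
  list(states = S[, idx, drop = FALSE], weights = w,
       tipnames = names(seqs), nsites = ncol(S))
}

# Unit-cost Sankoff message: from child (cost, count) arrays to the parent
# contribution m(s) = min_t cost(t) + [s != t], with MPR counts.
#' @noRd
sankoff_message <- function(cost, count) {
  minall <- pmin(cost[1, ], cost[2, ], cost[3, ], cost[4, ])
  minmat <- matrix(minall, 4, ncol(cost), byrow = TRUE)
  m <- pmin(cost, minmat + 1)
  totmin <- colSums((cost == minmat) * count)
  totminmat <- matrix(totmin, 4, ncol(cost), byrow = TRUE)
  ncount <- (cost == m) * count + (m == minmat + 1) * totminmat
  list(m = m, ncount = ncount)
}

# Tip cost/count arrays (4 x npat) for one tip's encoded states.
#' @noRd
tip_cost <- function(st, npat) {
  cost <- matrix(BIGCOST, 4, npat)
  count <- matrix(0, 4, npat)
  amb <- is.na(st)
  cost[, amb] <- 0
  count[, amb] <- 1
  known <- which(!amb)
  if (length(known) > 0) {
    cost[cbind(st[known], known)] <- 0
    count[cbind(st[known], known)] <- 1
  }
  list(cost = cost, count = count)
}

# Postorder Sankoff pass; returns per-node cost/count arrays and per-node
# child messages.
#' @noRd
sankoff_down <- function(ti, pdata) {
  npat <- length(pdata$weights)
  labs <- ti$tree$tip.label
  cost <- vector("list", max(ti$edge))
  count <- vector("list", max(ti$edge))
  msg <- vector("list", max(ti$edge))  # message from node to its parent
  for (i in seq_len(ti$ntip)) {
    tc <- tip_cost(pdata$states[match(labs[i], pdata$tipnames), ], npat)
    cost[[i]] <- tc$cost
    count[[i]] <- tc$count
  }
  for (v in c(seq_len(ti$ntip), ti$post_internal)) {
    if (v > ti$ntip) {
      cs <- matrix(0, 4, npat)
      ct <- matrix(1, 4, npat)
      for (ch in ti$children[[v]]) {
        cs <- cs + msg[[ch]]$m
        ct <- ct * msg[[ch]]$ncount
      }
      cost[[v]] <- cs
      count[[v]] <- ct
    }
    if (v != ti$root) msg[[v]] <- sankoff_message(cost[[v]], count[[v]])
  }
  list(cost = cost, count = count, msg = msg)
}

#' Parsimony score of a tree (Fitch criterion)
#'
#' Minimal number of unordered state changes over all sites, with N/gap as
#' the full ambiguity set. Computed by unit-cost Sankoff dynamic
#' programming, which is exact for polytomies as well as binary trees.
#'
#' @param tree A `phylo` tree whose tips match the alignment tip names plus
#'   the germline label.
#' @param aln A `clone_alignment`.
#' @param germline_label Tip label of the germline.
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, aln, germline_label = "Germline") {
  check_tip_match(tree, aln, germline_label)
  pdata <- make_parsimony_data(aln, germline_label)
  ti <- tree_info(tree)
  sk <- sankoff_down(ti, pdata)
  score_from_down(sk, ti, pdata)
}

#' @noRd
score_from_down <- function(sk, ti, pdata) {
  rc <- sk$cost[[ti$root]]
  per_pat <- pmin(rc[1, ], rc[2, ], rc[3, ], rc[4, ])
  sum(pdata$weights * per_pat)
}

# Expected number of changes per edge, averaged uniformly over all MPRs.
# Returns a vector over edge rows (total expected changes, not per site).
#' @noRd
mpr_edge_changes <- function(ti, pdata) {
  sk <- sankoff_down(ti, pdata)
  npat <- length(pdata$weights)
  nedge <- nrow(ti$edge)
  edge_changes <- numeric(nedge)

  recurse <- function(u, ucost, ucount) {
    kids <- ti$children[[u]]
    for (v in kids) {
      B <- ucost
      CB <- ucount
      for (w in kids) {
        if (w == v) next
        B <- B + sk$msg[[w]]$m
        CB <- CB * sk$msg[[w]]$ncount
      }
      # Joint minimization over (state at u, state at v) for this edge.
      G <- rep(Inf, npat)
      for (s in 1:4) for (t in 1:4) {
        tot <- B[s, ] + sk$cost[[v]][t, ] + (s != t)
        G <- pmin(G, tot)
      }
      sumw <- numeric(npat)
      sumw_change <- numeric(npat)
      for (s in 1:4) for (t in 1:4) {
        tot <- B[s, ] + sk$cost[[v]][t, ] + (s != t)
        wgt <- (tot == G) * CB[s, ] * sk$count[[v]][t, ]
        sumw <- sumw + wgt
        if (s != t) sumw_change <- sumw_change + wgt
      }
      e_change <- ifelse(sumw > 0, sumw_change / sumw, 0)
      edge_changes[ti$edge_of[v]] <<- sum(pdata$weights * e_change)
      if (v > ti$ntip) {
        um <- sankoff_message(B, CB)
        recurse(v, um$m, um$ncount)
      }
    }
  }
  recurse(ti$root, matrix(0, 4, npat), matrix(1, 4, npat))
  edge_changes
}
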