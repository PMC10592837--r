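# Felsenstein pruning under (partitioned) GTR with missing data.
#
# Alignment columns are compressed to unique site patterns per partition.
# Ambiguous characters (N and gaps) carry all-ones conditional vectors
# (missing at random). For partition p with branch-length scalar c_p,
# transition matrices on a branch of reference length t use t * c_p.

# Structural indexing of a phylo tree, recomputed cheaply after topology
# edits. Works for arbitrary polytomies.
#' @noRd
tree_info <- function(tree) {
  edge <- tree$edge
  nt <- length(tree$tip.label)
  nnode <- max(edge)
  parent <- integer(nnode)
  edge_of <- integer(nnode)  # edge row whose child is the node
  children <- vector("list", nnode)
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    parent[ch] <- p
    edge_of[ch] <- i
    children[[p]] <- c(children[[p]], ch)
  }
  root <- setdiff(unique(edge[, 1]), edge[, 2])
  # Postorder over internal nodes (children before parents), iterative DFS.
  post <- integer(0)
  stack <- root
  visited <- logical(nnode)
  order_stack <- integer(0)
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order_stack <- c(order_stack, v)
    kids <- children[[v]]
    if (length(kids) > 0) stack <- c(stack, kids)
  }
  post <- rev(order_stack)
  post_internal <- post[post > nt]
  list(tree = tree, edge = edge, ntip = nt, root = root, parent = parent,
       edge_of = edge_of, children = children,
       postorder = post, post_internal = post_internal)
}

#' Build a partition scheme for a clone alignment
#'
#' In `single` mode the whole alignment forms one partition with scalar 1.
#' In `scaled` mode the heavy and light intervals form separate partitions;
#' the heavy scalar is pinned at 1 (reference) and the light scalar is a
#' free parameter (any joint rescaling is absorbed by branch lengths, so
#' only the ratio is identifiable).
#'
#' @param aln A `clone_alignment`.
#' @param mode `"single"` or `"scaled"`.
#' @param models Optional list of [gtr_model()]s, one per partition.
#' @return A `partition_scheme` object.
#' @export
partition_scheme <- function(aln, mode = c("single", "scaled"), models = NULL) {
  mode <- match.arg(mode)
  L <- nchar(aln$germline)
  if (mode == "single" || aln$light_interval[2] <= aln$light_interval[1]) {
    parts <- list(list(name = "all", interval = c(0L, L), scalar = 1))
    mode <- "single"
  } else {
    parts <- list(
      list(name = "heavy", interval = aln$heavy_interval, scalar = 1),
      list(name = "light", interval = aln$light_interval, scalar = 1)
    )
  }
  for (i in seq_along(parts)) {
    parts[[i]]$model <- if (!is.null(models)) models[[i]] else gtr_model()
  }
  structure(list(partitions = parts, mode = mode), class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf("partition_scheme (%s mode)\n", x$mode))
  for (p in x$partitions) {
    cat(sprintf("  %s [%d,%d) scalar %.4g\n", p$name, p$interval[1],
                p$interval[2], p$scalar))
  }
  invisible(x)
}

# Pattern-compressed likelihood data for an alignment + scheme intervals.
# Returns, per partition: integer state matrix (tips x patterns, NA for
# ambiguous), pattern weights, and precomputed 4 x npat tip conditionals.
#' @noRd
make_likelihood_data <- function(aln, scheme, germline_label = "Germline") {
  seqs <- c(aln$tip_sequences, stats::setNames(aln$germline, germline_label))
  tipnames <- names(seqs)
  enc <- lapply(seqs, encode_nuc)
  out <- list()
  for (k in seq_along(scheme$partitions)) {
    iv <- scheme$partitions[[k]]$interval
    cols <- seq.int(iv[1] + 1L, iv[2])
    S <- do.call(rbind, lapply(enc, function(e) e[cols]))
    key <- apply(S, 2, function(col) paste(ifelse(is.na(col), 0L, col), collapse = ","))
    uk <- unique(key)
    idx <- match(uk, key)
    w <- as.numeric(table(factor(key, levels = uk)))
    Su <- S[, idx, drop = FALSE]
    npat <- length(uk)
    tipcond <- vector("list", nrow(Su))
    for (i in seq_len(nrow(Su))) {
      M <- matrix(1, 4, npat)
      st <- Su[i, ]
      known <- which(!is.na(st))
      if (length(known) > 0) {
        M[, known] <- 0
        M[cbind(st[known], known)] <- 1
      }
      tipcond[[i]] <- M
    }
    names(tipcond) <- tipnames
    out[[k]] <- list(states = Su, weights = w, tipcond = tipcond,
                     nsites = length(cols))
  }
  list(partitions = out, tipnames = tipnames)
}

# Conditional (down) partials for every node, one list per partition.
#' @noRd
compute_down <- function(ti, lengths, pdata, scheme) {
  nt <- ti$ntip
  labs <- ti$tree$tip.label
  lapply(seq_along(scheme$partitions), function(k) {
    part <- scheme$partitions[[k]]
    pd <- pdata$partitions[[k]]
    Pall <- transition_matrices(part$model, lengths * part$scalar)
    D <- vector("list", max(ti$edge))
    for (i in seq_len(nt)) D[[i]] <- pd$tipcond[[labs[i]]]
    for (v in ti$post_internal) {
      M <- NULL
      for (ch in ti$children[[v]]) {
        P <- Pall[, ti$edge_of[ch]]
        dim(P) <- c(4L, 4L)
        contrib <- P %*% D[[ch]]
        M <- if (is.null(M)) contrib else M * contrib
      }
      D[[v]] <- M
    }
    D
  })
}

#' @noRd
loglik_from_down <- function(down, ti, pdata, scheme) {
  ll <- 0
  for (k in seq_along(scheme$partitions)) {
    pi <- scheme$partitions[[k]]$model$pi
    site <- as.vector(pi %*% down[[k]][[ti$root]])
    ll <- ll + sum(pdata$partitions[[k]]$weights * log(site))
  }
  ll
}

#' @noRd
full_loglik <- function(ti, lengths, pdata, scheme) {
  loglik_from_down(compute_down(ti, lengths, pdata, scheme), ti, pdata, scheme)
}

#' Partitioned log-likelihood of a tree
#'
#' Felsenstein pruning per site under the scheme's per-partition GTR models
#' and branch-length scalars; N/gap sites carry all-ones conditionals
#' (missing at random). Site log-likelihoods are summed over partitions.
#'
#' @param tree A `phylo` tree with branch lengths whose tips match the
#'   alignment tip names plus the germline label.
#' @param aln A `clone_alignment`.
#' @param scheme A [partition_scheme()].
#' @param germline_label Tip label of the germline.
#' @return The log-likelihood (a scalar).
#' @export
partitioned_log_likelihood <- function(tree, aln, scheme,
                                       germline_label = "Germline") {
  check_tip_match(tree, aln, germline_label)
  pdata <- make_likelihood_data(aln, scheme, germline_label)
  ti <- tree_info(tree)
  full_loglik(ti, tree$edge.length, pdata, scheme)
}

#' @noRd
check_tip_match <- function(tree, aln, germline_label) {
  want <- c(names(aln$tip_sequences), germline_label)
  if (!setequal(tree$tip.label, want)) {
    stop("tree tips do not match alignment tips: missing [",
         paste(setdiff(want, tree$tip.label), collapse = ","),
         "], extra [", paste(setdiff(tree$tip.label, want), collapse = ","), "]",
         call. = FALSE)
  }
  iv <- rbind(aln$heavy_interval, aln$light_interval)
  invisible(TRUE)
}

# One full coordinate-ascent sweep over all branches. Exact: down partials
# are refreshed on entry and up partials (Uin) are propagated with the newly
# optimized lengths, so every 1-D optimization sees the current likelihood.
#' @noRd
branch_sweep <- function(ti, lengths, pdata, scheme,
                         min_bl = 1e-9, max_bl = 10, tol = 1e-7) {
  down <- compute_down(ti, lengths, pdata, scheme)
  npart <- length(scheme$partitions)
  weightsl <- lapply(pdata$partitions, function(p) p$weights)
  scalars <- vapply(scheme$partitions, function(p) p$scalar, numeric(1))
  models <- lapply(scheme$partitions, function(p) p$model)

  edge_loglik <- function(Alist, Dlist, t) {
    ll <- 0
    for (k in seq_len(npart)) {
      P <- transition_matrix(models[[k]], t * scalars[k])
      site <- colSums(Alist[[k]] * (P %*% Dlist[[k]]))
      ll <- ll + sum(weightsl[[k]] * log(site))
    }
    ll
  }

  recurse <- function(u, Uin) {
    kids <- ti$children[[u]]
    for (v in kids) {
      e <- ti$edge_of[v]
      # Rest-of-tree partial at u excluding subtree(v), per partition.
      A <- vector("list", npart)
      for (k in seq_len(npart)) {
        Ak <- Uin[[k]]
        for (w in kids) {
          if (w == v) next
          P <- transition_matrix(models[[k]], lengths[ti$edge_of[w]] * scalars[k])
          Ak <- Ak * (P %*% down[[k]][[w]])
        }
        A[[k]] <- Ak
      }
      Dv <- lapply(seq_len(npart), function(k) down[[k]][[v]])
      opt <- stats::optimize(function(lt) edge_loglik(A, Dv, exp(lt)),
                             lower = log(min_bl), upper = log(max_bl),
                             maximum = TRUE, tol = tol)
      lengths[e] <<- exp(opt$maximum)
      if (v > ti$ntip) {
        Uin_v <- vector("list", npart)
        for (k in seq_len(npart)) {
          P <- transition_matrix(models[[k]], lengths[e] * scalars[k])
          Uin_v[[k]] <- crossprod(P, A[[k]])
        }
        recurse(v, Uin_v)
      }
    }
  }

  npat <- vapply(pdata$partitions, function(p) length(p$weights), integer(1))
  Uin_root <- lapply(seq_len(npart), function(k) {
    matrix(models[[k]]$pi, 4, npat[k])
  })
  recurse(ti$root, Uin_root)
  lengths
}

#' Optimize branch lengths by maximum likelihood
#'
#' Repeated coordinate-ascent sweeps of bounded 1-D optimization (Brent)
#' over every branch, until the total log-likelihood gain of a sweep falls
#' below `tol_lnl`. The log-likelihood is non-decreasing across sweeps.
#'
#' @param tree A `phylo` tree (branch lengths used as the starting point).
#' @param aln A `clone_alignment`.
#' @param scheme A [partition_scheme()].
#' @param germline_label Tip label of the germline.
#' @param min_bl,max_bl Branch-length bounds in substitutions/site.
#' @param tol_lnl Convergence tolerance on the per-sweep lnL gain.
#' @param max_sweeps Sweep cap.
#' @return The tree with optimized branch lengths; attribute `logLik` holds
#'   the final log-likelihood.
#' @export
optimize_branch_lengths <- function(tree, aln, scheme,
                                    germline_label = "Germline",
                                    min_bl = 1e-9, max_bl = 10,
                                    tol_lnl = 1e-6, max_sweeps = 20) {
  check_tip_match(tree, aln, germline_label)
  pdata <- make_likelihood_data(aln, scheme, germline_label)
  ti <- tree_info(tree)
  lengths <- pmax(tree$edge.length, min_bl)
  ll <- full_loglik(ti, lengths, pdata, scheme)
  for (s in seq_len(max_sweeps)) {
    lengths <- branch_sweep(ti, lengths, pdata, scheme, min_bl, max_bl)
    ll_new <- full_loglik(ti, lengths, pdata, scheme)
    if (!is.finite(ll_new)) stop("non-finite log-likelihood during branch optimization")
    if (ll_new - ll < tol_lnl) { ll <- max(ll, ll_new); break }
    ll <- ll_new
  }
  tree$edge.length <- lengths
  attr(tree, "logLik") <- ll
  tree
}
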