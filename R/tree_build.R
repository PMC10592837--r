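# Tree inference: neighbor-joining start trees, NNI topology search,
# maximum parsimony (with ratchet restarts), single-partition GTR maximum
# likelihood, and the scaled multi-partition GTR model with a
# maximum-likelihood light-chain branch-length scalar.

#' Tree length
#'
#' Sum of all branch lengths. For a fitted scaled multi-partition model the
#' fit's tree already carries partition-weighted branch lengths, so the sum
#' is on the substitutions/site scale of the whole alignment.
#'
#' @param x A `phylo` tree or a `bcr_fit`.
#' @return Total branch length.
#' @export
tree_length <- function(x) UseMethod("tree_length")

#' @export
tree_length.phylo <- function(x) sum(x$edge.length)

#' @export
tree_length.bcr_fit <- function(x) sum(x$tree$edge.length)

# Renumber a (possibly edited) phylo object into ape's convention: tips
# keep 1..n, internal nodes numbered in preorder from n+1, edges cladewise.
#' @noRd
normalize_phylo <- function(tree) {
  ti <- tree_info(tree)
  nt <- ti$ntip
  newid <- integer(max(ti$edge))
  newid[seq_len(nt)] <- seq_len(nt)
  nxt <- nt
  edge_rows <- integer(0)
  new_edge <- matrix(0L, nrow(ti$edge), 2)
  new_len <- numeric(nrow(ti$edge))
  k <- 0L
  assign_walk <- function(v) {
    if (v > nt) {
      nxt <<- nxt + 1L
      newid[v] <<- nxt
    }
    for (ch in ti$children[[v]]) {
      k <<- k + 1L
      new_edge[k, 2] <<- ch  # parent id filled in after the walk
      new_len[k] <<- tree$edge.length[ti$edge_of[ch]]
      parent_of[ch] <<- v
      if (ch > nt) assign_walk(ch)
    }
  }
  parent_of <- integer(max(ti$edge))
  assign_walk(ti$root)
  # Map ids
  for (i in seq_len(nrow(new_edge))) {
    ch <- new_edge[i, 2]
    new_edge[i, 1] <- newid[parent_of[ch]]
    new_edge[i, 2] <- newid[ch]
  }
  out <- list(edge = new_edge, edge.length = new_len,
              tip.label = tree$tip.label, Nnode = nxt - nt)
  class(out) <- "phylo"
  attr(out, "order") <- "cladewise"
  out
}

# Pairwise JC69-corrected distance matrix with pairwise deletion of N/gap.
#' @noRd
jc_distance_matrix <- function(seqs) {
  n <- length(seqs)
  enc <- lapply(seqs, encode_nuc)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- enc[[i]]; b <- enc[[j]]
      ok <- !is.na(a) & !is.na(b)
      p <- if (any(ok)) sum(a[ok] != b[ok]) / sum(ok) else 0
      p <- min(p, 0.70)
      d <- -0.75 * log(1 - 4 * p / 3)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# Neighbor-joining start tree rooted on the germline tip.
#' @noRd
start_tree_nj <- function(aln, germline_label = "Germline", min_bl = 1e-9) {
  seqs <- c(aln$tip_sequences, stats::setNames(aln$germline, germline_label))
  n <- length(seqs)
  if (n < 3) {
    stop("tree building requires at least 3 tips (including the germline)",
         call. = FALSE)
  }
  if (n == 3) {
    tr <- list(edge = matrix(c(4L, 4L, 4L, 1L, 2L, 3L), 3, 2),
               edge.length = rep(0.01, 3),
               tip.label = names(seqs), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  D <- jc_distance_matrix(seqs)
  tr <- ape::nj(D)
  tr <- ape::root(tr, outgroup = germline_label, resolve.root = TRUE)
  tr$edge.length <- pmax(tr$edge.length, min_bl)
  normalize_phylo(tr)
}

# All NNI moves of a rooted tree: for each non-root internal node v with
# parent u, swap a child of v with a sibling of v. Returns list of moves.
#' @noRd
nni_moves <- function(ti) {
  moves <- list()
  for (v in seq_len(max(ti$edge))) {
    if (v <= ti$ntip || v == ti$root) next
    u <- ti$parent[v]
    sibs <- setdiff(ti$children[[u]], v)
    for (s in sibs) for (ch in ti$children[[v]]) {
      moves[[length(moves) + 1]] <- c(v = v, s = s, c = ch)
    }
  }
  moves
}

#' @noRd
apply_nni <- function(tree, move) {
  edge <- tree$edge
  row_s <- which(edge[, 2] == move["s"])
  row_c <- which(edge[, 2] == move["c"])
  u <- edge[row_s, 1]
  edge[row_s, 1] <- move["v"]
  edge[row_c, 1] <- u
  tree$edge <- edge
  tree
}

#' @noRd
new_fit <- function(method, mode, tree, logLik = NA_real_, score = NA_real_,
                    scheme = NULL, light_scalar = NA_real_, iterations = NA_integer_,
                    seed = NULL, germline_label = "Germline", convergence = list()) {
  structure(list(
    method = method, mode = mode, tree = tree, log_likelihood = logLik,
    parsimony_score = score, scheme = scheme, light_scalar = light_scalar,
    tree_length = sum(tree$edge.length), iterations = iterations,
    seed = seed, germline_label = germline_label, convergence = convergence
  ), class = "bcr_fit")
}

#' @export
print.bcr_fit <- function(x, ...) {
  cat(sprintf("bcr_fit [%s]: %d tips, tree length %.5g", x$method,
              length(x$tree$tip.label), x$tree_length))
  if (!is.na(x$log_likelihood)) cat(sprintf(", lnL %.4f", x$log_likelihood))
  if (!is.na(x$parsimony_score)) cat(sprintf(", score %g", x$parsimony_score))
  if (!is.na(x$light_scalar)) cat(sprintf(", light scalar %.3f", x$light_scalar))
  cat("\n")
  invisible(x)
}

#' Maximum parsimony tree search
#'
#' NNI hill-climb on the parsimony score with random-restart ratchet
#' perturbations, starting from a neighbor-joining topology. Branch lengths
#' are expected per-edge change counts averaged uniformly over all
#' most-parsimonious reconstructions, reported as changes per site.
#'
#' @param aln A `clone_alignment`.
#' @param germline_label Tip label of the germline.
#' @param seed Integer seed making the ratchet deterministic.
#' @param restarts Number of ratchet restarts (default 2).
#' @param perturb_moves Random NNI moves applied per restart perturbation.
#' @return A `bcr_fit` with `parsimony_score` and a germline-rooted tree in
#'   changes/site.
#' @export
parsimony_search <- function(aln, germline_label = "Germline", seed = NULL,
                             restarts = 2, perturb_moves = 4) {
  ntips <- length(aln$tip_sequences) + 1L
  pdata <- make_parsimony_data(aln, germline_label)
  if (ntips < 3) {
    warning("fewer than 3 tips; returning trivial tree")
    tr <- list(edge = matrix(c(rep(ntips + 1L, ntips), seq_len(ntips)), ntips, 2),
               edge.length = rep(0, ntips),
               tip.label = pdata$tipnames, Nnode = 1L)
    class(tr) <- "phylo"
    return(new_fit("parsimony", "HL", tr, score = fitch_score_pd(tr, pdata),
                   germline_label = germline_label))
  }
  climb <- function(tree) {
    ti <- tree_info(tree)
    sc <- score_from_down(sankoff_down(ti, pdata), ti, pdata)
    repeat {
      moves <- nni_moves(ti)
      best_sc <- sc
      best_tree <- NULL
      for (mv in moves) {
        cand <- apply_nni(tree, mv)
        tic <- tree_info(cand)
        s <- score_from_down(sankoff_down(tic, pdata), tic, pdata)
        if (s < best_sc) {  # strict improvement; first-found kept on ties
          best_sc <- s
          best_tree <- cand
        }
      }
      if (is.null(best_tree)) break
      tree <- best_tree
      ti <- tree_info(tree)
      sc <- best_sc
    }
    list(tree = tree, score = sc)
  }
  with_seed_opt(seed, {
    start <- start_tree_nj(aln, germline_label)
    best <- climb(start)
    r <- 0
    while (r < restarts) {
      r <- r + 1
      pert <- best$tree
      for (k in seq_len(perturb_moves)) {
        mvs <- nni_moves(tree_info(pert))
        if (length(mvs) == 0) break
        pert <- apply_nni(pert, mvs[[sample.int(length(mvs), 1)]])
      }
      cand <- climb(pert)
      if (cand$score < best$score) best <- cand
    }
    ti <- tree_info(best$tree)
    changes <- mpr_edge_changes(ti, pdata)
    tree <- best$tree
    tree$edge.length <- changes / pdata$nsites
    tree <- normalize_phylo(tree)
    new_fit("parsimony", "HL", tree, score = best$score,
            iterations = r, seed = seed, germline_label = germline_label)
  })
}

#' @noRd
fitch_score_pd <- function(tree, pdata) {
  ti <- tree_info(tree)
  score_from_down(sankoff_down(ti, pdata), ti, pdata)
}

# Log-likelihood of a single partition (used for per-partition parameter
# estimation; other partitions are unaffected by its parameters).
#' @noRd
partition_loglik <- function(ti, lengths, pd, model, scalar) {
  nt <- ti$ntip
  labs <- ti$tree$tip.label
  Pall <- transition_matrices(model, lengths * scalar)
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
  site <- as.vector(model$pi %*% D[[ti$root]])
  sum(pd$weights * log(site))
}

#' @noRd
estimate_exchangeabilities <- function(ti, lengths, pd, model, scalar,
                                       maxit = 15) {
  obj <- function(lr) {
    m <- gtr_model(model$pi, c(exp(lr), 1))
    -partition_loglik(ti, lengths, pd, m, scalar)
  }
  fit <- stats::optim(log(model$rates[1:5] / model$rates[6]), obj,
                      method = "L-BFGS-B",
                      lower = log(1e-3), upper = log(1e3),
                      control = list(maxit = maxit))
  gtr_model(model$pi, c(exp(fit$par), 1))
}

#' Estimate partition scalars and GTR parameters
#'
#' For a scaled multi-partition scheme: base frequencies are empirical
#' counts from each partition's non-ambiguous sites, exchangeabilities are
#' estimated by bounded numerical maximum likelihood per partition, and the
#' light-chain scalar is optimized by bounded 1-D search on `[1e-3, 100]`
#' (heavy scalar pinned at 1). Coordinate ascent alternates these updates
#' with branch-length sweeps until the joint log-likelihood gain falls
#' below `tol`. If the light partition is entirely ambiguous across all
#' tips the scalar is unidentifiable and fixed at 1 with a warning.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param aln A `clone_alignment`.
#' @param scheme A [partition_scheme()] in scaled (or single) mode.
#' @param germline_label Tip label of the germline.
#' @param optimize_model Estimate exchangeabilities (default TRUE).
#' @param tol Joint lnL convergence tolerance.
#' @param max_iter Coordinate-ascent cap.
#' @return A list with `scheme`, `tree` (branch lengths re-optimized) and
#'   `logLik`.
#' @export
optimize_scalars_and_model <- function(tree, aln, scheme,
                                       germline_label = "Germline",
                                       optimize_model = TRUE,
                                       tol = 1e-5, max_iter = 6) {
  pdata <- make_likelihood_data(aln, scheme, germline_label)
  ti <- tree_info(tree)
  lengths <- pmax(tree$edge.length, 1e-9)

  # Empirical frequencies per partition.
  for (k in seq_along(scheme$partitions)) {
    pd <- pdata$partitions[[k]]
    scheme$partitions[[k]]$model <- gtr_model(
      empirical_frequencies(pd$states, pd$weights),
      scheme$partitions[[k]]$model$rates)
  }

  light_k <- which(vapply(scheme$partitions, function(p) p$name == "light", logical(1)))
  scalar_identifiable <- TRUE
  if (length(light_k) == 1) {
    st <- pdata$partitions[[light_k]]$states
    cell_rows <- which(pdata$tipnames != germline_label)
    if (all(is.na(st[cell_rows, , drop = FALSE]))) {
      warning("light partition entirely ambiguous; scalar fixed at 1")
      scheme$partitions[[light_k]]$scalar <- 1
      scalar_identifiable <- FALSE
    }
  }

  ll <- full_loglik(ti, lengths, pdata, scheme)
  for (it in seq_len(max_iter)) {
    if (optimize_model) {
      for (k in seq_along(scheme$partitions)) {
        scheme$partitions[[k]]$model <- estimate_exchangeabilities(
          ti, lengths, pdata$partitions[[k]], scheme$partitions[[k]]$model,
          scheme$partitions[[k]]$scalar)
      }
    }
    if (length(light_k) == 1 && scalar_identifiable) {
      pd <- pdata$partitions[[light_k]]
      mdl <- scheme$partitions[[light_k]]$model
      opt <- stats::optimize(function(lc) {
        partition_loglik(ti, lengths, pd, mdl, exp(lc))
      }, lower = log(1e-3), upper = log(100), maximum = TRUE, tol = 1e-6)
      scheme$partitions[[light_k]]$scalar <- exp(opt$maximum)
    }
    lengths <- branch_sweep(ti, lengths, pdata, scheme)
    ll_new <- full_loglik(ti, lengths, pdata, scheme)
    if (ll_new - ll < tol) { ll <- max(ll, ll_new); break }
    ll <- ll_new
  }
  tree$edge.length <- lengths
  list(scheme = scheme, tree = tree, logLik = ll)
}

#' Maximum likelihood tree search
#'
#' Builds a start tree by neighbor joining on pairwise JC-corrected
#' distances (pairwise deletion of N/gap), then hill-climbs with NNI,
#' re-optimizing branch lengths after each accepted rearrangement, until no
#' rearrangement improves the log-likelihood by more than `tol`. In
#' `scaled` mode the heavy/light partitions get separate GTR parameters and
#' the light branch-length scalar is estimated by maximum likelihood; the
#' returned tree's branch lengths are partition-weighted so their sum is on
#' the substitutions/site scale of the whole alignment. The germline tip is
#' present throughout and the returned tree is rooted on it.
#'
#' @param aln A `clone_alignment`.
#' @param mode `"single"` (one partition) or `"scaled"` (heavy/light
#'   partitions with an ML light scalar).
#' @param germline_label Tip label of the germline.
#' @param optimize_model Estimate GTR exchangeabilities (default TRUE);
#'   base frequencies are always empirical.
#' @param max_nni_rounds NNI round cap.
#' @param tol lnL improvement threshold for accepting rearrangements.
#' @param seed Seed recorded in the fit (tie-breaking among equal-lnL
#'   rearrangements is deterministic: first-found order).
#' @return A `bcr_fit`.
#' @export
ml_search <- function(aln, mode = c("single", "scaled"),
                      germline_label = "Germline", optimize_model = TRUE,
                      max_nni_rounds = 20, tol = 1e-6, seed = NULL) {
  mode <- match.arg(mode)
  scheme <- partition_scheme(aln, mode)
  pdata <- make_likelihood_data(aln, scheme, germline_label)
  for (k in seq_along(scheme$partitions)) {
    pd <- pdata$partitions[[k]]
    scheme$partitions[[k]]$model <- gtr_model(
      empirical_frequencies(pd$states, pd$weights))
  }

  tree <- start_tree_nj(aln, germline_label)
  ti <- tree_info(tree)
  lengths <- pmax(tree$edge.length, 1e-9)
  for (s in 1:2) lengths <- branch_sweep(ti, lengths, pdata, scheme)
  if (optimize_model) {
    for (k in seq_along(scheme$partitions)) {
      scheme$partitions[[k]]$model <- estimate_exchangeabilities(
        ti, lengths, pdata$partitions[[k]], scheme$partitions[[k]]$model,
        scheme$partitions[[k]]$scalar, maxit = 10)
    }
    lengths <- branch_sweep(ti, lengths, pdata, scheme)
  }
  ll <- full_loglik(ti, lengths, pdata, scheme)

  rounds <- 0
  repeat {
    if (rounds >= max_nni_rounds) break
    rounds <- rounds + 1
    tree$edge.length <- lengths
    moves <- nni_moves(ti)
    if (length(moves) == 0) break
    best_ll <- ll
    best_tree <- NULL
    for (mv in moves) {
      cand <- apply_nni(tree, mv)
      llc <- full_loglik(tree_info(cand), lengths, pdata, scheme)
      if (llc > best_ll + tol) {
        best_ll <- llc
        best_tree <- cand
      }
    }
    if (is.null(best_tree)) {
      # Refinement: re-try the most promising rearrangements with their
      # central branch re-optimized before declaring convergence.
      scored <- vapply(moves, function(mv) {
        full_loglik(tree_info(apply_nni(tree, mv)), lengths, pdata, scheme)
      }, numeric(1))
      for (mi in order(-scored)[seq_len(min(5, length(moves)))]) {
        cand <- apply_nni(tree, moves[[mi]])
        tic <- tree_info(cand)
        e <- tic$edge_of[moves[[mi]]["v"]]
        lcand <- lengths
        opt <- stats::optimize(function(lt) {
          lcand[e] <- exp(lt)
          full_loglik(tic, lcand, pdata, scheme)
        }, lower = log(1e-9), upper = log(10), maximum = TRUE, tol = 1e-4)
        if (opt$objective > best_ll + tol) {
          best_ll <- opt$objective
          lengths[e] <- exp(opt$maximum)
          best_tree <- cand
          break
        }
      }
      if (is.null(best_tree)) break
    }
    tree <- best_tree
    ti <- tree_info(tree)
    for (s in 1:2) lengths <- branch_sweep(ti, lengths, pdata, scheme)
    ll <- full_loglik(ti, lengths, pdata, scheme)
  }

  # Final polish: scalars/model (scaled) and branch lengths to tolerance.
  tree$edge.length <- lengths
  if (mode == "scaled") {
    res <- optimize_scalars_and_model(tree, aln, scheme,
                                      germline_label = germline_label,
                                      optimize_model = optimize_model)
    tree <- res$tree
    scheme <- res$scheme
    ll <- res$logLik
  } else {
    tree <- optimize_branch_lengths(tree, aln, scheme,
                                    germline_label = germline_label)
    ll <- attr(tree, "logLik")
  }

  # Partition-weighted reporting scale.
  Ls <- vapply(seq_along(scheme$partitions), function(k) {
    pdata$partitions[[k]]$nsites
  }, numeric(1))
  cs <- vapply(scheme$partitions, function(p) p$scalar, numeric(1))
  wfac <- sum(cs * Ls) / sum(Ls)
  light_scalar <- if (mode == "scaled") {
    cs[vapply(scheme$partitions, function(p) p$name == "light", logical(1))]
  } else NA_real_
  out_tree <- tree
  out_tree$edge.length <- tree$edge.length * wfac
  out_tree <- normalize_phylo(out_tree)
  new_fit(paste0("ml-", mode), mode, out_tree, logLik = ll, scheme = scheme,
          light_scalar = if (length(light_scalar) == 1) light_scalar else NA_real_,
          iterations = rounds, seed = seed, germline_label = germline_label,
          convergence = list(nni_rounds = rounds))
}
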