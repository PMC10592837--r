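# Benchmark harness: simulate clones, mask light chains, fit trees with
# each method in paired (H+L) and matched heavy-only (H) modes, and score
# topology (RF cluster distance to the true tree) and tree-length error.

BENCH_METHODS <- c("parsimony", "ml-single", "ml-scaled")

#' @noRd
fit_method <- function(aln, method, germline_label = "Germline", seed = NULL,
                       optimize_model = TRUE, max_nni_rounds = 20) {
  switch(method,
    "parsimony" = parsimony_search(aln, germline_label = germline_label, seed = seed),
    "ml-single" = ml_search(aln, mode = "single", germline_label = germline_label,
                            optimize_model = optimize_model,
                            max_nni_rounds = max_nni_rounds, seed = seed),
    "ml-scaled" = ml_search(aln, mode = "scaled", germline_label = germline_label,
                            optimize_model = optimize_model,
                            max_nni_rounds = max_nni_rounds, seed = seed),
    stop("unknown method '", method, "'; valid: ",
         paste(BENCH_METHODS, collapse = ", "), call. = FALSE)
  )
}

#' Default benchmark configuration
#'
#' @param ... Overrides for the default fields.
#' @return A named list configuration for [run_benchmark()].
#' @export
benchmark_config <- function(...) {
  cfg <- list(
    n_replicates = 1,
    n_clones = 20,
    n_tips = 20,
    branch_mean_events = 4,
    rate_ratio = 0.5,
    len_h = 360, len_l = 330,
    methods = BENCH_METHODS,
    modes = c("H+L", "H"),
    fractions = 0,
    seed = 1,
    collapse_threshold = 0.001,
    min_clone_size = 3,
    optimize_model = TRUE,
    max_nni_rounds = 20
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the missing-light-chain benchmark
#'
#' For each (replicate, clone, masking fraction, method, chain mode):
#' simulates paired clones, masks the requested fraction of light chains
#' (every clone keeps at least one paired cell), builds the concatenated
#' H+L alignment (and the matched heavy-only alignment), fits the tree, and
#' records the RF cluster distance to the true tree and the percent
#' tree-length error. Fully reproducible from the config seed.
#'
#' @param config A [benchmark_config()] list. Unknown method names raise an
#'   error.
#' @return A tibble with one row per design cell per clone:
#'   `replicate`, `clone`, `fraction`, `method`, `mode`, `n_tips_fit`,
#'   `rf`, `tree_length_true`, `tree_length_est`, `percent_length_error`
#'   (signed, (true-est)/true), `light_scalar`.
#' @export
run_benchmark <- function(config = benchmark_config()) {
  cfg <- benchmark_config()
  cfg[names(config)] <- config
  bad <- setdiff(cfg$methods, BENCH_METHODS)
  if (length(bad) > 0) {
    stop("unknown method name(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(BENCH_METHODS, collapse = ", "), call. = FALSE)
  }
  bad_modes <- setdiff(cfg$modes, c("H+L", "H"))
  if (length(bad_modes) > 0) {
    stop("unknown mode(s): ", paste(bad_modes, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (rep_i in seq_len(cfg$n_replicates)) {
    sims <- lapply(seq_len(cfg$n_clones), function(ci) {
      simulate_clone(cfg$n_tips, cfg$branch_mean_events, cfg$rate_ratio,
                     germ = simulate_germline_pair(cfg$len_h, cfg$len_l,
                       seed = child_seed(cfg$seed, rep_i * 10000 + ci)),
                     seed = child_seed(cfg$seed, rep_i * 10000 + ci + 5000))
    })
    for (fi in seq_along(cfg$fractions)) {
      f <- cfg$fractions[fi]
      masked <- mask_light_chains(sims, f,
                                  seed = child_seed(cfg$seed, 90000 + rep_i * 100 + fi))
      for (ci in seq_along(masked)) {
        sim <- masked[[ci]]
        aln <- clone_sim_alignment(sim, clone_id = sprintf("c%03d", ci))
        if (length(aln$tip_sequences) < cfg$min_clone_size) next
        aln_h <- make_heavy_only(aln)
        # True trees pruned to the tips kept after duplicate collapsing.
        keep <- names(aln$tip_sequences)
        prune <- function(tr) {
          drop <- setdiff(tr$tip.label, c(keep, sim$germline_label))
          if (length(drop) > 0) ape::drop.tip(tr, drop) else tr
        }
        true_hl <- prune(sim$tree)
        true_h <- prune(sim$tree_heavy)
        for (method in cfg$methods) {
          for (mode in cfg$modes) {
            use_aln <- if (mode == "H+L") aln else aln_h
            true_tree <- if (mode == "H+L") true_hl else true_h
            fit <- fit_method(use_aln, method, seed = child_seed(cfg$seed, ci),
                              optimize_model = cfg$optimize_model,
                              max_nni_rounds = cfg$max_nni_rounds)
            rf <- rf_cluster_distance(fit$tree, true_tree,
                                      threshold = cfg$collapse_threshold)
            tl_true <- tree_length(true_tree)
            tl_est <- tree_length(fit)
            rows[[length(rows) + 1]] <- tibble::tibble(
              replicate = rep_i, clone = ci, fraction = f,
              method = method, mode = mode,
              n_tips_fit = length(use_aln$tip_sequences),
              rf = rf$distance,
              tree_length_true = tl_true,
              tree_length_est = tl_est,
              percent_length_error = percent_length_error(tl_true, tl_est),
              light_scalar = fit$light_scalar
            )
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the 3-taxa triplet benchmark
#'
#' Repeats the triplet simulation and estimates each branch length with the
#' requested methods under the single-cell (SC) and mixed (SC+bulk, tip B's
#' light chain removed) designs. Branches are identified by the tip they
#' lead to (`A`, `B`, `Germline`).
#'
#' @param n_reps Number of simulated triplets.
#' @param methods Subset of `parsimony`, `ml-single`, `ml-scaled`.
#' @param variants Subset of `SC`, `SC+bulk`.
#' @param m_h,m_l Heavy/light mutation events per branch.
#' @param seed Base seed.
#' @param optimize_model Estimate GTR exchangeabilities in ML fits.
#' @return A tibble: `rep`, `variant`, `method`, `branch`, `true_len`,
#'   `est_len`, `error` (signed, (est-true)/true).
#' @export
run_triplet_benchmark <- function(n_reps = 200,
                                  methods = BENCH_METHODS,
                                  variants = c("SC", "SC+bulk"),
                                  m_h = 25, m_l = 12, seed = 1,
                                  optimize_model = FALSE) {
  bad <- setdiff(methods, BENCH_METHODS)
  if (length(bad) > 0) stop("unknown method name(s): ", paste(bad, collapse = ", "))
  rows <- list()
  for (r in seq_len(n_reps)) {
    sim <- simulate_triplet(m_h = m_h, m_l = m_l, seed = child_seed(seed, r))
    for (variant in variants) {
      aln <- triplet_alignment(sim, variant)
      for (method in methods) {
        fit <- fit_method(aln, method, seed = child_seed(seed, r),
                          optimize_model = optimize_model)
        tr <- fit$tree
        ti <- tree_info(tr)
        for (tipname in c("A", "B", "Germline")) {
          tip <- match(tipname, tr$tip.label)
          est <- tr$edge.length[ti$edge_of[tip]]
          # All three branches of a triplet share the same true length.
          true_len <- sim$true_branch_length
          rows[[length(rows) + 1]] <- tibble::tibble(
            rep = r, variant = variant, method = method, branch = tipname,
            true_len = true_len, est_len = est,
            error = (est - true_len) / true_len)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
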