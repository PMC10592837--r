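test_that("targeted mutation applies exactly n events and never touches N or gaps", {
  seq <- "ACGTACGTNNACGT--ACGT"
  out <- apply_targeted_mutations(seq, 8, seed = 101)
  expect_equal(nrow(out$events), 8)
  expect_equal(nchar(out$sequence), nchar(seq))
  oc <- strsplit(seq, "")[[1]]
  nc <- strsplit(out$sequence, "")[[1]]
  expect_true(all(nc[oc == "N"] == "N"))
  expect_true(all(nc[oc == "-"] == "-"))
  # Each position is mutated at most once per call, so every event is an
  # observable point difference.
  expect_equal(sum(oc != nc), 8)
  expect_equal(anyDuplicated(out$events$pos), 0L)
  # Every recorded event changes the base it hits.
  expect_true(all(out$events$from != out$events$to))
  expect_true(all(out$events$to %in% c("A", "C", "G", "T")))
})

test_that("mutating an unmutable sequence errors and zero events is identity", {
  expect_error(apply_targeted_mutations("NNNNNNNN", 1), "no mutable")
  expect_error(apply_targeted_mutations("ACGTACGT", 9), "mutable positions")
  expect_equal(apply_targeted_mutations("ACGTACGT", 0)$sequence, "ACGTACGT")
})

test_that("targeted mutation is deterministic under a fixed seed", {
  s <- strrep("ACGT", 25)
  a <- apply_targeted_mutations(s, 10, seed = 77)
  b <- apply_targeted_mutations(s, 10, seed = 77)
  expect_equal(a$sequence, b$sequence)
  expect_equal(a$events, b$events)
})

test_that("hotspot contexts are mutated more often than coldspots", {
  # Alternate isolated AACAA (WRC hotspot at the C) and CCCAA (SYC coldspot
  # at the middle C) blocks separated by neutral spacers, and count hits at
  # the two focal positions over many 1-event draws.
  unit <- paste0("AACAA", "TTTTT", "CCCAA", "TTTTT")
  s <- strrep(unit, 5)
  hot_pos <- (0:4) * 20 + 3
  cold_pos <- (0:4) * 20 + 13
  hits_hot <- 0; hits_cold <- 0
  withr::with_seed(202, {
    for (i in 1:400) {
      ev <- apply_targeted_mutations(s, 1)$events
      if (ev$pos %in% hot_pos) hits_hot <- hits_hot + 1
      if (ev$pos %in% cold_pos) hits_cold <- hits_cold + 1
    }
  })
  # Mutability ratio hot/cold is 3.5/0.4 = 8.75; with 400 draws the counts
  # separate decisively.
  expect_gt(hits_hot, hits_cold * 2)
})

test_that("a table-backed targeting model validates and drives substitutions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "fivemer\tmutability\tp_a\tp_c\tp_g\tp_t",
    "ACGTA\t5\t1\t0\t0\t0",
    "AAAAA\t0.1\t0\t0.5\t0.5\t0"), path)
  tm <- read_targeting_model(path)
  expect_s3_class(tm, "targeting_model")
  expect_output(print(tm), "2 5-mers")
  # Center base of ACGTA is G; its distribution sends every hit to A.
  out <- apply_targeted_mutations("AACGTAA", 1, model = tm, seed = 3)
  expect_equal(out$sequence, "AACATAA")

  bad_id <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("fivemer\tmutability\tp_a\tp_c\tp_g\tp_t",
               "ACGTA\t5\t0\t0\t1\t0"), bad_id)
  expect_error(read_targeting_model(bad_id), "identity")

  bad_sum <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("fivemer\tmutability\tp_a\tp_c\tp_g\tp_t",
               "ACGTA\t5\t0.5\t0\t0\t0.4"), bad_sum)
  expect_error(read_targeting_model(bad_sum), "sum to 1")

  bad_cols <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("fivemer\tmutability", "ACGTA\t5"), bad_cols)
  expect_error(read_targeting_model(bad_cols), "p_a")
})

test_that("germline pairs have the requested lengths and plain bases", {
  g <- simulate_germline_pair(len_h = 50, len_l = 40, seed = 9)
  expect_equal(nchar(g$heavy), 50)
  expect_equal(nchar(g$light), 40)
  expect_true(grepl("^[ACGT]+$", g$heavy))
  expect_equal(simulate_germline_pair(seed = 9)$heavy,
               simulate_germline_pair(seed = 9)$heavy)
})

test_that("triplet truth bookkeeping matches the event counts and lengths", {
  sim <- simulate_triplet(m_h = 25, m_l = 12, seed = 301)
  expect_equal(sim$true_branch_length, 37 / 690)
  expect_equal(sim$true_branch_length_heavy, 25 / 360)
  # Each branch applies its events at distinct positions, so single-branch
  # Hamming distances equal the event counts (back mutations only arise
  # across branches).
  h <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  expect_equal(h(sim$germ$heavy, sim$internal$heavy), 25)
  expect_equal(h(sim$internal$heavy, sim$tipA$heavy), 25)
  expect_equal(h(sim$internal$light, sim$tipB$light), 12)
  expect_lte(h(sim$germ$heavy, sim$tipA$heavy), 50)
})

test_that("the SC+bulk variant replaces tip B's light chain with Ns", {
  sim <- simulate_triplet(seed = 302)
  sc <- triplet_alignment(sim, "SC")
  bulk <- triplet_alignment(sim, "SC+bulk")
  Lh <- sim$len_h
  expect_equal(substr(bulk$tip_sequences[["B"]], Lh + 1, Lh + sim$len_l),
               strrep("N", sim$len_l))
  expect_equal(substr(bulk$tip_sequences[["B"]], 1, Lh),
               substr(sc$tip_sequences[["B"]], 1, Lh))
  expect_false(bulk$light_present[["B"]])
  expect_true(all(sc$light_present))
  ho <- triplet_alignment(sim, "SC", heavy_only = TRUE)
  expect_equal(nchar(ho$germline), Lh)
})

test_that("simulated clone branch lengths equal event counts over sites", {
  sim <- simulate_clone(6, 4, 0.5, seed = 401)
  Lh <- sim$params$len_h; Ll <- sim$params$len_l
  expect_equal(tree_length(sim$tree),
               sum(sim$events$heavy + sim$events$light) / (Lh + Ll))
  expect_equal(tree_length(sim$tree_heavy), sum(sim$events$heavy) / Lh)
  # The germline pendant branch carries no events: root IS the germline.
  expect_equal(divergence(sim$tree, sim$germline_label), 0)
  expect_equal(length(sim$heavy), 6)
  expect_equal(names(sim$heavy), names(sim$light))
  expect_error(simulate_clone(1), "n_tips")
})

test_that("light events accrue at roughly the requested rate ratio", {
  withr::with_seed(411, {
    tot_h <- 0; tot_l <- 0
    for (i in 1:12) {
      sim <- simulate_clone(8, 6, rate_ratio = 0.5)
      tot_h <- tot_h + sum(sim$events$heavy)
      tot_l <- tot_l + sum(sim$events$light)
    }
  })
  # ~1000 heavy events; the ratio of Poisson totals concentrates near 0.5.
  expect_gt(tot_l / tot_h, 0.4)
  expect_lt(tot_l / tot_h, 0.6)
})

test_that("masking hits the rounded fraction but always leaves a paired cell", {
  sim <- simulate_clone(20, 4, 0.5, seed = 421)
  m50 <- mask_light_chains(sim, 0.5, seed = 1)
  expect_equal(length(m50$masked), 10)
  m95 <- mask_light_chains(sim, 0.95, seed = 1)
  expect_equal(length(m95$masked), 19)
  expect_equal(length(setdiff(names(m95$heavy), m95$masked)), 1)
  m0 <- mask_light_chains(sim, 0, seed = 1)
  expect_equal(length(m0$masked), 0)
  expect_error(mask_light_chains(sim, 1), "fraction")
  expect_error(mask_light_chains(sim, -0.1), "fraction")
  # List input masks each clone independently and preserves structure.
  sims <- mask_light_chains(list(sim, sim), 0.25, seed = 2)
  expect_equal(vapply(sims, function(s) length(s$masked), integer(1)), c(5L, 5L))
})

test_that("simulated AIRR export has one heavy row per cell and drops masked lights", {
  sim <- mask_light_chains(simulate_clone(5, 4, 0.5, seed = 431), 0.5, seed = 2)
  rec <- clone_sim_airr(sim, clone_id = "cl7", cell_prefix = "cl7_")
  expect_equal(sum(rec$locus == "IGH"), 5)
  expect_equal(sum(rec$locus == "IGK"), 5 - length(sim$masked))
  expect_true(all(startsWith(rec$cell_id, "cl7_")))
  expect_true(all(rec$clone_id == "cl7"))
  masked_ids <- paste0("cl7_", sim$masked)
  expect_false(any(rec$cell_id %in% masked_ids & rec$locus == "IGK"))
  expect_equal(validate_airr(rec), rec, ignore_attr = TRUE)
})

test_that("masked cells show an all-N light interval in the pipeline alignment", {
  sim <- mask_light_chains(simulate_clone(8, 4, 0.5, seed = 441), 0.95, seed = 3)
  aln <- clone_sim_alignment(sim, collapse = FALSE)
  Lh <- diff(aln$heavy_interval); Ll <- diff(aln$light_interval)
  expect_equal(Lh, nchar(sim$germ$heavy))
  expect_equal(Ll, nchar(sim$germ$light))
  light_part <- substr(aln$tip_sequences, Lh + 1, Lh + Ll)
  names(light_part) <- names(aln$tip_sequences)
  for (cell in names(aln$tip_sequences)) {
    if (cell %in% sim$masked) {
      expect_equal(light_part[[cell]], strrep("N", Ll))
      expect_false(aln$light_present[[cell]])
    } else {
      expect_true(grepl("[ACGT]", light_part[[cell]]))
    }
  }
  # The >= 1 paired-cell guarantee holds at the alignment level too.
  expect_gte(sum(aln$light_present), 1)
})
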