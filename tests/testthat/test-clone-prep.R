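# Helpers to assemble per-clone cell bundles through the public pipeline.
bundles_from <- function(df) group_cells(df)$bundles

pair_rows <- function(cell, heavy, light = NULL, light_v = "IGKV1-39*01",
                      light_j = "IGKJ2*01", light_jl = 33L,
                      germ_h = strrep("A", nchar(heavy)),
                      clone_id = "clone1") {
  rows <- airr_row(paste0(cell, "_H"), cell, "IGH", heavy, germ_h,
                   clone_id = clone_id)
  if (!is.null(light)) {
    rows <- dplyr::bind_rows(rows, airr_row(
      paste0(cell, "_L"), cell, "IGK", light, strrep("A", nchar(light)),
      v_call = light_v, j_call = light_j, junction_length = light_jl,
      clone_id = clone_id))
  }
  rows
}

test_that("cells sharing one light V/J/junction-length combination form one subgroup", {
  df <- dplyr::bind_rows(
    pair_rows("c1", "ACGTACGT", "GGCCGGCC"),
    pair_rows("c2", "ACGAACGT", "GGCCGGCA"),
    pair_rows("c3", "ACGTACGA", "GGCCGGCG")
  )
  res <- resolve_light_chains(bundles_from(df))
  expect_equal(nrow(res$subgroups), 1)
  expect_equal(res$subgroups$size, 3)
  expect_true(all(res$assignments$subgroup_index == 1))
})

test_that("allele suffixes are stripped so different alleles of one gene group together", {
  df <- dplyr::bind_rows(
    pair_rows("c1", "ACGTACGT", "GGCCGGCC", light_v = "IGKV1-39*01"),
    pair_rows("c2", "ACGAACGT", "GGCCGGCA", light_v = "IGKV1-39*02")
  )
  res <- resolve_light_chains(bundles_from(df))
  expect_equal(nrow(res$subgroups), 1)
  expect_equal(res$subgroups$light_v_gene, "IGKV1-39")
})

test_that("a multi-valued light v_call joins the largest compatible grouping", {
  # c1..c3 support IGKV1-39; c4 supports IGKV3-20 only; c5 is ambiguous
  # between both genes and must join the larger IGKV1-39 grouping.
  df <- dplyr::bind_rows(
    pair_rows("c1", "ACGTACGT", "GGCCGGCC"),
    pair_rows("c2", "ACGAACGT", "GGCCGGCA"),
    pair_rows("c3", "ACGTACGA", "GGCCGGCG"),
    pair_rows("c4", "TTTTACGT", "GGCCGGTT", light_v = "IGKV3-20*01"),
    pair_rows("c5", "ACGTACCC", "GGCCGGAA",
              light_v = "IGKV1-39*01,IGKV3-20*01")
  )
  res <- resolve_light_chains(bundles_from(df))
  asg <- res$assignments
  expect_equal(asg$subgroup_index[asg$cell_id == "c5"],
               asg$subgroup_index[asg$cell_id == "c1"])
  expect_equal(res$subgroups$size[res$subgroups$subgroup_index == 1], 4)
})

test_that("a light-less cell joins the subgroup of its nearest heavy chain", {
  base <- "AAAAAAAAAA"
  near_s1 <- "AAAAAAAATT"    # Hamming 2 from base
  far_s2 <- "GGGGGGGGGG"
  df <- dplyr::bind_rows(
    pair_rows("s1a", base, "GGCCGGCC"),
    pair_rows("s1b", "AAAAAAAAAC", "GGCCGGCA"),
    pair_rows("s1c", "AAAAAAAAAG", "GGCCGGCG"),
    pair_rows("s2a", far_s2, "TTCCGGCC", light_v = "IGKV3-20*01"),
    pair_rows("s2b", "GGGGGGGGGT", "TTCCGGCA", light_v = "IGKV3-20*01"),
    pair_rows("orphan", near_s1)  # no light chain
  )
  res <- resolve_light_chains(bundles_from(df))
  asg <- res$assignments
  expect_equal(asg$subgroup_index[asg$cell_id == "orphan"],
               asg$subgroup_index[asg$cell_id == "s1a"])
})

test_that("a light-less cell equidistant between subgroups joins the larger one", {
  # Heavy chains built so the orphan is Hamming-2 from the nearest member of
  # both subgroups; S1 has 3 members vs S2's 2, so S1 must win.
  df <- dplyr::bind_rows(
    pair_rows("s1a", "AAAAAAAAAA", "GGCCGGCC"),
    pair_rows("s1b", "AAAAAAAAAC", "GGCCGGCA"),
    pair_rows("s1c", "AAAAAAAAAG", "GGCCGGCG"),
    pair_rows("s2a", "AAAAAATTTT", "TTCCGGCC", light_v = "IGKV3-20*01"),
    pair_rows("s2b", "AAAAAATTTC", "TTCCGGCA", light_v = "IGKV3-20*01"),
    pair_rows("orphan", "AAAAAAAATT")  # Hamming 2 from s1a and from s2a
  )
  res <- resolve_light_chains(bundles_from(df))
  asg <- res$assignments
  s1 <- asg$subgroup_index[asg$cell_id == "s1a"]
  expect_equal(asg$subgroup_index[asg$cell_id == "orphan"], s1)
  expect_equal(res$subgroups$subgroup_index[which.max(res$subgroups$size)], s1)
})

test_that("hamming comparison for orphan assignment skips ambiguous positions", {
  # The s2 anchor matches the orphan exactly at its informative positions
  # (distance 0 if N is skipped); counting N as mismatch would instead give
  # distance 6 and send the orphan to the larger s1 subgroup.
  df <- dplyr::bind_rows(
    pair_rows("s1a", "AAAAAAAAAA", "GGCCGGCC"),
    pair_rows("s1b", "AAAAAAAAAC", "GGCCGGCA"),
    pair_rows("s1c", "AAAAAAAAAG", "GGCCGGCG"),
    pair_rows("s2a", "NNNNNNAAAT", "TTCCGGCC", light_v = "IGKV3-20*01"),
    pair_rows("orphan", "AAAAAAAAAT")
  )
  res <- resolve_light_chains(bundles_from(df))
  asg <- res$assignments
  expect_equal(asg$subgroup_index[asg$cell_id == "orphan"],
               asg$subgroup_index[asg$cell_id == "s2a"])
})

test_that("every cell receives exactly one subgroup and sizes are non-increasing", {
  df <- dplyr::bind_rows(
    pair_rows("c1", "ACGTACGT", "GGCCGGCC"),
    pair_rows("c2", "ACGAACGT", "GGCCGGCA"),
    pair_rows("c3", "TTTTACGT", "TTCCGGCC", light_v = "IGKV3-20*01"),
    pair_rows("c4", "ACGTAAAA")
  )
  res <- resolve_light_chains(bundles_from(df))
  expect_setequal(res$assignments$cell_id, c("c1", "c2", "c3", "c4"))
  expect_equal(anyDuplicated(res$assignments$cell_id), 0)
  expect_true(all(diff(res$subgroups$size) <= 0))
})

test_that("a clone with no light chains anywhere forms a single subgroup", {
  df <- dplyr::bind_rows(
    pair_rows("c1", "ACGTACGT"),
    pair_rows("c2", "ACGAACGT")
  )
  res <- resolve_light_chains(bundles_from(df))
  expect_equal(nrow(res$subgroups), 1)
  expect_true(all(res$assignments$subgroup_index == 1))
})

test_that("subgroup assignment is invariant to input cell order", {
  df <- dplyr::bind_rows(
    pair_rows("c1", "ACGTACGT", "GGCCGGCC"),
    pair_rows("c2", "ACGAACGT", "GGCCGGCA"),
    pair_rows("c3", "TTTTACGT", "TTCCGGCC", light_v = "IGKV3-20*01"),
    pair_rows("c4", "ACGTAAAA")
  )
  b <- bundles_from(df)
  a1 <- resolve_light_chains(b)$assignments
  a2 <- resolve_light_chains(rev(b))$assignments
  m <- match(a1$cell_id, a2$cell_id)
  expect_equal(a1$subgroup_index, a2$subgroup_index[m])
})

test_that("separate light V/J subgroups split into separate clone record sets", {
  df <- dplyr::bind_rows(
    pair_rows("c1", "ACGTACGT", "GGCCGGCC"),
    pair_rows("c2", "ACGAACGT", "GGCCGGCA"),
    pair_rows("c3", "TTTTACGT", "TTCCGGCC", light_v = "IGKV3-20*01")
  )
  res <- resolve_light_chains(bundles_from(df))
  sets <- split_subgroups(res)
  expect_length(sets, 2)
  expect_setequal(names(sets[["clone1_1"]]), c("c1", "c2"))
  expect_setequal(names(sets[["clone1_2"]]), "c3")
})

test_that("consensus germline takes the majority character and breaks ties with N", {
  expect_equal(build_clone_germline(rep("ACGT", 3)), "ACGT")
  expect_equal(build_clone_germline(c("AAGT", "AAGT", "AGGT")), "AAGT")
  expect_equal(build_clone_germline(c("AAGT", "AGGT")), "ANGT")
  expect_equal(build_clone_germline(c("NNGT", "N-GT")), "NNGT")
  expect_error(build_clone_germline(character(0)), "empty")
  expect_error(build_clone_germline(c("ACGT", "ACG")), "length")
})

test_that("clone formatting concatenates heavy and light and N-fills missing lights", {
  df <- dplyr::bind_rows(
    pair_rows("c1", "ACGT", "GGCC", germ_h = "ACGT"),
    pair_rows("c2", "ACGA", germ_h = "ACGT")
  )
  res <- resolve_light_chains(bundles_from(df))
  aln <- format_clone(res$bundles)
  expect_equal(unname(aln$tip_sequences[["c1"]]), "ACGTGGCC")
  expect_equal(unname(aln$tip_sequences[["c2"]]), "ACGANNNN")
  expect_equal(aln$heavy_interval, c(0L, 4L))
  expect_equal(aln$light_interval, c(4L, 8L))
  expect_false(aln$light_present[["c2"]])
  expect_true(all(nchar(c(aln$tip_sequences, aln$germline)) == 8))
})

test_that("tips differing only by ambiguous characters collapse into one", {
  df <- dplyr::bind_rows(
    pair_rows("c1", "ACGT", "GGCC", germ_h = "ACGT"),
    pair_rows("c2", "ACGT", "GGCN", germ_h = "ACGT"),
    pair_rows("c3", "ACGT", "GGTT", germ_h = "ACGT")
  )
  res <- resolve_light_chains(bundles_from(df))
  aln <- format_clone(res$bundles)
  expect_length(aln$tip_sequences, 2)
  expect_setequal(aln$collapse_map[["c1"]], c("c1", "c2"))
  # The merged tip keeps the determinate character.
  expect_equal(unname(aln$tip_sequences[["c1"]]), "ACGTGGCC")
})

test_that("collapse_map partitions the contributing cells", {
  df <- dplyr::bind_rows(
    pair_rows("c1", "ACGT", "GGCC", germ_h = "ACGT"),
    pair_rows("c2", "ACGT", "GGCN", germ_h = "ACGT"),
    pair_rows("c3", "ACGT", "GGTT", germ_h = "ACGT")
  )
  res <- resolve_light_chains(bundles_from(df))
  aln <- format_clone(res$bundles)
  expect_setequal(unlist(aln$collapse_map), c("c1", "c2", "c3"))
  expect_lte(length(aln$tip_sequences), 3)
})

test_that("mixed heavy alignment lengths are an error", {
  df <- dplyr::bind_rows(
    pair_rows("c1", "ACGT", "GGCC", germ_h = "ACGT"),
    pair_rows("c2", "ACGTA", "GGCC", germ_h = "ACGTA")
  )
  res <- resolve_light_chains(bundles_from(df))
  expect_error(format_clone(res$bundles), "lengths differ")
})

test_that("heavy-only filtering keeps the collapsed tip set without re-collapsing", {
  df <- dplyr::bind_rows(
    pair_rows("c1", "ACGT", "GGCC", germ_h = "ACGT"),
    pair_rows("c2", "ACGT", "TTAA", germ_h = "ACGT"),  # same heavy, distinct light
    pair_rows("c3", "ACGA", "GGCC", germ_h = "ACGT")
  )
  res <- resolve_light_chains(bundles_from(df))
  aln <- format_clone(res$bundles)
  h <- make_heavy_only(aln)
  expect_setequal(names(h$tip_sequences), names(aln$tip_sequences))
  expect_equal(unname(h$tip_sequences[["c1"]]), unname(h$tip_sequences[["c2"]]))
  expect_equal(h$germline, substr(aln$germline, 1, 4))
  expect_equal(h$light_interval, c(4L, 4L))
  expect_false(any(h$light_present))
})

test_that("SHM frequency is mismatches over informative V-region positions", {
  g <- strrep("A", 320)
  s <- g
  substr(s, 10, 12) <- "TTT"
  expect_equal(shm_frequency(g, g), 0)
  expect_equal(shm_frequency(s, g), 3 / 312)
  expect_true(is.na(shm_frequency(strrep("A", 320), strrep("N", 320))))
  # Ambiguity in either string removes the position from both counts.
  s2 <- g; substr(s2, 1, 1) <- "N"
  expect_equal(shm_frequency(s2, g), 0)
  expect_error(shm_frequency("ACG", "ACGT"), "length")
})

test_that("whole-table resolution annotates records with clone_subgroup_id", {
  df <- dplyr::bind_rows(
    pair_rows("c1", "ACGTACGT", "GGCCGGCC"),
    pair_rows("c2", "ACGAACGT", "GGCCGGCA"),
    pair_rows("d1", "TTGTACGT", "GGCCGGCC", clone_id = "clone2")
  )
  res <- resolve_clones(df)
  expect_true("clone_subgroup_id" %in% names(res$records))
  expect_setequal(unique(res$records$clone_subgroup_id),
                  c("clone1_1", "clone2_1"))
  expect_length(res$resolved, 2)
})
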