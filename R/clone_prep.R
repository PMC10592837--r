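# Clone preparation: light-chain subgroup resolution within clones, clonal
# consensus germlines, heavy+light concatenation with N-fill for missing
# light chains, duplicate collapsing, and matched heavy-only datasets.
#
# Coordinates are 0-based half-open internally; IMGT positions (1-based)
# are converted at the boundary.

# Strip the allele suffix ("*01") from a gene call and split comma-separated
# candidate lists into unique gene-level names.
#' @noRd
gene_level <- function(call) {
  genes <- unlist(strsplit(call, ",", fixed = TRUE))
  genes <- sub("\\*.*$", "", trimws(genes))
  unique(genes[genes != ""])
}

#' @noRd
combo_key <- function(v, j, jl) paste(v, j, jl, sep = "|")

# All candidate (V gene, J gene, junction length) combinations of a cell's
# light chain(s).
#' @noRd
light_candidates <- function(lights) {
  if (nrow(lights) == 0) return(character(0))
  keys <- character(0)
  for (i in seq_len(nrow(lights))) {
    vs <- gene_level(lights$v_call[i])
    js <- gene_level(lights$j_call[i])
    keys <- c(keys, as.vector(outer(vs, js, function(v, j) {
      combo_key(v, j, lights$junction_length[i])
    })))
  }
  unique(keys)
}

#' Resolve light-chain subgroups within a clone
#'
#' Assigns every cell of a clone to exactly one light-chain subgroup.
#' Cells whose light chains carry multiple candidate V/J genes contribute
#' every (V gene, J gene, junction length) combination; groups are formed
#' greedily from the largest candidate grouping downward (allele suffixes
#' stripped), cells spanning several groups joining the largest compatible
#' one. Cells without a light chain are assigned to the subgroup of the
#' nearest heavy chain by Hamming distance (positions with N or gaps in
#' either sequence skipped); distance ties go to the largest subgroup, then
#' to the lowest subgroup index. A clone with no light chains anywhere forms
#' a single subgroup. Subgroup indices are 1-based in decreasing size order.
#'
#' @param bundles List of cell bundles (from [group_cells()]) sharing one
#'   `clone_id`.
#' @return A list with `assignments` (tibble: `cell_id`, `subgroup_index`,
#'   `clone_subgroup_id`, light V/J genes and junction length),
#'   `subgroups` (tibble of subgroup definitions and sizes) and `bundles`
#'   (input bundles with a resolved one-row `light` tibble, or `NULL`).
#' @export
resolve_light_chains <- function(bundles) {
  if (length(bundles) == 0) stop("no cell bundles supplied", call. = FALSE)
  clone_id <- bundles[[1]]$heavy$clone_id[1]
  cell_ids <- vapply(bundles, function(b) b$cell_id, character(1))
  names(bundles) <- cell_ids
  cand <- lapply(bundles, function(b) light_candidates(b$lights))

  has_light <- vapply(cand, function(x) length(x) > 0, logical(1))
  assignment <- stats::setNames(rep(NA_integer_, length(bundles)), cell_ids)
  group_keys <- character(0)

  # Greedy grouping over cells that have light chains.
  unassigned <- cell_ids[has_light]
  # Canonical cell order for reproducible tie-breaking.
  unassigned <- sort(unassigned)
  while (length(unassigned) > 0) {
    support <- table(unlist(cand[unassigned]))
    best <- max(support)
    key <- sort(names(support)[support == best])[1]
    members <- unassigned[vapply(cand[unassigned], function(x) key %in% x, logical(1))]
    idx <- length(group_keys) + 1L
    group_keys <- c(group_keys, key)
    assignment[members] <- idx
    unassigned <- setdiff(unassigned, members)
  }

  if (length(group_keys) == 0) {
    # Degenerate clone: no light chains anywhere -> single subgroup.
    assignment[] <- 1L
    group_keys <- combo_key(NA_character_, NA_character_, NA_integer_)
  } else if (any(!has_light)) {
    # Nearest-heavy assignment for light-less cells, against the grouping as
    # it stands (sizes frozen at assignment time).
    sizes <- tabulate(assignment, nbins = length(group_keys))
    anchors <- cell_ids[has_light]
    for (cid in sort(cell_ids[!has_light])) {
      h <- bundles[[cid]]$heavy$sequence_alignment[1]
      d <- vapply(anchors, function(a) {
        hamming_informative(h, bundles[[a]]$heavy$sequence_alignment[1])
      }, numeric(1))
      nearest <- anchors[d == min(d)]
      groups <- unique(assignment[nearest])
      if (length(groups) > 1) {
        gsz <- sizes[groups]
        groups <- groups[gsz == max(gsz)]
        groups <- min(groups)
      }
      assignment[cid] <- groups[1]
    }
  }

  # Re-index subgroups by decreasing total size (stable on original index).
  sizes <- tabulate(assignment, nbins = length(group_keys))
  order_idx <- order(-sizes, seq_along(sizes))
  new_index <- integer(length(group_keys))
  new_index[order_idx] <- seq_along(order_idx)
  assignment <- stats::setNames(new_index[assignment], names(assignment))
  group_keys <- group_keys[order_idx]

  parts <- strsplit(group_keys, "|", fixed = TRUE)
  subgroups <- tibble::tibble(
    clone_id = clone_id,
    subgroup_index = seq_along(group_keys),
    light_v_gene = vapply(parts, `[`, character(1), 1),
    light_j_gene = vapply(parts, `[`, character(1), 2),
    light_junction_length = suppressWarnings(
      as.integer(vapply(parts, `[`, character(1), 3))),
    size = tabulate(assignment, nbins = length(group_keys))
  )

  # Pick, per cell, the light record consistent with its subgroup.
  for (cid in cell_ids) {
    b <- bundles[[cid]]
    key <- group_keys[assignment[cid]]
    chosen <- NULL
    if (nrow(b$lights) > 0) {
      for (i in order(b$lights$sequence_id)) {
        row <- b$lights[i, , drop = FALSE]
        if (key %in% light_candidates(row)) {
          chosen <- row
          break
        }
      }
      if (is.null(chosen)) chosen <- b$lights[order(b$lights$sequence_id)[1], , drop = FALSE]
    }
    bundles[[cid]]$light <- chosen
  }

  assignments <- tibble::tibble(
    cell_id = cell_ids,
    clone_id = clone_id,
    subgroup_index = as.integer(assignment[cell_ids]),
    clone_subgroup_id = paste(clone_id, assignment[cell_ids], sep = "_")
  )
  assignments <- dplyr::left_join(
    assignments,
    subgroups[, c("subgroup_index", "light_v_gene", "light_j_gene",
                  "light_junction_length")],
    by = "subgroup_index"
  )
  list(assignments = assignments, subgroups = subgroups, bundles = bundles)
}

#' Split a resolved clone into per-subgroup record sets
#'
#' Separate light-chain V/J subgroups are treated as separate clones for
#' tree building.
#'
#' @param resolved Output of [resolve_light_chains()].
#' @return A named list (by `clone_subgroup_id`) of bundle lists.
#' @export
split_subgroups <- function(resolved) {
  asg <- resolved$assignments
  out <- list()
  for (gid in unique(asg$clone_subgroup_id)) {
    cells <- asg$cell_id[asg$clone_subgroup_id == gid]
    out[[gid]] <- resolved$bundles[cells]
  }
  out
}

#' Build a clonal consensus germline for one chain
#'
#' Position-wise consensus over the members' `germline_alignment`: the most
#' frequent non-ambiguous character wins; ties and columns with no
#' determinate character become `N`.
#'
#' @param germlines Character vector of equal-length IMGT-gapped germline
#'   strings.
#' @return The consensus germline string.
#' @export
build_clone_germline <- function(germlines) {
  if (length(germlines) == 0) stop("empty germline list", call. = FALSE)
  lens <- nchar(germlines)
  if (length(unique(lens)) != 1) stop("germline alignment lengths differ", call. = FALSE)
  mat <- do.call(rbind, lapply(germlines, seq_to_chars))
  cons <- apply(mat, 2, function(col) {
    col <- col[!(col %in% AMBIG_CHARS)]
    if (length(col) == 0) return("N")
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) "N" else top
  })
  chars_to_seq(cons)
}

# TRUE when two equal-length sequences match at every position where neither
# is ambiguous (N and gaps match anything).
#' @noRd
ambiguity_compatible <- function(a, b) {
  ca <- seq_to_chars(a)
  cb <- seq_to_chars(b)
  ok <- !(ca %in% AMBIG_CHARS) & !(cb %in% AMBIG_CHARS)
  all(ca[ok] == cb[ok])
}

# Merge two compatible sequences, preferring determinate characters.
#' @noRd
merge_ambiguous <- function(a, b) {
  ca <- seq_to_chars(a)
  cb <- seq_to_chars(b)
  amb <- ca %in% AMBIG_CHARS
  ca[amb] <- cb[amb]
  chars_to_seq(ca)
}

#' Build the concatenated heavy+light clone alignment
#'
#' Concatenates each cell's heavy and light chain alignments; cells without
#' a light chain get a run of ambiguous `N` of the light alignment length.
#' The clonal germline is the concatenation of the per-chain consensus
#' germlines. Concatenated sequences that are identical or differ only by
#' ambiguous characters are collapsed into one tip (N and gaps match
#' anything); collapsing is computed on the concatenated sequences and the
#' merged tip keeps determinate characters wherever any member has one.
#'
#' @param bundles List of resolved cell bundles of one clone subgroup (each
#'   with `heavy` and resolved `light`, see [resolve_light_chains()]).
#' @param clone_subgroup_id Identifier for the output alignment.
#' @param germline_heavy,germline_light Optional per-chain germline strings;
#'   defaults to the consensus over members ([build_clone_germline()]).
#' @param collapse Collapse ambiguity-identical duplicates (default TRUE).
#' @return A `clone_alignment` object: list with `clone_subgroup_id`,
#'   `tip_sequences` (named), `germline`, `heavy_interval` / `light_interval`
#'   (0-based half-open), `collapse_map`, and `light_present`.
#' @export
format_clone <- function(bundles, clone_subgroup_id = NULL,
                         germline_heavy = NULL, germline_light = NULL,
                         collapse = TRUE) {
  if (length(bundles) == 0) stop("no bundles to format", call. = FALSE)
  cell_ids <- vapply(bundles, function(b) b$cell_id, character(1))
  names(bundles) <- cell_ids
  heavies <- vapply(bundles, function(b) b$heavy$sequence_alignment[1], character(1))
  if (length(unique(nchar(heavies))) != 1) {
    stop("heavy chain alignment lengths differ within clone", call. = FALSE)
  }
  Lh <- unname(nchar(heavies[1]))

  lights <- lapply(bundles, function(b) {
    if (!is.null(b$light) && nrow(b$light) > 0) b$light$sequence_alignment[1] else NULL
  })
  light_lens <- unique(nchar(unlist(lights)))
  if (length(light_lens) > 1) {
    stop("light chain alignment lengths differ within clone subgroup", call. = FALSE)
  }
  if (is.null(germline_heavy)) {
    germline_heavy <- build_clone_germline(
      vapply(bundles, function(b) b$heavy$germline_alignment[1], character(1)))
  }
  if (is.null(germline_light) && length(light_lens) == 1) {
    lg <- unlist(lapply(bundles, function(b) {
      if (!is.null(b$light) && nrow(b$light) > 0) b$light$germline_alignment[1] else NULL
    }))
    germline_light <- build_clone_germline(lg)
  }
  Ll <- unname(if (length(light_lens) == 1) light_lens
               else nchar(germline_light %||% ""))
  if (is.null(germline_light)) germline_light <- strrep("N", Ll)

  has_light <- !vapply(lights, is.null, logical(1))
  tips <- character(length(bundles))
  for (i in seq_along(bundles)) {
    lpart <- if (has_light[i]) lights[[i]] else strrep("N", Ll)
    tips[i] <- paste0(heavies[i], lpart)
  }
  names(tips) <- cell_ids
  germline <- paste0(germline_heavy, germline_light)

  # Iterative duplicate collapsing in canonical cell order.
  ord <- order(cell_ids)
  groups <- as.list(cell_ids[ord])
  seqs <- tips[cell_ids[ord]]
  lp <- has_light[ord]
  if (collapse && length(seqs) > 1) {
    repeat {
      merged <- FALSE
      n <- length(seqs)
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          if (ambiguity_compatible(seqs[i], seqs[j])) {
            seqs[i] <- merge_ambiguous(seqs[i], seqs[j])
            groups[[i]] <- c(groups[[i]], groups[[j]])
            lp[i] <- lp[i] || lp[j]
            seqs <- seqs[-j]
            groups[[j]] <- NULL
            lp <- lp[-j]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  tip_names <- vapply(groups, function(g) sort(g)[1], character(1))
  names(seqs) <- tip_names
  collapse_map <- stats::setNames(groups, tip_names)
  light_present <- stats::setNames(lp, tip_names)

  structure(list(
    clone_subgroup_id = clone_subgroup_id %||%
      paste(bundles[[1]]$heavy$clone_id[1], "1", sep = "_"),
    tip_sequences = seqs,
    germline = germline,
    heavy_interval = c(0L, Lh),
    light_interval = c(Lh, Lh + Ll),
    collapse_map = collapse_map,
    light_present = light_present
  ), class = "clone_alignment")
}

#' @export
print.clone_alignment <- function(x, ...) {
  cat(sprintf("clone_alignment %s: %d tips, heavy [%d,%d), light [%d,%d)\n",
              x$clone_subgroup_id, length(x$tip_sequences),
              x$heavy_interval[1], x$heavy_interval[2],
              x$light_interval[1], x$light_interval[2]))
  invisible(x)
}

#' Matched heavy-only clone alignment
#'
#' Restricts every tip and the germline to the heavy-chain interval, keeping
#' exactly the post-collapse tip set of the paired alignment (no
#' re-collapsing, even if heavy portions became identical). This is the
#' matched-filtering construction for fair heavy-only vs heavy+light
#' comparisons.
#'
#' @param clone A `clone_alignment` from [format_clone()].
#' @return A heavy-only `clone_alignment` with identical tip names.
#' @export
make_heavy_only <- function(clone) {
  Lh <- clone$heavy_interval[2]
  out <- clone
  out$tip_sequences <- vapply(clone$tip_sequences, substr, character(1), 1L, Lh)
  names(out$tip_sequences) <- names(clone$tip_sequences)
  out$germline <- substr(clone$germline, 1L, Lh)
  out$light_interval <- c(Lh, Lh)
  out$light_present <- stats::setNames(rep(FALSE, length(clone$light_present)),
                                       names(clone$light_present))
  out
}

#' Somatic hypermutation frequency
#'
#' Length-normalized Hamming distance between an observed sequence and its
#' germline over an IMGT position range (default V region, positions 1-312).
#' Positions with N or a gap in either string are excluded from both
#' numerator and denominator.
#'
#' @param seq,germline Equal-length IMGT-gapped strings.
#' @param region Two-element 1-based inclusive IMGT position range.
#' @return Mutation fraction, or `NA` when no informative positions remain.
#' @export
shm_frequency <- function(seq, germline, region = c(1, 312)) {
  if (nchar(seq) != nchar(germline)) stop("sequence lengths differ", call. = FALSE)
  lo <- max(1L, as.integer(region[1]))
  hi <- min(nchar(seq), as.integer(region[2]))
  ca <- seq_to_chars(substr(seq, lo, hi))
  cb <- seq_to_chars(substr(germline, lo, hi))
  ok <- !(ca %in% AMBIG_CHARS) & !(cb %in% AMBIG_CHARS)
  if (!any(ok)) return(NA_real_)
  sum(ca[ok] != cb[ok]) / sum(ok)
}

#' Resolve light-chain subgroups across a whole rearrangement table
#'
#' Convenience wrapper running [group_cells()] and [resolve_light_chains()]
#' per clone and annotating the input records with `clone_subgroup_id`.
#'
#' @param records A rearrangement tibble (see [read_airr()]).
#' @return A list with `records` (annotated tibble of retained records),
#'   `rejected` (tibble), and `resolved` (named list of per-clone
#'   resolutions).
#' @export
resolve_clones <- function(records) {
  grouped <- group_cells(records)
  by_clone <- split(grouped$bundles, vapply(grouped$bundles, function(b) {
    b$heavy$clone_id[1]
  }, character(1)))
  resolved <- lapply(by_clone, resolve_light_chains)
  asg <- dplyr::bind_rows(lapply(resolved, function(r) r$assignments))
  records <- tibble::as_tibble(records)
  if (!"cell_id" %in% names(records)) records$cell_id <- NA_character_
  key <- ifelse(is.na(records$cell_id), paste0("bulk_", records$sequence_id),
                records$cell_id)
  m <- match(key, asg$cell_id)
  out <- records[!is.na(m), , drop = FALSE]
  out$clone_subgroup_id <- asg$clone_subgroup_id[m[!is.na(m)]]
  list(records = out, rejected = grouped$rejected, resolved = resolved)
}
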