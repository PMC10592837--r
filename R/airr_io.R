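# AIRR Rearrangement TSV, FASTA and Newick input/output plus record
# validation. Column names follow the AIRR Rearrangement schema; extra
# columns pass through untouched.

AIRR_REQUIRED <- c(
  "sequence_id", "locus", "v_call", "j_call", "junction_length",
  "sequence_alignment", "germline_alignment", "clone_id"
)

#' Read an AIRR Rearrangement table
#'
#' Reads a tab-separated AIRR Rearrangement file carrying IMGT-gapped
#' `sequence_alignment` and `germline_alignment` columns. Sequences are
#' upper-cased; IUPAC ambiguity codes other than `N` are mapped to `N` with a
#' warning. Rows violating the record invariants (e.g. mismatched
#' sequence/germline lengths, unknown locus, empty v_call/j_call) are dropped
#' from the returned table and reported in the `rejected` attribute together
#' with their row numbers.
#'
#' @param path Path to a tab-separated file with a header row containing at
#'   least the AIRR columns `sequence_id`, `locus`, `v_call`, `j_call`,
#'   `junction_length`, `sequence_alignment`, `germline_alignment`,
#'   `clone_id`; `cell_id` is optional (empty/absent means a bulk
#'   heavy-chain read).
#' @return A tibble of valid rearrangement records, one per row, with an
#'   empty `cell_id` converted to `NA`. Attribute `rejected` holds a tibble
#'   of invalid rows (`row`, `sequence_id`, `reason`).
#' @export
read_airr <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  validate_airr(df)
}

#' Validate AIRR rearrangement records
#'
#' @param df A data frame of rearrangement records (see [read_airr()]).
#' @return A tibble of valid records with a `rejected` attribute.
#' @export
validate_airr <- function(df) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(AIRR_REQUIRED, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required AIRR column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"cell_id" %in% names(df)) df$cell_id <- NA_character_
  df$cell_id[!is.na(df$cell_id) & df$cell_id == ""] <- NA_character_
  df$junction_length <- as.integer(df$junction_length)
  df$sequence_alignment <- vapply(df$sequence_alignment, sanitize_seq, character(1),
                                  USE.NAMES = FALSE)
  df$germline_alignment <- vapply(df$germline_alignment, sanitize_seq, character(1),
                                  USE.NAMES = FALSE)

  reasons <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!r$locus %in% c("IGH", "IGK", "IGL")) {
      reasons[i] <- sprintf("unknown locus '%s'", r$locus)
    } else if (is.na(r$sequence_alignment) || is.na(r$germline_alignment) ||
               nchar(r$sequence_alignment) != nchar(r$germline_alignment)) {
      reasons[i] <- "sequence_alignment and germline_alignment lengths differ"
    } else if (is.na(r$v_call) || r$v_call == "" || is.na(r$j_call) || r$j_call == "") {
      reasons[i] <- "empty v_call or j_call"
    } else if (is.na(r$junction_length) || r$junction_length < 0) {
      reasons[i] <- "junction_length missing or negative"
    }
  }
  bad <- which(reasons != "")
  rejected <- tibble::tibble(
    row = bad,
    sequence_id = df$sequence_id[bad],
    reason = reasons[bad]
  )
  if (length(bad) > 0) {
    message(sprintf("validate_airr: dropped %d invalid row(s); see attr(,'rejected')",
                    length(bad)))
    df <- df[-bad, , drop = FALSE]
  }
  attr(df, "rejected") <- rejected
  df
}

#' Write an AIRR Rearrangement table
#'
#' @param df A tibble of rearrangement records.
#' @param path Output path (tab-separated).
#' @export
write_airr <- function(df, path) {
  out <- df
  if ("cell_id" %in% names(out)) out$cell_id[is.na(out$cell_id)] <- ""
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Group rearrangements into per-cell bundles
#'
#' Groups records by `cell_id` into cell bundles holding exactly one heavy
#' chain and the cell's light chain(s). Cells with more than one heavy chain
#' are removed entirely (all their records rejected); light chains whose cell
#' has no heavy chain are rejected; bulk heavy-chain reads (no `cell_id`) get
#' a synthesized cell id `bulk_<sequence_id>` and become single-member
#' bundles with no light chain.
#'
#' @param records A tibble of rearrangement records (see [read_airr()]).
#' @return A list with elements `bundles` (list of cell bundles, each a list
#'   with `cell_id`, `heavy` one-row tibble, `lights` tibble of zero or more
#'   light records) and `rejected` (tibble of rejected records with a
#'   `reason` column).
#' @export
group_cells <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"cell_id" %in% names(records)) records$cell_id <- NA_character_
  cid <- records$cell_id
  bulk <- is.na(cid)
  cid[bulk] <- paste0("bulk_", records$sequence_id[bulk])
  records$.cell_key <- cid

  bundles <- list()
  rejected <- records[0, , drop = FALSE]
  reasons <- character(0)
  for (key in unique(cid)) {
    rows <- records[records$.cell_key == key, , drop = FALSE]
    heavy <- rows[rows$locus == "IGH", , drop = FALSE]
    lights <- rows[rows$locus != "IGH", , drop = FALSE]
    if (nrow(heavy) > 1) {
      rejected <- dplyr::bind_rows(rejected, rows)
      reasons <- c(reasons, rep("cell has multiple heavy chains", nrow(rows)))
      next
    }
    if (nrow(heavy) == 0) {
      rejected <- dplyr::bind_rows(rejected, rows)
      reasons <- c(reasons, rep("light chain with no paired heavy chain", nrow(rows)))
      next
    }
    bundles[[length(bundles) + 1]] <- list(
      cell_id = key,
      heavy = heavy[, setdiff(names(heavy), ".cell_key"), drop = FALSE],
      lights = lights[, setdiff(names(lights), ".cell_key"), drop = FALSE]
    )
  }
  rejected$reason <- reasons
  rejected$.cell_key <- NULL
  list(bundles = bundles, rejected = tibble::as_tibble(rejected))
}

#' Read a Newick tree
#'
#' Parses a Newick string or file into an `ape` `phylo` object. Polytomies
#' and zero-length branches are legal. The germline is expected to be a tip
#' (default label "Germline").
#'
#' @param path Path to a Newick file, or a Newick string when `text = TRUE`.
#' @param text Treat `path` as the Newick string itself.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path, text = FALSE) {
  nwk <- if (text) path else paste(readLines(path, warn = FALSE), collapse = "")
  nwk <- trimws(nwk)
  # Pre-check bracket balance so malformed input reports a character offset.
  depth <- 0L
  chars <- seq_to_chars(nwk)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop(sprintf("malformed Newick: unbalanced ')' at character %d", i), call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop(sprintf("malformed Newick: %d unclosed '(' at end of input (character %d)",
                 depth, nchar(nwk)), call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = nwk),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick: parse failed", call. = FALSE)
  tr
}

#' Write a Newick tree
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @param digits Significant digits for branch lengths (default 10).
#' @export
write_newick <- function(tree, path, digits = 10) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Export a clone alignment as FASTA
#'
#' Writes the concatenated tip sequences and the germline of a
#' [format_clone()] alignment to FASTA, with a JSON sidecar carrying the
#' heavy/light partition intervals (0-based half-open) and the collapse map.
#'
#' @param clone A `clone_alignment` object.
#' @param path Output FASTA path; the sidecar is written to `<path>.json`.
#' @param germline_label Tip label used for the germline record.
#' @export
write_clone_fasta <- function(clone, path, germline_label = "Germline") {
  seqs <- c(clone$tip_sequences, stats::setNames(clone$germline, germline_label))
  seqinr::write.fasta(
    sequences = lapply(seqs, seq_to_chars),
    names = names(seqs),
    file.out = path
  )
  sidecar <- list(
    clone_subgroup_id = clone$clone_subgroup_id,
    heavy_interval = clone$heavy_interval,
    light_interval = clone$light_interval,
    collapse_map = clone$collapse_map,
    light_present = as.list(clone$light_present)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
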