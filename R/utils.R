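# Internal helpers shared across modules.

NUC <- c("A", "C", "G", "T")

# Characters treated as non-informative everywhere: ambiguous N plus both
# IMGT gap styles.
AMBIG_CHARS <- c("N", ".", "-")

#' @noRd
seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' @noRd
chars_to_seq <- function(x) paste(x, collapse = "")

# Encode a nucleotide string to integers 1..4 with NA for N/gap.
#' @noRd
encode_nuc <- function(x) {
  ch <- seq_to_chars(x)
  m <- match(ch, NUC)
  m
}

# Upper-case and map any IUPAC ambiguity other than N to N.
#' @noRd
sanitize_seq <- function(x, warn = TRUE) {
  x <- toupper(x)
  ch <- seq_to_chars(x)
  bad <- !(ch %in% c(NUC, AMBIG_CHARS))
  if (any(bad)) {
    if (warn) {
      warning(sprintf("%d ambiguous (non-N IUPAC) characters mapped to N", sum(bad)),
              call. = FALSE)
    }
    ch[bad] <- "N"
  }
  chars_to_seq(ch)
}

# Hamming distance between two equal-length aligned strings, skipping
# positions where either has N or a gap character.
#' @noRd
hamming_informative <- function(a, b) {
  ca <- seq_to_chars(a)
  cb <- seq_to_chars(b)
  stopifnot(length(ca) == length(cb))
  ok <- !(ca %in% AMBIG_CHARS) & !(cb %in% AMBIG_CHARS)
  sum(ca[ok] != cb[ok])
}

# Run expr under a fixed RNG seed when seed is non-NULL, leaving the global
# RNG state untouched; otherwise use the current RNG stream.
#' @noRd
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Deterministic child seed derivation, kept below 2^31.
#' @noRd
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + k) %% 2147483647L)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
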