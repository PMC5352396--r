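#' Consensus-motif enrichment against a shuffled background
#'
#' Scans each sequence for an IUPAC consensus motif on both strands (default
#' `TTCNNNGAA`, the canonical 9-bp STAT-family palindromic element with a
#' fixed 3-bp spacer) and tests whether more sequences carry a match than
#' expected under a per-sequence mononucleotide shuffle null. A sequence
#' "matches" when the consensus matches at any position on either strand.
#' The background rate is the mean per-sequence match frequency across
#' `n_shuffles` seeded shuffles of every sequence, and the p-value is the
#' upper tail of Binomial(n_sequences, background_rate) at the observed
#' number of matching sequences.
#'
#' @param sequences Character vector of DNA sequences over `{A,C,G,T,N}` (or
#'   a `Biostrings::DNAStringSet`).
#' @param consensus IUPAC consensus string (default `"TTCNNNGAA"`).
#' @param n_shuffles Number of mononucleotide shuffles per sequence for the
#'   background estimate (default 10).
#' @param seed Integer seed for the shuffles.
#' @return A list of class `motif_enrichment` with `consensus`,
#'   `n_sequences`, `n_with_match`, `background_rate`, `p_value`.
#' @export
consensus_motif_enrichment <- function(sequences, consensus = "TTCNNNGAA",
                                       n_shuffles = 10L, seed = 1L) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  if (!length(sequences)) stopf("no sequences supplied")
  sequences <- toupper(sequences)
  if (any(grepl("[^ACGTN]", sequences))) {
    stopf("sequences must be over the alphabet {A,C,G,T,N}")
  }
  iupac <- Biostrings::IUPAC_CODE_MAP
  if (any(!strsplit(toupper(consensus), "")[[1]] %in% names(iupac))) {
    stopf("'%s' is not a valid IUPAC consensus", consensus)
  }
  n_seq <- length(sequences)
  matches <- motif_matches(sequences, consensus)
  n_with_match <- sum(matches)

  shuffle_hits <- with_seed(seed, {
    hits <- 0L
    for (s in seq_len(n_shuffles)) {
      shuffled <- vapply(sequences, function(x) {
        paste(sample(strsplit(x, "")[[1]]), collapse = "")
      }, "", USE.NAMES = FALSE)
      hits <- hits + sum(motif_matches(shuffled, consensus))
    }
    hits
  })
  background_rate <- shuffle_hits / (n_seq * n_shuffles)

  p <- if (n_with_match == 0L) {
    1
  } else {
    stats::pbinom(n_with_match - 1L, n_seq, background_rate,
                  lower.tail = FALSE)
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(consensus = consensus, n_sequences = n_seq,
                 n_with_match = n_with_match,
                 background_rate = background_rate, p_value = p),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf("Consensus %s: %d / %d sequences match (background rate %.4f), binomial p = %.3g\n",
              x$consensus, x$n_with_match, x$n_sequences,
              x$background_rate, x$p_value))
  invisible(x)
}

# Per-sequence logical: does `consensus` (IUPAC) match anywhere on either
# strand? Biostrings handles IUPAC degeneracy with fixed = FALSE.
motif_matches <- function(sequences, consensus) {
  subj <- Biostrings::DNAStringSet(sequences)
  pat <- Biostrings::DNAString(consensus)
  fwd <- Biostrings::vcountPattern(pat, subj, fixed = "subject") > 0L
  rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat), subj,
                                   fixed = "subject") > 0L
  fwd | rev
}
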