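#' Construct a peak set
#'
#' A peak set is one sample's (or replicate's) called binding sites: genomic
#' intervals in 0-based half-open coordinates, each with a summit (the
#' position of maximal signal, given as an absolute 0-based coordinate inside
#' the interval), a nonnegative score, and a name unique within the set.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based half-open interval bounds
#'   (`start < end`).
#' @param summit Integer vector of absolute summit coordinates with
#'   `start <= summit < end`.
#' @param score Numeric vector of nonnegative peak scores (signal values).
#' @param name Character vector of unique peak identifiers; autogenerated
#'   when omitted.
#' @param sample_id Single string labelling the sample the peaks belong to.
#' @return A `peak_set`: a data frame with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `summit` and a `sample_id` attribute, sorted by
#'   (chrom, start).
#' @examples
#' peak_set(chrom = "chr1", start = 100, end = 200, summit = 150, score = 8.5)
#' @export
peak_set <- function(chrom, start, end, summit, score,
                     name = NULL, sample_id = "sample") {
  n <- length(chrom)
  if (is.null(name)) {
    name <- if (n) sprintf("peak_%0*d", max(5L, nchar(n)), seq_len(n)) else character(0)
  }
  start <- as.integer(start); end <- as.integer(end); summit <- as.integer(summit)
  if (any(lengths(list(start, end, summit, score, name)) != n)) {
    stopf("peak fields must all have length %d", n)
  }
  if (n) {
    if (any(!nzchar(chrom))) stopf("chromosome names must be non-empty")
    if (any(start < 0L) || any(start >= end)) {
      stopf("intervals must satisfy 0 <= start < end")
    }
    if (any(summit < start) || any(summit >= end)) {
      stopf("summits must lie within their interval (start <= summit < end)")
    }
    if (any(score < 0)) stopf("scores must be nonnegative")
    if (anyDuplicated(name)) {
      stopf("peak names must be unique within a set (first duplicate: '%s')",
            name[anyDuplicated(name)])
    }
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = as.character(name), score = as.numeric(score),
                   summit = summit, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  class(df) <- c("peak_set", "data.frame")
  df
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set '%s': %d peaks on %d chromosome(s)\n",
              attr(x, "sample_id"), nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
`[.peak_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "sample_id") <- attr(x, "sample_id")
    class(out) <- c("peak_set", "data.frame")
  }
  out
}

# GRanges view of a peak set (internal; all overlap machinery goes through
# GenomicRanges)
peaks_as_granges <- function(p) {
  GenomicRanges::GRanges(
    seqnames = p$chrom,
    ranges = IRanges::IRanges(start = p$start + 1L, end = p$end),
    name = p$name, score = p$score, summit = p$summit
  )
}
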