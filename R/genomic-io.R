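#' Read an ENCODE narrowPeak file
#'
#' Parses a BED6+4 narrowPeak file into a [peak_set()]. Coordinates are
#' 0-based half-open as in BED. The summit is `start + peak offset`
#' (field 10) when the offset is nonnegative; an offset of -1 (summit
#' unknown) falls back to the interval midpoint, `floor((start + end) / 2)`,
#' so that every peak stays usable by summit-window operations. The peak
#' score is taken from `signalValue` (field 7).
#'
#' @param path Path to a narrowPeak file.
#' @param sample_id Sample label for the returned set; defaults to the file
#'   base name.
#' @return A [peak_set()].
#' @export
read_narrowpeak <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(narrowPeak|bed)$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(peak_set(character(0), integer(0), integer(0), integer(0),
                    numeric(0), character(0), sample_id = sample_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 10L)
  if (length(bad)) {
    stopf("line %d: expected >= 10 tab-separated narrowPeak fields, found %d",
          bad[1L], nf[bad[1L]])
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:10))
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  signal <- suppressWarnings(as.numeric(m[, 7L]))
  offset <- suppressWarnings(as.integer(m[, 10L]))
  bad <- which(is.na(start) | is.na(end) | is.na(offset) | is.na(signal))
  if (length(bad)) stopf("line %d: non-numeric coordinate or score", bad[1L])
  bad <- which(start < 0L | start >= end)
  if (length(bad)) {
    stopf("line %d: invalid interval (start=%d, end=%d)",
          bad[1L], start[bad[1L]], end[bad[1L]])
  }
  bad <- which(offset >= end - start)
  if (length(bad)) {
    stopf("line %d: summit offset %d >= peak length %d",
          bad[1L], offset[bad[1L]], end[bad[1L]] - start[bad[1L]])
  }
  summit <- ifelse(offset >= 0L, start + offset, (start + end) %/% 2L)
  name <- m[, 4L]
  if (anyDuplicated(name)) {
    name <- make.unique(name, sep = "_dup")
  }
  peak_set(chrom = m[, 1L], start = start, end = end, summit = summit,
           score = pmax(signal, 0), name = name, sample_id = sample_id)
}

#' Write a peak set to a narrowPeak/BED file
#'
#' Emits 10-column narrowPeak lines (BED6+4), 0-based half-open, sorted by
#' (chrom, start), with the summit carried in the field-10 offset so that
#' `read_narrowpeak(write_bed(x))` round-trips every coordinate field
#' exactly. `signalValue` carries the peak score; `pValue`/`qValue` are
#' written as -1 (not available).
#'
#' @param peaks A [peak_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  p <- as.data.frame(peaks)
  p <- p[order(p$chrom, p$start, p$end), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t-1\t-1\t%d",
                   p$chrom, p$start, p$end, p$name,
                   format(p$score, trim = TRUE, scientific = FALSE),
                   p$summit - p$start)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stopf("cannot write to '%s'", path)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Reads a tab-separated transcript table with header columns
#' `transcript_id`, `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`
#' (0-based half-open transcript span) and derives the transcription start
#' site: `tss = tx_start` on the "+" strand and `tss = tx_end - 1` (the last
#' covered base, 0-based) on the "-" strand.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `tss`.
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "chrom", "strand", "tx_start", "tx_end")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stopf("TSS table missing column(s) %s; found: %s",
          paste(missing, collapse = ", "), paste(names(df), collapse = ", "))
  }
  if (anyDuplicated(df$transcript_id)) {
    stopf("duplicate transcript_id '%s' in TSS table",
          df$transcript_id[anyDuplicated(df$transcript_id)])
  }
  bad <- !df$strand %in% c("+", "-")
  if (any(bad)) stopf("unknown strand '%s' for transcript '%s'",
                      df$strand[which(bad)[1L]], df$transcript_id[which(bad)[1L]])
  transcript_annotation(df$transcript_id, df$gene_id, df$chrom, df$strand,
                        tx_start = df$tx_start, tx_end = df$tx_end)
}

#' Construct a transcript annotation in memory
#'
#' Either supply `tss` directly (0-based) or a transcript span
#' (`tx_start`/`tx_end`, 0-based half-open) from which the strand-aware TSS
#' is derived.
#'
#' @param transcript_id,gene_id,chrom,strand Character vectors.
#' @param tss Optional 0-based TSS coordinates.
#' @param tx_start,tx_end Optional transcript span used when `tss` is absent.
#' @return Data frame with class `transcript_annotation`.
#' @export
transcript_annotation <- function(transcript_id, gene_id, chrom, strand,
                                  tss = NULL, tx_start = NULL, tx_end = NULL) {
  if (is.null(tss)) {
    stopifnot(!is.null(tx_start), !is.null(tx_end))
    tss <- ifelse(strand == "+", as.integer(tx_start), as.integer(tx_end) - 1L)
  }
  if (anyDuplicated(transcript_id)) stopf("transcript ids must be unique")
  if (any(!strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (any(tss < 0L)) stopf("tss must be >= 0")
  df <- data.frame(transcript_id = as.character(transcript_id),
                   gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   tss = as.integer(tss), stringsAsFactors = FALSE)
  class(df) <- c("transcript_annotation", "data.frame")
  df
}

#' Read a differential-expression table
#'
#' Reads the tab-separated output of an upstream differential-expression
#' contrast (knockdown vs control). Required header columns:
#' `transcript_id`, `chrom`, `log2fc` (knockdown minus control, log2 scale),
#' `padj`. Rows whose `log2fc` is not numeric are dropped with a warning;
#' missing `padj` ("NA" or empty) is allowed and kept as `NA`.
#'
#' The negative-binomial model that produced the table is upstream of this
#' package: the table is an input contract, not a computation.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `transcript_id`, `chrom`, `log2fc`,
#'   `padj`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("transcript_id", "chrom", "log2fc", "padj")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stopf("DE table missing column(s) %s; found: %s",
          paste(missing, collapse = ", "), paste(names(df), collapse = ", "))
  }
  log2fc <- suppressWarnings(as.numeric(df$log2fc))
  drop <- is.na(log2fc)
  if (any(drop)) {
    warnf("dropping %d row(s) with non-numeric log2fc", sum(drop))
  }
  padj <- suppressWarnings(as.numeric(df$padj))
  out <- data.frame(transcript_id = df$transcript_id[!drop],
                    chrom = df$chrom[!drop],
                    log2fc = log2fc[!drop],
                    padj = padj[!drop], stringsAsFactors = FALSE)
  bad <- !is.na(out$padj) & (out$padj < 0 | out$padj > 1)
  if (any(bad)) stopf("padj outside [0,1] for transcript '%s'",
                      out$transcript_id[which(bad)[1L]])
  out
}

#' Read a GMT gene-set file
#'
#' Each line carries a set name, a description, and one or more member gene
#' ids, tab-separated. Duplicate members within a line are deduplicated;
#' lines with fewer than three fields and duplicate set names are errors.
#'
#' @param path Path to the GMT file.
#' @return Named list of gene sets; each element is a list with `name`,
#'   `description` and a character vector `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad)) {
    stopf("GMT line %d: expected name, description and >= 1 member", bad[1L])
  }
  names_ <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names_)) {
    stopf("duplicate gene-set name '%s' in GMT", names_[anyDuplicated(names_)])
  }
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stopf("gene set '%s' has no members", f[1L])
    list(name = f[1L], description = f[2L], members = members)
  })
  names(sets) <- names_
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A list of gene sets as returned by [read_gmt()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
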