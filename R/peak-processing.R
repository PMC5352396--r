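# Greedy one-to-one pairing of overlapping peaks across two sets.
# Peaks are processed in genomic order; each peak of `a` is paired with the
# first (by genomic order) not-yet-used overlapping peak of `b`. Overlap
# means >= 1 shared bp on half-open intervals. Returns a two-column matrix
# of row indices (into the sorted sets a, b).
pair_overlapping_peaks <- function(a, b) {
  ga <- peaks_as_granges(a)
  gb <- peaks_as_granges(b)
  hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (!length(qh)) return(matrix(integer(0), ncol = 2L))
  ord <- order(qh, sh)
  qh <- qh[ord]; sh <- sh[ord]
  used_b <- logical(nrow(b))
  pair_a <- integer(0); pair_b <- integer(0)
  last_a <- 0L
  for (i in seq_along(qh)) {
    if (qh[i] == last_a) next           # this a-peak already paired
    if (used_b[sh[i]]) next
    last_a <- qh[i]
    used_b[sh[i]] <- TRUE
    pair_a <- c(pair_a, qh[i])
    pair_b <- c(pair_b, sh[i])
  }
  cbind(pair_a, pair_b, deparse.level = 0)
}

#' Replicate concordance of two peak sets
#'
#' Counts reciprocally overlapping peak pairs between two replicate peak
#' sets and reports concordance relative to the smaller set. A pair counts
#' as shared when the intervals overlap by at least 1 bp; each peak can
#' participate in at most one pair (greedy pairing in genomic order, which
#' keeps Venn-style intersection counts free of double counting). Replicate
#' pairs exceeding a concordance threshold (80% in the motivating study) are
#' the ones worth combining into high-confidence sites.
#'
#' @param a,b Non-empty [peak_set()]s (the two replicates).
#' @param denominator `"min"` (default): concordance = shared / min(|a|,|b|);
#'   `"mean"`: the mean of the two per-replicate shared fractions.
#' @return A list of class `concordance_report` with `n_a`, `n_b`,
#'   `n_shared`, `concordance`.
#' @export
replicate_concordance <- function(a, b, denominator = c("min", "mean")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"))
  if (!nrow(a) || !nrow(b)) {
    stopf("concordance is undefined for an empty peak set")
  }
  n_shared <- nrow(pair_overlapping_peaks(a, b))
  conc <- switch(denominator,
                 min = n_shared / min(nrow(a), nrow(b)),
                 mean = mean(c(n_shared / nrow(a), n_shared / nrow(b))))
  structure(list(n_a = nrow(a), n_b = nrow(b), n_shared = n_shared,
                 concordance = conc, denominator = denominator),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Replicate concordance: %d / %s(%d, %d) = %.3f (%d shared pairs)\n",
              x$n_shared, x$denominator, x$n_a, x$n_b, x$concordance,
              x$n_shared))
  invisible(x)
}

#' Combine two replicates into high-confidence peaks
#'
#' Peaks called reproducibly in both replicates are combined into a single
#' set of high-confidence binding sites: each overlapping pair (greedy
#' one-to-one, genomic order) yields one merged peak whose interval is the
#' union of the two member intervals and whose summit and score come from
#' the higher-scoring member (ties resolved in favour of replicate `a`).
#' Peaks without a partner in the other replicate are dropped.
#'
#' @param a,b [peak_set()]s (the two replicates).
#' @param sample_id Sample label for the combined set; defaults to the two
#'   members' ids joined.
#' @return A [peak_set()] of merged high-confidence peaks.
#' @export
high_confidence_peaks <- function(a, b, sample_id = NULL) {
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"))
  if (is.null(sample_id)) {
    sample_id <- paste(attr(a, "sample_id"), attr(b, "sample_id"), sep = "+")
  }
  pairs <- pair_overlapping_peaks(a, b)
  if (!nrow(pairs)) {
    return(peak_set(character(0), integer(0), integer(0), integer(0),
                    numeric(0), character(0), sample_id = sample_id))
  }
  pa <- a[pairs[, 1L], , drop = FALSE]
  pb <- b[pairs[, 2L], , drop = FALSE]
  use_b <- pb$score > pa$score
  peak_set(chrom = pa$chrom,
           start = pmin(pa$start, pb$start),
           end = pmax(pa$end, pb$end),
           summit = ifelse(use_b, pb$summit, pa$summit),
           score = ifelse(use_b, pb$score, pa$score),
           name = sprintf("hc_%05d", seq_len(nrow(pa))),
           sample_id = sample_id)
}

#' Summit-centered windows
#'
#' Fixed-width windows centered on each peak summit,
#' `[summit - width/2, summit + width/2)`, clipped to the chromosome bounds.
#' These are the units on which normalized binding signal is quantified.
#'
#' @param p A [peak_set()].
#' @param width Even window width in bp (default 100).
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp). Every
#'   chromosome carrying a summit must be present.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
summit_windows <- function(p, width = 100L, chrom_sizes) {
  stopifnot(inherits(p, "peak_set"))
  width <- as.integer(width)
  if (width <= 0L || width %% 2L != 0L) {
    stopf("window width must be even and > 0 (got %d)", width)
  }
  absent <- setdiff(unique(p$chrom), names(chrom_sizes))
  if (length(absent)) {
    stopf("chromosome '%s' absent from chrom_sizes", absent[1L])
  }
  half <- width %/% 2L
  len <- as.integer(chrom_sizes[p$chrom])
  start <- pmax(0L, p$summit - half)
  end <- pmin(len, p$summit + half)
  data.frame(chrom = p$chrom, start = start, end = end, name = p$name,
             stringsAsFactors = FALSE)
}

#' Merge summit windows across samples
#'
#' Builds the reference window set for cross-sample correlation: the union
#' of every sample's summit-centered windows, with overlapping windows
#' merged (signal is then re-quantified on the merged windows).
#'
#' @param peak_sets List of [peak_set()]s.
#' @param width Window width in bp, passed to [summit_windows()].
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return Data frame of disjoint merged windows (`chrom`, `start`, `end`,
#'   `name`).
#' @export
merge_summit_windows <- function(peak_sets, width = 100L, chrom_sizes) {
  wins <- do.call(rbind, lapply(peak_sets, summit_windows,
                                width = width, chrom_sizes = chrom_sizes))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = wins$chrom,
    ranges = IRanges::IRanges(start = wins$start + 1L, end = wins$end)))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$name <- sprintf("win_%06d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df
}

#' Reads-per-million normalization
#'
#' Scales per-window read counts by the total number of aligned reads:
#' `count * 1e6 / library_size`. Scale-invariant: doubling all counts and
#' the library size leaves the RPM values unchanged.
#'
#' @param read_counts Nonnegative numeric vector (or matrix with samples in
#'   columns) of per-window read counts.
#' @param library_size Total aligned reads (> 0); a vector of per-sample
#'   sizes when `read_counts` is a matrix.
#' @return RPM values, same shape as `read_counts`.
#' @export
normalized_signal <- function(read_counts, library_size) {
  if (any(library_size <= 0)) stopf("library_size must be > 0")
  if (any(read_counts < 0)) stopf("read counts must be >= 0")
  if (is.matrix(read_counts)) {
    if (length(library_size) == 1L) {
      library_size <- rep(library_size, ncol(read_counts))
    }
    stopifnot(length(library_size) == ncol(read_counts))
    sweep(read_counts, 2L, library_size / 1e6, "/")
  } else {
    read_counts * 1e6 / library_size
  }
}

#' Spearman rank correlation
#'
#' Average ranks are assigned to ties; the coefficient is the Pearson
#' correlation of the two rank vectors. When either vector has zero rank
#' variance the coefficient is undefined and `NA` is returned with a
#' warning.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A single correlation in \[-1, 1\], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need at least 3 observations")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    warnf("zero rank variance: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Pairwise Spearman correlation matrix of binding signal
#'
#' All pairwise Spearman correlations between sample columns of a
#' normalized-signal matrix (windows x samples), as used to compare binding
#' profiles across samples and replicates.
#'
#' @param m Numeric matrix, windows in rows, samples in columns (>= 2
#'   columns), typically RPM values on a merged summit-window set
#'   ([merge_summit_windows()] + [normalized_signal()]).
#' @return Symmetric correlation matrix with unit diagonal and sample ids as
#'   dimnames.
#' @export
correlation_matrix <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stopf("need >= 2 samples")
  ids <- colnames(m)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(ncol(m)))
  rho <- diag(1, ncol(m))
  for (i in seq_len(ncol(m) - 1L)) {
    for (j in (i + 1L):ncol(m)) {
      rho[i, j] <- rho[j, i] <- spearman_rho(m[, i], m[, j])
    }
  }
  dimnames(rho) <- list(ids, ids)
  rho
}

#' Agglomerative hierarchical clustering
#'
#' Thin wrapper around [stats::hclust()] exposing the two configurations the
#' pipeline uses: Ward linkage on euclidean distances (the expression
#' heatmap; `"ward"` maps to `hclust` method `"ward.D"`, the classic Ward
#' update) and average linkage on a 1 - Spearman-rho dissimilarity (binding
#' patterns).
#'
#' @param vectors Numeric matrix, one item per row, or a `dist` object.
#' @param method `"ward"` or `"average"`.
#' @param metric `"euclidean"` or `"one_minus_rho"` (ignored when `vectors`
#'   is already a `dist`).
#' @return An [stats::hclust] object (merge steps, heights, leaf order).
#' @export
hierarchical_cluster <- function(vectors,
                                 method = c("ward", "average"),
                                 metric = c("euclidean", "one_minus_rho")) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  if (inherits(vectors, "dist")) {
    d <- vectors
  } else {
    vectors <- as.matrix(vectors)
    if (nrow(vectors) < 2L) stopf("need >= 2 items to cluster")
    if (any(!is.finite(vectors))) stopf("non-finite values in input")
    d <- switch(metric,
                euclidean = stats::dist(vectors, method = "euclidean"),
                one_minus_rho = {
                  rho <- suppressWarnings(
                    stats::cor(t(vectors), method = "spearman"))
                  rho[is.na(rho)] <- 0
                  stats::as.dist(1 - rho)
                })
  }
  stats::hclust(d, method = switch(method, ward = "ward.D",
                                   average = "average"))
}
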