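# Independent brute-force oracles and small fixture builders. Every oracle
# here deliberately takes a different route from the package implementation
# it checks.

# Spearman by hand: average ranks, then the Pearson formula written out
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# nearest summit by all-pairs scan
oracle_nearest <- function(ann, peaks) {
  vapply(seq_len(nrow(ann)), function(i) {
    same <- peaks$chrom == ann$chrom[i]
    if (!any(same)) return(Inf)
    min(abs(peaks$summit[same] - ann$tss[i]))
  }, 0)
}

# greedy one-to-one overlap pairing, plain-loop route
oracle_shared_pairs <- function(a, b) {
  used <- logical(nrow(b))
  shared <- 0L
  for (i in seq_len(nrow(a))) {
    cand <- which(b$chrom == a$chrom[i] & b$start < a$end[i] &
                    b$end > a$start[i] & !used)
    if (length(cand)) {
      used[cand[1L]] <- TRUE        # b is sorted, so cand[1] is genomic-first
      shared <- shared + 1L
    }
  }
  shared
}

# same greedy pairing, pruned by sorted start positions so 10,000-peak
# instances stay fast; still plain interval arithmetic, no overlap engine
oracle_shared_pairs_fast <- function(a, b) {
  shared <- 0L
  for (chr in unique(a$chrom)) {
    ai <- which(a$chrom == chr)
    bi <- which(b$chrom == chr)
    if (!length(bi)) next
    bs <- b$start[bi]; be <- b$end[bi]
    used <- logical(length(bi))
    maxw <- max(be - bs)
    for (i in ai) {
      lo <- findInterval(a$start[i] - maxw, bs)
      hi <- findInterval(a$end[i] - 1L, bs)
      if (hi < 1L) next
      cand <- max(lo, 1L):hi
      cand <- cand[bs[cand] < a$end[i] & be[cand] > a$start[i] & !used[cand]]
      if (length(cand)) {
        used[cand[1L]] <- TRUE
        shared <- shared + 1L
      }
    }
  }
  shared
}

# IUPAC consensus matching by regex expansion on both strands
oracle_motif_match <- function(seqs, consensus) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  pat <- paste(map[strsplit(consensus, "")[[1]]], collapse = "")
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  rc_pat <- paste(map[strsplit(rc(consensus), "")[[1]]], collapse = "")
  grepl(pat, seqs) | grepl(rc_pat, seqs)
}

# exact two-sample KS upper tail through stats::psmirnov (ties supported)
oracle_ks_exact_p <- function(x, y, d_stat) {
  1 - stats::psmirnov(d_stat - 1e-9, sizes = c(length(x), length(y)),
                      z = sort(c(x, y)), exact = TRUE)
}

# hypergeometric upper tail by direct enumeration of the pmf via choose()
oracle_hyper_upper <- function(k, n, K, N) {
  ks <- max(0, n - (N - K)):min(n, K)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pmf[ks >= k])
}

# fixture: a small peak set from summit positions (disjoint 200-bp peaks)
make_peaks <- function(summits, chrom = "chr1", score = NULL, id = "fix") {
  n <- length(summits)
  if (is.null(score)) score <- rep(10, n)
  peak_set(chrom = rep(chrom, n), start = summits - 100L,
           end = summits + 100L, summit = summits, score = score,
           sample_id = id)
}

# fixture: minimal annotation on one chromosome from TSS positions
make_annotation <- function(tss, chrom = "chr1") {
  n <- length(tss)
  transcript_annotation(sprintf("t%03d", seq_len(n)),
                        sprintf("g%03d", seq_len(n)),
                        rep(chrom, n), rep("+", n), tss = tss)
}

# a small cached "separated" scenario shared across test files
small_separated <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_scenario("separated", seed = 11,
                                  n_transcripts = 300, n_targets = 20,
                                  n_background_peaks = 60, n_null_de = 10)
    }
    cache
  }
})
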