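#' Distance from each TSS to the nearest peak summit
#'
#' For every transcript, the unstranded absolute distance from its TSS to
#' the nearest peak summit on the same chromosome. Transcripts on a
#' chromosome with no peaks get an infinite distance and no nearest peak —
#' they still count in downstream ECDF denominators (no nearby binding is
#' evidence against proximity).
#'
#' @param tss_records Transcript annotation (see [transcript_annotation()]).
#' @param peaks A [peak_set()].
#' @param reference `"summit"` (default) measures TSS-to-summit;
#'   `"edge"` measures to the nearest interval edge (0 inside a peak).
#' @return Data frame with columns `transcript_id`, `distance` (bp, `Inf`
#'   when no same-chromosome peak), `nearest_peak` (name or `NA`).
#' @export
nearest_peak_distance <- function(tss_records, peaks,
                                  reference = c("summit", "edge")) {
  reference <- match.arg(reference)
  stopifnot(inherits(peaks, "peak_set"))
  n <- nrow(tss_records)
  distance <- rep(Inf, n)
  nearest <- rep(NA_character_, n)
  for (chr in unique(tss_records$chrom)) {
    ti <- which(tss_records$chrom == chr)
    pk <- peaks[peaks$chrom == chr, , drop = FALSE]
    if (!nrow(pk)) next
    tss <- tss_records$tss[ti]
    if (reference == "summit") {
      pos <- sort(pk$summit)
      ord <- order(pk$summit)
      # nearest of the two flanking summits around each TSS
      right <- findInterval(tss, pos) + 1L
      left <- right - 1L
      d_left <- ifelse(left >= 1L, abs(tss - pos[pmax(left, 1L)]), Inf)
      d_right <- ifelse(right <= length(pos),
                        abs(pos[pmin(right, length(pos))] - tss), Inf)
      use_right <- d_right < d_left
      distance[ti] <- pmin(d_left, d_right)
      idx <- ifelse(use_right, pmin(right, length(pos)), pmax(left, 1L))
      nearest[ti] <- pk$name[ord][idx]
    } else {
      gr_t <- GenomicRanges::GRanges(chr, IRanges::IRanges(tss + 1L, tss + 1L))
      gr_p <- peaks_as_granges(pk)
      hit <- GenomicRanges::nearest(gr_t, gr_p, select = "arbitrary")
      d <- GenomicRanges::distance(gr_t, gr_p[hit])
      distance[ti] <- as.numeric(d)
      nearest[ti] <- pk$name[hit]
    }
  }
  data.frame(transcript_id = tss_records$transcript_id,
             distance = distance, nearest_peak = nearest,
             stringsAsFactors = FALSE)
}

#' Empirical CDF of nearest-peak distances
#'
#' Right-continuous step function `F(d) = #(distances <= d) / total`, where
#' the total includes transcripts with infinite distance (no same-chromosome
#' peak), so the curve plateaus below 1 when such transcripts exist.
#'
#' @param distances Numeric vector of nonnegative distances, `Inf` allowed;
#'   at least one finite value required.
#' @return List of class `ecdf_curve` with `support` (sorted unique finite
#'   distances), `fraction` (cumulative fraction at each support point),
#'   `n` (total count), `n_infinite`.
#' @export
distance_ecdf <- function(distances) {
  if (!length(distances) || !any(is.finite(distances))) {
    stopf("need at least one finite distance")
  }
  if (any(distances < 0, na.rm = TRUE)) stopf("distances must be >= 0")
  fin <- sort(distances[is.finite(distances)])
  support <- unique(fin)
  fraction <- cumsum(tabulate(match(fin, support))) / length(distances)
  structure(list(support = support, fraction = fraction,
                 n = length(distances),
                 n_infinite = sum(is.infinite(distances))),
            class = "ecdf_curve")
}

#' Evaluate an `ecdf_curve` at given distances
#'
#' @param curve An [distance_ecdf()] result.
#' @param d Numeric vector of evaluation points.
#' @return Cumulative fractions at `d`.
#' @export
ecdf_eval <- function(curve, d) {
  idx <- findInterval(d, curve$support)
  ifelse(idx == 0L, 0, curve$fraction[pmax(idx, 1L)])
}

#' @export
print.ecdf_curve <- function(x, ...) {
  cat(sprintf("Distance ECDF over %d transcripts (%d with no same-chromosome peak); F reaches %.3f at %s bp\n",
              x$n, x$n_infinite, max(x$fraction),
              format(max(x$support), big.mark = ",")))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The enrichment test behind the distance-CDF comparison: the statistic is
#' the supremum absolute difference between the two empirical CDFs,
#' evaluated at every observed value (so ties, including repeated
#' distances, are handled exactly). Three p-value routes:
#'
#' * `asymptotic`: the Kolmogorov limit with Stephens' small-sample
#'   correction, `lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) * D` with
#'   `ne = n1*n2/(n1+n2)`, and
#'   `Q(lambda) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 lambda^2)`, the
#'   series truncated once terms fall below 1e-10, clamped to (0, 1].
#' * `exact_permutation`: full enumeration of all `choose(n1+n2, n1)`
#'   assignments of the pooled values when that count is at most
#'   `exact_limit`, giving the exact permutation p (valid under ties);
#'   otherwise a seeded Monte-Carlo estimate with `n_mc` permutations
#'   (add-one estimator, so p stays in (0, 1]).
#' * `auto` (default): exact when feasible, else asymptotic.
#'
#' @param d1,d2 Numeric samples (e.g. nearest-peak distances of DE
#'   transcripts vs the annotated background); `Inf` values allowed.
#' @param method `"auto"`, `"asymptotic"` or `"exact_permutation"`.
#' @param seed Seed for the Monte-Carlo fallback.
#' @param exact_limit Largest enumerable number of splits (default 2e5,
#'   which covers `n1 = n2 = 10`).
#' @param n_mc Monte-Carlo permutation count (default 1e4).
#' @return List of class `ks_result`: `d_stat`, `p_value`, `n1`, `n2`,
#'   `method` (the route actually used: `"asymptotic"`,
#'   `"exact_permutation"` or `"monte_carlo"`).
#' @export
ks_two_sample <- function(d1, d2, method = c("auto", "asymptotic",
                                             "exact_permutation"),
                          seed = 1L, exact_limit = 2e5, n_mc = 1e4) {
  method <- match.arg(method)
  n1 <- length(d1); n2 <- length(d2)
  if (!n1 || !n2) stopf("both samples must be non-empty")
  d_stat <- ks_d_stat(d1, d2)

  n_splits <- choose(n1 + n2, n1)
  # enumeration is worthwhile only for genuinely small pooled samples
  exact_ok <- n_splits <= exact_limit && (n1 + n2) <= 40L
  route <- if (method == "asymptotic") {
    "asymptotic"
  } else if (method == "exact_permutation") {
    if (exact_ok) "exact_permutation" else "monte_carlo"
  } else {                                      # auto
    if (exact_ok) "exact_permutation" else "asymptotic"
  }

  p <- switch(route,
    asymptotic = ks_asymptotic_p(d_stat, n1, n2),
    exact_permutation = ks_exact_p(d1, d2, d_stat),
    monte_carlo = ks_mc_p(d1, d2, d_stat, seed = seed, n_mc = n_mc))
  structure(list(d_stat = d_stat, p_value = p, n1 = n1, n2 = n2,
                 method = route),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f (n1 = %d, n2 = %d), p = %.3g [%s]\n",
              x$d_stat, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

# sup_t |F1(t) - F2(t)| over every observed value (handles ties and Inf):
# single pooled sort, ECDF difference read off at the end of each tie group
ks_d_stat <- function(d1, d2) {
  n1 <- length(d1); n2 <- length(d2)
  z <- c(d1, d2)
  ord <- order(z)
  is1 <- c(rep(TRUE, n1), rep(FALSE, n2))[ord]
  z <- z[ord]
  f1 <- cumsum(is1) / n1
  f2 <- cumsum(!is1) / n2
  n <- n1 + n2
  keep <- c(z[-n] != z[-1L], TRUE)   # last position of every tie run
  max(abs(f1 - f2)[keep])
}

ks_asymptotic_p <- function(d_stat, n1, n2) {
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d_stat
  if (lambda < 1e-3) return(1)
  total <- 0
  for (j in 1:1000) {
    term <- (-1)^(j - 1) * exp(-2 * j^2 * lambda^2)
    total <- total + term
    if (abs(term) < 1e-10) break
  }
  min(max(2 * total, .Machine$double.xmin), 1)
}

# Exact permutation p by full enumeration. Assignments of pooled sorted
# values to sample 1 are enumerated as position subsets; per split, the ECDF
# difference is evaluated at the last index of every tie group, which is
# where the pooled ECDF can change.
ks_exact_p <- function(d1, d2, d_stat) {
  n1 <- length(d1); n2 <- length(d2); n <- n1 + n2
  z <- sort(c(d1, d2))
  # last position of each tie run
  eval_at <- which(c(z[-n] != z[-1L], TRUE))
  comb <- utils::combn(n, n1)
  nsplit <- ncol(comb)
  m <- matrix(0, nsplit, n)
  m[cbind(rep(seq_len(nsplit), each = n1), as.vector(comb))] <- 1
  # cumulative-sum operator: [j, i] = 1 when j <= i
  cum_op <- upper.tri(matrix(0, n, n), diag = TRUE)
  cum1 <- m %*% cum_op
  total <- matrix(rep(seq_len(n), each = nsplit), nsplit, n)
  diff <- abs(cum1 / n1 - (total - cum1) / n2)
  d_all <- rep(0, nsplit)
  for (j in eval_at) d_all <- pmax(d_all, diff[, j])
  mean(d_all >= d_stat - 1e-12)
}

ks_mc_p <- function(d1, d2, d_stat, seed, n_mc) {
  n1 <- length(d1); n <- n1 + length(d2)
  pooled <- c(d1, d2)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_mc)) {
      idx <- sample.int(n, n1)
      if (ks_d_stat(pooled[idx], pooled[-idx]) >= d_stat - 1e-12) {
        hits <- hits + 1L
      }
    }
    (hits + 1) / (n_mc + 1)
  })
}

#' Call direct targets by the distance rule
#'
#' A filtered differentially expressed transcript is a direct target when
#' its nearest high-confidence peak lies within `cutoff` bp of its TSS
#' (inclusive boundary: "within 50 kb" includes exactly 50,000). Targets are
#' split by regulation direction: transcripts down upon knockdown are
#' activated by the factor, transcripts up are repressed.
#'
#' @param filtered A [filter_de()] result.
#' @param distances A [nearest_peak_distance()] result covering every
#'   retained transcript.
#' @param cutoff Distance cutoff in bp (default 50,000).
#' @param sample_id Optional sample label.
#' @return List of class `direct_target_set`: `activated` and `repressed`
#'   (transcript-id vectors), `cutoff`, `sample_id`, `table` (per-target
#'   transcript, direction, distance, nearest peak), `n_boundary` (targets
#'   sitting exactly on the cutoff).
#' @export
call_direct_targets <- function(filtered, distances, cutoff = 50000,
                                sample_id = "sample") {
  stopifnot(inherits(filtered, "filtered_de"))
  if (cutoff < 0) stopf("cutoff must be >= 0")
  ret <- filtered$retained
  idx <- match(ret$transcript_id, distances$transcript_id)
  if (anyNA(idx)) {
    stopf("no distance recorded for transcript '%s'",
          ret$transcript_id[which(is.na(idx))[1L]])
  }
  d <- distances$distance[idx]
  hit <- d <= cutoff
  tab <- data.frame(transcript_id = ret$transcript_id[hit],
                    direction = ret$direction[hit],
                    distance = d[hit],
                    nearest_peak = distances$nearest_peak[idx][hit],
                    stringsAsFactors = FALSE)
  structure(list(activated = tab$transcript_id[tab$direction == "down_upon_kd"],
                 repressed = tab$transcript_id[tab$direction == "up_upon_kd"],
                 cutoff = cutoff, sample_id = sample_id, table = tab,
                 n_boundary = sum(d == cutoff)),
            class = "direct_target_set")
}

#' @export
print.direct_target_set <- function(x, ...) {
  cat(sprintf("Direct targets ('%s', cutoff %s bp): %d activated, %d repressed%s\n",
              x$sample_id, format(x$cutoff, big.mark = ","),
              length(x$activated), length(x$repressed),
              if (x$n_boundary) sprintf(" (%d exactly on the cutoff)",
                                        x$n_boundary) else ""))
  invisible(x)
}

#' Fraction of filtered transcripts that are direct targets
#'
#' @param targets A [call_direct_targets()] result.
#' @param filtered The [filter_de()] result it was derived from.
#' @return `(n activated + n repressed) / n retained`, in \[0, 1\].
#' @export
fraction_within <- function(targets, filtered) {
  stopifnot(inherits(targets, "direct_target_set"),
            inherits(filtered, "filtered_de"))
  n_ret <- nrow(filtered$retained)
  if (!n_ret) stopf("filtered set is empty")
  (length(targets$activated) + length(targets$repressed)) / n_ret
}

#' Intersect direct-target sets across samples
#'
#' Transcripts called as direct targets in both samples, with the per-sample
#' regulation direction and a concordance flag (a transcript can be
#' activated in one sample and repressed in the other; such discordant
#' cases are retained and flagged).
#'
#' @param a,b [call_direct_targets()] results.
#' @return Data frame with columns `transcript_id`, `direction_a`,
#'   `direction_b`, `direction_concordant`.
#' @export
intersect_target_sets <- function(a, b) {
  stopifnot(inherits(a, "direct_target_set"),
            inherits(b, "direct_target_set"))
  all_a <- c(a$activated, a$repressed)
  all_b <- c(b$activated, b$repressed)
  common <- intersect(all_a, all_b)
  dir_a <- ifelse(common %in% a$activated, "down_upon_kd", "up_upon_kd")
  dir_b <- ifelse(common %in% b$activated, "down_upon_kd", "up_upon_kd")
  data.frame(transcript_id = common, direction_a = dir_a,
             direction_b = dir_b, direction_concordant = dir_a == dir_b,
             stringsAsFactors = FALSE)
}
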