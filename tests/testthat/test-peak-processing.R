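test_that("replicate concordance: identity, shifted-overlap, disjoint cases", {
  a <- make_peaks(c(1000L, 5000L, 9000L), id = "A")
  expect_equal(replicate_concordance(a, a)$concordance, 1.0)

  # 10 peaks vs 8 shifted copies plus 1 disjoint peak: 8 shared, min = 9
  set.seed(3)
  s <- sort(sample(seq(2000L, 900000L, by = 3000L), 10L))
  a <- make_peaks(s, id = "A")
  b <- make_peaks(c(s[1:8] + 10L, max(s) + 50000L), id = "B")
  r <- replicate_concordance(a, b)
  expect_equal(r$n_shared, 8L)
  expect_equal(r$concordance, 8 / 9)
  expect_equal(r$n_shared, oracle_shared_pairs(a, b))

  disj <- make_peaks(s + 1000L, id = "C")   # gaps are > 200 bp
  expect_equal(replicate_concordance(a, disj)$concordance, 0)
  expect_error(replicate_concordance(a, a[0, ]), "empty")
})

test_that("concordance is symmetric and matches the brute-force pairing", {
  for (seed in 1:5) {
    set.seed(seed)
    sa <- sort(sample(seq(1000L, 2e6L, by = 500L), 40L))
    sb <- sort(sample(seq(1000L, 2e6L, by = 500L), 30L))
    a <- make_peaks(sa, id = "A"); b <- make_peaks(sb, id = "B")
    ab <- replicate_concordance(a, b)
    ba <- replicate_concordance(b, a)
    expect_equal(ab$concordance, ba$concordance)
    expect_equal(ab$n_shared, oracle_shared_pairs(a, b))
  }
  # mean-denominator option
  a <- make_peaks(c(1000L, 5000L), id = "A")
  b <- make_peaks(c(1010L, 5010L, 9000L, 12000L), id = "B")
  expect_equal(replicate_concordance(a, b, denominator = "mean")$concordance,
               mean(c(2 / 2, 2 / 4)))
})

test_that("high-confidence peaks merge by union and inherit the best summit", {
  a <- peak_set("chr1", 100L, 200L, 150L, 10, name = "a1", sample_id = "A")
  b <- peak_set("chr1", 150L, 250L, 180L, 20, name = "b1", sample_id = "B")
  hc <- high_confidence_peaks(a, b)
  expect_equal(hc$start, 100L)
  expect_equal(hc$end, 250L)
  expect_equal(hc$summit, 180L)   # higher-scoring member wins
  expect_equal(hc$score, 20)

  # tie goes to replicate a
  b2 <- peak_set("chr1", 150L, 250L, 180L, 10, name = "b1", sample_id = "B")
  expect_equal(high_confidence_peaks(a, b2)$summit, 150L)

  # identity and disjoint edge cases; count bounded by the smaller set
  set.seed(4)
  s <- sort(sample(seq(1000L, 5e5L, by = 1000L), 25L))
  p <- make_peaks(s, score = runif(25, 1, 50), id = "P")
  self <- high_confidence_peaks(p, p)
  expect_equal(nrow(self), nrow(p))
  expect_equal(self$start, p$start)
  expect_equal(self$summit, p$summit)
  q <- make_peaks(s[1:10] + 5000L, id = "Q")
  expect_equal(nrow(high_confidence_peaks(p, q)), 0L)
  expect_lte(nrow(high_confidence_peaks(p, q)), min(nrow(p), nrow(q)))
})

test_that("summit windows are centered, clipped, and validated", {
  sizes <- c(chr1 = 10000)
  p <- peak_set("chr1", 900L, 1100L, 1000L, 5, sample_id = "w")
  w <- summit_windows(p, width = 100L, chrom_sizes = sizes)
  expect_equal(c(w$start, w$end), c(950L, 1050L))

  edge <- peak_set("chr1", 0L, 200L, 30L, 5, sample_id = "w")
  w <- summit_windows(edge, width = 160L, chrom_sizes = sizes)
  expect_equal(c(w$start, w$end), c(0L, 110L))   # clipped at the origin

  expect_error(summit_windows(p, width = 101L, chrom_sizes = sizes), "even")
  expect_error(summit_windows(p, width = 100L, chrom_sizes = c(chr9 = 1e4)),
               "absent")
})

test_that("RPM normalization is linear and scale-invariant", {
  expect_equal(normalized_signal(c(5, 10), 1e6), c(5, 10))
  expect_equal(normalized_signal(7, 2e6), 3.5)
  expect_error(normalized_signal(5, 0), "> 0")
  x <- c(3, 0, 41, 17)
  expect_equal(normalized_signal(x, 1.7e7), normalized_signal(2 * x, 3.4e7))
  m <- cbind(a = c(2, 4), b = c(10, 0))
  expect_equal(normalized_signal(m, c(1e6, 2e6)),
               cbind(a = c(2, 4), b = c(5, 0)))
})

test_that("spearman_rho matches the rank-then-Pearson oracle", {
  expect_equal(spearman_rho(1:3, c(2, 4, 6)), 1.0)
  expect_equal(spearman_rho(1:3, c(6, 4, 2)), -1.0)
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(1, 3, 2, 4)),
               oracle_spearman(c(1, 2, 2, 3), c(1, 3, 2, 4)))
  set.seed(10)
  for (i in 1:25) {
    n <- sample(3:50, 1)
    x <- sample(1:12, n, replace = TRUE)   # heavy ties
    y <- rnorm(n)
    r <- spearman_rho(x, y)
    if (is.na(r)) next
    expect_equal(r, oracle_spearman(x, y), tolerance = 1e-12)
    expect_true(abs(r) <= 1 + 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(spearman_rho(exp(x / 3), y), r, tolerance = 1e-12)
  }
  expect_warning(r <- spearman_rho(rep(1, 5), rnorm(5)), "zero rank variance")
  expect_true(is.na(r))
})

test_that("correlation matrix recovers planted sample-group structure", {
  m <- cbind(s1 = c(1, 5, 2, 8), s2 = c(1, 5, 2, 8))
  cm <- correlation_matrix(m)
  expect_equal(cm["s1", "s2"], 1.0)
  expect_equal(diag(cm), c(s1 = 1, s2 = 1))
  m2 <- cbind(a = c(1, 5, 2, 8), b = -c(1, 5, 2, 8)^3)
  expect_equal(correlation_matrix(m2)["a", "b"], -1.0)

  scn <- small_separated()
  rpm <- normalized_signal(scn$signal$counts, scn$signal$library_sizes)
  cm <- correlation_matrix(rpm)
  groups <- scn$signal$sample_groups
  within <- c(cm["A_1", "A_2"], cm["B_1", "B_2"])
  between <- c(cm["A_1", "B_1"], cm["A_1", "B_2"],
               cm["A_2", "B_1"], cm["A_2", "B_2"])
  expect_true(min(within) > max(between))
})

test_that("hierarchical clustering: hand-checked merges and monotone heights", {
  two <- rbind(c(0, 0), c(0, 0))
  hc <- hierarchical_cluster(two, method = "average")
  expect_equal(hc$height, 0)

  line <- matrix(c(0, 1, 10), ncol = 1)
  hc <- hierarchical_cluster(line, method = "average")
  expect_equal(hc$merge[1, ], c(-1, -2))     # {0,1} merges first
  expect_equal(hc$height[1], 1)

  set.seed(2)
  x <- matrix(rnorm(60), nrow = 12)
  for (m in c("ward", "average")) {
    hc <- hierarchical_cluster(x, method = m)
    expect_true(all(diff(hc$height) >= -1e-12))      # monotone linkage
    expect_setequal(unlist(hc$merge)[unlist(hc$merge) < 0], -(1:12))
  }
  expect_error(hierarchical_cluster(matrix(c(1, NA), 2)), "non-finite")
})
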