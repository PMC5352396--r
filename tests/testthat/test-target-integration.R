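test_that("nearest-peak distance: worked cases and the all-pairs oracle", {
  ann <- make_annotation(c(10000L, 9000L, 500L))
  pk <- make_peaks(c(9000L, 60000L))
  d <- nearest_peak_distance(ann, pk)
  expect_equal(d$distance[1], 1000)
  expect_equal(d$nearest_peak[1], pk$name[1])
  expect_equal(d$distance[2], 0)                   # tss exactly at a summit

  ann2 <- make_annotation(5000L, chrom = "chr9")   # no peak on chr9
  d2 <- nearest_peak_distance(ann2, pk)
  expect_true(is.infinite(d2$distance))
  expect_true(is.na(d2$nearest_peak))

  set.seed(41)
  for (i in 1:5) {
    tss <- sample.int(5e6, 80)
    chroms <- sample(c("chr1", "chr2"), 80, replace = TRUE)
    ann <- transcript_annotation(sprintf("t%02d", 1:80), sprintf("g%02d", 1:80),
                                 chroms, rep("+", 80), tss = tss)
    pk_s <- sort(sample(seq(500L, 5e6L, by = 700L), 40))
    pk <- peak_set(sample(c("chr1", "chr2"), 40, replace = TRUE),
                   pk_s - 100L, pk_s + 100L, pk_s, runif(40, 1, 9))
    d <- nearest_peak_distance(ann, pk)
    expect_equal(d$distance, oracle_nearest(ann, pk))
  }
})

test_that("distance ECDF handles ties and infinite sentinels", {
  e <- distance_ecdf(c(0, 10, 20))
  expect_equal(ecdf_eval(e, 10), 2 / 3)
  expect_equal(ecdf_eval(e, 9.99), 1 / 3)
  expect_equal(max(e$fraction), 1)                 # all finite -> reaches 1

  e2 <- distance_ecdf(c(5, 5, 5))
  expect_equal(ecdf_eval(e2, 5), 1)

  e3 <- distance_ecdf(c(10, Inf))
  expect_equal(ecdf_eval(e3, 10), 0.5)             # sentinel in denominator
  expect_equal(max(e3$fraction), 0.5)

  expect_true(all(diff(distance_ecdf(runif(50) * 1e4)$fraction) >= 0))
  expect_error(distance_ecdf(c(Inf, Inf)), "finite")
  expect_error(distance_ecdf(numeric(0)), "finite")
})

test_that("KS worked example: separated triples give D = 1, exact p = 0.1", {
  k <- ks_two_sample(c(1, 2, 3), c(4, 5, 6), method = "exact_permutation")
  expect_equal(k$d_stat, 1.0)
  expect_equal(k$p_value, 2 / 20)                  # 2 of C(6,3) = 20 splits
  expect_equal(k$method, "exact_permutation")

  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$d_stat, 0)
  expect_equal(same$p_value, 1)
})

test_that("KS d_stat is exchange-symmetric and tie-exact", {
  set.seed(51)
  for (i in 1:10) {
    x <- sample(1:8, 12, replace = TRUE)
    y <- sample(1:8, 7, replace = TRUE)
    kxy <- ks_two_sample(x, y, method = "asymptotic")
    kyx <- ks_two_sample(y, x, method = "asymptotic")
    expect_equal(kxy$d_stat, kyx$d_stat)
    expect_equal(kxy$p_value, kyx$p_value)
    # R's ks.test computes the same statistic
    expect_equal(kxy$d_stat,
                 unname(suppressWarnings(stats::ks.test(x, y)$statistic)))
  }
  # infinite sentinels are legal sample values
  k <- ks_two_sample(c(1, 2, Inf), c(5, 6, 7, Inf), method = "asymptotic")
  expect_true(k$d_stat >= 0 && k$d_stat <= 1)
})

test_that("exact enumeration matches the independent distribution oracle", {
  set.seed(52)
  for (i in 1:10) {
    x <- sample(1:10, 7, replace = TRUE)
    y <- sample(1:10, 6, replace = TRUE)
    k <- ks_two_sample(x, y, method = "exact_permutation")
    expect_equal(k$p_value, oracle_ks_exact_p(x, y, k$d_stat),
                 tolerance = 1e-12)
  }
})

test_that("Monte-Carlo route is seeded and approximates the exact p", {
  set.seed(53)
  x <- rnorm(25); y <- rnorm(25, 0.8)              # C(50,25) >> enumerable
  k1 <- ks_two_sample(x, y, method = "exact_permutation", seed = 7)
  k2 <- ks_two_sample(x, y, method = "exact_permutation", seed = 7)
  expect_equal(k1$method, "monte_carlo")
  expect_identical(k1$p_value, k2$p_value)
  expect_gt(k1$p_value, 0)
  # the Monte-Carlo estimate approximates the exact permutation p
  expect_lt(abs(k1$p_value - oracle_ks_exact_p(x, y, k1$d_stat)), 0.02)
})

test_that("direct-target calling applies the inclusive 50-kb rule", {
  ret <- data.frame(transcript_id = c("a", "b", "c", "d"),
                    chrom = "chr1",
                    log2fc = c(-2.5, 2.5, -3, 3), padj = 0.01,
                    stringsAsFactors = FALSE)
  filt <- filter_de(ret)
  dist <- data.frame(transcript_id = c("a", "b", "c", "d"),
                     distance = c(49999, 50000, 50001, Inf),
                     nearest_peak = c("p1", "p2", "p3", NA),
                     stringsAsFactors = FALSE)
  tg <- call_direct_targets(filt, dist)
  expect_equal(tg$activated, "a")                  # down upon kd, within
  expect_equal(tg$repressed, "b")                  # boundary is inclusive
  expect_equal(tg$n_boundary, 1L)
  expect_length(intersect(tg$activated, tg$repressed), 0L)

  expect_equal(fraction_within(tg, filt), 0.5)

  # monotone in cutoff; zero cutoff keeps only distance-0 transcripts
  prev <- character(0)
  for (cut in c(0, 49999, 50001, 1e6)) {
    cur <- call_direct_targets(filt, dist, cutoff = cut)
    ids <- c(cur$activated, cur$repressed)
    expect_true(all(prev %in% ids))
    prev <- ids
  }
  expect_length(c(call_direct_targets(filt, dist, cutoff = 0)$activated,
                  call_direct_targets(filt, dist, cutoff = 0)$repressed), 0L)

  expect_error(call_direct_targets(filt, dist[1:3, ]), "no distance.*'d'")
})

test_that("target-set intersection flags direction discordance", {
  mk <- function(act, rep_) {
    structure(list(activated = act, repressed = rep_, cutoff = 5e4,
                   sample_id = "s", table = NULL, n_boundary = 0L),
              class = "direct_target_set")
  }
  common <- intersect_target_sets(mk(c("a", "b"), "c"), mk("b", c("c", "d")))
  expect_setequal(common$transcript_id, c("b", "c"))
  expect_true(all(common$direction_concordant))

  disc <- intersect_target_sets(mk("a", character(0)), mk(character(0), "a"))
  expect_equal(disc$transcript_id, "a")
  expect_false(disc$direction_concordant)

  none <- intersect_target_sets(mk("a", "b"), mk("x", "y"))
  expect_equal(nrow(none), 0L)
})
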