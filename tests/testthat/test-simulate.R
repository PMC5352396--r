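toy_sizes <- c(chr1 = 120e6, chr2 = 120e6, chrX = 60e6)

test_that("generators are bit-reproducible given the seed", {
  a1 <- generate_annotation(200, toy_sizes, seed = 3)
  a2 <- generate_annotation(200, toy_sizes, seed = 3)
  expect_identical(a1, a2)
  expect_false(identical(a1, generate_annotation(200, toy_sizes, seed = 4)))

  s1 <- simulate_scenario("separated", seed = 5, n_transcripts = 200,
                          n_targets = 15, n_background_peaks = 40,
                          n_null_de = 8)
  s2 <- simulate_scenario("separated", seed = 5, n_transcripts = 200,
                          n_targets = 15, n_background_peaks = 40,
                          n_null_de = 8)
  expect_identical(s1, s2)
})

test_that("annotation respects genome bounds and the chrX fraction", {
  ann <- generate_annotation(100, c(chrA = 1e7, chrB = 1e7), seed = 1,
                             chrx_fraction = 0.1)
  expect_equal(nrow(ann), 100L)
  expect_true(all(ann$tss < 1e7))
  expect_true(all(ann$strand %in% c("+", "-")))

  ann_x <- generate_annotation(100, toy_sizes, seed = 2, chrx_fraction = 0.1)
  expect_equal(sum(ann_x$chrom == "chrX"), 10L)    # deterministic rounding
})

test_that("planted peaks are within range and decoys verified far, by brute force", {
  ann <- generate_annotation(300, toy_sizes, seed = 7)
  pt <- generate_peak_truth(ann, toy_sizes, n_targets = 25,
                            n_background_peaks = 60, seed = 7)
  planted <- pt$truth$planted_targets
  expect_equal(nrow(planted), 25L)
  expect_true(all(planted$planted_distance <= 50000))
  expect_true(all(c("down_upon_kd", "up_upon_kd") %in% planted$direction))

  # brute-force all-pairs verification of the separation invariant
  d <- oracle_nearest(ann, pt$peaks)
  is_target <- ann$transcript_id %in% planted$transcript_id
  expect_true(all(d[is_target] <= 50000))
  expect_true(all(d[!is_target & is.finite(d)] >= 100000))
  expect_true(all(pt$truth$decoy_pool %in% ann$transcript_id[!is_target]))

  # infeasible geometry errors out rather than looping forever
  tiny <- c(chr1 = 2e6)
  dense <- generate_annotation(300, tiny, seed = 1, chrx_fraction = 0)
  expect_error(generate_peak_truth(dense, tiny, n_targets = 50,
                                   n_background_peaks = 10, seed = 1),
               "infeasible")
})

test_that("replicates: identity at full concordance, valid intervals under jitter", {
  ann <- generate_annotation(200, toy_sizes, seed = 9)
  pt <- generate_peak_truth(ann, toy_sizes, n_targets = 20,
                            n_background_peaks = 80, seed = 9)
  reps <- generate_replicates(pt$peaks, concordance = 1, jitter_sd = 0,
                              seed = 1)
  expect_equal(as.data.frame(reps$rep1)[c("chrom", "start", "end", "summit")],
               as.data.frame(pt$peaks)[c("chrom", "start", "end", "summit")])

  reps_j <- generate_replicates(pt$peaks, concordance = 0.8, jitter_sd = 25,
                                seed = 2)
  for (r in reps_j) {
    expect_true(all(r$start >= 0))
    expect_true(all(r$start < r$end))
    expect_true(all(r$summit >= r$start & r$summit < r$end))
  }
  expect_error(generate_replicates(pt$peaks, concordance = 0), "\\(0, 1\\]")
})

test_that("signal counts carry the planted group structure and RPM invariance", {
  scn <- small_separated()
  sig <- scn$signal
  expect_equal(dim(sig$counts), c(nrow(scn$peaks), 4L))
  expect_true(all(sig$counts >= 0))
  rpm <- normalized_signal(sig$counts, sig$library_sizes)
  rpm2 <- normalized_signal(2L * sig$counts, 2 * sig$library_sizes)
  expect_equal(rpm, rpm2)

  # near-zero dispersion behaves like Poisson around the mean
  pk <- scn$peaks
  sig0 <- generate_signal(pk, c(s1 = "A", s2 = "A"),
                          c(s1 = 1e6, s2 = 1e6), group_effect = 1,
                          dispersion = 0, base_mean = 100, seed = 3)
  expect_true(abs(mean(sig0$counts) - 100) < 25)
})

test_that("DE table plants exact effects, directions, and decoy counts", {
  ann <- generate_annotation(400, toy_sizes, seed = 13)
  pt <- generate_peak_truth(ann, toy_sizes, n_targets = 30,
                            n_background_peaks = 50, seed = 13)
  de <- generate_de_table(ann, pt$truth, noise_sd = 0, n_null_de = 20,
                          seed = 13)
  planted <- pt$truth$planted_targets
  idx <- match(planted$transcript_id, de$transcript_id)
  expect_true(all(abs(abs(de$log2fc[idx]) - 2) < 1e-12))  # exact +/- 2
  down <- planted$transcript_id[planted$direction == "down_upon_kd"]
  expect_true(all(de$log2fc[match(down, de$transcript_id)] < 0))

  f <- filter_de(de)
  untargeted <- setdiff(f$retained$transcript_id, planted$transcript_id)
  expect_length(untargeted, 20L)                   # exactly n_null_de decoys
  expect_true(all(untargeted %in% pt$truth$decoy_pool))

  expect_error(generate_de_table(ann, pt$truth, effect_log2fc = 1),
               "> 1")
})

test_that("GMT generator plants one enriched set per direction", {
  scn <- small_separated()
  expect_named(scn$planted_set_names, c("down_upon_kd", "up_upon_kd"))
  universe <- unique(scn$annotation$gene_id)
  planted <- scn$truth$planted_targets
  for (dir in names(scn$planted_set_names)) {
    nm <- scn$planted_set_names[[dir]]
    members <- scn$gene_sets[[nm]]$members
    genes <- planted$gene_id[planted$direction == dir]
    expect_gte(mean(genes %in% members), 0.8)      # >= 80% of that direction
    query <- genes
    res <- enrich_gene_sets(query, scn$gene_sets, universe)
    expect_equal(res$set_name[1], nm)              # rank 1 by q
  }
})

test_that("scenario files round-trip through the readers", {
  scn <- small_separated()
  dir <- withr::local_tempdir()
  paths <- write_scenario(scn, dir)
  r1 <- read_narrowpeak(paths$rep1)
  expect_equal(nrow(r1), nrow(scn$replicates$rep1))
  expect_equal(r1$summit, scn$replicates$rep1$summit)
  ann <- read_tss_table(paths$annotation)
  expect_equal(ann$tss, scn$annotation$tss)        # strand-aware re-derivation
  de <- read_de_table(paths$de)
  expect_equal(de$log2fc, scn$de_table$log2fc, tolerance = 1e-12)
  sets <- read_gmt(paths$gmt)
  expect_setequal(names(sets), names(scn$gene_sets))
})
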