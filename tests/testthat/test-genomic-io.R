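test_that("narrowPeak parsing: summit arithmetic, midpoint fallback, errors", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t200\tp1\t0\t.\t8.5\t-1\t-1\t50",
               "chr1\t300\t401\tp2\t0\t.\t3.0\t-1\t-1\t-1",
               "chr2\t0\t150\tp3\t0\t.\t1.25\t-1\t-1\t0"), f)
  p <- read_narrowpeak(f)
  expect_s3_class(p, "peak_set")
  expect_equal(p$summit[p$name == "p1"], 150L)          # start + offset
  expect_equal(p$score[p$name == "p1"], 8.5)            # signalValue
  expect_equal(p$summit[p$name == "p2"], 350L)          # floor midpoint
  expect_equal(p$summit[p$name == "p3"], 0L)            # offset 0 at start

  writeLines("chr1\t200\t100\tp1\t0\t.\t1\t-1\t-1\t5", f)
  expect_error(read_narrowpeak(f), "line 1.*invalid interval")
  writeLines("chr1\t100\t200\tp1\t0\t.\t1\t-1\t-1", f)
  expect_error(read_narrowpeak(f), "10 tab-separated")
  writeLines("chr1\tabc\t200\tp1\t0\t.\t1\t-1\t-1\t5", f)
  expect_error(read_narrowpeak(f), "non-numeric")
  writeLines("chr1\t100\t200\tp1\t0\t.\t1\t-1\t-1\t100", f)
  expect_error(read_narrowpeak(f), "offset")
})

test_that("write_bed round-trips coordinates and sorts output", {
  p <- peak_set(chrom = c("chr2", "chr1", "chr1"),
                start = c(500L, 900L, 100L), end = c(700L, 1000L, 300L),
                summit = c(600L, 950L, 120L), score = c(4.5, 2, 7.25),
                name = c("a", "b", "c"), sample_id = "rt")
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  write_bed(p, f)
  q <- read_narrowpeak(f, sample_id = "rt")
  expect_equal(q$chrom, p$chrom)
  expect_equal(q$start, p$start)
  expect_equal(q$end, p$end)
  expect_equal(q$summit, p$summit)
  expect_equal(q$score, p$score)
  # output is sorted by (chrom, start) regardless of construction order
  lines <- readLines(f)
  expect_equal(vapply(strsplit(lines, "\t"), `[`, "", 1L),
               c("chr1", "chr1", "chr2"))

  empty <- peak_set(character(0), integer(0), integer(0), integer(0),
                    numeric(0), character(0))
  write_bed(empty, f)
  expect_length(readLines(f), 0L)
})

test_that("TSS table: strand-aware TSS derivation and validation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tgene_id\tchrom\tstrand\ttx_start\ttx_end",
               "t1\tg1\tchr1\t+\t1000\t5000",
               "t2\tg1\tchr1\t-\t1000\t5000"), f)
  ann <- read_tss_table(f)
  expect_equal(ann$tss[ann$transcript_id == "t1"], 1000L)
  expect_equal(ann$tss[ann$transcript_id == "t2"], 4999L)  # 0-based last base

  writeLines(c("transcript_id\tgene_id\tchrom\tstrand\ttx_start\ttx_end",
               "t1\tg1\tchr1\t+\t1000\t5000",
               "t1\tg1\tchr1\t+\t2000\t6000"), f)
  expect_error(read_tss_table(f), "duplicate transcript_id")
  writeLines(c("transcript_id\tgene_id\tchrom\tstrand\ttx_start\ttx_end",
               "t1\tg1\tchr1\t*\t1000\t5000"), f)
  expect_error(read_tss_table(f), "unknown strand")
  writeLines(c("transcript_id\tchrom\tstrand", "t1\tchr1\t+"), f)
  expect_error(read_tss_table(f), "missing column")
})

test_that("DE table: numeric coercion, missing padj, column contract", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tchrom\tlog2fc\tpadj",
               "t1\tchr1\t2.0\t0.001",
               "t2\tchr2\tNA\t0.5",
               "t3\tchr1\t-1.5\tNA"), f)
  expect_warning(de <- read_de_table(f), "non-numeric log2fc")
  expect_equal(nrow(de), 2L)
  expect_equal(de$log2fc[de$transcript_id == "t1"], 2.0)
  expect_true(is.na(de$padj[de$transcript_id == "t3"]))

  writeLines(c("transcript_id\tchrom\tpadj", "t1\tchr1\t0.1"), f)
  expect_error(read_de_table(f), "missing column.*log2fc.*found")
})

test_that("GMT: dedup within line, minimum fields, duplicate set names", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tg1\tg2\tg2", "SETB\tother\tg3"), f)
  sets <- read_gmt(f)
  expect_named(sets, c("SETA", "SETB"))
  expect_equal(sort(sets$SETA$members), c("g1", "g2"))

  writeLines("SETB\tdesc", f)
  expect_error(read_gmt(f), ">= 1 member")
  writeLines(c("SETA\td\tg1", "SETA\td\tg2"), f)
  expect_error(read_gmt(f), "duplicate gene-set name")

  # write/read round-trip
  writeLines(c("SETA\tdesc\tg1\tg2", "SETB\tother\tg3"), f)
  sets <- read_gmt(f)
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f2)
  expect_identical(read_gmt(f2), sets)
})

test_that("peak_set enforces coordinate and summit invariants", {
  expect_error(peak_set("chr1", 200, 100, 150, 1), "start < end")
  expect_error(peak_set("chr1", 100, 200, 250, 1), "summit")
  expect_error(peak_set("chr1", 100, 200, 150, -1), "nonnegative")
  expect_error(peak_set(c("chr1", "chr1"), c(1, 5), c(4, 9), c(2, 6),
                        c(1, 1), name = c("p", "p")), "unique")
})
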