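# Seeded generators for every input the pipeline consumes, with planted
# ground truth. The "separated" scenario plants direct targets whose peaks
# sit within the distance cutoff while decoy DE transcripts stay far from
# every peak, making target recovery exactly checkable; the "null" scenario
# places peaks independently of transcripts so the KS enrichment test has
# nothing to find.

#' Generate a transcript annotation
#'
#' TSS positions are uniform within chromosomes, with transcripts allocated
#' to autosomes proportionally to length. When the genome contains a chrX, a
#' deterministic fraction of transcripts (rounded) is placed there so the
#' sex-chromosome filter is always exercised. Strands are Bernoulli(0.5).
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param seed Integer seed; output is bit-reproducible given
#'   (parameters, seed).
#' @param chrx_fraction Fraction of transcripts placed on chrX when present
#'   (default 0.1).
#' @return A [transcript_annotation()] with ids `t00001...` and one gene per
#'   transcript (`g00001...`).
#' @export
generate_annotation <- function(n_transcripts, chrom_sizes, seed,
                                chrx_fraction = 0.1) {
  stopifnot(n_transcripts >= 1, all(chrom_sizes > 0))
  with_seed(seed, {
    chroms <- names(chrom_sizes)
    x_chrom <- chroms[is_sex_chromosome(chroms)]
    auto <- setdiff(chroms, x_chrom)
    n_x <- if (length(x_chrom)) round(chrx_fraction * n_transcripts) else 0L
    n_auto <- n_transcripts - n_x
    chrom <- c(
      if (n_auto) sample(auto, n_auto, replace = TRUE,
                         prob = chrom_sizes[auto]),
      if (n_x) sample(rep(x_chrom, 2L), n_x, replace = TRUE,
                      prob = rep(chrom_sizes[x_chrom], 2L))
    )
    tss <- vapply(chrom, function(ch) {
      as.integer(floor(stats::runif(1, 0, chrom_sizes[[ch]])))
    }, 0L, USE.NAMES = FALSE)
    strand <- sample(c("+", "-"), n_transcripts, replace = TRUE)
    width <- nchar(as.character(n_transcripts))
    ids <- sprintf("t%0*d", max(5L, width), seq_len(n_transcripts))
    transcript_annotation(transcript_id = ids,
                          gene_id = sub("^t", "g", ids),
                          chrom = chrom, strand = strand, tss = tss)
  })
}

#' Plant direct-target peaks and background peaks
#'
#' Builds the "separated" binding-site truth: `n_targets` autosomal
#' transcripts, chosen among those whose TSS is isolated from every other
#' TSS by at least `max_target_distance + min_decoy_distance`, each receive
#' one peak with summit uniformly within `max_target_distance` of the TSS;
#' `n_background_peaks` further peaks are rejection-sampled at least
#' `min_decoy_distance` from every TSS. The isolation rule guarantees that
#' no non-target transcript ends up within `min_decoy_distance` of any
#' peak. Planted targets are split roughly evenly between the two
#' regulation directions.
#'
#' @param annotation A [transcript_annotation()].
#' @param chrom_sizes Named chromosome lengths.
#' @param n_targets Number of planted direct targets.
#' @param n_background_peaks Number of far-from-TSS background peaks.
#' @param max_target_distance Planted TSS-to-summit distance bound
#'   (default 50,000 bp).
#' @param min_decoy_distance Minimum distance of background peaks from
#'   every TSS (default 100,000 bp).
#' @param seed Integer seed.
#' @return List with `peaks` (a [peak_set()]) and `truth` (class
#'   `scenario_truth`: `planted_targets` data frame with direction and
#'   exact planted distance, `decoy_pool` of transcripts verified to be at
#'   least `min_decoy_distance` from every peak, and the generating
#'   parameters).
#' @export
generate_peak_truth <- function(annotation, chrom_sizes, n_targets = 50L,
                                n_background_peaks = 200L,
                                max_target_distance = 50000L,
                                min_decoy_distance = 100000L, seed = 1L) {
  stopifnot(n_targets <= nrow(annotation))
  with_seed(seed, {
    auto <- annotation[!is_sex_chromosome(annotation$chrom), , drop = FALSE]
    # nearest-TSS spacing per transcript (same chromosome, any strand)
    spacing <- rep(Inf, nrow(auto))
    for (ch in unique(auto$chrom)) {
      i <- which(auto$chrom == ch)
      others_all <- annotation$tss[annotation$chrom == ch]
      for (j in i) {
        d <- abs(others_all - auto$tss[j])
        spacing[j] <- min(d[d > 0], Inf)
      }
    }
    isolated <- which(spacing >= max_target_distance + min_decoy_distance)
    if (length(isolated) < n_targets) {
      stopf("placement infeasible: only %d sufficiently isolated transcripts for %d targets (genome too small or too dense)",
            length(isolated), n_targets)
    }
    target_rows <- sort(sample(isolated, n_targets))
    targets <- auto[target_rows, , drop = FALSE]

    offset <- round(stats::runif(n_targets, 0, max_target_distance)) *
      sample(c(-1L, 1L), n_targets, replace = TRUE)
    summit <- targets$tss + as.integer(offset)
    lo <- 300L
    hi <- as.integer(chrom_sizes[targets$chrom]) - 300L
    summit <- pmin(pmax(summit, lo), hi)
    planted_distance <- abs(summit - targets$tss)

    # background peaks: uniform over autosomes, >= min_decoy_distance from
    # every TSS (targets included, so planted distances stay exact)
    auto_chroms <- setdiff(names(chrom_sizes),
                           names(chrom_sizes)[is_sex_chromosome(names(chrom_sizes))])
    tss_by_chrom <- split(annotation$tss, annotation$chrom)
    bg_chrom <- character(0); bg_summit <- integer(0)
    tries <- 0L
    while (length(bg_summit) < n_background_peaks) {
      tries <- tries + 1L
      if (tries > 200L) {
        stopf("placement infeasible: could not place %d background peaks >= %d bp from every TSS",
              n_background_peaks, min_decoy_distance)
      }
      need <- n_background_peaks - length(bg_summit)
      cand_chrom <- sample(auto_chroms, 2L * need, replace = TRUE,
                           prob = chrom_sizes[auto_chroms])
      cand_pos <- vapply(cand_chrom, function(ch) {
        as.integer(floor(stats::runif(1, 300, chrom_sizes[[ch]] - 300)))
      }, 0L, USE.NAMES = FALSE)
      ok <- vapply(seq_along(cand_pos), function(i) {
        tss <- tss_by_chrom[[cand_chrom[i]]]
        is.null(tss) || all(abs(tss - cand_pos[i]) >= min_decoy_distance)
      }, TRUE)
      bg_chrom <- c(bg_chrom, cand_chrom[ok])
      bg_summit <- c(bg_summit, cand_pos[ok])
    }
    bg_chrom <- bg_chrom[seq_len(n_background_peaks)]
    bg_summit <- bg_summit[seq_len(n_background_peaks)]

    all_chrom <- c(targets$chrom, bg_chrom)
    all_summit <- c(summit, bg_summit)
    n_all <- length(all_summit)
    left <- sample(100:250, n_all, replace = TRUE)
    right <- sample(100:250, n_all, replace = TRUE)
    start <- pmax(0L, all_summit - left)
    end <- all_summit + right
    score <- c(stats::runif(n_targets, 10, 60),
               stats::runif(n_background_peaks, 5, 50))
    name <- c(sprintf("planted_%03d", seq_len(n_targets)),
              sprintf("bg_%04d", seq_len(n_background_peaks)))
    peaks <- peak_set(chrom = all_chrom, start = start, end = end,
                      summit = all_summit, score = score, name = name,
                      sample_id = "truth")

    n_down <- n_targets %/% 2L
    direction <- sample(rep(c("down_upon_kd", "up_upon_kd"),
                            c(n_down, n_targets - n_down)))
    planted <- data.frame(transcript_id = targets$transcript_id,
                          gene_id = targets$gene_id,
                          direction = direction,
                          planted_distance = planted_distance,
                          peak_name = name[seq_len(n_targets)],
                          stringsAsFactors = FALSE)

    dist_all <- nearest_peak_distance(annotation, peaks)
    decoy_ok <- dist_all$distance >= min_decoy_distance &
      !annotation$transcript_id %in% planted$transcript_id &
      !is_sex_chromosome(annotation$chrom)
    truth <- structure(list(planted_targets = planted,
                            decoy_pool = annotation$transcript_id[decoy_ok],
                            max_target_distance = max_target_distance,
                            min_decoy_distance = min_decoy_distance),
                       class = "scenario_truth")
    list(peaks = peaks, truth = truth)
  })
}

#' Generate two replicate peak sets from a truth set
#'
#' Each replicate retains every truth peak independently with probability
#' `concordance`, so the measured pairwise concordance (shared pairs over
#' the smaller replicate) matches the requested level in expectation.
#' Interval boundaries and summits are jittered by rounded
#' Normal(0, `jitter_sd`) noise while preserving `0 <= start < end` and
#' summit containment.
#'
#' @param truth A [peak_set()] of true binding sites.
#' @param concordance Target pairwise concordance in (0, 1].
#' @param jitter_sd Standard deviation of the boundary jitter in bp
#'   (default 10; 0 disables jitter).
#' @param seed Integer seed.
#' @return List with elements `rep1` and `rep2` ([peak_set()]s).
#' @export
generate_replicates <- function(truth, concordance, jitter_sd = 10, seed = 1L) {
  stopifnot(inherits(truth, "peak_set"))
  if (concordance <= 0 || concordance > 1) {
    stopf("concordance must be in (0, 1]")
  }
  with_seed(seed, {
    make_rep <- function(which_rep) {
      keep <- stats::runif(nrow(truth)) <= concordance
      p <- as.data.frame(truth)[keep, , drop = FALSE]
      n <- nrow(p)
      if (n && jitter_sd > 0) {
        s <- p$start + as.integer(round(stats::rnorm(n, 0, jitter_sd)))
        e <- p$end + as.integer(round(stats::rnorm(n, 0, jitter_sd)))
        s <- pmax(0L, s)
        e <- pmax(e, s + 1L)
        m <- pmin(pmax(p$summit +
                         as.integer(round(stats::rnorm(n, 0, jitter_sd))),
                       s), e - 1L)
        p$start <- s; p$end <- e; p$summit <- m
      }
      peak_set(p$chrom, p$start, p$end, p$summit, p$score, p$name,
               sample_id = paste0(attr(truth, "sample_id"), "_rep", which_rep))
    }
    list(rep1 = make_rep(1L), rep2 = make_rep(2L))
  })
}

#' Generate per-peak read counts with group structure
#'
#' Overdispersed (gamma-Poisson) read counts per peak and sample, with a
#' fold-change applied to a designated fraction of peaks in one sample
#' group, so that within-group Spearman correlation of the normalized
#' signal exceeds between-group correlation by construction.
#'
#' @param peaks A [peak_set()]; one count row per peak.
#' @param sample_groups Named character vector mapping sample id to group
#'   label (two groups expected).
#' @param library_sizes Named numeric vector of total aligned reads per
#'   sample (> 0).
#' @param group_effect Fold change applied on the affected peaks in the
#'   second group (default 4).
#' @param affected_fraction Fraction of peaks carrying the group effect
#'   (default 0.3).
#' @param dispersion Gamma-Poisson dispersion (default 0.1; values below
#'   1e-8 give pure Poisson counts).
#' @param base_mean Median per-peak expected count at 1e6 reads
#'   (default 50).
#' @param seed Integer seed.
#' @return List with `counts` (peaks x samples integer matrix),
#'   `library_sizes`, `sample_groups`, `affected` (logical per peak).
#' @export
generate_signal <- function(peaks, sample_groups, library_sizes,
                            group_effect = 4, affected_fraction = 0.3,
                            dispersion = 0.1, base_mean = 50, seed = 1L) {
  stopifnot(inherits(peaks, "peak_set"), all(library_sizes > 0),
            all(names(sample_groups) %in% names(library_sizes)))
  n <- nrow(peaks)
  samples <- names(sample_groups)
  groups <- unique(sample_groups)
  with_seed(seed, {
    base <- stats::rlnorm(n, log(base_mean), 0.6)
    affected <- seq_len(n) <= floor(affected_fraction * n)
    counts <- matrix(0L, n, length(samples),
                     dimnames = list(peaks$name, samples))
    for (s in samples) {
      fold <- ifelse(affected & sample_groups[[s]] == groups[length(groups)],
                     group_effect, 1)
      mu <- base * fold * library_sizes[[s]] / 1e6
      counts[, s] <- if (dispersion < 1e-8) {
        stats::rpois(n, mu)
      } else {
        stats::rnbinom(n, mu = mu, size = 1 / dispersion)
      }
    }
    list(counts = counts, library_sizes = library_sizes,
         sample_groups = sample_groups, affected = affected)
  })
}

#' Generate a knockdown-vs-control DE table with planted directions
#'
#' Planted direct targets receive `log2fc = sign * (effect_log2fc +
#' Normal(0, noise_sd))`, with a negative sign for targets activated by the
#' factor (down upon knockdown) and positive for repressed ones;
#' `n_null_de` additional transcripts drawn from the truth's decoy pool
#' (far from every peak) receive supra-threshold fold changes in random
#' directions, creating DE-but-not-target cases; every other transcript
#' gets Normal(0, noise_sd) noise. Adjusted p-values are a monotone
#' transform of |log2fc| (plausible, not modelled — the DE fit itself is
#' upstream of this package).
#'
#' @param annotation A [transcript_annotation()].
#' @param truth A `scenario_truth` from [generate_peak_truth()].
#' @param effect_log2fc Planted |log2fc| (> 1 so planted targets pass the
#'   2-fold filter; default 2).
#' @param noise_sd Normal noise SD on the log2 scale (default 0.2).
#' @param n_null_de Number of DE-but-untargeted decoy transcripts
#'   (default 100).
#' @param seed Integer seed.
#' @return Data frame with columns `transcript_id`, `chrom`, `log2fc`,
#'   `padj` (the [read_de_table()] contract).
#' @export
generate_de_table <- function(annotation, truth, effect_log2fc = 2,
                              noise_sd = 0.2, n_null_de = 25L, seed = 1L) {
  if (effect_log2fc <= 1) stopf("effect_log2fc must be > 1")
  stopifnot(inherits(truth, "scenario_truth"))
  if (n_null_de > length(truth$decoy_pool)) {
    stopf("n_null_de = %d exceeds the decoy pool (%d transcripts far from every peak)",
          n_null_de, length(truth$decoy_pool))
  }
  with_seed(seed, {
    n <- nrow(annotation)
    log2fc <- stats::rnorm(n, 0, noise_sd)
    planted <- truth$planted_targets
    idx <- match(planted$transcript_id, annotation$transcript_id)
    sign_ <- ifelse(planted$direction == "down_upon_kd", -1, 1)
    log2fc[idx] <- sign_ * (effect_log2fc +
                              stats::rnorm(nrow(planted), 0, noise_sd))
    null_ids <- if (n_null_de) sample(truth$decoy_pool, n_null_de) else character(0)
    nidx <- match(null_ids, annotation$transcript_id)
    log2fc[nidx] <- sample(c(-1, 1), n_null_de, replace = TRUE) *
      (effect_log2fc + stats::rnorm(n_null_de, 0, noise_sd))
    padj <- pmin(1, 2 * stats::pnorm(-abs(log2fc) / 0.5))
    data.frame(transcript_id = annotation$transcript_id,
               chrom = annotation$chrom, log2fc = log2fc, padj = padj,
               stringsAsFactors = FALSE)
  })
}

#' Generate gene sets with one planted enriched set per direction
#'
#' One planted set per regulation direction contains at least 80% (by
#' default 90%) of that direction's planted target genes plus uniform
#' filler to `set_size`; `n_decoy_sets` decoy sets are drawn uniformly from
#' the universe.
#'
#' @param truth A `scenario_truth` (may have no planted targets, in which
#'   case only decoys are produced).
#' @param universe Character vector of all gene ids.
#' @param n_decoy_sets Number of decoy sets (default 20).
#' @param set_size Members per set (default 50; must not exceed the
#'   universe).
#' @param planted_fraction Fraction of each direction's target genes placed
#'   in its planted set (default 0.9).
#' @param seed Integer seed.
#' @param path Optional path; when given the collection is also written as
#'   GMT.
#' @return List with `sets` (a [read_gmt()]-shaped list) and
#'   `planted_set_names` (named by direction).
#' @export
generate_gmt <- function(truth, universe, n_decoy_sets = 20L, set_size = 50L,
                         planted_fraction = 0.9, seed = 1L, path = NULL) {
  stopifnot(set_size <= length(universe))
  with_seed(seed, {
    sets <- list()
    planted_names <- character(0)
    planted <- truth$planted_targets
    if (!is.null(planted) && nrow(planted)) {
      for (dir in c("down_upon_kd", "up_upon_kd")) {
        genes <- unique(planted$gene_id[planted$direction == dir])
        if (!length(genes)) next
        core <- sample(genes, ceiling(planted_fraction * length(genes)))
        filler <- sample(setdiff(universe, genes),
                         max(0L, set_size - length(core)))
        nm <- if (dir == "down_upon_kd") "PLANTED_ACTIVATED" else "PLANTED_REPRESSED"
        sets[[nm]] <- list(name = nm,
                           description = sprintf("planted %s targets", dir),
                           members = c(core, filler))
        planted_names[dir] <- nm
      }
    }
    for (i in seq_len(n_decoy_sets)) {
      nm <- sprintf("DECOY_SET_%02d", i)
      sets[[nm]] <- list(name = nm, description = "uniform decoy",
                         members = sample(universe, set_size))
    }
    if (!is.null(path)) write_gmt(sets, path)
    list(sets = sets, planted_set_names = planted_names)
  })
}

#' Simulate a complete analysis scenario
#'
#' Builds every input the pipeline consumes — annotation, truth peaks,
#' two jittered replicates, per-peak counts with group structure, a DE
#' table and a gene-set collection — under one of two study designs:
#'
#' * `"separated"`: planted direct targets with peaks within
#'   `max_target_distance` of their TSS; DE decoys and background peaks at
#'   least `min_decoy_distance` from each other, so target recovery is
#'   exact and the KS enrichment is strong.
#' * `"null"`: peaks placed independently of transcripts and DE transcripts
#'   drawn uniformly, so nearest-peak distances of DE transcripts are
#'   exchangeable with the background and KS p-values are uniform.
#'
#' The default genome (two 120-Mb autosomes plus a 60-Mb chrX) is large
#' enough to honor the 100-kb separation constraints at 1,000 transcripts.
#'
#' @param scenario `"separated"` or `"null"`.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param chrom_sizes,n_transcripts,chrx_fraction Genome and annotation
#'   parameters.
#' @param n_targets,n_background_peaks,max_target_distance,min_decoy_distance
#'   Peak-planting parameters (see [generate_peak_truth()]); in the null
#'   scenario `n_targets` is the number of (non-proximal) DE transcripts.
#' @param concordance,jitter_sd Replicate-generation parameters.
#' @param effect_log2fc,noise_sd,n_null_de DE-table parameters.
#' @param n_decoy_sets,set_size Gene-set parameters.
#' @return List of class `regtarget_scenario` with components `scenario`,
#'   `seed`, `chrom_sizes`, `annotation`, `peaks`, `truth`, `replicates`,
#'   `signal`, `de_table`, `gene_sets`, `planted_set_names`.
#' @export
simulate_scenario <- function(scenario = c("separated", "null"), seed = 1L,
                              chrom_sizes = c(chr1 = 120e6, chr2 = 120e6,
                                              chrX = 60e6),
                              n_transcripts = 1000L, chrx_fraction = 0.1,
                              n_targets = 50L, n_background_peaks = 200L,
                              max_target_distance = 50000L,
                              min_decoy_distance = 100000L,
                              concordance = 0.9, jitter_sd = 10,
                              effect_log2fc = 2, noise_sd = 0.2,
                              n_null_de = 25L, n_decoy_sets = 20L,
                              set_size = 50L) {
  scenario <- match.arg(scenario)
  seed <- as.integer(seed)
  sub <- function(k) (seed %% 100000L) * 20L + k   # stage seeds, < 2^31

  annotation <- generate_annotation(n_transcripts, chrom_sizes, sub(1L),
                                    chrx_fraction = chrx_fraction)
  if (scenario == "separated") {
    pt <- generate_peak_truth(annotation, chrom_sizes,
                              n_targets = n_targets,
                              n_background_peaks = n_background_peaks,
                              max_target_distance = max_target_distance,
                              min_decoy_distance = min_decoy_distance,
                              seed = sub(2L))
    peaks <- pt$peaks
    truth <- pt$truth
    de_table <- generate_de_table(annotation, truth,
                                  effect_log2fc = effect_log2fc,
                                  noise_sd = noise_sd,
                                  n_null_de = n_null_de, seed = sub(3L))
  } else {
    peaks <- with_seed(sub(2L), {
      auto <- names(chrom_sizes)[!is_sex_chromosome(names(chrom_sizes))]
      n_pk <- n_background_peaks + n_targets
      chrom <- sample(auto, n_pk, replace = TRUE, prob = chrom_sizes[auto])
      summit <- vapply(chrom, function(ch) {
        as.integer(floor(stats::runif(1, 300, chrom_sizes[[ch]] - 300)))
      }, 0L, USE.NAMES = FALSE)
      left <- sample(100:250, n_pk, replace = TRUE)
      right <- sample(100:250, n_pk, replace = TRUE)
      peak_set(chrom, pmax(0L, summit - left), summit + right, summit,
               stats::runif(n_pk, 5, 50),
               sprintf("null_%04d", seq_len(n_pk)), sample_id = "truth")
    })
    truth <- structure(list(planted_targets =
                              data.frame(transcript_id = character(0),
                                         gene_id = character(0),
                                         direction = character(0),
                                         planted_distance = numeric(0),
                                         peak_name = character(0),
                                         stringsAsFactors = FALSE),
                            decoy_pool = character(0),
                            max_target_distance = max_target_distance,
                            min_decoy_distance = min_decoy_distance),
                       class = "scenario_truth")
    # DE status assigned independently of peak proximity
    de_table <- with_seed(sub(3L), {
      n <- nrow(annotation)
      log2fc <- stats::rnorm(n, 0, noise_sd)
      auto_idx <- which(!is_sex_chromosome(annotation$chrom))
      de_idx <- sample(auto_idx, min(n_targets, length(auto_idx)))
      log2fc[de_idx] <- sample(c(-1, 1), length(de_idx), replace = TRUE) *
        (effect_log2fc + stats::rnorm(length(de_idx), 0, noise_sd))
      data.frame(transcript_id = annotation$transcript_id,
                 chrom = annotation$chrom, log2fc = log2fc,
                 padj = pmin(1, 2 * stats::pnorm(-abs(log2fc) / 0.5)),
                 stringsAsFactors = FALSE)
    })
  }

  replicates <- generate_replicates(peaks, concordance = concordance,
                                    jitter_sd = jitter_sd, seed = sub(4L))
  sample_groups <- c(A_1 = "A", A_2 = "A", B_1 = "B", B_2 = "B")
  library_sizes <- c(A_1 = 18e6, A_2 = 22e6, B_1 = 19e6, B_2 = 21e6)
  signal <- generate_signal(peaks, sample_groups, library_sizes,
                            seed = sub(5L))
  gmt <- generate_gmt(truth, universe = unique(annotation$gene_id),
                      n_decoy_sets = n_decoy_sets, set_size = set_size,
                      seed = sub(6L))
  structure(list(scenario = scenario, seed = seed,
                 chrom_sizes = chrom_sizes, annotation = annotation,
                 peaks = peaks, truth = truth, replicates = replicates,
                 signal = signal, de_table = de_table,
                 gene_sets = gmt$sets,
                 planted_set_names = gmt$planted_set_names),
            class = "regtarget_scenario")
}

#' Write a simulated scenario to disk in standard formats
#'
#' Persists the scenario as the file set the pipeline reads: replicate
#' narrowPeak files, a TSS TSV, a DE TSV, a GMT collection, a per-peak
#' count TSV and a library-size TSV.
#'
#' @param scn A [simulate_scenario()] result.
#' @param outdir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_scenario <- function(scn, outdir) {
  stopifnot(inherits(scn, "regtarget_scenario"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    rep1 = file.path(outdir, "rep1.narrowPeak"),
    rep2 = file.path(outdir, "rep2.narrowPeak"),
    annotation = file.path(outdir, "annotation.tsv"),
    de = file.path(outdir, "de.tsv"),
    gmt = file.path(outdir, "sets.gmt"),
    counts = file.path(outdir, "counts.tsv"),
    library_sizes = file.path(outdir, "library_sizes.tsv")
  )
  write_bed(scn$replicates$rep1, paths$rep1)
  write_bed(scn$replicates$rep2, paths$rep2)
  ann <- scn$annotation
  # persist as a span table; TSS re-derives exactly on read
  ann_out <- data.frame(transcript_id = ann$transcript_id,
                        gene_id = ann$gene_id, chrom = ann$chrom,
                        strand = ann$strand,
                        tx_start = ifelse(ann$strand == "+", ann$tss,
                                          pmax(0L, ann$tss - 999L)),
                        tx_end = ifelse(ann$strand == "+", ann$tss + 1000L,
                                        ann$tss + 1L))
  utils::write.table(ann_out, paths$annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scn$de_table, paths$de, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(scn$gene_sets, paths$gmt)
  counts <- data.frame(window = rownames(scn$signal$counts),
                       scn$signal$counts, check.names = FALSE)
  utils::write.table(counts, paths$counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = names(scn$signal$library_sizes),
                                library_size = scn$signal$library_sizes),
                     paths$library_sizes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
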