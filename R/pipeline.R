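#' Integrated direct-target analysis for one sample
#'
#' The package's front door: takes two replicate peak sets, a transcript
#' annotation, a knockdown-vs-control DE table and (optionally) gene sets,
#' and runs the full binding-expression integration:
#'
#' 1. replicate concordance (a QC gate: pairs below `min_concordance` are
#'    still combined, with a warning — the threshold justifies combining
#'    replicates rather than aborting the run);
#' 2. high-confidence peaks (reproducible sites merged across replicates);
#' 3. fold-change filtering of the DE table (sex chromosomes dropped);
#' 4. nearest-peak distances for every autosomal annotated transcript —
#'    the background — and for the filtered DE transcripts;
#' 5. per-direction KS enrichment of DE distances against the background
#'    (DE transcripts are not removed from the background; at realistic DE
#'    fractions the effect on the test is negligible);
#' 6. direct-target calling at the distance cutoff, split by direction;
#' 7. per-direction hypergeometric gene-set enrichment over the autosomal
#'    gene universe.
#'
#' @param rep1,rep2 Replicate [peak_set()]s.
#' @param annotation A [transcript_annotation()].
#' @param de DE table (see [read_de_table()]).
#' @param gene_sets Optional gene sets ([read_gmt()]); enables the
#'   enrichment stage.
#' @param sample_id Sample label.
#' @param fold_threshold,drop_sex_chromosomes,padj_threshold Passed to
#'   [filter_de()].
#' @param cutoff Direct-target distance cutoff in bp (default 50,000).
#' @param min_concordance Replicate-concordance QC threshold (default 0.8).
#' @param background `"all"` (default) uses every autosomal annotated
#'   transcript as the KS background; a positive integer subsamples that
#'   many background transcripts using `seed`.
#' @param ks_method Passed to [ks_two_sample()].
#' @param seed Seed for background subsampling and any Monte-Carlo p-value.
#' @return An object of class `target_analysis`; see [print.target_analysis()],
#'   [summary.target_analysis()] and [plot.target_analysis()].
#' @examples
#' scn <- simulate_scenario("separated", seed = 1, n_transcripts = 300,
#'                          n_targets = 20, n_background_peaks = 50,
#'                          n_null_de = 20)
#' fit <- direct_target_analysis(scn$replicates$rep1, scn$replicates$rep2,
#'                               scn$annotation, scn$de_table,
#'                               gene_sets = scn$gene_sets)
#' fit
#' @export
direct_target_analysis <- function(rep1, rep2, annotation, de,
                                   gene_sets = NULL, sample_id = "sample",
                                   fold_threshold = 2,
                                   drop_sex_chromosomes = TRUE,
                                   padj_threshold = NULL,
                                   cutoff = 50000, min_concordance = 0.8,
                                   background = "all",
                                   ks_method = "auto", seed = 1L) {
  conc <- replicate_concordance(rep1, rep2)
  if (conc$concordance < min_concordance) {
    warnf("replicate concordance %.3f below the %.2f QC threshold for '%s'; replicates combined anyway",
          conc$concordance, min_concordance, sample_id)
  }
  hc <- high_confidence_peaks(rep1, rep2, sample_id = sample_id)

  filtered <- filter_de(de, fold_threshold = fold_threshold,
                        drop_sex_chromosomes = drop_sex_chromosomes,
                        padj_threshold = padj_threshold)

  bg_ann <- annotation[!is_sex_chromosome(annotation$chrom), , drop = FALSE]
  distances <- nearest_peak_distance(bg_ann, hc)
  bg_dist <- distances$distance
  if (!identical(background, "all")) {
    k <- as.integer(background)
    if (is.na(k) || k < 1L) stopf("background must be \"all\" or a positive integer")
    bg_dist <- with_seed(seed, sample(bg_dist, min(k, length(bg_dist))))
  }

  targets <- call_direct_targets(filtered, distances, cutoff = cutoff,
                                 sample_id = sample_id)
  frac <- fraction_within(targets, filtered)

  idx <- match(filtered$retained$transcript_id, distances$transcript_id)
  d_down <- distances$distance[idx[filtered$retained$direction == "down_upon_kd"]]
  d_up <- distances$distance[idx[filtered$retained$direction == "up_upon_kd"]]
  ks <- list(
    down_upon_kd = if (length(d_down)) {
      ks_two_sample(d_down, bg_dist, method = ks_method, seed = seed)
    },
    up_upon_kd = if (length(d_up)) {
      ks_two_sample(d_up, bg_dist, method = ks_method, seed = seed)
    }
  )
  ecdfs <- list(
    background = distance_ecdf(bg_dist),
    down_upon_kd = if (length(d_down) && any(is.finite(d_down))) distance_ecdf(d_down),
    up_upon_kd = if (length(d_up) && any(is.finite(d_up))) distance_ecdf(d_up)
  )

  enrichment <- NULL
  if (!is.null(gene_sets)) {
    universe <- unique(bg_ann$gene_id)
    enrichment <- list(
      activated = enrich_gene_sets(
        transcripts_to_genes(targets$activated, annotation),
        gene_sets, universe),
      repressed = enrich_gene_sets(
        transcripts_to_genes(targets$repressed, annotation),
        gene_sets, universe)
    )
  }

  structure(list(sample_id = sample_id, concordance = conc,
                 high_confidence = hc, filtered = filtered,
                 distances = distances, background_distances = bg_dist,
                 ks = ks, ecdfs = ecdfs, targets = targets,
                 fraction_within = frac, enrichment = enrichment,
                 params = list(fold_threshold = fold_threshold,
                               cutoff = cutoff,
                               min_concordance = min_concordance,
                               background = background, seed = seed)),
            class = "target_analysis")
}

#' @export
print.target_analysis <- function(x, ...) {
  cat(sprintf("Direct-target analysis: '%s'\n", x$sample_id))
  cat(sprintf("  replicate concordance:    %.3f (%d shared of %d / %d peaks)\n",
              x$concordance$concordance, x$concordance$n_shared,
              x$concordance$n_a, x$concordance$n_b))
  cat(sprintf("  high-confidence peaks:    %d\n", nrow(x$high_confidence)))
  cat(sprintf("  filtered DE transcripts:  %d (%d down, %d up upon knockdown)\n",
              nrow(x$filtered$retained), x$filtered$n_down, x$filtered$n_up))
  cat(sprintf("  direct targets (<= %s bp): %d activated, %d repressed (%.1f%% of DE)\n",
              format(x$params$cutoff, big.mark = ","),
              length(x$targets$activated), length(x$targets$repressed),
              100 * x$fraction_within))
  for (dir in c("down_upon_kd", "up_upon_kd")) {
    k <- x$ks[[dir]]
    if (!is.null(k)) {
      cat(sprintf("  KS vs background (%s): D = %.3f, p = %.3g\n",
                  dir, k$d_stat, k$p_value))
    }
  }
  if (!is.null(x$enrichment)) {
    for (side in names(x$enrichment)) {
      e <- x$enrichment[[side]]
      if (nrow(e)) {
        cat(sprintf("  top enrichment (%s): %s (k=%d/K=%d, q = %.3g)\n",
                    side, e$set_name[1L], e$k[1L], e$K[1L], e$q_value[1L]))
      }
    }
  }
  invisible(x)
}

#' Summarize a direct-target analysis
#'
#' @param object A `target_analysis`.
#' @param ... Unused.
#' @return A plain named list of the headline numbers (suitable for JSON
#'   serialization); every entry is recomputable from the object's stage
#'   outputs.
#' @export
summary.target_analysis <- function(object, ...) {
  x <- object
  ks_part <- lapply(x$ks, function(k) {
    if (is.null(k)) NULL else list(d_stat = k$d_stat, p_value = k$p_value,
                                   n1 = k$n1, n2 = k$n2, method = k$method)
  })
  top_enr <- if (is.null(x$enrichment)) NULL else {
    lapply(x$enrichment, function(e) {
      if (!nrow(e)) return(NULL)
      list(set_name = e$set_name[1L], k = e$k[1L], K = e$K[1L],
           p_value = e$p_value[1L], q_value = e$q_value[1L])
    })
  }
  list(sample_id = x$sample_id,
       concordance = x$concordance$concordance,
       n_replicate_peaks = c(x$concordance$n_a, x$concordance$n_b),
       n_high_confidence_peaks = nrow(x$high_confidence),
       n_filtered_de = nrow(x$filtered$retained),
       n_down_upon_kd = x$filtered$n_down,
       n_up_upon_kd = x$filtered$n_up,
       n_targets_activated = length(x$targets$activated),
       n_targets_repressed = length(x$targets$repressed),
       fraction_within = x$fraction_within,
       cutoff = x$params$cutoff,
       ks = ks_part,
       top_enrichment = top_enr)
}

#' Plot distance CDFs of a direct-target analysis
#'
#' Step curves of the nearest-peak distance ECDF for each DE direction
#' against the annotated background, with the direct-target cutoff marked.
#'
#' @param x A `target_analysis`.
#' @param xmax Right edge of the distance axis in bp (default 5x cutoff).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.target_analysis <- function(x, xmax = 5 * x$params$cutoff, ...) {
  cols <- c(background = "grey40", down_upon_kd = "#D55E00",
            up_upon_kd = "#0072B2")
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "distance from TSS to nearest peak summit (bp)",
                 ylab = "cumulative fraction of transcripts",
                 main = sprintf("%s: binding near DE transcripts",
                                x$sample_id), ...)
  for (nm in names(cols)) {
    cur <- x$ecdfs[[nm]]
    if (is.null(cur)) next
    graphics::lines(c(0, cur$support, xmax),
                    c(0, cur$fraction, max(cur$fraction)),
                    type = "s", col = cols[[nm]], lwd = 2)
  }
  graphics::abline(v = x$params$cutoff, lty = 2, col = "grey60")
  graphics::legend("bottomright",
                   legend = c("background", "down upon knockdown",
                              "up upon knockdown"),
                   col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a path to a YAML file holding one)
#' with fields `samples` (a list of entries with `sample_id`, `rep1`,
#' `rep2`, `de` file paths), `annotation` (TSS TSV path), optional `gmt`,
#' `outdir`, and optional `params` (`fold_threshold`, `cutoff`,
#' `min_concordance`, `background`, `seed`). All referenced paths must
#' exist and all parameters must be in range; every problem found is
#' reported in one aggregated error.
#'
#' @param cfg Named list or YAML file path.
#' @return The validated configuration with all defaults materialized.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) {
    if (!file.exists(cfg)) stopf("config file not found: %s", cfg)
    cfg <- yaml::read_yaml(cfg)
  }
  errs <- character(0)
  note <- function(fmt, ...) errs <<- c(errs, sprintf(fmt, ...))

  if (is.null(cfg$samples) || !length(cfg$samples)) {
    note("field 'samples' is missing or empty")
  } else {
    for (i in seq_along(cfg$samples)) {
      s <- cfg$samples[[i]]
      for (f in c("sample_id", "rep1", "rep2", "de")) {
        if (is.null(s[[f]])) {
          note("samples[%d]: field '%s' is missing", i, f)
        } else if (f != "sample_id" && !file.exists(s[[f]])) {
          note("samples[%d]: %s path '%s' does not exist", i, f, s[[f]])
        }
      }
    }
  }
  if (is.null(cfg$annotation)) {
    note("field 'annotation' is missing")
  } else if (!file.exists(cfg$annotation)) {
    note("annotation path '%s' does not exist", cfg$annotation)
  }
  if (!is.null(cfg$gmt) && !file.exists(cfg$gmt)) {
    note("gmt path '%s' does not exist", cfg$gmt)
  }
  p <- cfg$params
  if (is.null(p)) p <- list()
  defaults <- list(fold_threshold = 2, cutoff = 50000, min_concordance = 0.8,
                   background = "all", seed = 1L)
  for (nm in names(defaults)) if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
  if (p$fold_threshold <= 1) note("params$fold_threshold must be > 1 (got %s)",
                                  p$fold_threshold)
  if (p$cutoff < 0) note("params$cutoff must be >= 0 (got %s)", p$cutoff)
  if (p$min_concordance < 0 || p$min_concordance > 1) {
    note("params$min_concordance must be in [0, 1] (got %s)",
         p$min_concordance)
  }
  if (length(errs)) {
    stop(paste0("invalid configuration:\n  - ",
                paste(errs, collapse = "\n  - ")), call. = FALSE)
  }
  cfg$params <- p
  if (is.null(cfg$outdir)) cfg$outdir <- "regtarget_out"
  cfg
}

#' Run the full pipeline from a configuration
#'
#' Executes peaks -> DE filter -> integration -> enrichment for every
#' configured sample, persists stage outputs under
#' `outdir/<sample_id>/` (high-confidence narrowPeak, distance TSV, target
#' TSV, per-group ECDF TSVs, enrichment TSVs), intersects target sets
#' across samples, and writes a machine-readable `summary.json`. The whole
#' run is a pure function of (inputs, config, seed): identical inputs give
#' a byte-identical summary.
#'
#' @param cfg Configuration list or YAML path (see [validate_config()]).
#' @return List of class `pipeline_run` with `summary` (the summary list),
#'   `fits` (per-sample `target_analysis` objects), `summary_path`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  annotation <- read_tss_table(cfg$annotation)
  gene_sets <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else NULL
  p <- cfg$params
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  fits <- list()
  per_sample <- list()
  for (s in cfg$samples) {
    id <- s$sample_id
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stopf("stage '%s' failed for sample '%s': %s", what, id,
              conditionMessage(e))
      })
    }
    rep1 <- stage("read rep1", read_narrowpeak(s$rep1))
    rep2 <- stage("read rep2", read_narrowpeak(s$rep2))
    de <- stage("read DE table", read_de_table(s$de))
    fit <- stage("integration", direct_target_analysis(
      rep1, rep2, annotation, de, gene_sets = gene_sets, sample_id = id,
      fold_threshold = p$fold_threshold, cutoff = p$cutoff,
      min_concordance = p$min_concordance, background = p$background,
      seed = p$seed))
    fits[[id]] <- fit

    sdir <- file.path(cfg$outdir, id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    write_bed(fit$high_confidence, file.path(sdir, "high_confidence.narrowPeak"))
    utils::write.table(fit$distances, file.path(sdir, "distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fit$targets$table, file.path(sdir, "targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(fit$ecdfs)) {
      cur <- fit$ecdfs[[nm]]
      if (is.null(cur)) next
      utils::write.table(data.frame(distance = cur$support,
                                    fraction = cur$fraction),
                         file.path(sdir, sprintf("ecdf_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(fit$enrichment)) {
      for (side in names(fit$enrichment)) {
        utils::write.table(as.data.frame(fit$enrichment[[side]]),
                           file.path(sdir, sprintf("enrichment_%s.tsv", side)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    per_sample[[id]] <- summary(fit)
  }

  cross <- NULL
  if (length(fits) >= 2L) {
    ids <- names(fits)
    common <- intersect_target_sets(fits[[1L]]$targets, fits[[2L]]$targets)
    utils::write.table(common, file.path(cfg$outdir, "common_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cross <- list(samples = ids[1:2], n_common_targets = nrow(common),
                  n_direction_concordant = sum(common$direction_concordant))
  }

  summary_list <- list(schema_version = "1.0",
                       parameters = p,
                       samples = per_sample,
                       cross_sample = cross)
  summary_path <- file.path(cfg$outdir, "summary.json")
  jsonlite::write_json(summary_list, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  structure(list(summary = summary_list, fits = fits,
                 summary_path = summary_path, outdir = cfg$outdir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run: %d sample(s), outputs in '%s'\n",
              length(x$fits), x$outdir))
  for (f in x$fits) print(f)
  if (!is.null(x$summary$cross_sample)) {
    cat(sprintf("Common targets across %s: %d\n",
                paste(x$summary$cross_sample$samples, collapse = " and "),
                x$summary$cross_sample$n_common_targets))
  }
  invisible(x)
}
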