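#' Configuration for a full methylome-heterogeneity run
#'
#' Collects every tunable constant of the workflow in one validated list;
#' the configuration is serialised into the run manifest so a run can be
#' reproduced from its outputs.
#'
#' @param min_reads minimum reads per window (default 16).
#' @param window_cpgs CpGs per window (default 4).
#' @param min_read_cpgs minimum CpG calls per retained fragment (default
#'   `window_cpgs`).
#' @param n_reps null simulations per segment (default 1000).
#' @param seed global RNG seed.
#' @param p_threshold stochastic-methylation cutoff (default 0.05).
#' @param min_promoter_cpgs promoter CpG filter (default 10).
#' @param promoter_up,promoter_down detection promoter extent (1000/200 bp).
#' @param merge_gap region merge gap in bp (default 1).
#' @param hyper,hypo methylation-level class cutoffs (0.8/0.2).
#' @param profile_window,profile_span TSS profile bin width and half-span
#'   in bp (100/3000).
#' @return a validated `meth_config` list.
#' @export
meth_config <- function(min_reads = 16, window_cpgs = 4,
                        min_read_cpgs = window_cpgs, n_reps = 1000, seed = 1,
                        p_threshold = 0.05, min_promoter_cpgs = 10,
                        promoter_up = 1000, promoter_down = 200,
                        merge_gap = 1, hyper = 0.8, hypo = 0.2,
                        profile_window = 100, profile_span = 3000) {
  .assert_scalar_number(min_reads, "min_reads", lower = 1)
  .assert_scalar_number(window_cpgs, "window_cpgs", lower = 2)
  .assert_scalar_number(n_reps, "n_reps", lower = 1)
  .assert_scalar_number(p_threshold, "p_threshold", lower = 1e-12,
                        upper = 1 - 1e-12)
  .assert_scalar_number(hyper, "hyper", lower = 0, upper = 1)
  .assert_scalar_number(hypo, "hypo", lower = 0, upper = hyper)
  structure(list(
    min_reads = min_reads, window_cpgs = window_cpgs,
    min_read_cpgs = min_read_cpgs, n_reps = n_reps, seed = seed,
    p_threshold = p_threshold, min_promoter_cpgs = min_promoter_cpgs,
    promoter_up = promoter_up, promoter_down = promoter_down,
    merge_gap = merge_gap, hyper = hyper, hypo = hypo,
    profile_window = profile_window, profile_span = profile_span
  ), class = "meth_config")
}

#' Run the full methylation-heterogeneity workflow
#'
#' Chains every stage: fragment filtering, four-CpG window scanning,
#' level/entropy/weighted-entropy statistics, level-preserving null
#' simulation, cell-subset-specific region and gene detection, and — when
#' annotations are supplied — feature-class summaries and
#' expression-stratified TSS profiles. Deterministic given
#' `config$seed`.
#'
#' @param calls call tibble (`read_id`, `chrom`, `cpg_pos`, `state`) or a
#'   path to a Bismark-dialect calls file.
#' @param cpg_index CpG index tibble (`chrom`, `pos`).
#' @param genes optional gene tibble ([read_gene_table()] layout).
#' @param asm_regions optional ASM interval tibble; omitted, the ASM filter
#'   is skipped with a notice.
#' @param repeats,cgis optional repeat/CpG-island tibbles for feature
#'   summaries.
#' @param expression optional expression tibble for TSS profiles.
#' @param config a [meth_config()].
#' @param out_dir optional directory: when given, segments/stats TSVs,
#'   region BED, candidate-gene TSV, summaries and a JSON run manifest are
#'   written there.
#' @return list of class `meth_run`: `segments` (with stats and null
#'   columns), `bipolar` (a `meth_bipolar`), `feature_summary`,
#'   `tss_profile` (or `NULL`), `counts`, `config`.
#' @export
run_methylome_analysis <- function(calls, cpg_index, genes = NULL,
                                   asm_regions = NULL, repeats = NULL,
                                   cgis = NULL, expression = NULL,
                                   config = meth_config(), out_dir = NULL) {
  stopifnot(inherits(config, "meth_config"))
  if (is.character(calls)) {
    calls <- read_bismark_calls(calls, cpg_index)
  }
  counts <- c(input_calls = nrow(calls))

  kept <- filter_reads(calls, min_cpgs = config$min_read_cpgs)
  counts["calls_in_kept_fragments"] <- nrow(kept)

  segments <- scan_segments(kept, cpg_index, min_reads = config$min_reads,
                            w = config$window_cpgs)
  counts["segments"] <- nrow(segments)
  if (nrow(segments) == 0) {
    warn("no segments reached the depth threshold; outputs are empty")
  }
  stats <- if (nrow(segments) > 0) add_segment_stats(segments) else segments

  bip_input <- if (nrow(stats) > 0) stats else stats
  if (is.null(asm_regions)) {
    inform("no ASM regions supplied: allele-specific filter skipped")
  }
  bipolar <- run_bipolar_pipeline(
    bip_input, genes = genes %||% tibble(gene_id = character(),
                                         chrom = character(),
                                         strand = character(),
                                         tss = integer()),
    cpg_index = cpg_index, asm_regions = asm_regions,
    n_reps = config$n_reps, seed = config$seed,
    p_threshold = config$p_threshold, max_gap = config$merge_gap,
    up = config$promoter_up, down = config$promoter_down,
    min_promoter_cpgs = config$min_promoter_cpgs
  )
  counts <- c(counts, bipolar$counts[-1])

  feature_summary <- NULL
  if (nrow(stats) > 0 && (!is.null(genes) || !is.null(repeats) ||
                          !is.null(cgis))) {
    feats <- build_features(genes = genes, repeats = repeats, cgis = cgis)
    feature_summary <- summarise_features(assign_segments(stats, feats))
  }
  profile <- NULL
  if (nrow(stats) > 0 && !is.null(expression) && !is.null(genes)) {
    profile <- tss_profile(stats, genes, expression,
                           window = config$profile_window,
                           span = config$profile_span)
  }

  run <- structure(list(segments = stats, bipolar = bipolar,
                        feature_summary = feature_summary,
                        tss_profile = profile, counts = counts,
                        config = config),
                   class = "meth_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

#' Write the outputs of a run to a directory
#'
#' Emits `segments.tsv` (per-segment stats and null columns),
#' `bipolar_regions.bed` (BED6; score is `-10 log10(min_p + 1/n_reps)`),
#' `candidate_genes.tsv`, `feature_summary.tsv` and `tss_profile.tsv` when
#' present, and `manifest.json` (configuration and per-stage record
#' counts).
#'
#' @param run a `meth_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(run, out_dir) {
  stopifnot(inherits(run, "meth_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$segments, file.path(out_dir, "segments.tsv"))
  reg <- run$bipolar$regions
  score <- -10 * log10(pmax(dplyr::coalesce(reg$min_p, 1), 0) +
                         1 / run$config$n_reps)
  write_bed(tibble(chrom = reg$chrom, start = reg$start, end = reg$end,
                   name = sprintf("region%04d", seq_len(nrow(reg))),
                   score = round(score, 3), strand = "*"),
            file.path(out_dir, "bipolar_regions.bed"))
  genes <- run$bipolar$genes
  readr::write_tsv(
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           promoter_start = genes$promoter_start,
           promoter_end = genes$promoter_end,
           n_promoter_cpgs = genes$n_promoter_cpgs %||% NA_integer_,
           n_regions = genes$n_regions, min_p = genes$min_p),
    file.path(out_dir, "candidate_genes.tsv"))
  if (!is.null(run$feature_summary)) {
    readr::write_tsv(run$feature_summary,
                     file.path(out_dir, "feature_summary.tsv"))
  }
  if (!is.null(run$tss_profile)) {
    readr::write_tsv(as_tibble(run$tss_profile),
                     file.path(out_dir, "tss_profile.tsv"))
  }
  manifest <- list(
    package = "methentropy",
    version = as.character(utils::packageVersion("methentropy")),
    config = unclass(run$config),
    counts = as.list(run$counts)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.meth_run <- function(x, ...) {
  cat("Methylome heterogeneity run\n")
  for (nm in names(x$counts)) cat(sprintf("  %-25s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Candidate genes of a detection result as a tibble
#'
#' @param x a `meth_bipolar` object.
#' @param ... unused.
#' @return one row per candidate gene.
#' @method tidy meth_bipolar
#' @export
tidy.meth_bipolar <- function(x, ...) {
  g <- x$genes
  tibble(gene_id = g$gene_id, chrom = g$chrom,
         promoter_start = g$promoter_start, promoter_end = g$promoter_end,
         n_promoter_cpgs = g$n_promoter_cpgs %||%
           rep(NA_integer_, nrow(g)),
         n_regions = g$n_regions, min_p = g$min_p)
}

#' One-row summary of a detection result
#'
#' @inheritParams tidy.meth_bipolar
#' @return single-row tibble of per-step record counts.
#' @method glance meth_bipolar
#' @export
glance.meth_bipolar <- function(x, ...) {
  as_tibble(as.list(x$counts))
}

#' @rdname tidy.meth_bipolar
#' @method tidy meth_run
#' @export
tidy.meth_run <- function(x, ...) tidy(x$bipolar)

#' @rdname glance.meth_bipolar
#' @method glance meth_run
#' @export
glance.meth_run <- function(x, ...) {
  out <- as_tibble(as.list(x$counts))
  if (nrow(x$segments) > 0) {
    out$mean_level <- mean(x$segments$level)
    out$mean_entropy <- mean(x$segments$entropy)
  }
  out
}
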