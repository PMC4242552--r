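# tibbles with chrom/start/end (0-based half-open) <-> GRanges (1-based closed)
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# logical: does each row of x overlap any row of y by >= 1 bp?
.overlaps_any <- function(x, y) {
  if (nrow(y) == 0 || nrow(x) == 0) return(rep(FALSE, nrow(x)))
  IRanges::overlapsAny(.as_granges(x), .as_granges(y), minoverlap = 1L)
}

#' Keep segments carrying both fully methylated and fully unmethylated reads
#'
#' The first step of the cell-subset-specific detection: a bipolar segment
#' has at least one read with every CpG methylated and at least one with
#' every CpG unmethylated — the read-level signature of two epigenetically
#' distinct cell subsets (or two alleles) at one locus.
#'
#' @param segments segment tibble with pattern counts.
#' @return the bipolar subset of `segments`.
#' @export
select_bipolar <- function(segments) {
  w <- segment_width(segments)
  all_m <- paste0("n", 2^w - 1)
  filter(segments, .data$n0 >= 1, .data[[all_m]] >= 1)
}

#' Remove segments overlapping known allele-specific-methylation regions
#'
#' Allelic methylation (e.g. imprinting) produces the same bipolar read
#' signature as cell-subset-specific methylation; segments whose genomic
#' span overlaps a supplied ASM region by at least 1 bp are removed.
#'
#' @param segments segment tibble.
#' @param asm_regions tibble of ASM intervals (`chrom`, `start`, `end`,
#'   0-based half-open), e.g. from [read_bed()]; `NULL` or empty keeps all
#'   segments.
#' @return the filtered segment tibble.
#' @export
filter_asm <- function(segments, asm_regions = NULL) {
  if (is.null(asm_regions) || nrow(asm_regions) == 0) return(segments)
  segments[!.overlaps_any(segments, asm_regions), ]
}

#' Remove segments consistent with stochastic methylation
#'
#' Keeps segments whose level-preserving null p-value (see
#' [weighted_entropy_pvalue()]) is at most `p_threshold`; segments with
#' `p > p_threshold` are the ones a random arrangement explains.
#'
#' @param segments segment tibble carrying a `p_value` column.
#' @param p_threshold removal threshold (default 0.05; `p == p_threshold`
#'   is retained).
#' @return the filtered segment tibble.
#' @export
filter_stochastic <- function(segments, p_threshold = 0.05) {
  if (!"p_value" %in% names(segments)) {
    abort("`segments` lacks a p_value column; run add_null_stats() first")
  }
  if (anyNA(segments$p_value)) abort("missing p-values in `segments`")
  filter(segments, .data$p_value <= p_threshold)
}

#' Merge nearby segments into regions
#'
#' Transitively merges segment spans that overlap or are separated by at
#' most `max_gap` bp; resulting regions are disjoint with pairwise gaps
#' greater than `max_gap`. Idempotent and independent of input order.
#'
#' @param segments segment tibble (a `p_value` column, if present, is
#'   summarised as each region's `min_p`).
#' @param max_gap largest merged gap in bp (default 1).
#' @return tibble of regions: `chrom`, `start`, `end`, `n_segments`,
#'   `min_p`, and `segment_keys` (list-column of member segment keys).
#' @export
merge_regions <- function(segments, max_gap = 1) {
  .assert_scalar_number(max_gap, "max_gap", lower = 0)
  if (nrow(segments) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_segments = integer(), min_p = double(),
                  segment_keys = list()))
  }
  has_key <- all(paste0("cpg", 1:2) %in% names(segments))
  df <- segments |>
    mutate(
      .key = if (has_key) .segment_key(segments) else
        paste0(.data$chrom, ":", .data$start, "-", .data$end),
      .p = if ("p_value" %in% names(segments)) .data$p_value else NA_real_
    ) |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    mutate(.grp = cumsum(
      is.na(lag(.data$start)) |
        .data$start > cummax(dplyr::coalesce(lag(.data$end), .data$end[1])) + max_gap
    )) |>
    ungroup()
  df |>
    group_by(.data$chrom, .data$.grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_segments = n(), min_p = suppressWarnings(min(.data$.p)),
              segment_keys = list(.data$.key), .groups = "drop") |>
    mutate(min_p = if_else(is.finite(.data$min_p), .data$min_p, NA_real_)) |>
    select(-".grp") |>
    arrange(.data$chrom, .data$start)
}

# promoter interval(s) of each transcript under the detection definition:
# `up` bp upstream through `down` bp downstream of the strand-resolved TSS
.tss_promoters <- function(genes, up, down) {
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmax(0L, as.integer(if_else(genes$strand == "-",
                                        genes$tss - down, genes$tss - up))),
    end = as.integer(if_else(genes$strand == "-",
                             genes$tss + up, genes$tss + down))
  )
}

# merge intervals within each gene_id; returns one row per merged interval
.merge_by_gene <- function(iv) {
  iv |>
    arrange(.data$gene_id, .data$chrom, .data$start) |>
    group_by(.data$gene_id, .data$chrom) |>
    mutate(.grp = cumsum(
      is.na(lag(.data$start)) |
        .data$start > cummax(dplyr::coalesce(lag(.data$end), .data$end[1]))
    )) |>
    group_by(.data$gene_id, .data$chrom, .data$.grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select(-".grp")
}

#' Associate merged bipolar regions with gene promoters
#'
#' The promoter of a transcript is the interval from `up` bp upstream to
#' `down` bp downstream of its TSS (minus-strand promoters are reflected:
#' upstream is genomically rightward). Transcripts sharing a gene id
#' contribute the union of their promoters. A gene is a candidate iff at
#' least one region overlaps its promoter union by >= 1 bp; regions falling
#' in one promoter are merged regardless of gap.
#'
#' @param regions region tibble from [merge_regions()].
#' @param genes gene tibble from [read_gene_table()] (needs `gene_id`,
#'   `chrom`, `strand`, `tss`).
#' @param up,down promoter extent around the TSS in bp (defaults 1000/200).
#' @return candidate-gene tibble: `gene_id`, `chrom`, `promoter_start`,
#'   `promoter_end` (span of the promoter union), `n_regions`, `min_p`,
#'   plus list-columns `promoter_intervals` and `regions`.
#' @export
associate_promoters <- function(regions, genes, up = 1000, down = 200) {
  .assert_scalar_number(up, "up", lower = 0)
  .assert_scalar_number(down, "down", lower = 0)
  empty <- tibble(gene_id = character(), chrom = character(),
                  promoter_start = integer(), promoter_end = integer(),
                  n_regions = integer(), min_p = double(),
                  promoter_intervals = list(), regions = list())
  n_missing <- sum(is.na(genes$chrom) | is.na(genes$tss))
  if (n_missing > 0) {
    warn(sprintf("skipping %d gene record(s) without coordinates", n_missing))
    genes <- filter(genes, !is.na(.data$chrom), !is.na(.data$tss))
  }
  if (nrow(regions) == 0 || nrow(genes) == 0) return(empty)
  prom <- .merge_by_gene(.tss_promoters(genes, up, down))
  reg_tbl <- regions

  hits <- GenomicRanges::findOverlaps(.as_granges(prom), .as_granges(reg_tbl),
                                      minoverlap = 1L)
  if (length(hits) == 0) return(empty)
  pairs <- tibble(
    gene_id = prom$gene_id[S4Vectors::queryHits(hits)],
    region_i = S4Vectors::subjectHits(hits)
  ) |> distinct()

  pairs |>
    group_by(.data$gene_id) |>
    summarise(
      regions = list(merge_regions(reg_tbl[.data$region_i, ], max_gap = Inf)),
      min_p = suppressWarnings(min(reg_tbl$min_p[.data$region_i], na.rm = TRUE)),
      n_regions = length(unique(.data$region_i)),
      .groups = "drop"
    ) |>
    mutate(min_p = if_else(is.finite(.data$min_p), .data$min_p, NA_real_)) |>
    inner_join(
      prom |>
        group_by(.data$gene_id) |>
        summarise(promoter_intervals = {
                    ch <- .data$chrom; s <- .data$start; e <- .data$end
                    list(tibble(chrom = ch, start = s, end = e))
                  },
                  promoter_start = min(.data$start),
                  promoter_end = max(.data$end),
                  chrom = first(.data$chrom),
                  .groups = "drop"),
      by = "gene_id"
    ) |>
    select("gene_id", "chrom", "promoter_start", "promoter_end",
           "n_regions", "min_p", "promoter_intervals", "regions") |>
    arrange(.data$gene_id)
}

#' Drop candidate genes with CpG-poor promoters
#'
#' Counts indexed CpG units inside each candidate's promoter union and
#' keeps genes with at least `min_cpgs` (default 10) — promoters too
#' CpG-poor for the four-CpG segmentation to interrogate reliably are
#' removed.
#'
#' @param candidates candidate tibble from [associate_promoters()].
#' @param cpg_index CpG index tibble (`chrom`, `pos`).
#' @param min_cpgs minimum promoter CpG count (default 10; boundary kept).
#' @return filtered candidates with an `n_promoter_cpgs` column.
#' @export
filter_low_cpg <- function(candidates, cpg_index, min_cpgs = 10) {
  .assert_scalar_number(min_cpgs, "min_cpgs", lower = 0)
  if (nrow(candidates) == 0) {
    candidates$n_promoter_cpgs <- integer()
    return(candidates)
  }
  idx <- as_tibble(cpg_index)
  n_cpgs <- purrr::map_int(candidates$promoter_intervals, function(iv) {
    sum(purrr::pmap_int(iv, function(chrom, start, end) {
      sum(idx$chrom == chrom & idx$pos >= start & idx$pos < end)
    }))
  })
  candidates$n_promoter_cpgs <- n_cpgs
  filter(candidates, .data$n_promoter_cpgs >= min_cpgs) |>
    relocate("n_promoter_cpgs", .after = "promoter_end")
}

#' Run the cell-subset-specific methylation detection pipeline
#'
#' Executes, in order: bipolar-read preselection; level-preserving null
#' p-values (transition-weighted entropy); removal of allele-specific
#' methylation overlaps and of stochastic segments (`p > p_threshold`);
#' merging of surviving segments into regions (gap <= `max_gap`); promoter
#' association; and the promoter CpG-count filter.
#'
#' @param segments segment tibble from [scan_segments()] (stats columns are
#'   added if absent).
#' @param genes gene tibble from [read_gene_table()].
#' @param cpg_index CpG index tibble.
#' @param asm_regions optional ASM interval tibble; `NULL` skips the ASM
#'   filter.
#' @param n_reps,seed,p_threshold null-simulation settings (defaults 1000,
#'   1, 0.05).
#' @param max_gap region merge gap in bp (default 1).
#' @param up,down promoter extent around the TSS (defaults 1000/200).
#' @param min_promoter_cpgs promoter CpG-count threshold (default 10).
#' @return an object of class `meth_bipolar`: a list with `regions`,
#'   `genes` (final candidates), and `counts` (records surviving each
#'   step).
#' @export
run_bipolar_pipeline <- function(segments, genes, cpg_index,
                                 asm_regions = NULL, n_reps = 1000, seed = 1,
                                 p_threshold = 0.05, max_gap = 1,
                                 up = 1000, down = 200,
                                 min_promoter_cpgs = 10) {
  if (!"wentropy" %in% names(segments)) segments <- add_segment_stats(segments)
  counts <- c(input_segments = nrow(segments))

  bip <- select_bipolar(segments)
  counts["bipolar_segments"] <- nrow(bip)

  if (nrow(bip) > 0 && !"p_value" %in% names(bip)) {
    bip <- add_null_stats(bip, n_reps = n_reps, seed = seed)
  }
  kept <- filter_asm(bip, asm_regions)
  counts["after_asm_filter"] <- nrow(kept)
  kept <- if (nrow(kept) > 0) filter_stochastic(kept, p_threshold) else kept
  counts["after_stochastic_filter"] <- nrow(kept)

  regions <- merge_regions(kept, max_gap = max_gap)
  counts["merged_regions"] <- nrow(regions)

  cand <- associate_promoters(regions, genes, up = up, down = down)
  counts["promoter_genes"] <- nrow(cand)
  cand <- filter_low_cpg(cand, cpg_index, min_cpgs = min_promoter_cpgs)
  counts["candidate_genes"] <- nrow(cand)

  structure(list(regions = regions, genes = cand, counts = counts,
                 config = list(n_reps = n_reps, seed = seed,
                               p_threshold = p_threshold, max_gap = max_gap,
                               up = up, down = down,
                               min_promoter_cpgs = min_promoter_cpgs)),
            class = "meth_bipolar")
}

#' @export
print.meth_bipolar <- function(x, ...) {
  cat("Cell-subset-specific methylation detection\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-25s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}
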