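# merge plain intervals (chrom/start/end), no grouping key
.merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv[c("chrom", "start", "end")])
  iv |>
    select("chrom", "start", "end") |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(.grp = cumsum(
      is.na(lag(.data$start)) |
        .data$start > cummax(dplyr::coalesce(lag(.data$end), .data$end[1]))
    )) |>
    group_by(.data$chrom, .data$.grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select("chrom", "start", "end")
}

# subtract intervals in y from intervals in x (both tibbles, 0-based
# half-open); delegates to GenomicRanges::setdiff
.subtract_intervals <- function(x, y) {
  if (nrow(x) == 0) return(x[c("chrom", "start", "end")])
  if (nrow(y) == 0) return(.merge_intervals(x))
  gr <- GenomicRanges::setdiff(.as_granges(x), .as_granges(y))
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

.flank_intervals <- function(iv, inner, outer) {
  # bands [start-outer, start-inner) and [end+inner, end+outer)
  bind_rows(
    tibble(chrom = iv$chrom, start = pmax(0L, iv$start - as.integer(outer)),
           end = pmax(0L, iv$start - as.integer(inner))),
    tibble(chrom = iv$chrom, start = iv$end + as.integer(inner),
           end = iv$end + as.integer(outer))
  ) |> filter(.data$end > .data$start)
}

#' Build the genomic feature classes used for stratified summaries
#'
#' From a gene table, a repeat table and a CpG-island table, derives the
#' interval classes: `promoter_1kb` (1 kb upstream of each TSS,
#' strand-aware), `utr5`, `coding_exon`, `intron`, `utr3`, one class per
#' repeat family (e.g. LINE, SINE, LTR, Satellite, Simple_repeat), `cgi`,
#' `cgi_shore` (2 kb flanks minus islands), `cgi_shelf` (2-4 kb flanks
#' minus islands and shores), and the promoter split `promoter_cgi` /
#' `promoter_noncgi` (a promoter overlapping a CpG island by >= 1 bp is a
#' CGI promoter). Overlapping islands are merged before shores and shelves
#' are derived, and shores/shelves are clipped at neighbouring islands.
#'
#' @param genes gene tibble from [read_gene_table()]; `NULL` skips
#'   gene-derived classes.
#' @param repeats tibble with `chrom`, `start`, `end`, `class`; `NULL`
#'   skips repeats.
#' @param cgis tibble with `chrom`, `start`, `end`; `NULL` skips
#'   island-derived classes.
#' @param shore_width,shelf_width flank widths in bp (defaults 2000 each,
#'   shelves reaching 4 kb from the island).
#' @return feature tibble: `chrom`, `start`, `end`, `strand`, `class`.
#' @export
build_features <- function(genes = NULL, repeats = NULL, cgis = NULL,
                           shore_width = 2000, shelf_width = 2000) {
  out <- list()
  if (!is.null(genes) && nrow(genes) > 0) {
    minus <- genes$strand == "-"
    prom <- tibble(
      chrom = genes$chrom,
      start = pmax(0L, as.integer(if_else(minus, genes$tss,
                                          genes$tss - 1000L))),
      end = as.integer(if_else(minus, genes$tss + 1000L, genes$tss)),
      strand = genes$strand, class = "promoter_1kb"
    ) |> filter(.data$end > .data$start)
    out$promoter <- prom

    per_tx <- purrr::pmap_dfr(
      genes[c("chrom", "strand", "txStart", "txEnd", "cdsStart", "cdsEnd",
              "exon_starts", "exon_ends")],
      function(chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
               exon_starts, exon_ends) {
        if (length(exon_starts) == 0) {
          exon_starts <- txStart
          exon_ends <- txEnd
        }
        ex <- tibble(chrom = chrom, start = exon_starts, end = exon_ends,
                     strand = strand)
        introns <- if (nrow(ex) > 1) {
          tibble(chrom = chrom, start = head(exon_ends, -1),
                 end = tail(exon_starts, -1), strand = strand,
                 class = "intron")
        } else NULL
        coding <- ex |>
          mutate(start = pmax(.data$start, cdsStart),
                 end = pmin(.data$end, cdsEnd), class = "coding_exon") |>
          filter(.data$end > .data$start)
        left <- ex |>
          mutate(end = pmin(.data$end, cdsStart),
                 class = if_else(strand == "-", "utr3", "utr5")) |>
          filter(.data$end > .data$start)
        right <- ex |>
          mutate(start = pmax(.data$start, cdsEnd),
                 class = if_else(strand == "-", "utr5", "utr3")) |>
          filter(.data$end > .data$start)
        bind_rows(coding, left, right, introns)
      })
    out$gene_parts <- per_tx
  }
  if (!is.null(repeats) && nrow(repeats) > 0) {
    out$repeats <- tibble(chrom = repeats$chrom, start = repeats$start,
                          end = repeats$end, strand = "*",
                          class = repeats$class)
  }
  if (!is.null(cgis) && nrow(cgis) > 0) {
    cgi <- .merge_intervals(as_tibble(cgis))
    shores_raw <- .flank_intervals(cgi, 0, shore_width)
    shores <- .subtract_intervals(shores_raw, cgi)
    shelves_raw <- .flank_intervals(cgi, shore_width,
                                    shore_width + shelf_width)
    shelves <- .subtract_intervals(shelves_raw, bind_rows(cgi, shores))
    out$cgi <- bind_rows(
      mutate(cgi, strand = "*", class = "cgi"),
      mutate(shores, strand = "*", class = "cgi_shore"),
      mutate(shelves, strand = "*", class = "cgi_shelf")
    )
    if (!is.null(out$promoter)) {
      is_cgi_prom <- .overlaps_any(out$promoter, cgi)
      out$prom_split <- out$promoter |>
        mutate(class = if_else(is_cgi_prom, "promoter_cgi",
                               "promoter_noncgi"))
    }
  }
  feats <- bind_rows(out)
  if (nrow(feats) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), class = character()))
  }
  feats$strand <- feats$strand %||% "*"
  feats |>
    mutate(strand = dplyr::coalesce(.data$strand, "*")) |>
    select("chrom", "start", "end", "strand", "class") |>
    arrange(.data$class, .data$chrom, .data$start)
}

#' Assign segments to every feature class they overlap
#'
#' A segment belongs to each class its genomic span overlaps by at least
#' 1 bp; classes are not mutually exclusive, so a segment can appear under
#' several classes (once per class — duplicates from overlapping
#' transcripts are collapsed). Segments overlapping no feature are labelled
#' `intergenic`.
#'
#' @param segments segment tibble (stats columns are carried along).
#' @param features feature tibble from [build_features()].
#' @return long tibble: one row per (segment, class), with all segment
#'   columns plus `feature_class`.
#' @export
assign_segments <- function(segments, features) {
  if (nrow(segments) == 0) {
    segments$feature_class <- character()
    return(segments)
  }
  if (nrow(features) == 0) {
    return(mutate(segments, feature_class = "intergenic"))
  }
  hits <- GenomicRanges::findOverlaps(.as_granges(segments),
                                      .as_granges(features), minoverlap = 1L)
  assigned <- tibble(
    seg_i = S4Vectors::queryHits(hits),
    feature_class = features$class[S4Vectors::subjectHits(hits)]
  ) |> distinct()
  unhit <- setdiff(seq_len(nrow(segments)), unique(assigned$seg_i))
  assigned <- bind_rows(assigned,
                        tibble(seg_i = unhit, feature_class = "intergenic"))
  out <- segments[assigned$seg_i, ]
  out$feature_class <- assigned$feature_class
  arrange(out, .data$feature_class, .data$chrom, .data$start)
}

#' Summarise level and entropy per feature class
#'
#' @param assigned output of [assign_segments()] carrying `level` and
#'   `entropy` columns.
#' @return tibble per class: `feature_class`, `n_segments`, median and
#'   quartiles of entropy and level.
#' @export
summarise_features <- function(assigned) {
  assigned |>
    group_by(.data$feature_class) |>
    summarise(
      n_segments = n(),
      entropy_q1 = quantile(.data$entropy, 0.25),
      entropy_median = median(.data$entropy),
      entropy_q3 = quantile(.data$entropy, 0.75),
      level_q1 = quantile(.data$level, 0.25),
      level_median = median(.data$level),
      level_q3 = quantile(.data$level, 0.75),
      .groups = "drop"
    )
}

#' Classify a methylation level as hyper-, hypo- or intermediate
#'
#' Hypermethylated above `hyper` (strict), hypomethylated below `hypo`
#' (strict), intermediate otherwise. With the defaults, a level of exactly
#' 0.2 or 0.8 is intermediate; completely unmethylated segments (level 0)
#' form the extreme of the hypomethylated class.
#'
#' @param level numeric vector of methylation levels in `[0, 1]`.
#' @param hyper,hypo thresholds (defaults 0.8 and 0.2).
#' @return factor with levels `hypomethylated`, `intermediate`,
#'   `hypermethylated`.
#' @export
classify_level <- function(level, hyper = 0.8, hypo = 0.2) {
  factor(
    if_else(level > hyper, "hypermethylated",
            if_else(level < hypo, "hypomethylated", "intermediate")),
    levels = c("hypomethylated", "intermediate", "hypermethylated")
  )
}

#' Intersect segment sets across samples
#'
#' Segments are keyed by chromosome and their CpG positions; the common
#' set contains keys present in every sample, with each sample's `level`
#' and `entropy` side by side (suffixed with the sample name).
#'
#' @param stats_list named list of per-sample segment-stat tibbles.
#' @return wide tibble: `chrom`, `cpg1..cpgw`, then `level_<sample>` and
#'   `entropy_<sample>` for each sample.
#' @export
common_segments <- function(stats_list) {
  if (is.null(names(stats_list)) || any(!nzchar(names(stats_list)))) {
    abort("`stats_list` must be a named list of sample stats")
  }
  w <- segment_width(stats_list[[1]])
  keys <- c("chrom", paste0("cpg", seq_len(w)))
  tabs <- purrr::imap(stats_list, function(df, nm) {
    df <- select(df, dplyr::all_of(c(keys, "level", "entropy")))
    names(df)[names(df) == "level"] <- paste0("level_", nm)
    names(df)[names(df) == "entropy"] <- paste0("entropy_", nm)
    df
  })
  purrr::reduce(tabs, inner_join, by = keys)
}

#' Pairwise Pearson correlation of level or entropy across samples
#'
#' @param common wide tibble from [common_segments()].
#' @param metric `"level"` or `"entropy"`.
#' @return tibble `sample1`, `sample2`, `metric`, `r`.
#' @export
pairwise_correlation <- function(common, metric = c("level", "entropy")) {
  metric <- match.arg(metric)
  cols <- grep(paste0("^", metric, "_"), names(common), value = TRUE)
  samples <- sub(paste0("^", metric, "_"), "", cols)
  if (length(cols) < 2) abort("need at least two samples to correlate")
  if (nrow(common) < 2) abort("need at least two common segments to correlate")
  pairs <- utils::combn(seq_along(cols), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tibble(sample1 = samples[i1], sample2 = samples[i2], metric = metric,
           r = cor(common[[cols[i1]]], common[[cols[i2]]],
                   method = "pearson"))
  })
}

#' Assign expression quintiles
#'
#' Genes are split into five equally sized groups by expression (sizes
#' differing by at most one); quintile 5 is the highest-expressed fifth,
#' zero-expression genes fall in quintile 1, and ties are broken by stable
#' input order.
#'
#' @param expression tibble `gene_id`, `value` from [read_expression()].
#' @param n_groups number of groups (default 5).
#' @return the tibble with a `quintile` column added.
#' @export
assign_quintiles <- function(expression, n_groups = 5) {
  r <- rank(expression$value, ties.method = "first")
  expression$quintile <- as.integer(ceiling(r * n_groups / length(r)))
  expression
}

#' Mean level and entropy around TSSs, stratified by expression
#'
#' For each expression quintile and each `window`-bp bin of position
#' relative to the TSS (strand-oriented, upstream negative), averages the
#' `level` and `entropy` of segments whose midpoint falls in the bin.
#' Empty bins are absent from the output (missing, not zero).
#'
#' @param stats segment tibble with `level` and `entropy`.
#' @param genes gene tibble from [read_gene_table()].
#' @param expression tibble `gene_id`, `value` (quintiles are assigned if
#'   absent); genes without expression are excluded with a message.
#' @param window bin width in bp (default 100).
#' @param span half-width of the profiled region in bp (default 3000).
#' @return a `meth_tss_profile` tibble: `quintile`, `bin_start` (bin is
#'   `[bin_start, bin_start + window)` relative to TSS), `mean_level`,
#'   `mean_entropy`, `n_segments`.
#' @export
tss_profile <- function(stats, genes, expression, window = 100, span = 3000) {
  .assert_scalar_number(window, "window", lower = 1)
  .assert_scalar_number(span, "span", lower = window)
  if (!"quintile" %in% names(expression)) {
    expression <- assign_quintiles(expression)
  }
  g <- inner_join(genes, select(expression, "gene_id", "quintile"),
                  by = "gene_id")
  n_missing <- length(setdiff(genes$gene_id, expression$gene_id))
  if (n_missing > 0) {
    inform(sprintf("%d gene(s) without expression excluded from the profile",
                   n_missing))
  }
  if (nrow(g) == 0 || nrow(stats) == 0) {
    return(structure(tibble(quintile = integer(), bin_start = integer(),
                            mean_level = double(), mean_entropy = double(),
                            n_segments = integer()),
                     class = c("meth_tss_profile", "tbl_df", "tbl", "data.frame"),
                     window = window, span = span))
  }
  mid <- (stats$start + stats$end) %/% 2L
  seg <- tibble(chrom = stats$chrom, mid = mid, level = stats$level,
                entropy = stats$entropy)
  prof <- purrr::pmap_dfr(g[c("chrom", "tss", "strand", "quintile")],
                          function(chrom, tss, strand, quintile) {
    s <- seg[seg$chrom == chrom, ]
    rel <- if (strand == "-") tss - s$mid else s$mid - tss
    keep <- rel >= -span & rel < span
    if (!any(keep)) return(NULL)
    tibble(quintile = quintile,
           bin_start = as.integer(floor(rel[keep] / window) * window),
           level = s$level[keep], entropy = s$entropy[keep])
  })
  out <- prof |>
    group_by(.data$quintile, .data$bin_start) |>
    summarise(mean_level = mean(.data$level),
              mean_entropy = mean(.data$entropy),
              n_segments = n(), .groups = "drop") |>
    arrange(.data$quintile, .data$bin_start)
  structure(out, class = c("meth_tss_profile", class(out)),
            window = window, span = span)
}

#' Per-gene mean level and entropy around the TSS
#'
#' Averages segment `level` and `entropy` over segments overlapping (by at
#' least 1 bp) the window from `up` bp upstream to `down` bp downstream of
#' each transcript's TSS; transcripts sharing a gene id are pooled. Genes
#' without overlapping segments are absent from the output.
#'
#' @inheritParams tss_profile
#' @param up,down window extent around the TSS in bp (defaults 1000/200).
#' @return tibble `gene_id`, `n_segments`, `mean_level`, `mean_entropy`.
#' @export
gene_body_stats <- function(stats, genes, up = 1000, down = 200) {
  prom <- .merge_by_gene(.tss_promoters(genes, up, down))
  if (nrow(prom) == 0 || nrow(stats) == 0) {
    return(tibble(gene_id = character(), n_segments = integer(),
                  mean_level = double(), mean_entropy = double()))
  }
  hits <- GenomicRanges::findOverlaps(.as_granges(prom), .as_granges(stats),
                                      minoverlap = 1L)
  tibble(
    gene_id = prom$gene_id[S4Vectors::queryHits(hits)],
    seg_i = S4Vectors::subjectHits(hits)
  ) |>
    distinct() |>
    group_by(.data$gene_id) |>
    summarise(n_segments = n(),
              mean_level = mean(stats$level[.data$seg_i]),
              mean_entropy = mean(stats$entropy[.data$seg_i]),
              .groups = "drop")
}
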