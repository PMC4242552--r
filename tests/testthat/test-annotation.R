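test_that("CGI shores and shelves flank the island without overlapping it", {
  cgis <- tibble::tibble(chrom = "chr1", start = 5000L, end = 6000L)
  feats <- build_features(cgis = cgis)
  shores <- feats[feats$class == "cgi_shore", ]
  shelves <- feats[feats$class == "cgi_shelf", ]
  expect_equal(shores[c("start", "end")],
               tibble::tibble(start = c(3000L, 6000L), end = c(5000L, 8000L)))
  expect_equal(shelves[c("start", "end")],
               tibble::tibble(start = c(1000L, 8000L), end = c(3000L, 10000L)))

  # crowded islands: derived bands never overlap an island or each other
  cgis2 <- tibble::tibble(chrom = "chr1", start = c(1000L, 4000L, 5500L),
                          end = c(2000L, 5000L, 7000L))
  f2 <- build_features(cgis = cgis2)
  gr <- function(cl) f2[f2$class == cl, c("chrom", "start", "end")]
  ov <- function(a, b) {
    any(outer(seq_len(nrow(a)), seq_len(nrow(b)), Vectorize(function(i, j) {
      a$start[i] < b$end[j] & b$start[j] < a$end[i]
    })))
  }
  expect_false(ov(gr("cgi_shore"), gr("cgi")))
  expect_false(ov(gr("cgi_shelf"), gr("cgi")))
  expect_false(ov(gr("cgi_shelf"), gr("cgi_shore")))
})

test_that("promoters, UTRs, exons and introns derive from the gene model", {
  genes <- tibble::tibble(
    name = "NM_1", gene_id = "G1", chrom = "chr1", strand = "+",
    txStart = 10000L, txEnd = 12000L, cdsStart = 10300L, cdsEnd = 11700L,
    exon_starts = list(c(10000L, 11000L)), exon_ends = list(c(10500L, 12000L)),
    tss = 10000L
  )
  feats <- build_features(genes = genes)
  prom <- feats[feats$class == "promoter_1kb", ]
  expect_equal(c(prom$start, prom$end), c(9000L, 10000L))
  expect_equal(feats[feats$class == "utr5", ]$end, 10300L)
  expect_equal(feats[feats$class == "intron", ][c("start", "end")],
               tibble::tibble(start = 10500L, end = 11000L))
  expect_setequal(feats[feats$class == "coding_exon", ]$start,
                  c(10300L, 11000L))
  expect_equal(feats[feats$class == "utr3", ]$start, 11700L)

  # a promoter overlapping a CGI by one base is a CGI promoter
  cgis <- tibble::tibble(chrom = "chr1", start = 9999L, end = 10050L)
  split1 <- build_features(genes = genes, cgis = cgis)
  expect_true("promoter_cgi" %in% split1$class)
  cgis_off <- tibble::tibble(chrom = "chr1", start = 10000L, end = 10050L)
  split2 <- build_features(genes = genes, cgis = cgis_off)
  expect_true("promoter_noncgi" %in% split2$class)
})

test_that("segments join every overlapped class, or intergenic when none", {
  feats <- tibble::tibble(
    chrom = "chr1", start = c(100L, 120L), end = c(200L, 160L),
    strand = "*", class = c("intron", "SINE")
  )
  segs <- dplyr::bind_rows(
    make_seg(n15 = 16, cpgs = c(120L, 130L, 140L, 150L)),  # both classes
    make_seg(n15 = 16, cpgs = c(5000L, 5010L, 5020L, 5030L))  # none
  ) |> add_segment_stats()
  assigned <- assign_segments(segs, feats)
  expect_setequal(assigned$feature_class[assigned$start == 120L],
                  c("intron", "SINE"))
  expect_equal(assigned$feature_class[assigned$start == 5000L], "intergenic")
  sums <- summarise_features(assigned)
  expect_equal(sort(sums$n_segments), c(1L, 1L, 1L))
})

test_that("methylation-level classes use strict thresholds", {
  lv <- classify_level(c(0.85, 0.8, 0.2, 0.19, 0.0, 1.0))
  expect_equal(as.character(lv),
               c("hypermethylated", "intermediate", "intermediate",
                 "hypomethylated", "hypomethylated", "hypermethylated"))
})

test_that("the common segment set is keyed by chromosome and CpG positions", {
  a <- dplyr::bind_rows(
    make_seg(n15 = 16),
    make_seg(n15 = 8, n0 = 8, cpgs = c(500L, 510L, 520L, 530L)),
    make_seg(n0 = 16, cpgs = c(900L, 910L, 920L, 930L))
  ) |> add_segment_stats()
  b <- dplyr::bind_rows(
    make_seg(n12 = 16, cpgs = c(500L, 510L, 520L, 530L))
  ) |> add_segment_stats()
  common <- common_segments(list(s1 = a, s2 = b))
  expect_equal(nrow(common), 1L)
  expect_equal(common$cpg1, 500L)
  expect_equal(common$level_s1, 0.5)
  expect_equal(common$entropy_s2, 0)
  # identical samples share everything; disjoint share nothing
  expect_equal(nrow(common_segments(list(x = a, y = a))), nrow(a))
  expect_equal(nrow(common_segments(list(x = a[1, ], y = a[3, ]))), 0L)
})

test_that("pairwise Pearson correlations match the closed-form computation", {
  set.seed(2)
  lv1 <- runif(20); lv2 <- lv1 * 0.6 + runif(20) * 0.4
  segs <- stack_segs(do.call(rbind, lapply(1:20, function(i) random_counts(16))))
  s1 <- add_segment_stats(segs); s1$level <- lv1
  s2 <- add_segment_stats(segs); s2$level <- lv2
  common <- common_segments(list(a = s1, b = s2))
  r <- pairwise_correlation(common, "level")$r
  hand <- sum((lv1 - mean(lv1)) * (lv2 - mean(lv2))) /
    sqrt(sum((lv1 - mean(lv1))^2) * sum((lv2 - mean(lv2))^2))
  expect_equal(r, hand, tolerance = 1e-12)
  # identical vectors correlate at 1; mean-reflected at -1
  s3 <- s1; s3$level <- 2 * mean(lv1) - lv1
  expect_equal(pairwise_correlation(common_segments(list(a = s1, b = s1)),
                                    "level")$r, 1)
  expect_equal(pairwise_correlation(common_segments(list(a = s1, b = s3)),
                                    "level")$r, -1)
  expect_error(pairwise_correlation(common[0, ], "level"), "two common")
})

test_that("expression quintiles are equal-sized, stable and ordered", {
  e <- tibble::tibble(gene_id = paste0("G", 1:5), value = c(5, 1, 3, 2, 4))
  q <- assign_quintiles(e)
  expect_equal(q$quintile, c(5L, 1L, 3L, 2L, 4L))
  # sizes differ by at most one and zeros land in quintile 1
  e2 <- tibble::tibble(gene_id = paste0("G", 1:23),
                       value = c(0, 0, runif(21)))
  q2 <- assign_quintiles(e2)
  expect_lte(diff(range(table(q2$quintile))), 1)
  expect_true(all(q2$quintile[1:2] == 1L))
  # constant values: stable rank order gives equal groups
  e3 <- tibble::tibble(gene_id = paste0("G", 1:10), value = rep(1, 10))
  q3 <- assign_quintiles(e3)
  expect_equal(as.vector(table(q3$quintile)), rep(2L, 5))
  expect_equal(q3$quintile, rep(1:5, each = 2))
})

test_that("TSS profiles bin segment midpoints strand-consistently", {
  genes <- tibble::tibble(
    gene_id = c("P", "M"), chrom = "chr1", strand = c("+", "-"),
    tss = c(10000L, 20000L)
  )
  expr <- tibble::tibble(gene_id = c("P", "M"), value = c(1, 2))
  segs <- dplyr::bind_rows(
    # midpoint 9850 = TSS - 150 for the plus gene
    make_seg(n15 = 8, n0 = 8, cpgs = c(9834L, 9840L, 9850L, 9864L)),
    # midpoint 20150 = genomically right of the minus TSS -> upstream
    make_seg(n12 = 16, cpgs = c(20134L, 20140L, 20150L, 20164L))
  ) |> add_segment_stats()
  prof <- tss_profile(segs, genes, expr, window = 100, span = 3000)
  plus <- prof[prof$quintile == min(prof$quintile), ]
  expect_equal(plus$bin_start, -200L)
  expect_equal(plus$mean_entropy, 0.25)
  minus <- prof[prof$quintile == max(prof$quintile), ]
  expect_equal(minus$bin_start, -200L)
  expect_equal(minus$mean_level, 0.5)
  # empty bins are absent, not zero
  expect_equal(nrow(prof), 2L)
  expect_s3_class(autoplot(prof), "ggplot")
})

test_that("per-gene TSS-window statistics average the overlapping segments", {
  genes <- tibble::tibble(gene_id = "G", chrom = "chr1", strand = "+",
                          tss = 10000L)
  segs <- dplyr::bind_rows(
    make_seg(n15 = 8, n0 = 8, cpgs = c(9500L, 9510L, 9520L, 9530L)),
    make_seg(n12 = 8, n3 = 8, cpgs = c(9600L, 9610L, 9620L, 9630L)),
    make_seg(n15 = 16, cpgs = c(50000L, 50010L, 50020L, 50030L))
  ) |> add_segment_stats()
  gb <- gene_body_stats(segs, genes)
  expect_equal(gb$n_segments, 2L)
  expect_equal(gb$mean_entropy, mean(c(0.25, 0.25)))
  expect_equal(gb$mean_level, 0.5)
  # a segment overlapping the window by one base is included
  edge <- add_segment_stats(make_seg(n15 = 16,
                                     cpgs = c(8960L, 8970L, 8980L, 8999L)))
  expect_equal(gene_body_stats(edge, genes)$n_segments, 1L)
  none <- add_segment_stats(make_seg(n15 = 16,
                                     cpgs = c(8950L, 8960L, 8970L, 8978L)))
  expect_equal(nrow(gene_body_stats(none, genes)), 0L)
})
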