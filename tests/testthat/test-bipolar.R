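test_that("bipolar preselection requires both extreme read patterns", {
  segs <- dplyr::bind_rows(
    make_seg(n15 = 8, n0 = 8),
    make_seg(n15 = 16, cpgs = c(200L, 210L, 220L, 230L)),
    make_seg(n15 = 1, n0 = 1, n10 = 14, cpgs = c(300L, 310L, 320L, 330L))
  )
  kept <- select_bipolar(segs)
  expect_equal(kept$start, c(100L, 300L))
})

test_that("ASM overlap removal is half-open and needs only one base", {
  seg <- make_seg(n15 = 8, n0 = 8, cpgs = c(100L, 110L, 120L, 138L))  # span [100,140)
  one_bp <- tibble::tibble(chrom = "chr1", start = 139L, end = 200L)
  adjacent <- tibble::tibble(chrom = "chr1", start = 140L, end = 200L)
  expect_equal(nrow(filter_asm(seg, one_bp)), 0L)
  expect_equal(nrow(filter_asm(seg, adjacent)), 1L)
  expect_equal(nrow(filter_asm(seg, NULL)), 1L)
  expect_equal(nrow(filter_asm(seg, one_bp[0, ])), 1L)
})

test_that("the stochastic filter removes p > threshold and keeps the boundary", {
  segs <- dplyr::bind_rows(
    make_seg(n15 = 8, n0 = 8),
    make_seg(n15 = 8, n0 = 8, cpgs = c(200L, 210L, 220L, 230L)),
    make_seg(n15 = 8, n0 = 8, cpgs = c(300L, 310L, 320L, 330L))
  )
  segs$p_value <- c(0.0, 0.05, 0.051)
  kept <- filter_stochastic(segs)
  expect_equal(kept$p_value, c(0.0, 0.05))
  expect_error(filter_stochastic(make_seg(n15 = 16)), "p_value")
})

test_that("segments merge transitively within the gap and regions stay disjoint", {
  spans <- function(ranges) {
    segs <- purrr::map2_dfr(ranges[, 1], ranges[, 2], function(s, e) {
      make_seg(n15 = 8, n0 = 8,
               cpgs = as.integer(c(s, s + 10, s + 20, e - 2)))
    })
    segs$p_value <- 0
    segs
  }
  r1 <- merge_regions(spans(cbind(c(100, 141), c(140, 180))))  # gap 1 -> merge
  expect_equal(nrow(r1), 1L)
  expect_equal(c(r1$start, r1$end), c(100L, 180L))
  expect_equal(r1$n_segments, 2L)

  r2 <- merge_regions(spans(cbind(c(100, 142), c(140, 180))))  # gap 2 -> keep
  expect_equal(nrow(r2), 2L)

  r3 <- merge_regions(spans(cbind(c(100, 120), c(140, 160))))  # overlap
  expect_equal(c(r3$start, r3$end), c(100L, 160L))

  # idempotence and order independence
  segs <- spans(cbind(c(500, 100, 141), c(540, 140, 180)))
  merged <- merge_regions(segs)
  expect_equal(merge_regions(segs[c(3, 1, 2), ]), merged)
  remerged <- merge_regions(merged |> dplyr::mutate(chrom = "chr1"))
  expect_equal(remerged[c("chrom", "start", "end")],
               merged[c("chrom", "start", "end")])
  # pairwise gaps in the output exceed the merge gap
  expect_true(all(diff(merged$start) > merged$end[-nrow(merged)] -
                    merged$start[-nrow(merged)]))
})

test_that("promoter association respects strand and the half-open boundary", {
  genes <- tibble::tibble(
    gene_id = c("PLUS", "MINUS"), chrom = "chr1",
    strand = c("+", "-"), tss = c(10000L, 20000L)
  )
  region <- function(s, e) {
    tibble::tibble(chrom = "chr1", start = as.integer(s), end = as.integer(e),
                   n_segments = 1L, min_p = 0, segment_keys = list("k"))
  }
  # plus strand: promoter [9000, 10200)
  expect_equal(associate_promoters(region(9500, 9600), genes)$gene_id, "PLUS")
  expect_equal(nrow(associate_promoters(region(10200, 10300), genes)), 0L)
  # minus strand: promoter [19800, 21000)
  hit <- associate_promoters(region(20900, 20990), genes)
  expect_equal(hit$gene_id, "MINUS")
  expect_equal(c(hit$promoter_start, hit$promoter_end), c(19800L, 21000L))
  expect_equal(nrow(associate_promoters(region(21000, 21100), genes)), 0L)
})

test_that("transcripts of one gene pool their promoters and regions merge within them", {
  genes <- tibble::tibble(
    gene_id = "G", chrom = "chr1", strand = "+", tss = c(10000L, 10400L)
  )
  regions <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", start = 9100L, end = 9150L,
                   n_segments = 1L, min_p = 0.01, segment_keys = list("a")),
    tibble::tibble(chrom = "chr1", start = 10300L, end = 10350L,
                   n_segments = 1L, min_p = 0.002, segment_keys = list("b"))
  )
  cand <- associate_promoters(regions, genes)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$n_regions, 2L)
  expect_equal(cand$min_p, 0.002)
  # both regions merged into one entry under the promoter, gap notwithstanding
  expect_equal(nrow(cand$regions[[1]]), 1L)
})

test_that("the promoter CpG filter applies the >= 10 boundary", {
  cand <- tibble::tibble(
    gene_id = c("A", "B", "C"), chrom = "chr1",
    promoter_start = c(0L, 1000L, 2000L), promoter_end = c(500L, 1500L, 2500L),
    n_regions = 1L, min_p = 0,
    promoter_intervals = list(
      tibble::tibble(chrom = "chr1", start = 0L, end = 500L),
      tibble::tibble(chrom = "chr1", start = 1000L, end = 1500L),
      tibble::tibble(chrom = "chr1", start = 2000L, end = 2500L)
    ),
    regions = list(NULL, NULL, NULL)
  )
  idx <- tibble::tibble(
    chrom = "chr1",
    pos = c(seq(0L, 90L, 10L),        # 10 CpGs for A
            seq(1000L, 1080L, 10L))   # 9 CpGs for B; 0 for C
  )
  kept <- filter_low_cpg(cand, idx, min_cpgs = 10)
  expect_equal(kept$gene_id, "A")
  expect_equal(kept$n_promoter_cpgs, 10L)
})

test_that("the detection pipeline filters monotonically and finds nothing in a uniform methylome", {
  sim <- generate_methylome(population_spec(
    n_css = 0, n_hypo = 3, n_hyper = 3, n_asm = 0, n_intermediate = 0,
    depth = 20, error_rate = 0.01, seed = 21
  ))
  segs <- scan_segments(filter_reads(sim$calls), sim$cpg_index)
  res <- run_bipolar_pipeline(segs, sim$genes, sim$cpg_index,
                              asm_regions = sim$asm_regions,
                              n_reps = 100, seed = 5)
  expect_equal(nrow(res$genes), 0L)
  cn <- res$counts
  expect_lte(cn[["bipolar_segments"]], cn[["input_segments"]])
  expect_lte(cn[["after_asm_filter"]], cn[["bipolar_segments"]])
  expect_lte(cn[["after_stochastic_filter"]], cn[["after_asm_filter"]])
  expect_lte(cn[["merged_regions"]], cn[["after_stochastic_filter"]])
  expect_lte(cn[["candidate_genes"]], cn[["promoter_genes"]])
})
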