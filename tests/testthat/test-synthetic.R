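test_that("a pure fully-methylated population yields homogeneous windows", {
  sim <- generate_methylome(population_spec(
    n_css = 0, n_hypo = 0, n_hyper = 3, n_asm = 0, n_intermediate = 0,
    prob_hyper = 1, error_rate = 0, depth = 20, seed = 3
  ))
  segs <- scan_segments(filter_reads(sim$calls), sim$cpg_index)
  st <- add_segment_stats(segs)
  expect_gt(nrow(st), 0)
  expect_true(all(st$level == 1))
  expect_true(all(st$entropy == 0))
  expect_true(all(st$n15 == st$n_reads))
})

test_that("an equal two-subpopulation mixture produces bipolar windows at level one half", {
  sim <- generate_methylome(population_spec(
    n_css = 10, n_hypo = 0, n_hyper = 0, n_asm = 0, n_intermediate = 0,
    error_rate = 0, depth = 20, seed = 13
  ))
  st <- add_segment_stats(scan_segments(filter_reads(sim$calls),
                                        sim$cpg_index))
  expect_gt(nrow(st), 50)
  # only the two extreme patterns occur
  other <- rowSums(st[paste0("n", 1:14)])
  expect_true(all(other == 0))
  expect_equal(mean(st$level), 0.5, tolerance = 0.05)
  # closed form: per window ME = H2(k/N)/4 with k ~ Binomial(N, 1/2), so
  # the mean sits just below the 0.25 ceiling of a 50/50 mixture
  h2 <- function(p) ifelse(p <= 0 | p >= 1, 0, -p * log2(p) -
                             (1 - p) * log2(1 - p))
  expected <- mean(vapply(st$n_reads, function(N) {
    sum(stats::dbinom(0:N, N, 0.5) * h2((0:N) / N)) / 4
  }, numeric(1)))
  expect_lt(abs(mean(st$entropy) - expected), 0.01)
  expect_gt(mean(st$entropy), 0.2)
  expect_lt(mean(st$entropy), 0.25)
  expect_gte(mean(st$bipolar), 0.99)
})

test_that("a fully stochastic locus matches its own level-preserving null", {
  sim <- generate_methylome(population_spec(
    n_css = 0, n_hypo = 0, n_hyper = 0, n_asm = 0, n_intermediate = 12,
    prob_intermediate = 0.5, error_rate = 0, depth = 16, seed = 23
  ))
  st <- add_segment_stats(scan_segments(filter_reads(sim$calls),
                                        sim$cpg_index))
  expect_gt(nrow(st), 30)
  nulls <- null_median_entropy(st, n_reps = 100, seed = 1)
  expect_equal(mean(st$entropy), mean(nulls), tolerance = 0.05)
})

test_that("planted ASM loci carry the bipolar signature and are removable", {
  sim <- generate_methylome(population_spec(
    n_css = 0, n_hypo = 2, n_hyper = 2, n_asm = 4, n_intermediate = 0,
    error_rate = 0, depth = 20, seed = 31
  ))
  st <- add_segment_stats(scan_segments(filter_reads(sim$calls),
                                        sim$cpg_index))
  bip <- select_bipolar(st)
  expect_gt(nrow(bip), 0)
  # every bipolar segment lies in a truth ASM region, and the filter
  # removes them all
  expect_equal(nrow(filter_asm(bip, sim$asm_regions)), 0L)
})

test_that("a hypo/hyper-dominated mixture shows a bimodal segment-level histogram", {
  sim <- generate_methylome(population_spec(
    n_css = 0, n_hypo = 8, n_hyper = 8, n_asm = 0, n_intermediate = 4,
    depth = 20, error_rate = 0.01, seed = 41
  ))
  st <- add_segment_stats(scan_segments(filter_reads(sim$calls),
                                        sim$cpg_index))
  h <- hist(st$level, breaks = seq(0, 1, 0.2), plot = FALSE)$counts
  expect_gt(h[1], max(h[2:4]))
  expect_gt(h[5], max(h[2:4]))
})

test_that("the generator is deterministic and its files round-trip", {
  sim1 <- small_sim(seed = 17)
  sim2 <- small_sim(seed = 17)
  expect_identical(sim1$calls, sim2$calls)
  expect_false(identical(sim1$calls, small_sim(seed = 18)$calls))

  dir <- withr::local_tempdir()
  paths <- write_methylome_fixtures(sim1, dir)
  expect_true(all(file.exists(paths)))
  back <- read_bismark_calls(paths[["calls"]], sim1$cpg_index)
  expect_equal(
    as.data.frame(back),
    as.data.frame(dplyr::arrange(sim1$calls, chrom, read_id, cpg_pos)),
    ignore_attr = TRUE
  )
  genes <- read_gene_table(paths[["genes"]])
  expect_equal(genes$gene_id, sim1$genes$gene_id)
  expect_equal(genes$tss, sim1$genes$tss)
})

test_that("generated expression ranks genes by their methylation label", {
  sim <- small_sim(seed = 19)
  expr <- generate_expression(sim, seed = 2)
  expect_equal(expr$gene_id, sim$truth$gene_id)
  expect_true(all(expr$value > 0))
  by_label <- tapply(expr$value, sim$truth$label, stats::median)
  expect_gt(by_label[["uniform-hypo"]], by_label[["uniform-hyper"]])
  # five distinct values split one per quintile
  q <- assign_quintiles(tibble::tibble(gene_id = paste0("G", 1:5),
                                       value = c(2, 9, 4, 1, 7)))
  expect_setequal(q$quintile, 1:5)
})

test_that("population specs validate their invariants", {
  expect_error(population_spec(subpop_fractions = c(0.6, 0.6)), "sum to 1")
  expect_error(population_spec(error_rate = 1.5), "error_rate")
  expect_error(population_spec(depth = 0), "depth")
  expect_error(population_spec(cpgs_per_locus = 3), "cpgs_per_locus")
})
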