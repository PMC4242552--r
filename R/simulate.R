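#' Describe a synthetic mixed-cell methylome
#'
#' The generative model: the genome is a series of CpG loci on one
#' chromosome, each locus a run of `cpgs_per_locus` CpGs spaced
#' `cpg_spacing` bp apart, loci separated by `locus_spacing` bp. Every
#' locus carries one ground-truth label determining its per-CpG methylation
#' probability in each cell subpopulation:
#'
#' * `uniform-hyper` / `uniform-hypo`: all subpopulations methylate each
#'   CpG with probability `prob_hyper` / `prob_hypo`;
#' * `cell-subset-specific`: subpopulation 1 fully methylated (probability
#'   1), subpopulation 2 fully unmethylated (probability 0);
#' * `ASM`: each fragment draws one of two alleles at 50/50, methylated on
#'   one allele and unmethylated on the other — the same read-level
#'   signature as cell-subset-specific methylation, distinguishable only
#'   through the emitted truth regions;
#' * `stochastic-intermediate`: every call is an independent coin flip at
#'   `prob_intermediate`.
#'
#' Fragments span exactly one four-CpG window (`read_cpg_span = 4`), so the
#' per-window read count is Poisson with mean `depth`; every call is
#' flipped with probability `error_rate` (symmetric noise). The defaults —
#' 50 loci of 13 CpGs (10 overlapping windows each, 500 windows), depth 20,
#' 1% error, two equal subpopulations, 20/10/10/5/5 loci of type
#' cell-subset-specific/hypo/hyper/ASM/intermediate — describe a mixed
#' population with a bimodal segment-level methylation distribution at
#' typical whole-genome bisulfite depths.
#'
#' @param n_css,n_hypo,n_hyper,n_asm,n_intermediate loci per label.
#' @param cpgs_per_locus CpGs per locus (>= 4).
#' @param cpg_spacing bp between CpGs within a locus.
#' @param locus_spacing bp between locus starts (must exceed the locus span
#'   plus promoter extent so loci stay in distinct promoters).
#' @param depth mean fragments per four-CpG window.
#' @param read_cpg_span CpGs covered by one fragment (currently 4).
#' @param error_rate probability a call flips state.
#' @param subpop_fractions cell-subpopulation mixing fractions (sum 1).
#' @param prob_hyper,prob_hypo,prob_intermediate per-CpG methylation
#'   probabilities for the uniform and stochastic labels.
#' @param chrom chromosome name for the synthetic genome.
#' @param seed RNG seed; all randomness flows from it.
#' @return an object of class `population_spec` (a list of the above).
#' @export
population_spec <- function(n_css = 20, n_hypo = 10, n_hyper = 10,
                            n_asm = 5, n_intermediate = 5,
                            cpgs_per_locus = 13, cpg_spacing = 25,
                            locus_spacing = 3000, depth = 20,
                            read_cpg_span = 4, error_rate = 0.01,
                            subpop_fractions = c(0.5, 0.5),
                            prob_hyper = 0.98, prob_hypo = 0.02,
                            prob_intermediate = 0.5,
                            chrom = "chr1", seed = 1) {
  .assert_scalar_number(depth, "depth", lower = 1)
  .assert_scalar_number(error_rate, "error_rate", lower = 0, upper = 1)
  .assert_scalar_number(cpgs_per_locus, "cpgs_per_locus", lower = 4)
  if (abs(sum(subpop_fractions) - 1) > 1e-8 || any(subpop_fractions < 0)) {
    abort("`subpop_fractions` must be non-negative and sum to 1")
  }
  for (p in c(prob_hyper, prob_hypo, prob_intermediate)) {
    .assert_scalar_number(p, "methylation probability", lower = 0, upper = 1)
  }
  if (read_cpg_span != 4) {
    abort("only read_cpg_span = 4 (one window per fragment) is implemented")
  }
  structure(list(
    n_css = n_css, n_hypo = n_hypo, n_hyper = n_hyper, n_asm = n_asm,
    n_intermediate = n_intermediate, cpgs_per_locus = cpgs_per_locus,
    cpg_spacing = cpg_spacing, locus_spacing = locus_spacing, depth = depth,
    read_cpg_span = read_cpg_span, error_rate = error_rate,
    subpop_fractions = subpop_fractions, prob_hyper = prob_hyper,
    prob_hypo = prob_hypo, prob_intermediate = prob_intermediate,
    chrom = chrom, seed = seed
  ), class = "population_spec")
}

# per-subpopulation methylation probability for one locus label
.label_probs <- function(label, spec) {
  k <- length(spec$subpop_fractions)
  switch(label,
    "uniform-hyper" = rep(spec$prob_hyper, k),
    "uniform-hypo" = rep(spec$prob_hypo, k),
    "stochastic-intermediate" = rep(spec$prob_intermediate, k),
    "cell-subset-specific" = c(1, rep(0, k - 1)),
    "ASM" = NA_real_  # handled per-fragment (allelic, not subpopulation)
  )
}

#' Generate a synthetic mixed-cell methylome with ground truth
#'
#' Draws per-read CpG methylation calls under a [population_spec()] and
#' emits, alongside the calls, everything the downstream stages need: the
#' CpG index of the synthetic genome, a RefSeq-style gene table with one
#' gene per locus (its promoter covering the locus), the true
#' allele-specific regions as intervals, and a per-locus truth table.
#'
#' @param spec a [population_spec()].
#' @return list of class `meth_simulation`: `calls` (tibble `read_id`,
#'   `chrom`, `cpg_pos`, `state`), `cpg_index`, `genes`, `asm_regions`,
#'   `truth` (locus label, interval, gene and window count), and `spec`.
#' @export
generate_methylome <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed %% 2147483647)
  labels <- c(rep("cell-subset-specific", spec$n_css),
              rep("uniform-hypo", spec$n_hypo),
              rep("uniform-hyper", spec$n_hyper),
              rep("ASM", spec$n_asm),
              rep("stochastic-intermediate", spec$n_intermediate))
  n_loci <- length(labels)
  if (n_loci == 0) abort("spec describes no loci")
  # round-robin interleave label types so locus type is not confounded
  # with genomic position
  labels <- labels[order(stats::ave(seq_len(n_loci), labels,
                                    FUN = seq_along))]

  w <- spec$read_cpg_span
  k_cpg <- spec$cpgs_per_locus
  n_win <- k_cpg - w + 1L
  locus_start <- 1000L + (seq_len(n_loci) - 1L) * as.integer(spec$locus_spacing)
  frac <- spec$subpop_fractions

  loci <- vector("list", n_loci)
  calls <- vector("list", n_loci)
  for (li in seq_len(n_loci)) {
    pos <- locus_start[li] + (seq_len(k_cpg) - 1L) * as.integer(spec$cpg_spacing)
    lab <- labels[li]
    probs <- .label_probs(lab, spec)
    frags <- vector("list", n_win)
    for (wi in seq_len(n_win)) {
      n_frag <- rpois(1, spec$depth)
      if (n_frag == 0) next
      wpos <- pos[wi:(wi + w - 1L)]
      if (lab == "ASM") {
        allele <- rbinom(n_frag, 1, 0.5)
        p_mat <- matrix(rep(allele, each = w), nrow = w)  # allele 1 = meth
      } else {
        sub <- sample.int(length(frac), n_frag, replace = TRUE, prob = frac)
        p_mat <- matrix(rep(probs[sub], each = w), nrow = w)
      }
      states <- matrix(rbinom(w * n_frag, 1, as.vector(p_mat)), nrow = w)
      if (spec$error_rate > 0) {
        flip <- matrix(rbinom(w * n_frag, 1, spec$error_rate), nrow = w)
        states <- bitwXor(states, flip)
      }
      frags[[wi]] <- tibble(
        read_id = sprintf("L%03dW%02dR%03d", li, wi, rep(seq_len(n_frag),
                                                         each = w)),
        chrom = spec$chrom,
        cpg_pos = rep(wpos, times = n_frag),
        state = as.integer(as.vector(states))
      )
    }
    calls[[li]] <- bind_rows(frags)
    loci[[li]] <- tibble(
      locus_id = sprintf("locus%03d", li), label = lab, chrom = spec$chrom,
      start = pos[1], end = pos[k_cpg] + 2L, n_windows = n_win,
      gene_id = sprintf("GENE%03d", li)
    )
  }
  truth <- bind_rows(loci)
  calls <- bind_rows(calls)

  cpg_index <- tibble(
    chrom = spec$chrom,
    pos = as.vector(vapply(locus_start, function(s) {
      s + (seq_len(k_cpg) - 1L) * as.integer(spec$cpg_spacing)
    }, integer(k_cpg)))
  ) |> arrange(.data$chrom, .data$pos)

  # one plus-strand gene per locus, TSS 100 bp past the locus end so the
  # detection promoter [tss-1000, tss+200) covers the whole locus
  tss <- truth$end + 100L
  genes <- tibble(
    name = paste0("NM_", sprintf("%06d", seq_len(n_loci))),
    gene_id = truth$gene_id, chrom = spec$chrom, strand = "+",
    txStart = tss, txEnd = tss + 2000L, cdsStart = tss + 200L,
    cdsEnd = tss + 1800L,
    exon_starts = purrr::map(tss, ~ c(.x, .x + 1200L)),
    exon_ends = purrr::map(tss, ~ c(.x + 800L, .x + 2000L)),
    tss = tss
  )
  asm_regions <- truth |>
    filter(.data$label == "ASM") |>
    select("chrom", "start", "end") |>
    mutate(name = "ASM", score = 0, strand = "*")

  structure(list(calls = calls, cpg_index = cpg_index, genes = genes,
                 asm_regions = asm_regions, truth = truth, spec = spec),
            class = "meth_simulation")
}

#' @export
print.meth_simulation <- function(x, ...) {
  cat(sprintf(
    "Synthetic methylome: %d loci (%s), %d CpGs, %d calls, seed %d\n",
    nrow(x$truth),
    paste(sprintf("%d %s", table(x$truth$label),
                  names(table(x$truth$label))), collapse = ", "),
    nrow(x$cpg_index), nrow(x$calls), x$spec$seed))
  invisible(x)
}

#' Generate expression values with a planted methylation association
#'
#' Assigns each gene a log-normal expression value whose mean depends on
#' the methylation label of its locus: hypomethylated-promoter genes are
#' expressed highest and hypermethylated lowest, planting the negative
#' methylation-expression association the TSS profiles should recover.
#'
#' @param sim a `meth_simulation` from [generate_methylome()].
#' @param label_log_means named vector of log-scale means per locus label.
#' @param sdlog log-scale standard deviation (default 0.3).
#' @param seed RNG seed.
#' @return expression tibble `gene_id`, `value`.
#' @export
generate_expression <- function(sim,
                                label_log_means = c(
                                  "uniform-hypo" = 4,
                                  "cell-subset-specific" = 2,
                                  "ASM" = 2,
                                  "stochastic-intermediate" = 1,
                                  "uniform-hyper" = 0),
                                sdlog = 0.3, seed = 1) {
  stopifnot(inherits(sim, "meth_simulation"))
  set.seed(seed %% 2147483647)
  mu <- label_log_means[sim$truth$label]
  if (anyNA(mu)) abort("`label_log_means` must cover every locus label")
  tibble(gene_id = sim$truth$gene_id,
         value = stats::rlnorm(nrow(sim$truth), meanlog = mu, sdlog = sdlog))
}

#' Write the files of a synthetic methylome
#'
#' Emits the calls in the Bismark extractor dialect, the CpG index and ASM
#' truth as BED, the gene table as TSV and the truth table as TSV, all
#' under `dir`. Generated files embed the generator seed in a header
#' comment.
#'
#' @param sim a `meth_simulation`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_methylome_fixtures <- function(sim, dir) {
  stopifnot(inherits(sim, "meth_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    calls = file.path(dir, "calls.tsv"),
    cpg_index = file.path(dir, "cpg_index.bed"),
    asm = file.path(dir, "asm_regions.bed"),
    genes = file.path(dir, "genes.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_bismark_calls(sim$calls, paths["calls"],
                      header = paste0("synthetic methylome, seed ",
                                      sim$spec$seed))
  write_bed(tibble(chrom = sim$cpg_index$chrom, start = sim$cpg_index$pos,
                   end = sim$cpg_index$pos + 2L), paths["cpg_index"])
  write_bed(sim$asm_regions, paths["asm"])
  genes_out <- sim$genes |>
    mutate(exonStarts = purrr::map_chr(.data$exon_starts,
                                       ~ paste0(paste(.x, collapse = ","), ",")),
           exonEnds = purrr::map_chr(.data$exon_ends,
                                     ~ paste0(paste(.x, collapse = ","), ","))) |>
    select("name", "chrom", "strand", "txStart", "txEnd", "cdsStart",
           "cdsEnd", "exonStarts", "exonEnds", name2 = "gene_id")
  readr::write_tsv(genes_out, paths["genes"])
  readr::write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
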