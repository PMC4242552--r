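# Shared fixtures and independent oracles, built in code.

# Segment tibble from named pattern counts, e.g. make_seg(n15 = 8, n0 = 8).
make_seg <- function(..., chrom = "chr1", cpgs = c(100L, 110L, 120L, 130L)) {
  counts <- list(...)
  seg <- tibble::tibble(chrom = chrom, start = cpgs[1],
                        end = cpgs[length(cpgs)] + 2L)
  for (j in seq_along(cpgs)) seg[[paste0("cpg", j)]] <- cpgs[j]
  for (p in paste0("n", 0:15)) seg[[p]] <- 0L
  for (nm in names(counts)) seg[[nm]] <- as.integer(counts[[nm]])
  seg$n_reads <- as.integer(rowSums(seg[paste0("n", 0:15)]))
  seg
}

# Segment tibble from a full 16-vector of counts (pattern 0..15 order).
make_seg_counts <- function(counts, chrom = "chr1",
                            cpgs = c(100L, 110L, 120L, 130L)) {
  stopifnot(length(counts) == 16)
  args <- as.list(as.integer(counts))
  names(args) <- paste0("n", 0:15)
  do.call(make_seg, c(args, list(chrom = chrom, cpgs = cpgs)))
}

# Stack many count vectors as one segment tibble at distinct positions so
# keys differ (vectorised: used with thousands of rows).
stack_segs <- function(count_matrix, chrom = "chr1") {
  n <- nrow(count_matrix)
  offs <- (seq_len(n) - 1L) * 1000L
  out <- tibble::tibble(chrom = chrom, start = 100L + offs,
                        end = 132L + offs)
  for (j in 1:4) out[[paste0("cpg", j)]] <- 100L + (j - 1L) * 10L + offs
  for (p in 0:15) out[[paste0("n", p)]] <- as.integer(count_matrix[, p + 1])
  out$n_reads <- as.integer(rowSums(count_matrix))
  out
}

# ---- independent oracles (string-based, never share code with R/) ----

# pattern id -> "MUUM"-style string, MSB = leftmost CpG
pattern_string <- function(id, w = 4) {
  bits <- as.integer(intToBits(id))[w:1]
  paste(c("U", "M")[bits + 1], collapse = "")
}

# Shannon entropy over the empirical pattern distribution, divided by b.
oracle_entropy <- function(counts, b = 4) {
  reads <- rep(vapply(seq_along(counts) - 1, pattern_string, "", w = b),
               counts)
  p <- table(reads) / length(reads)
  -sum(p * log2(p)) / b
}

# transitions by literally counting adjacent character changes
oracle_transitions <- function(id, w = 4) {
  s <- strsplit(pattern_string(id, w), "")[[1]]
  sum(s[-1] != s[-length(s)])
}

oracle_weighted_entropy <- function(counts, b = 4) {
  n <- sum(counts)
  total <- 0
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    p <- counts[i] / n
    total <- total + oracle_transitions(i - 1, b) * (-p * log2(p))
  }
  total / b
}

oracle_level <- function(counts, b = 4) {
  reads <- rep(vapply(seq_along(counts) - 1, pattern_string, "", w = b),
               counts)
  mean(unlist(strsplit(reads, "")) == "M")
}

# all compositions of n into k non-negative parts (columns = parts)
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  out <- lapply(0:n, function(i) cbind(i, compositions(n - i, k - 1)))
  do.call(rbind, out)
}

# all partitions of n (decreasing positive parts)
partitions_of <- function(n, max_part = n) {
  if (n == 0) return(list(integer()))
  out <- list()
  for (p in seq_len(min(n, max_part))) {
    for (rest in partitions_of(n - p, p)) out <- c(out, list(c(p, rest)))
  }
  out
}

# complement every pattern (M <-> U on each CpG): count vector reindexed
flip_counts <- function(counts) {
  counts[16:1]
}

# random segment count vectors at depth n (multinomial over a random
# pattern simplex); deterministic under the caller's seed
random_counts <- function(n, concentration = rep(1, 16)) {
  probs <- stats::rgamma(16, concentration)
  as.vector(stats::rmultinom(1, n, probs / sum(probs)))
}

# calls tibble for fragments fully covering given CpG positions with the
# given pattern strings ("MMUU", one fragment per element)
calls_for_patterns <- function(patterns, cpgs = c(100L, 110L, 120L, 130L),
                               chrom = "chr1", id_prefix = "r") {
  rows <- lapply(seq_along(patterns), function(i) {
    states <- as.integer(strsplit(patterns[i], "")[[1]] == "M")
    tibble::tibble(read_id = paste0(id_prefix, i), chrom = chrom,
                   cpg_pos = cpgs[seq_along(states)], state = states)
  })
  dplyr::bind_rows(rows)
}

toy_index <- function(pos = c(100L, 110L, 120L, 130L), chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = pos)
}

# small synthetic run used by several pipeline tests (cheap: few loci)
small_sim <- function(seed = 11) {
  generate_methylome(population_spec(
    n_css = 4, n_hypo = 2, n_hyper = 2, n_asm = 2, n_intermediate = 2,
    cpgs_per_locus = 13, depth = 20, error_rate = 0.01, seed = seed
  ))
}
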