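# Simulate `reps` level-preserving pattern-count vectors for one segment:
# the b*N call matrix is refilled with exactly M methylated calls placed
# uniformly at random, then read patterns are re-tabulated.
# Returns a reps x 2^w count matrix. Uses the current RNG state.
.simulate_counts <- function(n_reads, n_meth, w, reps) {
  bn <- n_reads * w
  wts <- 2^((w - 1):0)
  base <- c(rep(1L, n_meth), rep(0L, bn - n_meth))
  out <- matrix(0L, nrow = reps, ncol = 2^w)
  if (n_meth == 0L || n_meth == bn) {
    # a fully (un)methylated segment has a single admissible arrangement
    out[, if (n_meth == 0L) 1L else 2^w] <- n_reads
    return(out)
  }
  for (r in seq_len(reps)) {
    x <- base[sample.int(bn)]
    pid <- colSums(matrix(x, nrow = w) * wts)
    out[r, ] <- tabulate(pid + 1L, nbins = 2^w)
  }
  out
}

# Methylated-call count per segment (exact observed M, not recomputed from a
# rounded level).
.meth_calls <- function(segments, w) {
  m <- .counts_matrix(segments, w)
  as.integer(round(as.vector(m %*% .popcount(seq_len(2^w) - 1L))))
}

# Entropy / weighted entropy over a count matrix (rows = replicates).
.me_of_counts <- function(m, w) {
  rowSums(.shannon_terms(m, rowSums(m))) / w
}
.wme_of_counts <- function(m, w) {
  t_i <- pattern_transitions(seq_len(2^w) - 1L, w)
  as.vector(.shannon_terms(m, rowSums(m)) %*% t_i) / w
}

# Run fn(counts_matrix_of_sims, i) once per segment under that segment's
# own RNG stream (derived from the global seed and the segment key, so
# results are independent of row order). Returns a list.
.per_segment_sim <- function(segments, seed, n_reps, fn) {
  w <- segment_width(segments)
  mm <- .meth_calls(segments, w)
  seeds <- .segment_seed(seed, .segment_key(segments, w))
  purrr::map(seq_len(nrow(segments)), function(i) {
    set.seed(seeds[i])
    sims <- .simulate_counts(segments$n_reads[i], mm[i], w, n_reps)
    fn(sims, i)
  })
}

#' Draw one level-preserving random counterpart of each segment
#'
#' For every segment, the `b * N` binary calls are rearranged uniformly at
#' random subject to keeping the observed number of methylated calls (and
#' hence the methylation level) exactly; pattern counts are re-tabulated
#' from the shuffled call matrix. This is the null model of purely
#' stochastic methylation at the observed level and depth.
#'
#' @param segments segment tibble (see [scan_segments()]).
#' @param seed integer seed; each segment gets its own stream derived from
#'   the seed and the segment key.
#' @return a segment tibble of identical shape with simulated counts.
#' @export
simulate_level_preserving <- function(segments, seed = 1) {
  w <- segment_width(segments)
  .check_depth(segments$n_reads)
  mm <- .meth_calls(segments, w)
  seeds <- .segment_seed(seed, .segment_key(segments, w))
  sims <- purrr::map(seq_len(nrow(segments)), function(i) {
    set.seed(seeds[i])
    .simulate_counts(segments$n_reads[i], mm[i], w, 1L)[1, ]
  })
  counts <- do.call(rbind, sims)
  out <- segments
  out[.count_cols(w)] <- as_tibble(setNames(as.data.frame(counts),
                                            .count_cols(w)))
  out
}

#' Median methylation entropy of the level-preserving null
#'
#' Simulates `n_reps` level-preserving random pattern distributions per
#' segment and returns the median of their methylation entropies — the
#' entropy a segment of this depth and level would show under purely
#' stochastic methylation.
#'
#' @inheritParams simulate_level_preserving
#' @param n_reps number of simulations per segment (default 1000).
#' @return numeric vector of null median entropies.
#' @export
null_median_entropy <- function(segments, n_reps = 1000, seed = 1) {
  .assert_scalar_number(n_reps, "n_reps", lower = 1)
  .check_depth(segments$n_reads)
  w <- segment_width(segments)
  unlist(.per_segment_sim(segments, seed, n_reps,
                          function(sims, i) median(.me_of_counts(sims, w))))
}

#' Monte-Carlo p-value for non-stochastic pattern arrangement
#'
#' For each segment, the p-value is the fraction of level-preserving
#' simulations whose transition-weighted entropy is strictly lower than the
#' observed one. Segments whose read patterns are more "sorted" than chance
#' (e.g. bipolar all-M/all-U mixtures, WME = 0) obtain small p-values;
#' stochastic methylation yields large ones. Ties count against
#' significance (strict inequality), so the bipolar-read preselection must
#' precede this test in the detection pipeline.
#'
#' @inheritParams null_median_entropy
#' @return numeric p-values in `[0, 1]`, one per segment.
#' @export
weighted_entropy_pvalue <- function(segments, n_reps = 1000, seed = 1) {
  .assert_scalar_number(n_reps, "n_reps", lower = 1)
  .check_depth(segments$n_reads)
  w <- segment_width(segments)
  obs <- weighted_entropy(segments)
  unlist(.per_segment_sim(segments, seed, n_reps, function(sims, i) {
    sum(.wme_of_counts(sims, w) < obs[i] - 1e-12) / n_reps
  }))
}

#' Add null-simulation columns to a segment tibble
#'
#' One pass of `n_reps` level-preserving simulations per segment supplies
#' both `null_median_entropy` and `p_value` (see
#' [weighted_entropy_pvalue()]).
#'
#' @inheritParams null_median_entropy
#' @return the segment tibble with `null_median_entropy` and `p_value`
#'   columns added.
#' @export
add_null_stats <- function(segments, n_reps = 1000, seed = 1) {
  .assert_scalar_number(n_reps, "n_reps", lower = 1)
  .check_depth(segments$n_reads)
  w <- segment_width(segments)
  obs <- weighted_entropy(segments)
  res <- .per_segment_sim(segments, seed, n_reps, function(sims, i) {
    c(median(.me_of_counts(sims, w)),
      sum(.wme_of_counts(sims, w) < obs[i] - 1e-12) / n_reps)
  })
  segments |>
    mutate(null_median_entropy = purrr::map_dbl(res, 1),
           p_value = purrr::map_dbl(res, 2))
}

#' Downsample the reads of each segment
#'
#' Keeps `round(fraction * N)` reads per segment, sampled without
#' replacement, and re-tabulates pattern counts — used to check that depth
#' differences between samples do not drive entropy differences (e.g.
#' sampling 20 of 28 reads, 71.4%).
#'
#' @inheritParams simulate_level_preserving
#' @param fraction fraction of reads to keep, in `(0, 1]`.
#' @return a segment tibble with downsampled counts and updated `n_reads`.
#' @export
downsample_reads <- function(segments, fraction, seed = 1) {
  .assert_scalar_number(fraction, "fraction", lower = 1e-9, upper = 1)
  .check_depth(segments$n_reads)
  w <- segment_width(segments)
  m <- .counts_matrix(segments, w)
  keep_n <- as.integer(round(fraction * segments$n_reads))
  if (any(keep_n < 1)) abort("downsampling would leave a segment with no reads")
  seeds <- .segment_seed(seed, .segment_key(segments, w))
  counts <- do.call(rbind, purrr::map(seq_len(nrow(segments)), function(i) {
    reads <- rep(seq_len(2^w) - 1L, m[i, ])
    set.seed(seeds[i])
    kept <- sample(reads, keep_n[i], replace = FALSE)
    tabulate(kept + 1L, nbins = 2^w)
  }))
  out <- segments
  out[.count_cols(w)] <- as_tibble(setNames(as.data.frame(counts),
                                            .count_cols(w)))
  out$n_reads <- keep_n
  out
}

#' @rdname add_null_stats
#' @param p_threshold retained for interface completeness; thresholds are
#'   applied downstream by [filter_stochastic()].
#' @param downsample_fraction see [downsample_reads()].
#' @export
null_config <- function(n_reps = 1000, seed = 1, p_threshold = 0.05,
                        downsample_fraction = 1) {
  .assert_scalar_number(n_reps, "n_reps", lower = 1)
  .assert_scalar_number(p_threshold, "p_threshold", lower = 1e-12,
                        upper = 1 - 1e-12)
  .assert_scalar_number(downsample_fraction, "downsample_fraction",
                        lower = 1e-9, upper = 1)
  list(n_reps = as.integer(n_reps), seed = as.integer(seed),
       p_threshold = p_threshold, downsample_fraction = downsample_fraction)
}
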