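# Shannon term -p*log2(p) with 0 log 0 := 0, applied to a count matrix.
.shannon_terms <- function(m, n) {
  p <- m / n
  t <- ifelse(p > 0, -p * log2(p), 0)
  t
}

.check_depth <- function(n_reads) {
  if (any(n_reads < 1)) {
    abort("segment with zero reads: level/entropy are undefined at N = 0")
  }
}

#' Methylation level of each segment
#'
#' The fraction of methylated CpG calls among all `b * N` calls of the
#' segment (b CpG sites, N reads).
#'
#' @param segments segment tibble with pattern counts (see
#'   [scan_segments()]).
#' @return numeric vector in `[0, 1]`, one value per segment.
#' @export
methylation_level <- function(segments) {
  w <- segment_width(segments)
  m <- .counts_matrix(segments, w)
  .check_depth(rowSums(m))
  as.vector(m %*% .popcount(seq_len(2^w) - 1L)) / (w * rowSums(m))
}

#' Methylation entropy of each segment
#'
#' Shannon entropy (log base 2) of the empirical pattern distribution,
#' normalised by the number of CpG sites b:
#' `ME = (1/b) * sum_i -(n_i/N) log2(n_i/N)` over patterns with `n_i > 0`.
#' Zero for a homogeneous segment (a single observed pattern); 1 when all
#' 16 four-CpG patterns are used equally.
#'
#' @inheritParams methylation_level
#' @return numeric vector, one value per segment.
#' @export
methylation_entropy <- function(segments) {
  w <- segment_width(segments)
  m <- .counts_matrix(segments, w)
  n <- rowSums(m)
  .check_depth(n)
  rowSums(.shannon_terms(m, n)) / w
}

#' Number of methylation-state transitions within a pattern
#'
#' Counts adjacent state changes (methylated to unmethylated or the
#' reverse) along the CpGs of one pattern: 0 for all-M or all-U, up to
#' `w - 1` (3 for a four-CpG segment) for alternating patterns.
#'
#' @param pattern integer pattern id(s) in `0 .. 2^w - 1`.
#' @param w number of CpG sites (default 4).
#' @return integer vector of transition counts.
#' @export
pattern_transitions <- function(pattern, w = 4) {
  pattern <- as.integer(pattern)
  if (anyNA(pattern) || any(pattern < 0 | pattern >= 2^w)) {
    abort(sprintf("pattern id out of range 0..%d", 2^w - 1))
  }
  # adjacent-bit XOR: transitions = popcount(p XOR (p >> 1)) over w-1 pairs
  .popcount(bitwAnd(bitwXor(pattern, bitwShiftR(pattern, 1L)), 2^(w - 1) - 1L))
}

#' Transition-weighted methylation entropy of each segment
#'
#' Methylation entropy with each pattern's Shannon term multiplied by its
#' transition count:
#' `WME = (1/b) * sum_i t_i * [-(n_i/N) log2(n_i/N)]`.
#' All-M and all-U patterns have weight 0, so a purely bipolar segment
#' (only completely methylated and completely unmethylated reads) scores
#' exactly 0 — the signature the cell-subset-specific detection exploits.
#' Weights are applied inside the sum without renormalisation.
#'
#' @inheritParams methylation_level
#' @return numeric vector, one value per segment.
#' @export
weighted_entropy <- function(segments) {
  w <- segment_width(segments)
  m <- .counts_matrix(segments, w)
  n <- rowSums(m)
  .check_depth(n)
  t_i <- pattern_transitions(seq_len(2^w) - 1L, w)
  as.vector(.shannon_terms(m, n) %*% t_i) / w
}

#' Add per-segment heterogeneity statistics
#'
#' Appends `level`, `entropy`, `wentropy` and `bipolar` (both an all-M and
#' an all-U read observed) columns to a segment tibble.
#'
#' @inheritParams methylation_level
#' @return the segment tibble with the four columns added.
#' @examples
#' seg <- tibble::tibble(chrom = "chr1", start = 100L, end = 132L,
#'                       cpg1 = 100L, cpg2 = 110L, cpg3 = 120L, cpg4 = 130L)
#' seg[paste0("n", 0:15)] <- as.list(c(8L, rep(0L, 14), 8L))
#' seg$n_reads <- 16L
#' add_segment_stats(seg)[, c("level", "entropy", "wentropy", "bipolar")]
#' @export
add_segment_stats <- function(segments) {
  w <- segment_width(segments)
  all_m <- paste0("n", 2^w - 1)
  segments |>
    mutate(
      level = methylation_level(segments),
      entropy = methylation_entropy(segments),
      wentropy = weighted_entropy(segments),
      bipolar = .data$n0 > 0 & .data[[all_m]] > 0
    )
}
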