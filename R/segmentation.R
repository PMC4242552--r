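#' Keep fragments that report enough CpG calls
#'
#' A fragment is all calls sharing one `(read_id, chrom)` pair. Fragments
#' with fewer than `min_cpgs` distinct CpG calls carry no complete window
#' pattern and are removed; retained fragments pass through unchanged.
#'
#' @param calls call tibble (`read_id`, `chrom`, `cpg_pos`, `state`).
#' @param min_cpgs minimum CpG calls per fragment (default 4, the window
#'   width).
#' @return filtered call tibble.
#' @export
filter_reads <- function(calls, min_cpgs = 4) {
  .assert_scalar_number(min_cpgs, "min_cpgs", lower = 1)
  if (nrow(calls) == 0) return(calls)
  calls |>
    group_by(.data$read_id, .data$chrom) |>
    filter(n_distinct(.data$cpg_pos) >= min_cpgs) |>
    ungroup()
}

#' Encode an ordered run of methylation states as a pattern id
#'
#' The id is the binary number whose most significant bit is the leftmost
#' (5'-most) CpG: for four CpGs, MMMM = 15, UUUU = 0, MUUU = 8.
#'
#' @param states vector of 0/1 (or logical) states, leftmost CpG first.
#' @return integer pattern id in `0 .. 2^length(states) - 1`.
#' @export
pattern_of <- function(states) {
  w <- length(states)
  if (w < 1) abort("`states` must contain at least one state")
  states <- as.integer(states)
  if (anyNA(states) || any(states < 0 | states > 1)) {
    abort("`states` must be binary (0/1)")
  }
  as.integer(sum(states * 2^((w - 1):0)))
}

#' Scan a methylome for fixed-width CpG windows with pattern counts
#'
#' Slides a window of `w` consecutive indexed CpGs one CpG at a time
#' (windows overlap). A fragment contributes one pattern occurrence to a
#' window iff it carries unambiguous calls at all `w` positions; partial
#' coverage contributes nothing. Windows are emitted only at depth
#' `n_reads >= min_reads` — with the default four-CpG window, 16 reads is
#' the smallest depth that can realise all 2^4 patterns.
#'
#' @param calls call tibble (`read_id`, `chrom`, `cpg_pos`, `state`); calls
#'   at positions absent from `cpg_index` are ignored.
#' @param cpg_index CpG index tibble (`chrom`, `pos`).
#' @param min_reads minimum fragments fully covering the window (default 16).
#' @param w window width in CpGs (default 4).
#' @return segment tibble: `chrom`, `start`, `end` (half-open span from the
#'   first CpG to two bases past the last C), `cpg1..cpgw`, pattern counts
#'   `n0..n{2^w-1}`, `n_reads`.
#' @export
scan_segments <- function(calls, cpg_index, min_reads = 16, w = 4) {
  .assert_scalar_number(min_reads, "min_reads", lower = 1)
  .assert_scalar_number(w, "w", lower = 2)
  w <- as.integer(w)
  n_pat <- 2L^w
  empty <- tibble(chrom = character(), start = integer(), end = integer())
  for (j in seq_len(w)) empty[[paste0("cpg", j)]] <- integer()
  for (p in .count_cols(w)) empty[[p]] <- integer()
  empty$n_reads <- integer()
  if (nrow(calls) == 0) return(empty)

  idx <- as_tibble(cpg_index) |>
    distinct(.data$chrom, .data$pos) |>
    arrange(.data$chrom, .data$pos) |>
    group_by(.data$chrom) |>
    mutate(ord = row_number()) |>
    ungroup()

  df <- calls |>
    inner_join(idx, by = c("chrom", "cpg_pos" = "pos")) |>
    distinct(.data$read_id, .data$chrom, .data$ord, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$read_id, .data$ord)

  # shift within the sorted frame; a window is valid only when all w rows
  # belong to the same fragment and sit at consecutive index ordinals
  shift_up <- function(x, k) c(x[-seq_len(k)], rep(NA, k))
  frag <- paste(df$chrom, df$read_id, sep = "\r")
  ok <- rep(TRUE, nrow(df))
  pid <- df$state * 2^(w - 1)
  for (k in seq_len(w - 1)) {
    fragk <- shift_up(frag, k)
    ordk <- shift_up(df$ord, k)
    ok <- ok & !is.na(fragk) & fragk == frag & ordk == df$ord + k
    pid <- pid + dplyr::coalesce(shift_up(df$state, k), 0L) * 2^(w - 1 - k)
  }
  hits <- tibble(chrom = df$chrom, ord = df$ord,
                 pattern = as.integer(pid))[ok, ]
  if (nrow(hits) == 0) return(empty)

  counts <- hits |>
    count(.data$chrom, .data$ord, .data$pattern) |>
    tidyr::pivot_wider(names_from = "pattern", values_from = "n",
                       names_prefix = "n", values_fill = 0L)
  for (p in setdiff(.count_cols(w), names(counts))) counts[[p]] <- 0L
  counts <- counts[c("chrom", "ord", .count_cols(w))]
  counts$n_reads <- as.integer(rowSums(counts[.count_cols(w)]))
  counts <- filter(counts, .data$n_reads >= min_reads)
  if (nrow(counts) == 0) return(empty)

  # attach the w CpG positions of each window
  pos_by <- split(idx$pos, idx$chrom)
  for (j in seq_len(w)) {
    counts[[paste0("cpg", j)]] <- as.integer(purrr::map2_dbl(
      counts$chrom, counts$ord, function(ch, o) pos_by[[ch]][o + j - 1]
    ))
  }
  counts |>
    mutate(start = .data$cpg1, end = .data[[paste0("cpg", w)]] + 2L) |>
    select("chrom", "start", "end", dplyr::all_of(paste0("cpg", seq_len(w))),
           dplyr::all_of(.count_cols(w)), "n_reads") |>
    arrange(.data$chrom, .data$start)
}
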