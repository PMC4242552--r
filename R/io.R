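#' Build a CpG position index from a reference FASTA
#'
#' Scans every sequence for the dinucleotide `CG` (case-insensitive) and
#' records the 0-based position of the C on the forward strand. Because CpG
#' methylation is symmetric, one index entry stands for both strand
#' cytosines of the dinucleotide.
#'
#' @param fasta path to a FASTA file.
#' @return a tibble with columns `chrom`, `pos` (0-based C position), sorted
#'   and unique within each chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTCG"), fa)
#' build_cpg_index(fa)
#' @export
build_cpg_index <- function(fasta) {
  if (!file.exists(fasta)) abort(paste0("FASTA file not found: ", fasta))
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  hits <- Biostrings::vmatchPattern("CG", seqs)
  purrr::map2_dfr(names(seqs), as.list(hits), function(chrom, ir) {
    tibble(chrom = chrom, pos = IRanges::start(ir) - 1L)
  }) |>
    arrange(.data$chrom, .data$pos) |>
    distinct()
}

#' Read per-read CpG methylation calls in the Bismark extractor dialect
#'
#' Input lines are tab-separated with at least five columns: read id,
#' orientation, chromosome, 1-based position, single-letter context code.
#' Codes `Z`/`z` are methylated/unmethylated CpG-context calls; all other
#' codes (CHG/CHH/unknown contexts) are ignored. Positions are converted to
#' 0-based; a call at position p+1 whose p is an indexed CpG is the
#' reverse-strand cytosine of the dinucleotide and is collapsed onto p
#' (disable with `collapse_strands = FALSE` for strand-resolved work).
#' Calls matching no indexed CpG are dropped with a counted warning, as are
#' calls on chromosomes absent from the index. Paired-end mates share a read
#' id and are treated as one fragment: duplicate concordant calls at one CpG
#' are kept once; conflicting calls at one CpG are discarded for that
#' position.
#'
#' @param path calls file; `#`-prefixed header lines are skipped.
#' @param cpg_index CpG index tibble from [build_cpg_index()] (or any tibble
#'   with `chrom`, `pos`).
#' @param collapse_strands collapse p+1 reverse-strand calls onto the CpG
#'   unit at p (default TRUE).
#' @return a tibble of calls: `read_id`, `chrom`, `cpg_pos` (0-based),
#'   `state` (1 methylated, 0 unmethylated). Attribute `dropped` carries the
#'   per-reason drop counts.
#' @export
read_bismark_calls <- function(path, cpg_index, collapse_strands = TRUE) {
  if (!file.exists(path)) abort(paste0("calls file not found: ", path))
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 5)) {
    abort(sprintf("malformed calls line %d: expected >= 5 tab-separated fields, got %d",
                  lineno[which(nf < 5)[1]], nf[which(nf < 5)[1]]))
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:5)), ncol = 5, byrow = TRUE)
  pos1 <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(pos1)) {
    abort(sprintf("malformed calls line %d: position '%s' is not an integer",
                  lineno[which(is.na(pos1))[1]], m[which(is.na(pos1))[1], 4]))
  }
  calls <- tibble(
    read_id = m[, 1], chrom = m[, 3],
    pos0 = pos1 - 1L, code = m[, 5]
  )
  calls <- filter(calls, .data$code %in% c("Z", "z"))
  calls$state <- as.integer(calls$code == "Z")

  known <- unique(cpg_index$chrom)
  n_bad_chrom <- sum(!calls$chrom %in% known)
  calls <- filter(calls, .data$chrom %in% known)

  idx <- distinct(select(as_tibble(cpg_index), "chrom", "pos"))
  fwd <- mutate(idx, pos0 = .data$pos, cpg_pos = .data$pos)
  calls <- left_join(calls, select(fwd, "chrom", "pos0", "cpg_pos"),
                     by = c("chrom", "pos0"))
  if (collapse_strands) {
    rev <- mutate(idx, pos0 = .data$pos + 1L, cpg_rev = .data$pos)
    calls <- left_join(calls, select(rev, "chrom", "pos0", "cpg_rev"),
                       by = c("chrom", "pos0"))
    calls$cpg_pos <- if_else(is.na(calls$cpg_pos), calls$cpg_rev, calls$cpg_pos)
    calls$cpg_rev <- NULL
  }
  n_no_cpg <- sum(is.na(calls$cpg_pos))
  calls <- filter(calls, !is.na(.data$cpg_pos))

  # mate reconciliation: concordant duplicates collapse, discordant drop
  calls <- calls |>
    group_by(.data$read_id, .data$chrom, .data$cpg_pos) |>
    summarise(n_states = n_distinct(.data$state),
              state = first(.data$state), .groups = "drop")
  n_conflict <- sum(calls$n_states > 1)
  calls <- calls |>
    filter(.data$n_states == 1) |>
    select("read_id", "chrom", "cpg_pos", "state") |>
    arrange(.data$chrom, .data$read_id, .data$cpg_pos)

  dropped <- c(unknown_chrom = n_bad_chrom, no_cpg_match = n_no_cpg,
               mate_conflict = n_conflict)
  if (any(dropped > 0)) {
    warn(sprintf(
      "dropped calls: %d on unknown chromosomes, %d matching no indexed CpG, %d mate-conflicting",
      dropped[["unknown_chrom"]], dropped[["no_cpg_match"]],
      dropped[["mate_conflict"]]))
  }
  attr(calls, "dropped") <- dropped
  calls
}

#' Write per-read calls in the Bismark extractor dialect
#'
#' Inverse of [read_bismark_calls()] for synthetic data: positions become
#' 1-based, states become `Z`/`z`, orientation is written as `+`.
#'
#' @param calls call tibble (`read_id`, `chrom`, `cpg_pos`, `state`).
#' @param path output path.
#' @param header optional `#`-prefixed comment lines (e.g. provenance).
#' @return `path`, invisibly.
#' @export
write_bismark_calls <- function(calls, path, header = NULL) {
  lines <- sprintf("%s\t+\t%s\t%d\t%s", calls$read_id, calls$chrom,
                   calls$cpg_pos + 1L, c("z", "Z")[calls$state + 1L])
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read genomic intervals from a BED3/BED6 file
#'
#' BED is 0-based half-open; coordinates are kept as-is. Records with
#' `end <= start` are rejected.
#'
#' @param path BED file; `#`/`track`/`browser` lines are skipped.
#' @return tibble `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (missing BED columns filled with `"."`, `0`, `"*"`).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  grab <- function(i, default) {
    vapply(parts, function(p) if (length(p) >= i) p[i] else default, character(1))
  }
  out <- tibble(
    chrom = grab(1, NA_character_),
    start = as.integer(grab(2, NA_character_)),
    end = as.integer(grab(3, NA_character_)),
    name = grab(4, "."),
    score = suppressWarnings(as.numeric(grab(5, "0"))),
    strand = grab(6, "*")
  )
  bad <- which(is.na(out$start) | is.na(out$end) | out$end <= out$start)
  if (length(bad) > 0) {
    abort(sprintf("invalid BED record %d (%s): end must exceed start",
                  bad[1], lines[bad[1]]))
  }
  out
}

#' Write genomic intervals as BED
#'
#' Writes BED6 when any of `name`/`score`/`strand` is present, else BED3.
#' Round-trips [read_bed()] output exactly.
#'
#' @param intervals tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  has6 <- any(c("name", "score", "strand") %in% names(intervals))
  if (has6) {
    name <- intervals$name %||% rep(".", nrow(intervals))
    score <- intervals$score %||% rep(0, nrow(intervals))
    strand <- intervals$strand %||% rep("*", nrow(intervals))
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", intervals$chrom,
                     intervals$start, intervals$end, name,
                     format(score, trim = TRUE, scientific = FALSE), strand)
  } else {
    lines <- sprintf("%s\t%d\t%d", intervals$chrom, intervals$start,
                     intervals$end)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a RefSeq-style gene annotation table
#'
#' Expects a TSV with columns (header optional, detected from the first
#' line): `name`, `chrom`, `strand`, `txStart`, `txEnd`, `cdsStart`,
#' `cdsEnd`, `exonStarts`, `exonEnds`, optionally `name2` (gene symbol).
#' Coordinates are 0-based half-open as distributed by UCSC. Exon lists are
#' comma-separated. The strand-resolved TSS is `txStart` on `+` and `txEnd`
#' on `-`.
#'
#' @param path gene table TSV.
#' @return tibble with the columns above plus `gene_id` (symbol when
#'   present, else transcript name) and `tss`; exon lists as integer
#'   list-columns `exon_starts`, `exon_ends`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) abort(paste0("gene table not found: ", path))
  first <- readLines(path, n = 1)
  has_header <- grepl("name", first) && grepl("chrom", first)
  df <- readr::read_tsv(path, col_names = has_header,
                        show_col_types = FALSE, comment = "#",
                        col_types = readr::cols(.default = readr::col_character()))
  if (!has_header) {
    base <- c("name", "chrom", "strand", "txStart", "txEnd", "cdsStart",
              "cdsEnd", "exonStarts", "exonEnds", "name2")
    names(df) <- base[seq_len(min(ncol(df), length(base)))]
  }
  needed <- c("name", "chrom", "strand", "txStart", "txEnd")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("gene table lacks columns: ", paste(missing, collapse = ", ")))
  }
  parse_list <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) return(integer())
      as.integer(strsplit(sub(",$", "", s), ",", fixed = TRUE)[[1]])
    })
  }
  out <- tibble(
    name = df$name,
    gene_id = if ("name2" %in% names(df)) {
      if_else(is.na(df$name2) | !nzchar(df$name2), df$name, df$name2)
    } else df$name,
    chrom = df$chrom,
    strand = df$strand,
    txStart = as.integer(df$txStart),
    txEnd = as.integer(df$txEnd),
    cdsStart = as.integer(df$cdsStart %||% df$txStart),
    cdsEnd = as.integer(df$cdsEnd %||% df$txEnd),
    exon_starts = parse_list(df$exonStarts %||% rep(NA_character_, nrow(df))),
    exon_ends = parse_list(df$exonEnds %||% rep(NA_character_, nrow(df)))
  )
  bad <- which(out$txEnd <= out$txStart)
  if (length(bad) > 0) {
    abort(sprintf("gene record '%s': txEnd must exceed txStart", out$name[bad[1]]))
  }
  out$tss <- if_else(out$strand == "-", out$txEnd, out$txStart)
  out
}

#' Read a two-column gene expression table
#'
#' @param path TSV of `gene_id`, `value` (>= 0); header optional.
#' @return tibble `gene_id`, `value`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("expression table not found: ", path))
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        comment = "#",
                        col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 2) abort("expression table needs two columns: gene_id, value")
  if (suppressWarnings(is.na(as.numeric(df[[2]][1])))) df <- df[-1, ]
  out <- tibble(gene_id = df[[1]], value = as.numeric(df[[2]]))
  bad <- which(is.na(out$value) | out$value < 0)
  if (length(bad) > 0) {
    abort(sprintf("expression record '%s': value must be a non-negative number",
                  out$gene_id[bad[1]]))
  }
  out
}
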