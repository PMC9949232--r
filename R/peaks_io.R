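#' Peak tables
#'
#' Peaks are plain tibbles with one row per enriched region:
#' `chrom`, `start`, `end` (0-based half-open), `name`, `summit` (0-based
#' base of maximum IP enrichment, `start <= summit < end`), `score`
#' (-log10 p-value), `pvalue` (Poisson tail probability), `qvalue`
#' (BH-adjusted, `NA` where not computed), `fold_enrichment` (IP pileup at
#' the summit over expected background) and `reads` (IP coverage integral
#' over the peak divided by the read length), plus `sample_id`.
#'
#' The on-disk format is a 10-column narrowPeak-like TSV (no header):
#' `chrom start end name reads strand fold_enrichment -log10(pvalue)
#' -log10(qvalue) summit_offset`, with the summit as an offset from `start`,
#' `-1` for missing q-values, and the IP read count in column 5 in place of
#' the conventional integer display score.
#'
#' @param chrom,start,end Interval coordinates (0-based half-open).
#' @param summit Summit positions; defaults to the interval midpoint.
#' @param pvalue,qvalue,fold_enrichment,reads Optional statistics (`NA` when
#'   absent).
#' @param name Peak names; generated when omitted.
#' @param sample_id Sample label.
#' @return A peak tibble.
#' @export
peak_table <- function(chrom, start, end, summit = NULL, name = NULL,
                       pvalue = NA_real_, qvalue = NA_real_,
                       fold_enrichment = NA_real_, reads = NA_real_,
                       sample_id = NA_character_) {
  validate_intervals(chrom, start, end, what = "peak_table")
  n <- length(start)
  if (is.null(summit)) summit <- start + (end - start) %/% 2L
  if (any(summit < start | summit >= end)) {
    abort("peak_table: summit must satisfy start <= summit < end")
  }
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  pv <- rep_len(pvalue, n)
  if (any(!is.na(pv) & (pv <= 0 | pv > 1))) abort("peak_table: pvalue must be in (0, 1]")
  fe <- rep_len(fold_enrichment, n)
  if (any(!is.na(fe) & fe < 0)) abort("peak_table: fold_enrichment must be >= 0")
  rd <- rep_len(reads, n)
  if (any(!is.na(rd) & rd < 0)) abort("peak_table: reads must be >= 0")
  tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    name = name, summit = as.integer(summit),
    score = ifelse(is.na(pv), NA_real_, -log10(pv)),
    pvalue = pv, qvalue = rep_len(qvalue, n),
    fold_enrichment = fe, reads = rd,
    sample_id = rep_len(sample_id, n)
  )
}

empty_peak_table <- function() {
  peak_table(character(0), integer(0), integer(0))
}

#' Read peaks from a BED/narrowPeak-like file
#'
#' Accepts a headerless TSV with at least 3 columns. With exactly 3 columns
#' the summit defaults to the interval midpoint and all statistics are `NA`.
#' With 10 columns the full dialect documented in [peak_table()] is read.
#'
#' @param path Input path.
#' @param sample_id Sample label attached to all peaks.
#' @return A peak tibble.
#' @export
read_peaks <- function(path, sample_id = NA_character_) {
  tb <- suppressWarnings(
    readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                    progress = FALSE)
  )
  if (nrow(tb) == 0) return(empty_peak_table())
  if (ncol(tb) < 3) abort("read_peaks: expected >= 3 tab-separated columns")
  chrom <- as.character(tb[[1]])
  start <- as.integer(tb[[2]])
  end <- as.integer(tb[[3]])
  validate_intervals(chrom, start, end, what = "read_peaks")
  if (ncol(tb) >= 10) {
    neglogq <- as.numeric(tb[[9]])
    peak_table(
      chrom, start, end,
      summit = start + as.integer(tb[[10]]),
      name = as.character(tb[[4]]),
      reads = as.numeric(tb[[5]]),
      fold_enrichment = as.numeric(tb[[7]]),
      pvalue = 10^(-as.numeric(tb[[8]])),
      qvalue = ifelse(neglogq < 0, NA_real_, 10^(-neglogq)),
      sample_id = sample_id
    )
  } else {
    nm <- if (ncol(tb) >= 4) as.character(tb[[4]]) else NULL
    peak_table(chrom, start, end, name = nm, sample_id = sample_id)
  }
}

#' Write peaks in the 10-column narrowPeak-like dialect
#'
#' `write_peaks()` followed by [read_peaks()] restores every persisted field
#' (the `sample_id` label is not stored in the file).
#'
#' @param peaks A peak tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  out <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$name,
    reads = peaks$reads,
    strand = ".",
    fold_enrichment = peaks$fold_enrichment,
    neglog10p = -log10(peaks$pvalue),
    neglog10q = ifelse(is.na(peaks$qvalue), -1, -log10(peaks$qvalue)),
    summit_offset = peaks$summit - peaks$start
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read/write a gene-by-sample count table
#'
#' TSV with a header row; the first column (`gene_id`) holds gene
#' identifiers, remaining columns are per-sample non-negative integer
#' counts.
#'
#' @param path Input or output path.
#' @return `read_counts()` returns a tibble with `gene_id` plus one column
#'   per sample.
#' @export
read_counts <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tb)[1] <- "gene_id"
  cnt <- as.matrix(tb[-1])
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    abort("read_counts: counts must be non-negative integers")
  }
  tb
}

#' @rdname read_counts
#' @param counts Count tibble (`gene_id` plus sample columns).
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}
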