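#' Overlap length between genomic intervals
#'
#' Computes the number of bases shared by two intervals in 0-based half-open
#' coordinates. Intervals on different sequences overlap by 0 bases. All
#' arguments are vectorized and recycled to a common length.
#'
#' @param chrom_a,chrom_b Sequence names.
#' @param start_a,start_b 0-based inclusive start offsets.
#' @param end_a,end_b 0-based exclusive end offsets.
#' @return Integer vector of overlap lengths, `max(0, min(end) - max(start))`
#'   where the sequence names agree and 0 otherwise.
#' @examples
#' interval_overlap("chr1", 0, 100, "chr1", 50, 150)  # 50
#' interval_overlap("chr1", 0, 100, "chr1", 100, 200) # 0 (half-open adjacency)
#' @export
interval_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  validate_intervals(chrom_a, start_a, end_a)
  validate_intervals(chrom_b, start_b, end_b)
  ov <- pmax(0L, pmin(end_a, end_b) - pmax(start_a, start_b))
  as.integer(ifelse(chrom_a == chrom_b, ov, 0L))
}

validate_intervals <- function(chrom, start, end, what = "interval") {
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    abort(sprintf("%s: sequence name must be non-empty", what))
  }
  if (any(start < 0)) abort(sprintf("%s: start must be >= 0", what))
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf("%s: start >= end at position %d (start=%s, end=%s)",
                  what, bad[1], start[bad[1]], end[bad[1]]))
  }
  invisible(TRUE)
}

## GRanges helpers: 0-based half-open tibble <-> 1-based closed GRanges
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

granges_to_intervals <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}
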