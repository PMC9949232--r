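#' Per-base coverage track
#'
#' A coverage track holds one non-negative depth vector per sequence plus a
#' library-size equivalent. Depth is the number of (extended) fragments
#' covering each base; the library size is defined as the total per-base
#' depth divided by the read length, i.e. the number of read equivalents that
#' produced the pileup. Tracks are strandless: the assays analysed here are
#' sequenced unstranded and strand is used only for annotation and metagene
#' orientation.
#'
#' @param depth Named list of non-negative numeric vectors, one per sequence.
#' @param read_length Read length (bp) used to convert summed depth to a
#'   read-count equivalent. Default 50.
#' @return An object of class `coverage_track` with elements `depth`,
#'   `chrom_sizes`, `read_length` and `library_size`.
#' @export
coverage_track <- function(depth, read_length = 50) {
  stopifnot(is.list(depth), !is.null(names(depth)), all(nzchar(names(depth))))
  for (v in depth) {
    if (any(v < 0)) abort("coverage_track: depth values must be >= 0")
  }
  structure(
    list(
      depth = depth,
      chrom_sizes = vapply(depth, length, integer(1)),
      read_length = read_length,
      library_size = sum(vapply(depth, sum, numeric(1))) / read_length
    ),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d sequence(s), %s bp, library size %.1f reads\n",
              length(x$depth), format(sum(x$chrom_sizes), big.mark = ","),
              x$library_size))
  invisible(x)
}

is_coverage_track <- function(x) inherits(x, "coverage_track")

#' Read a bedGraph file into a coverage track
#'
#' bedGraph intervals are 0-based half-open; bases not covered by any
#' interval get depth 0 (the writer omits zero runs).
#'
#' @param path Path to a bedGraph file.
#' @param chrom_sizes Named integer vector of sequence lengths (bedGraph does
#'   not carry them).
#' @param read_length Read length used for the library-size equivalent.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, chrom_sizes, read_length = 50) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  depth <- lapply(names(chrom_sizes), function(ch) numeric(chrom_sizes[[ch]]))
  names(depth) <- names(chrom_sizes)
  tb <- granges_to_intervals(gr)
  tb$score <- gr$score
  for (ch in unique(tb$chrom)) {
    if (!ch %in% names(depth)) {
      abort(sprintf("read_bedgraph: sequence '%s' not in chrom_sizes", ch))
    }
    sub <- tb[tb$chrom == ch, ]
    for (i in seq_len(nrow(sub))) {
      depth[[ch]][(sub$start[i] + 1L):sub$end[i]] <- sub$score[i]
    }
  }
  coverage_track(depth, read_length = read_length)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal depth are merged into single intervals; zero-depth runs are
#' omitted (the reader restores them).
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(is_coverage_track(track))
  rows <- purrr::imap(track$depth, function(v, ch) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    tibble(chrom = ch, start = starts[keep], end = ends[keep],
           score = r$values[keep])
  })
  tb <- dplyr::bind_rows(rows)
  gr <- intervals_to_granges(tb)
  gr$score <- tb$score
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

## mean of `v` over centered windows of size w (edge-truncated)
running_mean <- function(v, w) {
  n <- length(v)
  half <- w %/% 2
  cs <- c(0, cumsum(v))
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

## sum of depth over [start, end) half-open, via cumsum; vectorized
region_sums <- function(v, start, end) {
  cs <- c(0, cumsum(v))
  cs[end + 1L] - cs[start + 1L]
}
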