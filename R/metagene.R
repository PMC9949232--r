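#' Metagene profile over scaled gene bodies with fixed flanks
#'
#' For each transcript, coverage is normalized to per-million library scale,
#' the upstream and downstream flanks are binned at `flank_bin` bp, and the
#' gene body is scaled to `body_bins` bins (mean within bin; transcripts
#' shorter than `body_bins` are binned by linear interpolation rather than
#' dropped). Minus-strand rows are reversed so the bin index always runs
#' 5' to 3'. Flank bases beyond a chromosome end contribute 0.
#'
#' @param track A [coverage_track()].
#' @param transcripts Transcript tibble.
#' @param flank Flank size in bp on each side (default 5000).
#' @param flank_bin Flank bin width in bp (default 100).
#' @param body_bins Number of scaled gene-body bins (default 100).
#' @return An object of class `metagene_matrix`: a list with `matrix`
#'   (transcripts x bins), `profile` (tibble `bin`, `region`, `mean`) and
#'   the binning parameters. Row length is `2 * flank/flank_bin + body_bins`.
#' @export
metagene_profile <- function(track, transcripts, flank = 5000,
                             flank_bin = 100, body_bins = 100) {
  stopifnot(is_coverage_track(track), flank >= 0)
  if (nrow(transcripts) == 0) abort("metagene_profile: no transcripts")
  if (flank %% flank_bin != 0) abort("metagene_profile: flank must be a multiple of flank_bin")
  nf <- flank %/% flank_bin
  norm <- 1e6 / track$library_size

  slice_cov <- function(ch, lo, hi) {  # 0-based half-open, 0-padded
    v <- numeric(hi - lo)
    n <- length(track$depth[[ch]])
    a <- max(lo, 0L); b <- min(hi, n)
    if (a < b) v[(a - lo + 1L):(b - lo)] <- track$depth[[ch]][(a + 1L):b]
    v
  }
  bin_means <- function(v, nbins) {
    L <- length(v)
    if (L == nbins) return(v)
    if (L < nbins) {
      return(approx(seq_len(L), v, xout = seq(1, L, length.out = nbins))$y)
    }
    b <- round(seq(0, L, length.out = nbins + 1))
    cs <- c(0, cumsum(v))
    (cs[b[-1] + 1] - cs[b[-length(b)] + 1]) / diff(b)
  }

  rows <- purrr::map(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    up <- slice_cov(tx$chrom, tx$start - flank, tx$start)
    body <- slice_cov(tx$chrom, tx$start, tx$end)
    down <- slice_cov(tx$chrom, tx$end, tx$end + flank)
    row <- c(if (nf > 0) bin_means(up, nf),
             bin_means(body, body_bins),
             if (nf > 0) bin_means(down, nf))
    if (tx$strand == "-") row <- rev(row)
    row * norm
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- transcripts$transcript_id
  region <- c(rep("upstream", nf), rep("body", body_bins), rep("downstream", nf))
  profile <- tibble(bin = seq_len(ncol(mat)), region = region,
                    mean = colMeans(mat))
  structure(list(matrix = mat, profile = profile, flank = flank,
                 flank_bin = flank_bin, body_bins = body_bins),
            class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat(sprintf("<metagene_matrix> %d transcripts x %d bins (flank %d bp / %d bp bins, %d body bins)\n",
              nrow(x$matrix), ncol(x$matrix), x$flank, x$flank_bin, x$body_bins))
  invisible(x)
}
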