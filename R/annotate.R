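#' Genomic feature index
#'
#' Derives the seven genomic feature classes — promoter-TSS, TTS, 5'UTR,
#' 3'UTR, exon, intron, intergenic — from a transcript table. The promoter
#' window is strand-oriented TSS -`promoter_upstream` .. +`promoter_downstream`
#' (defaults -1000..+100 bp, a HOMER-like convention); the TTS window is
#' +/- `tts_flank` bp. Intergenic is the complement of all gene spans and
#' promoter/TTS windows, so every base resolves to at least one class.
#'
#' @param transcripts Transcript tibble (see [read_gtf()]).
#' @param promoter_upstream,promoter_downstream Promoter window (bp) around
#'   the TSS, oriented by strand.
#' @param tts_flank Half-width (bp) of the TTS window.
#' @return An object of class `feature_index`: a tibble of classed intervals
#'   plus the window parameters and a per-chromosome TSS lookup.
#' @export
feature_index <- function(transcripts, promoter_upstream = 1000,
                          promoter_downstream = 100, tts_flank = 100) {
  mk <- function(class, chrom, start, end, gene_id) {
    tibble(class = class, chrom = chrom,
           start = as.integer(pmax(0, start)), end = as.integer(end),
           gene_id = gene_id)
  }
  rows <- purrr::map(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    s <- if (tx$strand == "-") -1L else 1L
    prom <- sort(c(tx$tss - s * promoter_upstream, tx$tss + s * promoter_downstream))
    elems <- transcript_element_positions(tx)
    bind_rows(
      mk("promoter-TSS", tx$chrom, prom[1], prom[2] + 1L, tx$gene_id),
      mk("TTS", tx$chrom, tx$tts - tts_flank, tx$tts + tts_flank + 1L, tx$gene_id),
      if (length(elems$utr5) > 0) {
        iv <- positions_to_intervals(sort(elems$utr5))
        mk("5'UTR", tx$chrom, iv$start, iv$end, tx$gene_id)
      },
      if (length(elems$utr3) > 0) {
        iv <- positions_to_intervals(sort(elems$utr3))
        mk("3'UTR", tx$chrom, iv$start, iv$end, tx$gene_id)
      },
      mk("exon", tx$chrom, tx$exons[[1]]$start, tx$exons[[1]]$end, tx$gene_id),
      if (length(elems$intron) > 0) {
        iv <- positions_to_intervals(sort(elems$intron))
        mk("intron", tx$chrom, iv$start, iv$end, tx$gene_id)
      }
    )
  })
  structure(
    list(
      intervals = bind_rows(rows),
      classes = c("promoter-TSS", "TTS", "5'UTR", "3'UTR", "exon",
                  "intron", "intergenic"),
      promoter_upstream = promoter_upstream,
      promoter_downstream = promoter_downstream,
      tts_flank = tts_flank,
      tss = transcripts %>% select("gene_id", "chrom", "tss")
    ),
    class = "feature_index"
  )
}

#' Annotate peaks with genomic feature classes and nearest genes
#'
#' Each peak is assigned a single class by its summit position with priority
#' promoter-TSS > TTS > 5'UTR > 3'UTR > exon > intron > intergenic
#' (annotation is by summit, the enrichment point, which avoids multi-class
#' ambiguity for wide peaks). The nearest gene is the gene whose TSS is
#' closest to the summit (ties to the leftmost TSS).
#'
#' @param peaks Peak tibble with `chrom` and `summit`.
#' @param index A [feature_index()].
#' @return `peaks` with `feature_class` (factor), `nearest_gene` and
#'   `tss_distance` columns added.
#' @export
annotate_peaks <- function(peaks, index) {
  stopifnot(inherits(index, "feature_index"))
  if (any(peaks$summit < 0)) abort("annotate_peaks: summit outside genome")
  n <- nrow(peaks)
  cls <- rep("intergenic", n)
  if (n > 0 && nrow(index$intervals) > 0) {
    summit_gr <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$summit + 1L, width = 1L))
    iv_gr <- intervals_to_granges(index$intervals)
    hits <- GenomicRanges::findOverlaps(summit_gr, iv_gr)
    if (length(hits) > 0) {
      ht <- tibble(
        peak = S4Vectors::queryHits(hits),
        class = index$intervals$class[S4Vectors::subjectHits(hits)]
      ) %>%
        mutate(rank = match(.data$class, index$classes)) %>%
        group_by(.data$peak) %>%
        summarise(class = index$classes[min(.data$rank)], .groups = "drop")
      cls[ht$peak] <- ht$class
    }
  }
  nearest <- purrr::map(seq_len(n), function(i) {
    tsub <- index$tss[index$tss$chrom == peaks$chrom[i], ]
    if (nrow(tsub) == 0) return(list(gene = NA_character_, d = NA_integer_))
    d <- abs(tsub$tss - peaks$summit[i])
    cand <- which(d == min(d))
    j <- cand[which.min(tsub$tss[cand])]     # ties -> leftmost TSS
    list(gene = tsub$gene_id[j], d = d[j])
  })
  peaks %>%
    mutate(feature_class = factor(cls, levels = index$classes),
           nearest_gene = purrr::map_chr(nearest, "gene"),
           tss_distance = purrr::map_int(nearest, ~ as.integer(.x$d)))
}

#' Genome-wide feature-class distribution of peaks
#'
#' @param peaks Annotated peak tibble (see [annotate_peaks()]).
#' @return Tibble with `feature_class`, `n` and `fraction` (fractions sum
#'   to 1).
#' @export
feature_distribution <- function(peaks) {
  if (nrow(peaks) == 0) abort("feature_distribution: no peaks")
  if (!"feature_class" %in% names(peaks)) {
    abort("feature_distribution: run annotate_peaks() first")
  }
  peaks %>%
    count(.data$feature_class, .drop = FALSE, name = "n") %>%
    mutate(fraction = .data$n / sum(.data$n))
}

#' Peak-score summaries per genomic feature class
#'
#' Summarises the enrichment score (-log10 p) of peaks by feature class —
#' the "strength of binding by region" readout.
#'
#' @param peaks Annotated peak tibble with a `score` column.
#' @return Tibble with per-class `n`, `mean`, `median`, `q25`, `q75`.
#' @export
score_by_region <- function(peaks) {
  if (!"feature_class" %in% names(peaks)) {
    abort("score_by_region: run annotate_peaks() first")
  }
  peaks %>%
    group_by(.data$feature_class) %>%
    summarise(n = dplyr::n(),
              mean = mean(.data$score),
              median = median(.data$score),
              q25 = unname(quantile(.data$score, 0.25)),
              q75 = unname(quantile(.data$score, 0.75)),
              .groups = "drop")
}

#' Fraction of peaks co-localizing with a second peak set
#'
#' A peak of `peaks_a` co-localizes when its interval overlaps an interval
#' of `peaks_b` by at least `min_overlap` bases. When `peaks_a` carries a
#' `feature_class` column the promoter-restricted fraction is also reported
#' (the "promoter Tet peaks overlapping H3K4me3" readout).
#'
#' @param peaks_a Peak tibble (optionally annotated).
#' @param peaks_b Interval tibble with `chrom`, `start`, `end`.
#' @param min_overlap Minimum overlap in bases (default 1).
#' @return Tibble with rows `all` (and `promoter-TSS` when available):
#'   `n`, `n_overlapping`, `fraction`.
#' @export
colocalization_fraction <- function(peaks_a, peaks_b, min_overlap = 1) {
  if (nrow(peaks_a) == 0) abort("colocalization_fraction: empty peak set A")
  hit <- rep(FALSE, nrow(peaks_a))
  if (nrow(peaks_b) > 0) {
    hits <- GenomicRanges::findOverlaps(intervals_to_granges(peaks_a),
                                        intervals_to_granges(peaks_b),
                                        minoverlap = min_overlap)
    hit[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  out <- tibble(subset = "all", n = nrow(peaks_a),
                n_overlapping = sum(hit), fraction = mean(hit))
  if ("feature_class" %in% names(peaks_a)) {
    pr <- peaks_a$feature_class == "promoter-TSS"
    if (any(pr)) {
      out <- bind_rows(out, tibble(subset = "promoter-TSS", n = sum(pr),
                                   n_overlapping = sum(hit[pr]),
                                   fraction = mean(hit[pr])))
    }
  }
  out
}
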