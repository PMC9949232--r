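#' Call 5hmrC peaks on RNA from IP and input coverage
#'
#' Runs the same Poisson caller as the ChIP stage, restricted to transcript
#' footprints, with the expected background given by each transcript's own
#' (scaled) input rate rather than genomic local windows — this controls
#' for expression level, so highly expressed transcripts do not produce
#' spurious peaks and weakly expressed neighbours of strong transcripts are
#' not masked. Peaks are selected at `p_threshold` and assigned
#' to their host transcript by summit; peaks whose summit falls outside any
#' transcript are flagged and excluded.
#'
#' @param ip,input [coverage_track()]s.
#' @param transcripts Transcript tibble.
#' @param p_threshold Poisson p-value cutoff (default 1e-5).
#' @param config Optional [peak_call_config()]; default embryo dialect.
#' @param sample_id Label recorded on the peaks.
#' @return Peak tibble with `transcript_id` and `gene_id` columns. Peaks
#'   not assignable to a transcript are dropped with a warning and returned
#'   in the `"unassigned"` attribute.
#' @export
call_rna_peaks <- function(ip, input, transcripts, p_threshold = 1e-5,
                           config = peak_call_config(), sample_id = NA_character_) {
  stopifnot(is_coverage_track(ip), is_coverage_track(input))
  mask <- lapply(ip$chrom_sizes, function(n) logical(n))
  floor_ <- lapply(ip$chrom_sizes, function(n) numeric(n))
  scale <- ip$library_size / input$library_size
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    idx <- (tx$start + 1L):tx$end
    mask[[tx$chrom]][idx] <- TRUE
    floor_[[tx$chrom]][idx] <- pmax(
      floor_[[tx$chrom]][idx],
      scale * mean(input$depth[[tx$chrom]][idx]), 0.25)
  }
  peaks <- call_peaks(ip, input, config, mask = mask, lambda_floor = floor_,
                      global_background = FALSE, sample_id = sample_id) %>%
    filter(.data$pvalue < p_threshold)
  if (nrow(peaks) == 0) {
    out <- mutate(peaks, transcript_id = character(0), gene_id = character(0))
    attr(out, "unassigned") <- peaks
    return(out)
  }
  host <- purrr::map_int(seq_len(nrow(peaks)), function(i) {
    j <- which(transcripts$chrom == peaks$chrom[i] &
                 transcripts$start <= peaks$summit[i] &
                 transcripts$end > peaks$summit[i])
    if (length(j) == 0) NA_integer_ else j[1]
  })
  out <- peaks %>%
    mutate(transcript_id = transcripts$transcript_id[host],
           gene_id = transcripts$gene_id[host])
  unassigned <- out[is.na(out$transcript_id), ]
  if (nrow(unassigned) > 0) {
    warn(sprintf("call_rna_peaks: %d peak(s) outside any transcript excluded",
                 nrow(unassigned)))
  }
  out <- out[!is.na(out$transcript_id), ]
  attr(out, "unassigned") <- unassigned
  out
}

rna_elements <- c("5'UTR", "CDS", "intron", "3'UTR")
element_key <- c(utr5 = "5'UTR", cds = "CDS", intron = "intron", utr3 = "3'UTR")

## element of a summit within its host transcript
classify_element <- function(tx, pos) {
  elems <- transcript_element_positions(tx)
  if (pos %in% elems$cds) return("CDS")
  if (pos %in% elems$utr5) return("5'UTR")
  if (pos %in% elems$utr3) return("3'UTR")
  "intron"
}

#' Distribution of RNA peaks over transcript structural elements
#'
#' Each peak is classed by its summit into 5'UTR / CDS / intron / 3'UTR
#' using exact CDS boundaries (intron = non-exonic transcript span; for a
#' transcript without CDS the exonic bases are split at the midpoint into
#' 5' and 3' UTR).
#'
#' @param peaks Transcript-assigned peak tibble (see [call_rna_peaks()]).
#' @param transcripts Transcript tibble.
#' @return Tibble of class `element_distribution` with `element`, `n`,
#'   `fraction` (fractions sum to 1).
#' @export
element_distribution <- function(peaks, transcripts) {
  if (nrow(peaks) == 0) abort("element_distribution: no peaks")
  if (!"transcript_id" %in% names(peaks)) {
    abort("element_distribution: peaks must be transcript-assigned")
  }
  el <- purrr::map_chr(seq_len(nrow(peaks)), function(i) {
    tx <- transcripts[match(peaks$transcript_id[i], transcripts$transcript_id), ]
    classify_element(tx, peaks$summit[i])
  })
  tibble(element = factor(el, levels = rna_elements)) %>%
    count(.data$element, .drop = FALSE, name = "n") %>%
    mutate(fraction = .data$n / sum(.data$n))
}

#' Expected (predicted) element distribution of RNA peaks
#'
#' The null model for "where would peaks fall if placed at random within
#' transcripts". `length_proportional` uses exact element length totals;
#' `monte_carlo_uniform` places `n_iter` pseudo-peaks uniformly within
#' transcript bases (seeded) and tallies them. The two agree within
#' Monte-Carlo error.
#'
#' @param transcripts Transcript tibble.
#' @param model `"monte_carlo_uniform"` (default) or `"length_proportional"`.
#' @param n_iter Pseudo-peaks for the Monte-Carlo model.
#' @param seed Seed for the Monte-Carlo model.
#' @return Tibble with `element` and `expected_fraction` (sums to 1).
#' @export
expected_element_distribution <- function(transcripts,
                                          model = c("monte_carlo_uniform",
                                                    "length_proportional"),
                                          n_iter = 10000, seed = 1) {
  model <- match.arg(model)
  lens <- purrr::map(seq_len(nrow(transcripts)), function(i) {
    el <- transcript_element_positions(transcripts[i, ])
    vapply(el[names(element_key)], length, integer(1))
  })
  lens <- do.call(rbind, lens)
  colnames(lens) <- element_key
  if (model == "length_proportional") {
    tot <- colSums(lens)
    frac <- tot / sum(tot)
  } else {
    if (n_iter < 1000) warn("expected_element_distribution: n_iter < 1000 gives a noisy expectation")
    set.seed(seed)
    tx_len <- transcripts$end - transcripts$start
    pick_tx <- sample.int(nrow(transcripts), n_iter, replace = TRUE,
                          prob = tx_len)
    pos <- transcripts$start[pick_tx] +
      floor(runif(n_iter) * tx_len[pick_tx])
    el <- purrr::map_chr(seq_len(n_iter), function(i) {
      classify_element(transcripts[pick_tx[i], ], as.integer(pos[i]))
    })
    frac <- table(factor(el, levels = rna_elements)) / n_iter
    frac <- as.numeric(frac)
    names(frac) <- rna_elements
  }
  tibble(element = factor(rna_elements, levels = rna_elements),
         expected_fraction = as.numeric(frac[rna_elements]))
}

#' Goodness of fit of an actual element distribution against the expectation
#'
#' Chi-square test of observed element counts against expected fractions.
#'
#' @param actual Output of [element_distribution()].
#' @param expected Output of [expected_element_distribution()].
#' @return Tibble with `statistic`, `df` and `p_value`.
#' @export
element_gof <- function(actual, expected) {
  stopifnot(identical(as.character(actual$element), as.character(expected$element)))
  ht <- suppressWarnings(chisq.test(actual$n, p = expected$expected_fraction))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Expression levels from a count table
#'
#' Counts per million per kilobase of exonic transcript length, averaged
#' over the selected samples — the internal expression measure used for
#' abundance stratification.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param transcripts Transcript tibble (maps genes to transcripts and
#'   exonic lengths).
#' @param samples Optional character vector of sample columns (default all).
#' @return Tibble with `transcript_id`, `gene_id`, `level`.
#' @export
expression_levels <- function(counts, transcripts, samples = NULL) {
  samples <- samples %||% setdiff(names(counts), "gene_id")
  m <- as.matrix(counts[samples])
  cpm <- t(t(m) / colSums(m)) * 1e6
  lev <- rowMeans(cpm)
  len_kb <- exonic_length(transcripts) / 1000
  idx <- match(transcripts$gene_id, counts$gene_id)
  tibble(transcript_id = transcripts$transcript_id,
         gene_id = transcripts$gene_id,
         level = lev[idx] / len_kb)
}

#' Stratify transcripts by expression, overall and modified-only
#'
#' Bins transcripts into `n_bins` equal-width bins of log10 expression and
#' counts all versus 5hmrC-modified transcripts per bin; also reports the
#' Spearman rank correlation between modification status and expression
#' with an approximate 95% CI (Fisher transform).
#'
#' @param modified_ids Transcript ids carrying >= 1 RNA peak.
#' @param expression Tibble from [expression_levels()].
#' @param n_bins Number of expression bins (default 10).
#' @return Tibble of class `abundance_strata` (`bin`, `level_lo`,
#'   `level_hi`, `n_all`, `n_modified`), with attribute `correlation`
#'   (tibble `estimate`, `conf_lo`, `conf_hi`, `p_value`).
#' @export
abundance_stratification <- function(modified_ids, expression, n_bins = 10) {
  lv <- log10(expression$level + 1e-9)
  brk <- seq(min(lv), max(lv), length.out = n_bins + 1)
  brk[1] <- brk[1] - 1e-9
  bin <- cut(lv, brk, labels = FALSE, include.lowest = TRUE)
  mod <- expression$transcript_id %in% modified_ids
  strata <- tibble(bin = seq_len(n_bins),
                   level_lo = 10^head(brk, -1), level_hi = 10^brk[-1]) %>%
    left_join(tibble(bin = bin, mod = mod) %>%
                group_by(.data$bin) %>%
                summarise(n_all = dplyr::n(), n_modified = sum(.data$mod),
                          .groups = "drop"),
              by = "bin") %>%
    mutate(n_all = tidyr::replace_na(.data$n_all, 0L),
           n_modified = tidyr::replace_na(.data$n_modified, 0L))
  rho <- suppressWarnings(cor(rank(expression$level), as.numeric(mod),
                              method = "pearson"))
  n <- length(mod)
  z <- atanh(rho); se <- 1 / sqrt(n - 3)
  corr <- tibble(estimate = rho,
                 conf_lo = tanh(z - 1.96 * se), conf_hi = tanh(z + 1.96 * se),
                 p_value = 2 * pnorm(-abs(z) / se))
  structure(strata, correlation = corr,
            class = c("abundance_strata", class(strata)))
}

#' Reduction-classifier configuration
#'
#' The reduction rule: a peak is reduced when the normalized wild-type
#' signal is at least `fold_threshold`-fold higher than the Tet-null signal
#' (inclusive, "at least 1.4-fold"). Signal is the mean per-million IP
#' coverage over the peak interval, averaged across replicates; the
#' Tet-null signal is floored at `pseudocount` per million to avoid
#' division by zero.
#'
#' @param fold_threshold Inclusive wt/ko fold-change threshold (default 1.4).
#' @param pseudocount Per-million floor on the Tet-null signal (default 0.5).
#' @param prior_df Prior degrees of freedom of the moderated variance
#'   (shrinkage of per-peak variances toward their global mean).
#' @return A list of class `reduction_config`.
#' @export
reduction_config <- function(fold_threshold = 1.4, pseudocount = 0.5,
                             prior_df = 4) {
  if (fold_threshold <= 1) abort("reduction_config: fold_threshold must be > 1")
  structure(list(fold_threshold = fold_threshold, pseudocount = pseudocount,
                 prior_df = prior_df),
            class = "reduction_config")
}

## background-equivalent library size, in read equivalents: the coverage
## vector is split into contiguous covered runs (segments of transcript
## footprints between zero-depth bases) and each run contributes its median
## depth times its length. Peak bases are a minority within any one run, so
## run medians track the local baseline and the total is robust to
## enrichment mass differences between genotypes — a library-total
## denominator deflates every fold change when one genotype loses real
## peak signal.
effective_library <- function(track) {
  tot <- 0
  for (v in track$depth) {
    r <- rle(v > 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) next
    s <- starts[keep]; e <- ends[keep]
    tot <- tot + sum(vapply(seq_along(s), function(i) {
      seg <- v[s[i]:e[i]]
      median(seg) * length(seg)
    }, numeric(1)))
  }
  if (tot <= 0) return(track$library_size)
  tot / track$read_length
}

## mean per-million (background-equivalent) coverage of each peak interval
peak_signal <- function(track, peaks) {
  norm <- 1e6 / effective_library(track)
  cs <- lapply(track$depth, function(v) c(0, cumsum(v)))
  out <- numeric(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    i <- which(peaks$chrom == ch)
    out[i] <- (cs[[ch]][peaks$end[i] + 1L] - cs[[ch]][peaks$start[i] + 1L]) /
      (peaks$end[i] - peaks$start[i])
  }
  norm * out
}

#' Classify peaks as reduced in the Tet-null genotype
#'
#' For each peak, the wild-type and Tet-null signals are the mean IP
#' coverage over the peak interval, normalized to per-million
#' background-equivalent library scale (median covered depth times covered
#' length; robust to global enrichment loss in the Tet-null genotype) and
#' averaged across replicates; `fold_change = wt / max(ko, pseudocount)`
#' and a peak is
#' reduced iff `fold_change >= fold_threshold`. A per-peak p-value comes
#' from a two-sample moderated-t-style test on replicate-level log2
#' signals, with per-peak variances shrunk toward the global mean variance
#' (`NA` with a single replicate per genotype). The classifier is
#' scale-invariant: multiplying all tracks of both genotypes by a constant
#' changes no call.
#'
#' @param peaks Peak tibble (typically wild-type [call_rna_peaks()] output).
#' @param wt_tracks,ko_tracks Lists of IP [coverage_track()]s, one per
#'   replicate.
#' @param config A [reduction_config()].
#' @return Tibble of reduced-peak calls: peak/transcript ids, `wt_signal`,
#'   `ko_signal`, `fold_change`, `is_reduced`, `p_value`.
#' @export
classify_reduced <- function(peaks, wt_tracks, ko_tracks,
                             config = reduction_config()) {
  stopifnot(inherits(config, "reduction_config"))
  if (length(wt_tracks) < 1 || length(ko_tracks) < 1) {
    abort("classify_reduced: need >= 1 replicate per genotype")
  }
  wt_mat <- vapply(wt_tracks, peak_signal, numeric(nrow(peaks)), peaks = peaks)
  ko_mat <- vapply(ko_tracks, peak_signal, numeric(nrow(peaks)), peaks = peaks)
  wt_mat <- matrix(wt_mat, nrow = nrow(peaks))
  ko_mat <- matrix(ko_mat, nrow = nrow(peaks))
  wt <- rowMeans(wt_mat)
  ko <- rowMeans(ko_mat)
  fc <- wt / pmax(ko, config$pseudocount)

  n1 <- ncol(wt_mat); n2 <- ncol(ko_mat)
  d <- n1 + n2 - 2
  p_value <- rep(NA_real_, nrow(peaks))
  if (d > 0 && nrow(peaks) > 0) {
    lw <- log2(wt_mat + config$pseudocount)
    lk <- log2(ko_mat + config$pseudocount)
    s2 <- (apply(lw, 1, var) * (n1 - 1) + apply(lk, 1, var) * (n2 - 1)) / d
    s2[is.na(s2)] <- 0
    s2_0 <- mean(s2)
    d0 <- config$prior_df
    s2_mod <- (d0 * s2_0 + d * s2) / (d0 + d)
    tstat <- (rowMeans(lw) - rowMeans(lk)) /
      sqrt(pmax(s2_mod, 1e-12) * (1 / n1 + 1 / n2))
    p_value <- 2 * pt(-abs(tstat), df = d + d0)
  }
  tibble(
    peak_id = peaks$name,
    transcript_id = if ("transcript_id" %in% names(peaks)) peaks$transcript_id else NA_character_,
    gene_id = if ("gene_id" %in% names(peaks)) peaks$gene_id else NA_character_,
    wt_signal = wt, ko_signal = ko, fold_change = fc,
    is_reduced = fc >= config$fold_threshold,
    p_value = p_value
  )
}

#' Per-transcript reduction summary
#'
#' A transcript is flagged reduced iff at least one of its peaks is
#' reduced. When the calls carry an `element` column the per-element
#' reduction fractions are also reported (the CDS/intron versus UTR
#' readout).
#'
#' @param reduced_calls Output of [classify_reduced()], optionally with an
#'   `element` column.
#' @return Tibble with `transcript_id`, `gene_id`, `reduced`; attributes
#'   `fraction_reduced` (overall flagged fraction) and `by_element`
#'   (per-element peak reduction fractions, when available).
#' @export
transcript_reduction_summary <- function(reduced_calls) {
  out <- reduced_calls %>%
    group_by(.data$transcript_id, .data$gene_id) %>%
    summarise(reduced = any(.data$is_reduced), .groups = "drop")
  by_element <- NULL
  if ("element" %in% names(reduced_calls)) {
    by_element <- reduced_calls %>%
      group_by(.data$element) %>%
      summarise(n = dplyr::n(), n_reduced = sum(.data$is_reduced),
                fraction_reduced = mean(.data$is_reduced), .groups = "drop")
  }
  structure(out,
            fraction_reduced = if (nrow(out) > 0) mean(out$reduced) else NA_real_,
            by_element = by_element,
            class = class(out))
}
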