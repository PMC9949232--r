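#' Peak-calling configuration
#'
#' Two dialects mirror the two stages of the study design. The `embryo`
#' dialect emits all candidate peaks (candidate p-value 1e-2, effective
#' genome size 1.2e8 on the real genome) and leaves the strict selection to
#' [apply_peak_filters()]. The `larva` dialect additionally applies a
#' Benjamini-Hochberg q-value threshold (0.05), with q-values computed over
#' the per-base p-values of the whole genome so the multiplicity correction
#' reflects every tested position, and resizes each peak to 100 bp on both
#' sides of its summit.
#'
#' @param dialect `"embryo"` or `"larva"`.
#' @param candidate_pvalue Per-summit Poisson p-value below which a region
#'   becomes a candidate peak.
#' @param effective_genome_size Denominator of the genome-wide background
#'   rate; `NULL` (default) uses the actual track length. The study presets
#'   are 1.2e8 (embryo) and 142573024 (larva) for the fly genome.
#' @param ext_size Fragment extension footprint (bp); candidate regions
#'   separated by gaps smaller than this are merged.
#' @param local_windows Window sizes (bp) of the local background rates; the
#'   expected background at each base is the maximum of the genome-wide rate
#'   and these local rates on the (scaled) input track.
#' @param q_threshold BH q-value cutoff applied by the larva dialect.
#' @param summit_flank Resize half-width (bp) applied by the larva dialect.
#' @return A list of class `peak_call_config`.
#' @export
peak_call_config <- function(dialect = c("embryo", "larva"),
                             candidate_pvalue = 1e-2,
                             effective_genome_size = NULL,
                             ext_size = 147,
                             local_windows = c(1000, 10000),
                             q_threshold = 0.05,
                             summit_flank = 100) {
  dialect <- match.arg(dialect)
  if (candidate_pvalue <= 0 || candidate_pvalue >= 1) {
    abort("peak_call_config: candidate_pvalue must be in (0, 1)")
  }
  if (q_threshold <= 0 || q_threshold >= 1) {
    abort("peak_call_config: q_threshold must be in (0, 1)")
  }
  if (ext_size <= 0 || any(local_windows <= 0)) {
    abort("peak_call_config: sizes must be > 0")
  }
  structure(list(dialect = dialect, candidate_pvalue = candidate_pvalue,
                 effective_genome_size = effective_genome_size,
                 ext_size = ext_size, local_windows = local_windows,
                 q_threshold = q_threshold, summit_flank = summit_flank),
            class = "peak_call_config")
}

#' Poisson enrichment tail probability
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Poisson(lambda)` — the
#' enrichment p-value of an observed IP count against its expected local
#' background. Monotone decreasing in `k` and increasing in `lambda`.
#'
#' @param k Non-negative integer observed count(s).
#' @param lambda Positive expected background count(s).
#' @return Numeric vector of tail probabilities in (0, 1].
#' @examples
#' poisson_enrichment_pvalue(0, 5)   # 1
#' poisson_enrichment_pvalue(1, 1)   # 1 - exp(-1)
#' @export
poisson_enrichment_pvalue <- function(k, lambda) {
  if (any(lambda <= 0)) abort("poisson_enrichment_pvalue: lambda must be > 0")
  if (any(k < 0) || any(k != round(k))) {
    abort("poisson_enrichment_pvalue: k must be a non-negative integer")
  }
  ppois(k - 1, lambda, lower.tail = FALSE)
}

## local-background expected depth at every base of one chromosome
local_lambda <- function(scaled_input, genome_rate, windows) {
  lam <- rep(genome_rate, length(scaled_input))
  for (w in windows) lam <- pmax(lam, running_mean(scaled_input, w))
  pmax(lam, 1e-9)
}

## merge candidate runs separated by < gap into [start, end) regions
merge_candidate_runs <- function(cand, gap) {
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths       # 0-based
  keep <- r$values
  if (!any(keep)) return(tibble(start = integer(0), end = integer(0)))
  s <- starts[keep]; e <- ends[keep]
  if (length(s) > 1) {
    new_run <- c(TRUE, s[-1] - e[-length(e)] >= gap)
    grp <- cumsum(new_run)
    s <- tapply(s, grp, min)
    e <- tapply(e, grp, max)
  }
  tibble(start = as.integer(s), end = as.integer(e))
}

#' Call peaks from IP and input coverage
#'
#' A local-background Poisson caller. The input track is scaled to the IP
#' library size; the expected background at each base is the maximum of the
#' genome-wide rate and local-window rates on the scaled input (and any
#' per-base `lambda_floor` supplied by the RNA caller). Bases whose IP depth
#' beats the candidate p-value are merged into regions when separated by
#' less than `ext_size`; each region's summit is the leftmost IP-depth
#' argmax, its p-value the Poisson tail at the summit, its fold enrichment
#' the summit IP depth over the summit background, and its read count the IP
#' coverage integral over the region divided by the read length. The larva
#' dialect then applies a BH q-value cutoff and resizes peaks to
#' `summit_flank` bp on both sides of the summit.
#'
#' @param ip,input [coverage_track()]s with matching sequences.
#' @param config A [peak_call_config()].
#' @param mask Optional named list of logical vectors (one per sequence)
#'   restricting candidate bases, e.g. transcript footprints.
#' @param lambda_floor Optional named list of numeric vectors with an
#'   additional per-base floor on the expected background.
#' @param global_background Use the genome-wide and local-window input
#'   rates (default). The RNA caller disables this and relies on
#'   `lambda_floor` alone, so each transcript is tested against its own
#'   expression-matched background.
#' @param sample_id Label recorded on the returned peaks.
#' @return A peak tibble (see [peak_table()]), sorted by position.
#' @export
call_peaks <- function(ip, input, config = peak_call_config(),
                       mask = NULL, lambda_floor = NULL,
                       global_background = TRUE,
                       sample_id = NA_character_) {
  stopifnot(is_coverage_track(ip), is_coverage_track(input),
            inherits(config, "peak_call_config"))
  if (!identical(ip$chrom_sizes, input$chrom_sizes)) {
    abort("call_peaks: IP and input tracks must cover the same sequences")
  }
  if (input$library_size <= 0) abort("call_peaks: input library size is zero")
  if (ip$library_size <= 0) {
    warn("call_peaks: empty IP coverage; returning no peaks")
    return(empty_peak_table())
  }
  ## scale input to the IP background level: ratio of median per-base depths
  ## (robust to the IP's enrichment mass), falling back to the library-size
  ## ratio when a median is zero (sparse coverage)
  med_ip <- median(unlist(ip$depth, use.names = FALSE))
  med_in <- median(unlist(input$depth, use.names = FALSE))
  scale <- if (med_ip > 0 && med_in > 0) med_ip / med_in else
    ip$library_size / input$library_size
  egs <- config$effective_genome_size %||% sum(ip$chrom_sizes)
  genome_rate <- scale * sum(vapply(input$depth, sum, numeric(1))) / egs

  per_chrom <- function(ch) {
    ipd <- ip$depth[[ch]]
    lam <- if (global_background) {
      local_lambda(input$depth[[ch]] * scale, genome_rate,
                   config$local_windows)
    } else {
      rep(1e-9, length(ipd))
    }
    if (!is.null(lambda_floor)) lam <- pmax(lam, lambda_floor[[ch]])
    pv <- ppois(round(ipd) - 1, lam, lower.tail = FALSE)
    cand <- pv < config$candidate_pvalue
    if (!is.null(mask)) cand <- cand & mask[[ch]]
    regions <- merge_candidate_runs(cand, config$ext_size)
    if (nrow(regions) == 0) return(list(peaks = NULL, pvec = pv))
    summit <- purrr::map2_int(regions$start, regions$end, function(s, e) {
      seg <- ipd[(s + 1L):e]
      s + which.max(seg) - 1L          # ties -> leftmost
    })
    list(peaks = tibble(
      chrom = ch, start = regions$start, end = regions$end,
      summit = summit,
      pvalue = pmax(pv[summit + 1L], 1e-320),
      fold_enrichment = ipd[summit + 1L] / lam[summit + 1L],
      reads = region_sums(ipd, regions$start, regions$end) / ip$read_length
    ), pvec = pv)
  }
  res <- purrr::map(names(ip$depth), per_chrom)
  names(res) <- names(ip$depth)
  out <- bind_rows(purrr::compact(purrr::map(res, "peaks")))
  if (nrow(out) == 0) return(empty_peak_table())

  qvalue <- rep(NA_real_, nrow(out))
  if (config$dialect == "larva") {
    ## genome-wide q-values: BH over the per-base p-values (MACS-style), so
    ## the multiplicity reflects every tested position, not just the
    ## max-selected candidate summits
    all_p <- unlist(purrr::map(res, "pvec"), use.names = FALSE)
    offsets <- cumsum(c(0, head(ip$chrom_sizes, -1)))
    names(offsets) <- names(ip$chrom_sizes)
    q_all <- p.adjust(all_p, method = "BH")
    qvalue <- q_all[offsets[out$chrom] + out$summit + 1L]
    keep <- qvalue < config$q_threshold
    out <- out[keep, ]
    qvalue <- qvalue[keep]
    if (nrow(out) == 0) return(empty_peak_table())
    sizes <- ip$chrom_sizes[out$chrom]
    out$start <- pmax(0L, out$summit - config$summit_flank)
    out$end <- pmin(as.integer(sizes), out$summit + config$summit_flank)
  }
  peak_table(out$chrom, out$start, out$end, summit = out$summit,
             name = sprintf("%s_peak_%d",
                            ifelse(is.na(sample_id), "epitet", sample_id),
                            seq_len(nrow(out))),
             pvalue = out$pvalue, qvalue = qvalue,
             fold_enrichment = out$fold_enrichment, reads = out$reads,
             sample_id = sample_id) %>%
    arrange(.data$chrom, .data$start)
}

#' Peak selection criteria
#'
#' The study's peak filters: p-value below `max_pvalue` (1e-5), fold
#' enrichment over control strictly greater than `min_fold_enrichment` (10)
#' and read count strictly greater than `min_reads` (50). Read counts are
#' whole-peak IP read equivalents.
#'
#' @param max_pvalue Exclusive upper bound on the Poisson p-value.
#' @param min_fold_enrichment Exclusive lower bound on fold enrichment.
#' @param min_reads Exclusive lower bound on supporting reads.
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(max_pvalue = 1e-5, min_fold_enrichment = 10,
                            min_reads = 50) {
  if (max_pvalue <= 0 || max_pvalue >= 1) {
    abort("filter_criteria: max_pvalue must be in (0, 1)")
  }
  if (min_fold_enrichment <= 0 || min_reads <= 0) {
    abort("filter_criteria: bounds must be > 0")
  }
  structure(list(max_pvalue = max_pvalue,
                 min_fold_enrichment = min_fold_enrichment,
                 min_reads = min_reads),
            class = "filter_criteria")
}

#' Apply peak selection criteria
#'
#' Retains exactly the peaks with `pvalue < max_pvalue`,
#' `fold_enrichment > min_fold_enrichment` and `reads > min_reads`
#' (both bounds strict). Filtering is monotone: relaxing any criterion
#' never removes a retained peak.
#'
#' @param peaks A peak tibble carrying `pvalue`, `fold_enrichment`, `reads`.
#' @param criteria A [filter_criteria()].
#' @return The retained peak tibble.
#' @export
apply_peak_filters <- function(peaks, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  for (fld in c("pvalue", "fold_enrichment", "reads")) {
    bad <- which(is.na(peaks[[fld]]))
    if (length(bad) > 0) {
      abort(sprintf("apply_peak_filters: peak '%s' is missing field '%s'",
                    peaks$name[bad[1]], fld))
    }
  }
  peaks %>%
    filter(.data$pvalue < criteria$max_pvalue,
           .data$fold_enrichment > criteria$min_fold_enrichment,
           .data$reads > criteria$min_reads)
}

#' Reproducible peaks between two replicates at a summit window
#'
#' A peak in `peaks_a` is reproducible iff some peak in `peaks_b` on the
#' same sequence has a summit within `w` bp (window = maximum
#' summit-to-summit distance). Each A-peak reports its nearest B summit
#' (ties broken to the leftmost B summit).
#'
#' @param peaks_a,peaks_b Peak tibbles.
#' @param w Window size in bp (>= 0).
#' @return The reproducible subset of `peaks_a` with columns
#'   `matched_summit` and `summit_distance` added.
#' @export
overlap_at_window <- function(peaks_a, peaks_b, w) {
  stopifnot(w >= 0)
  if (nrow(peaks_a) == 0 || nrow(peaks_b) == 0) {
    return(mutate(peaks_a[0, ], matched_summit = integer(0),
                  summit_distance = integer(0)))
  }
  nearest <- purrr::map(seq_len(nrow(peaks_a)), function(i) {
    bs <- sort(peaks_b$summit[peaks_b$chrom == peaks_a$chrom[i]])
    if (length(bs) == 0) return(c(NA_integer_, NA_integer_))
    d <- abs(bs - peaks_a$summit[i])
    j <- which(d == min(d))[1]        # ties -> leftmost B summit
    c(bs[j], d[j])
  })
  out <- peaks_a %>%
    mutate(matched_summit = purrr::map_int(nearest, 1),
           summit_distance = purrr::map_int(nearest, 2))
  filter(out, !is.na(.data$summit_distance), .data$summit_distance <= w)
}

#' Summit-window saturation analysis
#'
#' Counts reproducible peaks between two replicates for a ladder of window
#' sizes and selects the smallest window whose count is within a relative
#' tolerance of the count at the largest window — the point where the curve
#' saturates.
#'
#' @param peaks_a,peaks_b Peak tibbles.
#' @param windows Ascending window sizes (bp); default the 50-300 bp ladder.
#' @param tolerance Relative tolerance defining saturation (default 0.02).
#' @return A tibble of class `saturation_curve` with columns `window` and
#'   `n_overlapping`, and attribute `selected_window`.
#' @export
saturation_analysis <- function(peaks_a, peaks_b,
                                windows = c(50, 100, 150, 200, 250, 300),
                                tolerance = 0.02) {
  if (length(windows) < 2 || is.unsorted(windows, strictly = TRUE)) {
    abort("saturation_analysis: need >= 2 strictly ascending windows")
  }
  counts <- vapply(windows, function(w) nrow(overlap_at_window(peaks_a, peaks_b, w)),
                   integer(1))
  stopifnot(!is.unsorted(counts))  # non-decreasing by construction
  ref <- counts[length(counts)]
  sel <- windows[which(counts >= (1 - tolerance) * ref)[1]]
  structure(tibble(window = windows, n_overlapping = counts),
            selected_window = sel,
            class = c("saturation_curve", "tbl_df", "tbl", "data.frame"))
}

#' Consensus peaks across replicates
#'
#' Returns the peaks of the first replicate that are reproducible against
#' every other replicate at window `w`; the consensus summit is the
#' first-replicate summit.
#'
#' @param peaksets List of >= 2 peak tibbles (first = reference replicate).
#' @param w Summit window in bp (default 250, the saturation point of the
#'   study's ladder).
#' @return Peak tibble of consensus peaks.
#' @export
multi_replicate_consensus <- function(peaksets, w = 250) {
  if (!is.list(peaksets) || length(peaksets) < 2) {
    abort("multi_replicate_consensus: need >= 2 peak sets")
  }
  out <- peaksets[[1]]
  for (other in peaksets[-1]) {
    out <- overlap_at_window(out, other, w) %>%
      select(-"matched_summit", -"summit_distance")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
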