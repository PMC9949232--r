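#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the study
#' conditions the analysis assumes: a compact gene-dense genome, Tet ChIP
#' coverage with promoter-enriched planted peaks carrying a CG-rich motif,
#' H3K4me3 peaks co-occurring with a configurable probability, hMeRIP
#' coverage over transcript footprints in wild-type and Tet-null genotypes
#' with 45% of modified transcripts carrying a reduced peak, and
#' negative-binomial RNA-seq counts with a small differential-expression
#' fraction.
#'
#' @param genome_length Total genome length in bp, split evenly over
#'   `n_chroms` sequences.
#' @param n_chroms Number of chromosomes.
#' @param n_genes Number of genes (one transcript per gene).
#' @param exons_per_gene Length-2 integer range of exon counts per gene.
#' @param exon_length,intron_length,utr5_length,utr3_length Length-2 ranges
#'   (bp) for exon/intron lengths and UTR lengths in exonic bases.
#' @param expr_sdlog Log-sd of the lognormal baseline expression level.
#' @param min_expression Floor on the expression level so every transcript
#'   is detectably expressed in the RNA assays.
#' @param read_length Read length (bp) for library-size equivalents.
#' @param chip_depth,hmerip_depth Mean background depth per base. For hMeRIP
#'   the per-transcript baseline is `hmerip_depth * expression`.
#' @param n_chip_peaks Number of planted Tet ChIP peaks.
#' @param promoter_peak_fraction Fraction of ChIP peaks centred in promoter
#'   windows.
#' @param chip_fe_range Length-2 range of planted ChIP fold enrichments.
#' @param summit_jitter_sd Per-replicate sd (bp) of the summit position.
#' @param ext_size Half-width (bp) of the triangular peak-shape kernel,
#'   honouring the 147 bp fragment-extension convention.
#' @param h3k4me3_cooccurrence_prob Probability that a planted Tet peak
#'   carries a co-occurring H3K4me3 peak.
#' @param motif_fg_fraction Fraction of planted peaks with the consensus
#'   motif planted near the summit (both assays).
#' @param chip_motif CG-rich DNA 6-mer planted in ChIP peaks.
#' @param rna_motif UC-rich motif (DNA alphabet) planted on the sense strand
#'   of hMeRIP peaks.
#' @param n_rna_peaks Number of planted 5hmrC RNA peaks; peaks are spread
#'   over transcripts evenly before any transcript receives a second one.
#' @param rna_fe_range Length-2 range of planted RNA-peak fold enrichments.
#' @param element_weights Named weights (`utr5`, `cds`, `intron`, `utr3`)
#'   for RNA-peak placement among transcript structural elements.
#' @param reduced_transcript_fraction Fraction of modified transcripts with
#'   at least one peak reduced in the Tet-null genotype.
#' @param reduction_factor Factor by which the Tet-null IP coverage over a
#'   reduced peak's footprint is divided (>= 1; 1 means no reduction).
#' @param nb_dispersion Negative-binomial dispersion of the count generator.
#' @param de_fraction Fraction of genes differentially expressed in
#'   Tet-null.
#' @param de_fold_change Fold change applied to DE genes.
#' @param de_up_fraction Fraction of DE genes shifted up (the remainder
#'   down).
#' @param count_scale Mean count of a gene at expression level 1.
#' @param chip_replicates,hmerip_replicates,rna_replicates Replicates per
#'   condition for each assay.
#' @param min_peak_separation Minimum distance (bp) between planted ChIP
#'   summits.
#' @param edge_margin Unused margin (bp) kept free at chromosome ends.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 5e5,
                       n_chroms = 2,
                       n_genes = 60,
                       exons_per_gene = c(2, 4),
                       exon_length = c(150, 400),
                       intron_length = c(60, 200),
                       utr5_length = c(80, 150),
                       utr3_length = c(100, 250),
                       expr_sdlog = 1,
                       min_expression = 0.2,
                       read_length = 50,
                       chip_depth = 10,
                       hmerip_depth = 20,
                       n_chip_peaks = 100,
                       promoter_peak_fraction = 0.6,
                       chip_fe_range = c(10, 20),
                       summit_jitter_sd = 40,
                       ext_size = 147,
                       h3k4me3_cooccurrence_prob = 0.4,
                       motif_fg_fraction = 0.6,
                       chip_motif = "CGCGCG",
                       rna_motif = "TCTCCT",
                       n_rna_peaks = 80,
                       rna_fe_range = c(6, 12),
                       element_weights = c(utr5 = 0.1, cds = 0.5,
                                           intron = 0.3, utr3 = 0.1),
                       reduced_transcript_fraction = 0.45,
                       reduction_factor = 1.5,
                       nb_dispersion = 0.05,
                       de_fraction = 0.06,
                       de_fold_change = 4,
                       de_up_fraction = 0.8,
                       count_scale = 200,
                       chip_replicates = 3,
                       hmerip_replicates = 2,
                       rna_replicates = 3,
                       min_peak_separation = 800,
                       edge_margin = 2000) {
  cfg <- as.list(environment())
  fracs <- c(promoter_peak_fraction, h3k4me3_cooccurrence_prob,
             motif_fg_fraction, reduced_transcript_fraction, de_fraction,
             de_up_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("sim_config: fractions must be in [0, 1]")
  if (reduction_factor < 1) abort("sim_config: reduction_factor must be >= 1")
  if (chip_depth <= 0 || hmerip_depth <= 0) abort("sim_config: depths must be > 0")
  if (abs(sum(element_weights)) < 1e-12) abort("sim_config: element_weights sum to 0")
  if (!all(c("utr5", "cds", "intron", "utr3") %in% names(element_weights))) {
    abort("sim_config: element_weights needs names utr5, cds, intron, utr3")
  }
  cfg$element_weights <- element_weights / sum(element_weights)
  structure(cfg, class = "sim_config")
}

## deterministic per-module seed stream, kept below 2^31
fork_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7 + k * 1000003) %% 2147483647)
}

empty_transcripts <- function() {
  tibble(transcript_id = character(0), gene_id = character(0),
         chrom = character(0), start = integer(0), end = integer(0),
         strand = character(0), tss = integer(0), tts = integer(0),
         exons = list(), cds = list(), expr = numeric(0))
}

## consecutive-run encoding of a sorted integer position vector -> intervals
positions_to_intervals <- function(pos) {
  if (length(pos) == 0) return(tibble(start = integer(0), end = integer(0)))
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  tibble(start = pos[head(brk, -1) + 1L], end = pos[brk[-1]] + 1L)
}

build_gene_structure <- function(cfg) {
  n_ex <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1)
  ex_len <- round(runif(n_ex, cfg$exon_length[1], cfg$exon_length[2]))
  in_len <- if (n_ex > 1) round(runif(n_ex - 1, cfg$intron_length[1],
                                      cfg$intron_length[2])) else integer(0)
  starts <- cumsum(c(0, head(ex_len, -1) + in_len))
  list(exons = tibble(start = as.integer(starts),
                      end = as.integer(starts + ex_len)),
       span = as.integer(starts[n_ex] + ex_len[n_ex]))
}

#' Simulate a toy genome and annotation
#'
#' Places `n_genes` non-overlapping genes (random strand, one transcript
#' each) with exons, introns, UTRs and a CDS, assigns each a lognormal
#' baseline expression level, and draws a uniform-random sequence (planted
#' motifs are added later by [simulate_run()]).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the output is byte-identical given the seed.
#' @return A list with `transcripts` (tibble, see [read_gtf()], plus an
#'   `expr` column), `genome` (a [Biostrings::DNAStringSet]) and
#'   `chrom_sizes` (named integer vector).
#' @export
simulate_genome <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  per <- config$genome_length %/% config$n_chroms
  chrom_sizes <- setNames(rep(as.integer(per), config$n_chroms),
                          sprintf("chr%d", seq_len(config$n_chroms)))
  genome <- Biostrings::DNAStringSet(vapply(
    chrom_sizes,
    function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                      collapse = ""),
    character(1)
  ))
  names(genome) <- names(chrom_sizes)
  if (config$n_genes == 0) {
    return(list(transcripts = empty_transcripts(), genome = genome,
                chrom_sizes = chrom_sizes))
  }

  rows <- vector("list", config$n_genes)
  gi <- 1L
  for (ch in names(chrom_sizes)) {
    cursor <- config$edge_margin
    limit <- chrom_sizes[[ch]] - config$edge_margin
    while (gi <= config$n_genes) {
      gap <- round(runif(1, 200, 1500))
      gs <- build_gene_structure(config)
      gstart <- as.integer(cursor + gap)
      if (gstart + gs$span > limit) break
      strand <- sample(c("+", "-"), 1)
      exons <- tibble(start = gs$exons$start + gstart,
                      end = gs$exons$end + gstart)
      pos <- unlist(purrr::map2(exons$start, exons$end - 1L, seq))
      total <- length(pos)
      u5 <- round(runif(1, config$utr5_length[1], config$utr5_length[2]))
      u3 <- round(runif(1, config$utr3_length[1], config$utr3_length[2]))
      if (u5 + u3 > total - 60) {  # keep a >= 60 bp CDS
        u5 <- max(20L, (total - 60L) %/% 3L)
        u3 <- u5
      }
      cds_pos <- if (strand == "+") {
        pos[(u5 + 1):(total - u3)]
      } else {
        pos[(u3 + 1):(total - u5)]
      }
      gend <- as.integer(gstart + gs$span)
      rows[[gi]] <- tibble(
        transcript_id = sprintf("tx%04d", gi),
        gene_id = sprintf("g%04d", gi),
        chrom = ch, start = gstart, end = gend, strand = strand,
        tss = if (strand == "-") gend - 1L else gstart,
        tts = if (strand == "-") gstart else gend - 1L,
        exons = list(exons),
        cds = list(positions_to_intervals(cds_pos))
      )
      cursor <- gend
      gi <- gi + 1L
    }
  }
  placed <- sum(!vapply(rows, is.null, logical(1)))
  if (placed < config$n_genes) {
    abort(sprintf(paste0(
      "simulate_genome: could only place %d of %d genes in %d bp; ",
      "increase genome_length to >= %d or reduce n_genes"),
      placed, config$n_genes, config$genome_length,
      ceiling(config$genome_length * config$n_genes / max(placed, 1))))
  }
  transcripts <- bind_rows(rows)
  transcripts$expr <- pmax(config$min_expression,
                           rlnorm(nrow(transcripts), 0, config$expr_sdlog))
  list(transcripts = transcripts, genome = genome, chrom_sizes = chrom_sizes)
}

## add amp * triangular kernel (half-width hw) centred at `center` (0-based)
## to mu, truncated to [lo, hi) (0-based half-open bounds)
add_triangle <- function(mu, center, amp, hw, lo = 0L, hi = length(mu)) {
  a <- max(lo, center - hw + 1L)
  b <- min(hi - 1L, center + hw - 1L)
  if (a > b) return(mu)
  d <- abs(seq(a, b) - center)
  idx <- (a:b) + 1L
  mu[idx] <- mu[idx] + amp * (1 - d / hw)
  mu
}

zero_depth <- function(chrom_sizes) {
  setNames(lapply(chrom_sizes, function(n) numeric(n)), names(chrom_sizes))
}

#' Simulate Tet ChIP IP/input coverage with planted peaks
#'
#' Background coverage is Poisson at `chip_depth`; each planted peak adds a
#' triangular enrichment (summit depth `fold_enrichment * chip_depth`) whose
#' replicate summits are jittered with sd `summit_jitter_sd`. A fraction of
#' peaks is centred in promoter windows, and an H3K4me3 peak set is emitted
#' with the configured co-occurrence probability (plus unrelated promoter
#' H3K4me3 peaks).
#'
#' @param config A [sim_config()].
#' @param transcripts Transcript tibble from [simulate_genome()].
#' @param chrom_sizes Named integer vector of sequence lengths.
#' @param seed Integer seed.
#' @return A list with `ip` and `input` (lists of [coverage_track()], one
#'   per replicate), `h3k4me3` (interval tibble) and `truth` (one row per
#'   planted peak: summit, fold enrichment, promoter/H3K4me3/motif flags).
#' @export
simulate_chip <- function(config, transcripts, chrom_sizes, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_chip_peaks
  hw <- config$ext_size
  if (n == 0) {
    truth <- tibble(peak_id = character(0), chrom = character(0),
                    summit = integer(0), fold_enrichment = numeric(0),
                    promoter = logical(0), transcript_id = character(0),
                    h3k4me3 = logical(0), has_motif = logical(0),
                    motif_pos = integer(0))
  } else {
    n_prom <- round(config$promoter_peak_fraction * n)
    if (n_prom > nrow(transcripts)) {
      abort("simulate_chip: more promoter peaks requested than transcripts")
    }
    ## promoter summits on distinct transcripts, honouring the separation;
    ## multiple passes redraw the within-window offset, and the separation
    ## is progressively relaxed (ultimately to zero) when the annotation is
    ## too dense for the requested spacing — overlapping promoter peaks are
    ## legitimate for dense layouts and simply merge at calling time
    cand_order <- sample.int(nrow(transcripts))
    prom_rows <- list()
    used <- character(0)
    sep <- config$min_peak_separation
    for (pass in 1:60) {
      if (length(prom_rows) >= n_prom) break
      if (pass %% 10 == 0) sep <- sep %/% 2
      if (pass >= 55) sep <- 0
      for (ti in cand_order) {
        if (length(prom_rows) >= n_prom) break
        tx <- transcripts[ti, ]
        if (tx$transcript_id %in% used) next
        sgn <- if (tx$strand == "-") -1L else 1L
        s <- as.integer(tx$tss - sgn * round(runif(1, -50, 600)))
        prev <- purrr::map_int(purrr::keep(prom_rows, ~ .x$chrom == tx$chrom),
                               "summit")
        if (length(prev) == 0 || min(abs(prev - s)) >= sep) {
          prom_rows[[length(prom_rows) + 1]] <-
            tibble(chrom = tx$chrom, summit = s, promoter = TRUE,
                   transcript_id = tx$transcript_id)
          used <- c(used, tx$transcript_id)
        }
      }
    }
    if (length(prom_rows) < n_prom) {
      abort("simulate_chip: cannot place promoter peaks; reduce n_chip_peaks or promoter_peak_fraction")
    }
    prom_summits <- bind_rows(prom_rows)
    ## background (non-promoter) summits: uniform, min separation enforced
    placed <- prom_summits[, c("chrom", "summit")]
    bg <- list()
    tries <- 0
    while (length(bg) < n - n_prom) {
      tries <- tries + 1
      if (tries > 200 * n) abort("simulate_chip: cannot place peaks with the requested separation")
      ch <- sample(names(chrom_sizes), 1)
      pos <- as.integer(round(runif(1, config$edge_margin,
                                    chrom_sizes[[ch]] - config$edge_margin)))
      same <- placed$summit[placed$chrom == ch]
      if (length(same) == 0 || min(abs(same - pos)) >= config$min_peak_separation) {
        bg[[length(bg) + 1]] <- tibble(chrom = ch, summit = pos)
        placed <- bind_rows(placed, tibble(chrom = ch, summit = pos))
      }
    }
    bg_summits <- if (length(bg) > 0) {
      bind_rows(bg) %>% mutate(promoter = FALSE, transcript_id = NA_character_)
    } else prom_summits[0, ]
    truth <- bind_rows(prom_summits, bg_summits) %>%
      mutate(
        peak_id = sprintf("chip_peak_%03d", row_number()),
        fold_enrichment = runif(n(), config$chip_fe_range[1], config$chip_fe_range[2]),
        h3k4me3 = as.logical(rbinom(n(), 1, config$h3k4me3_cooccurrence_prob)),
        has_motif = as.logical(rbinom(n(), 1, config$motif_fg_fraction)),
        motif_pos = as.integer(.data$summit + sample(-20:20, n(), replace = TRUE))
      ) %>%
      select("peak_id", "chrom", "summit", "fold_enrichment", "promoter",
             "transcript_id", "h3k4me3", "has_motif", "motif_pos")
  }

  ## realized (jittered) summit of every peak in every replicate; the truth
  ## records these so recovery can be scored against what was planted
  rep_summits <- purrr::map(seq_len(config$chip_replicates), function(r) {
    if (nrow(truth) == 0) return(integer(0))
    jit <- round(rnorm(nrow(truth), 0, config$summit_jitter_sd))
    vapply(seq_len(nrow(truth)), function(i) {
      as.integer(min(max(truth$summit[i] + jit[i], hw),
                     chrom_sizes[[truth$chrom[i]]] - hw))
    }, integer(1))
  })
  make_rep <- function(r) {
    mu <- zero_depth(chrom_sizes)
    for (ch in names(mu)) mu[[ch]] <- rep(config$chip_depth, chrom_sizes[[ch]])
    for (i in seq_len(nrow(truth))) {
      ch <- truth$chrom[i]
      mu[[ch]] <- add_triangle(mu[[ch]], rep_summits[[r]][i],
                               config$chip_depth * (truth$fold_enrichment[i] - 1),
                               hw)
    }
    ip <- lapply(mu, function(m) as.numeric(rpois(length(m), m)))
    input <- lapply(chrom_sizes, function(nn) as.numeric(rpois(nn, config$chip_depth)))
    list(ip = coverage_track(ip, config$read_length),
         input = coverage_track(input, config$read_length))
  }
  reps <- lapply(seq_len(config$chip_replicates), make_rep)
  replicate_summits <- if (nrow(truth) > 0) {
    bind_rows(purrr::imap(rep_summits, function(s, r) {
      tibble(peak_id = truth$peak_id, replicate = r, summit = s)
    }))
  } else {
    tibble(peak_id = character(0), replicate = integer(0), summit = integer(0))
  }

  ## H3K4me3 peak set: co-occurring peaks plus unrelated promoter peaks
  h3_cooc <- truth %>%
    filter(.data$h3k4me3) %>%
    transmute(chrom = .data$chrom,
              start = pmax(0L, .data$summit - 300L),
              end = .data$summit + 300L)
  free_tx <- transcripts %>% filter(!.data$transcript_id %in% truth$transcript_id)
  n_extra <- min(nrow(free_tx), round(0.3 * max(n, 1)))
  extra_tx <- if (n_extra > 0) free_tx[sample.int(nrow(free_tx), n_extra), ] else free_tx[0, ]
  h3_extra <- transmute(extra_tx, chrom = .data$chrom,
                        start = pmax(0L, .data$tss - 300L),
                        end = .data$tss + 300L)
  h3 <- bind_rows(h3_cooc, h3_extra) %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(name = sprintf("h3k4me3_%03d", row_number()))

  list(ip = lapply(reps, `[[`, "ip"),
       input = lapply(reps, `[[`, "input"),
       h3k4me3 = h3, truth = truth, replicate_summits = replicate_summits)
}

## structural element base positions (genomic, 0-based) for one transcript
transcript_element_positions <- function(tx) {
  ex <- tx$exons[[1]]
  cd <- tx$cds[[1]]
  exonic <- unlist(purrr::map2(ex$start, ex$end - 1L, seq))
  all_pos <- seq(tx$start, tx$end - 1L)
  intron <- setdiff(all_pos, exonic)
  if (nrow(cd) > 0) {
    cds_lo <- min(cd$start); cds_hi <- max(cd$end)
    inside <- exonic >= cds_lo & exonic < cds_hi
    left <- exonic[exonic < cds_lo]
    right <- exonic[exonic >= cds_hi]
    if (tx$strand == "+") {
      list(utr5 = left, cds = exonic[inside], intron = intron, utr3 = right)
    } else {
      list(utr5 = right, cds = exonic[inside], intron = intron, utr3 = left)
    }
  } else {
    ## non-coding: exonic bases split at the midpoint into 5'/3' UTR
    half <- length(exonic) %/% 2
    ord <- if (tx$strand == "-") rev(exonic) else exonic
    list(utr5 = head(ord, half), cds = integer(0), intron = intron,
         utr3 = tail(ord, length(exonic) - half))
  }
}

#' Simulate hMeRIP IP/input coverage in wild-type and Tet-null genotypes
#'
#' Coverage is restricted to transcript footprints (pre-mRNA style: exons
#' and introns at the per-transcript baseline `hmerip_depth * expression`).
#' RNA peaks are placed within transcripts according to `element_weights`;
#' in the Tet-null genotype, `reduced_transcript_fraction` of the modified
#' transcripts has one peak whose IP coverage over the peak footprint is
#' divided by `reduction_factor`.
#'
#' @inheritParams simulate_chip
#' @return A list with `tracks` (`wt`/`tetnull`, each with `ip` and `input`
#'   replicate lists), `truth_peaks` and `truth_transcripts` tibbles.
#' @export
simulate_hmerip <- function(config, transcripts, chrom_sizes, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  hw <- config$ext_size
  n <- config$n_rna_peaks
  if (n > 0 && nrow(transcripts) == 0) {
    abort("simulate_hmerip: RNA peaks requested but no transcripts")
  }
  ## spread peaks over transcripts evenly before reusing any transcript
  host_idx <- integer(0)
  while (length(host_idx) < n) {
    host_idx <- c(host_idx,
                  sample.int(nrow(transcripts),
                             min(nrow(transcripts), n - length(host_idx))))
  }
  peaks <- vector("list", n)
  for (i in seq_len(n)) {
    tx <- transcripts[host_idx[i], ]
    elems <- transcript_element_positions(tx)
    prev <- purrr::keep(peaks[seq_len(i - 1)],
                        ~ !is.null(.x) && .x$transcript_id == tx$transcript_id)
    prev_summits <- purrr::map_int(prev, "summit")
    w <- config$element_weights
    avail <- names(w)[vapply(elems[names(w)], length, integer(1)) > 0 & w > 0]
    if (length(avail) == 0) avail <- names(w)[vapply(elems[names(w)], length, integer(1)) > 0]
    pick <- NULL
    for (try in 1:50) {
      el <- sample(avail, 1, prob = w[avail] / sum(w[avail]))
      pos <- elems[[el]][sample.int(length(elems[[el]]), 1)]
      if (length(prev_summits) == 0 || min(abs(prev_summits - pos)) >= 600) {
        pick <- list(element = el, summit = pos)
        break
      }
    }
    if (is.null(pick)) pick <- list(element = el, summit = pos)
    peaks[[i]] <- tibble(
      peak_id = sprintf("rna_peak_%04d", i),
      transcript_id = tx$transcript_id, gene_id = tx$gene_id,
      chrom = tx$chrom, summit = as.integer(pick$summit),
      element = pick$element,
      fold_enrichment = runif(1, config$rna_fe_range[1], config$rna_fe_range[2])
    )
  }
  truth_peaks <- if (n > 0) bind_rows(peaks) else {
    tibble(peak_id = character(0), transcript_id = character(0),
           gene_id = character(0), chrom = character(0), summit = integer(0),
           element = character(0), fold_enrichment = numeric(0))
  }
  modified <- unique(truth_peaks$transcript_id)
  n_red <- round(config$reduced_transcript_fraction * length(modified))
  reduced_tx <- if (n_red > 0) sample(modified, n_red) else character(0)
  truth_peaks$reduced <- FALSE
  for (tid in reduced_tx) {
    idx <- which(truth_peaks$transcript_id == tid)
    truth_peaks$reduced[idx[sample.int(length(idx), 1)]] <- TRUE
  }
  truth_peaks$has_motif <- as.logical(rbinom(nrow(truth_peaks), 1,
                                             config$motif_fg_fraction))
  truth_peaks$motif_pos <- as.integer(truth_peaks$summit +
                                        sample(-20:20, nrow(truth_peaks),
                                               replace = TRUE))

  tx_by_id <- transcripts[match(truth_peaks$transcript_id,
                                transcripts$transcript_id), ]
  baseline <- function() {
    mu <- zero_depth(chrom_sizes)
    for (i in seq_len(nrow(transcripts))) {
      tx <- transcripts[i, ]
      b <- config$hmerip_depth * tx$expr
      mu[[tx$chrom]][(tx$start + 1L):tx$end] <- b
    }
    mu
  }
  mu_input <- baseline()
  mu_ip_wt <- baseline()
  for (i in seq_len(nrow(truth_peaks))) {
    tx <- tx_by_id[i, ]
    amp <- config$hmerip_depth * tx$expr * (truth_peaks$fold_enrichment[i] - 1)
    mu_ip_wt[[tx$chrom]] <- add_triangle(mu_ip_wt[[tx$chrom]],
                                         truth_peaks$summit[i], amp, hw,
                                         lo = tx$start, hi = tx$end)
  }
  mu_ip_ko <- mu_ip_wt
  for (i in which(truth_peaks$reduced)) {
    tx <- tx_by_id[i, ]
    a <- max(tx$start, truth_peaks$summit[i] - hw + 1L)
    b <- min(tx$end - 1L, truth_peaks$summit[i] + hw - 1L)
    idx <- (a:b) + 1L
    mu_ip_ko[[tx$chrom]][idx] <- mu_ip_ko[[tx$chrom]][idx] / config$reduction_factor
  }

  draw <- function(mu) {
    coverage_track(lapply(mu, function(m) as.numeric(rpois(length(m), m))),
                   config$read_length)
  }
  tracks <- list(
    wt = list(ip = lapply(seq_len(config$hmerip_replicates), function(i) draw(mu_ip_wt)),
              input = lapply(seq_len(config$hmerip_replicates), function(i) draw(mu_input))),
    tetnull = list(ip = lapply(seq_len(config$hmerip_replicates), function(i) draw(mu_ip_ko)),
                   input = lapply(seq_len(config$hmerip_replicates), function(i) draw(mu_input)))
  )
  is_red <- modified %in% reduced_tx
  truth_transcripts <- tibble(
    transcript_id = modified,
    gene_id = transcripts$gene_id[match(modified, transcripts$transcript_id)],
    modified = TRUE,
    reduced = is_red
  )
  list(tracks = tracks, truth_peaks = truth_peaks,
       truth_transcripts = truth_transcripts)
}

#' Simulate a gene-by-sample count matrix with planted differential expression
#'
#' Counts are negative binomial with gene means `count_scale * expression`
#' and the configured dispersion; `de_fraction` of genes are shifted by
#' `de_fold_change` in the Tet-null condition (up with probability
#' `de_up_fraction`, otherwise down). With `nb_dispersion = 0` counts are
#' Poisson.
#'
#' @inheritParams simulate_chip
#' @return A list with `counts` (tibble, `gene_id` + one column per sample),
#'   `design` (tibble `sample`/`condition`) and `truth` (per-gene DE status
#'   and direction).
#' @export
simulate_counts <- function(config, transcripts, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$rna_replicates < 2) abort("simulate_counts: need >= 2 replicates per condition")
  set.seed(seed)
  genes <- transcripts$gene_id
  mu <- config$count_scale * transcripts$expr
  n_de <- round(config$de_fraction * length(genes))
  de_idx <- if (n_de > 0) sample.int(length(genes), n_de) else integer(0)
  direction <- rep("unchanged", length(genes))
  direction[de_idx] <- ifelse(rbinom(n_de, 1, config$de_up_fraction) == 1, "up", "down")
  mu_ko <- mu
  mu_ko[direction == "up"] <- mu[direction == "up"] * config$de_fold_change
  mu_ko[direction == "down"] <- mu[direction == "down"] / config$de_fold_change

  draw <- function(m) {
    if (config$nb_dispersion <= 0) rpois(length(m), m)
    else rnbinom(length(m), mu = m, size = 1 / config$nb_dispersion)
  }
  samples <- c(sprintf("wt_%d", seq_len(config$rna_replicates)),
               sprintf("tetnull_%d", seq_len(config$rna_replicates)))
  condition <- rep(c("wt", "tetnull"), each = config$rna_replicates)
  cols <- lapply(seq_along(samples), function(j) {
    draw(if (condition[j] == "wt") mu else mu_ko)
  })
  counts <- bind_cols(tibble(gene_id = genes),
                      setNames(as_tibble(cols, .name_repair = "minimal"), samples))
  list(
    counts = counts,
    design = tibble(sample = samples, condition = condition),
    truth = tibble(gene_id = genes, base_mean = mu, is_de = direction != "unchanged",
                   direction = direction,
                   fold_change = ifelse(direction == "up", config$de_fold_change,
                                        ifelse(direction == "down",
                                               1 / config$de_fold_change, 1)))
  )
}

#' Plant motif sequences into a genome
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param placements Tibble with `chrom`, `pos` (0-based motif start) and
#'   `motif` (DNA-alphabet string; already reverse-complemented by the
#'   caller where a sense-strand RNA motif sits on a minus-strand
#'   transcript).
#' @return The modified `DNAStringSet`.
#' @export
plant_motifs <- function(genome, placements) {
  for (ch in unique(placements$chrom)) {
    sub <- placements[placements$chrom == ch, ]
    ## overlapping placements (e.g. a DNA and an RNA peak sharing a summit)
    ## cannot both be written; keep the first of each overlapping pair
    sub <- sub[order(sub$pos), ]
    keep <- rep(TRUE, nrow(sub))
    last_end <- -1L
    for (i in seq_len(nrow(sub))) {
      if (sub$pos[i] <= last_end) keep[i] <- FALSE
      else last_end <- sub$pos[i] + nchar(sub$motif[i]) - 1L
    }
    sub <- sub[keep, ]
    at <- IRanges::IRanges(start = sub$pos + 1L,
                           width = nchar(sub$motif))
    genome[[ch]] <- Biostrings::replaceAt(genome[[ch]], at,
                                          Biostrings::DNAStringSet(sub$motif))
  }
  genome
}

#' Run the full synthetic-data generator
#'
#' Orchestrates [simulate_genome()], [simulate_chip()], [simulate_hmerip()]
#' and [simulate_counts()] under a single forked seed stream, and plants the
#' ChIP (CG-rich, DNA strandless) and RNA (UC-rich, transcript sense strand)
#' motifs into the genome sequence.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed; each stage uses a seed forked from it so
#'   stage order cannot silently change results.
#' @return A list with `config`, `transcripts`, `genome`, `chrom_sizes`,
#'   `chip`, `hmerip`, `rna` (counts) and the seed.
#' @export
simulate_run <- function(config = sim_config(), seed = 1) {
  gen <- simulate_genome(config, fork_seed(seed, 1))
  chip <- simulate_chip(config, gen$transcripts, gen$chrom_sizes,
                        fork_seed(seed, 2))
  hmerip <- simulate_hmerip(config, gen$transcripts, gen$chrom_sizes,
                            fork_seed(seed, 3))
  rna <- simulate_counts(config, gen$transcripts, fork_seed(seed, 4))

  genome <- gen$genome
  chip_pl <- chip$truth %>%
    filter(.data$has_motif) %>%
    transmute(chrom = .data$chrom, pos = .data$motif_pos,
              motif = config$chip_motif)
  strand_of <- gen$transcripts$strand[match(hmerip$truth_peaks$transcript_id,
                                            gen$transcripts$transcript_id)]
  rc_motif <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(config$rna_motif)))
  rna_pl <- hmerip$truth_peaks %>%
    mutate(tx_strand = strand_of) %>%
    filter(.data$has_motif) %>%
    transmute(chrom = .data$chrom, pos = .data$motif_pos,
              motif = ifelse(.data$tx_strand == "-", rc_motif, config$rna_motif))
  pl <- bind_rows(chip_pl, rna_pl)
  if (nrow(pl) > 0) genome <- plant_motifs(genome, pl)

  list(config = config, seed = seed, transcripts = gen$transcripts,
       genome = genome, chrom_sizes = gen$chrom_sizes,
       chip = chip, hmerip = hmerip, rna = rna)
}

#' Write a simulation to a run directory
#'
#' Writes `genome.fa`, `genes.gtf`, one bedGraph per sample, `h3k4me3.bed`,
#' `counts.tsv`, `design.tsv` and per-stage truth tables under `truth/`,
#' plus a `manifest.tsv` with the md5 checksum of every file. All outputs
#' are deterministic given the simulation seed.
#'
#' @param sim Result of [simulate_run()].
#' @param dir Output directory (created if needed).
#' @return Tibble manifest (file, md5), invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  write_gtf(sim$transcripts, p("genes.gtf"))
  for (r in seq_along(sim$chip$ip)) {
    write_bedgraph(sim$chip$ip[[r]], p(sprintf("chip_ip_rep%d.bedGraph", r)))
    write_bedgraph(sim$chip$input[[r]], p(sprintf("chip_input_rep%d.bedGraph", r)))
  }
  for (g in names(sim$hmerip$tracks)) {
    for (r in seq_along(sim$hmerip$tracks[[g]]$ip)) {
      write_bedgraph(sim$hmerip$tracks[[g]]$ip[[r]],
                     p(sprintf("hmerip_%s_ip_rep%d.bedGraph", g, r)))
      write_bedgraph(sim$hmerip$tracks[[g]]$input[[r]],
                     p(sprintf("hmerip_%s_input_rep%d.bedGraph", g, r)))
    }
  }
  readr::write_tsv(sim$chip$h3k4me3[, c("chrom", "start", "end", "name")],
                   p("h3k4me3.bed"), col_names = FALSE, progress = FALSE)
  write_counts(sim$rna$counts, p("counts.tsv"))
  readr::write_tsv(sim$rna$design, p("design.tsv"), progress = FALSE)
  readr::write_tsv(sim$chip$truth, p("truth", "chip_peaks.tsv"), progress = FALSE)
  readr::write_tsv(sim$hmerip$truth_peaks, p("truth", "rna_peaks.tsv"), progress = FALSE)
  readr::write_tsv(sim$hmerip$truth_transcripts, p("truth", "rna_transcripts.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$rna$truth, p("truth", "de_genes.tsv"), progress = FALSE)
  files <- sort(setdiff(list.files(dir, recursive = TRUE), "manifest.tsv"))
  manifest <- tibble(file = files,
                     md5 = unname(tools::md5sum(file.path(dir, files))))
  readr::write_tsv(manifest, p("manifest.tsv"), progress = FALSE)
  invisible(manifest)
}

#' Extract sequences around peak summits
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param peaks Tibble with `chrom` and `summit` columns (and optionally
#'   `strand`, in which case minus-strand sequences are
#'   reverse-complemented so RNA-mode k-mer counting sees the sense
#'   strand).
#' @param flank Bases kept on each side of the summit.
#' @return Character vector of sequences.
#' @export
peak_sequences <- function(genome, peaks, flank = 50) {
  out <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    lo <- max(0L, peaks$summit[i] - flank)
    hi <- min(length(genome[[ch]]), peaks$summit[i] + flank + 1L)
    s <- Biostrings::subseq(genome[[ch]], lo + 1L, hi)
    if ("strand" %in% names(peaks) && isTRUE(peaks$strand[i] == "-")) {
      s <- Biostrings::reverseComplement(s)
    }
    out[i] <- as.character(s)
  }
  out
}
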