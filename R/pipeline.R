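#' End-to-end run configuration
#'
#' Bundles the simulation parameters (or a directory of existing inputs),
#' the per-module thresholds, the seed and the output directory. The
#' configuration round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param sim A [sim_config()] (used when `input_dir` is `NULL`).
#' @param input_dir Optional directory of existing inputs laid out as
#'   written by [write_simulation()]; when given, simulation is skipped.
#' @param seed Master seed for the run.
#' @param outdir Output directory.
#' @param dialect Peak-caller dialect for the ChIP stage.
#' @param chip_filters A [filter_criteria()].
#' @param consensus_window Summit window (bp) for replicate consensus.
#' @param saturation_windows Window ladder for the saturation analysis.
#' @param rna_p_threshold RNA peak p-value cutoff.
#' @param reduction A [reduction_config()].
#' @param de A [de_config()].
#' @param metagene_flank Metagene flank (bp).
#' @param motif_k K-mer size for motif enrichment.
#' @param motif_shuffles Shuffle iterations for motif enrichment.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL, seed = 1,
                       outdir = "epitet_run",
                       dialect = "embryo",
                       chip_filters = filter_criteria(),
                       consensus_window = 250,
                       saturation_windows = c(50, 100, 150, 200, 250, 300),
                       rna_p_threshold = 1e-5,
                       reduction = reduction_config(),
                       de = de_config(),
                       metagene_flank = 2000,
                       motif_k = 6,
                       motif_shuffles = 50) {
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  keep_names <- function(x) {
    # yaml drops names on atomic vectors; emit named vectors as maps
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    if (is.list(x)) return(lapply(x, keep_names))
    x
  }
  plain <- lapply(config, function(x) {
    keep_names(if (is.object(x)) unclass(x) else x)
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  unlist_fields <- function(x) lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  y$sim <- do.call(sim_config, unlist_fields(y$sim %||% list()))
  y$chip_filters <- do.call(filter_criteria, y$chip_filters %||% list())
  y$reduction <- do.call(reduction_config, y$reduction %||% list())
  y$de <- do.call(de_config, y$de %||% list())
  if (!is.null(y$saturation_windows)) {
    y$saturation_windows <- unlist(y$saturation_windows)
  }
  defaults <- run_config()
  cfg <- modifyList(unclass(defaults), y, keep.null = TRUE)
  structure(cfg[names(defaults)], class = "run_config")
}

read_simulation_inputs <- function(dir, read_length = 50) {
  need <- c("genome.fa", "genes.gtf", "h3k4me3.bed", "counts.tsv", "design.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    abort(sprintf("run_all: missing input file(s) in '%s': %s",
                  dir, paste(missing, collapse = ", ")))
  }
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  chrom_sizes <- setNames(Biostrings::width(genome), names(genome))
  rd_reps <- function(pattern) {
    fs <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
    lapply(fs, read_bedgraph, chrom_sizes = chrom_sizes, read_length = read_length)
  }
  h3 <- readr::read_tsv(file.path(dir, "h3k4me3.bed"), col_names = FALSE,
                        show_col_types = FALSE, progress = FALSE)
  names(h3)[1:3] <- c("chrom", "start", "end")
  list(
    genome = genome, chrom_sizes = chrom_sizes,
    transcripts = read_gtf(file.path(dir, "genes.gtf")),
    chip = list(ip = rd_reps("^chip_ip_rep\\d+\\.bedGraph$"),
                input = rd_reps("^chip_input_rep\\d+\\.bedGraph$"),
                h3k4me3 = h3),
    hmerip = list(tracks = list(
      wt = list(ip = rd_reps("^hmerip_wt_ip_rep\\d+\\.bedGraph$"),
                input = rd_reps("^hmerip_wt_input_rep\\d+\\.bedGraph$")),
      tetnull = list(ip = rd_reps("^hmerip_tetnull_ip_rep\\d+\\.bedGraph$"),
                     input = rd_reps("^hmerip_tetnull_input_rep\\d+\\.bedGraph$"))
    )),
    rna = list(counts = read_counts(file.path(dir, "counts.tsv")),
               design = readr::read_tsv(file.path(dir, "design.tsv"),
                                        show_col_types = FALSE, progress = FALSE))
  )
}

#' Run the full pipeline
#'
#' Executes simulate (unless `input_dir` is set), ChIP peak calling and
#' filtering per replicate, saturation and replicate consensus, feature
#' annotation, H3K4me3 co-localization and metagene profiling, RNA peak
#' calling, reduction classification, motif enrichment, differential
#' expression, and the final integration report. Every stage logs one
#' message; a stage failure halts with the stage name (partial outputs are
#' preserved). A `manifest.tsv` with md5 checksums of every output makes
#' determinism checkable: the same config and seed reproduce byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return An [integration_report()], invisibly; all outputs under
#'   `config$outdir`.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir)) {
    abort(sprintf("run_all: input_dir '%s' does not exist", config$input_dir))
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  row_counts <- list()
  stage <- function(name, expr) {
    message(sprintf("[epitet] stage %-12s ...", name))
    tryCatch(expr, error = function(e) {
      abort(sprintf("run_all: stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  p <- function(...) file.path(outdir, ...)

  dat <- if (is.null(config$input_dir)) {
    stage("simulate", {
      sim <- simulate_run(config$sim, seed = config$seed)
      write_simulation(sim, p("sim"))
      sim
    })
  } else {
    stage("load", read_simulation_inputs(config$input_dir))
  }
  tx <- dat$transcripts
  pcfg <- peak_call_config(dialect = config$dialect)

  chip <- stage("callpeaks", {
    reps <- purrr::imap(dat$chip$ip, function(ip, r) {
      call_peaks(ip, dat$chip$input[[r]], pcfg,
                 sample_id = sprintf("chip_rep%d", r)) %>%
        apply_peak_filters(config$chip_filters)
    })
    for (r in seq_along(reps)) {
      write_peaks(reps[[r]], p(sprintf("chip_peaks_rep%d.narrowPeak", r)))
    }
    reps
  })
  row_counts$chip_peaks <- sum(purrr::map_int(chip, nrow))

  sat <- stage("overlap", {
    sat <- saturation_analysis(chip[[1]], chip[[2]], config$saturation_windows)
    readr::write_tsv(as_tibble(sat), p("saturation.tsv"), progress = FALSE)
    sat
  })
  consensus <- stage("consensus", {
    cons <- multi_replicate_consensus(chip, w = config$consensus_window)
    write_peaks(cons, p("chip_consensus.narrowPeak"))
    cons
  })
  row_counts$consensus <- nrow(consensus)

  idx <- feature_index(tx)
  ann <- stage("annotate", {
    ann <- annotate_peaks(consensus, idx)
    readr::write_tsv(feature_distribution(ann), p("feature_distribution.tsv"),
                     progress = FALSE)
    readr::write_tsv(score_by_region(ann), p("score_by_region.tsv"),
                     progress = FALSE)
    readr::write_tsv(colocalization_fraction(ann, dat$chip$h3k4me3),
                     p("h3k4me3_colocalization.tsv"), progress = FALSE)
    ann
  })
  stage("metagene", {
    mg <- metagene_profile(dat$chip$ip[[1]], tx, flank = config$metagene_flank)
    readr::write_tsv(mg$profile, p("metagene_chip.tsv"), progress = FALSE)
  })

  rna_peaks <- stage("hmerip", {
    pk <- call_rna_peaks(dat$hmerip$tracks$wt$ip[[1]],
                         dat$hmerip$tracks$wt$input[[1]], tx,
                         p_threshold = config$rna_p_threshold,
                         sample_id = "hmerip_wt")
    pk$element <- purrr::map_chr(seq_len(nrow(pk)), function(i) {
      classify_element(tx[match(pk$transcript_id[i], tx$transcript_id), ],
                       pk$summit[i])
    })
    write_peaks(pk, p("rna_peaks.narrowPeak"))
    readr::write_tsv(element_distribution(pk, tx), p("element_distribution.tsv"),
                     progress = FALSE)
    pk
  })
  row_counts$rna_peaks <- nrow(rna_peaks)

  reduction <- stage("reduce", {
    calls <- classify_reduced(rna_peaks, dat$hmerip$tracks$wt$ip,
                              dat$hmerip$tracks$tetnull$ip, config$reduction)
    calls$element <- rna_peaks$element
    readr::write_tsv(calls, p("reduced_calls.tsv"), progress = FALSE)
    summ <- transcript_reduction_summary(calls)
    readr::write_tsv(summ, p("reduction_summary.tsv"), progress = FALSE)
    list(calls = calls, summary = summ)
  })

  stage("motif", {
    chip_seqs <- peak_sequences(dat$genome, consensus, flank = 50)
    mt_chip <- kmer_enrichment(chip_seqs, k = config$motif_k, mode = "dna",
                               n_shuffles = config$motif_shuffles,
                               seed = fork_seed(config$seed, 11))
    readr::write_tsv(head(as_tibble(mt_chip), 50), p("motif_chip.tsv"),
                     progress = FALSE)
    rp <- rna_peaks
    rp$strand <- tx$strand[match(rp$transcript_id, tx$transcript_id)]
    mt_rna <- kmer_enrichment(peak_sequences(dat$genome, rp, flank = 50),
                              k = config$motif_k, mode = "rna",
                              n_shuffles = config$motif_shuffles,
                              seed = fork_seed(config$seed, 12))
    readr::write_tsv(head(as_tibble(mt_rna), 50), p("motif_rna.tsv"),
                     progress = FALSE)
  })

  de <- stage("de", {
    fit <- differential_expression(dat$rna$counts, dat$rna$design,
                                   config$de, reference = "wt")
    readr::write_tsv(tidy(fit), p("de.tsv"), progress = FALSE)
    fit
  })
  row_counts$de_genes <- nrow(de)

  report <- stage("integrate", {
    sets <- build_gene_sets(ann, rna_peaks, reduction$summary, de,
                            gene_map = tx[, c("gene_id", "transcript_id")])
    rep_ <- integration_report(sets)
    write_integration_report(rep_, p("report"))
    rep_
  })

  stage("manifest", {
    files <- sort(setdiff(list.files(outdir, recursive = TRUE), "manifest.tsv"))
    manifest <- tibble(file = files,
                       md5 = unname(tools::md5sum(file.path(outdir, files))))
    header <- tibble(
      file = c("#package", "#r_version", "#seed", "#stage_counts"),
      md5 = c(as.character(utils::packageVersion("epitet")),
              paste(R.version$major, R.version$minor, sep = "."),
              as.character(config$seed),
              paste(sprintf("%s=%d", names(row_counts), unlist(row_counts)),
                    collapse = ";"))
    )
    readr::write_tsv(bind_rows(header, manifest), p("manifest.tsv"),
                     progress = FALSE)
  })
  message(sprintf("[epitet] done: %d target gene(s)", length(report$targets)))
  invisible(report)
}
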