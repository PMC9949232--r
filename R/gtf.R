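#' Read a GTF annotation into a transcript table
#'
#' Parses `transcript`, `exon` and `CDS` features (1-based inclusive GTF
#' coordinates) and returns one row per transcript in the package's internal
#' 0-based half-open convention. The transcription start site (`tss`) is the
#' 5' base under strand (`start` for `+`, `end - 1` for `-`) and the
#' termination site (`tts`) is the 3' base.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `tss`, `tts` and list-columns `exons` and
#'   `cds`, each a tibble of 0-based half-open `start`/`end` intervals sorted
#'   by genomic position (`cds` may be an empty tibble for non-coding
#'   transcripts).
#' @export
read_gtf <- function(path) {
  lines <- readr::read_lines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9)) {
    abort(sprintf("read_gtf: malformed GTF line %d in '%s' (%d field(s), expected 9)",
                  body[which(nf < 9)[1]], path, nf[which(nf < 9)[1]]))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  tb <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,      # GTF 1-based -> 0-based
    end = GenomicRanges::end(gr),               # inclusive end -> exclusive end
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(meta$type),
    gene_id = as.character(meta$gene_id),
    transcript_id = if ("transcript_id" %in% names(meta)) {
      as.character(meta$transcript_id)
    } else NA_character_
  )
  exons <- tb %>%
    filter(.data$type == "exon") %>%
    arrange(.data$transcript_id, .data$start)
  if (nrow(exons) == 0) abort("read_gtf: no exon features found")
  cds <- tb %>% filter(.data$type == "CDS") %>% arrange(.data$transcript_id, .data$start)
  tx_rows <- tb %>% filter(.data$type %in% c("transcript", "mRNA"))

  build_one <- function(ex) {
    tid <- ex$transcript_id[1]
    txr <- tx_rows[!is.na(tx_rows$transcript_id) & tx_rows$transcript_id == tid, ]
    span_start <- if (nrow(txr) > 0) txr$start[1] else min(ex$start)
    span_end <- if (nrow(txr) > 0) txr$end[1] else max(ex$end)
    if (any(ex$start < span_start) || any(ex$end > span_end)) {
      abort(sprintf("read_gtf: exon outside transcript span for '%s'", tid))
    }
    strand <- ex$strand[1]
    cd <- cds[!is.na(cds$transcript_id) & cds$transcript_id == tid, c("start", "end")]
    tibble(
      transcript_id = tid,
      gene_id = ex$gene_id[1],
      chrom = ex$chrom[1],
      start = span_start,
      end = span_end,
      strand = strand,
      tss = if (strand == "-") span_end - 1L else span_start,
      tts = if (strand == "-") span_start else span_end - 1L,
      exons = list(tibble(start = ex$start, end = ex$end)),
      cds = list(as_tibble(cd))
    )
  }
  out <- exons %>%
    group_by(.data$transcript_id) %>%
    group_split() %>%
    purrr::map(build_one) %>%
    bind_rows() %>%
    arrange(.data$chrom, .data$start)
  out
}

#' Write a transcript table as GTF
#'
#' Emits `gene`, `transcript`, `exon` and `CDS` features, converting the
#' internal 0-based half-open coordinates back to 1-based inclusive GTF.
#' `write_gtf()` and [read_gtf()] are inverse on valid inputs.
#'
#' @param transcripts Transcript tibble as returned by [read_gtf()] or
#'   [simulate_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  rows_for <- function(tx) {
    base <- tibble(chrom = tx$chrom, strand = tx$strand,
                   gene_id = tx$gene_id, transcript_id = tx$transcript_id)
    feats <- bind_rows(
      mutate(base, type = "gene", start = tx$start, end = tx$end,
             phase = NA_integer_),
      mutate(base, type = "transcript", start = tx$start, end = tx$end,
             phase = NA_integer_),
      bind_cols(base[rep(1, nrow(tx$exons[[1]])), ],
                tibble(type = "exon",
                       start = tx$exons[[1]]$start, end = tx$exons[[1]]$end,
                       phase = NA_integer_)),
      if (nrow(tx$cds[[1]]) > 0) {
        cd <- tx$cds[[1]]
        lens <- cd$end - cd$start                 # genomic order
        if (tx$strand == "-") lens <- rev(lens)   # transcription order
        phase <- (3L - cumsum(c(0L, head(lens, -1))) %% 3L) %% 3L
        if (tx$strand == "-") phase <- rev(phase)
        bind_cols(base[rep(1, nrow(cd)), ],
                  tibble(type = "CDS", start = cd$start, end = cd$end,
                         phase = phase))
      }
    )
    feats
  }
  feats <- transcripts %>%
    group_by(.data$transcript_id) %>%
    group_split() %>%
    purrr::map(rows_for) %>%
    bind_rows()
  gr <- GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    strand = feats$strand
  )
  gr$source <- "epitet"
  gr$type <- feats$type
  gr$gene_id <- feats$gene_id
  gr$transcript_id <- feats$transcript_id
  gr$phase <- feats$phase
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

## total exonic length per transcript (bp)
exonic_length <- function(transcripts) {
  purrr::map_int(transcripts$exons, function(ex) as.integer(sum(ex$end - ex$start)))
}
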