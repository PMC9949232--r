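# Shared fixtures and independent oracles. Expensive simulations are
# memoised so multiple test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small complete simulation shared across unit tests
small_sim <- function() {
  memo("small_sim", {
    cfg <- sim_config(genome_length = 2e5, n_chroms = 1, n_genes = 30,
                      n_chip_peaks = 30, n_rna_peaks = 25,
                      chip_replicates = 2, hmerip_replicates = 2)
    simulate_run(cfg, seed = 301)
  })
}

# brute-force per-base interval overlap oracle
bf_overlap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0L)
  length(intersect(seq(s1, e1 - 1L), seq(s2, e2 - 1L)))
}

# all-pairs reproducibility oracle: indices of peaks in a with some summit
# of b (same chrom) within w
bf_reproducible <- function(a, b, w) {
  which(vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & abs(b$summit - a$summit[i]) <= w)
  }, logical(1)))
}

# term-by-term Poisson upper-tail oracle, independent of ppois
poisson_tail_oracle <- function(k, lam) {
  if (k == 0) return(1)
  # P(X >= k) = 1 - sum_{i=0}^{k-1} e^-lam lam^i / i!
  term <- exp(-lam)
  acc <- term
  if (k > 1) {
    for (i in 1:(k - 1)) {
      term <- term * lam / i
      acc <- acc + term
    }
  }
  max(1 - acc, 0)
}

random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

# hand-built five-gene annotation with known coordinates, used for the
# enumerated annotation checks; all on chrT (length 100000)
toy_transcripts <- function() {
  mk <- function(id, start, end, strand, exons, cds) {
    tibble::tibble(
      transcript_id = id, gene_id = sub("tx", "g", id), chrom = "chrT",
      start = start, end = end, strand = strand,
      tss = if (strand == "-") end - 1L else start,
      tts = if (strand == "-") start else end - 1L,
      exons = list(exons), cds = list(cds)
    )
  }
  dplyr::bind_rows(
    # plus-strand two-exon gene: [10000,12000), exons [10000,10800)+[11200,12000)
    # CDS spans exonic bases from 10300 to 11800
    mk("txA", 10000L, 12000L, "+",
       tibble::tibble(start = c(10000L, 11200L), end = c(10800L, 12000L)),
       tibble::tibble(start = c(10300L, 11200L), end = c(10800L, 11800L))),
    # minus-strand single-exon gene: [20000,21500), CDS [20200,21300)
    mk("txB", 20000L, 21500L, "-",
       tibble::tibble(start = 20000L, end = 21500L),
       tibble::tibble(start = 20200L, end = 21300L)),
    # plus-strand single-exon gene far from others
    mk("txC", 40000L, 41000L, "+",
       tibble::tibble(start = 40000L, end = 41000L),
       tibble::tibble(start = 40100L, end = 40900L)),
    # minus-strand two-exon gene: [60000,62000)
    mk("txD", 60000L, 62000L, "-",
       tibble::tibble(start = c(60000L, 61000L), end = c(60600L, 62000L)),
       tibble::tibble(start = c(60200L, 61000L), end = c(60600L, 61700L))),
    # plus-strand gene adjacent to txC's downstream region
    mk("txE", 80000L, 81200L, "+",
       tibble::tibble(start = 80000L, end = 81200L),
       tibble::tibble(start = 80150L, end = 81000L))
  )
}

# generator element labels -> element_distribution() labels
element_key_of <- function(x) {
  unname(c(utr5 = "5'UTR", cds = "CDS", intron = "intron", utr3 = "3'UTR")[x])
}

# summit -> expected feature class for toy_transcripts(), with the default
# promoter window TSS-1000..+100 and TTS +/-100
toy_annotation_cases <- function() {
  tibble::tribble(
    ~summit, ~expected,
    9500L,  "promoter-TSS",  # 500 bp upstream of txA TSS
    10000L, "promoter-TSS",  # exactly at txA TSS
    10100L, "promoter-TSS",  # downstream edge of txA promoter window
    10101L, "5'UTR",         # first base past the promoter window, exonic 5'UTR
    10500L, "exon",          # CDS-covered exonic base (exon class, CDS peaks
                             # are an RNA-side concept; genomic priority puts
                             # non-UTR exonic bases in 'exon')
    11000L, "intron",        # txA intron
    11850L, "3'UTR",         # exonic base past CDS end on + strand
    21499L, "promoter-TSS",  # txB TSS (minus strand, tss = end-1)
    20050L, "TTS",           # within 100 bp of txB TTS (minus strand)
    20210L, "exon",          # CDS region of txB
    21350L, "5'UTR",         # minus-strand 5'UTR (genomically right of CDS)
    30000L, "intergenic"     # >= promoter distance from any gene
  )
}
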