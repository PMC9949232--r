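test_that("interval overlap handles half-open adjacency and disjoint chroms", {
  expect_equal(interval_overlap("chr1", 0, 100, "chr1", 100, 200), 0L)
  expect_equal(interval_overlap("chr1", 0, 100, "chr1", 50, 150), 50L)
  expect_equal(interval_overlap("chr1", 0, 100, "chr2", 0, 100), 0L)
})

test_that("interval overlap matches the per-base brute-force oracle", {
  set.seed(101)
  for (i in 1:1000) {
    c1 <- sample(c("chr1", "chr2"), 1); c2 <- sample(c("chr1", "chr2"), 1)
    s1 <- sample(0:500, 1); e1 <- s1 + sample(1:200, 1)
    s2 <- sample(0:500, 1); e2 <- s2 + sample(1:200, 1)
    expect_equal(interval_overlap(c1, s1, e1, c2, s2, e2),
                 bf_overlap(c1, s1, e1, c2, s2, e2))
  }
})

test_that("interval overlap is symmetric and rejects invalid intervals", {
  expect_equal(interval_overlap("chr1", 10, 90, "chr1", 50, 400),
               interval_overlap("chr1", 50, 400, "chr1", 10, 90))
  expect_error(interval_overlap("chr1", 100, 100, "chr1", 0, 10), "start >= end")
  expect_error(interval_overlap("", 0, 10, "chr1", 0, 10), "non-empty")
})

test_that("GTF coordinates convert exactly between 1-based and 0-based", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  ), gtf)
  tx <- read_gtf(gtf)
  expect_equal(tx$exons[[1]]$start, 100L)
  expect_equal(tx$exons[[1]]$end, 200L)
  expect_equal(tx$tss, 100L)
})

test_that("minus-strand TSS/TTS follow strand symmetry", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t501\t700\t.\t-\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t501\t700\t.\t-\t.\tgene_id "g1"; transcript_id "t1";'
  ), gtf)
  tx <- read_gtf(gtf)
  expect_equal(tx$tss, 699L)
  expect_equal(tx$tts, 500L)
})

test_that("GTF read/write round-trips a simulated annotation", {
  cfg <- sim_config(genome_length = 5e4, n_chroms = 1, n_genes = 5)
  gen <- simulate_genome(cfg, seed = 11)
  f1 <- tempfile(fileext = ".gtf")
  write_gtf(gen$transcripts, f1)
  tx1 <- read_gtf(f1)
  cols <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand",
            "tss", "tts")
  expect_equal(as.data.frame(tx1[cols]),
               as.data.frame(gen$transcripts[order(gen$transcripts$start), cols]))
  expect_identical(tx1$exons, gen$transcripts$exons[order(gen$transcripts$start)])
  expect_identical(tx1$cds, gen$transcripts$cds[order(gen$transcripts$start)])
  # second write is byte-stable
  f2 <- tempfile(fileext = ".gtf")
  write_gtf(tx1, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("malformed GTF input fails with the offending line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1 broken line"
  ), gtf)
  expect_error(read_gtf(gtf), "line 2")
})

test_that("exon outside the transcript span is a validation error", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t101\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  ), gtf)
  expect_error(read_gtf(gtf), "outside transcript")
})

test_that("peak IO: empty file, 3-column defaults and validation", {
  f <- tempfile()
  writeLines(character(0), f)
  expect_equal(nrow(read_peaks(f)), 0)
  writeLines(c("chr1\t100\t300", "chr2\t0\t50"), f)
  pk <- read_peaks(f)
  expect_equal(pk$summit, c(200L, 25L))   # midpoint default
  expect_true(all(is.na(pk$pvalue)))
  expect_true(all(is.na(pk$fold_enrichment)))
  writeLines("chr1\t300\t100", f)
  expect_error(read_peaks(f), "start >= end")
})

test_that("peak write/read is an identity on all persisted fields", {
  set.seed(77)
  n <- 100
  start <- sample(0:1e6, n)
  pk <- peak_table(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = start, end = start + sample(100:400, n, TRUE),
    summit = start + sample(0:99, n, TRUE),
    pvalue = 10^-runif(n, 1, 80),
    qvalue = 10^-runif(n, 1, 40),
    fold_enrichment = runif(n, 0, 50),
    reads = runif(n, 0, 2000)
  )
  f <- tempfile(fileext = ".narrowPeak")
  write_peaks(pk, f)
  back <- read_peaks(f)
  persisted <- c("chrom", "start", "end", "name", "summit", "score",
                 "pvalue", "qvalue", "fold_enrichment", "reads")
  expect_equal(as.data.frame(back[persisted]), as.data.frame(pk[persisted]),
               tolerance = 1e-10)
})

test_that("count table IO round-trips and validates non-negative integers", {
  cnt <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(3L, 0L), s2 = c(10L, 7L))
  f <- tempfile(fileext = ".tsv")
  write_counts(cnt, f)
  expect_equal(as.data.frame(read_counts(f)), as.data.frame(cnt))
  readr::write_tsv(dplyr::mutate(cnt, s1 = c(-1, 2)), f)
  expect_error(read_counts(f), "non-negative")
})

test_that("bedGraph round-trips coverage with zero runs omitted", {
  depth <- list(chrA = c(0, 0, 3, 3, 1, 0, 2, 0, 0, 0), chrB = rep(0, 5))
  tr <- coverage_track(depth, read_length = 1)
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, chrom_sizes = c(chrA = 10L, chrB = 5L),
                        read_length = 1)
  expect_equal(back$depth$chrA, depth$chrA)
  expect_equal(back$depth$chrB, depth$chrB)
  expect_equal(back$library_size, tr$library_size)
})
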