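test_that("simulation outputs are byte-identical under a fixed seed", {
  cfg <- sim_config(genome_length = 6e4, n_chroms = 1, n_genes = 8,
                    n_chip_peaks = 6, n_rna_peaks = 6,
                    chip_replicates = 2, hmerip_replicates = 2)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- write_simulation(simulate_run(cfg, seed = 5), d1)
  m2 <- write_simulation(simulate_run(cfg, seed = 5), d2)
  expect_identical(m1$file, m2$file)
  expect_identical(m1$md5, m2$md5)
  # and a different seed changes the data
  m3 <- write_simulation(simulate_run(cfg, seed = 6), tempfile())
  expect_false(identical(m1$md5, m3$md5))
})

test_that("an empty annotation is handled and genome length is honoured", {
  cfg <- sim_config(genome_length = 5e4, n_chroms = 1, n_genes = 0,
                    n_chip_peaks = 0, n_rna_peaks = 0)
  gen <- simulate_genome(cfg, seed = 1)
  expect_equal(nrow(gen$transcripts), 0)
  expect_equal(sum(Biostrings::width(gen$genome)), 5e4)
})

test_that("simulated genes are pairwise disjoint with consistent structure", {
  cfg <- sim_config(genome_length = 1e6, n_chroms = 2, n_genes = 50)
  gen <- simulate_genome(cfg, seed = 13)
  tx <- gen$transcripts
  expect_equal(nrow(tx), 50)
  for (i in seq_len(nrow(tx) - 1)) {
    for (j in (i + 1):nrow(tx)) {
      expect_equal(interval_overlap(tx$chrom[i], tx$start[i], tx$end[i],
                                    tx$chrom[j], tx$start[j], tx$end[j]), 0L)
    }
  }
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    expect_true(all(ex$start >= tx$start[i] & ex$end <= tx$end[i]))
    expect_true(all(ex$end[-nrow(ex)] <= ex$start[-1]))  # ordered, disjoint
    cd <- tx$cds[[i]]
    expect_gt(nrow(cd), 0)
    # CDS contained in exons
    for (k in seq_len(nrow(cd))) {
      cov <- sum(interval_overlap(rep(tx$chrom[i], nrow(ex)), ex$start, ex$end,
                                  tx$chrom[i], cd$start[k], cd$end[k]))
      expect_equal(cov, cd$end[k] - cd$start[k])
    }
  }
})

test_that("infeasible gene packing fails with a sizing suggestion", {
  cfg <- sim_config(genome_length = 2e4, n_chroms = 1, n_genes = 50)
  expect_error(simulate_genome(cfg, seed = 1), "increase genome_length")
})

test_that("planted ChIP summit depth matches fold enrichment by construction", {
  cfg <- sim_config(genome_length = 3e5, n_chroms = 1, n_genes = 40,
                    n_chip_peaks = 25, chip_fe_range = c(20, 20),
                    chip_depth = 10, summit_jitter_sd = 0, chip_replicates = 1)
  gen <- simulate_genome(cfg, seed = 21)
  chip <- simulate_chip(cfg, gen$transcripts, gen$chrom_sizes, seed = 22)
  at_summit <- vapply(seq_len(nrow(chip$truth)), function(i) {
    chip$ip[[1]]$depth[[chip$truth$chrom[i]]][chip$truth$summit[i] + 1L]
  }, numeric(1))
  expect_equal(mean(at_summit), 200, tolerance = 0.05)  # 20 x depth 10
})

test_that("H3K4me3 co-occurrence flags follow the configured probability", {
  sims <- memo("cooc_sim", {
    cfg <- sim_config(genome_length = 4e6, n_chroms = 2, n_genes = 600,
                      n_chip_peaks = 500, h3k4me3_cooccurrence_prob = 0.4,
                      chip_replicates = 1, n_rna_peaks = 0)
    gen <- simulate_genome(cfg, seed = 23)
    simulate_chip(cfg, gen$transcripts, gen$chrom_sizes, seed = 24)
  })
  n <- nrow(sims$truth)
  ci <- 0.4 + c(-1, 1) * 1.96 * sqrt(0.4 * 0.6 / n)
  expect_gte(mean(sims$truth$h3k4me3), ci[1])
  expect_lte(mean(sims$truth$h3k4me3), ci[2])
})

test_that("hMeRIP truth is internally consistent", {
  sim <- small_sim()
  tr <- sim$hmerip$truth_peaks
  tx <- sim$transcripts
  host <- tx[match(tr$transcript_id, tx$transcript_id), ]
  expect_true(all(tr$summit >= host$start & tr$summit < host$end))
  expect_true(all(sim$hmerip$truth_transcripts$transcript_id[
    sim$hmerip$truth_transcripts$reduced] %in%
      tr$transcript_id[tr$reduced]))
  # every reduced transcript is a modified transcript
  expect_true(all(tr$transcript_id[tr$reduced] %in%
                    sim$hmerip$truth_transcripts$transcript_id))
})

test_that("element weights steer RNA-peak placement", {
  cfg <- sim_config(genome_length = 2e5, n_chroms = 1, n_genes = 25,
                    n_rna_peaks = 40, n_chip_peaks = 0,
                    element_weights = c(utr5 = 0, cds = 1, intron = 0, utr3 = 0))
  gen <- simulate_genome(cfg, seed = 31)
  hm <- simulate_hmerip(cfg, gen$transcripts, gen$chrom_sizes, seed = 32)
  expect_true(all(hm$truth_peaks$element == "cds"))
})

test_that("reduction factor 1 leaves wild-type and Tet-null identical in law", {
  cfg <- sim_config(genome_length = 1e5, n_chroms = 1, n_genes = 12,
                    n_rna_peaks = 10, n_chip_peaks = 0, reduction_factor = 1,
                    hmerip_replicates = 2)
  gen <- simulate_genome(cfg, seed = 41)
  hm <- simulate_hmerip(cfg, gen$transcripts, gen$chrom_sizes, seed = 42)
  wt <- unlist(hm$tracks$wt$ip[[1]]$depth)
  ko <- unlist(hm$tracks$tetnull$ip[[1]]$depth)
  # same expected coverage: totals agree within Poisson error
  expect_equal(sum(ko) / sum(wt), 1, tolerance = 0.02)
})

test_that("count generator: Poisson limit, null exchangeability, determinism", {
  tx <- tibble::tibble(gene_id = sprintf("g%03d", 1:400),
                       expr = rep(1, 400))
  cfg0 <- sim_config(nb_dispersion = 0, de_fraction = 0)
  rna <- simulate_counts(cfg0, tx, seed = 51)
  m <- as.matrix(rna$counts[-1])
  vm <- apply(m, 1, var) / rowMeans(m)
  expect_equal(mean(vm), 1, tolerance = 0.1)     # variance/mean -> 1
  expect_true(all(rna$truth$direction == "unchanged"))
  rna2 <- simulate_counts(cfg0, tx, seed = 51)
  expect_identical(rna$counts, rna2$counts)      # seeded determinism
})
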