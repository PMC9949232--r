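test_that("summit annotation matches the enumerated expectations exactly", {
  idx <- feature_index(toy_transcripts())
  cases <- toy_annotation_cases()
  pk <- peak_table("chrT", cases$summit - 50L, cases$summit + 50L,
                   summit = cases$summit)
  ann <- annotate_peaks(pk, idx)
  expect_equal(as.character(ann$feature_class), cases$expected)
})

test_that("every summit gets exactly one class and the distribution sums to 1", {
  idx <- feature_index(toy_transcripts())
  set.seed(71)
  s <- sample(0:99000, 300)
  ann <- annotate_peaks(peak_table("chrT", s, s + 200L, summit = s + 100L), idx)
  expect_true(all(!is.na(ann$feature_class)))
  fd <- feature_distribution(ann)
  expect_equal(sum(fd$fraction), 1, tolerance = 1e-12)
  expect_error(feature_distribution(ann[0, ]), "no peaks")
})

test_that("nearest gene is assigned by TSS distance", {
  idx <- feature_index(toy_transcripts())
  ann <- annotate_peaks(peak_table("chrT", 9000L, 9200L, summit = 9100L), idx)
  expect_equal(ann$nearest_gene, "gA")
  expect_equal(ann$tss_distance, 900L)
})

test_that("score summaries are permutation invariant", {
  idx <- feature_index(toy_transcripts())
  set.seed(72)
  s <- sample(5000:95000, 100)
  pk <- peak_table("chrT", s, s + 200L, summit = s + 100L,
                   pvalue = 10^-runif(100, 2, 30))
  ann <- annotate_peaks(pk, idx)
  perm <- ann[sample.int(nrow(ann)), ]
  expect_equal(score_by_region(ann), score_by_region(perm))
  one <- score_by_region(ann[1, ])
  expect_equal(one$mean[1], ann$score[1])
  expect_equal(one$median[1], ann$score[1])
})

test_that("co-localization fractions: disjoint, nested and monotone growth", {
  a <- peak_table("chr1", c(0L, 1000L), c(200L, 1200L))
  b_far <- tibble::tibble(chrom = "chr1", start = 5000L, end = 5200L)
  expect_equal(colocalization_fraction(a, b_far)$fraction[1], 0)
  b_sup <- tibble::tibble(chrom = "chr1", start = c(0L, 900L), end = c(300L, 1300L))
  expect_equal(colocalization_fraction(a, b_sup)$fraction[1], 1)
  grown <- dplyr::bind_rows(b_far, b_sup[1, ])
  expect_gte(colocalization_fraction(a, grown)$fraction[1],
             colocalization_fraction(a, b_far)$fraction[1])
  expect_error(colocalization_fraction(a[0, ], b_far), "empty")
})

test_that("promoter-restricted co-localization is reported for annotated peaks", {
  idx <- feature_index(toy_transcripts())
  s <- c(9500L, 30000L)   # one promoter, one intergenic
  ann <- annotate_peaks(peak_table("chrT", s - 100L, s + 100L, summit = s), idx)
  h3 <- tibble::tibble(chrom = "chrT", start = 9300L, end = 9700L)
  cf <- colocalization_fraction(ann, h3)
  expect_equal(cf$fraction[cf$subset == "all"], 0.5)
  expect_equal(cf$fraction[cf$subset == "promoter-TSS"], 1)
})

test_that("metagene of constant coverage is flat at the normalized level", {
  tx <- toy_transcripts()
  track <- coverage_track(list(chrT = rep(4, 1e5)), read_length = 50)
  mg <- metagene_profile(track, tx, flank = 2000)
  expected <- 4 * 1e6 / track$library_size
  expect_equal(max(abs(mg$profile$mean - expected)), 0, tolerance = 1e-9)
  expect_equal(ncol(mg$matrix), 2 * 2000 / 100 + 100)
})

test_that("TSS-proximal coverage peaks at the body start in the profile", {
  tx <- toy_transcripts()
  depth <- numeric(1e5)
  for (i in seq_len(nrow(tx))) {
    lo <- max(0L, tx$tss[i] - 50L); hi <- min(1e5, tx$tss[i] + 51L)
    depth[(lo + 1):hi] <- 100
  }
  mg <- metagene_profile(coverage_track(list(chrT = depth)), tx, flank = 2000)
  nf <- 2000 / 100
  peak_bin <- which.max(mg$profile$mean)
  expect_true(peak_bin %in% c(nf, nf + 1))   # last upstream or first body bin
})

test_that("metagene is invariant under a full genome mirror (strand flip)", {
  tx <- toy_transcripts()
  G <- 1e5
  set.seed(73)
  depth <- as.numeric(rpois(G, 3 + 50 * (sin(seq_len(G) / 500)^2)))
  mg1 <- metagene_profile(coverage_track(list(chrT = depth)), tx, flank = 1000)
  flip <- tibble::tibble(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id, chrom = "chrT",
    start = G - tx$end, end = G - tx$start,
    strand = ifelse(tx$strand == "+", "-", "+"),
    tss = G - 1L - tx$tss, tts = G - 1L - tx$tts,
    exons = lapply(tx$exons, function(e) {
      tibble::tibble(start = G - rev(e$end), end = G - rev(e$start))
    }),
    cds = lapply(tx$cds, function(e) {
      tibble::tibble(start = G - rev(e$end), end = G - rev(e$start))
    })
  )
  mg2 <- metagene_profile(coverage_track(list(chrT = rev(depth))), flip,
                          flank = 1000)
  expect_equal(mg1$profile$mean, mg2$profile$mean, tolerance = 1e-12)
})

test_that("transcripts shorter than the bin count are interpolated, not dropped", {
  short <- tibble::tibble(
    transcript_id = "txS", gene_id = "gS", chrom = "chrT",
    start = 500L, end = 560L, strand = "+", tss = 500L, tts = 559L,
    exons = list(tibble::tibble(start = 500L, end = 560L)),
    cds = list(tibble::tibble(start = 510L, end = 550L))
  )
  track <- coverage_track(list(chrT = rep(2, 1000)))
  mg <- metagene_profile(track, short, flank = 100, flank_bin = 50)
  expect_equal(nrow(mg$matrix), 1)
  expect_equal(ncol(mg$matrix), 2 * 2 + 100)
  body <- mg$matrix[1, 3:102]
  expect_equal(unname(body), rep(2 * 1e6 / track$library_size, 100),
               tolerance = 1e-9)
})
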