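test_that("Poisson tail probability: closed forms and monotonicity", {
  expect_equal(poisson_enrichment_pvalue(0, 5), 1)
  expect_equal(poisson_enrichment_pvalue(1, 1), 1 - exp(-1), tolerance = 1e-12)
  k <- 0:40
  p <- poisson_enrichment_pvalue(k, 5)
  expect_true(all(diff(p) < 0))                         # decreasing in k
  lam <- seq(0.5, 30, by = 0.5)
  expect_true(all(diff(poisson_enrichment_pvalue(10, lam)) > 0))  # increasing in lambda
  expect_error(poisson_enrichment_pvalue(3, 0), "lambda")
  expect_error(poisson_enrichment_pvalue(-1, 2), "non-negative")
})

test_that("identical IP and input yield no peaks at the study filters", {
  set.seed(61)
  depth <- list(chr1 = as.numeric(rpois(2e5, 10)))
  ip <- coverage_track(depth)
  input <- coverage_track(list(chr1 = as.numeric(rpois(2e5, 10))))
  pk <- apply_peak_filters(call_peaks(ip, input))
  expect_equal(nrow(pk), 0)
})

test_that("peak filters apply the strict study boundaries", {
  pk <- peak_table(rep("chr1", 3), c(0L, 500L, 1000L), c(300L, 800L, 1300L),
                   pvalue = 1e-6,
                   fold_enrichment = c(12, 10, 12),
                   reads = c(60, 60, 50))
  kept <- apply_peak_filters(pk)
  expect_equal(kept$start, 0L)        # FE == 10 and reads == 50 are excluded
  pk2 <- dplyr::mutate(pk, pvalue = c(1e-6, 1e-6, 2e-5))
  expect_equal(nrow(apply_peak_filters(pk2)), 1)
})

test_that("filtering is monotone when any criterion is relaxed", {
  set.seed(62)
  n <- 200
  pk <- peak_table("chr1", seq(0, by = 1000, length.out = n),
                   seq(300, by = 1000, length.out = n),
                   pvalue = 10^-runif(n, 2, 9),
                   fold_enrichment = runif(n, 0, 30),
                   reads = runif(n, 0, 200))
  strict <- apply_peak_filters(pk, filter_criteria(1e-5, 10, 50))
  for (relaxed in list(filter_criteria(1e-4, 10, 50),
                       filter_criteria(1e-5, 5, 50),
                       filter_criteria(1e-5, 10, 20))) {
    expect_true(all(strict$name %in% apply_peak_filters(pk, relaxed)$name))
  }
})

test_that("missing statistics fields are reported by peak name", {
  pk <- peak_table("chr1", 0L, 300L, name = "p1", pvalue = 1e-6,
                   fold_enrichment = 12)
  expect_error(apply_peak_filters(pk), "p1.*reads")
})

test_that("window overlap follows the max-summit-distance rule", {
  a <- peak_table("chr1", c(1000L, 5000L), c(1400L, 5400L),
                  summit = c(1200L, 5200L))
  b <- peak_table("chr1", c(1240L, 9000L), c(1640L, 9400L),
                  summit = c(1440L, 9200L))
  expect_equal(nrow(overlap_at_window(a, a, 0)), 2)     # identical sets at w=0
  expect_equal(nrow(overlap_at_window(a, b, 200)), 0)   # 240 bp apart
  expect_equal(nrow(overlap_at_window(a, b, 250)), 1)
})

test_that("window overlap agrees with the all-pairs brute-force oracle", {
  set.seed(63)
  for (rep in 1:20) {
    a <- peak_table(sample(c("chr1", "chr2"), 30, TRUE),
                    s <- sample(0:5e4, 30), s + 200L, summit = s + 100L)
    b <- peak_table(sample(c("chr1", "chr2"), 30, TRUE),
                    t <- sample(0:5e4, 30), t + 200L, summit = t + 100L)
    w <- sample(c(0, 50, 250, 1000), 1)
    got <- overlap_at_window(a, b, w)
    expect_setequal(got$name, a$name[bf_reproducible(a, b, w)])
  }
})

test_that("saturation analysis: flat, disjoint and jittered curves", {
  a <- peak_table("chr1", seq(0, by = 2000, length.out = 50),
                  seq(400, by = 2000, length.out = 50))
  flat <- saturation_analysis(a, a)
  expect_true(all(flat$n_overlapping == 50))
  expect_equal(attr(flat, "selected_window"), 50)       # smallest window

  b <- dplyr::mutate(a, chrom = "chr9")
  zero <- saturation_analysis(a, b)
  expect_true(all(zero$n_overlapping == 0))
  expect_equal(attr(zero, "selected_window"), 50)

  set.seed(64)
  jit <- dplyr::mutate(a, summit = summit + round(rnorm(50, 0, 60)))
  jit$summit <- pmin(pmax(jit$summit, jit$start), jit$end - 1L)
  curve <- saturation_analysis(a, jit)
  expect_true(!is.unsorted(curve$n_overlapping))
  expect_error(saturation_analysis(a, a, windows = c(100)), "ascending")
})

test_that("multi-replicate consensus handles identical, empty and short input", {
  a <- peak_table("chr1", c(100L, 900L), c(500L, 1300L))
  expect_equal(multi_replicate_consensus(list(a, a, a))$name, a$name)
  empty <- a[0, ]
  expect_equal(nrow(multi_replicate_consensus(list(a, empty, a))), 0)
  expect_error(multi_replicate_consensus(list(a)), ">= 2")
})

test_that("larva dialect resizes peaks to 100 bp each side of the summit", {
  set.seed(65)
  n <- 5e4
  mu <- rep(10, n)
  centre <- 10000L
  d <- abs(seq_len(n) - 1L - centre)
  mu <- mu + ifelse(d < 147, 200 * (1 - d / 147), 0)
  ip <- coverage_track(list(chr1 = as.numeric(rpois(n, mu))))
  input <- coverage_track(list(chr1 = as.numeric(rpois(n, 10))))
  pk <- call_peaks(ip, input, peak_call_config(dialect = "larva"))
  expect_gte(nrow(pk), 1)
  # every reported interval is summit +/- 100 bp
  expect_equal(pk$start, pk$summit - 100L)
  expect_equal(pk$end, pk$summit + 100L)
  expect_true(all(!is.na(pk$qvalue)))
  # the planted site is the top-scoring call, at the planted summit
  top <- pk[which.max(pk$score), ]
  expect_lt(abs(top$summit - centre), 20)
  expect_equal(top$start, top$summit - 100L)
  expect_equal(top$end, top$summit + 100L)
})

test_that("empty coverage warns and zero input library errors", {
  zero <- coverage_track(list(chr1 = numeric(100)))
  ten <- coverage_track(list(chr1 = rep(10, 100)))
  expect_error(call_peaks(ten, zero), "input library")
  expect_warning(pk <- call_peaks(zero, ten), "empty IP")
  expect_equal(nrow(pk), 0)
})
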