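#' Library-size normalization of a count table
#'
#' Scales each sample so all totals equal the mean library size; the size
#' factor is `mean_total / sample_total` and normalized counts are
#' `counts * size_factor`.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @return A list with `normalized` (tibble, same shape) and `size_factors`
#'   (tibble `sample`, `total`, `size_factor`).
#' @export
normalize_counts <- function(counts) {
  samples <- setdiff(names(counts), "gene_id")
  m <- as.matrix(counts[samples])
  totals <- colSums(m)
  if (any(totals <= 0)) {
    abort(sprintf("normalize_counts: sample '%s' has zero total counts",
                  samples[which(totals <= 0)[1]]))
  }
  sf <- mean(totals) / totals
  norm <- t(t(m) * sf)
  list(
    normalized = bind_cols(tibble(gene_id = counts$gene_id),
                           as_tibble(norm)),
    size_factors = tibble(sample = samples, total = unname(totals),
                          size_factor = unname(sf))
  )
}

#' Differential-expression configuration
#'
#' The study's significance rule: a gene is significantly changed when the
#' fold change is >= 2 or <= -2 (i.e. |log2 FC| >= 1) and the BH-adjusted
#' p-value is < 0.05.
#'
#' @param fold_change Two-sided fold-change threshold (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_mean Genes with mean normalized count below this are excluded
#'   (default 0: only all-zero genes are excluded).
#' @param prior_count Pseudo-count added to condition means before taking
#'   log2 fold changes.
#' @param prior_weight Weight of the trend dispersion in the shrunken
#'   per-gene dispersion.
#' @return A list of class `de_config`.
#' @export
de_config <- function(fold_change = 2, alpha = 0.05, min_mean = 0,
                      prior_count = 0.5, prior_weight = 2) {
  if (fold_change <= 0 || alpha <= 0) abort("de_config: thresholds must be > 0")
  structure(list(fold_change = fold_change, alpha = alpha,
                 min_mean = min_mean, prior_count = prior_count,
                 prior_weight = prior_weight),
            class = "de_config")
}

#' Negative-binomial differential expression (Wald test)
#'
#' Library-size-normalizes the counts, estimates a per-gene NB dispersion
#' by method of moments pooled across conditions and shrinks it toward the
#' across-gene trend (the median positive dispersion), then Wald-tests the
#' log2 fold change (Tet-null over wild-type) with a delta-method standard
#' error, BH-adjusts, and assigns the direction by the [de_config()] rule.
#' Genes with all-zero counts are excluded and reported in the `excluded`
#' attribute.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param design Tibble with `sample` and `condition` columns; exactly two
#'   conditions, the first level taken as reference (wild-type).
#' @param config A [de_config()].
#' @param reference Reference condition name; defaults to the first
#'   condition in `design`.
#' @return A tibble of class `tet_de`: `gene_id`, `base_mean`, `log2_fc`,
#'   `stat`, `p_value`, `p_adjust`, `direction` (`up` / `down` /
#'   `unchanged`).
#' @export
differential_expression <- function(counts, design, config = de_config(),
                                    reference = NULL) {
  stopifnot(inherits(config, "de_config"))
  conds <- unique(design$condition)
  if (length(conds) != 2) abort("differential_expression: need exactly 2 conditions")
  reference <- reference %||% conds[1]
  other <- setdiff(conds, reference)
  s1 <- design$sample[design$condition == reference]
  s2 <- design$sample[design$condition == other]
  if (length(s1) < 2 || length(s2) < 2) {
    abort("differential_expression: need >= 2 replicates per condition")
  }
  norm <- normalize_counts(counts)$normalized
  m1 <- as.matrix(norm[s1]); m2 <- as.matrix(norm[s2])
  base_mean <- rowMeans(cbind(m1, m2))
  keep <- base_mean > config$min_mean & base_mean > 0
  excluded <- counts$gene_id[!keep]
  g <- counts$gene_id[keep]
  m1 <- m1[keep, , drop = FALSE]; m2 <- m2[keep, , drop = FALSE]

  mu1 <- rowMeans(m1); mu2 <- rowMeans(m2)
  v1 <- apply(m1, 1, var); v2 <- apply(m2, 1, var)
  n1 <- ncol(m1); n2 <- ncol(m2)
  ## pooled method-of-moments dispersion, shrunk toward the trend
  disp_raw <- ((n1 - 1) * pmax(0, (v1 - mu1)) / pmax(mu1, 1e-8)^2 +
                 (n2 - 1) * pmax(0, (v2 - mu2)) / pmax(mu2, 1e-8)^2) /
    (n1 + n2 - 2)
  trend <- median(disp_raw[disp_raw > 0])
  if (!is.finite(trend)) trend <- 0
  w <- config$prior_weight
  disp <- ((n1 + n2 - 2) * disp_raw + w * trend) / (n1 + n2 - 2 + w)

  pc <- config$prior_count
  log2_fc <- log2((mu2 + pc) / (mu1 + pc))
  se <- sqrt((1 / pmax(mu1, pc) + disp) / n1 +
               (1 / pmax(mu2, pc) + disp) / n2) / log(2)
  stat <- log2_fc / se
  p <- 2 * pnorm(-abs(stat))
  padj <- p.adjust(p, method = "BH")
  lfc_thr <- log2(config$fold_change)
  direction <- dplyr::case_when(
    padj < config$alpha & log2_fc >= lfc_thr ~ "up",
    padj < config$alpha & log2_fc <= -lfc_thr ~ "down",
    TRUE ~ "unchanged"
  )
  out <- tibble(gene_id = g, base_mean = base_mean[keep],
                log2_fc = log2_fc, stat = stat, p_value = p,
                p_adjust = padj, direction = direction)
  structure(out, excluded = excluded, config = config,
            reference = reference, contrast = other,
            class = c("tet_de", class(out)))
}

#' @export
print.tet_de <- function(x, ...) {
  cat(sprintf("<tet_de> %s vs %s (reference): %d genes, %d up, %d down\n",
              attr(x, "contrast"), attr(x, "reference"), nrow(x),
              sum(x$direction == "up"), sum(x$direction == "down")))
  NextMethod()
}

#' Tidy a differential-expression fit
#'
#' @param x A `tet_de` object.
#' @param ... Unused.
#' @return The per-gene result tibble.
#' @export
#' @importFrom generics tidy
tidy.tet_de <- function(x, ...) {
  as_tibble(unclass(x)[c("gene_id", "base_mean", "log2_fc", "stat",
                         "p_value", "p_adjust", "direction")])
}

#' One-row summary of a differential-expression fit
#'
#' @param x A `tet_de` object.
#' @param ... Unused.
#' @return Tibble with gene counts by direction and the excluded-gene
#'   count.
#' @export
#' @importFrom generics glance
glance.tet_de <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_up = sum(x$direction == "up"),
         n_down = sum(x$direction == "down"),
         n_unchanged = sum(x$direction == "unchanged"),
         n_excluded = length(attr(x, "excluded")))
}

#' @export
generics::tidy

#' @export
generics::glance
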