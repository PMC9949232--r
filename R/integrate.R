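#' Build the multi-omic gene sets
#'
#' Collects the gene sets that define Tet targets: `bound` (genes nearest
#' to a ChIP consensus peak), `modified` (genes with >= 1 5hmrC RNA peak),
#' `reduced` (genes with >= 1 reduced peak), `up` / `down` / `unchanged`
#' (differential expression), plus `promoter_bound` (genes with a
#' promoter-annotated consensus peak). Ids not resolvable against the gene
#' map are collected in the `unresolved` element rather than dropped
#' silently.
#'
#' @param chip_consensus Annotated consensus peak tibble (needs
#'   `nearest_gene`, optionally `feature_class`).
#' @param rna_peaks Transcript-assigned RNA peak tibble (needs `gene_id`).
#' @param reduced_summary Output of [transcript_reduction_summary()].
#' @param de A `tet_de` object (or its [tidy()] tibble).
#' @param gene_map Tibble with `gene_id` (and optionally `transcript_id`)
#'   listing all known genes; duplicate transcript ids are an error.
#' @return A list of class `gene_sets` of character vectors plus
#'   `unresolved` and `universe`.
#' @export
build_gene_sets <- function(chip_consensus, rna_peaks, reduced_summary, de,
                            gene_map) {
  if ("transcript_id" %in% names(gene_map) &&
      anyDuplicated(gene_map$transcript_id) > 0) {
    abort("build_gene_sets: duplicate transcript ids in gene_map")
  }
  universe <- unique(gene_map$gene_id)
  grab <- function(ids) {
    ids <- unique(ids[!is.na(ids)])
    list(known = sort(intersect(ids, universe)),
         unknown = sort(setdiff(ids, universe)))
  }
  bound <- grab(chip_consensus$nearest_gene)
  promoter_bound <- if ("feature_class" %in% names(chip_consensus)) {
    grab(chip_consensus$nearest_gene[chip_consensus$feature_class == "promoter-TSS"])
  } else list(known = character(0), unknown = character(0))
  modified <- grab(rna_peaks$gene_id)
  reduced <- grab(reduced_summary$gene_id[reduced_summary$reduced])
  de_tb <- if (inherits(de, "tet_de")) tidy(de) else de
  up <- grab(de_tb$gene_id[de_tb$direction == "up"])
  down <- grab(de_tb$gene_id[de_tb$direction == "down"])
  unchanged <- grab(de_tb$gene_id[de_tb$direction == "unchanged"])
  structure(
    list(bound = bound$known, promoter_bound = promoter_bound$known,
         modified = modified$known, reduced = reduced$known,
         up = up$known, down = down$known, unchanged = unchanged$known,
         unresolved = sort(unique(c(bound$unknown, modified$unknown,
                                    reduced$unknown, up$unknown,
                                    down$unknown, unchanged$unknown))),
         universe = sort(universe)),
    class = "gene_sets"
  )
}

#' Multi-omic integration report
#'
#' Computes all pairwise intersection counts and fractions among the gene
#' sets, optional cross-stage overlaps (e.g. embryo vs larval-brain bound
#' genes), and the final Tet target list: genes that are bound, modified,
#' reduced and expression-unchanged, with per-gene evidence columns.
#'
#' @param sets A [build_gene_sets()] result.
#' @param cross_stage_sets Optional named list of character vectors to
#'   intersect against the `bound` and `modified` sets of `sets`.
#' @return A list of class `integration_report` with `pairwise` (tibble:
#'   `set_a`, `set_b`, `n_a`, `n_b`, `n_intersection`,
#'   `fraction_a_in_b`), `cross_stage`, `targets` (character vector) and
#'   `evidence` (per-target tibble).
#' @export
integration_report <- function(sets, cross_stage_sets = NULL) {
  stopifnot(inherits(sets, "gene_sets"))
  core <- c("bound", "promoter_bound", "modified", "reduced", "up", "down",
            "unchanged")
  pairs <- tidyr::expand_grid(set_a = core, set_b = core) %>%
    filter(.data$set_a != .data$set_b)
  pairwise <- pairs %>%
    mutate(
      n_a = purrr::map_int(.data$set_a, ~ length(sets[[.x]])),
      n_b = purrr::map_int(.data$set_b, ~ length(sets[[.x]])),
      n_intersection = purrr::map2_int(.data$set_a, .data$set_b,
                                       ~ length(intersect(sets[[.x]], sets[[.y]]))),
      fraction_a_in_b = ifelse(.data$n_a > 0,
                               .data$n_intersection / .data$n_a, 0)
    )
  cross <- NULL
  if (!is.null(cross_stage_sets)) {
    cross <- purrr::imap(cross_stage_sets, function(gs, nm) {
      tibble(stage = nm,
             set = c("bound", "modified"),
             n_this = c(length(sets$bound), length(sets$modified)),
             n_other = length(gs),
             n_intersection = c(length(intersect(sets$bound, gs)),
                                length(intersect(sets$modified, gs))),
             fraction_this_in_other = ifelse(
               c(length(sets$bound), length(sets$modified)) > 0,
               c(length(intersect(sets$bound, gs)),
                 length(intersect(sets$modified, gs))) /
                 c(length(sets$bound), length(sets$modified)), 0))
    }) %>% bind_rows()
  }
  targets <- Reduce(intersect, list(sets$bound, sets$modified, sets$reduced,
                                    sets$unchanged))
  evidence <- tibble(
    gene_id = targets,
    promoter_peak = targets %in% sets$promoter_bound,
    modified = TRUE, reduced = TRUE,
    de_direction = "unchanged"
  )
  structure(list(pairwise = pairwise, cross_stage = cross,
                 targets = sort(targets), evidence = evidence, sets = sets),
            class = "integration_report")
}

#' @export
print.integration_report <- function(x, ...) {
  s <- x$sets
  cat(sprintf(paste0("<integration_report> bound %d | modified %d | reduced %d | ",
                     "up %d | down %d -> %d target gene(s)\n"),
              length(s$bound), length(s$modified), length(s$reduced),
              length(s$up), length(s$down), length(x$targets)))
  invisible(x)
}

#' Write an integration report to disk
#'
#' Writes `report.tsv` (pairwise fractions), `targets.tsv` (per-gene
#' evidence), optional `cross_stage.tsv`, and `report.json` with the set
#' sizes, pairwise table and target list. Output is deterministic: the
#' same report writes byte-identical files.
#'
#' @param report An [integration_report()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_integration_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(file.path(dir, "report.tsv"), file.path(dir, "targets.tsv"),
             file.path(dir, "report.json"))
  readr::write_tsv(report$pairwise, paths[1], progress = FALSE)
  readr::write_tsv(report$evidence, paths[2], progress = FALSE)
  if (!is.null(report$cross_stage)) {
    p <- file.path(dir, "cross_stage.tsv")
    readr::write_tsv(report$cross_stage, p, progress = FALSE)
    paths <- c(paths, p)
  }
  sizes <- purrr::map_int(report$sets[c("bound", "promoter_bound", "modified",
                                        "reduced", "up", "down", "unchanged")],
                          length)
  jsonlite::write_json(
    list(set_sizes = as.list(sizes),
         n_targets = length(report$targets),
         targets = report$targets,
         pairwise = report$pairwise),
    paths[3], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
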