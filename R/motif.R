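#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: treats the sequence as an Eulerian walk on the
#' dinucleotide multigraph, fixes a random in-tree toward the terminal
#' character, permutes the remaining edges, and rebuilds the walk. The
#' result has exactly the same dinucleotide (and hence mononucleotide)
#' counts as the input.
#'
#' @param seq A single character string over the DNA alphabet.
#' @return A shuffled string with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3) return(seq)
  code <- match(ch, c("A", "C", "G", "T"))
  if (anyNA(code)) {  # leave non-ACGT sequences untouched
    return(seq)
  }
  from <- code[-n]; to <- code[-1]
  last <- code[n]
  edges <- split(to, from)              # outgoing-edge multisets
  verts <- as.integer(names(edges))
  repeat {
    tree <- rep(NA_integer_, 4L)
    for (v in verts) {
      if (v == last) next
      e <- edges[[as.character(v)]]
      tree[v] <- e[sample.int(length(e), 1)]
    }
    ok <- TRUE
    for (v in verts) {                  # every vertex must reach `last`
      if (v == last) next
      cur <- v
      for (step in 1:5) {
        cur <- tree[cur]
        if (is.na(cur) || cur == last) break
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  ord <- vector("list", 4L)
  ptr <- integer(4L)
  for (v in verts) {
    e <- edges[[as.character(v)]]
    if (!is.na(tree[v])) {
      drop1 <- match(tree[v], e)
      e <- e[-drop1]
    }
    e <- if (length(e) > 1) e[sample.int(length(e))] else e
    ord[[v]] <- c(e, tree[v][!is.na(tree[v])])  # tree edge last
  }
  out <- integer(n)
  out[1] <- code[1]
  cur <- code[1]
  for (i in 2:n) {
    ptr[cur] <- ptr[cur] + 1L
    nxt <- ord[[cur]][ptr[cur]]
    out[i] <- nxt
    cur <- nxt
  }
  paste(c("A", "C", "G", "T")[out], collapse = "")
}

## k-mer counts over a character vector of sequences; DNA mode collapses
## reverse complements onto canonical k-mers
kmer_counts <- function(seqs, k, collapse_rc) {
  x <- Biostrings::DNAStringSet(seqs)
  cnt <- Biostrings::oligonucleotideFrequency(x, width = k,
                                              simplify.as = "collapse")
  if (collapse_rc) {
    kmers <- names(cnt)
    rcs <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
    canon <- pmin(kmers, rcs)
    cnt <- tapply(cnt + cnt[rcs] * (kmers != rcs), canon, function(v) v[1])
    cnt <- cnt[sort(names(cnt))]
  }
  cnt
}

#' Exhaustive k-mer enrichment against a shuffled background
#'
#' A simplified stand-in for de novo motif discovery: counts every k-mer in
#' the foreground sequences (both strands collapsed in DNA mode; sense
#' strand only in RNA mode, since hMeRIP motifs live on the transcript) and
#' compares against the mean and sd over `n_shuffles` seeded
#' dinucleotide-preserving shuffles of the same sequences (or a provided
#' background set). Scores are `z = (fg - mean) / sd`; p-values use a t
#' tail with `n_shuffles - 1` degrees of freedom and a 0.5 continuity
#' correction (accounting for the shuffle-estimated sd), BH-adjusted across
#' all k-mers. Rows are ranked by z, ties broken lexicographically.
#'
#' Non-ACGT/U characters trigger a warning; affected k-mer windows are
#' skipped in counting.
#'
#' @param fg_sequences Character vector of foreground sequences (peak
#'   sequences). `U` is accepted and treated as `T`.
#' @param k K-mer size, 4..8 (default 6).
#' @param mode `"dna"` (collapse reverse complements) or `"rna"`
#'   (strand-specific).
#' @param background `"dinucleotide_shuffle"` (default) or `"provided"`.
#' @param bg_sequences Background sequences when `background = "provided"`
#'   (shuffling statistics are then computed over shuffles of these).
#' @param n_shuffles Number of shuffle iterations (default 100).
#' @param seed Seed for the shuffles.
#' @return A tibble of class `motif_table`: `kmer`, `fg_count`,
#'   `bg_mean`, `bg_sd`, `z`, `p_value`, `p_adjust`, ranked by z.
#' @export
kmer_enrichment <- function(fg_sequences, k = 6,
                            mode = c("dna", "rna"),
                            background = c("dinucleotide_shuffle", "provided"),
                            bg_sequences = NULL,
                            n_shuffles = 100, seed = 1) {
  mode <- match.arg(mode)
  background <- match.arg(background)
  if (k < 4 || k > 8) abort("kmer_enrichment: k must be in 4..8")
  fg_sequences <- toupper(fg_sequences)
  fg_sequences <- gsub("U", "T", fg_sequences, fixed = TRUE)
  if (any(grepl("[^ACGT]", fg_sequences))) {
    warn("kmer_enrichment: non-ACGT characters present; affected k-mer windows are skipped")
  }
  basis <- if (background == "provided") {
    if (is.null(bg_sequences)) abort("kmer_enrichment: bg_sequences required")
    bg <- toupper(gsub("U", "T", bg_sequences, fixed = TRUE))
    bg
  } else {
    fg_sequences
  }
  collapse_rc <- mode == "dna"
  fg <- kmer_counts(fg_sequences, k, collapse_rc)

  set.seed(seed)
  bg_mat <- vapply(seq_len(n_shuffles), function(s) {
    shuf <- vapply(basis, dinucleotide_shuffle, character(1), USE.NAMES = FALSE)
    kmer_counts(shuf, k, collapse_rc)
  }, numeric(length(fg)))
  bg_mean <- rowMeans(bg_mat)
  bg_sd <- apply(bg_mat, 1, sd)
  sd_floor <- pmax(bg_sd, sqrt(pmax(bg_mean, 1)) * 0.1, 0.5)
  z <- (fg - bg_mean) / sd_floor
  ## p-value: the larger of a Poisson tail on the shuffle mean (correct for
  ## the discreteness of low counts) and a continuity-corrected t tail
  ## (guards against overdispersion and the shuffle-estimated sd)
  p_pois <- ppois(fg - 1, pmax(bg_mean, 0.5), lower.tail = FALSE)
  p_t <- pt((fg - bg_mean - 0.5) / sd_floor, df = n_shuffles - 1,
            lower.tail = FALSE)
  p <- pmax(p_pois, p_t)
  out <- tibble(kmer = names(fg), fg_count = as.numeric(fg),
                bg_mean = bg_mean, bg_sd = bg_sd, z = as.numeric(z),
                p_value = as.numeric(p),
                p_adjust = p.adjust(p, method = "BH")) %>%
    arrange(desc(.data$z), .data$kmer) %>%
    mutate(rank = row_number())
  structure(out, k = k, mode = mode, n_shuffles = n_shuffles,
            class = c("motif_table", class(out)))
}
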