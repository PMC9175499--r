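# Gene-set enrichment analysis by weighted Kolmogorov-Smirnov running sum
# with gene-set permutation. Phenotype permutation is not offered: with 6-12
# ROIs per class the permutation space is too small to estimate tail
# probabilities.

# Signed enrichment score of one set against a ranked list.
# ranked_genes: character vector in decreasing score order; weights: |score|
# aligned to ranked_genes. The running sum is the weighted hit CDF minus the
# uniform CDF i/N; ES is the extremum of largest magnitude.
gsea_es <- function(set_positions, weights, n) {
  k <- length(set_positions)
  pos <- sort(set_positions)
  w <- weights[pos]
  tw <- sum(w)
  cumw <- if (tw > 0) cumsum(w) / tw else seq_len(k) / k  # all-zero scores: unweighted
  # running sum is piecewise linear in -i/N between hits: extrema occur just
  # after each hit and just before each hit
  after <- cumw - pos / n
  before <- c(0, cumw[-k]) - (pos - 1) / n
  cand <- c(after, before)
  unname(cand[which.max(abs(cand))])
}

#' Gene-set enrichment analysis for one gene set
#'
#' Genes are ranked by decreasing score; the enrichment score is the extremum
#' of a weighted Kolmogorov-Smirnov running sum (weight exponent 1 on the
#' absolute score). Significance comes from resampling gene sets of equal
#' size from the ranked universe: NES is the ES divided by the mean absolute
#' permuted ES of matching sign, with nominal p (and, for a single set, the
#' FDR q) from the same matching-sign permutation tail.
#'
#' @param scores Named numeric vector of per-gene ranking scores (e.g.
#'   log2 fold changes or t statistics).
#' @param gene_set Character vector of gene ids; must intersect the names of
#'   `scores` and must not exhaust the universe.
#' @param n_perm Number of gene-set permutations (default 1000).
#' @param seed RNG seed for reproducible permutation (required).
#' @return A `gsea_result` list: `gene_set_size`, `es`, `nes`, `nominal_p`,
#'   `fdr_q`.
#' @export
gsea <- function(scores, gene_set, n_perm = 1000, seed = 1) {
  stopifnot(!is.null(names(scores)), all(is.finite(scores)))
  ranked <- names(sort(scores, decreasing = TRUE))
  n <- length(ranked)
  in_set <- which(ranked %in% gene_set)
  if (length(in_set) == 0) {
    stop("gene set has empty intersection with the ranked list", call. = FALSE)
  }
  if (length(in_set) == n) {
    stop("degenerate gene set: covers the whole ranked universe", call. = FALSE)
  }
  weights <- abs(scores[ranked])
  es <- gsea_es(in_set, weights, n)
  k <- length(in_set)
  perm_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    gsea_es(sample.int(n, k), weights, n)
  }, numeric(1)))
  same_sign <- perm_es[sign(perm_es) == sign(es)]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
  structure(list(gene_set_size = k, es = es, nes = nes,
                 nominal_p = p, fdr_q = p, n_perm = n_perm),
            class = "gsea_result")
}

#' GSEA over a collection of gene sets
#'
#' Runs [gsea()] for every set sharing one permutation null, then estimates
#' each set's FDR q the standard way: the fraction of same-sign permuted NES
#' at least as extreme, divided by the fraction of same-sign observed NES at
#' least as extreme (clipped to `[0, 1]`).
#'
#' @inheritParams gsea
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]); sets with no overlap with the universe are skipped with a
#'   message.
#' @return Data frame: `gene_set`, `size`, `es`, `nes`, `nominal_p`, `fdr_q`,
#'   ordered by decreasing NES.
#' @export
gsea_batch <- function(scores, gene_sets, n_perm = 1000, seed = 1) {
  stopifnot(length(gene_sets) >= 1, !is.null(names(gene_sets)))
  ranked <- names(sort(scores, decreasing = TRUE))
  n <- length(ranked)
  weights <- abs(scores[ranked])
  keep <- vapply(gene_sets, function(s) {
    k <- sum(ranked %in% s)
    k > 0 && k < n
  }, logical(1))
  if (any(!keep)) {
    message(sprintf("skipping %d gene set(s) with no usable overlap", sum(!keep)))
  }
  gene_sets <- gene_sets[keep]
  sizes <- vapply(gene_sets, function(s) sum(ranked %in% s), integer(1))
  es <- vapply(gene_sets, function(s) gsea_es(which(ranked %in% s), weights, n),
               numeric(1))
  # one permutation null per distinct set size
  perm_by_size <- with_seed(seed, {
    out <- list()
    for (k in sort(unique(sizes))) {
      out[[as.character(k)]] <- vapply(seq_len(n_perm), function(i) {
        gsea_es(sample.int(n, k), weights, n)
      }, numeric(1))
    }
    out
  })
  nes <- numeric(length(es))
  p <- numeric(length(es))
  perm_nes_all <- list()
  for (i in seq_along(es)) {
    perm <- perm_by_size[[as.character(sizes[i])]]
    pos_mean <- mean(abs(perm[perm > 0]))
    neg_mean <- mean(abs(perm[perm < 0]))
    same <- perm[sign(perm) == sign(es[i])]
    nes[i] <- es[i] / if (es[i] > 0) pos_mean else neg_mean
    p[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
    perm_nes_all[[i]] <- c(perm[perm > 0] / pos_mean, perm[perm < 0] / neg_mean)
  }
  perm_nes <- unlist(perm_nes_all)
  fdr_q <- vapply(seq_along(nes), function(i) {
    s <- sign(nes[i])
    num_pool <- perm_nes[sign(perm_nes) == s]
    obs_pool <- nes[sign(nes) == s]
    num <- mean(abs(num_pool) >= abs(nes[i]))
    den <- mean(abs(obs_pool) >= abs(nes[i]))
    min(1, max(0, num / max(den, .Machine$double.eps)))
  }, numeric(1))
  res <- data.frame(gene_set = names(gene_sets), size = sizes,
                    es = es, nes = nes, nominal_p = p, fdr_q = fdr_q,
                    row.names = NULL, stringsAsFactors = FALSE)
  res[order(-res$nes), ]
}

#' Read gene sets in GMT format
#'
#' @param path GMT file path (one set per line: name, description, genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets in GMT format
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
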