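# Digital spatial profiling analysis of ROI-level gene counts: QC,
# housekeeping and upper-quartile (Q3) normalization, per-gene differential
# expression with BH false-discovery control, hierarchical clustering on
# uncentered correlation, PCA, and gene-set enrichment.

ROI_CLASSES <- c("focus", "fibrosis", "normal")

#' Construct a DSP experiment
#'
#' ROI-class-labelled gene count matrix with its housekeeping gene list,
#' emulating a GeoMX-style targeted panel readout.
#'
#' @param counts Non-negative numeric matrix, genes x ROIs, with row and
#'   column names.
#' @param roi_meta Data frame with `roi_id`, `class` (focus / fibrosis /
#'   normal) and `case_id`, one row per ROI column.
#' @param housekeeping Character vector of housekeeping gene ids, all present
#'   in `rownames(counts)`.
#' @return A `dsp_experiment` object.
#' @export
dsp_experiment <- function(counts, roi_meta, housekeeping) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene row names and ROI column names", call. = FALSE)
  }
  stopifnot(all(c("roi_id", "class") %in% names(roi_meta)))
  roi_meta <- roi_meta[match(colnames(counts), roi_meta$roi_id), , drop = FALSE]
  if (anyNA(roi_meta$roi_id)) {
    stop("every counts column needs a matching roi_meta row", call. = FALSE)
  }
  bad <- setdiff(roi_meta$class, ROI_CLASSES)
  if (length(bad)) {
    stop(sprintf("unknown ROI class(es): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  hk_missing <- setdiff(housekeeping, rownames(counts))
  if (length(hk_missing)) {
    stop(sprintf("housekeeping gene(s) absent from counts: %s",
                 paste(hk_missing, collapse = ", ")), call. = FALSE)
  }
  structure(list(counts = counts, roi_meta = roi_meta,
                 housekeeping = housekeeping),
            class = "dsp_experiment")
}

#' @export
print.dsp_experiment <- function(x, ...) {
  cat(sprintf("DSP experiment: %d genes x %d ROIs (%s); %d housekeeping genes\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$roi_meta$class)),
                            table(x$roi_meta$class)), collapse = ", "),
              length(x$housekeeping)))
  invisible(x)
}

#' QC filter on ROI depth and gene abundance
#'
#' Drops under-sequenced ROIs (total counts below `min_roi_total`) and weakly
#' detected genes (mean count below `min_gene_mean`); housekeeping genes are
#' never dropped. Every removal is reported via a message. Removing every ROI
#' of a class is an error.
#'
#' @param exp A [dsp_experiment()].
#' @param min_roi_total Minimum ROI total count.
#' @param min_gene_mean Minimum gene mean count.
#' @return Filtered [dsp_experiment()].
#' @export
qc_filter <- function(exp, min_roi_total = 0, min_gene_mean = 0) {
  stopifnot(inherits(exp, "dsp_experiment"))
  roi_tot <- colSums(exp$counts)
  keep_roi <- roi_tot >= min_roi_total
  if (any(!keep_roi)) {
    message(sprintf("QC: dropping under-sequenced ROI(s): %s",
                    paste(colnames(exp$counts)[!keep_roi], collapse = ", ")))
  }
  classes_present <- unique(exp$roi_meta$class)
  classes_left <- unique(exp$roi_meta$class[keep_roi])
  lost <- setdiff(classes_present, classes_left)
  if (length(lost)) {
    stop(sprintf("QC failure: every ROI of class '%s' removed", lost[1]),
         call. = FALSE)
  }
  gene_mean <- rowMeans(exp$counts[, keep_roi, drop = FALSE])
  keep_gene <- gene_mean >= min_gene_mean | rownames(exp$counts) %in% exp$housekeeping
  if (any(!keep_gene)) {
    message(sprintf("QC: dropping %d low-abundance gene(s)", sum(!keep_gene)))
  }
  dsp_experiment(exp$counts[keep_gene, keep_roi, drop = FALSE],
                 exp$roi_meta[keep_roi, , drop = FALSE],
                 exp$housekeeping)
}

#' Housekeeping normalization
#'
#' Per-ROI scale factor: the geometric mean of the ROI's housekeeping counts
#' divided by the study-wide geometric mean of those per-ROI geometric means;
#' counts are divided by the factor. Zero housekeeping counts are a hard
#' error (no silent pseudo-count imputation).
#'
#' @param exp A [dsp_experiment()].
#' @return List with `matrix` (normalized counts), `factors` (per-ROI) and
#'   `method = "housekeeping"`.
#' @export
hk_normalize <- function(exp) {
  stopifnot(inherits(exp, "dsp_experiment"))
  hk <- exp$counts[exp$housekeeping, , drop = FALSE]
  zero <- which(hk == 0, arr.ind = TRUE)
  if (nrow(zero)) {
    stop(sprintf("zero housekeeping count: gene %s in ROI %s",
                 rownames(hk)[zero[1, 1]], colnames(hk)[zero[1, 2]]),
         call. = FALSE)
  }
  gm <- apply(hk, 2, geomean)
  factors <- gm / geomean(gm)
  list(matrix = sweep(exp$counts, 2, factors, "/"), factors = factors,
       method = "housekeeping")
}

#' Upper-quartile (Q3) normalization
#'
#' Per-ROI factor: the ROI's 75th-percentile count (linear interpolation)
#' divided by the geometric mean of all ROIs' 75th percentiles.
#'
#' @param exp A [dsp_experiment()].
#' @return List with `matrix`, `factors` and `method = "q3"`.
#' @export
q3_normalize <- function(exp) {
  stopifnot(inherits(exp, "dsp_experiment"))
  q3 <- apply(exp$counts, 2, stats::quantile, probs = 0.75, names = FALSE)
  if (any(q3 <= 0)) {
    stop(sprintf("non-positive 75th percentile in ROI %s",
                 colnames(exp$counts)[which(q3 <= 0)[1]]), call. = FALSE)
  }
  factors <- q3 / geomean(q3)
  list(matrix = sweep(exp$counts, 2, factors, "/"), factors = factors,
       method = "q3")
}

# Vectorized Welch two-sample t-test on rows of a matrix.
row_welch <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate rows: zero variance in both classes
  degen <- se2 == 0
  p[degen & mA == mB] <- 1   # identical constants: no evidence
  p[degen & mA != mB] <- 0   # distinct constants: infinitely strong evidence
  list(mean_a = mA, mean_b = mB, t = t, df = df, p = p)
}

#' Differential expression between two ROI classes
#'
#' Per-gene Welch two-sample t-test on log2(count + 1) (Wilcoxon rank-sum
#' available behind `method`), Benjamini-Hochberg adjustment over all tested
#' genes, and selection at q < 0.05 with linear fold change >= 1.5 in either
#' direction (inclusive).
#'
#' @param norm Normalized count matrix (genes x ROIs).
#' @param class_a,class_b Column names (ROI ids) of the two classes, at least
#'   two each.
#' @param q_cutoff,fc_cutoff Selection thresholds (defaults 0.05 and 1.5).
#' @param method `"welch"` (default) or `"wilcoxon"`.
#' @return Data frame (class `de_result`): `gene`, `mean_log2_a`,
#'   `mean_log2_b`, `log2_fold_change` (a over b), `fold_change`
#'   (`2^|log2FC|`), `direction` (+1 up in a, -1 down), `p_value`, `q_value`,
#'   `selected`.
#' @export
de_test <- function(norm, class_a, class_b, q_cutoff = 0.05, fc_cutoff = 1.5,
                    method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(length(class_a) >= 2, length(class_b) >= 2)
  A <- log2(norm[, class_a, drop = FALSE] + 1)
  B <- log2(norm[, class_b, drop = FALSE] + 1)
  if (method == "welch") {
    w <- row_welch(A, B)
    p <- w$p
  } else {
    p <- vapply(seq_len(nrow(A)), function(i) {
      if (all(A[i, ] == A[i, 1]) && all(B[i, ] == B[i, 1]) && A[i, 1] == B[i, 1]) return(1)
      stats::wilcox.test(A[i, ], B[i, ], exact = FALSE)$p.value
    }, numeric(1))
    w <- list(mean_a = rowMeans(A), mean_b = rowMeans(B))
  }
  lfc <- w$mean_a - w$mean_b
  fc <- 2^abs(lfc)
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(gene = rownames(norm),
                    mean_log2_a = w$mean_a,
                    mean_log2_b = w$mean_b,
                    log2_fold_change = lfc,
                    fold_change = fc,
                    direction = sign(lfc),
                    p_value = p,
                    q_value = q,
                    selected = q < q_cutoff & fc >= fc_cutoff,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

# Uncentered Pearson correlation distance between rows: 1 - sum(xy) /
# sqrt(sum(x^2) sum(y^2)). Zero-norm rows are an error.
uncentered_cor_dist <- function(mat) {
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) {
    stop(sprintf("zero vector under uncentered correlation: %s",
                 rownames(mat)[which(norms == 0)[1]]), call. = FALSE)
  }
  s <- mat / norms
  d <- 1 - tcrossprod(s)
  d[d < 0] <- 0  # numerical guard
  stats::as.dist(d)
}

#' Hierarchical clustering on uncentered correlation
#'
#' Average-linkage (UPGMA) clustering with distance 1 - uncentered Pearson
#' correlation, the Cluster 3.0 convention. Items are matrix rows; pass the
#' transpose to cluster ROIs of a genes x ROIs matrix.
#'
#' @param mat Numeric matrix; rows are the items to cluster (>= 2).
#' @return List with `hclust` (the merge tree), `order` (leaf order),
#'   `newick` (tree serialization).
#' @export
hier_cluster <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 2)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("item", seq_len(nrow(mat)))
  hc <- stats::hclust(uncentered_cor_dist(mat), method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, order = hc$order,
       labels = rownames(mat)[hc$order],
       newick = ape::write.tree(phy))
}

#' Scale rows to [-1, 1] for heat-map export
#'
#' Divides each gene's centered values by its maximal absolute value, the
#' red/green heat-map convention.
#'
#' @param mat Numeric matrix (genes x ROIs).
#' @return Matrix of the same shape with entries in `[-1, 1]`.
#' @export
heatmap_scale <- function(mat) {
  centered <- mat - rowMeans(mat)
  m <- apply(abs(centered), 1, max)
  m[m == 0] <- 1
  centered / m
}

#' Principal component analysis of ROI expression
#'
#' Log2(count + 1) transform, per-gene (row) centering, then singular-value
#' decomposition of the ROI profiles; components ordered by decreasing
#' variance, with the sign convention that each component's
#' largest-magnitude gene loading is positive.
#'
#' @param norm Normalized count matrix (genes x ROIs).
#' @param log2_transform Apply the log2(x + 1) transform first (default TRUE).
#' @return List with `scores` (ROIs x components), `loadings` (genes x
#'   components), `explained` (variance fractions, summing to 1).
#' @export
dsp_pca <- function(norm, log2_transform = TRUE) {
  x <- if (log2_transform) log2(norm + 1) else norm
  stopifnot(ncol(x) >= 2)
  pr <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  flip <- apply(pr$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pr$x, 2, flip, "*")
  loadings <- sweep(pr$rotation, 2, flip, "*")
  explained <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = scores, loadings = loadings, explained = explained)
}
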