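# Spatial profiling: QC, normalization, differential expression, clustering,
# PCA.

tiny_experiment <- function(counts, classes = NULL, hk = NULL) {
  n_roi <- ncol(counts)
  if (is.null(classes)) classes <- rep(c("focus", "fibrosis"), length.out = n_roi)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("r", seq_len(n_roi))
  if (is.null(hk)) hk <- rownames(counts)[1]
  meta <- data.frame(roi_id = colnames(counts), class = classes,
                     case_id = "c1", stringsAsFactors = FALSE)
  dsp_experiment(counts, meta, hk)
}

test_that("QC drops under-sequenced ROIs and spares housekeeping genes", {
  g <- gen_dsp(dsp_sim_spec(n_genes = 300, n_de = 20), seed = 51)
  exp <- g$experiment
  # plant one focus ROI at 1% of the median depth
  victim <- exp$roi_meta$roi_id[exp$roi_meta$class == "focus"][1]
  exp$counts[, victim] <- round(exp$counts[, victim] * 0.01)
  filtered <- suppressMessages(
    qc_filter(exp, min_roi_total = 0.1 * median(colSums(exp$counts))))
  expect_false(victim %in% colnames(filtered$counts))
  expect_equal(ncol(filtered$counts), ncol(exp$counts) - 1)
  # identity at zero thresholds
  same <- qc_filter(exp, 0, 0)
  expect_equal(dim(same$counts), dim(exp$counts))
  # housekeeping genes survive an aggressive gene-mean threshold
  harsh <- suppressMessages(qc_filter(exp, 0, min_gene_mean = 1e6))
  expect_true(all(exp$housekeeping %in% rownames(harsh$counts)))
  # removing a whole class is a QC failure
  few <- exp$counts[, exp$roi_meta$class != "focus" |
                      exp$roi_meta$roi_id == victim, drop = FALSE]
  few_exp <- dsp_experiment(few, exp$roi_meta[match(colnames(few),
                                                    exp$roi_meta$roi_id), ],
                            exp$housekeeping)
  expect_error(suppressMessages(
    qc_filter(few_exp, min_roi_total = 0.5 * median(colSums(few)))),
    "QC failure")
})

test_that("housekeeping normalization matches hand geometric means", {
  # HK geomeans {2, 4, 8} -> study geomean 4 -> factors {0.5, 1, 2}
  counts <- rbind(hk1 = c(1, 2, 4), hk2 = c(4, 8, 16), g1 = c(10, 10, 10))
  colnames(counts) <- c("r1", "r2", "r3")
  exp <- tiny_experiment(counts, classes = c("focus", "fibrosis", "normal"),
                         hk = c("hk1", "hk2"))
  nm <- hk_normalize(exp)
  expect_equal(unname(nm$factors), c(0.5, 1, 2))
  expect_equal(unname(nm$matrix["g1", ]), c(20, 10, 5))
  # identical ROIs: identity
  same <- tiny_experiment(matrix(5, 4, 3), hk = "g1",
                          classes = c("focus", "fibrosis", "normal"))
  expect_equal(hk_normalize(same)$matrix, same$counts)
  # zero housekeeping count is a named hard error
  counts0 <- counts; counts0["hk1", "r2"] <- 0
  exp0 <- tiny_experiment(counts0, classes = c("focus", "fibrosis", "normal"),
                          hk = c("hk1", "hk2"))
  expect_error(hk_normalize(exp0), "hk1.*r2")
})

test_that("Q3 normalization uses interpolated percentiles and scale factors", {
  expect_equal(unname(quantile(c(1, 2, 3, 4, 100), 0.75)), 4)  # hand check
  counts <- cbind(r1 = c(1, 2, 3, 4, 100), r2 = 3 * c(1, 2, 3, 4, 100))
  rownames(counts) <- paste0("g", 1:5)
  exp <- tiny_experiment(counts, classes = c("focus", "fibrosis"), hk = "g1")
  nm <- q3_normalize(exp)
  expect_equal(unname(nm$factors[2] / nm$factors[1]), 3)
  expect_equal(unname(nm$matrix[, 1]), unname(nm$matrix[, 2]))
})

test_that("both normalizations are idempotent and scale-invariant", {
  g <- gen_dsp(dsp_sim_spec(n_genes = 200, n_de = 10), seed = 53)
  exp <- g$experiment
  for (normalize in list(hk_normalize, q3_normalize)) {
    m1 <- normalize(exp)$matrix
    renorm <- dsp_experiment(m1, exp$roi_meta, exp$housekeeping)
    m2 <- normalize(renorm)$matrix
    expect_lt(max(abs(m2 - m1)), 1e-10)
    scaled <- dsp_experiment(exp$counts * 7.3, exp$roi_meta, exp$housekeeping)
    expect_equal(normalize(scaled)$matrix, m1 * 7.3, tolerance = 1e-12)
  }
})

test_that("differential expression wiring matches per-gene t-tests and BH", {
  set.seed(59)
  counts <- matrix(rnbinom(50 * 8, mu = 60, size = 10), 50, 8)
  rownames(counts) <- paste0("g", 1:50)
  colnames(counts) <- paste0("r", 1:8)
  a <- paste0("r", 1:4); b <- paste0("r", 5:8)
  de <- de_test(counts, a, b)
  logm <- log2(counts + 1)
  for (i in c(1, 17, 50)) {
    ref <- t.test(logm[i, a], logm[i, b])
    expect_equal(de$p_value[i], ref$p.value, tolerance = 1e-12)
    expect_equal(de$log2_fold_change[i],
                 mean(logm[i, a]) - mean(logm[i, b]))
  }
  expect_equal(de$q_value, p.adjust(de$p_value, "BH"))
  # BH monotonicity: same ordering by p and by q; q >= p elementwise
  expect_equal(order(de$p_value), order(de$q_value, de$p_value))
  expect_true(all(de$q_value >= de$p_value - 1e-15))
})

test_that("identical classes yield no selected genes, constants give p = 1", {
  counts <- matrix(rep(c(5, 9, 14, 3), each = 6), 4, 6, byrow = TRUE)
  rownames(counts) <- paste0("g", 1:4)
  colnames(counts) <- paste0("r", 1:6)
  de <- de_test(counts, paste0("r", 1:3), paste0("r", 4:6))
  expect_true(all(de$log2_fold_change == 0))
  expect_true(all(de$p_value == 1))
  expect_false(any(de$selected))
})

test_that("the DE rule recovers a planted 97-gene focus signature", {
  g <- gen_dsp(dsp_sim_spec(), seed = 61)  # study-scale defaults
  exp <- g$experiment
  norm <- hk_normalize(exp)$matrix
  focus <- exp$roi_meta$roi_id[exp$roi_meta$class == "focus"]
  others <- exp$roi_meta$roi_id[exp$roi_meta$class != "focus"]
  de <- de_test(norm, focus, others)
  hits <- de$gene[de$selected]
  sens <- mean(g$truth$de_genes %in% hits)
  fdp <- if (length(hits)) mean(!hits %in% g$truth$de_genes) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdp, 0.1)
})

test_that("the selection rule keeps its false discovery rate under the null", {
  set.seed(67)
  fdps <- replicate(100, {
    counts <- matrix(rnbinom(500 * 24, mu = 50, size = 10), 500, 24)
    rownames(counts) <- paste0("g", 1:500)
    colnames(counts) <- paste0("r", 1:24)
    de <- de_test(counts, paste0("r", 1:12), paste0("r", 13:24))
    n_sel <- sum(de$selected)
    if (n_sel == 0) 0 else 1  # every selection is false under the null
  })
  expect_lte(mean(fdps), 0.10)
})

test_that("hierarchical clustering follows a hand UPGMA trace", {
  # unit vectors at angles 0, 10, 50, 90 degrees: uncentered correlation is
  # the cosine of the angle difference, so merges go (1,2), (3,4), then all
  ang <- c(0, 10, 50, 90) * pi / 180
  mat <- cbind(cos(ang), sin(ang))
  rownames(mat) <- paste0("v", 1:4)
  cl <- hier_cluster(mat)
  merges <- cl$hclust$merge
  expect_equal(sort(-merges[1, ]), c(1, 2))
  expect_equal(sort(-merges[2, ]), c(3, 4))
  expect_equal(cl$hclust$height[1], 1 - cos(ang[2] - ang[1]))
  expect_equal(cl$hclust$height[2], 1 - cos(ang[4] - ang[3]))
  expect_equal(cl$hclust$height[3],
               mean(1 - cos(outer(ang[1:2], ang[3:4], "-"))))
  expect_match(cl$newick, "^\\(")
  # identical profiles merge first at distance 0
  twin <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 1, 0))
  cl2 <- hier_cluster(twin)
  expect_equal(cl2$hclust$height[1], 0, tolerance = 1e-12)
  expect_error(hier_cluster(rbind(a = c(0, 0), b = c(1, 1))), "zero vector")
})

test_that("cluster topology is invariant to input row permutation", {
  g <- gen_dsp(dsp_sim_spec(n_genes = 150, n_de = 20), seed = 71)
  m <- t(log2(hk_normalize(g$experiment)$matrix + 1))
  cl <- hier_cluster(m)
  idx <- sample(nrow(m))
  clp <- hier_cluster(m[idx, ])
  co <- as.matrix(cophenetic(cl$hclust))
  cop <- as.matrix(cophenetic(clp$hclust))[rownames(co), colnames(co)]
  expect_equal(co, cop, tolerance = 1e-12)
})

test_that("focus ROIs form one clade under the planted signature", {
  g <- gen_dsp(dsp_sim_spec(), seed = 73)
  exp <- g$experiment
  m <- t(log2(hk_normalize(exp)$matrix + 1))
  cl <- hier_cluster(m)
  # cut into two groups: one must be exactly the 12 focus ROIs
  groups <- cutree(cl$hclust, k = 2)
  focus <- exp$roi_meta$roi_id[exp$roi_meta$class == "focus"]
  split_sets <- split(names(groups), groups)
  expect_true(any(vapply(split_sets, function(s) setequal(s, focus),
                         logical(1))))
})

test_that("PCA matches a direct eigendecomposition and sums variance to 1", {
  set.seed(79)
  m <- matrix(rlnorm(60, 3, 1), 10, 6)
  rownames(m) <- paste0("g", 1:10); colnames(m) <- paste0("r", 1:6)
  p <- dsp_pca(m)
  expect_equal(sum(p$explained), 1)
  # oracle: eigendecomposition of the covariance of row-centered log2 data
  x <- log2(m + 1)
  xc <- t(x - rowMeans(x))           # ROIs x genes, gene-centered
  ev <- eigen(stats::cov(xc))
  k <- ncol(m) - 1
  expect_equal(p$explained[seq_len(k)],
               (ev$values / sum(ev$values))[seq_len(k)], tolerance = 1e-8)
  scores_oracle <- xc %*% ev$vectors
  for (j in seq_len(k)) {
    expect_equal(abs(unname(p$scores[, j])), abs(unname(scores_oracle[, j])),
                 tolerance = 1e-8)
  }
  # sign convention: the largest-magnitude loading is positive
  for (j in seq_len(k)) {
    expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  # collinear points: PC1 explains everything
  line <- outer(1:5, c(1, 2, 3))
  rownames(line) <- paste0("g", 1:5); colnames(line) <- paste0("r", 1:3)
  pl <- dsp_pca(line, log2_transform = FALSE)
  expect_equal(pl$explained[1], 1)
})

test_that("PCA separates the three ROI classes of the planted experiment", {
  g <- gen_dsp(dsp_sim_spec(), seed = 83)
  exp <- g$experiment
  p <- dsp_pca(hk_normalize(exp)$matrix)
  cls <- exp$roi_meta$class[match(rownames(p$scores), exp$roi_meta$roi_id)]
  pc1 <- p$scores[, 1]
  gap <- min(abs(outer(pc1[cls == "focus"], pc1[cls != "focus"], "-")))
  spread <- max(abs(pc1))
  # focus and non-focus ROIs do not interleave on PC1
  expect_true(max(pc1[cls == "focus"]) < min(pc1[cls != "focus"]) ||
              min(pc1[cls == "focus"]) > max(pc1[cls != "focus"]))
  expect_gt(gap / spread, 0)
})

test_that("heat-map scaling bounds every gene in [-1, 1]", {
  g <- gen_dsp(dsp_sim_spec(n_genes = 100, n_de = 10), seed = 89)
  h <- heatmap_scale(log2(g$experiment$counts + 1))
  expect_lte(max(h), 1)
  expect_gte(min(h), -1)
  expect_true(any(abs(h) == 1))
})
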