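# Orchestration: configuration, the three pipeline entry points and run
# manifests. A thin command-line wrapper over these functions ships in
# inst/cli/p16foci.

#' Pipeline run configuration
#'
#' @param cutoff Density dichotomization value (foci per 100 mm^2).
#' @param roc_rederive Re-derive the cutoff by ROC against the survival
#'   endpoint instead of using `cutoff` as given.
#' @param survival_covariates Covariates for the multivariate Cox model.
#' @param exclude_lung_cancer Apply the `post_biopsy_lung_cancer` row filter
#'   before survival modelling.
#' @param dsp_normalization `"housekeeping"` (default) or `"q3"`.
#' @param gsea_n_perm Gene-set permutations (>= 100).
#' @param seed RNG seed threaded through seeded stages.
#' @return A `run_config` list.
#' @export
run_config <- function(cutoff = 2.1, roc_rederive = FALSE,
                       survival_covariates = c("p16_high", "antifibrotic"),
                       exclude_lung_cancer = TRUE,
                       dsp_normalization = c("housekeeping", "q3"),
                       gsea_n_perm = 1000, seed = 1) {
  dsp_normalization <- match.arg(dsp_normalization)
  stopifnot(cutoff > 0, gsea_n_perm >= 100)
  structure(as.list(environment()), class = "run_config")
}

write_manifest <- function(out_dir, inputs, config) {
  manifest <- list(
    package = "p16foci",
    version = as.character(utils::packageVersion("p16foci")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    config = unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Quantify a set of annotation files
#'
#' Reads each GeoJSON annotation file, quantifies it, and assembles the
#' per-slide table. Per-file failures are reported to the error stream and
#' the run continues; no valid slide at all is an error.
#'
#' @param files Character vector of GeoJSON paths.
#' @param config A [run_config()].
#' @param microns_per_pixel Calibration override for files lacking one.
#' @param out_dir Optional output directory for the TSV and manifest.
#' @return Per-slide data frame (see [quantify_slides()]).
#' @export
run_quantify <- function(files, config = run_config(),
                         microns_per_pixel = NULL, out_dir = NULL) {
  if (length(files) == 0) stop("no annotation files supplied", call. = FALSE)
  rows <- list()
  for (f in files) {
    row <- tryCatch({
      slide <- read_slide_geojson(f, microns_per_pixel)
      quantify_slides(list(slide), config$cutoff)
    }, error = function(e) {
      message(sprintf("skipping %s: %s", f, conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0) stop("no valid slides among the inputs", call. = FALSE)
  tab <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(tab, file.path(out_dir, "slide_quantification.tsv"))
    write_manifest(out_dir, list(files = files), config)
  }
  tab
}

#' Run the cohort study analysis
#'
#' Assembles the cohort-level results: descriptive summary, the diagnosis by
#' p16-class cross-tabulation, diagnostic performance of any-foci and of
#' p16-high for IPF, the ROC of density against the transplant-free survival
#' endpoint, Kaplan-Meier curves and log-rank test by p16 class, and
#' univariate plus multivariate Cox fits.
#'
#' @param cohort Cohort data frame or TSV path.
#' @param config A [run_config()].
#' @param out_dir Optional output directory (TSV/JSON bundle + manifest).
#' @return List of result objects.
#' @export
run_study <- function(cohort, config = run_config(), out_dir = NULL) {
  input_desc <- if (is.character(cohort)) cohort else "<data.frame>"
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  cutoff <- config$cutoff
  records_all <- ltx_free_records(cohort, cutoff)
  if (config$roc_rederive && nrow(records_all) > 0) {
    dens <- cohort$density[match(records_all$patient_id, cohort$patient_id)]
    roc_surv <- roc_curve(dens, records_all$event)
    cutoff <- roc_surv$best_cutoff
  }
  cohort$p16_class <- classify_density(cohort$density, cutoff)

  summary <- cohort_summary(cohort)
  crosstab <- table(diagnosis = cohort$diagnosis, p16 = cohort$p16_class)
  is_ipf <- cohort$diagnosis == "IPF"
  perf_any <- diagnostic_performance(cohort, cohort$density > 0, is_ipf)
  perf_high <- diagnostic_performance(cohort, cohort$p16_class == "high", is_ipf)

  records <- ltx_free_records(cohort, cutoff)
  roc_surv <- if (length(unique(records$event)) == 2) {
    roc_curve(cohort$density[match(records$patient_id, cohort$patient_id)],
              records$event)
  } else NULL

  high <- records[records$p16_high == 1, , drop = FALSE]
  low <- records[records$p16_high == 0, , drop = FALSE]
  km <- list(high = if (nrow(high)) km_estimate(high),
             low = if (nrow(low)) km_estimate(low))
  logrank <- if (nrow(high) && nrow(low)) logrank_test(high, low) else NULL
  cox_uni <- tryCatch(cox_fit(records, "p16_high"),
                      error = function(e) NULL)

  multi_records <- records
  if (config$exclude_lung_cancer && "post_biopsy_lung_cancer" %in% names(cohort)) {
    keep_ids <- cohort$patient_id[is_ipf & cohort$post_biopsy_lung_cancer == 0]
    multi_records <- records[records$patient_id %in% keep_ids, , drop = FALSE]
  } else {
    multi_records <- records[records$patient_id %in% cohort$patient_id[is_ipf], ,
                             drop = FALSE]
  }
  cox_multi <- tryCatch(
    cox_fit(multi_records, intersect(config$survival_covariates,
                                     names(multi_records))),
    error = function(e) { message("multivariate Cox fit: ", conditionMessage(e)); NULL })

  res <- list(cutoff = cutoff, summary = summary, crosstab = crosstab,
              perf_any_foci = perf_any, perf_p16_high = perf_high,
              roc_survival = roc_surv, km = km, logrank = logrank,
              cox_univariate = cox_uni, cox_multivariate = cox_multi)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (grp in names(km)) {
      if (!is.null(km[[grp]])) {
        write_tsv(data.frame(time = km[[grp]]$time, at_risk = km[[grp]]$n_risk,
                             events = km[[grp]]$n_events,
                             survival = km[[grp]]$survival,
                             se = km[[grp]]$greenwood_se),
                  file.path(out_dir, sprintf("km_p16_%s.tsv", grp)))
      }
    }
    cox_json <- lapply(Filter(Negate(is.null),
                              list(univariate = cox_uni, multivariate = cox_multi)),
                       function(fit) list(
                         covariate = names(fit$coefficients),
                         hazard_ratio = unname(fit$hazard_ratios),
                         ci_lower = unname(fit$wald_ci_95[, "lower"]),
                         ci_upper = unname(fit$wald_ci_95[, "upper"]),
                         p_value = unname(fit$p_values),
                         n = fit$n, n_events = fit$n_events))
    jsonlite::write_json(
      list(cutoff = cutoff,
           logrank = logrank,
           cox = cox_json,
           diagnostic = list(
             any_foci = list(sensitivity = perf_any$sensitivity,
                             specificity = perf_any$specificity),
             p16_high = list(sensitivity = perf_high$sensitivity,
                             specificity = perf_high$specificity))),
      file.path(out_dir, "study_results.json"), auto_unbox = TRUE, digits = NA)
    write_manifest(out_dir, list(cohort = input_desc), config)
  }
  res
}

#' Run the spatial-profiling analysis
#'
#' QC, the configured normalization, differential expression of focus ROIs
#' against the pooled fibrosis/normal ROIs, hierarchical clustering of ROIs,
#' PCA, and (when gene sets are supplied) GSEA on the DE ranking. Seeded and
#' deterministic.
#'
#' @param exp A [dsp_experiment()].
#' @param gene_sets Optional named list of gene sets (see [read_gmt()]).
#' @param config A [run_config()].
#' @param min_roi_total,min_gene_mean QC thresholds.
#' @param out_dir Optional output directory.
#' @return List with `normalized`, `de`, `cluster`, `pca`, `gsea`,
#'   `normalization`.
#' @export
run_dsp <- function(exp, gene_sets = NULL, config = run_config(),
                    min_roi_total = 0, min_gene_mean = 0, out_dir = NULL) {
  stopifnot(inherits(exp, "dsp_experiment"))
  classes <- table(exp$roi_meta$class)
  if (any(classes < 2)) {
    stop(sprintf("class '%s' has fewer than 2 ROIs",
                 names(classes)[which(classes < 2)[1]]), call. = FALSE)
  }
  exp <- qc_filter(exp, min_roi_total, min_gene_mean)
  norm <- if (config$dsp_normalization == "housekeeping") hk_normalize(exp)
          else q3_normalize(exp)
  focus <- exp$roi_meta$roi_id[exp$roi_meta$class == "focus"]
  others <- exp$roi_meta$roi_id[exp$roi_meta$class != "focus"]
  de <- de_test(norm$matrix, focus, others)
  cluster <- hier_cluster(t(log2(norm$matrix + 1)))
  pca <- dsp_pca(norm$matrix)
  gsea_res <- NULL
  if (!is.null(gene_sets)) {
    scores <- stats::setNames(de$log2_fold_change, de$gene)
    gsea_res <- gsea_batch(scores, gene_sets, n_perm = config$gsea_n_perm,
                           seed = config$seed)
  }
  res <- list(normalized = norm$matrix, normalization = norm$method,
              de = de, cluster = cluster, pca = pca, gsea = gsea_res)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(data.frame(gene = rownames(norm$matrix), norm$matrix,
                         check.names = FALSE),
              file.path(out_dir, "normalized_counts.tsv"))
    write_tsv(de[, c("gene", "log2_fold_change", "fold_change", "p_value",
                     "q_value", "selected")],
              file.path(out_dir, "de_table.tsv"))
    writeLines(cluster$newick, file.path(out_dir, "roi_cluster.newick"))
    write_tsv(data.frame(roi_id = rownames(pca$scores),
                         pca$scores[, seq_len(min(5, ncol(pca$scores))),
                                    drop = FALSE]),
              file.path(out_dir, "pca_scores.tsv"))
    if (!is.null(gsea_res)) {
      write_tsv(gsea_res, file.path(out_dir, "gsea_table.tsv"))
    }
    write_manifest(out_dir, list(n_genes = nrow(exp$counts),
                                 n_rois = ncol(exp$counts),
                                 normalization = norm$method), config)
  }
  res
}
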