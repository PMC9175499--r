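# Seeded generators for slide annotations, cohorts and DSP count matrices
# with known ground truth. Every generator is a pure function of its spec and
# seed; ground-truth records accompany the data so recovery tests never
# re-derive parameters.

#' Generate a synthetic calibrated slide
#'
#' Emits a square tissue polygon whose shoelace area matches the target, with
#' foci placed uniformly inside and, on request, in a band outside the
#' tissue.
#'
#' @param seed RNG seed.
#' @param tissue_area_mm2 Target tissue area in mm^2 (positive).
#' @param n_foci_inside,n_foci_outside Number of focus marks to place.
#' @param mpp Microns per pixel (default 0.5, a typical 20x scan).
#' @return List with `slide` (a [calibrated_slide()]) and `truth`
#'   (`tissue_area_mm2`, `n_foci_inside`, `n_foci_outside`, `density`).
#' @export
gen_slide <- function(seed, tissue_area_mm2, n_foci_inside = 0,
                      n_foci_outside = 0, mpp = 0.5) {
  if (tissue_area_mm2 <= 0) {
    if (n_foci_inside > 0) {
      stop("cannot place in-tissue foci on a slide with zero tissue area",
           call. = FALSE)
    }
    stop("tissue_area_mm2 must be positive", call. = FALSE)
  }
  with_seed(seed, {
    side <- sqrt(tissue_area_mm2 * 1e6 / mpp^2)  # px
    outer <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
    region <- tissue_region(outer)
    marks <- list()
    if (n_foci_inside > 0) {
      # uniform in the open square (margin avoids boundary ambiguity)
      xy <- cbind(stats::runif(n_foci_inside, side * 1e-6, side * (1 - 1e-6)),
                  stats::runif(n_foci_inside, side * 1e-6, side * (1 - 1e-6)))
      for (i in seq_len(n_foci_inside)) {
        marks[[length(marks) + 1L]] <-
          focus_mark(sprintf("in_%03d", i), xy[i, ])
      }
    }
    if (n_foci_outside > 0) {
      xy <- cbind(stats::runif(n_foci_outside, side * 1.1, side * 1.5),
                  stats::runif(n_foci_outside, 0, side))
      for (i in seq_len(n_foci_outside)) {
        marks[[length(marks) + 1L]] <-
          focus_mark(sprintf("out_%03d", i), xy[i, ])
      }
    }
    slide <- calibrated_slide(sprintf("synthetic_%d", seed), mpp,
                              list(region), marks)
    list(slide = slide,
         truth = list(tissue_area_mm2 = tissue_area_mm2,
                      n_foci_inside = n_foci_inside,
                      n_foci_outside = n_foci_outside,
                      density = 100 * n_foci_inside / tissue_area_mm2))
  })
}

#' Cohort simulation specification
#'
#' Defaults emulate the study cohort: 86 subjects, the published diagnosis
#' mix, a zero-inflated lognormal focus-density model for IPF (zero fraction
#' 12/52, median 1.97 per 100 mm^2) with rare low positives outside IPF,
#' exponential event times whose log-hazard shifts by the published
#' multivariate effects (p16-high and antifibrotic treatment), and
#' exponential censoring.
#'
#' @param n Cohort size.
#' @param diagnosis_mix Named proportions over the five diagnoses.
#' @param true_log_hr Named log hazard ratios applied to `p16_high` and
#'   `antifibrotic`.
#' @param baseline_hazard Events per month for the reference subject.
#' @param censor_rate Exponential censoring rate per month.
#' @param treatment_mix Named proportions (antifibrotic / immunomodulatory /
#'   none).
#' @param p16_mode `"density"` draws densities from the diagnosis-specific
#'   model and derives `p16_high` at `cutoff`; `"binary"` assigns `p16_high`
#'   directly as Bernoulli(`p16_prevalence`) (used in recovery experiments).
#' @param p16_prevalence Prevalence for `p16_mode = "binary"`.
#' @param cutoff Density dichotomization value.
#' @param ipf_zero_prob,ipf_meanlog,ipf_sdlog Zero-inflated lognormal density
#'   model for IPF.
#' @param nonipf_pos_prob Probability that a non-IPF case shows any foci.
#' @return A `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n = 86,
                            diagnosis_mix = c(IPF = 52, NSIP = 16,
                                              unclassifiable = 11,
                                              chronic_HP = 6,
                                              smoking_related = 1) / 86,
                            true_log_hr = c(p16_high = log(2.40),
                                            antifibrotic = log(0.28)),
                            baseline_hazard = 0.02,
                            censor_rate = 0.019,
                            treatment_mix = c(antifibrotic = 0.36,
                                              immunomodulatory = 0.29,
                                              none = 0.35),
                            p16_mode = c("density", "binary"),
                            p16_prevalence = 0.5,
                            cutoff = 2.1,
                            ipf_zero_prob = 12 / 52,
                            ipf_meanlog = log(1.97),
                            ipf_sdlog = 0.9,
                            nonipf_pos_prob = 3 / 34) {
  p16_mode <- match.arg(p16_mode)
  stopifnot(abs(sum(diagnosis_mix) - 1) < 1e-8,
            abs(sum(treatment_mix) - 1) < 1e-8,
            baseline_hazard > 0, censor_rate >= 0)
  structure(as.list(environment()), class = "cohort_sim_spec")
}

#' Generate a synthetic cohort
#'
#' Draws diagnoses, densities, demographics, treatment and exponential
#' survival/censoring times according to the spec, returning the cohort table
#' together with the generating parameters.
#'
#' @param spec A [cohort_sim_spec()].
#' @param seed RNG seed.
#' @return List with `cohort` (data frame in the cohort-table layout) and
#'   `truth` (generating parameters).
#' @export
gen_cohort <- function(spec = cohort_sim_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_seed(seed, {
    n <- spec$n
    diagnosis <- sample(names(spec$diagnosis_mix), n, replace = TRUE,
                        prob = spec$diagnosis_mix)
    density <- numeric(n)
    if (spec$p16_mode == "density") {
      ipf <- diagnosis == "IPF"
      pos_ipf <- ipf & stats::runif(n) > spec$ipf_zero_prob
      density[pos_ipf] <- stats::rlnorm(sum(pos_ipf), spec$ipf_meanlog,
                                        spec$ipf_sdlog)
      pos_other <- !ipf & stats::runif(n) < spec$nonipf_pos_prob
      density[pos_other] <- stats::rlnorm(sum(pos_other), log(1.3), 0.5)
      p16_high <- as.numeric(density > spec$cutoff)
    } else {
      p16_high <- stats::rbinom(n, 1, spec$p16_prevalence)
      density <- ifelse(p16_high == 1,
                        spec$cutoff * exp(stats::runif(n, 0.1, 1.5)),
                        spec$cutoff * exp(-stats::runif(n, 0.1, 1.5)))
    }
    treatment <- sample(names(spec$treatment_mix), n, replace = TRUE,
                        prob = spec$treatment_mix)
    antifibrotic <- as.numeric(treatment == "antifibrotic")
    age <- round(stats::rnorm(n, 62, 10), 1)
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.56, 0.44))
    bmi <- round(stats::rnorm(n, 30, 6), 1)
    pack_years <- round(pmax(stats::rnorm(n, 24, 19), 0), 1)
    fvc_pct <- round(stats::rnorm(n, 75, 19), 1)
    tlc_pct <- round(stats::rnorm(n, 70, 15), 1)
    dlco_pct <- round(stats::rnorm(n, 48, 17), 1)
    hrct_pattern <- sample(c("probable_UIP", "indeterminate", "inconsistent"),
                           n, replace = TRUE, prob = c(0.43, 0.34, 0.23))
    hrct_score_pct <- round(pmin(pmax(stats::rnorm(n, 20, 8), 0), 100), 1)

    lp <- spec$true_log_hr["p16_high"] * p16_high +
      spec$true_log_hr["antifibrotic"] * antifibrotic
    hazard <- spec$baseline_hazard * exp(lp)
    t_event <- stats::rexp(n, hazard)
    t_censor <- if (spec$censor_rate > 0) stats::rexp(n, spec$censor_rate) else Inf
    time <- pmin(t_event, t_censor)
    event <- t_event <= t_censor
    # among events, transplant vs death in the published 13:42 ratio
    transplanted <- event & stats::runif(n) < 13 / 55
    status <- ifelse(!event, "alive",
                     ifelse(transplanted, "transplanted", "died"))
    cohort <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      diagnosis = diagnosis,
      density = round(density, 4),
      p16_class = classify_density(density, spec$cutoff),
      age = age, sex = sex, bmi = bmi, pack_years = pack_years,
      fvc_pct = fvc_pct, tlc_pct = tlc_pct, dlco_pct = dlco_pct,
      hrct_pattern = hrct_pattern, hrct_score_pct = hrct_score_pct,
      treatment = treatment,
      followup_months = time,  # months, unrounded (rounding would tie times)
      status = status,
      post_biopsy_lung_cancer = 0L,
      stringsAsFactors = FALSE)
    truth <- list(seed = seed,
                  n = n,
                  true_log_hr = as.list(spec$true_log_hr),
                  true_hr = as.list(exp(spec$true_log_hr)),
                  baseline_hazard = spec$baseline_hazard,
                  censor_rate = spec$censor_rate,
                  cutoff = spec$cutoff,
                  p16_mode = spec$p16_mode,
                  event_fraction = mean(event))
    list(cohort = cohort, truth = truth)
  })
}

#' DSP simulation specification
#'
#' Defaults emulate the profiling design: 1825 panel genes of which 31 are
#' housekeeping, 12 fibroblastic-focus / 6 dense-fibrosis / 6 normal ROIs,
#' negative-binomial counts (dispersion 0.1) with lognormal per-ROI depth
#' factors, and 97 genes up-regulated in focus ROIs at log2 fold change 2.
#'
#' @param n_genes Total panel size.
#' @param n_housekeeping Number of housekeeping genes (stable, never DE).
#' @param rois_per_class Named integer vector (focus / fibrosis / normal).
#' @param n_de Number of planted focus-up genes.
#' @param de_log2fc Planted log2 fold change in focus ROIs.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param depth_sdlog Lognormal sd of per-ROI depth factors.
#' @param base_meanlog,base_sdlog Lognormal baseline gene means.
#' @return A `dsp_sim_spec` list.
#' @export
dsp_sim_spec <- function(n_genes = 1825, n_housekeeping = 31,
                         rois_per_class = c(focus = 12, fibrosis = 6,
                                            normal = 6),
                         n_de = 97, de_log2fc = 2, dispersion = 0.1,
                         depth_sdlog = 0.25,
                         base_meanlog = log(40), base_sdlog = 1) {
  stopifnot(n_de <= n_genes - n_housekeeping, dispersion > 0,
            all(rois_per_class >= 0))
  structure(as.list(environment()), class = "dsp_sim_spec")
}

#' Generate a synthetic DSP experiment
#'
#' Negative-binomial counts with per-ROI depth factors; housekeeping genes
#' have elevated stable means and zero planted effect; planted
#' differentially expressed genes (readable labels echoing CDK-inhibitor,
#' matrix-protease and collagen families) are up-regulated in focus ROIs.
#'
#' @param spec A [dsp_sim_spec()].
#' @param seed RNG seed.
#' @return List with `experiment` (a [dsp_experiment()]) and `truth`
#'   (`de_genes`, `de_log2fc`, `depth_factors`, `dispersion`, `seed`).
#' @export
gen_dsp <- function(spec = dsp_sim_spec(), seed = 1) {
  stopifnot(inherits(spec, "dsp_sim_spec"))
  with_seed(seed, {
    n_hk <- spec$n_housekeeping
    n_other <- spec$n_genes - n_hk
    hk_ids <- sprintf("HK_%02d", seq_len(n_hk))
    families <- c("CDKN1A_like", "MMP_like", "ADAM_like", "COL_like")
    n_de <- spec$n_de
    de_ids <- sprintf("%s_%03d",
                      rep(families, length.out = n_de), seq_len(n_de))
    bg_ids <- sprintf("GENE_%04d", seq_len(n_other - n_de))
    genes <- c(hk_ids, de_ids, bg_ids)

    roi_class <- rep(names(spec$rois_per_class), spec$rois_per_class)
    n_roi <- length(roi_class)
    roi_ids <- sprintf("ROI_%02d_%s", seq_len(n_roi), roi_class)
    case_id <- rep(c("case_1", "case_2"), length.out = n_roi)

    base <- stats::rlnorm(length(genes), spec$base_meanlog, spec$base_sdlog)
    base[seq_len(n_hk)] <- stats::rlnorm(n_hk, log(200), 0.3)
    depth <- stats::rlnorm(n_roi, 0, spec$depth_sdlog)

    lfc <- numeric(length(genes))
    lfc[genes %in% de_ids] <- spec$de_log2fc
    focus_col <- as.numeric(roi_class == "focus")
    mu <- outer(base, depth) * 2^(outer(lfc, focus_col))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / spec$dispersion),
                     nrow = length(genes),
                     dimnames = list(genes, roi_ids))
    meta <- data.frame(roi_id = roi_ids, class = roi_class, case_id = case_id,
                       stringsAsFactors = FALSE)
    list(experiment = dsp_experiment(counts, meta, hk_ids),
         truth = list(seed = seed, de_genes = de_ids,
                      de_log2fc = spec$de_log2fc,
                      dispersion = spec$dispersion,
                      depth_factors = stats::setNames(depth, roi_ids)))
  })
}

#' Write a generated dataset beside its ground truth
#'
#' Serializes a `gen_*` result: the data in the format the analysis modules
#' read (GeoJSON / TSV), plus a `<stem>.truth.json` ground-truth file.
#'
#' @param generated Result of [gen_slide()], [gen_cohort()] or [gen_dsp()].
#' @param stem Output path stem (no extension).
#' @return Character vector of written paths, invisibly.
#' @export
write_generated <- function(generated, stem) {
  paths <- character(0)
  if (!is.null(generated$slide)) {
    p <- paste0(stem, ".geojson")
    write_slide_geojson(generated$slide, p)
    paths <- c(paths, p)
  }
  if (!is.null(generated$cohort)) {
    p <- paste0(stem, ".cohort.tsv")
    write_tsv(generated$cohort, p)
    paths <- c(paths, p)
  }
  if (!is.null(generated$experiment)) {
    exp <- generated$experiment
    counts_path <- paste0(stem, ".counts.tsv")
    cnt <- data.frame(gene = rownames(exp$counts), exp$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(cnt, counts_path)
    meta_path <- paste0(stem, ".roi_meta.tsv")
    write_tsv(exp$roi_meta, meta_path)
    hk_path <- paste0(stem, ".housekeeping.txt")
    writeLines(exp$housekeeping, hk_path)
    paths <- c(paths, counts_path, meta_path, hk_path)
  }
  truth_path <- paste0(stem, ".truth.json")
  jsonlite::write_json(generated$truth, truth_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, truth_path))
}

#' Read a DSP experiment from its TSV components
#'
#' @param counts_path Genes-by-ROIs TSV, first column the gene id.
#' @param meta_path ROI metadata TSV (`roi_id`, `class`, `case_id`).
#' @param hk_path Housekeeping gene list, one id per line.
#' @return A [dsp_experiment()].
#' @export
read_dsp <- function(counts_path, meta_path, hk_path) {
  cnt <- read_tsv(counts_path, check.names = FALSE)
  mat <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(mat) <- cnt[[1]]
  dsp_experiment(mat, read_tsv(meta_path), readLines(hk_path))
}
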