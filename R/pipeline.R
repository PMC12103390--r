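# End-to-end driver: generate (or accept) a cohort, re-segment regions from
# the PANCK+ pattern, summarize every sample, run the paired treatment
# comparisons, the density-density rank correlations, and the dichotomized
# survival analyses, and write deterministic CSV outputs.

fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.10g", x))

write_result_csv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full cohort analysis
#'
#' Generates a synthetic cohort from `config`, re-derives tumor/stroma
#' regions with [segment_regions()] (the algorithmic stand-in for manual
#' annotation), summarizes all samples, and writes:
#' \describe{
#'   \item{sample_metrics.csv}{one row per sample, all spatial metrics}
#'   \item{paired_ratios.csv}{per-patient on-treatment/baseline density ratios}
#'   \item{treatment_tests.csv}{paired Wilcoxon tests, baseline vs on-treatment}
#'   \item{correlations.csv}{Spearman tests between LAG3+ T density and
#'     CD4/CD8 T density per timepoint}
#'   \item{survival_results.csv}{optimal-cutpoint KM/log-rank per feature}
#'   \item{km_curves.csv}{KM curve coordinates per feature and group}
#' }
#' All randomness derives from `config$seed`, so a fixed configuration
#' reproduces byte-identical files.
#'
#' @param config a [cohort_config()].
#' @param outdir output directory (created if needed).
#' @param rules phenotype rule set.
#' @param radius pairing radius (um).
#' @param resegment re-run algorithmic segmentation instead of using the
#'   generator's ground-truth regions.
#' @param n_perm permutations for the calibrated log-rank p (0 = skip).
#' @return invisibly, a list with the cohort, summaries and result tables.
#' @export
run_cohort_analysis <- function(config, outdir,
                                rules = default_phenotype_rules(),
                                radius = 50, resegment = TRUE, n_perm = 0) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  samples <- cohort$samples
  if (resegment) samples <- lapply(samples, segment_regions)
  summ <- summarize_cohort(samples, rules = rules, radius = radius)
  ratios <- paired_changes(summ)

  bl <- summ[summ$timepoint == "baseline", , drop = FALSE]
  ot <- summ[summ$timepoint == "on_treatment", , drop = FALSE]
  ot <- ot[match(bl$patient_id, ot$patient_id), , drop = FALSE]

  treat_metrics <- c("density_CD4_T_stroma", "density_CD8_T_stroma",
                     "density_LAG3_T_stroma",
                     "pct_IFNG_in_CD4_T_all", "pct_IFNG_in_CD8_T_all",
                     "pct_KI67_in_CD4_T_all", "pct_KI67_in_CD8_T_all",
                     "nndist_mean_CD4_T", "nndist_mean_CD8_T",
                     "ncount_mean_CD4_T", "ncount_mean_CD8_T")
  treatment_tests <- do.call(rbind, lapply(treat_metrics, function(m) {
    ok <- is.finite(bl[[m]]) & is.finite(ot[[m]])
    if (sum(ok) < 2) {
      return(data.frame(metric = m, n = sum(ok), statistic = NA_real_,
                        p_value = NA_real_, median_baseline = NA_real_,
                        median_on_treatment = NA_real_))
    }
    tst <- wilcoxon_signed_rank(ot[[m]][ok], bl[[m]][ok])
    data.frame(metric = m, n = tst$n, statistic = tst$statistic,
               p_value = tst$p_value,
               median_baseline = stats::median(bl[[m]][ok]),
               median_on_treatment = stats::median(ot[[m]][ok]))
  }))

  corr_specs <- expand.grid(timepoint = c("baseline", "on_treatment"),
                            partner = c("density_CD4_T_stroma", "density_CD8_T_stroma"),
                            stringsAsFactors = FALSE)
  correlations <- do.call(rbind, lapply(seq_len(nrow(corr_specs)), function(i) {
    tp <- corr_specs$timepoint[i]; m <- corr_specs$partner[i]
    d <- summ[summ$timepoint == tp, , drop = FALSE]
    res <- tryCatch(spearman_test(d$density_LAG3_T_stroma, d[[m]]),
                    error = function(e) NULL)
    data.frame(timepoint = tp, x = "density_LAG3_T_stroma", y = m,
               rho = if (is.null(res)) NA_real_ else res$statistic,
               p_value = if (is.null(res)) NA_real_ else res$p_value,
               n = if (is.null(res)) 0L else res$n)
  }))

  surv_features <- list(
    list(name = "density_CD4_T_stroma_baseline", tp = "baseline", col = "density_CD4_T_stroma"),
    list(name = "density_CD8_T_stroma_baseline", tp = "baseline", col = "density_CD8_T_stroma"),
    list(name = "density_LAG3_T_stroma_baseline", tp = "baseline", col = "density_LAG3_T_stroma"),
    list(name = "density_CD4_T_stroma_on_treatment", tp = "on_treatment", col = "density_CD4_T_stroma"),
    list(name = "density_CD8_T_stroma_on_treatment", tp = "on_treatment", col = "density_CD8_T_stroma"),
    list(name = "density_LAG3_T_stroma_on_treatment", tp = "on_treatment", col = "density_LAG3_T_stroma"),
    list(name = "ratio_density_CD4_T_stroma", tp = "ratio", col = "ratio_density_CD4_T_stroma"),
    list(name = "ratio_density_CD8_T_stroma", tp = "ratio", col = "ratio_density_CD8_T_stroma"),
    list(name = "nndist_mean_CD8_T_on_treatment", tp = "on_treatment", col = "nndist_mean_CD8_T"),
    list(name = "ncount_mean_CD8_T_on_treatment", tp = "on_treatment", col = "ncount_mean_CD8_T"))
  clin <- cohort$clinical
  surv_rows <- list(); km_rows <- list()
  for (sf in surv_features) {
    src <- if (sf$tp == "ratio") ratios else summ[summ$timepoint == sf$tp, , drop = FALSE]
    if (!sf$col %in% names(src)) next
    idx <- match(clin$patient_id, src$patient_id)
    feature <- src[[sf$col]][idx]
    ds <- dichotomized_survival(feature, clin$os_months, clin$event,
                                n_perm = n_perm, seed = config$seed + 7L)
    if (ds$degenerate) {
      surv_rows[[sf$name]] <- data.frame(feature = sf$name, n = ds$n,
                                         cutoff = NA_real_, n_high = NA_integer_,
                                         n_low = NA_integer_, median_high = NA_real_,
                                         median_low = NA_real_, chisq = NA_real_,
                                         p_logrank = NA_real_, p_permutation = NA_real_,
                                         note = ds$reason)
      next
    }
    surv_rows[[sf$name]] <- data.frame(feature = sf$name, n = ds$n,
                                       cutoff = ds$cutpoint$cutoff,
                                       n_high = ds$cutpoint$n_high,
                                       n_low = ds$cutpoint$n_low,
                                       median_high = ds$median_high,
                                       median_low = ds$median_low,
                                       chisq = ds$test$statistic,
                                       p_logrank = ds$test$p_value,
                                       p_permutation = ds$p_permutation,
                                       note = "")
    for (g in c("high", "low")) {
      km <- if (g == "high") ds$km_high else ds$km_low
      km_rows[[paste(sf$name, g)]] <- data.frame(feature = sf$name, group = g,
                                                 time = km$time, surv = km$surv,
                                                 n_risk = km$n_risk,
                                                 n_event = km$n_event)
    }
  }
  survival_results <- do.call(rbind, surv_rows)
  km_curves <- do.call(rbind, km_rows)

  write_result_csv(summ, file.path(outdir, "sample_metrics.csv"))
  write_result_csv(ratios, file.path(outdir, "paired_ratios.csv"))
  write_result_csv(treatment_tests, file.path(outdir, "treatment_tests.csv"))
  write_result_csv(correlations, file.path(outdir, "correlations.csv"))
  if (!is.null(survival_results)) {
    write_result_csv(survival_results, file.path(outdir, "survival_results.csv"))
  }
  if (!is.null(km_curves)) {
    write_result_csv(km_curves, file.path(outdir, "km_curves.csv"))
  }
  invisible(list(cohort = cohort, summaries = summ, ratios = ratios,
                 treatment_tests = treatment_tests, correlations = correlations,
                 survival_results = survival_results, km_curves = km_curves))
}
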