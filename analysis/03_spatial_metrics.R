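#!/usr/bin/env Rscript
# Per-sample spatial readouts at baseline: regional densities, positivity
# rates, and the paper-style stroma-vs-tumor and correlation analyses.

source("analysis/00_config.R")

st <- study_summaries()
summ <- st$summaries
write.csv(summ, file.path(RESULTS_DIR, "sample_metrics.csv"), row.names = FALSE)

bl <- summ[summ$timepoint == "baseline", ]

cat("Baseline regional densities (cells/mm^2, cohort medians):\n")
for (ph in c("CD4_T", "CD8_T")) {
  s_col <- bl[[paste0("density_", ph, "_stroma")]]
  t_col <- bl[[paste0("density_", ph, "_tumor")]]
  w <- wilcoxon_signed_rank(s_col, t_col)
  cat(sprintf("  %s: stroma %.1f vs tumor %.1f (Wilcoxon p = %.2g)\n",
              ph, median(s_col, na.rm = TRUE), median(t_col, na.rm = TRUE),
              w$p_value))
}

cat("Marker positivity in T cells, tumor vs stroma (medians, %):\n")
for (m in c("KI67", "IFNG")) {
  for (ph in c("CD4_T", "CD8_T")) {
    tv <- bl[[paste0("pct_", m, "_in_", ph, "_tumor")]]
    sv <- bl[[paste0("pct_", m, "_in_", ph, "_stroma")]]
    cat(sprintf("  %s in %s: tumor %.2f vs stroma %.2f\n", m, ph,
                median(tv, na.rm = TRUE), median(sv, na.rm = TRUE)))
  }
}

cat("Density-density rank correlations, stromal region at baseline:\n")
cors <- list()
for (ph in c("CD4_T", "CD8_T")) {
  sp <- spearman_test(bl$density_LAG3_T_stroma, bl[[paste0("density_", ph, "_stroma")]])
  cors[[ph]] <- data.frame(x = "density_LAG3_T_stroma",
                           y = paste0("density_", ph, "_stroma"),
                           rho = sp$statistic, p_value = sp$p_value, n = sp$n)
  cat(sprintf("  LAG3+T vs %s: rho = %.3f, p = %.3g (n = %d)\n",
              ph, sp$statistic, sp$p_value, sp$n))
}
write.csv(do.call(rbind, cors), file.path(RESULTS_DIR, "correlations_baseline.csv"),
          row.names = FALSE)

cat("Tumor-cell-centered spatial metrics at baseline (medians):\n")
cat(sprintf("  nearest CD4+T distance %.1f um; nearest CD8+T distance %.1f um\n",
            median(bl$nndist_mean_CD4_T, na.rm = TRUE),
            median(bl$nndist_mean_CD8_T, na.rm = TRUE)))
cat(sprintf("  mean CD4+T within 50 um: %.3f; mean CD8+T within 50 um: %.3f\n",
            median(bl$ncount_mean_CD4_T, na.rm = TRUE),
            median(bl$ncount_mean_CD8_T, na.rm = TRUE)))
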