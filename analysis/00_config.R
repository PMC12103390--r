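# Shared study configuration for the analysis scripts.
#
# One synthetic cohort stands in for the undeposited clinical dataset:
# 40 patients, each with a paired baseline and on-treatment section.
# Tissue defaults encode the stromal-dominant immune densities, the
# on-treatment density contraction and IFN-gamma rate elevation, a
# positive LAG3 local-density coupling, and a protective survival link to
# stromal CD4 T-cell density.

library(tilspatial)

STUDY_SEED <- 20260901L

study_cohort_config <- function() {
  cohort_config(
    n_patients = 40,
    tissue = tissue_config(lag3_coupling = 0.8, seed = STUDY_SEED),
    density_multiplier = c(CD4_T = 0.67, CD8_T = 0.69),
    ifng_shift = c(CD4_T = 0.095, CD8_T = 0.170),
    patient_sdlog = 0.4,
    hazard = list(baseline = 0.03, feature = "CD4_T",
                  form = "linear", log_hr = -0.5),
    censor_time = 76,
    seed = STUDY_SEED)
}

RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch"
dir.create(RESULTS_DIR, showWarnings = FALSE)
dir.create(SCRATCH_DIR, showWarnings = FALSE)

# Per-sample summaries are recomputed by each script from the same seeded
# configuration, so scripts can run independently and in any order.
study_summaries <- function(resegment = TRUE) {
  co <- generate_cohort(study_cohort_config())
  samples <- if (resegment) lapply(co$samples, segment_regions) else co$samples
  list(cohort = co, samples = samples,
       summaries = summarize_cohort(samples))
}
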