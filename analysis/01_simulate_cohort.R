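#!/usr/bin/env Rscript
# Simulate the study cohort and export its raw artifacts: per-section cell
# tables and ground-truth region masks (bulky, to scratch/) plus the
# clinical table and generator ground truth (small, to results/).

source("analysis/00_config.R")

co <- generate_cohort(study_cohort_config())

cell_dir <- file.path(SCRATCH_DIR, "cohort_cells")
dir.create(cell_dir, showWarnings = FALSE, recursive = TRUE)
for (s in co$samples) {
  stem <- paste0(s$patient_id, "_", s$timepoint)
  write_cell_table(s, file.path(cell_dir, paste0(stem, ".csv")))
  write_polygons(s$geometry$tumor_polygons,
                 file.path(cell_dir, paste0(stem, "_tumor.geojson")))
}
write.csv(co$clinical, file.path(RESULTS_DIR, "clinical.csv"), row.names = FALSE)
write.csv(co$truth, file.path(RESULTS_DIR, "cohort_truth.csv"), row.names = FALSE)

n_cells <- vapply(co$samples, function(s) nrow(s$cells), 0)
cat(sprintf("Simulated %d patients (%d sections, %d cells total).\n",
            nrow(co$clinical), length(co$samples), sum(n_cells)))
cat(sprintf("Median cells per section: %.0f; events observed: %d/%d.\n",
            median(n_cells), sum(co$clinical$event), nrow(co$clinical)))
cat("Cell tables and region masks in", cell_dir,
    "; clinical and truth tables in", RESULTS_DIR, "\n")
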