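# Per-sample spatial readouts: region-stratified densities, marker
# positivity rates within a base phenotype, tumor-cell-centered nearest
# distances and fixed-radius neighbor counts, and paired timepoint ratios.
#
# Distances are computed across region boundaries (a stromal immune cell
# can be the nearest neighbor of a tumor cell) and without edge correction;
# validation against analytic spatial laws is restricted to interior
# centers instead.  Undefined quantities (empty denominator, no neighbor
# cells) are carried as NA, never as 0.

region_area_mm2 <- function(sample, region) {
  g <- sample$geometry
  switch(region,
         tumor = g$tumor_area_mm2,
         stroma = g$stroma_area_mm2,
         all = g$tumor_area_mm2 + g$stroma_area_mm2,
         stop("region must be tumor, stroma or all"))
}

#' Phenotype density
#'
#' Count of phenotype cells in a region divided by the region area.
#' `region = "all"` uses tumor + stroma cells over tumor + stroma area.
#'
#' @param sample a [tissue_sample()].
#' @param phenotype rule name.
#' @param region `"tumor"`, `"stroma"` or `"all"`.
#' @param rules named list of [phenotype_rule()]s.
#' @return cells per mm^2, or `NA` (with a `"diagnostic"` attribute) when
#'   the region area is zero.
#' @export
cell_density <- function(sample, phenotype, region = "stroma",
                         rules = default_phenotype_rules()) {
  region <- match.arg(region, c("tumor", "stroma", "all"))
  area <- region_area_mm2(sample, region)
  if (!is.finite(area) || area <= 0) {
    return(structure(NA_real_,
                     diagnostic = paste0("zero ", region, " area; density undefined")))
  }
  hit <- match_rule(sample, rules[[phenotype]])
  in_region <- if (region == "all") sample$cells$region %in% c("tumor", "stroma")
               else sample$cells$region == region
  sum(hit & in_region) / area
}

#' Marker positivity rate within a base phenotype
#'
#' 100 x count(base phenotype with marker positive) / count(base phenotype)
#' in the region; `NA` when the base count is zero.
#'
#' @param sample a [tissue_sample()].
#' @param base base phenotype rule name (e.g. `CD8_T`).
#' @param marker marker whose positive fraction is reported (e.g. `LAG3`).
#' @param region `"tumor"`, `"stroma"` or `"all"`.
#' @param rules named list of [phenotype_rule()]s.
#' @return percentage in `[0, 100]` or `NA`.
#' @export
positivity_rate <- function(sample, base, marker, region = "all",
                            rules = default_phenotype_rules()) {
  region <- match.arg(region, c("tumor", "stroma", "all"))
  if (is.null(rules[[base]])) stop("unknown base phenotype: ", base)
  if (!marker %in% sample$panel) stop("unknown marker: ", marker)
  hit <- match_rule(sample, rules[[base]])
  in_region <- if (region == "all") sample$cells$region %in% c("tumor", "stroma")
               else sample$cells$region == region
  denom <- sum(hit & in_region)
  if (denom == 0) {
    return(structure(NA_real_,
                     diagnostic = paste0("no ", base, " cells in ", region)))
  }
  100 * sum(hit & in_region & sample$cells[[marker]] == 1L) / denom
}

# Chunked brute-force distances from centers to neighbor set; identical
# cells (same id in both roles) are never their own neighbor.
center_neighbor_stats <- function(cx, cy, cid, nx, ny, nid, radius) {
  m <- length(cx)
  nn <- length(nx)
  mind <- rep(NA_real_, m)
  cnt <- rep(0, m)
  if (m == 0) return(list(min_dist = mind, count = cnt))
  chunk <- max(1L, floor(4e6 / max(1L, nn)))
  r2 <- radius * radius
  for (s in seq(1, m, by = chunk)) {
    idx <- s:min(m, s + chunk - 1L)
    dx <- outer(cx[idx], nx, "-")
    dy <- outer(cy[idx], ny, "-")
    d2 <- dx * dx + dy * dy
    same <- outer(cid[idx], nid, "==")
    if (nn > 0) {
      cnt[idx] <- rowSums(d2 <= r2 & !same)
      d2[same] <- Inf
      md <- apply(d2, 1, min)
      md[!is.finite(md)] <- NA_real_
      mind[idx] <- sqrt(md)
    }
  }
  if (nn == 0) mind[] <- NA_real_
  list(min_dist = mind, count = cnt)
}

#' Nearest-neighbor distances from center cells to a phenotype
#'
#' For each center cell (tumor cells by default) the Euclidean distance to
#' the closest cell of the neighbor phenotype, in any region.  A cell
#' matching both rules is never its own neighbor.
#'
#' @param sample a [tissue_sample()].
#' @param neighbors neighbor phenotype rule name.
#' @param centers center phenotype rule name (default `TUMOR`).
#' @param rules named list of [phenotype_rule()]s.
#' @return list with `per_center` (data frame `cell_id`, `distance`),
#'   `mean`, `median` (of the per-center minima) and `n_centers`,
#'   `n_neighbors`.  Distances are `NA` when no neighbor cells exist;
#'   `mean`/`median` are `NA` with a `"diagnostic"` attribute when there
#'   are no centers or no neighbors.
#' @export
nearest_distances <- function(sample, neighbors, centers = "TUMOR",
                              rules = default_phenotype_rules()) {
  ci <- which(match_rule(sample, rules[[centers]]))
  ni <- which(match_rule(sample, rules[[neighbors]]))
  cells <- sample$cells
  if (length(ci) == 0 || length(ni) == 0) {
    why <- if (length(ci) == 0) paste0("no ", centers, " center cells")
           else paste0("no ", neighbors, " neighbor cells")
    return(structure(list(per_center = data.frame(cell_id = cells$cell_id[ci],
                                                  distance = rep(NA_real_, length(ci))),
                          mean = NA_real_, median = NA_real_,
                          n_centers = length(ci), n_neighbors = length(ni)),
                     diagnostic = why))
  }
  st <- center_neighbor_stats(cells$x_um[ci], cells$y_um[ci], cells$cell_id[ci],
                              cells$x_um[ni], cells$y_um[ni], cells$cell_id[ni],
                              radius = 0)
  d <- st$min_dist
  list(per_center = data.frame(cell_id = cells$cell_id[ci], distance = d),
       mean = mean(d, na.rm = TRUE), median = stats::median(d, na.rm = TRUE),
       n_centers = length(ci), n_neighbors = length(ni))
}

#' Fixed-radius neighbor counts around center cells
#'
#' Number of neighbor-phenotype cells within `radius` of each center cell
#' (the center itself never counted), plus the mean over centers.
#'
#' @inheritParams nearest_distances
#' @param radius pairing radius in micrometres (default 50).
#' @return list with `per_center` (data frame `cell_id`, `count`), `mean`,
#'   `n_centers`, `n_neighbors`, `radius`.  With no neighbor cells all
#'   counts are 0; with no centers the mean is `NA`.
#' @export
neighbor_counts <- function(sample, neighbors, centers = "TUMOR", radius = 50,
                            rules = default_phenotype_rules()) {
  if (radius <= 0) stop("radius must be > 0")
  ci <- which(match_rule(sample, rules[[centers]]))
  ni <- which(match_rule(sample, rules[[neighbors]]))
  cells <- sample$cells
  if (length(ci) == 0) {
    return(structure(list(per_center = data.frame(cell_id = character(0), count = numeric(0)),
                          mean = NA_real_, n_centers = 0L, n_neighbors = length(ni),
                          radius = radius),
                     diagnostic = paste0("no ", centers, " center cells")))
  }
  st <- center_neighbor_stats(cells$x_um[ci], cells$y_um[ci], cells$cell_id[ci],
                              cells$x_um[ni], cells$y_um[ni], cells$cell_id[ni],
                              radius = radius)
  list(per_center = data.frame(cell_id = cells$cell_id[ci], count = st$count),
       mean = mean(st$count), n_centers = length(ci), n_neighbors = length(ni),
       radius = radius)
}

# Metric grid used by summarize_sample / the cohort drivers.
density_phenotypes <- function() c("TUMOR", "CD4_T", "CD8_T", "LAG3_T",
                                   "LAG3_CD4_T", "LAG3_CD8_T")
positivity_pairs <- function() {
  rbind(expand.grid(base = c("CD4_T", "CD8_T"),
                    marker = c("LAG3", "KI67", "IFNG"),
                    stringsAsFactors = FALSE),
        data.frame(base = "TUMOR", marker = "KI67"))
}
spatial_neighbor_phenotypes <- function() c("CD4_T", "CD8_T",
                                            "LAG3_CD4_T", "LAG3_CD8_T")

#' Summarize one sample
#'
#' One row with every per-sample metric: densities per phenotype and
#' region, positivity percentages per (base phenotype, marker, region),
#' and tumor-cell-centered nearest-distance summaries (mean and median of
#' the per-center minima) and mean neighbor counts within `radius`.
#'
#' @param sample a segmented, phenotyped [tissue_sample()].
#' @param rules named list of [phenotype_rule()]s.
#' @param radius pairing radius in micrometres.
#' @return one-row data frame; undefined metrics are `NA`.  A character
#'   vector of diagnostics is attached as attribute `"diagnostics"`.
#' @export
summarize_sample <- function(sample, rules = default_phenotype_rules(),
                             radius = 50) {
  out <- list(patient_id = sample$patient_id, timepoint = sample$timepoint,
              n_cells = nrow(sample$cells),
              tumor_area_mm2 = sample$geometry$tumor_area_mm2,
              stroma_area_mm2 = sample$geometry$stroma_area_mm2)
  diags <- character(0)
  note <- function(x) {
    d <- attr(x, "diagnostic")
    if (!is.null(d)) diags <<- c(diags, d)
    as.numeric(x)
  }
  for (ph in intersect(density_phenotypes(), names(rules))) {
    for (rg in c("tumor", "stroma", "all")) {
      out[[paste0("density_", ph, "_", rg)]] <-
        note(cell_density(sample, ph, rg, rules))
    }
  }
  pp <- positivity_pairs()
  for (i in seq_len(nrow(pp))) {
    if (!pp$base[i] %in% names(rules)) next
    for (rg in c("tumor", "stroma", "all")) {
      out[[paste0("pct_", pp$marker[i], "_in_", pp$base[i], "_", rg)]] <-
        note(positivity_rate(sample, pp$base[i], pp$marker[i], rg, rules))
    }
  }
  for (ph in intersect(spatial_neighbor_phenotypes(), names(rules))) {
    nd <- nearest_distances(sample, ph, "TUMOR", rules)
    nc <- neighbor_counts(sample, ph, "TUMOR", radius, rules)
    out[[paste0("nndist_mean_", ph)]] <- note(structure(nd$mean, diagnostic = attr(nd, "diagnostic")))
    out[[paste0("nndist_median_", ph)]] <- as.numeric(nd$median)
    out[[paste0("ncount_mean_", ph)]] <- note(structure(nc$mean, diagnostic = attr(nc, "diagnostic")))
  }
  res <- as.data.frame(out, stringsAsFactors = FALSE)
  attr(res, "diagnostics") <- diags
  res
}

#' Summarize a list of samples
#'
#' @param samples list of [tissue_sample()]s.
#' @inheritParams summarize_sample
#' @return data frame, one row per sample.
#' @export
summarize_cohort <- function(samples, rules = default_phenotype_rules(),
                             radius = 50) {
  do.call(rbind, lapply(samples, summarize_sample, rules = rules, radius = radius))
}

#' Paired on-treatment / baseline change
#'
#' Elementwise on/baseline ratio for the density metrics of one patient
#' (the CCRT/BL ratio); the ratio is `NA` when the baseline value is
#' missing or zero.
#'
#' @param baseline,on_treatment one-row summaries from
#'   [summarize_sample()] for the same patient.
#' @return one-row data frame with `patient_id` and `ratio_<metric>`
#'   columns.
#' @export
paired_change <- function(baseline, on_treatment) {
  if (!identical(baseline$patient_id, on_treatment$patient_id)) {
    stop("paired summaries must come from the same patient")
  }
  dens <- grep("^density_", names(baseline), value = TRUE)
  out <- list(patient_id = baseline$patient_id)
  for (m in dens) {
    b <- baseline[[m]]; a <- on_treatment[[m]]
    out[[paste0("ratio_", m)]] <-
      if (is.na(b) || is.na(a) || b <= 0) NA_real_ else a / b
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Paired changes for a whole cohort summary
#'
#' @param summaries data frame from [summarize_cohort()] containing
#'   `baseline` and `on_treatment` rows per patient.
#' @return data frame of per-patient CCRT/BL ratios.
#' @export
paired_changes <- function(summaries) {
  pts <- intersect(summaries$patient_id[summaries$timepoint == "baseline"],
                   summaries$patient_id[summaries$timepoint == "on_treatment"])
  do.call(rbind, lapply(pts, function(p) {
    paired_change(summaries[summaries$patient_id == p &
                              summaries$timepoint == "baseline", , drop = FALSE],
                  summaries[summaries$patient_id == p &
                              summaries$timepoint == "on_treatment", , drop = FALSE])
  }))
}
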