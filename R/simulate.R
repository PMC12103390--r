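# Synthetic tissue and cohort generator.
#
# A section is emulated as a Neyman-Scott-style pattern: hard (mutually
# non-overlapping) tumor nests with uniform PANCK+ cells inside each disc,
# and CD4/CD8 T cells as independent Poisson processes with region-specific
# intensities (higher in stroma than inside nests).  Marker positivity
# (LAG3, Ki67, IFN-gamma) is Bernoulli per (phenotype, marker); an optional
# logistic coupling raises a T cell's LAG3 odds with its 50 um T-cell
# neighbor count (standardized within the sample).  Cohorts add per-patient
# density heterogeneity, a paired on-treatment section with multiplicative
# density changes and an additive IFN-gamma rate shift, and exponential
# proportional-hazards survival with administrative censoring.

#' Tissue generator configuration
#'
#' Defaults reproduce the qualitative structure reported for ESCC
#' sections: stromal CD4/CD8 densities of 184 and 62 cells/mm^2 against 40
#' and 30 cells/mm^2 inside tumor nests, low (about 1%) LAG3 positivity,
#' a few percent Ki67/IFN-gamma positivity in T cells, and compact PANCK+
#' cancer nests in a stromal field.
#'
#' @param window c(width, height) of the section in micrometres.
#' @param n_nests number of tumor nests (hard discs, mutually
#'   non-overlapping, fully inside the window).
#' @param nest_radius_mean mean nest radius (um); radii are uniform within
#'   `nest_radius_mean * (1 +/- nest_radius_cv)`.
#' @param nest_radius_cv relative half-range of nest radii.
#' @param tumor_density_in_nest PANCK+ cells per mm^2 inside a nest.
#' @param immune_density_stroma,immune_density_tumor named vectors
#'   (`CD4_T`, `CD8_T`) of cells per mm^2 in stroma / inside nests.
#' @param marker_rates named list, phenotype -> named vector of Bernoulli
#'   positivity rates (markers LAG3/KI67/IFNG for T cells, KI67 for
#'   TUMOR).
#' @param lag3_coupling coefficient (>= 0) adding `coupling * z` to the
#'   LAG3 log-odds of a T cell, where z is its standardized T-cell
#'   neighbor count within `coupling_radius`.
#' @param coupling_radius neighborhood radius (um) for the coupling.
#' @param seed integer seed; the same configuration and seed reproduce the
#'   sample bit-for-bit.
#' @return object of class `tissue_config`.
#' @export
tissue_config <- function(window = c(2000, 2000),
                          n_nests = 5,
                          nest_radius_mean = 150,
                          nest_radius_cv = 0.15,
                          tumor_density_in_nest = 2000,
                          immune_density_stroma = c(CD4_T = 184, CD8_T = 62),
                          immune_density_tumor = c(CD4_T = 40, CD8_T = 30),
                          marker_rates = list(
                            CD4_T = c(LAG3 = 0.012, KI67 = 0.010, IFNG = 0.034),
                            CD8_T = c(LAG3 = 0.010, KI67 = 0.014, IFNG = 0.059),
                            TUMOR = c(KI67 = 0.30)),
                          lag3_coupling = 0,
                          coupling_radius = 50,
                          seed = 1L) {
  window <- as.numeric(window)
  if (length(window) != 2 || any(!is.finite(window)) || any(window <= 0)) {
    stop("window must be c(width, height) > 0")
  }
  if (n_nests < 0) stop("n_nests must be >= 0")
  if (tumor_density_in_nest < 0 || any(immune_density_stroma < 0) ||
      any(immune_density_tumor < 0)) {
    stop("densities must be >= 0")
  }
  rates <- unlist(marker_rates)
  if (length(rates) && any(rates < 0 | rates > 1)) stop("marker rates must be in [0, 1]")
  if (lag3_coupling < 0) stop("lag3_coupling must be >= 0")
  if (n_nests > 0) {
    rmax <- nest_radius_mean * (1 + nest_radius_cv)
    if (2 * rmax >= min(window)) stop("nests do not fit within the window")
  }
  structure(list(window = window, n_nests = as.integer(n_nests),
                 nest_radius_mean = nest_radius_mean,
                 nest_radius_cv = nest_radius_cv,
                 tumor_density_in_nest = tumor_density_in_nest,
                 immune_density_stroma = immune_density_stroma,
                 immune_density_tumor = immune_density_tumor,
                 marker_rates = marker_rates,
                 lag3_coupling = lag3_coupling,
                 coupling_radius = coupling_radius,
                 seed = as.integer(seed)),
            class = "tissue_config")
}

# Deterministic per-sample stream seed derived from (seed, patient index,
# timepoint); all arithmetic stays below 2^53 so it is exact in doubles.
derive_stream_seed <- function(seed, patient_index, timepoint) {
  tp <- match(timepoint, timepoint_levels())
  as.integer((as.numeric(seed) * 48271 + patient_index * 30269 + tp * 20011) %%
               2147483563) + 1L
}

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  expr
}

# Uniform points inside a convex ring, by rejection from the circumscribed
# disc of the generating nest.
sample_in_polygon <- function(n, poly, cx, cy, r) {
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(16L, ceiling((n - length(xs)) * 1.2))
    rr <- r * sqrt(stats::runif(m))
    th <- stats::runif(m, 0, 2 * pi)
    px <- cx + rr * cos(th); py <- cy + rr * sin(th)
    keep <- points_in_polygon(px, py, poly, tol = 0)
    xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
  }
  cbind(xs[seq_len(n)], ys[seq_len(n)])
}

#' Generate one synthetic tissue sample
#'
#' @param config a [tissue_config()].
#' @param patient_id,timepoint metadata stored on the sample.
#' @return a validated [tissue_sample()] whose geometry carries the
#'   ground-truth nest polygons and whose `region` labels are the
#'   generating truth.
#' @export
generate_tissue <- function(config, patient_id = "P1", timepoint = "baseline") {
  stopifnot(inherits(config, "tissue_config"))
  with_seed(config$seed, generate_tissue_impl(config, patient_id, timepoint))
}

generate_tissue_impl <- function(config, patient_id, timepoint) {
  w <- config$window
  window <- c(0, 0, w[1], w[2])
  # --- hard-disc nest centers -------------------------------------------
  n_nests <- config$n_nests
  radii <- numeric(0); cxs <- numeric(0); cys <- numeric(0)
  if (n_nests > 0) {
    gap <- 20  # minimum clearance between nest boundaries (um)
    tries <- 0L
    while (length(radii) < n_nests) {
      tries <- tries + 1L
      if (tries > 10000L) stop("could not place non-overlapping nests; reduce n_nests or radius")
      r <- config$nest_radius_mean *
        stats::runif(1, 1 - config$nest_radius_cv, 1 + config$nest_radius_cv)
      cx <- stats::runif(1, r, w[1] - r)
      cy <- stats::runif(1, r, w[2] - r)
      if (length(radii) == 0 ||
          all(sqrt((cxs - cx)^2 + (cys - cy)^2) >= radii + r + gap)) {
        radii <- c(radii, r); cxs <- c(cxs, cx); cys <- c(cys, cy)
      }
    }
  }
  polys <- mapply(function(cx, cy, r) disc_polygon(cx, cy, r),
                  cxs, cys, radii, SIMPLIFY = FALSE)
  poly_areas_um2 <- vapply(polys, polygon_area, numeric(1))
  tumor_area_mm2 <- sum(poly_areas_um2) / UM2_PER_MM2
  win_area_mm2 <- w[1] * w[2] / UM2_PER_MM2
  stroma_area_mm2 <- win_area_mm2 - tumor_area_mm2

  xs <- list(); ph <- list()
  # --- PANCK+ tumor cells, uniform within each nest polygon -------------
  for (i in seq_along(polys)) {
    ni <- stats::rpois(1, config$tumor_density_in_nest * poly_areas_um2[i] / UM2_PER_MM2)
    if (ni > 0) {
      pts <- sample_in_polygon(ni, polys[[i]], cxs[i], cys[i], radii[i])
      xs <- c(xs, list(cbind(pts, 1)))  # third column: region code 1 = tumor
      ph <- c(ph, list(rep("TUMOR", ni)))
    }
  }
  # --- immune cells: Poisson in stroma and inside nests -----------------
  in_any_nest <- function(px, py) {
    hit <- logical(length(px))
    for (i in seq_along(polys)) {
      todo <- which(!hit)
      if (!length(todo)) break
      near <- (px[todo] - cxs[i])^2 + (py[todo] - cys[i])^2 <= radii[i]^2 * 1.01
      cand <- todo[near]
      if (length(cand)) {
        hit[cand] <- points_in_polygon(px[cand], py[cand], polys[[i]], tol = 0)
      }
    }
    hit
  }
  for (phen in names(config$immune_density_stroma)) {
    lam <- config$immune_density_stroma[[phen]]
    ni <- if (lam > 0) stats::rpois(1, lam * stroma_area_mm2) else 0L
    if (ni > 0) {
      got_x <- numeric(0); got_y <- numeric(0)
      while (length(got_x) < ni) {
        m <- max(32L, ceiling((ni - length(got_x)) / max(1e-6, stroma_area_mm2 / win_area_mm2)))
        px <- stats::runif(m, 0, w[1]); py <- stats::runif(m, 0, w[2])
        keep <- !in_any_nest(px, py)
        got_x <- c(got_x, px[keep]); got_y <- c(got_y, py[keep])
      }
      xs <- c(xs, list(cbind(got_x[seq_len(ni)], got_y[seq_len(ni)], 2)))
      ph <- c(ph, list(rep(phen, ni)))
    }
  }
  for (phen in names(config$immune_density_tumor)) {
    lam <- config$immune_density_tumor[[phen]]
    if (lam <= 0 || length(polys) == 0) next
    for (i in seq_along(polys)) {
      ni <- stats::rpois(1, lam * poly_areas_um2[i] / UM2_PER_MM2)
      if (ni > 0) {
        pts <- sample_in_polygon(ni, polys[[i]], cxs[i], cys[i], radii[i])
        xs <- c(xs, list(cbind(pts, 1)))
        ph <- c(ph, list(rep(phen, ni)))
      }
    }
  }

  if (length(xs)) {
    coords <- do.call(rbind, xs)
    phen <- unlist(ph)
  } else {
    coords <- matrix(numeric(0), ncol = 3)
    phen <- character(0)
  }
  n <- nrow(coords)
  cells <- data.frame(cell_id = sprintf("c%05d", seq_len(n)),
                      x_um = coords[, 1], y_um = coords[, 2],
                      PANCK = as.integer(phen == "TUMOR"),
                      CD4 = as.integer(phen == "CD4_T"),
                      CD8 = as.integer(phen == "CD8_T"),
                      LAG3 = 0L, KI67 = 0L, IFNG = 0L,
                      region = ifelse(coords[, 3] == 1, "tumor", "stroma"),
                      stringsAsFactors = FALSE)

  # --- marker positivity -------------------------------------------------
  rate_of <- function(phen_name, marker) {
    r <- config$marker_rates[[phen_name]]
    if (is.null(r) || is.na(r[marker])) 0 else unname(r[marker])
  }
  for (phen_name in unique(phen)) {
    idx <- which(phen == phen_name)
    for (marker in c("KI67", "IFNG")) {
      rt <- rate_of(phen_name, marker)
      if (rt > 0) cells[[marker]][idx] <- stats::rbinom(length(idx), 1, rt)
    }
  }
  t_idx <- which(phen %in% c("CD4_T", "CD8_T"))
  if (length(t_idx)) {
    base_rate <- vapply(phen[t_idx], rate_of, numeric(1), marker = "LAG3")
    if (config$lag3_coupling > 0 && length(t_idx) > 1) {
      st <- center_neighbor_stats(cells$x_um[t_idx], cells$y_um[t_idx],
                                  cells$cell_id[t_idx],
                                  cells$x_um[t_idx], cells$y_um[t_idx],
                                  cells$cell_id[t_idx],
                                  radius = config$coupling_radius)
      z <- st$count - mean(st$count)
      sdv <- stats::sd(st$count)
      if (is.finite(sdv) && sdv > 0) z <- z / sdv else z <- z * 0
      pr <- stats::plogis(stats::qlogis(pmin(pmax(base_rate, 1e-12), 1 - 1e-12)) +
                            config$lag3_coupling * z)
      pr[base_rate == 0] <- 0
    } else {
      pr <- base_rate
    }
    cells$LAG3[t_idx] <- stats::rbinom(length(t_idx), 1, pr)
  }

  geom <- region_geometry(window = window, tumor_polygons = polys,
                          tumor_area_mm2 = tumor_area_mm2,
                          stroma_area_mm2 = stroma_area_mm2,
                          exclusion_area_mm2 = 0)
  tissue_sample(cells, geometry = geom, patient_id = patient_id,
                timepoint = timepoint)
}

#' Cohort generator configuration
#'
#' @param n_patients number of patients (>= 1); each contributes a paired
#'   baseline and on-treatment section.
#' @param tissue baseline [tissue_config()] shared by the cohort.
#' @param density_multiplier named vector of multiplicative on-treatment
#'   density changes per immune phenotype (defaults follow the observed
#'   stromal CD4 x0.67 and CD8 x0.69 contractions under chemoradiation).
#' @param ifng_shift named vector of additive on-treatment IFN-gamma rate
#'   changes per phenotype (defaults: CD4_T +0.095, CD8_T +0.170).
#' @param patient_sdlog log-sd of the per-patient lognormal density
#'   heterogeneity (mean 1), applied independently per immune phenotype.
#' @param hazard list describing the survival link: `baseline` hazard per
#'   month, `feature` (phenotype whose patient-level density effect drives
#'   survival), `form` (`"linear"`: log-hazard = log(baseline) + log_hr *
#'   standardized log-multiplier; `"binary"`: patients above the median
#'   multiplier have hazard ratio `exp(log_hr)`), `log_hr`.
#' @param censor_time administrative censoring time in months.
#' @param seed master integer seed; per-sample streams are derived from
#'   (seed, patient, timepoint) so generation is reproducible.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 40,
                          tissue = tissue_config(),
                          density_multiplier = c(CD4_T = 0.67, CD8_T = 0.69),
                          ifng_shift = c(CD4_T = 0.095, CD8_T = 0.170),
                          patient_sdlog = 0.4,
                          hazard = list(baseline = 0.03, feature = "CD4_T",
                                        form = "linear", log_hr = -0.5),
                          censor_time = 76,
                          seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (any(density_multiplier <= 0)) stop("density multipliers must be > 0")
  if (censor_time <= 0) stop("censor_time must be > 0")
  if (is.null(hazard$baseline) || hazard$baseline <= 0) stop("baseline hazard must be > 0")
  hazard$form <- match.arg(hazard$form, c("linear", "binary"))
  structure(list(n_patients = as.integer(n_patients), tissue = tissue,
                 density_multiplier = density_multiplier,
                 ifng_shift = ifng_shift,
                 patient_sdlog = patient_sdlog,
                 hazard = hazard, censor_time = censor_time,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a paired synthetic cohort
#'
#' Per patient: a baseline and an on-treatment tissue sample (on-treatment
#' immune intensities = baseline x patient multiplier x treatment
#' multiplier, IFN-gamma rates shifted up and capped at 0.95), plus an
#' exponential proportional-hazards survival time censored at
#' `censor_time`.
#'
#' @param config a [cohort_config()].
#' @return list with `samples` (length 2 x n, baseline then on_treatment
#'   per patient), `clinical` (patient_id, os_months, event) and `truth`
#'   (per-patient multipliers, standardized feature, hazard, group).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  tc <- config$tissue
  phs <- names(tc$immune_density_stroma)
  # patient-level draws from the master stream
  sdlog <- config$patient_sdlog
  mult <- with_seed(config$seed, {
    matrix(stats::rlnorm(n * length(phs), meanlog = -sdlog^2 / 2, sdlog = sdlog),
           nrow = n, dimnames = list(NULL, phs))
  })
  hz <- config$hazard
  feat_mult <- mult[, hz$feature]
  if (sdlog > 0) {
    z <- (log(feat_mult) + sdlog^2 / 2) / sdlog
  } else {
    z <- rep(0, n)
  }
  high <- feat_mult > stats::median(feat_mult)
  rate <- switch(hz$form,
                 linear = hz$baseline * exp(hz$log_hr * z),
                 binary = hz$baseline * exp(hz$log_hr * as.numeric(high)))
  surv <- with_seed(config$seed + 1L, stats::rexp(n, rate = rate))
  event <- as.integer(surv <= config$censor_time)
  os <- pmin(surv, config$censor_time)

  ids <- sprintf("P%03d", seq_len(n))
  samples <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    base_cfg <- tc
    base_cfg$immune_density_stroma <- tc$immune_density_stroma * mult[i, ]
    base_cfg$immune_density_tumor <- tc$immune_density_tumor * mult[i, names(tc$immune_density_tumor)]
    base_cfg$seed <- derive_stream_seed(config$seed, i, "baseline")
    on_cfg <- base_cfg
    dm <- config$density_multiplier
    on_cfg$immune_density_stroma <- base_cfg$immune_density_stroma * dm[names(base_cfg$immune_density_stroma)]
    on_cfg$immune_density_tumor <- base_cfg$immune_density_tumor * dm[names(base_cfg$immune_density_tumor)]
    for (p in names(config$ifng_shift)) {
      r <- on_cfg$marker_rates[[p]]
      if (!is.null(r) && "IFNG" %in% names(r)) {
        r["IFNG"] <- min(0.95, r[["IFNG"]] + config$ifng_shift[[p]])
        on_cfg$marker_rates[[p]] <- r
      }
    }
    on_cfg$seed <- derive_stream_seed(config$seed, i, "on_treatment")
    samples[[2L * i - 1L]] <- generate_tissue(base_cfg, patient_id = ids[i],
                                              timepoint = "baseline")
    samples[[2L * i]] <- generate_tissue(on_cfg, patient_id = ids[i],
                                         timepoint = "on_treatment")
  }
  truth <- data.frame(patient_id = ids, mult, feature_z = z,
                      high_feature = high, hazard = rate,
                      stringsAsFactors = FALSE)
  names(truth)[seq_along(phs) + 1L] <- paste0("mult_", phs)
  clinical <- data.frame(patient_id = ids, os_months = os, event = event,
                         stringsAsFactors = FALSE)
  list(samples = samples, clinical = clinical, truth = truth)
}
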