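# Densities, positivity rates, nearest distances, neighbor counts,
# per-sample summaries and paired ratios.

test_that("density is count over area with the unit convention /mm^2", {
  # 100 cells on 2 mm^2 of stroma -> 50 / mm^2
  set.seed(1)
  s <- make_sample(x = runif(100, 0, 1999), y = runif(100, 0, 999),
                   markers = list(CD4 = rep(1, 100)),
                   window = c(0, 0, 2000, 1000))
  expect_equal(cell_density(s, "CD4_T", "stroma"), 50)
  expect_equal(cell_density(s, "CD8_T", "stroma"), 0)
  expect_equal(cell_density(s, "CD4_T", "all"), 50)
})

test_that("zero-area regions give NA with a diagnostic, not 0", {
  s <- make_sample(x = 1, y = 1, markers = list(CD4 = 1),
                   window = c(0, 0, 100, 100))
  d <- cell_density(s, "CD4_T", "tumor")
  expect_true(is.na(d))
  expect_match(attr(d, "diagnostic"), "zero tumor area")
})

test_that("positivity rate is a percentage of the base phenotype", {
  s <- make_sample(x = 1:8, y = 1:8,
                   markers = list(CD8 = rep(1, 8), LAG3 = c(1, 1, 1, 1, 0, 0, 0, 0)),
                   window = c(0, 0, 10, 10))
  expect_equal(positivity_rate(s, "CD8_T", "LAG3"), 50)
  r <- positivity_rate(s, "CD4_T", "LAG3")
  expect_true(is.na(r))                       # empty denominator is missing
  expect_match(attr(r, "diagnostic"), "no CD4_T")
  expect_error(positivity_rate(s, "CD8_T", "CD57"), "unknown marker")
})

test_that("positivity estimates cover the configured binomial rate", {
  cfg <- stroma_only_config(seed = 77,
                            immune_density_stroma = c(CD4_T = 0, CD8_T = 500),
                            immune_density_tumor = c(CD4_T = 0, CD8_T = 0),
                            marker_rates = list(CD8_T = c(LAG3 = 0.30)))
  s <- generate_tissue(cfg)
  n <- sum(s$cells$CD8)
  p_hat <- positivity_rate(s, "CD8_T", "LAG3") / 100
  ci <- 2.576 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(p_hat - 0.30), ci)
})

test_that("nearest distance solves the 3-4-5 triangle and missing cases", {
  s <- make_sample(x = c(0, 3, 6), y = c(0, 4, 8),
                   markers = list(PANCK = c(1, 0, 0), CD4 = c(0, 1, 1)),
                   window = c(0, 0, 10, 10))
  nd <- nearest_distances(s, "CD4_T")
  expect_equal(nd$per_center$distance, 5)
  expect_equal(nd$mean, 5)
  miss <- nearest_distances(s, "CD8_T")
  expect_true(is.na(miss$mean))
  expect_match(attr(miss, "diagnostic"), "no CD8_T")
})

test_that("neighbor counts respect the radius and never count the center", {
  s <- make_sample(x = c(0, 10, 60), y = c(0, 0, 0),
                   markers = list(PANCK = c(1, 0, 0), CD4 = c(0, 1, 1)),
                   window = c(0, 0, 100, 100))
  nc <- neighbor_counts(s, "CD4_T", radius = 50)
  expect_equal(nc$per_center$count, 1)
  # a cell matching both rules is not its own neighbor
  s2 <- make_sample(x = c(0, 10), y = c(0, 0),
                    markers = list(PANCK = c(1, 0), CD4 = c(1, 1), CD8 = c(1, 0)),
                    window = c(0, 0, 100, 100))
  nc2 <- neighbor_counts(s2, "TUMOR", centers = "TUMOR", radius = 50)
  expect_equal(nc2$per_center$count, 0)
  # no neighbors -> zero counts, mean 0
  nc3 <- neighbor_counts(s, "CD8_T", radius = 50)
  expect_equal(nc3$mean, 0)
})

test_that("spatial metrics match the O(n^2) brute-force oracle exactly", {
  set.seed(23)
  rules <- default_phenotype_rules()
  for (rep in 1:8) {
    n <- sample(50:300, 1)
    s <- make_sample(x = runif(n, 0, 400), y = runif(n, 0, 400),
                     markers = list(PANCK = rbinom(n, 1, 0.4),
                                    CD4 = rbinom(n, 1, 0.4)),
                     window = c(0, 0, 400, 400))
    ci <- which(match_rule(s, rules$TUMOR))
    ni <- which(match_rule(s, rules$CD4_T))
    if (!length(ci) || !length(ni)) next
    cells <- s$cells
    nd <- nearest_distances(s, "CD4_T")
    expect_equal(nd$per_center$distance,
                 oracle_nn(cells$x_um[ci], cells$y_um[ci], cells$cell_id[ci],
                           cells$x_um[ni], cells$y_um[ni], cells$cell_id[ni]))
    r <- runif(1, 10, 120)
    nc <- neighbor_counts(s, "CD4_T", radius = r)
    expect_equal(nc$per_center$count,
                 as.numeric(oracle_count(cells$x_um[ci], cells$y_um[ci],
                                         cells$cell_id[ci], cells$x_um[ni],
                                         cells$y_um[ni], cells$cell_id[ni], r)))
  }
})

test_that("rigid motions leave spatial metrics unchanged", {
  set.seed(31)
  n <- 150
  x <- runif(n, 100, 300); y <- runif(n, 100, 300)
  mk <- list(PANCK = rbinom(n, 1, 0.5), CD4 = rbinom(n, 1, 0.5))
  s1 <- make_sample(x = x, y = y, markers = mk, window = c(0, 0, 1000, 1000))
  th <- 0.7; dx <- 210; dy <- 130
  x2 <- cos(th) * x - sin(th) * y + dx
  y2 <- sin(th) * x + cos(th) * y + dy
  s2 <- make_sample(x = x2, y = y2, markers = mk, window = c(-1000, -1000, 2000, 2000))
  for (f in list(function(s) nearest_distances(s, "CD4_T")$per_center$distance,
                 function(s) neighbor_counts(s, "CD4_T", radius = 42)$per_center$count)) {
    expect_equal(f(s1), f(s2), tolerance = 1e-9)
  }
})

test_that("neighbor counts are non-decreasing in the radius", {
  s <- generate_tissue(small_tissue_config(seed = 14))
  prev <- -Inf
  for (r in c(10, 25, 50, 100, 200)) {
    m <- neighbor_counts(s, "CD4_T", radius = r)$mean
    expect_gte(m, prev)
    prev <- m
  }
})

test_that("summarize_sample equals independent single-metric calls", {
  s <- segment_regions(generate_tissue(small_tissue_config(seed = 4)))
  sm <- summarize_sample(s)
  expect_equal(sm$density_CD4_T_stroma, cell_density(s, "CD4_T", "stroma"))
  expect_equal(sm$pct_LAG3_in_CD8_T_all,
               as.numeric(positivity_rate(s, "CD8_T", "LAG3", "all")))
  nd <- nearest_distances(s, "CD8_T")
  expect_equal(sm$nndist_mean_CD8_T, nd$mean)
  expect_equal(sm$nndist_median_CD8_T, nd$median)
  expect_equal(sm$ncount_mean_CD8_T, neighbor_counts(s, "CD8_T", radius = 50)$mean)
})

test_that("empty samples summarize to zero counts and missing rates", {
  s <- make_sample(x = numeric(0), y = numeric(0), window = c(0, 0, 1000, 1000))
  sm <- summarize_sample(s)
  expect_equal(sm$density_CD4_T_stroma, 0)
  expect_true(is.na(sm$pct_LAG3_in_CD8_T_all))
  expect_true(is.na(sm$nndist_mean_CD4_T))
  expect_gt(length(attr(sm, "diagnostics")), 0)
})

test_that("paired ratios divide on-treatment by baseline and propagate missing", {
  bl <- data.frame(patient_id = "P1", timepoint = "baseline",
                   density_CD4_T_stroma = 100, density_CD8_T_stroma = 0,
                   density_LAG3_T_stroma = NA_real_)
  ot <- data.frame(patient_id = "P1", timepoint = "on_treatment",
                   density_CD4_T_stroma = 50, density_CD8_T_stroma = 10,
                   density_LAG3_T_stroma = 4)
  pc <- paired_change(bl, ot)
  expect_equal(pc$ratio_density_CD4_T_stroma, 0.5)
  expect_true(is.na(pc$ratio_density_CD8_T_stroma))  # baseline zero
  expect_true(is.na(pc$ratio_density_LAG3_T_stroma)) # baseline missing
  ot2 <- ot; ot2$patient_id <- "P2"
  expect_error(paired_change(bl, ot2), "same patient")
})
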