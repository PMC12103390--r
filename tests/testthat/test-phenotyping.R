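# Phenotype rules, thresholding, and counts.

test_that("match_rule implements the marker logic and region exclusion", {
  s <- make_sample(x = 1:4, y = 1:4,
                   markers = list(CD4 = c(1, 1, 0, 1), CD8 = c(0, 0, 1, 0),
                                  PANCK = c(0, 1, 0, 0)),
                   region = c("stroma", "stroma", "tumor", "excluded"),
                   window = c(0, 0, 10, 10))
  rules <- default_phenotype_rules()
  expect_equal(match_rule(s, rules$CD4_T), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(match_rule(s, rules$CD8_T), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(match_rule(s, rules$TUMOR), c(FALSE, TRUE, FALSE, FALSE))
  # excluded-region cell never matches, even with matching markers
  expect_false(match_rule(s, rules$CD4_T)[4])
})

test_that("LAG3_T requires LAG3 plus either T marker, not PANCK", {
  s <- make_sample(x = 1:4, y = 1:4,
                   markers = list(LAG3 = c(1, 1, 1, 0), CD4 = c(1, 0, 0, 1),
                                  CD8 = c(0, 0, 1, 0), PANCK = c(0, 1, 0, 0)),
                   window = c(0, 0, 10, 10))
  rules <- default_phenotype_rules()
  expect_equal(match_rule(s, rules$LAG3_T), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("CD4+CD8+ double positives are excluded from subsets but kept in LAG3_T", {
  s <- make_sample(x = 1, y = 1,
                   markers = list(CD4 = 1, CD8 = 1, LAG3 = 1),
                   window = c(0, 0, 10, 10))
  rules <- default_phenotype_rules()
  expect_false(match_rule(s, rules$CD4_T))
  expect_false(match_rule(s, rules$CD8_T))
  expect_true(match_rule(s, rules$LAG3_T))
  inc <- default_phenotype_rules(double_positive = "include")
  expect_true(match_rule(s, inc$CD4_T))
  expect_true(match_rule(s, inc$CD8_T))
})

test_that("rules referencing unknown markers raise configuration errors", {
  s <- make_sample(x = 1, y = 1, window = c(0, 0, 10, 10))
  bad <- phenotype_rule("X", positive = "CD103")
  expect_error(match_rule(s, bad), "unknown marker")
  expect_error(phenotype_rule("Y", positive = "CD4", negative = "CD4"),
               "overlap")
})

test_that("thresholding uses a closed cutoff and leaves other fields alone", {
  n <- 5
  cells <- data.frame(cell_id = letters[1:n], x_um = 1:n, y_um = 1:n,
                      PANCK = 0L, CD4 = 0L, CD8 = 0L, LAG3 = 0L,
                      KI67 = 0L, IFNG = 0L,
                      LAG3_intensity = c(0, 4.99, 5, 5.01, 10))
  s <- tissue_sample(cells, geometry = region_geometry(c(0, 0, 10, 10)))
  s2 <- apply_thresholds(s, c(LAG3 = 5))
  expect_equal(s2$cells$LAG3, c(0L, 0L, 1L, 1L, 1L))   # intensity 5 at cutoff 5 is positive
  expect_identical(s2$cells$CD4, s$cells$CD4)
  expect_error(apply_thresholds(s, c(CD4 = 1)), "intensity")
  # all intensities below positive cutoffs -> all negative
  s3 <- apply_thresholds(s, c(LAG3 = 100))
  expect_true(all(s3$cells$LAG3 == 0L))
})

test_that("random thresholding equals the element-wise comparison oracle", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 50
    cells <- data.frame(cell_id = sprintf("c%02d", 1:n), x_um = runif(n, 0, 9),
                        y_um = runif(n, 0, 9), PANCK = 0L, CD4 = 0L, CD8 = 0L,
                        LAG3 = 0L, KI67 = 0L, IFNG = 0L,
                        CD4_intensity = rexp(n), KI67_intensity = rexp(n))
    s <- tissue_sample(cells, geometry = region_geometry(c(0, 0, 10, 10)))
    cut <- c(CD4 = runif(1, 0, 2), KI67 = runif(1, 0, 2))
    s2 <- apply_thresholds(s, cut)
    for (m in names(cut)) {
      expected <- integer(n)
      for (i in 1:n) expected[i] <- as.integer(cells[[paste0(m, "_intensity")]][i] >= cut[[m]])
      expect_identical(s2$cells[[m]], expected)
    }
  }
})

test_that("phenotype_counts equals an exhaustive per-cell loop oracle", {
  set.seed(3)
  rules <- default_phenotype_rules()
  for (rep in 1:10) {
    n <- sample(c(0, 1, 60), 1)
    s <- make_sample(x = runif(n, 0, 99), y = runif(n, 0, 99),
                     markers = list(PANCK = rbinom(n, 1, 0.3),
                                    CD4 = rbinom(n, 1, 0.4),
                                    CD8 = rbinom(n, 1, 0.4),
                                    LAG3 = rbinom(n, 1, 0.3),
                                    KI67 = rbinom(n, 1, 0.3),
                                    IFNG = rbinom(n, 1, 0.3)),
                     region = sample(c("tumor", "stroma", "excluded"), max(n, 1), TRUE)[seq_len(n)],
                     window = c(0, 0, 100, 100))
    counts <- phenotype_counts(s, rules)
    for (k in seq_len(nrow(counts))) {
      r <- rules[[counts$phenotype[k]]]
      expected <- 0L
      for (i in seq_len(n)) {
        cell <- s$cells[i, ]
        if (cell$region != counts$region[k]) next
        ok <- all(vapply(r$positive, function(m) cell[[m]] == 1, TRUE)) &&
          all(vapply(r$negative, function(m) cell[[m]] == 0, TRUE)) &&
          (length(r$any_of) == 0 || any(vapply(r$any_of, function(m) cell[[m]] == 1, TRUE)))
        if (ok) expected <- expected + 1L
      }
      expect_identical(as.integer(counts$count[k]), expected)
    }
  }
})

test_that("empty samples give all-zero counts", {
  s <- make_sample(x = numeric(0), y = numeric(0), window = c(0, 0, 10, 10))
  counts <- phenotype_counts(s)
  expect_true(all(counts$count == 0))
})

test_that("nesting: marker-refined phenotype counts never exceed the base", {
  set.seed(21)
  cfg <- small_tissue_config(seed = 5, lag3_coupling = 0.8)
  s <- generate_tissue(cfg)
  counts <- phenotype_counts(s)
  get <- function(ph) sum(counts$count[counts$phenotype == ph])
  for (base in c("CD4_T", "CD8_T")) {
    for (pre in c("LAG3_", "KI67_", "IFNG_")) {
      expect_lte(get(paste0(pre, base)), get(base))
    }
  }
  expect_lte(get("KI67_TUMOR"), get("TUMOR"))
  # monotonicity: adding a required-positive marker never increases a count
  rules <- default_phenotype_rules()
  wider <- rules$CD4_T
  narrower <- phenotype_rule("CD4_T_KI67", positive = c(wider$positive, "KI67"),
                             negative = wider$negative)
  expect_lte(sum(match_rule(s, narrower)), sum(match_rule(s, wider)))
})

test_that("raising a cutoff never increases counts requiring that marker", {
  set.seed(13)
  n <- 200
  cells <- data.frame(cell_id = sprintf("c%03d", 1:n),
                      x_um = runif(n, 0, 99), y_um = runif(n, 0, 99),
                      PANCK = 0L, CD4 = rbinom(n, 1, 0.5), CD8 = 0L,
                      LAG3 = 0L, KI67 = 0L, IFNG = 0L,
                      LAG3_intensity = rexp(n))
  s <- tissue_sample(cells, geometry = region_geometry(c(0, 0, 100, 100)))
  rules <- default_phenotype_rules()
  prev <- Inf
  for (cut in c(0.1, 0.5, 1, 2, 4)) {
    cnt <- sum(match_rule(apply_thresholds(s, c(LAG3 = cut)), rules$LAG3_CD4_T))
    expect_lte(cnt, prev)
    prev <- cnt
  }
})
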