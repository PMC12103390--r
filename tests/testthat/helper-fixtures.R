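# Shared fixtures and independent oracles.  The oracles are deliberately
# naive (per-element loops, textbook formulas) and share no code with the
# package implementations they check.

# Minimal hand-built sample: explicit coordinates/markers/regions.
make_sample <- function(x, y, markers = list(), region = NULL,
                        window = NULL, geometry = NULL, ...) {
  n <- length(x)
  cells <- data.frame(cell_id = sprintf("h%03d", seq_len(n)),
                      x_um = x, y_um = y,
                      PANCK = rep(0L, n), CD4 = rep(0L, n), CD8 = rep(0L, n),
                      LAG3 = rep(0L, n), KI67 = rep(0L, n), IFNG = rep(0L, n),
                      stringsAsFactors = FALSE)
  for (m in names(markers)) cells[[m]] <- as.integer(markers[[m]])
  if (!is.null(region)) cells$region <- region
  if (is.null(geometry) && !is.null(window)) geometry <- region_geometry(window)
  tissue_sample(cells, geometry = geometry, ...)
}

# Small tissue configuration for fast simulations.
small_tissue_config <- function(seed = 1L, ...) {
  tissue_config(window = c(1000, 1000), n_nests = 2, nest_radius_mean = 120,
                seed = seed, ...)
}

# Pure-stroma configuration (no nests).
stroma_only_config <- function(seed = 1L, window = c(2000, 2000), ...) {
  tissue_config(window = window, n_nests = 0, seed = seed, ...)
}

# O(n^2) per-center nearest distance, plain loops.
oracle_nn <- function(cx, cy, cid, nx, ny, nid) {
  out <- rep(NA_real_, length(cx))
  for (i in seq_along(cx)) {
    best <- Inf
    for (j in seq_along(nx)) {
      if (cid[i] == nid[j]) next
      d <- sqrt((cx[i] - nx[j])^2 + (cy[i] - ny[j])^2)
      if (d < best) best <- d
    }
    if (is.finite(best)) out[i] <- best
  }
  out
}

# O(n^2) fixed-radius neighbor count, plain loops.
oracle_count <- function(cx, cy, cid, nx, ny, nid, r) {
  out <- integer(length(cx))
  for (i in seq_along(cx)) {
    k <- 0L
    for (j in seq_along(nx)) {
      if (cid[i] == nid[j]) next
      if ((cx[i] - nx[j])^2 + (cy[i] - ny[j])^2 <= r * r) k <- k + 1L
    }
    out[i] <- k
  }
  out
}

# Shoelace area from the raw cross-product sum (textbook form).
oracle_shoelace <- function(poly) {
  n <- nrow(poly)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]
  }
  abs(s) / 2
}

# Crossing-number point-in-polygon (strict interior; used where tests keep
# points away from boundaries).
oracle_pip <- function(px, py, poly) {
  n <- nrow(poly)
  out <- logical(length(px))
  for (k in seq_along(px)) {
    crossings <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      yi <- poly[i, 2]; yj <- poly[j, 2]
      if ((yi > py[k]) != (yj > py[k])) {
        xint <- poly[i, 1] + (py[k] - yi) * (poly[j, 1] - poly[i, 1]) / (yj - yi)
        if (px[k] < xint) crossings <- crossings + 1L
      }
    }
    out[k] <- crossings %% 2L == 1L
  }
  out
}

# Full 2^n enumeration of the signed-rank null (exact oracle, n <= 12).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    vs[mask + 1] <- sum(r[signs])
  }
  p_le <- mean(vs <= v_obs + 1e-12)
  p_ge <- mean(vs >= v_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# Exhaustive cutpoint enumeration oracle: every midpoint in both
# orientations; direction with the larger best J wins (">=" on ties), then
# the balanced-then-smaller tie-break.
oracle_cutpoint <- function(values, outcome) {
  uv <- sort(unique(values))
  cuts <- (uv[-length(uv)] + uv[-1]) / 2
  best_dir <- function(dir) {
    best <- NULL
    for (cc in cuts) {
      pred <- if (dir == ">=") values >= cc else values <= cc
      # note: with midpoint cuts, values <= cc is the complement of >= cc
      sens <- sum(pred & outcome == 1) / sum(outcome == 1)
      spec <- sum(!pred & outcome == 0) / sum(outcome == 0)
      j <- sens + spec - 1
      bal <- abs(sum(values >= cc) - sum(values < cc))
      cand <- list(cut = cc, j = j, bal = bal, dir = dir)
      if (is.null(best) || j > best$j + 1e-12 ||
          (abs(j - best$j) <= 1e-12 && bal < best$bal - 1e-12)) {
        best <- cand
      }
    }
    best
  }
  b_ge <- best_dir(">="); b_le <- best_dir("<=")
  if (b_ge$j >= b_le$j - 1e-12) b_ge else b_le
}

expect_sample_valid <- function(s) {
  expect_s3_class(s, "tissue_sample")
  # re-validation through the constructor must succeed
  expect_silent(tissue_sample(s$cells, geometry = s$geometry,
                              patient_id = s$patient_id,
                              timepoint = s$timepoint))
}
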