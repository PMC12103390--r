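# Statistical layer: paired Wilcoxon signed-rank (exact by enumeration for
# small n, tie- and continuity-corrected normal approximation otherwise),
# Spearman rank correlation, ROC-derived Youden cutpoints, Kaplan-Meier
# estimation and log-rank tests, and the dichotomized survival pipeline
# with an optional permutation-calibrated p-value.

til_test <- function(statistic, p_value, n, method, ...) {
  structure(c(list(statistic = statistic, p_value = p_value, n = n,
                   method = method, two_sided = TRUE), list(...)),
            class = "til_test")
}

#' @export
print.til_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d%s)\n",
              x$method, x$statistic, x$p_value, x$n,
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

# Exact two-sided p for the signed-rank statistic given the (mid)ranks of
# the non-zero |differences|.  The null distribution is built by dynamic
# programming over doubled ranks (midranks are multiples of 1/2), which is
# equivalent to full 2^n enumeration but polynomial time; ties are handled
# by conditioning on the observed rank multiset.
signed_rank_exact_p <- function(ranks, v) {
  s <- as.integer(round(2 * ranks))
  tot <- sum(s)
  f <- numeric(tot + 1L)
  f[1L] <- 1
  for (si in s) {
    shifted <- c(rep(0, si), f[seq_len(tot + 1L - si)])
    f <- f + shifted
  }
  f <- f / 2^length(s)
  v2 <- as.integer(round(2 * v))
  p_le <- sum(f[seq_len(v2 + 1L)])
  p_ge <- sum(f[(v2 + 1L):(tot + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (classic Wilcoxon convention; `zeros =
#' "pratt"` ranks them first and then discards their contribution).  With
#' at most `exact_max` non-zero pairs the two-sided p-value comes from the
#' exact null distribution (enumeration over sign assignments, valid under
#' ties); otherwise from the normal approximation with tie correction and
#' a continuity correction.
#'
#' @param a,b paired numeric vectors, or `b = NULL` and `a` the vector of
#'   differences.
#' @param exact_max largest number of non-zero pairs for which the exact
#'   distribution is enumerated.
#' @param zeros `"drop"` (default) or `"pratt"`.
#' @return a `til_test` with `statistic` (V, sum of positive ranks),
#'   `p_value`, `n` (non-zero pairs).  All-zero differences yield a
#'   degenerate result with p = 1.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, exact_max = 25,
                                 zeros = c("drop", "pratt")) {
  zeros <- match.arg(zeros)
  d <- if (is.null(b)) as.numeric(a) else as.numeric(a) - as.numeric(b)
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("no usable pairs")
  if (zeros == "drop") {
    d_ranked <- d[d != 0]
    r_all <- rank(abs(d_ranked))
    r_nz <- r_all
    d_nz <- d_ranked
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    r_nz <- r_all[keep]
    d_nz <- d[keep]
  }
  n <- length(d_nz)
  if (n == 0) {
    return(til_test(statistic = 0, p_value = 1, n = 0L,
                    method = "Wilcoxon signed-rank (degenerate: all differences zero)",
                    degenerate = TRUE))
  }
  v <- sum(r_nz[d_nz > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r_nz, v)
    method <- "Wilcoxon signed-rank (exact)"
  } else {
    mu <- sum(r_nz) / 2
    # with midranks, sum(r^2)/4 equals n(n+1)(2n+1)/24 minus the usual
    # tie correction sum(t^3 - t)/48
    sig2 <- sum(r_nz^2) / 4
    z_num <- v - mu
    z <- (z_num - sign(z_num) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  til_test(statistic = v, p_value = min(1, p), n = as.integer(n),
           method = method, degenerate = FALSE)
}

#' Spearman rank correlation test
#'
#' rho is the Pearson correlation of midranks (average ranks for ties);
#' the p-value uses the t approximation on n - 2 degrees of freedom.
#' Pairs with a missing value in either vector are removed listwise.
#'
#' @param x,y numeric vectors.
#' @return a `til_test` with `statistic` = rho.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs for a rank correlation")
  rho <- stats::cor(rank(x), rank(y))
  if (is.na(rho)) stop("rank correlation undefined (constant ranks)")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  til_test(statistic = rho, p_value = p, n = as.integer(n),
           method = "Spearman rank correlation (t approximation)")
}

#' ROC-optimal cutpoint by the Youden index
#'
#' Every midpoint between adjacent sorted unique values is evaluated.
#' `direction = ">="` treats `value >= cutoff` as predicting the positive
#' outcome; `"<="` the reverse (a protective feature); `"auto"` (default)
#' picks the direction whose best cutpoint attains the larger Youden J
#' (i.e. the orientation a ROC curve with AUC >= 0.5 would use), preferring
#' `">="` on ties.  Ties in J are then broken toward the cutoff giving the
#' most balanced high/low groups, then toward the smaller cutoff.
#'
#' @param values numeric feature vector.
#' @param outcome binary vector (1 = positive class), same length.
#' @param direction `"auto"`, `">="` or `"<="`.
#' @return list with `cutoff`, `direction`, `sensitivity`, `specificity`,
#'   `youden_j`, `n_high`, `n_low` (`n_high` counts `value >= cutoff`
#'   regardless of direction).
#' @export
roc_cutpoint <- function(values, outcome, direction = c("auto", ">=", "<=")) {
  direction <- match.arg(direction)
  ok <- is.finite(values) & !is.na(outcome)
  values <- values[ok]; outcome <- as.integer(outcome[ok])
  if (any(!outcome %in% c(0L, 1L))) stop("outcome must be binary 0/1")
  if (length(unique(outcome)) < 2) stop("both outcome classes must be present")
  uv <- sort(unique(values))
  if (length(uv) < 2) stop("no valid split: feature is constant")
  cuts <- (uv[-length(uv)] + uv[-1]) / 2
  n_pos <- sum(outcome == 1L); n_neg <- sum(outcome == 0L)
  sens_ge <- vapply(cuts, function(cc) sum(values >= cc & outcome == 1L), 0) / n_pos
  spec_ge <- vapply(cuts, function(cc) sum(values < cc & outcome == 0L), 0) / n_neg
  j_ge <- sens_ge + spec_ge - 1
  # under "<=", sensitivity/specificity swap complements and J flips sign
  if (direction == "auto") {
    direction <- if (max(j_ge) >= max(-j_ge) - 1e-12) ">=" else "<="
  }
  j <- if (direction == ">=") j_ge else -j_ge
  n_high <- vapply(cuts, function(cc) sum(values >= cc), 0L)
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1) {
    imbalance <- abs(n_high[best] - (length(values) - n_high[best]))
    best <- best[imbalance <= min(imbalance) + 1e-12]
  }
  best <- best[1]  # candidates sorted ascending: smaller cutoff wins
  list(cutoff = cuts[best],
       direction = direction,
       sensitivity = if (direction == ">=") sens_ge[best] else 1 - sens_ge[best],
       specificity = if (direction == ">=") spec_ge[best] else 1 - spec_ge[best],
       youden_j = j[best],
       n_high = as.integer(n_high[best]),
       n_low = as.integer(length(values) - n_high[best]))
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator via [survival::survfit()].  The median is the
#' smallest observed time at which the survival estimate falls to 0.5 or
#' below; when the curve never reaches 0.5 the median is `NA` ("not
#' reached").
#'
#' @param time survival times (months, >= 0).
#' @param event 1 = death observed, 0 = censored.
#' @return object of class `km_fit`: `time`, `n_risk`, `n_event`, `surv`,
#'   `median`, `n`.
#' @export
km_estimate <- function(time, event) {
  if (any(!is.finite(time) | time < 0)) stop("survival times must be finite and >= 0")
  if (any(!event %in% c(0, 1))) stop("event must be 0 or 1")
  if (length(time) < 1) stop("need at least one record")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  reached <- fit$surv <= 0.5 + 1e-12
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv,
                 median = if (any(reached)) min(fit$time[reached]) else NA_real_,
                 n = length(time)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  med <- if (is.na(x$median)) "NR" else sprintf("%.2f", x$median)
  cat(sprintf("<km_fit> n = %d, events = %d, median = %s\n",
              x$n, sum(x$n_event), med))
  invisible(x)
}

#' Log-rank test
#'
#' Two- or k-group log-rank chi-square via [survival::survdiff()].
#'
#' @param time,event survival data.
#' @param group group labels (>= 2 non-empty groups).
#' @return a `til_test` with `statistic` = chi-square and `df`.
#' @export
log_rank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stop("need at least two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  til_test(statistic = sd$chisq,
           p_value = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
           n = length(time), method = "log-rank", df = df)
}

#' Optimal-cutpoint survival dichotomization
#'
#' The paper-style pipeline: a ROC cutpoint on the feature (positive class
#' = observed death by default) splits patients into high/low groups;
#' Kaplan-Meier curves, group medians and the log-rank p are reported.
#' Because optimizing the cutpoint inflates the type-I error, an optional
#' permutation-calibrated p is computed by permuting the feature values
#' and rerunning the full cutpoint + log-rank pipeline.
#'
#' @param feature per-patient feature values.
#' @param time,event survival data aligned with `feature`.
#' @param n_perm number of permutations for the calibrated p (0 = skip).
#' @param seed optional integer seed for the permutations.
#' @return list with `cutpoint`, `km_high`, `km_low`, `test`,
#'   `median_high`, `median_low`, `p_permutation` (NA when not computed),
#'   `degenerate` flag, and `n`.
#' @export
dichotomized_survival <- function(feature, time, event, n_perm = 0, seed = NULL) {
  ok <- is.finite(feature) & is.finite(time) & !is.na(event)
  feature <- feature[ok]; time <- time[ok]; event <- as.integer(event[ok])
  n <- length(feature)
  degenerate <- function(reason) {
    list(cutpoint = NULL, km_high = NULL, km_low = NULL, test = NULL,
         median_high = NA_real_, median_low = NA_real_,
         p_permutation = NA_real_, degenerate = TRUE, reason = reason, n = n)
  }
  if (n < 4) return(degenerate("fewer than 4 usable records"))
  if (length(unique(feature)) < 2) return(degenerate("constant feature: no valid split"))
  if (length(unique(event)) < 2) return(degenerate("single outcome class for ROC"))
  cp <- roc_cutpoint(feature, event)
  run_split <- function(f) {
    grp <- ifelse(f >= roc_cutpoint(f, event)$cutoff, "high", "low")
    if (length(unique(grp)) < 2) return(NULL)
    log_rank_test(time, event, grp)
  }
  grp <- ifelse(feature >= cp$cutoff, "high", "low")
  if (length(unique(grp)) < 2) return(degenerate("degenerate group after split"))
  test <- log_rank_test(time, event, grp)
  km_h <- km_estimate(time[grp == "high"], event[grp == "high"])
  km_l <- km_estimate(time[grp == "low"], event[grp == "low"])
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed)
    }
    obs <- test$statistic
    hits <- 0L
    for (i in seq_len(n_perm)) {
      tt <- run_split(sample(feature))
      if (!is.null(tt) && tt$statistic >= obs - 1e-12) hits <- hits + 1L
    }
    p_perm <- (1 + hits) / (n_perm + 1)
  }
  list(cutpoint = cp, km_high = km_h, km_low = km_l, test = test,
       median_high = km_h$median, median_low = km_l$median,
       p_permutation = p_perm, degenerate = FALSE, n = n)
}

# RNG bookkeeping so seeded helpers do not disturb the caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
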