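# Phenotype calling: named marker-logic predicates over the per-cell
# positivity calls, plus intensity thresholding when raw intensities are
# available.  A cell may satisfy several phenotypes at once (e.g. CD8_T and
# LAG3_CD8_T); cells in excluded regions never match any rule.

#' Define a phenotype rule
#'
#' A named predicate over marker calls: all `positive` markers must be
#' positive, all `negative` markers negative, and (when given) at least one
#' of `any_of` positive.  `any_of` covers phenotypes such as LAG3+ T cells,
#' which require LAG3 plus either CD4 or CD8.
#'
#' @param name phenotype name (unique within a rule set).
#' @param positive,negative,any_of character vectors of marker names;
#'   `positive` and `negative` must be disjoint.
#' @return object of class `phenotype_rule`.
#' @export
phenotype_rule <- function(name, positive = character(), negative = character(),
                           any_of = character()) {
  if (length(intersect(positive, negative))) {
    stop("rule ", name, ": require_positive and require_negative overlap")
  }
  structure(list(name = name, positive = positive, negative = negative,
                 any_of = any_of),
            class = "phenotype_rule")
}

#' Default phenotype rule set
#'
#' TUMOR = PANCK+; CD4_T = CD4+ CD8- PANCK-; CD8_T = CD8+ CD4- PANCK-;
#' LAG3_T = LAG3+ PANCK- with CD4 or CD8 positive; refined phenotypes
#' (LAG3_/KI67_/IFNG_ prefixed) add one marker to a base T rule, and
#' KI67_TUMOR adds Ki67 to PANCK+.
#'
#' CD4+CD8+ double positives are excluded from both T subsets by default
#' (the subsets are treated as disjoint) but still count towards LAG3_T;
#' set `double_positive = "include"` to drop the mutual exclusion.
#'
#' @param double_positive how CD4+CD8+ cells enter the CD4_T/CD8_T subsets.
#' @return named list of [phenotype_rule()]s.
#' @export
default_phenotype_rules <- function(double_positive = c("exclude", "include")) {
  double_positive <- match.arg(double_positive)
  cd4_neg <- c("PANCK", if (double_positive == "exclude") "CD8")
  cd8_neg <- c("PANCK", if (double_positive == "exclude") "CD4")
  rules <- list(
    phenotype_rule("TUMOR", positive = "PANCK"),
    phenotype_rule("CD4_T", positive = "CD4", negative = cd4_neg),
    phenotype_rule("CD8_T", positive = "CD8", negative = cd8_neg),
    phenotype_rule("LAG3_T", positive = "LAG3", negative = "PANCK",
                   any_of = c("CD4", "CD8")),
    phenotype_rule("LAG3_CD4_T", positive = c("LAG3", "CD4"), negative = cd4_neg),
    phenotype_rule("LAG3_CD8_T", positive = c("LAG3", "CD8"), negative = cd8_neg),
    phenotype_rule("KI67_CD4_T", positive = c("KI67", "CD4"), negative = cd4_neg),
    phenotype_rule("KI67_CD8_T", positive = c("KI67", "CD8"), negative = cd8_neg),
    phenotype_rule("IFNG_CD4_T", positive = c("IFNG", "CD4"), negative = cd4_neg),
    phenotype_rule("IFNG_CD8_T", positive = c("IFNG", "CD8"), negative = cd8_neg),
    phenotype_rule("KI67_TUMOR", positive = c("KI67", "PANCK"))
  )
  stats::setNames(rules, vapply(rules, `[[`, "", "name"))
}

#' Apply intensity cutoffs to derive marker positivity
#'
#' Positivity is the closed comparison `intensity >= cutoff`.  Only markers
#' named in `cutoffs` are recomputed; all other columns are untouched.
#'
#' @param sample a [tissue_sample()] carrying `<marker>_intensity` columns
#'   for every marker in `cutoffs`.
#' @param cutoffs named numeric vector, marker -> intensity cutoff
#'   (finite, >= 0).
#' @return the sample with updated positivity calls.
#' @export
apply_thresholds <- function(sample, cutoffs) {
  stopifnot(inherits(sample, "tissue_sample"))
  if (is.null(names(cutoffs)) || any(!nzchar(names(cutoffs)))) {
    stop("cutoffs must be a named vector")
  }
  if (any(!is.finite(cutoffs) | cutoffs < 0)) stop("cutoffs must be finite and >= 0")
  for (m in names(cutoffs)) {
    icol <- paste0(m, "_intensity")
    if (!icol %in% names(sample$cells)) {
      stop("no intensity column for marker ", m, " (expected ", icol, ")")
    }
    if (!m %in% sample$panel) stop("marker ", m, " is not in the panel")
    sample$cells[[m]] <- as.integer(sample$cells[[icol]] >= cutoffs[[m]])
  }
  sample
}

# Logical match vector of a rule over a cell data frame.
match_rule_cells <- function(cells, rule, panel) {
  used <- c(rule$positive, rule$negative, rule$any_of)
  unknown <- setdiff(used, panel)
  if (length(unknown)) {
    stop("rule ", rule$name, " references unknown marker(s): ",
         paste(unknown, collapse = ", "))
  }
  n <- nrow(cells)
  ok <- rep(TRUE, n)
  for (m in rule$positive) ok <- ok & cells[[m]] == 1L
  for (m in rule$negative) ok <- ok & cells[[m]] == 0L
  if (length(rule$any_of)) {
    any_ok <- rep(FALSE, n)
    for (m in rule$any_of) any_ok <- any_ok | cells[[m]] == 1L
    ok <- ok & any_ok
  }
  ok & cells$region != "excluded"
}

#' Match a phenotype rule against a sample
#'
#' @param sample a [tissue_sample()].
#' @param rule a [phenotype_rule()].
#' @return logical vector, one entry per cell; excluded-region cells are
#'   always `FALSE`.
#' @export
match_rule <- function(sample, rule) {
  stopifnot(inherits(sample, "tissue_sample"), inherits(rule, "phenotype_rule"))
  match_rule_cells(sample$cells, rule, sample$panel)
}

#' Phenotype membership matrix
#'
#' @param sample a [tissue_sample()].
#' @param rules named list of [phenotype_rule()]s.
#' @return logical matrix, cells x phenotypes.
#' @export
phenotype_matrix <- function(sample, rules = default_phenotype_rules()) {
  stopifnot(inherits(sample, "tissue_sample"))
  out <- vapply(rules, function(r) match_rule_cells(sample$cells, r, sample$panel),
                logical(nrow(sample$cells)))
  if (nrow(sample$cells) == 1L) out <- matrix(out, nrow = 1,
                                              dimnames = list(NULL, names(rules)))
  if (nrow(sample$cells) == 0L) out <- matrix(logical(0), nrow = 0, ncol = length(rules),
                                              dimnames = list(NULL, names(rules)))
  colnames(out) <- vapply(rules, `[[`, "", "name")
  out
}

#' Phenotype counts per region
#'
#' @param sample a [tissue_sample()].
#' @param rules named list of [phenotype_rule()]s.
#' @return data frame with columns `phenotype`, `region` (tumor/stroma) and
#'   `count`; a cell may contribute to several phenotypes.
#' @export
phenotype_counts <- function(sample, rules = default_phenotype_rules()) {
  pm <- phenotype_matrix(sample, rules)
  regions <- c("tumor", "stroma")
  out <- expand.grid(phenotype = colnames(pm), region = regions,
                     stringsAsFactors = FALSE)
  out$count <- mapply(function(ph, rg) {
    sum(pm[, ph] & sample$cells$region == rg)
  }, out$phenotype, out$region)
  out <- out[order(match(out$phenotype, colnames(pm)),
                   match(out$region, regions)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
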