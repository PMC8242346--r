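#' Associate gene expression with ordinal tumor stage
#'
#' Spearman rank correlation of expression with the ordinal stage code;
#' positive effect = higher expression at higher stage. Requires at least 3
#' populated stage levels; otherwise the gene is skipped with a warning.
#'
#' @param expression Numeric vector of expression values.
#' @param stage Ordinal stage codes (integers; NA allowed).
#' @return List with `effect` and `p`, or NULL when skipped.
#' @export
stage_association <- function(expression, stage) {
  keep <- !is.na(stage) & !is.na(expression)
  if (length(unique(stage[keep])) < 3) {
    warning("fewer than 3 stage levels populated; association skipped",
            call. = FALSE)
    return(NULL)
  }
  ct <- suppressWarnings(stats::cor.test(expression[keep], stage[keep],
                                         method = "spearman"))
  list(effect = unname(ct$estimate), p = ct$p.value)
}

#' Associate gene expression with gender
#'
#' Two-sided Mann-Whitney test between the two gender categories; the
#' effect is the signed rank-biserial correlation, positive when
#' expression is higher in the reference (first-sorted) category.
#'
#' @param expression Numeric vector.
#' @param gender Character/factor with two categories; the reference is the
#'   first level after sorting (e.g. "female" before "male").
#' @return List with `effect`, `p` and `reference`, or NULL when one
#'   category has fewer than 3 samples.
#' @export
gender_association <- function(expression, gender) {
  keep <- !is.na(gender) & !is.na(expression)
  g <- as.character(gender[keep]); e <- expression[keep]
  lev <- sort(unique(g))
  if (length(lev) != 2 || min(table(g)) < 3) {
    warning("need two gender categories with >= 3 samples each; skipped",
            call. = FALSE)
    return(NULL)
  }
  a <- e[g == lev[1]]; b <- e[g == lev[2]]
  p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  u <- sum(rank(c(a, b))[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  effect <- 2 * u / (length(a) * length(b)) - 1  # rank-biserial, in [-1, 1]
  list(effect = effect, p = p, reference = lev[1])
}

#' Associate gene expression with age
#'
#' Spearman rank correlation with continuous age (invariant to monotone
#' transformations of age). Requires >= 10 samples with age; constant age
#' is skipped.
#'
#' @param expression Numeric vector.
#' @param age Numeric ages (NA allowed).
#' @param age_cut Optional dichotomizing cutoff; when given, a two-sided
#'   Mann-Whitney of expression in age > cut versus age <= cut is used
#'   instead, with a rank-biserial effect (positive = higher expression in
#'   the older group).
#' @return List with `effect` and `p`, or NULL when skipped.
#' @export
age_association <- function(expression, age, age_cut = NULL) {
  keep <- !is.na(age) & !is.na(expression)
  if (sum(keep) < 10) {
    warning("fewer than 10 samples with age; association skipped", call. = FALSE)
    return(NULL)
  }
  e <- expression[keep]; a <- age[keep]
  if (stats::sd(a) == 0) {
    warning("constant age; association skipped", call. = FALSE)
    return(NULL)
  }
  if (!is.null(age_cut)) {
    older <- a > age_cut
    if (min(sum(older), sum(!older)) < 3) {
      warning("age dichotomy leaves a group with < 3 samples; skipped",
              call. = FALSE)
      return(NULL)
    }
    x <- e[older]; y <- e[!older]
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    u <- sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    return(list(effect = 2 * u / (length(x) * length(y)) - 1, p = p))
  }
  ct <- suppressWarnings(stats::cor.test(e, a, method = "spearman"))
  list(effect = unname(ct$estimate), p = ct$p.value)
}

#' Clinical associations for all genes in a cohort
#'
#' Runs the stage, gender and age associations for every gene over the
#' tumor samples and applies BH FDR per covariate within the cancer type.
#'
#' @param cohort An `omics_cohort` with clinical data.
#' @param genes Genes to test (default: all rows).
#' @param age_cut Optional age dichotomy passed to [age_association()].
#' @return Data frame: gene, cancer_code, covariate, effect, p_value, fdr.
#' @export
clinical_associations <- function(cohort, genes = rownames(cohort$expression),
                                  age_cut = NULL) {
  if (is.null(cohort$clinical)) stop("cohort has no clinical data", call. = FALSE)
  cl <- cohort$clinical
  tum <- intersect(tumor_samples(cohort), cl$sample)
  cl <- cl[match(tum, cl$sample), , drop = FALSE]
  rows <- list()
  for (g in genes) {
    e <- cohort$expression[g, tum]
    res <- list(
      stage = suppressWarnings(stage_association(e, cl$stage)),
      gender = suppressWarnings(gender_association(e, cl$gender)),
      age = suppressWarnings(age_association(e, cl$age, age_cut = age_cut)))
    for (cv in names(res)) {
      if (is.null(res[[cv]])) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, cancer_code = cohort$cancer_code, covariate = cv,
        effect = res[[cv]]$effect, p_value = res[[cv]]$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(0), cancer_code = character(0),
                      covariate = character(0), effect = numeric(0),
                      p_value = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  for (cv in unique(out$covariate)) {
    sel <- out$covariate == cv
    out$fdr[sel] <- bh_fdr(out$p_value[sel])
  }
  rownames(out) <- NULL
  out
}
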