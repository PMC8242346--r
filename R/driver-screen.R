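#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with p from the t-transform on n - 2 degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return List with `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need >= 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Default driver-calling thresholds
#'
#' The composite criteria used to attribute a gene's dysregulation to copy
#' number or DNA methylation: CNV calls require >40% of tumors altered in
#' one direction with <40% altered in the other, |mean tumor CNV| > 0.1,
#' and CNV-expression Pearson r > 0.3 at FDR < 0.05; methylation calls
#' require |delta beta| > 0.05 with a Mann-Whitney differential-methylation
#' FDR < 0.05 and beta-expression Pearson r < -0.3 at FDR < 0.05. All
#' comparisons are strict.
#'
#' @return Named list of thresholds.
#' @export
driver_thresholds <- function() {
  list(cnv_frac = 0.4, cnv_value = 0.1, cnv_mean = 0.1, corr_r = 0.3,
       corr_fdr = 0.05, delta_beta = 0.05, meth_diff_fdr = 0.05)
}

# per-gene CNV criterion values over tumor samples
.cnv_gene_stats <- function(cohort, gene, tum) {
  cn <- cohort$cnv[gene, intersect(tum, colnames(cohort$cnv))]
  ex <- cohort$expression[gene, names(cn)]
  ok_corr <- stats::sd(cn) > 0 && stats::sd(ex) > 0
  ct <- if (ok_corr) pearson_with_p(cn, ex) else list(r = NA_real_, p = 1)
  list(frac_gain = mean(cn > 0.1), frac_loss = mean(cn < -0.1),
       mean_cnv = mean(cn), r = ct$r, p = ct$p)
}

#' Screen a cohort for CNV-driven genes
#'
#' Applies the composite CNV criteria per gene: the gain branch requires
#' frac(CNV > 0.1) > 0.4 and frac(CNV < -0.1) < 0.4 and mean tumor
#' CNV > 0.1; the loss branch mirrors the signs. Both additionally require
#' Pearson r(CNV, expression) > `corr_r` over tumor samples at BH FDR <
#' `corr_fdr`, where the FDR is computed across all genes tested in this
#' cancer. Gain and loss are mutually exclusive by construction.
#'
#' @param cohort An `omics_cohort` with a CNV matrix and >= 10 tumor samples.
#' @param genes Genes to test (default: genes present in both layers).
#' @param thresholds See [driver_thresholds()].
#' @param report_all Keep rows for genes that fail the criteria (with
#'   mechanism "none") rather than only the calls.
#' @return Data frame: gene, cancer_code, mechanism, frac_altered, mean_cnv,
#'   pearson_r, corr_p, corr_fdr.
#' @export
screen_cnv_drivers <- function(cohort, genes = NULL,
                               thresholds = driver_thresholds(),
                               report_all = FALSE) {
  if (is.null(cohort$cnv)) stop("cohort has no CNV matrix", call. = FALSE)
  tum <- tumor_samples(cohort)
  if (length(intersect(tum, colnames(cohort$cnv))) < 10)
    stop("insufficient data: need >= 10 tumor samples with CNV", call. = FALSE)
  if (is.null(genes))
    genes <- intersect(rownames(cohort$expression), rownames(cohort$cnv))
  th <- thresholds
  st <- lapply(genes, function(g) .cnv_gene_stats(cohort, g, tum))
  p <- vapply(st, function(s) s$p, numeric(1))
  q <- bh_fdr(p)
  rows <- lapply(seq_along(genes), function(i) {
    s <- st[[i]]
    corr_ok <- !is.na(s$r) && s$r > th$corr_r && q[i] < th$corr_fdr
    mech <- "none"
    frac <- NA_real_
    if (s$frac_gain > th$cnv_frac && s$frac_loss < th$cnv_frac &&
        s$mean_cnv > th$cnv_mean && corr_ok) {
      mech <- "cnv_gain"; frac <- s$frac_gain
    } else if (s$frac_loss > th$cnv_frac && s$frac_gain < th$cnv_frac &&
               s$mean_cnv < -th$cnv_mean && corr_ok) {
      mech <- "cnv_loss"; frac <- s$frac_loss
    }
    data.frame(gene = genes[i], cancer_code = cohort$cancer_code,
               mechanism = mech, frac_altered = frac, mean_cnv = s$mean_cnv,
               pearson_r = s$r, corr_p = p[i], corr_fdr = q[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!report_all) out <- out[out$mechanism != "none", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen a cohort for methylation-driven genes
#'
#' Per gene: delta beta = mean tumor beta - mean normal beta; differential
#' methylation is tested by a two-sided Mann-Whitney on beta (BH across the
#' tested genes, FDR < `meth_diff_fdr` required); the beta-expression
#' Pearson correlation over tumor samples must fall below `-corr_r` at BH
#' FDR < `corr_fdr`. Mechanism is hypermethylation when delta beta >
#' `+delta_beta` (expected downregulation) and hypomethylation when below
#' the negative threshold (expected upregulation).
#'
#' @inheritParams screen_cnv_drivers
#' @return Data frame: gene, cancer_code, mechanism, delta_beta, pearson_r,
#'   corr_fdr, meth_diff_p, meth_diff_fdr.
#' @export
screen_methylation_drivers <- function(cohort, genes = NULL,
                                       thresholds = driver_thresholds(),
                                       report_all = FALSE) {
  if (is.null(cohort$methylation))
    stop("cohort has no methylation matrix", call. = FALSE)
  tum <- intersect(tumor_samples(cohort), colnames(cohort$methylation))
  nor <- intersect(normal_samples(cohort), colnames(cohort$methylation))
  if (length(nor) < 3)
    stop("delta beta undefined: need >= 3 normal samples with beta values",
         call. = FALSE)
  if (is.null(genes))
    genes <- intersect(rownames(cohort$expression), rownames(cohort$methylation))
  th <- thresholds
  beta <- cohort$methylation
  db <- vapply(genes, function(g) mean(beta[g, tum]) - mean(beta[g, nor]),
               numeric(1))
  diff_p <- vapply(genes, function(g)
    suppressWarnings(stats::wilcox.test(beta[g, tum], beta[g, nor],
                                        exact = FALSE)$p.value), numeric(1))
  diff_q <- bh_fdr(diff_p)
  corr <- lapply(genes, function(g) {
    b <- beta[g, tum]; e <- cohort$expression[g, tum]
    if (stats::sd(b) == 0 || stats::sd(e) == 0) list(r = NA_real_, p = 1)
    else pearson_with_p(b, e)
  })
  corr_p <- vapply(corr, function(s) s$p, numeric(1))
  corr_q <- bh_fdr(corr_p)
  r <- vapply(corr, function(s) s$r, numeric(1))
  mech <- rep("none", length(genes))
  corr_ok <- !is.na(r) & r < -th$corr_r & corr_q < th$corr_fdr
  diff_ok <- diff_q < th$meth_diff_fdr
  mech[db > th$delta_beta & diff_ok & corr_ok] <- "hypermethylation"
  mech[db < -th$delta_beta & diff_ok & corr_ok] <- "hypomethylation"
  out <- data.frame(gene = genes, cancer_code = cohort$cancer_code,
                    mechanism = mech, delta_beta = unname(db),
                    pearson_r = unname(r), corr_fdr = unname(corr_q),
                    meth_diff_p = unname(diff_p),
                    meth_diff_fdr = unname(diff_q),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!report_all) out <- out[out$mechanism != "none", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-gene driver calls
#'
#' Convenience wrappers that run the cohort-wide screen (so the FDR scope
#' stays the full tested panel) and return the row for one gene, or NULL
#' when no mechanism is called.
#'
#' @param cohort An `omics_cohort`.
#' @param gene Gene name.
#' @param thresholds See [driver_thresholds()].
#' @return One-row data frame or NULL.
#' @export
call_cnv_driver <- function(cohort, gene, thresholds = driver_thresholds()) {
  tab <- screen_cnv_drivers(cohort, thresholds = thresholds, report_all = TRUE)
  if (!gene %in% tab$gene) stop("gene not testable: ", gene, call. = FALSE)
  row <- tab[tab$gene == gene, , drop = FALSE]
  if (row$mechanism == "none") NULL else row
}

#' @rdname call_cnv_driver
#' @export
call_methylation_driver <- function(cohort, gene,
                                    thresholds = driver_thresholds()) {
  tab <- screen_methylation_drivers(cohort, thresholds = thresholds,
                                    report_all = TRUE)
  if (!gene %in% tab$gene) stop("gene not testable: ", gene, call. = FALSE)
  row <- tab[tab$gene == gene, , drop = FALSE]
  if (row$mechanism == "none") NULL else row
}

#' Summarize driver calls per cancer and per gene
#'
#' @param calls Data frame of driver calls (possibly zero rows) with columns
#'   `gene`, `cancer_code`, `mechanism`.
#' @param dysregulation Optional data frame from
#'   [differential_expression()]; when given, each call is annotated with a
#'   `concordant_dysregulation` flag (gain/hypomethylation with "up",
#'   loss/hypermethylation with "down").
#' @return List with `per_cancer` and `per_gene` count tables and the
#'   annotated `calls`.
#' @export
driver_summary <- function(calls, dysregulation = NULL) {
  if (!is.null(dysregulation) && nrow(calls)) {
    key <- paste(dysregulation$gene, dysregulation$cancer_code)
    dirs <- stats::setNames(dysregulation$direction, key)
    expected <- c(cnv_gain = "up", cnv_loss = "down",
                  hypermethylation = "down", hypomethylation = "up")
    got <- dirs[paste(calls$gene, calls$cancer_code)]
    calls$concordant_dysregulation <-
      !is.na(got) & got == expected[calls$mechanism]
  }
  if (nrow(calls)) {
    per_cancer <- as.data.frame(table(cancer_code = calls$cancer_code),
                                stringsAsFactors = FALSE)
    names(per_cancer)[2] <- "n_calls"
    per_gene <- as.data.frame(table(gene = calls$gene,
                                    mechanism = calls$mechanism),
                              stringsAsFactors = FALSE)
    names(per_gene)[3] <- "n_calls"
    per_gene <- per_gene[per_gene$n_calls > 0, , drop = FALSE]
    rownames(per_gene) <- NULL
  } else {
    per_cancer <- data.frame(cancer_code = character(0),
                             n_calls = integer(0), stringsAsFactors = FALSE)
    per_gene <- data.frame(gene = character(0), mechanism = character(0),
                           n_calls = integer(0), stringsAsFactors = FALSE)
  }
  list(per_cancer = per_cancer, per_gene = per_gene, calls = calls)
}
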