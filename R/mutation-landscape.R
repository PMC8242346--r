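#' Canonical nonsynonymous variant classes
#'
#' The protein-altering MAF variant classifications retained by the
#' mutation screen; Silent and non-coding classes are excluded.
#'
#' @return Character vector of MAF Variant_Classification values.
#' @export
nonsynonymous_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

#' Filter mutation records to nonsynonymous classes
#'
#' @param records MAF-style data frame with a `Variant_Classification`
#'   column.
#' @param allowlist Classes to retain (default [nonsynonymous_classes()]).
#' @return The retained records. Classifications that are neither in the
#'   allowlist nor recognized as silent/non-coding trigger a warning and
#'   are dropped.
#' @export
filter_nonsynonymous <- function(records, allowlist = nonsynonymous_classes()) {
  known_excluded <- c("Silent", "3'UTR", "5'UTR", "3'Flank", "5'Flank",
                      "Intron", "IGR", "RNA", "lincRNA",
                      "Targeted_Region", "De_novo_Start_InFrame",
                      "De_novo_Start_OutOfFrame")
  cls <- records$Variant_Classification
  unknown <- setdiff(unique(cls), c(allowlist, known_excluded))
  if (length(unknown))
    warning("unknown variant classification(s) dropped: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  records[cls %in% allowlist, , drop = FALSE]
}

#' Classify a single-nucleotide substitution into six categories
#'
#' SNVs are collapsed to the pyrimidine-reference frame: a purine reference
#' (A/G) is complemented together with its alternate allele, giving the six
#' classes C>A, C>G, C>T, T>A, T>C, T>G.
#'
#' @param ref,alt Single nucleotides, `ref != alt`. Vectorized.
#' @return Character vector of categories.
#' @export
classify_substitution <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ok <- ref %in% names(comp) & alt %in% names(comp) & ref != alt
  if (!all(ok))
    stop("cannot classify substitution: ref/alt must be distinct single ",
         "nucleotides (got ref=", ref[!ok][1], ", alt=", alt[!ok][1], ")",
         call. = FALSE)
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, comp[ref], ref)
  a <- ifelse(purine, comp[alt], alt)
  paste0(r, ">", a)
}

#' Mutation rates and substitution spectrum for a cohort
#'
#' Computes per-gene mutation rates (fraction of samples carrying at least
#' one record for the gene), the cohort rate (fraction of samples with at
#' least one panel-gene mutation), and the six-category substitution
#' spectrum over SNV records. The denominator is the number of samples with
#' mutation data, which may be fewer than the expression samples. Records
#' should already be filtered with [filter_nonsynonymous()].
#'
#' @param records MAF-style data frame.
#' @param gene_panel Genes over which rates are reported.
#' @param samples_with_data Character vector of all samples with mutation
#'   data (the rate denominator). Every record's sample must be listed.
#' @return List with `per_gene_rate` (named numeric), `cohort_rate`,
#'   and `spectrum` (named fractions summing to 1 when SNVs are present).
#' @export
mutation_rates <- function(records, gene_panel, samples_with_data) {
  n <- length(samples_with_data)
  if (n < 1) stop("need >= 1 sample with mutation data", call. = FALSE)
  bad <- setdiff(unique(records$Tumor_Sample_Barcode), samples_with_data)
  if (length(bad))
    stop("inconsistent denominator: record sample(s) not in ",
         "samples_with_data: ", paste(utils::head(bad, 3), collapse = ", "),
         call. = FALSE)
  rec <- records[records$Hugo_Symbol %in% gene_panel, , drop = FALSE]
  per_gene <- vapply(gene_panel, function(g)
    length(unique(rec$Tumor_Sample_Barcode[rec$Hugo_Symbol == g])) / n,
    numeric(1))
  cohort_rate <- length(unique(rec$Tumor_Sample_Barcode)) / n
  snv <- rec[rec$Variant_Type == "SNP" &
               nchar(rec$Reference_Allele) == 1L &
               nchar(rec$Tumor_Seq_Allele2) == 1L &
               rec$Reference_Allele %in% c("A", "C", "G", "T") &
               rec$Tumor_Seq_Allele2 %in% c("A", "C", "G", "T"), ,
             drop = FALSE]
  cats <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  spectrum <- stats::setNames(rep(NA_real_, 6), cats)
  if (nrow(snv)) {
    cl <- classify_substitution(snv$Reference_Allele, snv$Tumor_Seq_Allele2)
    counts <- table(factor(cl, levels = cats))
    spectrum <- as.numeric(counts) / sum(counts)
    names(spectrum) <- cats
  }
  list(per_gene_rate = per_gene, cohort_rate = cohort_rate,
       spectrum = spectrum)
}

#' Compare expression across normal, wild-type and mutant samples
#'
#' Splits samples into normals, tumors without a nonsynonymous mutation in
#' the gene (wild-type) and mutant tumors; reports group medians, a
#' Kruskal-Wallis overall p, pairwise two-sided Mann-Whitney p-values, and
#' a monotone-trend flag when the three medians are strictly ordered
#' (either direction).
#'
#' @param cohort An `omics_cohort` with normals and mutation data.
#' @param gene Gene name.
#' @param min_group Minimum per-group size; smaller groups skip the
#'   comparison with a warning (default 3).
#' @return Data frame with medians, group sizes, p-values and trend flag,
#'   or NULL when skipped.
#' @export
expression_by_mutation_status <- function(cohort, gene, min_group = 3) {
  if (is.null(cohort$mutations)) stop("cohort has no mutation data", call. = FALSE)
  nonsyn <- filter_nonsynonymous(cohort$mutations)
  mut_samples <- unique(nonsyn$Tumor_Sample_Barcode[nonsyn$Hugo_Symbol == gene])
  tum <- tumor_samples(cohort)
  nor <- normal_samples(cohort)
  groups <- list(normal = cohort$expression[gene, nor],
                 wildtype = cohort$expression[gene, setdiff(tum, mut_samples)],
                 mutant = cohort$expression[gene, intersect(tum, mut_samples)])
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < min_group)) {
    warning(sprintf("gene %s: group(s) below %d samples (%s); comparison skipped",
                    gene, min_group,
                    paste(names(sizes)[sizes < min_group], collapse = ", ")),
            call. = FALSE)
    return(NULL)
  }
  kw <- stats::kruskal.test(groups)$p.value
  mw <- function(a, b)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  med <- vapply(groups, stats::median, numeric(1))
  trend <- (med[1] > med[2] && med[2] > med[3]) ||
           (med[1] < med[2] && med[2] < med[3])
  data.frame(gene = gene, cancer_code = cohort$cancer_code,
             median_normal = med[["normal"]],
             median_wildtype = med[["wildtype"]],
             median_mutant = med[["mutant"]],
             n_normal = sizes[["normal"]], n_wildtype = sizes[["wildtype"]],
             n_mutant = sizes[["mutant"]],
             kruskal_p = kw,
             p_normal_vs_wildtype = mw(groups$normal, groups$wildtype),
             p_wildtype_vs_mutant = mw(groups$wildtype, groups$mutant),
             p_normal_vs_mutant = mw(groups$normal, groups$mutant),
             monotone_trend = trend, stringsAsFactors = FALSE)
}

#' Mutation summary for a cohort
#'
#' Convenience wrapper: filters to nonsynonymous records and computes
#' [mutation_rates()] over the cohort's tumor samples.
#'
#' @param cohort An `omics_cohort` with mutation data.
#' @param gene_panel Genes over which rates are reported (default: the
#'   expression rows).
#' @return Data frame with one row per gene (rate) plus attributes; see
#'   also the `spectrum` and `cohort_rate` columns repeated per row for
#'   flat-table export.
#' @export
mutation_summary <- function(cohort, gene_panel = rownames(cohort$expression)) {
  if (is.null(cohort$mutations)) stop("cohort has no mutation data", call. = FALSE)
  nonsyn <- filter_nonsynonymous(cohort$mutations)
  rates <- mutation_rates(nonsyn, gene_panel, tumor_samples(cohort))
  out <- data.frame(gene = gene_panel, cancer_code = cohort$cancer_code,
                    mutation_rate = unname(rates$per_gene_rate),
                    cohort_rate = rates$cohort_rate,
                    stringsAsFactors = FALSE)
  for (cat in names(rates$spectrum))
    out[[paste0("spec_", sub(">", "_", cat))]] <- rates$spectrum[[cat]]
  out
}
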