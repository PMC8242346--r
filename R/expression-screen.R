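#' Log2 fold change of one gene between tumor and normal samples
#'
#' Defined on log2-scale input as mean(tumor) - mean(normal).
#'
#' @param expression Genes x samples log2 matrix.
#' @param tumor_ids,normal_ids Column identifiers of the two groups.
#' @param gene Gene (row) name.
#' @return Numeric log2 fold change.
#' @export
log2_fold_change <- function(expression, tumor_ids, normal_ids, gene) {
  if (!gene %in% rownames(expression))
    stop("gene not found in expression matrix: ", gene, call. = FALSE)
  if (!length(tumor_ids) || !length(normal_ids))
    stop("both sample groups must be non-empty", call. = FALSE)
  mean(expression[gene, tumor_ids]) - mean(expression[gene, normal_ids])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]); values are
#' returned in the input order, are monotone after enforcement and never
#' fall below the raw p-value.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Differential expression screen over a gene panel
#'
#' Per-gene two-sided Mann-Whitney (Wilcoxon rank-sum) test of tumor versus
#' normal log2 expression, with BH FDR across the panel within one cancer
#' type. A direction ("up"/"down") is assigned only when both the FDR and
#' the absolute log2 fold-change thresholds are met; otherwise "ns".
#'
#' @param cohort An `omics_cohort` with at least 3 tumor and 3 normal samples.
#' @param genes Genes to test (default: all rows).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param log2fc_threshold Minimum absolute log2 fold change (default 1).
#' @return Data frame: gene, cancer_code, log2fc, p_value, fdr, direction.
#' @export
differential_expression <- function(cohort, genes = rownames(cohort$expression),
                                    fdr_threshold = 0.05,
                                    log2fc_threshold = 1) {
  tum <- tumor_samples(cohort)
  nor <- normal_samples(cohort)
  if (length(tum) < 3 || length(nor) < 3)
    stop("insufficient data: need >= 3 tumor and >= 3 normal samples",
         call. = FALSE)
  expr <- cohort$expression
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("genes not in expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  lfc <- vapply(genes, function(g) mean(expr[g, tum]) - mean(expr[g, nor]),
                numeric(1))
  p <- vapply(genes, function(g)
    suppressWarnings(stats::wilcox.test(expr[g, tum], expr[g, nor],
                                        exact = FALSE)$p.value),
    numeric(1))
  q <- bh_fdr(p)
  direction <- ifelse(q < fdr_threshold & lfc >= log2fc_threshold, "up",
               ifelse(q < fdr_threshold & lfc <= -log2fc_threshold, "down", "ns"))
  data.frame(gene = genes, cancer_code = cohort$cancer_code,
             log2fc = unname(lfc), p_value = unname(p), fdr = unname(q),
             direction = unname(direction), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running-sum statistic: genes are ranked by a per-gene
#' statistic (decreasing); walking down the list, hits increment the sum
#' proportionally to `|statistic|^weight_exponent` (normalized over hits)
#' and misses decrement it by `1/(N - Nh)`. The enrichment score is the
#' running-sum value of maximum absolute deviation from zero, signed. When
#' the positive and negative extremes tie in magnitude (within a relative
#' 1e-9), the extreme reached earlier in the ranked list is taken.
#'
#' @param stats_ranked Named numeric vector of per-gene ranking statistics
#'   (names = gene universe; need not be pre-sorted).
#' @param gene_set Character vector; non-empty strict subset of the universe.
#' @param weight_exponent Hit-weight exponent (default 1).
#' @return List with `es` and the `running_sum` profile (in ranked order).
#' @export
enrichment_score <- function(stats_ranked, gene_set, weight_exponent = 1) {
  universe <- names(stats_ranked)
  if (is.null(universe)) stop("stats_ranked must be named", call. = FALSE)
  gene_set <- unique(gene_set)
  in_set <- universe %in% gene_set
  nh <- sum(in_set)
  if (nh == 0L) stop("gene_set shares no genes with the universe", call. = FALSE)
  if (nh == length(universe))
    stop("gene_set equals the whole universe; miss penalty undefined",
         call. = FALSE)
  ord <- order(stats_ranked, decreasing = TRUE)
  s <- stats_ranked[ord]
  hit <- in_set[ord]
  w <- abs(s)^weight_exponent
  hit_inc <- ifelse(hit, w / sum(w[hit]), 0)
  miss_dec <- ifelse(hit, 0, 1 / (length(universe) - nh))
  running <- cumsum(hit_inc - miss_dec)
  es <- .max_deviation(running)
  list(es = es, running_sum = stats::setNames(running, universe[ord]))
}

# signed maximum deviation of a running sum; exact-magnitude ties between
# the positive and negative extremes go to the earlier position so the
# result is stable against last-bit accumulation differences
.max_deviation <- function(running, rel_tol = 1e-9) {
  i_max <- which.max(running)
  i_min <- which.min(running)
  a <- running[i_max]
  b <- -running[i_min]
  scale <- max(abs(a), abs(b), 1)
  if (abs(a - b) <= rel_tol * scale) {
    return(unname(running[min(i_max, i_min)]))
  }
  if (a > b) unname(running[i_max]) else unname(running[i_min])
}

# signal-to-noise ranking statistic with the standard sd floor
.signal_to_noise <- function(expr, a_ids, b_ids, sd_floor_frac = 0.1) {
  ma <- rowMeans(expr[, a_ids, drop = FALSE])
  mb <- rowMeans(expr[, b_ids, drop = FALSE])
  sa <- apply(expr[, a_ids, drop = FALSE], 1, stats::sd)
  sb <- apply(expr[, b_ids, drop = FALSE], 1, stats::sd)
  sa <- pmax(sa, sd_floor_frac * abs(ma), 1e-8)
  sb <- pmax(sb, sd_floor_frac * abs(mb), 1e-8)
  (ma - mb) / (sa + sb)
}

#' Phenotype-permutation enrichment test
#'
#' Ranks all genes by the signal-to-noise ratio between tumor and normal
#' samples, computes the weighted KS enrichment score of `gene_set`, and
#' builds its null distribution by permuting the phenotype labels. The
#' permutation p-value uses the add-one convention; the normalized score
#' divides by the mean absolute null score of matching sign.
#'
#' @param cohort An `omics_cohort` with both phenotypes present.
#' @param gene_set Character vector of genes.
#' @param n_perm Number of label permutations (>= 10; default 1000).
#' @param seed Integer seed for the permutations.
#' @param weight_exponent Passed to [enrichment_score()].
#' @return Data frame: set_name, es, nes, perm_p, n_perm.
#' @export
enrichment_test <- function(cohort, gene_set, n_perm = 1000, seed = 1,
                            weight_exponent = 1) {
  if (n_perm < 10) stop("n_perm must be >= 10", call. = FALSE)
  tum <- tumor_samples(cohort)
  nor <- normal_samples(cohort)
  if (!length(tum) || !length(nor))
    stop("both phenotypes must be present", call. = FALSE)
  expr <- cohort$expression
  obs <- enrichment_score(.signal_to_noise(expr, tum, nor), gene_set,
                          weight_exponent)$es
  all_ids <- c(tum, nor)
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    perm <- sample(all_ids)
    a <- perm[seq_along(tum)]
    b <- perm[-seq_along(tum)]
    enrichment_score(.signal_to_noise(expr, a, b), gene_set,
                     weight_exponent)$es
  }, numeric(1))
  perm_p <- (1 + sum(abs(null_es) >= abs(obs))) / (1 + n_perm)
  same_sign <- null_es[sign(null_es) == sign(obs)]
  nes <- if (length(same_sign)) obs / mean(abs(same_sign)) else NA_real_
  data.frame(set_name = "gene_set", es = obs, nes = nes, perm_p = perm_p,
             n_perm = as.integer(n_perm), stringsAsFactors = FALSE)
}

#' Jaccard index of two sets
#'
#' `|A intersect B| / |A union B|`; 0 when both sets are empty.
#' @param set_a,set_b Character vectors.
#' @return Value in \[0, 1\].
#' @export
jaccard_index <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0L) return(0)
  length(intersect(set_a, set_b)) / u
}

#' Cross-cancer connectivity of dysregulated gene sets
#'
#' Pairwise Jaccard indices between per-cancer dysregulated sets, with
#' average-linkage hierarchical clustering on the distance 1 - J.
#'
#' @param sets Named list (by cancer code) of gene character vectors; at
#'   least two cancers.
#' @return List with `matrix` (symmetric, unit diagonal), `hclust`, and
#'   `leaf_order` (cancer codes in dendrogram order).
#' @export
connectivity_matrix <- function(sets) {
  if (length(sets) < 2) stop("need at least two cancers", call. = FALSE)
  codes <- names(sets)
  n <- length(sets)
  m <- matrix(1, n, n, dimnames = list(codes, codes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- jaccard_index(sets[[i]], sets[[j]])
  }
  hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
  list(matrix = m, hclust = hc, leaf_order = codes[hc$order])
}

#' Gene-gene co-expression matrix
#'
#' Pairwise Pearson correlations among genes over a sample subset.
#' Zero-variance genes get missing rows/columns with a warning.
#'
#' @param cohort An `omics_cohort`.
#' @param genes Genes to correlate (default: all).
#' @param samples Sample subset (default: tumor samples).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
coexpression_matrix <- function(cohort, genes = rownames(cohort$expression),
                                samples = tumor_samples(cohort)) {
  if (length(samples) < 3) stop("need >= 3 samples", call. = FALSE)
  x <- t(cohort$expression[genes, samples, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  m <- suppressWarnings(stats::cor(x))
  if (any(sds == 0)) {
    warning("zero-variance gene(s): ",
            paste(genes[sds == 0], collapse = ", "), call. = FALSE)
    m[sds == 0, ] <- NA_real_
    m[, sds == 0] <- NA_real_
  }
  diag(m) <- 1
  m
}
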