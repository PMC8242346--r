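maf_row <- function(gene, sample, cls, vtype = "SNP", ref = "C", alt = "T") {
  data.frame(Hugo_Symbol = gene, Tumor_Sample_Barcode = sample,
             Variant_Classification = cls, Variant_Type = vtype,
             Reference_Allele = ref, Tumor_Seq_Allele2 = alt,
             stringsAsFactors = FALSE)
}

test_that("nonsynonymous filter retains protein-altering classes only", {
  rec <- rbind(maf_row("A", "s1", "Missense_Mutation"),
               maf_row("A", "s2", "Silent"),
               maf_row("B", "s1", "Nonsense_Mutation"),
               maf_row("B", "s3", "3'UTR"),
               maf_row("C", "s1", "Splice_Site"))
  out <- filter_nonsynonymous(rec)
  expect_setequal(out$Variant_Classification,
                  c("Missense_Mutation", "Nonsense_Mutation", "Splice_Site"))
  expect_equal(nrow(filter_nonsynonymous(rbind(maf_row("A", "s1", "Silent")))), 0)
  expect_warning(filter_nonsynonymous(rbind(maf_row("A", "s1", "Weird_Class"))),
                 "unknown")
  # membership recount oracle on a mixed fixture
  set.seed(6)
  classes <- c(nonsynonymous_classes(), "Silent", "Intron", "RNA")
  cls <- sample(classes, 100, replace = TRUE)
  fix <- do.call(rbind, lapply(seq_along(cls), function(i)
    maf_row("G", paste0("s", i), cls[i])))
  expect_equal(nrow(filter_nonsynonymous(fix)),
               sum(cls %in% nonsynonymous_classes()))
})

test_that("substitutions collapse to the pyrimidine-reference frame", {
  expect_equal(classify_substitution("C", "T"), "C>T")
  expect_equal(classify_substitution("G", "A"), "C>T")
  expect_equal(classify_substitution("A", "C"), "T>G")
  expect_equal(classify_substitution("T", "G"), "T>G")
  expect_equal(classify_substitution("G", "T"), "C>A")
  expect_error(classify_substitution("C", "C"), "distinct")
  expect_error(classify_substitution("-", "A"), "single")
})

test_that("spectrum is invariant under strand flip of the input", {
  set.seed(9)
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, 60, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), character(1))
  rec <- do.call(rbind, lapply(1:60, function(i)
    maf_row("G", paste0("s", i), "Missense_Mutation", ref = ref[i],
            alt = alt[i])))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flipped <- rec
  flipped$Reference_Allele <- unname(comp[rec$Reference_Allele])
  flipped$Tumor_Seq_Allele2 <- unname(comp[rec$Tumor_Seq_Allele2])
  samples <- paste0("s", 1:60)
  s1 <- mutation_rates(rec, "G", samples)$spectrum
  s2 <- mutation_rates(flipped, "G", samples)$spectrum
  expect_equal(s1, s2)
  expect_equal(sum(s1), 1, tolerance = 1e-9)
})

test_that("mutation rates use de-duplicated samples and a checked denominator", {
  samples <- paste0("s", 1:50)
  rec <- rbind(maf_row("G1", "s1", "Missense_Mutation"),
               maf_row("G1", "s2", "Missense_Mutation"),
               maf_row("G2", "s1", "Nonsense_Mutation"),
               maf_row("G3", "s1", "Missense_Mutation"))
  r <- mutation_rates(rec, c("G1", "G2", "G3"), samples)
  expect_equal(r$per_gene_rate[["G1"]], 2 / 50)
  # one sample carrying mutations in 3 genes contributes once
  expect_equal(r$cohort_rate, 2 / 50)
  expect_gte(r$cohort_rate, max(r$per_gene_rate))
  expect_lte(r$cohort_rate, sum(r$per_gene_rate))
  expect_error(mutation_rates(rec, "G1", paste0("x", 1:5)),
               "inconsistent denominator")
  # brute-force per-sample recount on a random fixture
  set.seed(12)
  genes <- paste0("G", 1:5)
  n_rec <- 80
  fix <- do.call(rbind, lapply(1:n_rec, function(i)
    maf_row(sample(genes, 1), sample(samples, 1), "Missense_Mutation")))
  rr <- mutation_rates(fix, genes, samples)
  brute <- mean(vapply(samples, function(s)
    any(fix$Tumor_Sample_Barcode == s & fix$Hugo_Symbol %in% genes),
    logical(1)))
  expect_equal(rr$cohort_rate, brute)
})

test_that("expression by mutation status flags planted monotone trends", {
  set.seed(13)
  nt <- 60; nn <- 30
  samples <- c(paste0("t", 1:nt), paste0("n", 1:nn))
  mutant <- paste0("t", 1:20)
  expr_t <- rnorm(nt, 9, 0.5)
  expr_t[1:20] <- expr_t[1:20] - 2       # mutants shifted down
  expr <- matrix(c(expr_t, rnorm(nn, 10, 0.5)), 1,
                 dimnames = list("G", samples))
  st <- setNames(rep(c("tumor", "normal"), c(nt, nn)), samples)
  maf <- do.call(rbind, lapply(mutant, function(s)
    maf_row("G", s, "Missense_Mutation")))
  co <- new_omics_cohort("X", expr, st, mutations = maf)
  res <- expression_by_mutation_status(co, "G")
  expect_true(res$monotone_trend)
  expect_gt(res$median_normal, res$median_wildtype)
  expect_gt(res$median_wildtype, res$median_mutant)
  expect_lt(res$kruskal_p, 0.01)
  # no mutants -> skip with warning
  co2 <- new_omics_cohort("X", expr, st,
                          mutations = maf_row("OTHERGENE", "t1",
                                              "Missense_Mutation"))
  expect_warning(res2 <- expression_by_mutation_status(co2, "G"), "skipped")
  expect_null(res2)
})

test_that("cohort-level mutation summary flattens rates and spectrum", {
  g <- small_cohort(seed = 17, n_tumor = 80, n_normal = 10,
                    mutation_rate_per_gene = 0.2)
  ms <- mutation_summary(g$cohort)
  expect_equal(nrow(ms), nrow(g$cohort$expression))
  expect_true(all(ms$mutation_rate >= 0 & ms$mutation_rate <= 1))
  expect_true(all(ms$cohort_rate >= max(ms$mutation_rate)))
  spec_cols <- grep("^spec_", names(ms), value = TRUE)
  expect_length(spec_cols, 6)
  expect_equal(sum(ms[1, spec_cols]), 1, tolerance = 1e-9)
})
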