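# hand-constructed cohort: gene-wise CNV/beta patterns with controlled coupling
make_cnv_cohort <- function(cnv_values, couple = TRUE, seed = 1) {
  set.seed(seed)
  n <- length(cnv_values)
  samples <- paste0("t", seq_len(n))
  noise <- rnorm(n, 0, 0.3)
  expr_g <- if (couple) 8 + 2 * cnv_values + noise else 8 + noise
  expr <- rbind(G = expr_g, OTHER = rnorm(n, 8, 1))
  colnames(expr) <- samples
  cnv <- rbind(G = cnv_values, OTHER = rnorm(n, 0, 0.05))
  colnames(cnv) <- samples
  new_omics_cohort("FIX", expr, setNames(rep("tumor", n), samples), cnv = cnv)
}

test_that("CNV gain is called when all three criteria hold", {
  cnv <- c(rep(0.5, 30), rep(0, 20))  # 60% altered
  co <- make_cnv_cohort(cnv)
  call <- call_cnv_driver(co, "G")
  expect_identical(call$mechanism, "cnv_gain")
  # verify each criterion independently on the fixture
  expect_gt(mean(cnv > 0.1), 0.4)
  expect_lt(mean(cnv < -0.1), 0.4)
  expect_gt(mean(cnv), 0.1)
  expect_gt(call$pearson_r, 0.3)
  expect_lt(call$corr_fdr, 0.05)
  expect_equal(call$frac_altered, 0.6)
})

test_that("CNV call fails when any single criterion fails", {
  # criterion (3): expression independent of CNV
  co_nocorr <- make_cnv_cohort(c(rep(0.5, 30), rep(0, 20)), couple = FALSE)
  expect_null(call_cnv_driver(co_nocorr, "G"))
  # criterion (1): only 30% altered
  co_lowfrac <- make_cnv_cohort(c(rep(0.5, 15), rep(0, 35)))
  expect_null(call_cnv_driver(co_lowfrac, "G"))
  # loss branch mirrors signs
  co_loss <- make_cnv_cohort(c(rep(-0.5, 30), rep(0, 20)))
  call <- call_cnv_driver(co_loss, "G")
  expect_identical(call$mechanism, "cnv_loss")
})

test_that("gain and loss branches are mutually exclusive on any input", {
  set.seed(8)
  for (i in 1:20) {
    cnv <- sample(c(-0.5, 0, 0.5), 40, replace = TRUE)
    tab <- screen_cnv_drivers(make_cnv_cohort(cnv, seed = i),
                              report_all = TRUE)
    expect_equal(nrow(tab), 2)
    expect_true(all(tab$mechanism %in%
                      c("none", "cnv_gain", "cnv_loss")))
    s <- tab[tab$gene == "G", ]
    if (s$mechanism == "cnv_gain") expect_gt(s$mean_cnv, 0.1)
    if (s$mechanism == "cnv_loss") expect_lt(s$mean_cnv, -0.1)
  }
})

make_meth_cohort <- function(beta_tumor, beta_normal, couple_sign = -1,
                             seed = 2) {
  set.seed(seed)
  nt <- length(beta_tumor); nn <- length(beta_normal)
  samples <- c(paste0("t", 1:nt), paste0("n", 1:nn))
  beta <- rbind(G = c(beta_tumor, beta_normal),
                OTHER = runif(nt + nn, 0.4, 0.6))
  colnames(beta) <- samples
  expr_tumor <- 8 + couple_sign * 5 * (beta_tumor - mean(beta_tumor)) +
    rnorm(nt, 0, 0.2)
  expr <- rbind(G = c(expr_tumor, rnorm(nn, 8, 0.5)),
                OTHER = rnorm(nt + nn, 8, 1))
  colnames(expr) <- samples
  new_omics_cohort("FIX", expr,
                   setNames(rep(c("tumor", "normal"), c(nt, nn)), samples),
                   methylation = beta)
}

test_that("hypomethylation is called for low tumor beta with negative coupling", {
  set.seed(3)
  co <- make_meth_cohort(runif(40, 0.1, 0.3), runif(20, 0.5, 0.7))
  call <- call_methylation_driver(co, "G")
  expect_identical(call$mechanism, "hypomethylation")
  expect_lt(call$delta_beta, -0.05)
  expect_lt(call$pearson_r, -0.3)
  expect_lt(call$corr_fdr, 0.05)
  expect_lt(call$meth_diff_fdr, 0.05)
})

test_that("methylation calls respect magnitude and sign requirements", {
  set.seed(4)
  # delta beta magnitude below 0.05 -> none
  co_small <- make_meth_cohort(runif(40, 0.48, 0.52) + 0.04,
                               runif(20, 0.48, 0.52))
  expect_null(call_methylation_driver(co_small, "G"))
  # large delta beta but positive beta-expression correlation -> none
  co_possign <- make_meth_cohort(runif(40, 0.7, 0.9), runif(20, 0.4, 0.6),
                                 couple_sign = +1)
  expect_null(call_methylation_driver(co_possign, "G"))
  # hypermethylation branch: high tumor beta, negative coupling
  co_hyper <- make_meth_cohort(runif(40, 0.7, 0.9), runif(20, 0.4, 0.6))
  expect_identical(call_methylation_driver(co_hyper, "G")$mechanism,
                   "hypermethylation")
  # no normals with beta -> error
  expr <- matrix(rnorm(20), 1, 20, dimnames = list("G", paste0("t", 1:20)))
  st <- setNames(rep("tumor", 20), colnames(expr))
  beta <- matrix(runif(20), 1, 20, dimnames = list("G", colnames(expr)))
  co_nonormal <- new_omics_cohort("X", expr, st, methylation = beta)
  expect_error(screen_methylation_drivers(co_nonormal), "normal")
})

test_that("pearson_with_p matches the closed form and flags degenerate input", {
  expect_equal(pearson_with_p(1:10, 1:10)$r, 1)
  expect_equal(pearson_with_p(1:10, -(1:10))$r, -1)
  r <- pearson_with_p(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r$r, 9 / sqrt(84))
  expect_error(pearson_with_p(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_with_p(1:2, 1:2), ">= 3")
})

test_that("driver summary counts conserve totals and annotate concordance", {
  empty <- driver_summary(data.frame(gene = character(0),
                                     cancer_code = character(0),
                                     mechanism = character(0)))
  expect_equal(nrow(empty$per_cancer), 0)
  calls <- data.frame(
    gene = c("ITGB8", "ITGB8", "ITGA4"),
    cancer_code = c("AAA", "BBB", "AAA"),
    mechanism = c("cnv_gain", "cnv_gain", "hypomethylation"),
    stringsAsFactors = FALSE)
  de <- data.frame(gene = c("ITGB8", "ITGB8", "ITGA4"),
                   cancer_code = c("AAA", "BBB", "AAA"),
                   direction = c("up", "down", "up"),
                   stringsAsFactors = FALSE)
  s <- driver_summary(calls, de)
  expect_equal(sum(s$per_cancer$n_calls), nrow(calls))
  expect_equal(sum(s$per_gene$n_calls), nrow(calls))
  expect_equal(s$calls$concordant_dysregulation, c(TRUE, FALSE, TRUE))
})

test_that("planted drivers are recovered on a synthetic cohort", {
  cnv_sd <- integrinscape:::planted_cnv_sd(0.6, 0.5)
  coup <- integrinscape:::coupling_for_r(0.7, cnv_sd)
  meth_coup <- integrinscape:::coupling_for_r(
    0.7, integrinscape:::planted_beta_sd(0.5))
  g <- generate_cohort(cohort_config(
    "REC", n_tumor = 150, n_normal = 60, seed = 31,
    planted_cnv_drivers = list(
      ITGB8 = list(direction = "gain", alteration_fraction = 0.6,
                   cnv_magnitude = 0.5, coupling_strength = coup),
      ITGA1 = list(direction = "loss", alteration_fraction = 0.6,
                   cnv_magnitude = 0.5, coupling_strength = coup)),
    planted_meth_drivers = list(
      ITGA4 = list(direction = "hyper", delta_beta = 0.2,
                   coupling_strength = meth_coup),
      ITGB6 = list(direction = "hypo", delta_beta = 0.2,
                   coupling_strength = meth_coup))))
  cnv_calls <- screen_cnv_drivers(g$cohort)
  meth_calls <- screen_methylation_drivers(g$cohort)
  expect_setequal(cnv_calls$gene, c("ITGB8", "ITGA1"))
  expect_identical(cnv_calls$mechanism[cnv_calls$gene == "ITGB8"], "cnv_gain")
  expect_setequal(meth_calls$gene, c("ITGA4", "ITGB6"))
  expect_identical(meth_calls$mechanism[meth_calls$gene == "ITGA4"],
                   "hypermethylation")
})
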