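# Bundled three-cancer synthetic study configuration: one cohort with a
# planted CNV gain driver and a prognostic upregulated gene, one with a
# planted hypermethylation driver, one with downregulation only. Coupling
# strengths come from the attenuation formula targeting r = 0.7.
three_cancer_config <- function(out_dir = NULL, seed = 1) {
  coup <- integrinscape:::coupling_for_r(
    0.7, integrinscape:::planted_cnv_sd(0.6, 0.5))
  meth_coup <- integrinscape:::coupling_for_r(
    0.7, integrinscape:::planted_beta_sd(0.5))
  run_config(list(
    cohort_config("AAA", n_tumor = 60, n_normal = 25, seed = seed,
                  planted_up = c(ITGA11 = 2, ITGB4 = 1.8),
                  planted_down = c(ITGA9 = 1.6),
                  planted_cnv_drivers = list(ITGB8 = list(
                    direction = "gain", alteration_fraction = 0.6,
                    cnv_magnitude = 0.5, coupling_strength = coup)),
                  planted_prognostic = c(ITGA11 = 0.8)),
    cohort_config("BBB", n_tumor = 60, n_normal = 25, seed = seed + 1,
                  planted_up = c(ITGA11 = 2, ITGA3 = 1.7),
                  planted_meth_drivers = list(ITGA4 = list(
                    direction = "hyper", delta_beta = 0.2,
                    coupling_strength = meth_coup)),
                  planted_prognostic = c(ITGA3 = 0.7)),
    cohort_config("CCC", n_tumor = 60, n_normal = 25, seed = seed + 2,
                  planted_down = c(ITGA1 = 1.8, ITGA7 = 1.6))),
    seed = seed, out_dir = out_dir)
}

# driver-recovery study conditions: 200 tumors / 100 normals, 200 genes,
# 30 planted CNV drivers (alteration fraction 0.6, coupling targeting
# r = 0.7) and 30 planted methylation drivers (|delta beta| = 0.2)
driver_recovery_config <- function(seed) {
  panel <- sprintf("GENE%03d", 1:200)
  cnv_genes <- panel[1:30]
  meth_genes <- panel[31:60]
  coup <- integrinscape:::coupling_for_r(
    0.7, integrinscape:::planted_cnv_sd(0.6, 0.5))
  meth_coup <- integrinscape:::coupling_for_r(
    0.7, integrinscape:::planted_beta_sd(0.5))
  cnv_drv <- lapply(seq_along(cnv_genes), function(i) list(
    direction = if (i %% 2) "gain" else "loss", alteration_fraction = 0.6,
    cnv_magnitude = 0.5, coupling_strength = coup))
  names(cnv_drv) <- cnv_genes
  meth_drv <- lapply(seq_along(meth_genes), function(i) list(
    direction = if (i %% 2) "hyper" else "hypo", delta_beta = 0.2,
    coupling_strength = meth_coup))
  names(meth_drv) <- meth_genes
  cohort_config("DRV", n_tumor = 200, n_normal = 100, gene_panel = panel,
                planted_cnv_drivers = cnv_drv,
                planted_meth_drivers = meth_drv, seed = seed)
}
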