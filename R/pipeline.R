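#' Assemble a pan-cancer run configuration
#'
#' Bundles the synthetic cohort configurations (or directories of cohort
#' files) with every stage threshold. Every threshold defaults to the
#' screening value used throughout the pipeline (DE FDR 0.05 and |log2FC|
#' >= 1; CNV fraction 0.4 at |CNV| > 0.1 with r > 0.3; |delta beta| > 0.05
#' with r < -0.3; FDR 0.05 everywhere; cutpoints within the 10th-90th
#' percentiles; 5/10-year horizons; median risk split) and is overridable.
#'
#' @param cohorts List of [cohort_config()] objects, or a named character
#'   vector of directories readable by [read_cohort()].
#' @param gene_panel Genes screened (default [itg_panel()]).
#' @param de_fdr,de_log2fc Differential-expression thresholds.
#' @param driver Driver thresholds, see [driver_thresholds()].
#' @param percentile_bounds Admissible cutpoint bounds.
#' @param horizons Named horizons in months.
#' @param split_percentile Risk-model split quantile.
#' @param n_perm Permutations for enrichment tests.
#' @param seed Global seed.
#' @param out_dir Optional output directory for [write_results()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohorts, gene_panel = itg_panel(),
                       de_fdr = 0.05, de_log2fc = 1,
                       driver = driver_thresholds(),
                       percentile_bounds = c(0.1, 0.9),
                       horizons = c(total = Inf, "10yr" = 120, "5yr" = 60),
                       split_percentile = 0.5, n_perm = 1000,
                       seed = 1L, out_dir = NULL) {
  structure(list(cohorts = cohorts, gene_panel = gene_panel,
                 de_fdr = de_fdr, de_log2fc = de_log2fc, driver = driver,
                 percentile_bounds = percentile_bounds, horizons = horizons,
                 split_percentile = split_percentile, n_perm = n_perm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Collects all configuration errors and warnings before any computation.
#'
#' @param config A [run_config()].
#' @return List with character vectors `errors` and `warnings`; an empty
#'   `errors` element means the configuration is runnable.
#' @export
validate_run_config <- function(config) {
  errors <- character(0); warnings <- character(0)
  add_err <- function(msg) errors <<- c(errors, msg)
  if (!length(config$cohorts)) add_err("cohorts: need at least one cohort")
  if (is.list(config$cohorts)) {
    codes <- vapply(config$cohorts, function(c) c$cancer_code, character(1))
    if (anyDuplicated(codes))
      add_err(paste("cohorts: duplicate cancer_code",
                    paste(codes[duplicated(codes)], collapse = ", ")))
  }
  in01 <- function(v) is.numeric(v) && all(v >= 0 & v <= 1)
  if (!in01(config$de_fdr)) add_err("de_fdr: must be in [0, 1]")
  if (!is.numeric(config$de_log2fc) || config$de_log2fc < 0)
    add_err("de_log2fc: must be >= 0")
  if (!in01(config$driver$corr_fdr)) add_err("driver$corr_fdr: must be in [0, 1]")
  pb <- config$percentile_bounds
  if (length(pb) != 2 || !in01(pb) || pb[1] >= pb[2])
    add_err("percentile_bounds: need increasing bounds within [0, 1]")
  if (!is.numeric(config$n_perm) || config$n_perm < 10)
    add_err("n_perm: must be a positive count >= 10")
  if (!in01(config$split_percentile))
    add_err("split_percentile: must be in [0, 1]")
  if (any(config$horizons <= 0)) add_err("horizons: must be > 0")
  list(errors = errors, warnings = warnings)
}

.stage_log <- function(verbose, code, stage, detail) {
  if (verbose) message(sprintf("[%s] %s: %s", code, stage, detail))
}

#' Run the full pan-cancer analysis
#'
#' Executes, per cohort: differential expression, CNV and methylation
#' driver screens, mutation summary, survival cutpoint screening with
#' prognosis classification, the Cox risk model over dysregulated
#' prognosis-related genes plus TNM indexes, and clinical associations;
#' then cross-cancer Jaccard connectivity of the up- and down-regulated
#' sets. Stages whose required omics layer is absent are skipped with a
#' logged reason, never an error. When `out_dir` is set, all result tables
#' and a run manifest are written.
#'
#' @param config A [run_config()].
#' @param verbose Log one line per stage per cancer (default TRUE).
#' @return Named list of result tables: `dysregulation`, `drivers`,
#'   `mutation_summary`, `survival_calls`, `prognostic_genes`,
#'   `risk_models`, `associations`, `connectivity_up`, `connectivity_down`,
#'   plus `truth` for synthetic cohorts and `risk_details` (full model
#'   objects, not written to disk).
#' @export
run_pan_cancer <- function(config, verbose = TRUE) {
  val <- validate_run_config(config)
  if (length(val$errors))
    stop("invalid run configuration:\n  ",
         paste(val$errors, collapse = "\n  "), call. = FALSE)

  if (is.character(config$cohorts)) {
    cohorts <- lapply(names(config$cohorts), function(code)
      list(cohort = read_cohort(config$cohorts[[code]], code,
                                gene_panel = config$gene_panel),
           truth = NULL))
    names(cohorts) <- names(config$cohorts)
  } else {
    cohorts <- generate_pan_cancer(config$cohorts)
  }

  de_all <- drv_all <- mut_all <- surv_all <- prog_all <- risk_all <-
    assoc_all <- truth_all <- list()
  risk_details <- list()

  for (code in names(cohorts)) {
    co <- cohorts[[code]]$cohort
    truth <- cohorts[[code]]$truth
    if (!is.null(truth)) {
      truth$cancer_code <- code
      truth_all[[code]] <- truth
    }
    genes <- intersect(config$gene_panel, rownames(co$expression))
    if (!length(genes)) genes <- rownames(co$expression)

    de <- differential_expression(co, genes, fdr_threshold = config$de_fdr,
                                  log2fc_threshold = config$de_log2fc)
    de_all[[code]] <- de
    .stage_log(verbose, code, "expression",
               sprintf("%d up, %d down of %d genes",
                       sum(de$direction == "up"), sum(de$direction == "down"),
                       nrow(de)))

    drv <- list()
    if (!is.null(co$cnv)) {
      drv$cnv <- screen_cnv_drivers(co, genes, thresholds = config$driver)
      .stage_log(verbose, code, "cnv-drivers", sprintf("%d calls", nrow(drv$cnv)))
    } else .stage_log(verbose, code, "cnv-drivers", "skipped: no CNV layer")
    if (!is.null(co$methylation)) {
      drv$meth <- screen_methylation_drivers(co, genes,
                                             thresholds = config$driver)
      .stage_log(verbose, code, "meth-drivers", sprintf("%d calls", nrow(drv$meth)))
    } else .stage_log(verbose, code, "meth-drivers", "skipped: no methylation layer")
    if (length(drv)) {
      shared <- c("gene", "cancer_code", "mechanism", "pearson_r", "corr_fdr")
      drv_tab <- do.call(rbind, lapply(drv, function(d) {
        base <- d[, shared, drop = FALSE]
        for (col in c("frac_altered", "mean_cnv", "delta_beta",
                      "meth_diff_fdr"))
          base[[col]] <- if (col %in% names(d)) d[[col]] else
            rep(NA_real_, nrow(d))
        base
      }))
      rownames(drv_tab) <- NULL
      drv_all[[code]] <- drv_tab
    }

    if (!is.null(co$mutations)) {
      mut_all[[code]] <- mutation_summary(co, genes)
      .stage_log(verbose, code, "mutations",
                 sprintf("cohort rate %.3f", mut_all[[code]]$cohort_rate[1]))
    } else .stage_log(verbose, code, "mutations", "skipped: no mutation layer")

    if (!is.null(co$clinical)) {
      sv <- suppressWarnings(
        survival_screen(co, genes, horizons = config$horizons,
                        percentile_bounds = config$percentile_bounds))
      surv_all[[code]] <- sv
      prog <- prognostic_dysregulated(de, sv)
      prog_all[[code]] <- prog
      .stage_log(verbose, code, "survival",
                 sprintf("%d prognostic dysregulated genes", nrow(prog)))
      if (nrow(prog) >= 1) {
        has_tnm <- all(c("t_index", "n_index", "m_index") %in%
                         names(co$clinical))
        rm_res <- tryCatch(
          build_risk_model(co, prog$gene, use_tnm = has_tnm,
                           split_percentile = config$split_percentile),
          error = function(e) {
            .stage_log(verbose, code, "risk-model",
                       paste("skipped:", conditionMessage(e)))
            NULL
          })
        if (!is.null(rm_res)) {
          s <- rm_res$summary
          s$km_logrank_p <- rm_res$stratification$logrank_p
          s$auc_5yr <- rm_res$auc_5yr
          risk_all[[code]] <- s
          risk_details[[code]] <- rm_res
          .stage_log(verbose, code, "risk-model",
                     sprintf("KM p=%.3g, AUC=%.3f",
                             rm_res$stratification$logrank_p, rm_res$auc_5yr))
        }
      } else .stage_log(verbose, code, "risk-model",
                        "skipped: no prognostic dysregulated genes")
      assoc_all[[code]] <- clinical_associations(co, genes)
      .stage_log(verbose, code, "clinical",
                 sprintf("%d association rows", nrow(assoc_all[[code]])))
    } else .stage_log(verbose, code, "survival", "skipped: no clinical layer")
  }

  bind <- function(lst) if (length(lst)) {
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  } else NULL
  results <- list(dysregulation = bind(de_all), drivers = bind(drv_all),
                  mutation_summary = bind(mut_all),
                  survival_calls = bind(surv_all),
                  prognostic_genes = bind(prog_all),
                  risk_models = bind(risk_all),
                  associations = bind(assoc_all),
                  truth = bind(truth_all))

  if (length(cohorts) >= 2 && !is.null(results$dysregulation)) {
    de <- results$dysregulation
    mk_sets <- function(dir) {
      sets <- lapply(names(cohorts), function(code)
        de$gene[de$cancer_code == code & de$direction == dir])
      names(sets) <- names(cohorts)
      sets
    }
    conn_table <- function(dir) {
      cm <- connectivity_matrix(mk_sets(dir))
      m <- cm$matrix
      df <- data.frame(cancer_code = rownames(m), as.data.frame(m),
                       check.names = FALSE, stringsAsFactors = FALSE)
      attr(df, "leaf_order") <- cm$leaf_order
      df
    }
    results$connectivity_up <- conn_table("up")
    results$connectivity_down <- conn_table("down")
    .stage_log(verbose, "pan", "connectivity",
               sprintf("%d cancers clustered", length(cohorts)))
  }

  if (!is.null(config$out_dir)) {
    tables <- results[!vapply(results, is.null, logical(1))]
    hashable <- unclass(config)
    hashable$out_dir <- NULL  # hash the analysis settings, not the destination
    write_results(tables, config$out_dir, seed = config$seed,
                  config_hash = config_hash(hashable))
    .stage_log(verbose, "pan", "write",
               sprintf("results written to %s", config$out_dir))
  }
  results$risk_details <- risk_details
  results
}
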