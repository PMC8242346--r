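#' Configure a synthetic multi-omics cohort
#'
#' Builds a validated configuration for [generate_cohort()]. The generator
#' emulates the statistical structure of TCGA-style per-cancer inputs:
#' log2-scale expression with tumor/normal shifts, per-gene continuous CNV
#' values coupled to tumor expression, methylation beta-values with
#' tumor-normal differences and negative beta-expression coupling,
#' Weibull proportional-hazards survival linked to gene expression, and
#' MAF-style mutation records.
#'
#' @param cancer_code Short cohort label, e.g. `"STAD"`.
#' @param n_tumor,n_normal Sample counts (each at least 2).
#' @param gene_panel Character vector of gene names; defaults to [itg_panel()].
#' @param n_genes Total number of genes. When larger than
#'   `length(gene_panel)` the panel is padded with filler null genes
#'   (`NULLG0001`, ...); when smaller, the head of the panel is used.
#' @param noise_sd Residual standard deviation of log2 expression.
#' @param planted_up,planted_down Named numeric vectors, gene -> log2 effect
#'   magnitude added to (up) or subtracted from (down) tumor expression.
#' @param planted_cnv_drivers Named list, gene -> list with elements
#'   `direction` ("gain"/"loss"), `alteration_fraction`, `cnv_magnitude`,
#'   `coupling_strength` (log2 expression units per CNV unit).
#' @param planted_meth_drivers Named list, gene -> list with elements
#'   `direction` ("hyper"/"hypo"), `delta_beta` (positive magnitude),
#'   `coupling_strength` (log2 expression units per beta unit; applied with
#'   a negative sign so beta and expression are anticorrelated).
#' @param planted_prognostic Named numeric vector, gene -> log hazard per
#'   unit of standardized tumor expression.
#' @param baseline_hazard_scale,baseline_hazard_shape Weibull parameters of
#'   the baseline event-time distribution (scale in months).
#' @param censoring_rate Target fraction of tumor samples censored
#'   (random exponential censoring plus administrative truncation).
#' @param max_followup Administrative censoring horizon in months.
#' @param mutation_rate_per_gene Either a single probability applied to all
#'   genes or a named numeric vector, gene -> per-sample mutation probability.
#' @param seed Integer seed; identical configurations produce bit-identical
#'   cohorts.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [generate_pan_cancer()]
#' @export
cohort_config <- function(cancer_code,
                          n_tumor = 100L,
                          n_normal = 50L,
                          gene_panel = itg_panel(),
                          n_genes = length(gene_panel),
                          noise_sd = 1,
                          planted_up = numeric(0),
                          planted_down = numeric(0),
                          planted_cnv_drivers = list(),
                          planted_meth_drivers = list(),
                          planted_prognostic = numeric(0),
                          baseline_hazard_scale = 60,
                          baseline_hazard_shape = 1.2,
                          censoring_rate = 0.3,
                          max_followup = 120,
                          mutation_rate_per_gene = 0.03,
                          seed = 1L) {
  if (!is.character(cancer_code) || length(cancer_code) != 1L || !nzchar(cancer_code))
    .fail_field("cancer_code", "must be a non-empty string")
  if (!is.numeric(n_tumor) || n_tumor < 2) .fail_field("n_tumor", "must be >= 2")
  if (!is.numeric(n_normal) || n_normal < 2) .fail_field("n_normal", "must be >= 2")
  if (!is.numeric(n_genes) || n_genes < 1) .fail_field("n_genes", "must be >= 1")
  if (!is.numeric(noise_sd) || noise_sd <= 0) .fail_field("noise_sd", "must be > 0")
  if (censoring_rate < 0 || censoring_rate > 1)
    .fail_field("censoring_rate", "must be in [0, 1]")
  if (baseline_hazard_scale <= 0) .fail_field("baseline_hazard_scale", "must be > 0")
  if (baseline_hazard_shape <= 0) .fail_field("baseline_hazard_shape", "must be > 0")
  if (max_followup <= 0) .fail_field("max_followup", "must be > 0")

  genes <- gene_panel
  n_genes <- as.integer(n_genes)
  if (n_genes > length(genes)) {
    genes <- c(genes, sprintf("NULLG%04d", seq_len(n_genes - length(genes))))
  } else if (n_genes < length(genes)) {
    genes <- genes[seq_len(n_genes)]
  }
  if (anyDuplicated(genes)) .fail_field("gene_panel", "gene names must be unique")

  check_subset <- function(x, field) {
    bad <- setdiff(names(x), genes)
    if (length(bad))
      .fail_field(field, paste("planted genes not in gene panel:",
                               paste(bad, collapse = ", ")))
  }
  check_subset(planted_up, "planted_up")
  check_subset(planted_down, "planted_down")
  check_subset(planted_cnv_drivers, "planted_cnv_drivers")
  check_subset(planted_meth_drivers, "planted_meth_drivers")
  check_subset(planted_prognostic, "planted_prognostic")
  if (length(intersect(names(planted_up), names(planted_down))))
    .fail_field("planted_up", "gene planted both up and down")

  for (g in names(planted_cnv_drivers)) {
    d <- planted_cnv_drivers[[g]]
    if (!d$direction %in% c("gain", "loss"))
      .fail_field("planted_cnv_drivers", paste0(g, ": direction must be gain/loss"))
    if (d$alteration_fraction < 0 || d$alteration_fraction > 1)
      .fail_field("planted_cnv_drivers", paste0(g, ": alteration_fraction not in [0,1]"))
  }
  for (g in names(planted_meth_drivers)) {
    d <- planted_meth_drivers[[g]]
    if (!d$direction %in% c("hyper", "hypo"))
      .fail_field("planted_meth_drivers", paste0(g, ": direction must be hyper/hypo"))
    if (d$delta_beta < 0 || d$delta_beta > 1)
      .fail_field("planted_meth_drivers", paste0(g, ": delta_beta not in [0,1]"))
  }
  if (is.null(names(mutation_rate_per_gene)) && length(mutation_rate_per_gene) == 1L) {
    mutation_rate_per_gene <- stats::setNames(rep(mutation_rate_per_gene, length(genes)), genes)
  } else {
    check_subset(mutation_rate_per_gene, "mutation_rate_per_gene")
    full <- stats::setNames(rep(0, length(genes)), genes)
    full[names(mutation_rate_per_gene)] <- mutation_rate_per_gene
    mutation_rate_per_gene <- full
  }
  if (any(mutation_rate_per_gene < 0 | mutation_rate_per_gene > 1))
    .fail_field("mutation_rate_per_gene", "rates must be in [0, 1]")
  if (!is.numeric(seed) || is.na(seed)) .fail_field("seed", "must be an integer")

  structure(list(
    cancer_code = cancer_code,
    n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
    genes = genes, noise_sd = noise_sd,
    planted_up = planted_up, planted_down = planted_down,
    planted_cnv_drivers = planted_cnv_drivers,
    planted_meth_drivers = planted_meth_drivers,
    planted_prognostic = planted_prognostic,
    baseline_hazard_scale = baseline_hazard_scale,
    baseline_hazard_shape = baseline_hazard_shape,
    censoring_rate = censoring_rate, max_followup = max_followup,
    mutation_rate_per_gene = mutation_rate_per_gene,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# coupling coefficient that yields correlation r_target between a covariate
# with sd x_sd and expression with residual sd noise_sd (attenuation formula)
coupling_for_r <- function(r_target, x_sd, noise_sd = 1) {
  stopifnot(abs(r_target) < 1, x_sd > 0)
  r_target / sqrt(1 - r_target^2) * noise_sd / x_sd
}

# sd of the planted CNV mixture: fraction f altered at N(m, 0.1), rest N(0, 0.05)
planted_cnv_sd <- function(alteration_fraction, cnv_magnitude) {
  f <- alteration_fraction
  sqrt(f * (1 - f) * cnv_magnitude^2 + f * 0.1^2 + (1 - f) * 0.05^2)
}

# approximate sd of logit-normal beta draws (delta method at the mean)
planted_beta_sd <- function(beta_mean = 0.5, logit_sd = 0.25) {
  logit_sd * beta_mean * (1 - beta_mean)
}

# exponential censoring rate giving the target overall censoring fraction
# under Weibull(shape, scale) event times with administrative cutoff at maxfu
.calibrate_censoring_rate <- function(target, shape, scale, maxfu) {
  surv <- function(t) exp(-(t / scale)^shape)
  admin_only <- surv(maxfu)        # minimum achievable censoring fraction
  if (target <= admin_only) return(0)
  frac_cens <- function(r) {
    if (r <= 0) return(admin_only)
    integrand <- function(t) r * exp(-r * t) * surv(t)
    stats::integrate(integrand, 0, maxfu, rel.tol = 1e-8)$value +
      exp(-r * maxfu) * surv(maxfu)
  }
  f <- function(logr) frac_cens(exp(logr)) - target
  exp(stats::uniroot(f, c(-15, 5), tol = 1e-10)$root)
}

.substream <- function(seed, offset, code) {
  # deterministic per-cohort, per-omic substream; kept within 32-bit range
  (abs(seed) + offset * 7919L + sum(utf8ToInt(code)) * 104729L) %% 2147483587L
}

#' Generate one synthetic multi-omics cohort
#'
#' Draws a complete cohort (expression, CNV, methylation, mutations,
#' clinical/survival) from a [cohort_config()], together with a truth table
#' recording which genes carry planted dysregulation, driver mechanisms and
#' prognostic effects.
#'
#' Expression is Gaussian on the log2 scale around per-gene baselines, with
#' planted shifts added to tumor samples. CNV-driven genes draw per-sample
#' CNV values (a configured fraction of tumors altered at the configured
#' magnitude) and add `coupling_strength * CNV` to tumor expression.
#' Methylation beta-values are logit-normal in (0, 1); driver genes shift the
#' tumor mean by `delta_beta` and couple negatively to expression. Survival
#' times follow a Weibull proportional-hazards model whose linear predictor
#' sums the planted log-hazards over standardized tumor expression, with
#' independent exponential censoring truncated at `max_followup`. Mutations
#' are Bernoulli per gene and tumor sample, emitted as MAF records mixing
#' nonsynonymous and Silent classes.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `cohort` (an `omics_cohort`) and
#'   `truth` (data frame: gene, dysregulation, mechanism, prognostic).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("config must be a cohort_config object", call. = FALSE)
  cfg <- config
  genes <- cfg$genes
  nG <- length(genes)
  code <- cfg$cancer_code
  tumor_ids <- sprintf("%s_T%03d", code, seq_len(cfg$n_tumor))
  normal_ids <- sprintf("%s_N%03d", code, seq_len(cfg$n_normal))
  samples <- c(tumor_ids, normal_ids)
  is_tumor <- c(rep(TRUE, cfg$n_tumor), rep(FALSE, cfg$n_normal))

  # per-gene baselines (own substream so matrices are independent of them)
  set.seed(.substream(cfg$seed, 0L, code))
  base_expr <- stats::runif(nG, 5, 10)
  base_beta <- stats::runif(nG, 0.25, 0.75)
  names(base_expr) <- names(base_beta) <- genes

  # expression: baseline + noise + planted tumor shifts
  set.seed(.substream(cfg$seed, 1L, code))
  expr <- matrix(stats::rnorm(nG * length(samples), mean = base_expr, sd = cfg$noise_sd),
                 nrow = nG, ncol = length(samples),
                 dimnames = list(genes, samples))
  for (g in names(cfg$planted_up))
    expr[g, is_tumor] <- expr[g, is_tumor] + cfg$planted_up[[g]]
  for (g in names(cfg$planted_down))
    expr[g, is_tumor] <- expr[g, is_tumor] - abs(cfg$planted_down[[g]])

  # CNV: tumors only; drivers get a point-mass-plus-noise mixture
  set.seed(.substream(cfg$seed, 2L, code))
  cnv <- matrix(stats::rnorm(nG * cfg$n_tumor, 0, 0.05),
                nrow = nG, ncol = cfg$n_tumor,
                dimnames = list(genes, tumor_ids))
  for (g in names(cfg$planted_cnv_drivers)) {
    d <- cfg$planted_cnv_drivers[[g]]
    sign_d <- if (d$direction == "gain") 1 else -1
    altered <- stats::runif(cfg$n_tumor) < d$alteration_fraction
    cnv[g, altered] <- stats::rnorm(sum(altered), sign_d * d$cnv_magnitude, 0.1)
    expr[g, which(is_tumor)] <- expr[g, which(is_tumor)] + d$coupling_strength * cnv[g, ]
  }

  # methylation: logit-normal; driver genes shift the tumor mean by delta_beta
  set.seed(.substream(cfg$seed, 3L, code))
  logit <- function(p) log(p / (1 - p))
  beta <- matrix(stats::plogis(stats::rnorm(nG * length(samples),
                                            mean = logit(base_beta), sd = 0.25)),
                 nrow = nG, ncol = length(samples),
                 dimnames = list(genes, samples))
  for (g in names(cfg$planted_meth_drivers)) {
    d <- cfg$planted_meth_drivers[[g]]
    sign_d <- if (d$direction == "hyper") 1 else -1
    target <- min(max(base_beta[[g]] + sign_d * d$delta_beta, 0.02), 0.98)
    beta[g, is_tumor] <- stats::plogis(stats::rnorm(cfg$n_tumor, logit(target), sd = 0.25))
    centred <- beta[g, is_tumor] - mean(beta[g, is_tumor])
    expr[g, which(is_tumor)] <- expr[g, which(is_tumor)] - d$coupling_strength * centred
  }

  # survival: Weibull PH over standardized tumor expression
  set.seed(.substream(cfg$seed, 4L, code))
  lp <- rep(0, cfg$n_tumor)
  for (g in names(cfg$planted_prognostic)) {
    z <- as.numeric(scale(expr[g, tumor_ids]))
    lp <- lp + cfg$planted_prognostic[[g]] * z
  }
  u <- stats::runif(cfg$n_tumor)
  t_event <- cfg$baseline_hazard_scale *
    (-log(u) / exp(lp))^(1 / cfg$baseline_hazard_shape)
  cens_rate <- .calibrate_censoring_rate(cfg$censoring_rate,
                                         cfg$baseline_hazard_shape,
                                         cfg$baseline_hazard_scale,
                                         cfg$max_followup)
  t_cens <- if (cens_rate > 0) stats::rexp(cfg$n_tumor, cens_rate) else rep(Inf, cfg$n_tumor)
  t_cens <- pmin(t_cens, cfg$max_followup)
  os_time <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)
  os_time <- pmax(os_time, 1e-6)  # strictly positive

  # clinical covariates
  set.seed(.substream(cfg$seed, 6L, code))
  t_index <- sample(1:4, cfg$n_tumor, replace = TRUE, prob = c(0.2, 0.3, 0.3, 0.2))
  n_index <- sample(0:3, cfg$n_tumor, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  m_index <- sample(0:1, cfg$n_tumor, replace = TRUE, prob = c(0.85, 0.15))
  stage <- pmin(4L, pmax(1L, as.integer(round((t_index + n_index + 2 * m_index) / 2))))
  gender <- sample(c("male", "female"), cfg$n_tumor, replace = TRUE)
  age <- round(stats::rnorm(cfg$n_tumor, 65, 10))
  clinical <- data.frame(
    sample = tumor_ids, os_time = os_time, os_event = os_event,
    t_index = t_index, n_index = n_index, m_index = m_index,
    stage = stage, gender = gender, age = age,
    stringsAsFactors = FALSE
  )

  # mutations: Bernoulli per gene per tumor sample, MAF-style records
  set.seed(.substream(cfg$seed, 5L, code))
  classes <- c("Missense_Mutation", "Silent", "Nonsense_Mutation",
               "Frame_Shift_Del", "Frame_Shift_Ins", "Splice_Site")
  class_p <- c(0.55, 0.20, 0.10, 0.05, 0.05, 0.05)
  nts <- c("A", "C", "G", "T")
  recs <- list()
  for (gi in seq_len(nG)) {
    hit <- which(stats::runif(cfg$n_tumor) < cfg$mutation_rate_per_gene[[gi]])
    if (!length(hit)) next
    cls <- sample(classes, length(hit), replace = TRUE, prob = class_p)
    ref <- sample(nts, length(hit), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1L), character(1))
    vtype <- ifelse(cls == "Frame_Shift_Del", "DEL",
                    ifelse(cls == "Frame_Shift_Ins", "INS", "SNP"))
    ref[vtype == "INS"] <- "-"
    alt[vtype == "DEL"] <- "-"
    alt[vtype == "INS"] <- sample(nts, sum(vtype == "INS"), replace = TRUE)
    recs[[length(recs) + 1L]] <- data.frame(
      Hugo_Symbol = genes[gi], Tumor_Sample_Barcode = tumor_ids[hit],
      Variant_Classification = cls, Variant_Type = vtype,
      Reference_Allele = ref, Tumor_Seq_Allele2 = alt,
      stringsAsFactors = FALSE
    )
  }
  mutations <- if (length(recs)) do.call(rbind, recs) else
    data.frame(Hugo_Symbol = character(0), Tumor_Sample_Barcode = character(0),
               Variant_Classification = character(0), Variant_Type = character(0),
               Reference_Allele = character(0), Tumor_Seq_Allele2 = character(0),
               stringsAsFactors = FALSE)
  rownames(mutations) <- NULL

  cohort <- new_omics_cohort(
    cancer_code = code, expression = expr,
    sample_type = stats::setNames(ifelse(is_tumor, "tumor", "normal"), samples),
    cnv = cnv, methylation = beta, mutations = mutations, clinical = clinical
  )

  # truth table: explicit planted labels, with driver-implied dysregulation
  dysreg <- stats::setNames(rep("none", nG), genes)
  mech <- stats::setNames(rep("none", nG), genes)
  prog <- stats::setNames(rep("none", nG), genes)
  for (g in names(cfg$planted_cnv_drivers)) {
    d <- cfg$planted_cnv_drivers[[g]]
    mech[g] <- if (d$direction == "gain") "cnv_gain" else "cnv_loss"
    dysreg[g] <- if (d$direction == "gain") "up" else "down"
  }
  for (g in names(cfg$planted_meth_drivers)) {
    d <- cfg$planted_meth_drivers[[g]]
    mech[g] <- if (d$direction == "hyper") "hypermethylation" else "hypomethylation"
    dysreg[g] <- if (d$direction == "hyper") "down" else "up"
  }
  dysreg[names(cfg$planted_up)] <- "up"
  dysreg[names(cfg$planted_down)] <- "down"
  prog[names(cfg$planted_prognostic)] <-
    ifelse(cfg$planted_prognostic > 0, "poor", "favorable")
  truth <- data.frame(gene = genes, dysregulation = unname(dysreg),
                      mechanism = unname(mech), prognostic = unname(prog),
                      stringsAsFactors = FALSE)

  list(cohort = cohort, truth = truth)
}

#' Generate several independent synthetic cohorts
#'
#' @param configs List of [cohort_config()] objects with distinct
#'   `cancer_code`s. Each cohort is drawn from its own seed (offset
#'   deterministically by cancer code), so per-code output does not depend
#'   on the order of the configurations.
#' @return Named list (by cancer code) of `list(cohort, truth)` pairs.
#' @export
generate_pan_cancer <- function(configs) {
  if (!length(configs)) stop("need at least one cohort_config", call. = FALSE)
  codes <- vapply(configs, function(c) c$cancer_code, character(1))
  if (anyDuplicated(codes))
    stop("duplicate cancer_code: ", paste(codes[duplicated(codes)], collapse = ", "),
         call. = FALSE)
  out <- lapply(configs, generate_cohort)
  names(out) <- codes
  out
}
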