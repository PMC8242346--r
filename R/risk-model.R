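#' Multivariate Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood with Efron handling of tied event
#' times by Newton-Raphson with step-halving. Convergence is declared when
#' the largest absolute coefficient change falls below `tol` (default 1e-8)
#' within `max_iter` iterations; non-convergence is reported explicitly.
#' Rank-deficient covariate matrices raise an error naming the offending
#' columns; monotone likelihood (separation) yields a warning with the
#' coefficient capped.
#'
#' @param x Numeric covariate matrix (n samples x p covariates) with column
#'   names.
#' @param time,event Survival times and 0/1 event indicators.
#' @param tol Convergence tolerance on the coefficient change.
#' @param max_iter Maximum Newton iterations.
#' @return List with `coefficients`, `se`, `vcov`, `loglik` (final partial
#'   log-likelihood), `iterations`, `converged`, `separated`.
#' @export
fit_cox <- function(x, time, event, tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (length(time) != n || length(event) != n)
    stop("time/event length must match nrow(x)", call. = FALSE)
  if (n <= p) stop("need more samples than covariates", call. = FALSE)
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  qrx <- qr(scale(x, scale = FALSE))
  if (qrx$rank < p) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1):p]]
    stop("collinear covariates (rank deficiency): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  ord <- order(time)
  x <- x[ord, , drop = FALSE]
  time <- time[ord]; event <- event[ord]
  dtimes <- unique(time[event == 1])
  # index sets per distinct event time
  risk_idx <- lapply(dtimes, function(u) which(time >= u))
  death_idx <- lapply(dtimes, function(u) which(time == u & event == 1))

  efron <- function(beta) {
    eta <- drop(x %*% beta)
    w <- exp(eta)
    ll <- 0
    U <- numeric(p)
    I <- matrix(0, p, p)
    for (k in seq_along(dtimes)) {
      R <- risk_idx[[k]]; D <- death_idx[[k]]
      d <- length(D)
      s0 <- sum(w[R])
      s1 <- colSums(x[R, , drop = FALSE] * w[R])
      s2 <- crossprod(x[R, , drop = FALSE] * sqrt(w[R]))
      s0d <- sum(w[D])
      s1d <- colSums(x[D, , drop = FALSE] * w[D])
      s2d <- crossprod(x[D, , drop = FALSE] * sqrt(w[D]))
      ll <- ll + sum(eta[D])
      U <- U + colSums(x[D, , drop = FALSE])
      for (l in seq_len(d) - 1L) {
        f <- l / d
        z0 <- s0 - f * s0d
        z1 <- s1 - f * s1d
        z2 <- s2 - f * s2d
        ll <- ll - log(z0)
        U <- U - z1 / z0
        I <- I + z2 / z0 - tcrossprod(z1 / z0)
      }
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- numeric(p)
  st <- efron(beta)
  converged <- FALSE
  iter <- 0L
  cap <- 15
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(st$I, st$U), error = function(e)
      stop("information matrix singular during Cox fit", call. = FALSE))
    new_beta <- beta + step
    new_st <- efron(new_beta)
    halvings <- 0L
    while ((is.na(new_st$ll) || new_st$ll < st$ll) && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new_st <- efron(new_beta)
      halvings <- halvings + 1L
    }
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    st <- new_st
    if (delta < tol) { converged <- TRUE; break }
  }
  separated <- any(abs(beta) > cap)
  if (separated) {
    warning("monotone partial likelihood (separation); coefficients capped",
            call. = FALSE)
    beta <- pmin(pmax(beta, -cap), cap)
    st <- efron(beta)
  }
  if (!converged && !separated)
    warning(sprintf("Cox fit did not converge in %d iterations", max_iter),
            call. = FALSE)
  vcov <- solve(st$I)
  se <- sqrt(diag(vcov))
  names(beta) <- names(se) <- colnames(x)
  dimnames(vcov) <- list(colnames(x), colnames(x))
  list(coefficients = beta, se = se, vcov = vcov, loglik = st$ll,
       iterations = iter, converged = converged, separated = separated)
}

# partial log-likelihood at an arbitrary coefficient vector (for checks)
cox_loglik <- function(x, time, event, beta) {
  x <- as.matrix(x)
  ord <- order(time)
  x <- x[ord, , drop = FALSE]; time <- time[ord]; event <- event[ord]
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ll <- 0
  for (u in unique(time[event == 1])) {
    R <- which(time >= u); D <- which(time == u & event == 1)
    d <- length(D)
    s0 <- sum(w[R]); s0d <- sum(w[D])
    ll <- ll + sum(eta[D]) -
      sum(log(s0 - (seq_len(d) - 1) / d * s0d))
  }
  ll
}

#' Per-sample risk scores from a fitted model
#'
#' The linear predictor `x %*% coefficients`, with covariate columns
#' matched by name to the model order.
#'
#' @param model Result of [fit_cox()] (or any list with named
#'   `coefficients`).
#' @param x Covariate matrix with column names covering the model
#'   covariates; rows may be named by sample.
#' @return Named numeric vector of risk scores.
#' @export
risk_score <- function(model, x) {
  x <- as.matrix(x)
  need <- names(model$coefficients)
  missing <- setdiff(need, colnames(x))
  if (length(missing))
    stop("missing covariate column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  drop(x[, need, drop = FALSE] %*% model$coefficients)
}

#' Stratify by risk score and compare survival
#'
#' Splits the cohort at a score percentile (default the median) into high-
#' and low-risk groups, computes Kaplan-Meier curves per group and the
#' log-rank p-value between them after horizon censoring.
#'
#' @param scores Named numeric vector, sample -> risk score.
#' @param clinical Data frame with `sample`, `os_time`, `os_event`.
#' @param horizon_months Administrative horizon (default `Inf`).
#' @param split_percentile Score quantile for the split (default 0.5).
#' @return List with `groups` (named "high"/"low"), `split_value`,
#'   `logrank_p`, and `km` (data frame of per-group KM coordinates:
#'   group, time, surv).
#' @export
stratify_and_compare <- function(scores, clinical, horizon_months = Inf,
                                 split_percentile = 0.5) {
  common <- intersect(names(scores), clinical$sample)
  cl <- apply_horizon(clinical[match(common, clinical$sample), , drop = FALSE],
                      horizon_months)
  s <- scores[common]
  split <- stats::quantile(s, split_percentile, names = FALSE)
  high <- s > split
  n <- length(s)
  if (mean(s == split) > 0.5) {
    warning("majority of scores tied at the split; using quantile-adjacent split",
            call. = FALSE)
    split <- max(s[s < split], -Inf)
    high <- s > split
  }
  if (sum(high) < 10 || sum(!high) < 10)
    stop("need >= 10 samples per risk group", call. = FALSE)
  lr <- logrank_test(cl$os_time[high], cl$os_event[high],
                     cl$os_time[!high], cl$os_event[!high])
  km_df <- do.call(rbind, lapply(c(TRUE, FALSE), function(h) {
    fit <- survival::survfit(
      survival::Surv(cl$os_time[high == h], cl$os_event[high == h]) ~ 1)
    data.frame(group = if (h) "high" else "low",
               time = c(0, fit$time), surv = c(1, fit$surv),
               stringsAsFactors = FALSE)
  }))
  list(groups = stats::setNames(ifelse(high, "high", "low"), names(s)),
       split_value = split, logrank_p = lr$p, km = km_df)
}

#' Area under the ROC curve
#'
#' Concordant-pair counting with half credit for ties; algebraically equal
#' to the Mann-Whitney U statistic divided by `n_pos * n_neg` (computed via
#' mid-ranks).
#'
#' @param scores Numeric predictor.
#' @param outcome 0/1 (or logical) outcome; both classes must be present.
#'   `NA` outcomes are dropped with their scores.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, outcome) {
  keep <- !is.na(outcome) & !is.na(scores)
  scores <- scores[keep]; outcome <- as.integer(outcome[keep])
  n_pos <- sum(outcome == 1); n_neg <- sum(outcome == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("undefined AUC: both outcome classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[outcome == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Five-year death status for ROC evaluation
#'
#' Deaths on or before the horizon are positives, samples followed past the
#' horizon without an event are negatives, and samples censored before the
#' horizon have indeterminable status and are excluded (`NA`).
#'
#' @param clinical Data frame with `os_time`, `os_event`.
#' @param horizon_months Horizon in months (default 60).
#' @return Integer vector of 1/0/NA aligned with the clinical rows.
#' @export
death_within_horizon <- function(clinical, horizon_months = 60) {
  ifelse(clinical$os_event == 1 & clinical$os_time <= horizon_months, 1L,
         ifelse(clinical$os_time > horizon_months, 0L, NA_integer_))
}

#' Build a risk model over prognostic genes and TNM indexes
#'
#' Fits a multivariate Cox model on standardized (z-scored within the
#' cohort) expression of the given genes plus ordinal-coded T/N/M staging
#' indexes, computes per-sample risk scores, stratifies at the median
#' score, compares the groups by Kaplan-Meier/log-rank, and evaluates the
#' five-year AUC of the score. Samples with missing TNM codes are excluded.
#'
#' @param cohort An `omics_cohort` with clinical data.
#' @param genes Genes entering the model (e.g. from
#'   [prognostic_dysregulated()]).
#' @param use_tnm Include the T/N/M indexes as covariates (default TRUE).
#' @param split_percentile Risk-split quantile (default 0.5).
#' @param horizon_months Horizon for the AUC outcome (default 60).
#' @return List with `model` (the [fit_cox()] result), `covariates`,
#'   `risk_scores`, `stratification` (see [stratify_and_compare()]),
#'   `auc_5yr`, and a tidy `summary` data frame.
#' @export
build_risk_model <- function(cohort, genes, use_tnm = TRUE,
                             split_percentile = 0.5, horizon_months = 60) {
  if (is.null(cohort$clinical)) stop("cohort has no clinical data", call. = FALSE)
  if (!length(genes)) stop("need at least one gene", call. = FALSE)
  cl <- cohort$clinical
  keep <- cl$sample %in% colnames(cohort$expression) &
    !is.na(cl$os_time) & !is.na(cl$os_event)
  if (use_tnm)
    keep <- keep & !is.na(cl$t_index) & !is.na(cl$n_index) & !is.na(cl$m_index)
  cl <- cl[keep, , drop = FALSE]
  gx <- t(cohort$expression[genes, cl$sample, drop = FALSE])
  gx <- scale(gx)
  colnames(gx) <- genes
  xmat <- if (use_tnm) {
    cbind(gx, t_index = cl$t_index, n_index = cl$n_index,
          m_index = cl$m_index)
  } else gx
  rownames(xmat) <- cl$sample
  model <- fit_cox(xmat, cl$os_time, cl$os_event)
  scores <- risk_score(model, xmat)
  names(scores) <- cl$sample
  strat <- stratify_and_compare(scores, cl, horizon_months = Inf,
                                split_percentile = split_percentile)
  outcome <- death_within_horizon(cl, horizon_months)
  auc <- if (sum(outcome == 1, na.rm = TRUE) > 0 &&
             sum(outcome == 0, na.rm = TRUE) > 0)
    roc_auc(scores, outcome) else NA_real_
  z <- model$coefficients / model$se
  summary_df <- data.frame(
    cancer_code = cohort$cancer_code,
    covariate = names(model$coefficients),
    coefficient = unname(model$coefficients), se = unname(model$se),
    p = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE)
  list(model = model, covariates = colnames(xmat), risk_scores = scores,
       stratification = strat, auc_5yr = auc, summary = summary_df)
}
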