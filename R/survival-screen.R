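#' Apply an administrative follow-up horizon
#'
#' Events after the horizon become censored at the horizon and all times are
#' truncated there. An event exactly at the horizon remains an event
#' (closed-interval convention). `horizon_months = Inf` (the "total"
#' analysis) leaves the input unchanged.
#'
#' @param clinical Data frame with `os_time` (months) and `os_event` (0/1).
#' @param horizon_months Positive number of months, or `Inf`.
#' @return The clinical data frame with truncated `os_time`/`os_event`.
#' @export
apply_horizon <- function(clinical, horizon_months = Inf) {
  if (!is.infinite(horizon_months) && horizon_months <= 0)
    stop("horizon_months must be > 0", call. = FALSE)
  over <- clinical$os_time > horizon_months
  clinical$os_event[over] <- 0L
  clinical$os_time[over] <- horizon_months
  clinical
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square: at each distinct event time the observed
#' number of group-A events is compared with its hypergeometric expectation
#' and variance given the risk sets; the statistic is
#' `(O - E)^2 / V` with a 1-df chi-square p-value.
#'
#' @param times_a,events_a,times_b,events_b Survival times and 0/1 event
#'   indicators for the two groups.
#' @return List with `statistic`, `p`, and the observed/expected
#'   group-A event counts.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b))
    stop("both groups must be non-empty", call. = FALSE)
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  in_a <- c(rep(TRUE, length(times_a)), rep(FALSE, length(times_b)))
  if (sum(event) == 0)
    stop("undefined test: no events in the data", call. = FALSE)
  st <- .logrank_stat(time, event, in_a)
  list(statistic = st$chisq, p = st$p, observed_a = st$obs, expected_a = st$exp)
}

# core log-rank computation on (time, event, group) vectors
.logrank_stat <- function(time, event, in_a) {
  ut <- sort(unique(time[event == 1]))
  obs <- exp_a <- varsum <- 0
  for (u in ut) {
    at_risk <- time >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_a)
    dying <- time == u & event == 1
    d <- sum(dying)
    d1 <- sum(dying & in_a)
    obs <- obs + d1
    exp_a <- exp_a + d * n1 / n
    if (n > 1)
      varsum <- varsum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (varsum <= 0) return(list(chisq = NA_real_, p = NA_real_, obs = obs, exp = exp_a))
  chisq <- (obs - exp_a)^2 / varsum
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       obs = obs, exp = exp_a)
}

#' Hazard ratio of a binary grouping
#'
#' Univariate Cox proportional-hazards fit (Efron tie handling, via
#' \pkg{survival}) of a binary group indicator; returns the hazard ratio of
#' `group = TRUE/1` versus the reference with a Wald confidence interval.
#' With no events in one group (monotone likelihood) the HR is reported as
#' an `Inf`/0 sentinel with a warning.
#'
#' @param time,event Survival times and 0/1 indicators.
#' @param group Logical or 0/1 vector (TRUE/1 = the "high" group).
#' @param conf_level Confidence level for the Wald interval.
#' @return List with `hr`, `lower`, `upper`, `coef`, `se`, `p`,
#'   `separated` flag.
#' @export
hazard_ratio <- function(time, event, group, conf_level = 0.95) {
  group <- as.numeric(group)
  if (length(unique(group)) != 2)
    stop("group must take exactly two values", call. = FALSE)
  if (sum(event) == 0) stop("no events in the data", call. = FALSE)
  ev_by_grp <- tapply(event, group, sum)
  if (any(ev_by_grp == 0)) {
    warning("no events in one group; hazard ratio reported as sentinel",
            call. = FALSE)
    hr <- if (ev_by_grp[["1"]] == 0) 0 else Inf
    return(list(hr = hr, lower = NA_real_, upper = NA_real_,
                coef = log(hr), se = NA_real_, p = NA_real_,
                separated = TRUE))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ group,
                         ties = "efron")
  b <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(b), lower = exp(b - z * se), upper = exp(b + z * se),
       coef = b, se = se,
       p = 2 * stats::pnorm(-abs(b / se)), separated = abs(b) > 15)
}

#' Minimum-p expression cutpoint scan for one gene
#'
#' Scans the distinct expression values whose induced low-group size lies
#' between the 10th and 90th percentile of the samples; each candidate
#' splits the cohort into low (expression <= cut) and high groups and is
#' scored by the log-rank p-value after horizon censoring. The cut with the
#' smallest p is selected (ties broken toward the cut closest to the median
#' expression), and the hazard ratio of high versus low expression is
#' estimated at that cut.
#'
#' @param expr_values Named numeric vector, sample -> log2 expression.
#' @param clinical Data frame with `sample`, `os_time`, `os_event`.
#' @param horizon_months Administrative horizon (default `Inf` = total).
#' @param percentile_bounds Admissible low-group size bounds as fractions
#'   (default `c(0.1, 0.9)`).
#' @param p_threshold Significance level for the poor/favorable label
#'   (default 0.05).
#' @return One-row data frame: cut_value, cut_percentile, hr, hr_lower,
#'   hr_upper, logrank_p, n_low, n_high, label.
#' @export
optimal_cutpoint_scan <- function(expr_values, clinical,
                                  horizon_months = Inf,
                                  percentile_bounds = c(0.1, 0.9),
                                  p_threshold = 0.05) {
  common <- intersect(names(expr_values), clinical$sample)
  if (length(common) < 20)
    stop("need >= 20 samples with both expression and survival", call. = FALSE)
  cl <- apply_horizon(clinical[match(common, clinical$sample), , drop = FALSE],
                      horizon_months)
  x <- expr_values[common]
  n <- length(x)
  time <- cl$os_time
  event <- cl$os_event
  empty_call <- function(label) data.frame(
    cut_value = NA_real_, cut_percentile = NA_real_, hr = NA_real_,
    hr_lower = NA_real_, hr_upper = NA_real_, logrank_p = NA_real_,
    n_low = NA_integer_, n_high = NA_integer_, label = label,
    stringsAsFactors = FALSE)
  vals <- sort(unique(x))
  if (length(vals) < 2) {
    warning("all expression values identical; no valid cutpoint", call. = FALSE)
    return(empty_call("ns"))
  }
  lo_min <- ceiling(percentile_bounds[1] * n)
  lo_max <- floor(percentile_bounds[2] * n)
  n_low_at <- vapply(vals, function(v) sum(x <= v), integer(1))
  cand <- vals[n_low_at >= lo_min & n_low_at <= lo_max]
  if (!length(cand)) {
    warning("no admissible cutpoint within the percentile bounds", call. = FALSE)
    return(empty_call("ns"))
  }
  if (sum(event) == 0) {
    warning("no events after horizon censoring; label ns", call. = FALSE)
    return(empty_call("ns"))
  }
  ps <- vapply(cand, function(v)
    .logrank_stat(time, event, in_a = x > v)$p, numeric(1))
  ok <- !is.na(ps)
  if (!any(ok)) return(empty_call("ns"))
  cand <- cand[ok]; ps <- ps[ok]
  best_p <- min(ps)
  tied <- cand[ps == best_p]
  med <- stats::median(x)
  cut <- tied[order(abs(tied - med), tied)][1]
  low <- x <= cut
  hr <- suppressWarnings(hazard_ratio(time, event, group = !low))
  # only a zero-event group (HR sentinel 0/Inf) forces ns; a large but
  # estimable HR with significant p keeps its label
  label <- if (!is.finite(hr$hr) || hr$hr == 0 || is.na(best_p) ||
               best_p >= p_threshold) "ns"
           else if (hr$hr > 1) "poor" else "favorable"
  data.frame(cut_value = cut, cut_percentile = mean(x <= cut),
             hr = hr$hr, hr_lower = hr$lower, hr_upper = hr$upper,
             logrank_p = best_p, n_low = sum(low), n_high = sum(!low),
             label = label, stringsAsFactors = FALSE)
}

#' Screen all genes across survival horizons
#'
#' Runs [optimal_cutpoint_scan()] for every gene at each horizon (total,
#' 10-year, 5-year by default) over a cohort's tumor samples.
#'
#' @param cohort An `omics_cohort` with clinical data.
#' @param genes Genes to screen (default: all rows).
#' @param horizons Named numeric vector of horizons in months
#'   (default `c(total = Inf, "10yr" = 120, "5yr" = 60)`).
#' @param ... Passed to [optimal_cutpoint_scan()].
#' @return Data frame of survival calls, one row per gene x horizon.
#' @export
survival_screen <- function(cohort, genes = rownames(cohort$expression),
                            horizons = c(total = Inf, "10yr" = 120, "5yr" = 60),
                            ...) {
  if (is.null(cohort$clinical)) stop("cohort has no clinical data", call. = FALSE)
  tum <- tumor_samples(cohort)
  rows <- list()
  for (g in genes) {
    ev <- cohort$expression[g, intersect(tum, cohort$clinical$sample)]
    for (h in names(horizons)) {
      call <- optimal_cutpoint_scan(ev, cohort$clinical,
                                    horizon_months = horizons[[h]], ...)
      call <- cbind(data.frame(gene = g, cancer_code = cohort$cancer_code,
                               horizon = h, stringsAsFactors = FALSE), call)
      rows[[length(rows) + 1L]] <- call
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prognosis label from per-horizon survival calls
#'
#' Applies the five-year rule: HR > 1 with five-year log-rank p < 0.05 is
#' "poor", 0 < HR < 1 with p < 0.05 is "favorable", otherwise "ns". Total
#' and 10-year calls are annotation only.
#'
#' @param calls Data frame of survival calls for one gene (rows = horizons,
#'   with a `horizon` column).
#' @param p_threshold Significance level (default 0.05).
#' @return "poor", "favorable" or "ns".
#' @export
classify_prognosis <- function(calls, p_threshold = 0.05) {
  five <- calls[calls$horizon == "5yr", , drop = FALSE]
  if (nrow(five) != 1 || is.na(five$hr) || is.na(five$logrank_p)) {
    warning("missing five-year call; classified ns", call. = FALSE)
    return("ns")
  }
  if (five$logrank_p >= p_threshold) return("ns")
  if (five$hr > 1) "poor" else if (five$hr > 0) "favorable" else "ns"
}

#' Dysregulated prognosis-related genes
#'
#' Intersects differential-expression calls with survival labels: genes
#' with direction != "ns" and prognosis label != "ns" in the same cancer,
#' annotated with a concordance flag (up & poor, or down & favorable).
#'
#' @param de_calls Data frame from [differential_expression()].
#' @param survival_calls Data frame from [survival_screen()] (all horizons).
#' @param p_threshold Passed to [classify_prognosis()].
#' @return Data frame: gene, cancer_code, direction, label, concordant.
#' @export
prognostic_dysregulated <- function(de_calls, survival_calls,
                                    p_threshold = 0.05) {
  genes <- unique(survival_calls$gene)
  labels <- vapply(genes, function(g)
    suppressWarnings(classify_prognosis(
      survival_calls[survival_calls$gene == g, , drop = FALSE], p_threshold)),
    character(1))
  lab <- data.frame(gene = genes, label = unname(labels),
                    stringsAsFactors = FALSE)
  m <- merge(de_calls[, c("gene", "cancer_code", "direction")], lab,
             by = "gene")
  m <- m[m$direction != "ns" & m$label != "ns", , drop = FALSE]
  m$concordant <- (m$direction == "up" & m$label == "poor") |
                  (m$direction == "down" & m$label == "favorable")
  m <- m[order(m$gene), , drop = FALSE]
  rownames(m) <- NULL
  m
}
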