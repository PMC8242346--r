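# Independent oracle implementations used to cross-check the package.
# These deliberately use different code paths (brute force, survdiff,
# survival::coxph) than the functions they validate.

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  running_min <- Inf
  for (i in n:1) {
    val <- p[ord[i]] * n / i
    running_min <- min(running_min, val)
    q[ord[i]] <- min(running_min, 1)
  }
  q
}

# exhaustive prefix-sum enrichment score: walk every position of the ranked
# list, accumulating the weighted hit/miss running sum directly
oracle_es <- function(stats_named, gene_set, w_exp = 1) {
  ord <- names(sort(stats_named, decreasing = TRUE))
  s <- stats_named[ord]
  hit <- ord %in% gene_set
  nh <- sum(hit)
  n <- length(ord)
  denom_hit <- sum(abs(s[hit])^w_exp)
  running <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    if (hit[i]) acc <- acc + abs(s[i])^w_exp / denom_hit
    else acc <- acc - 1 / (n - nh)
    running[i] <- acc
  }
  # same documented tie convention as the package: magnitude ties between
  # the extremes (relative 1e-9) go to the earlier position
  i_max <- which.max(running); i_min <- which.min(running)
  a <- running[i_max]; b <- -running[i_min]
  if (abs(a - b) <= 1e-9 * max(abs(a), abs(b), 1))
    return(running[min(i_max, i_min)])
  if (a > b) running[i_max] else running[i_min]
}

# log-rank oracle via survival::survdiff
oracle_logrank <- function(times_a, events_a, times_b, events_b) {
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- c(rep(1, length(times_a)), rep(2, length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

# brute-force min-p cutpoint search over every admissible split, scored
# with survdiff, ties broken toward the cut closest to the median
oracle_cutpoint <- function(x, time, event, bounds = c(0.1, 0.9)) {
  n <- length(x)
  vals <- sort(unique(x))
  lo_min <- ceiling(bounds[1] * n)
  lo_max <- floor(bounds[2] * n)
  best_p <- Inf
  best_cuts <- numeric(0)
  for (v in vals) {
    n_low <- sum(x <= v)
    if (n_low < lo_min || n_low > lo_max) next
    grp <- as.integer(x > v)
    p <- tryCatch({
      sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
      stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    }, error = function(e) NA_real_)
    if (is.na(p)) next
    if (p < best_p - 1e-12) { best_p <- p; best_cuts <- v }
    else if (abs(p - best_p) <= 1e-12) best_cuts <- c(best_cuts, v)
  }
  if (!length(best_cuts)) return(NULL)
  med <- stats::median(x)
  list(cut = best_cuts[order(abs(best_cuts - med), best_cuts)][1], p = best_p)
}

# random survival dataset with ties
random_surv_data <- function(n, tie_prob = 0.4) {
  time <- ceiling(stats::rexp(n, 0.1))       # integer times induce ties
  event <- stats::rbinom(n, 1, 0.7)
  list(time = time, event = event)
}

# tiny deterministic cohort with planted signal for unit tests
small_cohort <- function(seed = 42, n_tumor = 50, n_normal = 50, ...) {
  cfg <- cohort_config("TST", n_tumor = n_tumor, n_normal = n_normal,
                       seed = seed, ...)
  generate_cohort(cfg)
}
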