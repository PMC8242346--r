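test_that("horizon censoring truncates events with a closed boundary", {
  cl <- data.frame(sample = c("a", "b", "c"),
                   os_time = c(80, 40, 60), os_event = c(1L, 1L, 1L))
  out <- apply_horizon(cl, 60)
  expect_equal(out$os_time, c(60, 40, 60))
  expect_equal(out$os_event, c(0L, 1L, 1L))  # event at the horizon stays
  expect_identical(apply_horizon(cl, Inf), cl)
  expect_error(apply_horizon(cl, -1), "> 0")
})

test_that("log-rank statistic matches a hand-tabulated small case", {
  # A: times 1,2 both events; B: times 3,4 both events
  # t=1: n=4, n_A=2, d=1, dA=1 -> E=0.5, V=0.25
  # t=2: n=3, n_A=1, d=1, dA=1 -> E=1/3, V=2/9
  # t=3: n=2, n_A=0, d=1, dA=0 -> E=0,   V=0
  # t=4: n=1, n_A=0, d=1, dA=0 -> E=0,   V=0
  # O-E = 2 - 5/6 = 7/6; V = 0.25 + 2/9 = 17/36; chisq = (7/6)^2/(17/36)
  res <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(res$statistic, (7 / 6)^2 / (17 / 36))
  expect_equal(res$observed_a, 2)
  expect_equal(res$expected_a, 5 / 6)
  # symmetry in group labels
  swapped <- logrank_test(c(3, 4), c(1, 1), c(1, 2), c(1, 1))
  expect_equal(swapped$statistic, res$statistic)
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3), c(0)), "no events")
})

test_that("log-rank matches survdiff on random tied datasets", {
  set.seed(20)
  for (i in 1:60) {
    na <- sample(5:15, 1); nb <- sample(5:15, 1)
    a <- random_surv_data(na); b <- random_surv_data(nb)
    if (sum(a$event) + sum(b$event) == 0) next
    mine <- logrank_test(a$time, a$event, b$time, b$event)
    if (is.na(mine$statistic)) next  # degenerate: no between-group variance
    orc <- oracle_logrank(a$time, a$event, b$time, b$event)
    expect_equal(mine$statistic, orc$statistic, tolerance = 1e-8)
    expect_equal(mine$p, orc$p, tolerance = 1e-8)
  }
})

test_that("hazard ratio recovers planted effects and inverts under relabel", {
  set.seed(21)
  n <- 600
  grp <- rep(c(0, 1), each = n / 2)
  time <- rexp(n, 0.02 * exp(0.7 * grp))
  event <- rep(1L, n)
  hr <- hazard_ratio(time, event, grp)
  expect_lt(abs(hr$coef - 0.7), 0.25)
  expect_true(hr$lower < exp(0.7) && exp(0.7) < hr$upper ||
                abs(hr$coef - 0.7) < 2 * hr$se)
  inv <- hazard_ratio(time, event, 1 - grp)
  expect_equal(inv$hr, 1 / hr$hr, tolerance = 1e-8)
  # no events in one group -> sentinel with warning
  expect_warning(
    sep <- hazard_ratio(c(1, 2, 3, 4), c(1, 1, 0, 0), c(0, 0, 1, 1)),
    "sentinel")
  expect_equal(sep$hr, 0)
  expect_true(sep$separated)
})

test_that("cutpoint scan equals exhaustive brute force on random data", {
  set.seed(22)
  agreements <- 0L
  for (i in 1:25) {
    n <- sample(25:45, 1)
    x <- setNames(round(rnorm(n), 2), paste0("s", 1:n))
    d <- random_surv_data(n)
    cl <- data.frame(sample = names(x), os_time = d$time, os_event = d$event)
    if (sum(d$event) < 2) next
    scan <- suppressWarnings(optimal_cutpoint_scan(x, cl))
    orc <- oracle_cutpoint(as.numeric(x), d$time, d$event)
    if (is.null(orc) || is.na(scan$cut_value)) next
    expect_equal(scan$cut_value, orc$cut, info = paste("dataset", i))
    expect_equal(scan$logrank_p, orc$p, tolerance = 1e-8)
    agreements <- agreements + 1L
  }
  expect_gte(agreements, 15L)
})

test_that("cutpoint scan is invariant to monotone expression transforms", {
  set.seed(23)
  n <- 40
  x <- setNames(rnorm(n), paste0("s", 1:n))
  d <- random_surv_data(n)
  cl <- data.frame(sample = names(x), os_time = d$time, os_event = d$event)
  s1 <- suppressWarnings(optimal_cutpoint_scan(x, cl))
  s2 <- suppressWarnings(optimal_cutpoint_scan(exp(x), cl))
  # same induced partition: identical low-group size and p-value
  expect_equal(s2$n_low, s1$n_low)
  expect_equal(s2$logrank_p, s1$logrank_p, tolerance = 1e-10)
})

test_that("perfectly anti-ordered expression yields a poor label", {
  n <- 30
  x <- setNames(seq_len(n), paste0("s", 1:n))
  # highest expression dies first, all events
  cl <- data.frame(sample = names(x), os_time = rev(seq_len(n)),
                   os_event = rep(1L, n))
  scan <- optimal_cutpoint_scan(x, cl)
  expect_identical(scan$label, "poor")
  expect_gt(scan$hr, 1)
  # degenerate input: constant expression
  flat <- setNames(rep(1, 25), paste0("s", 1:25))
  cl2 <- data.frame(sample = names(flat), os_time = 1:25,
                    os_event = rep(1L, 25))
  expect_warning(res <- optimal_cutpoint_scan(flat, cl2), "identical")
  expect_identical(res$label, "ns")
  expect_error(optimal_cutpoint_scan(flat[1:5], cl2[1:5, ]), ">= 20")
})

test_that("prognosis classification follows the five-year HR and p rule", {
  mk <- function(hr, p) data.frame(horizon = c("total", "10yr", "5yr"),
                                   hr = c(1, 1, hr),
                                   logrank_p = c(0.5, 0.5, p))
  expect_identical(classify_prognosis(mk(2.0, 0.01)), "poor")
  expect_identical(classify_prognosis(mk(0.5, 0.01)), "favorable")
  expect_identical(classify_prognosis(mk(2.0, 0.20)), "ns")
  expect_warning(lab <- classify_prognosis(
    data.frame(horizon = "total", hr = 2, logrank_p = 0.01)), "five-year")
  expect_identical(lab, "ns")
})

test_that("dysregulated prognosis-related genes are the labelled intersection", {
  de <- data.frame(gene = c("A", "B", "C", "D"), cancer_code = "X",
                   direction = c("up", "up", "ns", "down"),
                   stringsAsFactors = FALSE)
  sv <- do.call(rbind, lapply(c("A", "B", "C", "D"), function(g)
    data.frame(gene = g, horizon = c("total", "10yr", "5yr"),
               hr = c(1, 1, switch(g, A = 2, B = 1.5, C = 3, D = 0.4)),
               logrank_p = c(0.9, 0.9,
                             switch(g, A = 0.01, B = 0.2, C = 0.01, D = 0.01)),
               stringsAsFactors = FALSE)))
  out <- prognostic_dysregulated(de, sv)
  expect_setequal(out$gene, c("A", "D"))   # B fails p, C is ns in DE
  expect_true(all(out$concordant))
  # planted recovery on a synthetic cohort
  g <- small_cohort(seed = 33, n_tumor = 150, n_normal = 60,
                    planted_up = c(ITGA11 = 2),
                    planted_prognostic = c(ITGA11 = 0.8))
  de2 <- differential_expression(g$cohort)
  sv2 <- suppressWarnings(survival_screen(g$cohort, genes = "ITGA11"))
  out2 <- prognostic_dysregulated(de2, sv2)
  expect_true("ITGA11" %in% out2$gene)
  expect_identical(out2$label[out2$gene == "ITGA11"], "poor")
})

test_that("scan power increases with the planted effect size", {
  sig_frac <- vapply(c(0.0, 0.5, 1.2), function(eff) {
    hits <- vapply(1:12, function(s) {
      set.seed(1000 + s)
      n <- 120
      x <- setNames(rnorm(n), paste0("s", 1:n))
      time <- rexp(n, 0.02 * exp(eff * x))
      cl <- data.frame(sample = names(x),
                       os_time = pmin(time, 100),
                       os_event = as.integer(time <= 100))
      suppressWarnings(optimal_cutpoint_scan(x, cl))$logrank_p < 0.05
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(sig_frac[3] >= sig_frac[1])
  expect_gte(sig_frac[3], 0.9)
})
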