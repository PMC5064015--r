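rec <- function(time, event) tibble::tibble(time = time, event = as.integer(event))

test_that("scaled MAD matches its definition", {
  expect_equal(mad_scaled(c(1, 1, 2, 2, 4, 6, 9)), 1.4826)
  expect_equal(mad_scaled(rep(3, 5)), 0)
  expect_equal(mad_scaled(c(0, 1, 2), constant = 1), 1)
  expect_error(mad_scaled(numeric(0)), "finite value")
})

test_that("expression-high stratification uses a strict median + 1 MAD cutoff", {
  v <- setNames(c(1, 2, 3, 4, 100), sprintf("S%d", 1:5))
  s <- stratify_high(v)
  expect_equal(attr(s, "cutoff"), 3 + 1.4826)
  expect_equal(sum(s$group == "high"), 1L)
  expect_equal(s$sample[s$group == "high"], "S5")

  # a value exactly at the cutoff stays in the rest group
  v2 <- setNames(c(1, 2, 3, 4, 3 + 1.4826), sprintf("S%d", 1:5))
  s2 <- stratify_high(v2)
  expect_equal(sum(s2$group == "high"), 0L)

  expect_warning(s3 <- stratify_high(setNames(rep(2, 4), sprintf("S%d", 1:4))),
                 "constant")
  expect_equal(sum(s3$group == "high"), 0L)
})

test_that("follow-up truncation administratively censors at the cap", {
  r <- truncate_followup(rec(c(150, 120, 36), c(1, 1, 0)), 120)
  expect_equal(r$time, c(120, 120, 36))
  expect_equal(r$event, c(0L, 1L, 0L))
})

test_that("the product-limit estimate matches closed forms and a hand oracle", {
  k <- km_estimate(rec(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(k$survival, c(2/3, 1/3, 0))
  expect_equal(k$n_risk, c(3L, 2L, 1L))

  k2 <- km_estimate(rec(c(1, 5, 9), c(0, 0, 0)))
  expect_equal(nrow(k2), 0L)
  expect_equal(km_survival_at(k2, c(0, 10)), c(1, 1))

  # {1+, 2, 2, 3+, 4}: S(2) = 1 * (1 - 2/4) = 0.5; S(4) = 0.5 * (1 - 1/1) = 0
  k3 <- km_estimate(rec(c(1, 2, 2, 3, 4), c(0, 1, 1, 0, 1)))
  expect_equal(k3$time, c(2, 4))
  expect_equal(k3$n_risk, c(4L, 1L))
  expect_equal(k3$survival, c(0.5, 0))
})

test_that("without censoring the estimate equals the empirical survival function", {
  set.seed(21)
  for (rep in 1:5) {
    t <- round(rexp(40, 0.1), 1)
    k <- km_estimate(rec(t, rep(1, 40)))
    grid <- c(0, sort(unique(t)))
    expect_equal(km_survival_at(k, grid), vapply(grid, function(x) mean(t > x),
                                                 numeric(1)))
  }
})

test_that("the estimate agrees with the survival package under censoring", {
  skip_if_not_installed("survival")
  set.seed(31)
  for (rep in 1:5) {
    t <- round(rexp(60, 0.05), 1)
    e <- rbinom(60, 1, 0.6)
    k <- km_estimate(rec(t, e))
    fit <- survival::survfit(survival::Surv(t, e) ~ 1)
    ref_t <- fit$time[fit$n.event > 0]
    ref_s <- fit$surv[fit$n.event > 0]
    expect_equal(k$time, ref_t)
    expect_equal(k$survival, ref_s, tolerance = 1e-12)
  }
})

test_that("the log-rank test matches independent references", {
  a <- rec(c(1, 3, 5, 7, 9), c(1, 0, 1, 1, 0))
  b <- rec(c(2, 4, 6, 8, 10), c(1, 1, 0, 1, 1))
  lr <- logrank_test(a, b)
  # frozen reference values computed with an independent implementation
  expect_equal(lr$statistic, 0.05889945359893294, tolerance = 1e-9)
  expect_equal(lr$p, 0.8082439306895639, tolerance = 1e-9)

  skip_if_not_installed("survival")
  set.seed(41)
  for (rep in 1:5) {
    t <- round(rexp(80, 0.05), 1)
    e <- rbinom(80, 1, 0.7)
    g <- rep(1:2, each = 40)
    sd <- survival::survdiff(survival::Surv(t, e) ~ g)
    mine <- logrank_test(rec(t[g == 1], e[g == 1]), rec(t[g == 2], e[g == 2]))
    expect_equal(mine$statistic, unname(sd$chisq), tolerance = 1e-8)
  }
})

test_that("log-rank symmetry and insensitivity to late censoring", {
  a <- rec(c(2, 4, 6, 9), c(1, 1, 0, 1))
  b <- rec(c(1, 3, 8, 12), c(1, 0, 1, 1))
  expect_equal(logrank_test(a, b)$statistic, logrank_test(b, a)$statistic)
  # a censoring time beyond the last event can be moved freely
  b2 <- rbind(b, rec(20, 0))
  b3 <- rbind(b, rec(999, 0))
  expect_equal(logrank_test(a, b2)$statistic, logrank_test(a, b3)$statistic)
  # identical groups carry no signal
  same <- logrank_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(logrank_test(a[0, ], b), "non-empty")
  expect_error(logrank_test(rec(1, 0), rec(2, 0)), "no events")
})

test_that("the Gehan-Breslow test weights by the pooled risk set", {
  a <- rec(c(1, 3, 5, 7, 9), c(1, 0, 1, 1, 0))
  b <- rec(c(2, 4, 6, 8, 10), c(1, 1, 0, 1, 1))
  gw <- gehan_wilcoxon_test(a, b)
  # frozen reference value from an independent implementation (= 1/18 here)
  expect_equal(gw$statistic, 1 / 18, tolerance = 1e-9)
  expect_equal(gw$p, 0.8136637157667919, tolerance = 1e-9)

  # single event time: the weight is a constant, so it equals the log-rank
  a1 <- rec(c(5, 5, 7), c(1, 1, 0))
  b1 <- rec(c(5, 9), c(1, 0))
  expect_equal(gehan_wilcoxon_test(a1, b1)$statistic,
               logrank_test(a1, b1)$statistic)
})

test_that("without censoring the Gehan statistic tracks the Mann-Whitney discrepancy", {
  set.seed(51)
  stats_g <- numeric(30); stats_u <- numeric(30)
  for (i in 1:30) {
    shift <- runif(1, 0, 1.5)
    x <- rexp(15) ; y <- rexp(15) * exp(shift)
    g <- gehan_wilcoxon_test(rec(x, rep(1, 15)), rec(y, rep(1, 15)))
    u <- stats::wilcox.test(x, y)$statistic
    stats_g[i] <- g$statistic
    stats_u[i] <- abs(u - 15 * 15 / 2)
  }
  expect_gt(cor(stats_g, stats_u, method = "spearman"), 0.8)
})

test_that("the combined survival workflow stratifies, truncates and tests", {
  b <- get_cohort(101)
  fit <- survival_by_expression(b$expression, b$truth$survival_gene, b$clinical)
  expect_setequal(names(fit$curves), c("high", "rest"))
  expect_true(all(fit$curves$high$time <= 120))
  expect_lt(fit$logrank$p, 0.05)
  # the planted hazard ratio of 2 makes the expression-high group do worse
  expect_lt(glance(fit$curves$high)$median_survival,
            glance(fit$curves$rest)$median_survival)
  # tidiers return well-formed rows
  expect_equal(tidy(fit$logrank)$p.value, fit$logrank$p)
  expect_named(tidy(fit$curves$high),
               c("time", "n_risk", "n_event", "n_censor", "estimate"))
})
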