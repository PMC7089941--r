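test_that("fisher_exact matches hand enumeration and conventions", {
  # perfect symmetry
  expect_equal(fisher_exact(matrix(5, 2, 2))$p_value, 1.0)
  # full hypergeometric enumeration: 2*(1 + 100 + 2025)/184756
  expect_equal(fisher_exact(matrix(c(2, 8, 8, 2), 2))$p_value,
               2 * (1 + 100 + 2025) / 184756, tolerance = 1e-10)
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  expect_error(fisher_exact(matrix(1:3, 3, 1)), "2 x 2")
})

test_that("fisher_exact(2x2) equals the enumeration oracle on random tables", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    m <- matrix(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)), 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact(m)$p_value, fisher2x2_enum(m), tolerance = 1e-8)
  }
})

test_that("km_curve equals the hand product-limit estimator", {
  # times (1 event, 2 censored, 3 event): S(1) = 2/3, S(3) = 0
  r <- tibble::tibble(sample = c("a", "b", "c"), time = c(1, 2, 3),
                      event = c(1, 0, 1))
  k <- km_curve(r, horizon_months = Inf)
  expect_equal(k$survival[k$time == 1], 2 / 3)
  expect_equal(k$survival[k$time == 3], 0)

  # 4 distinct event times, no censoring: steps 0.75, 0.5, 0.25, 0
  r2 <- tibble::tibble(sample = letters[1:4], time = c(3, 1, 4, 2), event = 1)
  k2 <- km_curve(r2, horizon_months = Inf)
  expect_equal(k2$survival, c(0.75, 0.5, 0.25, 0))

  # no events: survival identically 1
  r3 <- tibble::tibble(sample = c("a", "b"), time = c(5, 9), event = 0)
  expect_true(all(km_curve(r3)$survival == 1))

  # KM with no censoring equals the empirical survival function
  set.seed(5)
  t4 <- round(rexp(40, 0.02), 3)
  r4 <- tibble::tibble(sample = paste0("s", 1:40), time = t4, event = 1)
  k4 <- km_curve(r4, horizon_months = Inf)
  emp <- sapply(k4$time, function(t) mean(t4 > t))
  expect_equal(k4$survival, emp)

  # agreement with the independent hand oracle under censoring
  set.seed(6)
  r5 <- tibble::tibble(sample = paste0("s", 1:30), time = round(rexp(30, 0.02), 2),
                       event = stats::rbinom(30, 1, 0.7))
  k5 <- km_curve(r5, horizon_months = Inf)
  o5 <- km_hand(r5$time, r5$event)
  expect_equal(k5$survival[k5$n_event > 0], o5$survival)

  expect_error(km_curve(r[0, ]), "no survival records")
})

test_that("km_curve horizon censors follow-up at 120 months", {
  r <- tibble::tibble(sample = c("a", "b"), time = c(100, 200), event = c(1, 1))
  k <- km_curve(r)  # default horizon 120
  expect_equal(max(k$time), 120)
  expect_equal(sum(k$n_event), 1)
  expect_equal(sum(k$n_censor), 1)
})

test_that("logrank matches the hand O-E/V oracle and its chi-square tail", {
  d <- toy_surv()
  lr <- logrank(d, horizon_months = Inf)
  expect_equal(lr$statistic, logrank_hand(d$time, d$event, d$group),
               tolerance = 1e-10)
  expect_equal(lr$df, 1)
  expect_equal(lr$p_value, pchisq(lr$statistic, 1, lower.tail = FALSE))

  # two identical copies of one group: statistic 0, p = 1
  dd <- dplyr::bind_rows(
    dplyr::mutate(d[d$group == "a", ], group = "g1", sample = paste0(sample, "x")),
    dplyr::mutate(d[d$group == "a", ], group = "g2", sample = paste0(sample, "y"))
  )
  lr0 <- logrank(dd, horizon_months = Inf)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  expect_error(logrank(dplyr::mutate(d, group = "one")), "2 groups")
})

test_that("pairwise log-rank adjusts over the pair family only", {
  set.seed(9)
  n <- 40
  d <- tibble::tibble(
    sample = paste0("s", 1:(3 * n)),
    group = rep(c("g1", "g2", "g3"), each = n),
    time = c(rexp(n, 0.02), rexp(n, 0.05), rexp(n, 0.12)),
    event = 1
  )
  pw <- pairwise_logrank_bh(d, horizon_months = Inf)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adj, bh_adjust(pw$p_value))
  expect_true(all(pw$p_adj >= pw$p_value))
  m <- as.matrix(pw)
  expect_true(isSymmetric(m))
  expect_true(all(is.na(diag(m))))
  expect_error(pairwise_logrank_bh(d[d$group != "g3", ]), "3 groups")
})

test_that("bh_adjust implements the step-up with clipping and stable ties", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # equality with the reference implementation on random vectors; adjusted
  # values preserve the rank order of the raw p-values and never shrink
  set.seed(10)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, method = "BH"))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in rank
    expect_true(all(adj >= p & adj <= 1))
  }
})

test_that("cox_fit matches a grid-search Efron partial likelihood at n = 8", {
  d <- toy_surv()
  fit <- cox_fit(d, covariates = "group", horizon_months = Inf)
  beta_hat <- log(tidy(fit)$hazard_ratio)
  x <- as.numeric(d$group == "b")
  beta_grid <- stats::optimize(function(b) efron_loglik(b, d$time, d$event, x),
                               c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
  expect_lt(abs(beta_hat - beta_grid), 1e-4)
})

test_that("cox_fit tidy/glance expose HR, CI95 and reference levels", {
  cohort <- gen_cohort(list(n = 120), seed = 21)
  rec <- dplyr::inner_join(cohort$clinical,
                           cohort$truth[, c("sample", "stratum_true")],
                           by = "sample")
  fit <- cox_fit(rec, covariates = c("stratum_true", "stage"),
                 reference_levels = list(stratum_true = "LST_high/non_Fibrosis"))
  td <- tidy(fit)
  expect_equal(nrow(td), 4)  # 3 stratum levels + 1 stage level
  expect_true(all(td$ci95_low <= td$hazard_ratio & td$hazard_ratio <= td$ci95_high))
  expect_equal(unique(td$reference_level[td$term == "stratum_true"]),
               "LST_high/non_Fibrosis")
  g <- glance(fit)
  expect_equal(g$n, nrow(rec))

  expect_error(cox_fit(rec, covariates = "nope"), "missing covariate")
  expect_error(cox_fit(dplyr::mutate(rec, stage = "III-IV"),
                       covariates = "stage"), "single level")
})

test_that("cox_fit is near-null for exchangeable groups", {
  set.seed(22)
  d <- tibble::tibble(sample = paste0("s", 1:2000),
                      time = rexp(2000, 0.02),
                      event = 1,
                      group = rep(c("a", "b"), 1000))
  td <- tidy(cox_fit(d, covariates = "group", horizon_months = Inf))
  expect_lt(abs(log(td$hazard_ratio)), 0.1)
  expect_true(td$ci95_low < 1 && td$ci95_high > 1)
})
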