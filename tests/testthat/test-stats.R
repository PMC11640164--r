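test_that("Mann-Whitney U and exact p match hand-derived small cases", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$u_statistic, 0)
  expect_equal(res$p_two_sided, 1 / 3, tolerance = 1e-12)
  expect_identical(res$method, "exact")

  # identical multisets: U = n^2/2, p = 1
  res2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$u_statistic, 9 / 2)
  expect_equal(res2$p_two_sided, 1)

  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
  expect_error(mann_whitney_u(c(1, NA), c(2, 3)), "finite")
})

test_that("label swap maps U to n_a*n_b - U with the same p", {
  set.seed(101)
  for (i in 1:25) {
    a <- round(rnorm(sample(2:7, 1)), 1)
    b <- round(rnorm(sample(2:7, 1)), 1)
    r1 <- mann_whitney_u(a, b)
    r2 <- mann_whitney_u(b, a)
    expect_equal(r1$u_statistic + r2$u_statistic, r1$n_a * r1$n_b)
    expect_equal(r1$p_two_sided, r2$p_two_sided, tolerance = 1e-12)
  }
})

test_that("exact p equals the enumeration oracle on random instances", {
  set.seed(7)
  for (i in 1:120) {
    n_a <- sample(1:8, 1)
    n_b <- sample(1:min(8, 10 - n_a), 1)
    # half the instances with heavy ties
    vals <- if (i %% 2 == 0) sample(1:3, n_a + n_b, replace = TRUE)
    else rnorm(n_a + n_b)
    a <- vals[seq_len(n_a)]
    b <- vals[-seq_len(n_a)]
    res <- mann_whitney_u(a, b)
    expect_equal(res$u_statistic, oracle_u(a, b), tolerance = 1e-12)
    expect_equal(res$p_two_sided, oracle_exact_p(a, b), tolerance = 1e-12)
  }
})

test_that("exact p agrees with wilcox.test when there are no ties", {
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1))
    res <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(res$u_statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_two_sided, ref$p.value, tolerance = 1e-10)
  }
})

test_that("normal approximation converges to the exact p", {
  # at n_a = n_b = 8 without ties both p-values are functions of U alone,
  # so the worst-case gap can be enumerated exactly: it is 0.0109 (at
  # U = 24), and the continuity correction is what keeps it that small
  set.seed(33)
  diffs <- replicate(60, {
    a <- rnorm(8)
    b <- rnorm(8)
    exact <- mann_whitney_u(a, b, exact_threshold = 8)$p_two_sided
    approx <- mann_whitney_u(a, b, exact_threshold = 0)$p_two_sided
    abs(exact - approx)
  })
  expect_lt(max(diffs), 0.011)
})

test_that("BH adjustment matches hand cases and the double-loop oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(5)
  for (i in 1:40) {
    p <- runif(sample(1:20, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
    # monotone in the order statistics
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("AUROC equals brute-force pair counting and is symmetric", {
  expect_equal(auroc(c(3, 5), c(1, 4)), 0.75)
  expect_equal(auroc(c(2, 3), c(0, 1)), 1)
  expect_equal(auroc(rep(1, 4), rep(1, 3)), 0.5)

  set.seed(13)
  for (i in 1:60) {
    pos <- sample(0:5, sample(1:12, 1), replace = TRUE) + rnorm(1)
    neg <- sample(0:5, sample(1:12, 1), replace = TRUE) + rnorm(1)
    expect_equal(auroc(pos, neg), oracle_auroc(pos, neg), tolerance = 1e-12)
    expect_equal(auroc(pos, neg) + auroc(neg, pos), 1, tolerance = 1e-12)
    # consistency with U
    expect_equal(
      auroc(pos, neg),
      mann_whitney_u(pos, neg)$u_statistic / (length(pos) * length(neg)),
      tolerance = 1e-12
    )
  }
})

test_that("Kaplan-Meier estimator reproduces hand-computed curves", {
  fit <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(fit$curve$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)

  fit2 <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(fit2$curve$survival[fit2$curve$time == 1], 2 / 3)
  expect_equal(fit2$curve$survival[fit2$curve$time == 3], 0)

  # no events: S == 1 everywhere
  fit3 <- km_fit(c(1, 5, 9), c(0, 0, 0))
  expect_true(all(fit3$curve$survival == 1))

  expect_error(km_fit(c(-1, 2), c(1, 1)), "non-negative")
  expect_error(km_fit(c(1, 2), c(1, 2)), "0 .*or 1")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(41)
  for (i in 1:20) {
    times <- round(rexp(sample(5:40, 1), 0.1), 1)
    fit <- km_fit(times, rep(1, length(times)))
    for (k in seq_len(nrow(fit$curve))) {
      expect_equal(
        fit$curve$survival[k],
        oracle_empirical_survival(times, fit$curve$time[k]),
        tolerance = 1e-12
      )
    }
  }
})

test_that("KM survival is non-increasing and matches survival::survfit", {
  set.seed(43)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    times <- round(rexp(n, 0.05), 1)
    events <- rbinom(n, 1, 0.7)
    if (sum(events) == 0) events[1] <- 1
    fit <- km_fit(times, events)
    expect_true(all(diff(fit$curve$survival) <= 1e-12))
    ref <- survival::survfit(survival::Surv(times, events) ~ 1)
    ref_s <- summary(ref, times = fit$curve$time)$surv
    expect_equal(fit$curve$survival, ref_s, tolerance = 1e-10)
  }
})

test_that("log-rank test matches the hand-tabulated worked example", {
  # A = {1, 2} events, B = {3, 4} events. O/E/V by hand:
  # t=1: n=4, nA=2, d=1 -> E=1/2, V=1/4
  # t=2: n=3, nA=1, d=1 -> E=1/3, V=2/9
  # t=3: n=2, nA=0, d=1 -> E=0, V=0; t=4: n=1 -> V=0
  # chi2 = (2 - 5/6)^2 / (17/36) = 49/17
  lr <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 5 / 6, tolerance = 1e-12)
  expect_equal(lr$chi2, 49 / 17, tolerance = 1e-12)
  expect_equal(lr$p, 2 * pnorm(-sqrt(49 / 17)), tolerance = 1e-12)
})

test_that("log-rank is symmetric, null on identical groups, and tracks survdiff", {
  t1 <- c(2, 4, 6, 8, 10)
  e1 <- c(1, 1, 0, 1, 1)
  lr_same <- logrank_test(t1, e1, t1, e1)
  expect_equal(lr_same$chi2, 0)
  expect_equal(lr_same$p, 1)

  set.seed(59)
  for (i in 1:10) {
    na <- sample(8:25, 1)
    nb <- sample(8:25, 1)
    ta <- round(rexp(na, 0.05), 2)
    tb <- round(rexp(nb, 0.08), 2)
    ea <- rbinom(na, 1, 0.8)
    eb <- rbinom(nb, 1, 0.8)
    if (sum(ea) == 0) ea[1] <- 1
    if (sum(eb) == 0) eb[1] <- 1
    f <- logrank_test(ta, ea, tb, eb)
    g <- logrank_test(tb, eb, ta, ea)
    expect_equal(f$chi2, g$chi2, tolerance = 1e-12)
    expect_equal(f$p, g$p, tolerance = 1e-12)
    grp <- c(rep(1, na), rep(2, nb))
    ref <- survival::survdiff(
      survival::Surv(c(ta, tb), c(ea, eb)) ~ grp
    )
    expect_equal(f$chi2, unname(ref$chisq), tolerance = 1e-9)
  }
})

test_that("median split labels high above the quantile, ties to low", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(5, 1, 3)), c("high", "low", "low"))
  expect_equal(median_split(rep(2, 5)), rep("low", 5))
  expect_error(median_split(1), "at least 2")
  expect_error(median_split(c(1, 2), prob = 1), "strictly between")
  # configurable quantile
  expect_equal(median_split(1:10, prob = 0.8), rep(c("low", "high"), c(8, 2)))
})

test_that("tidy methods return one-row/curve tibbles", {
  mw <- tidy(mann_whitney_u(c(1, 2), c(3, 4)))
  expect_s3_class(mw, "tbl_df")
  expect_named(mw, c("u_statistic", "p_value", "n_a", "n_b", "method"))

  km <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_named(tidy(km), c("time", "n_risk", "n_event", "n_censor", "survival"))
  expect_equal(glance(km)$n, 3)

  lr <- tidy(logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1)))
  expect_equal(lr$chi2, 49 / 17, tolerance = 1e-12)
})
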