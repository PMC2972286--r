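test_that("fit_cox maximizes the Breslow partial likelihood and matches coxph", {
  # tiny instance against the grid-search oracle
  t3 <- c(1, 2, 3); e3 <- c(1, 1, 1); x3 <- c(1, 0, 1)
  f <- fit_cox(t3, e3, cbind(x = x3))
  expect_lt(abs(f$coefficients[["x"]] - grid_cox_beta(t3, e3, x3)), 1e-3)

  # independent implementation cross-check on richer data
  set.seed(21)
  n <- 80
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  tt <- rexp(n, exp(0.5 * X[, 1] - 0.7 * X[, 2]))
  ev <- rbinom(n, 1, 0.75)
  f <- fit_cox(tt, ev, X)
  cf <- survival::coxph(survival::Surv(tt, ev) ~ X, ties = "breslow")
  expect_equal(unname(f$coefficients), unname(coef(cf)), tolerance = 1e-6)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(cf)))), tolerance = 1e-6)
  expect_equal(f$loglik, cf$loglik[2], tolerance = 1e-8)
  expect_true(all(f$wald_p >= 0 & f$wald_p <= 1))
})

test_that("fit_cox rejects degenerate inputs and flags separation", {
  expect_error(fit_cox(c(1, 2, 3), c(1, 1, 0), cbind(z = c(0, 0, 0))),
               "constant")
  expect_error(fit_cox(c(1, 2, 3), c(0, 0, 0), cbind(z = c(1, 0, 1))),
               "no events")
  # covariate perfectly ordered with event times: monotone likelihood
  tt <- 1:8
  x <- 8:1
  f <- fit_cox(tt, rep(1, 8), cbind(x = x))
  expect_false(f$converged)
  expect_lte(abs(f$coefficients[["x"]]), 15)
})

test_that("duplicating the dataset keeps the coefficient and shrinks se by sqrt(2)", {
  set.seed(5)
  n <- 40
  x <- rnorm(n)
  tt <- rexp(n, exp(0.6 * x))
  ev <- rbinom(n, 1, 0.8)
  f1 <- fit_cox(tt, ev, cbind(x = x))
  f2 <- fit_cox(c(tt, tt), c(ev, ev), cbind(x = c(x, x)))
  # Breslow ties: the stacked partial likelihood is the square of the
  # original (up to a constant), so the maximizer is unchanged
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-6)
  expect_equal(unname(f1$se / f2$se), sqrt(2), tolerance = 1e-6)
})

test_that("km_estimate reproduces the product-limit estimator", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))[[1]]
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 3], 0)
  # all censored: curve stays at 1
  km <- km_estimate(c(2, 4, 5), c(0, 0, 0))[[1]]
  expect_true(all(km$surv == 1))
  # single subject with an event
  km <- km_estimate(5, 1)[[1]]
  expect_equal(km$surv, 0)
  # no censoring: equals the empirical survival function
  set.seed(3)
  tt <- sort(runif(25))
  km <- km_estimate(tt, rep(1, 25))[[1]]
  expect_equal(km$surv, 1 - seq_len(25) / 25)
})

test_that("logrank_test matches the hand-computed O-E/V statistic", {
  # identical groups: perfect symmetry, statistic 0
  lr <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                     rep(c("a", "b"), each = 3))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-10)
  # group A events at 1,2; group B censored at 3,3
  # time 1: O=1 E=1/2 V=1/4; time 2: O=1 E=1/3 V=2/9
  # chi2 = (2 - 5/6)^2 / (1/4 + 2/9)
  lr <- logrank_test(c(1, 2, 3, 3), c(1, 1, 0, 0), c("A", "A", "B", "B"))
  expect_equal(lr$statistic, (2 - 5 / 6)^2 / (1 / 4 + 2 / 9),
               tolerance = 1e-10)
  expect_true(lr$p >= 0 && lr$p <= 1)
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "two groups")
})

test_that("log-rank p-values are uniform under permuted group labels", {
  set.seed(17)
  n <- 50
  s <- null_surv(n)
  p <- replicate(1000, {
    logrank_test(s$time, s$event, sample(rep(c("a", "b"), n / 2)))$p
  })
  expect_lt(unname(ks.test(p, "punif")$statistic), 0.05)
})

test_that("AIC/BIC values follow their definitions exactly", {
  set.seed(9)
  n <- 120
  clin <- data.frame(sample_id = sprintf("s%d", 1:n),
                     time = rexp(n, 0.2), event = rbinom(n, 1, 0.6),
                     x1 = rnorm(n), x2 = rnorm(n))
  for (cr in c("AIC", "BIC")) {
    m <- select_clinical_model(clin, c("x1", "x2"), criterion = cr)
    pen <- if (cr == "AIC") 2 * m$npar else m$npar * log(m$n_events)
    expect_equal(m$criterion_value, -2 * m$loglik + pen, tolerance = 1e-10)
  }
})

test_that("model search behaves: null variable dropped by BIC, AIC picks supersets", {
  set.seed(31)
  n <- 500
  # single null candidate: BIC should almost always prefer the empty model
  empty_wins <- replicate(50, {
    clin <- data.frame(sample_id = seq_len(n), time = rexp(n, 0.1),
                       event = rbinom(n, 1, 0.7), x = rnorm(n))
    length(select_clinical_model(clin, "x", criterion = "BIC")$variables) == 0
  })
  expect_gt(mean(empty_wins), 0.5)

  # one real signal among three candidates: AIC's pick contains BIC's
  superset <- replicate(50, {
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
    clin <- data.frame(sample_id = seq_len(n),
                       time = rexp(n, 0.1 * exp(0.5 * x1)),
                       event = rbinom(n, 1, 0.7),
                       x1 = x1, x2 = x2, x3 = x3)
    va <- select_clinical_model(clin, c("x1", "x2", "x3"), "AIC",
                                interactions = FALSE)$variables
    vb <- select_clinical_model(clin, c("x1", "x2", "x3"), "BIC",
                                interactions = FALSE)$variables
    all(vb %in% va)
  })
  expect_gte(mean(superset), 0.8)
})

test_that("a single candidate enumerates exactly empty vs singleton", {
  set.seed(12)
  n <- 200
  x <- rnorm(n)
  clin <- data.frame(sample_id = seq_len(n), time = rexp(n, 0.1 * exp(x)),
                     event = rep(1, n), x = x)
  m <- select_clinical_model(clin, "x", criterion = "AIC")
  expect_true(identical(m$variables, "x") || length(m$variables) == 0)
  # strong signal: the singleton must win
  expect_identical(m$variables, "x")
})
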