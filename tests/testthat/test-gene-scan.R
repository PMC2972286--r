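test_that("bh_fdr implements step-up rejection", {
  expect_identical(bh_fdr(c(0.01, 0.02, 0.5), q = 0.2),
                   c(TRUE, TRUE, FALSE))
  expect_identical(bh_fdr(rep(1, 10), q = 0.2), rep(FALSE, 10))
  expect_identical(bh_fdr(rep(0, 10), q = 0.2), rep(TRUE, 10))
  expect_identical(bh_fdr(numeric(0)), logical(0))
  expect_error(bh_fdr(c(0.1, 1.5)), "\\[0,1\\]")
})

test_that("null univariate scan gives standard-normal z and one row per gene", {
  spec <- simulation_spec(n_studies = 1, n_samples_per_study = 200,
                          n_genes = 1000, gene_overlap_fraction = 1,
                          n_pathways = 2, pathway_size_range = c(10, 10),
                          beta_er = 0, beta_size = 0, seed = 41)
  st <- generate_cohort(spec, generate_pathway_db(spec), 1)
  tb <- scan_genes(st, "univariate")
  expect_equal(nrow(tb), 1000)
  expect_lt(abs(mean(tb$z)), 0.1)
  expect_lt(abs(sd(tb$z) - 1), 0.1)
  # p-values approximately uniform downstream of the null generator
  expect_lt(unname(ks.test(tb$p, "punif")$statistic), 0.05)
})

test_that("a gene duplicating a model covariate is flagged with p = 1", {
  set.seed(13)
  n <- 60
  expr <- matrix(rnorm(3 * n), 3, n,
                 dimnames = list(c("g1", "g2", "gdup"), NULL))
  size <- rlnorm(n, log(2), 0.5)
  expr["gdup", ] <- size
  st <- make_study(expr, time = rexp(n, 0.2 * exp(0.3 * size)),
                   event = rbinom(n, 1, 0.8),
                   er = sample(c("positive", "negative"), n, TRUE),
                   size = size)
  tb <- scan_genes(st, "er_size")
  row <- tb[tb$gene_id == "gdup", ]
  expect_false(row$converged)
  expect_equal(row$p, 1)
  expect_equal(row$z, 0)
})

test_that("a strongly prognostic gene is recovered as rank 1", {
  set.seed(61)
  hits <- replicate(20, {
    n <- 150
    expr <- matrix(rnorm(500 * n), 500, n,
                   dimnames = list(sprintf("g%03d", 1:500), NULL))
    st <- make_study(expr, time = rexp(n, 0.1 * exp(1.5 * expr[1, ])),
                     event = rbinom(n, 1, 0.8))
    tb <- scan_genes(st, "univariate")
    tb$gene_id[which.min(tb$p)] == "g001"
  })
  expect_gte(mean(hits), 0.9)
})

test_that("the top gene is stable when null clinical covariates are added", {
  set.seed(77)
  changed <- replicate(20, {
    n <- 150
    expr <- matrix(rnorm(200 * n), 200, n,
                   dimnames = list(sprintf("g%03d", 1:200), NULL))
    st <- make_study(expr, time = rexp(n, 0.1 * exp(1.2 * expr[5, ])),
                     event = rbinom(n, 1, 0.8),
                     er = sample(c("positive", "negative"), n, TRUE),
                     size = rlnorm(n, log(2), 0.5))
    t1 <- scan_genes(st, "univariate")
    t2 <- scan_genes(st, "er_size")  # pure-noise covariates here
    t1$gene_id[which.min(t1$p)] != t2$gene_id[which.min(t2$p)]
  })
  expect_lte(mean(changed), 0.1)
})

test_that("er_size spec is skipped with a warning when covariates are missing", {
  set.seed(2)
  n <- 40
  expr <- matrix(rnorm(5 * n), 5, n,
                 dimnames = list(sprintf("g%d", 1:5), NULL))
  st <- make_study(expr, time = rexp(n, 0.2), event = rbinom(n, 1, 0.8))
  expect_warning(tb <- scan_genes(st, "er_size"), "unavailable")
  expect_null(tb)
})

test_that("count_significant summarizes per-spec counts with sane bounds", {
  spec <- simulation_spec(n_studies = 1, n_samples_per_study = 100,
                          n_genes = 60, gene_overlap_fraction = 1,
                          n_pathways = 2, pathway_size_range = c(10, 10),
                          beta_er = 0, beta_size = 0, seed = 55)
  st <- generate_cohort(spec, generate_pathway_db(spec), 1)
  tabs <- list(scan_genes(st, "univariate"), scan_genes(st, "er_size"))
  cnt <- count_significant(tabs)
  expect_identical(cnt$model_spec, c("univariate", "er_size"))
  expect_true(all(cnt$n_significant >= 0 & cnt$n_significant <= cnt$n_genes))
})

test_that("planted prognostic genes dominate the significant count", {
  set.seed(83)
  hits <- replicate(20, {
    n <- 200
    expr <- matrix(rnorm(1000 * n), 1000, n,
                   dimnames = list(sprintf("g%04d", 1:1000), NULL))
    a <- rnorm(n)  # latent risk factor carried by the 10 planted genes
    expr[1:10, ] <- expr[1:10, ] + rep(a, each = 10)
    st <- make_study(expr, time = rexp(n, 0.1 * exp(2 * a)),
                     event = rbinom(n, 1, 0.8))
    tb <- scan_genes(st, "univariate", q = 0.2)
    sum(tb$significant[1:10]) >= 8
  })
  expect_gte(mean(hits), 0.8)
})
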