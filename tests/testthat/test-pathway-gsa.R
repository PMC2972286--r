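test_that("maxmean follows its definition", {
  expect_equal(maxmean(c(0, 0, 0)), 0)
  expect_equal(maxmean(c(3, -1, -1, 0)), 0.75)  # s+ = 0.75 beats s- = 0.5
  expect_equal(maxmean(-2), -2)
  expect_error(maxmean(numeric(0)), "empty")
  # positive homogeneity
  set.seed(6)
  for (i in 1:20) {
    z <- rnorm(sample(3:30, 1))
    c0 <- runif(1, 0.1, 5)
    expect_equal(maxmean(c0 * z), c0 * maxmean(z), tolerance = 1e-12)
  }
})

test_that("pathway size filter is inclusive at both bounds", {
  genes <- sprintf("g%03d", 1:300)
  db <- pathway_db(list(a = genes[1:10], b = genes[1:15], c = genes[1:100],
                        d = genes[1:250], e = c(genes, sprintf("x%d", 1:50))))
  fdb <- filter_pathways(db, genes, 15, 250)
  expect_identical(names(fdb$pathways), c("b", "c", "d"))
  dropped <- attr(fdb, "dropped")
  expect_setequal(dropped$pathway, c("a", "e"))
  expect_equal(dropped$size[dropped$pathway == "a"], 10)
  expect_equal(dropped$size[dropped$pathway == "e"], 300)  # post-intersection
  # boundary: 14 dropped, 15 kept; 250 kept, 251 dropped
  db2 <- pathway_db(list(s14 = genes[1:14], s15 = genes[1:15],
                         s250 = genes[1:250], s251 = c(genes[1:250], "x1")))
  fdb2 <- filter_pathways(db2, c(genes, "x1"), 15, 250)
  expect_identical(names(fdb2$pathways), c("s15", "s250"))
})

test_that("generalized Sidak-Holm step-down matches hand-computed examples", {
  # u = 1 reduces to plain Sidak-Holm
  expect_identical(gfwer_sidak_holm(c(0.02, 0.9), alpha = 0.2, u = 1),
                   c(TRUE, FALSE))
  expect_lt(0.02, 1 - 0.8^(1 / 2))
  # m = 6, u = 2: c1 = c2 = 1-0.8^(1/3), c3 = 1-0.8^(2/5); stop at p(4)
  p <- c(0.05, 0.06, 0.07, 0.5, 0.6, 0.7)
  expect_identical(gfwer_sidak_holm(p, alpha = 0.2, u = 2),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(gfwer_sidak_holm(rep(1, 8), 0.2, 5), rep(FALSE, 8))
  expect_identical(gfwer_sidak_holm(numeric(0), 0.2, 5), logical(0))
})

test_that("step-down rejections are monotone in the p-values", {
  set.seed(14)
  for (i in 1:50) {
    p <- runif(sample(5:40, 1))
    base <- gfwer_sidak_holm(p, 0.2, 3)
    j <- sample(length(p), 1)
    p2 <- p; p2[j] <- p[j] * runif(1)
    lowered <- gfwer_sidak_holm(p2, 0.2, 3)
    expect_true(all(lowered[base]))  # old rejections survive
  }
})

test_that("adjusted gene scores: null calibration, collinearity, planted signal", {
  spec <- simulation_spec(n_studies = 1, n_samples_per_study = 200,
                          n_genes = 500, gene_overlap_fraction = 1,
                          n_pathways = 2, pathway_size_range = c(20, 20),
                          beta_er = 0, beta_size = 0, seed = 19)
  st <- generate_cohort(spec, generate_pathway_db(spec), 1)
  z <- adjusted_gene_scores(st)
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(sd(z) - 1), 0.1)

  # exact copy of a covariate -> flagged, neutral score
  st2 <- st
  st2$expression[1, ] <- st$clinical$tumor_size
  z2 <- adjusted_gene_scores(st2)
  expect_equal(unname(z2[1]), 0)
  expect_true(attr(z2, "flagged")[1])

  # planted pathway genes score above background
  spec3 <- simulation_spec(n_studies = 1, n_samples_per_study = 200,
                           n_genes = 300, gene_overlap_fraction = 1,
                           n_pathways = 5, pathway_size_range = c(20, 25),
                           enriched_pathway_ids = "pw001", beta_pathway = 1,
                           seed = 23)
  db3 <- generate_pathway_db(spec3)
  st3 <- generate_cohort(spec3, db3, 1)
  z3 <- adjusted_gene_scores(st3)
  members <- names(z3) %in% db3$pathways$pw001
  expect_lt(t.test(z3[members], z3[!members])$p.value, 1e-6)
  expect_gt(mean(z3[members]), mean(z3[!members]))
})

test_that("the restandardized statistic is exactly scale-invariant", {
  # maxmean is positively homogeneous, so rescaling every gene score by a
  # positive constant cancels exactly in (S - mu)/sigma
  set.seed(33)
  z <- rnorm(12)
  zr <- function(zz) {
    mo <- pathsurv:::.randomization_moments(zz, 4L, R = 0, exhaustive = TRUE)
    pathsurv:::.restandardize(maxmean_direct(zz[1:4]), 4L, mo)
  }
  for (c0 in c(0.2, 1.7, 10)) expect_equal(zr(c0 * z), zr(z), tolerance = 1e-10)
})

test_that("null pathways give calibrated permutation p-values", {
  spec <- simulation_spec(n_studies = 1, n_samples_per_study = 60,
                          n_genes = 150, gene_overlap_fraction = 1,
                          n_pathways = 50, pathway_size_range = c(15, 20),
                          beta_er = 0, beta_size = 0, seed = 47)
  db <- generate_pathway_db(spec)
  st <- generate_cohort(spec, db, 1)
  res <- restandardized_pathway_test(st, db,
                                     gsa_config(B = 200, R = 200, seed = 3))
  expect_true(all(res$p_perm >= 1 / 201 & res$p_perm <= 1))
  expect_lte(abs(mean(res$p_perm < 0.1) - 0.10), 0.06)
})

test_that("the planted enriched pathway is detected with a small p", {
  spec <- simulation_spec(n_studies = 1, n_samples_per_study = 200,
                          n_genes = 300, gene_overlap_fraction = 1,
                          n_pathways = 20, pathway_size_range = c(15, 40),
                          enriched_pathway_ids = "pw001", beta_pathway = 1,
                          seed = 11)
  db <- generate_pathway_db(spec)
  st <- generate_cohort(spec, db, 1)
  res <- restandardized_pathway_test(st, db,
                                     gsa_config(B = 200, R = 200, seed = 5))
  row <- res[res$pathway == "pw001", ]
  expect_lte(row$p_perm, 0.05)
  expect_true(row$gfwer_reject)
})

test_that("gsa_config guards B and the test refuses tiny B without override", {
  expect_error(gsa_config(B = 50), "B < 100")
  expect_s3_class(gsa_config(B = 50, allow_small_B = TRUE), "gsa_config")
  expect_error(gsa_config(min_set = 10, max_set = 5), "min_set")
  expect_error(gsa_config(u = 0), "u must be")
})

test_that("gsa results are deterministic given the config seed", {
  spec <- simulation_spec(n_studies = 1, n_samples_per_study = 50,
                          n_genes = 60, gene_overlap_fraction = 1,
                          n_pathways = 4, pathway_size_range = c(10, 15),
                          seed = 71)
  db <- generate_pathway_db(spec)
  st <- generate_cohort(spec, db, 1)
  cfg <- gsa_config(B = 100, R = 100, min_set = 5, max_set = 50, seed = 9)
  expect_identical(restandardized_pathway_test(st, db, cfg),
                   restandardized_pathway_test(st, db, cfg))
})
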