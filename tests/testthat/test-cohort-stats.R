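test_that("normality screen verdicts match the distributions drawn", {
  set.seed(31)
  nrm <- rnorm(200); expn <- rexp(200)
  expect_identical(assess_normality(list(g = nrm))$verdict, "normal")
  expect_identical(assess_normality(list(g = expn))$verdict, "non-normal")
  # one bad group spoils the joint verdict
  expect_identical(assess_normality(list(a = nrm, b = expn))$verdict,
                   "non-normal")
  # degenerate inputs are untestable, not errors
  expect_identical(assess_normality(list(g = c(5, 5, 5, 5)))$verdict,
                   "untestable")
  expect_identical(assess_normality(list(g = c(1, 2)))$verdict, "untestable")
  # Q-Q coordinates are sorted sample values against normal quantiles
  rep <- assess_normality(list(g = nrm))
  expect_identical(rep$qq$g$sample, sort(nrm))
  expect_equal(rep$qq$g$theoretical, qnorm(ppoints(200)))
})

test_that("Mann-Whitney branch reproduces the exact enumeration", {
  r <- compare_two_groups(c(1, 2, 3), c(4, 5, 6), test = "mann_whitney")
  expect_identical(r$statistic, 0)
  expect_identical(r$p_value, 0.1)
  expect_identical(r$direction, "down")
  # full-permutation oracle over random small samples without ties
  set.seed(17)
  for (i in 1:20) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    v <- sample(seq_len(40), m + n)  # distinct values, no ties
    x <- v[seq_len(m)]; y <- v[-seq_len(m)]
    got <- compare_two_groups(x, y, test = "mann_whitney")
    expect_equal(got$p_value, mw_exact_enum(x, y), tolerance = 1e-12)
  }
})

test_that("identical groups give p = 1 and no direction", {
  r <- compare_two_groups(c(1, 2, 3), c(1, 2, 3), test = "mann_whitney")
  expect_identical(r$direction, "none")
  expect_equal(r$p_value, 1)
  r2 <- compare_two_groups(c(2, 2, 2), c(2, 2, 2))
  expect_identical(r2$p_value, 1)
  expect_identical(r2$direction, "none")
  expect_error(compare_two_groups(1, c(1, 2)), "at least 2")
})

test_that("the normality gate routes to t-test or Mann-Whitney", {
  set.seed(5)
  x <- rnorm(30); y <- rnorm(30)
  expect_identical(compare_two_groups(x, y)$test_used, "t_test")
  xs <- rexp(200); ys <- rexp(200)
  expect_identical(compare_two_groups(xs, ys)$test_used, "mann_whitney")
})

test_that("chi-square matches the direct formula oracle", {
  expect_identical(chi_square_contingency(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  set.seed(23)
  for (i in 1:10) {
    counts <- matrix(sample(5:60, 6), 2, 3)
    got <- chi_square_contingency(counts)
    e <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    expect_equal(got$statistic, sum((counts - e)^2 / e), tolerance = 1e-10)
    expect_equal(got$df, 2)
  }
  expect_error(chi_square_contingency(matrix(c(0, 0, 3, 4), 2)),
               "marginal")
  expect_error(chi_square_contingency(matrix(c(-1, 2, 3, 4), 2)),
               "non-negative")
})

test_that("Kruskal-Wallis matches hand computation and formula oracle", {
  expect_equal(kruskal_wallis(list(c(1, 2), c(3, 4)))$statistic, 2.4)
  r <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$statistic, 0)
  all_same <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_identical(all_same$statistic, 0)
  expect_identical(all_same$p_value, 1)
  set.seed(29)
  for (i in 1:10) {
    g <- lapply(1:3, function(j) sample(1:10, sample(3:8, 1), replace = TRUE))
    got <- kruskal_wallis(g)
    expect_equal(got$statistic, kw_formula(g), tolerance = 1e-10)
  }
})

test_that("covariate adjustment leaves orthogonal outcomes untouched", {
  tab <- tiny_table(matrix(c(1, 2, 3), 3), rep("HC", 3),
                    analytes = "C16:0")
  tab$age <- c(0, 1, 0)
  r <- adjust_for_covariates(tab, "age", "C16:0")
  expect_equal(unname(r$adjusted), c(1, 2, 3))
})

test_that("a perfectly explained outcome adjusts to the pooled mean", {
  tab <- tiny_table(matrix(c(10, 20, 30, 40), 4), rep("HC", 4),
                    analytes = "C16:0")
  tab$age <- c(1, 2, 3, 4)
  r <- adjust_for_covariates(tab, "age", "C16:0")
  expect_equal(unname(r$adjusted), rep(25, 4))
})

test_that("rank-deficient designs fail naming the collinear column", {
  tab <- tiny_table(matrix(1:4, 4), rep("HC", 4), analytes = "C16:0")
  tab$age <- c(1, 2, 3, 4)
  tab$education_years <- 2 * tab$age
  expect_error(adjust_for_covariates(tab, c("age", "education_years"),
                                     "C16:0"),
               "collinear.*education_years")
})

test_that("adjustment is invariant to affine rescaling of covariates", {
  set.seed(41)
  tab <- tiny_table(matrix(rlnorm(20, 2, 0.4), 20), rep(c("HC", "MDD"), 10),
                    analytes = "C16:0")
  tab$age <- rnorm(20, 15, 2)
  a1 <- adjust_for_covariates(tab, "age", "C16:0")$adjusted
  tab$age <- 100 * tab$age - 7
  a2 <- adjust_for_covariates(tab, "age", "C16:0")$adjusted
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("a known simulated sex effect is recovered by the adjustment", {
  beta <- 0.4  # additive effect on log concentration for females
  panel <- ffa_panel()[11, ]  # a high-abundance analyte, log values stay > 0
  cfg <- sim_config(panel, 150, 150,
                    covariate_model = .default_covariate_model(),
                    covariate_effects = matrix(beta, 1, 1,
                                               dimnames = list(NULL, "sex")),
                    seed = 77L)
  tab <- simulate_cohort(cfg, c("HC", "MDD"))
  a <- analyte_names(tab)[1]
  tab[[a]] <- log(tab[[a]])
  r <- adjust_for_covariates(tab, "sex", a)
  fit <- lm(tab[[a]] ~ factor(tab$sex))
  se <- summary(fit)$coefficients[2, 2]
  # male coefficient estimates -beta (female is the simulated +beta level)
  expect_lt(abs(unname(r$coefficients["sexmale"]) + beta), 3 * se)
})

test_that("sucrose preference follows its defining formula", {
  expect_equal(sucrose_preference(3, 1), 75)
  expect_equal(sucrose_preference(2, 2), 50)
  expect_equal(sucrose_preference(0, 5), 0)
  expect_equal(sucrose_preference(c(3, 1), c(1, 3)), c(75, 25))
  expect_error(sucrose_preference(0, 0), "zero")
  expect_error(sucrose_preference(-1, 2), "non-negative")
})

test_that("published marginals are checked against cell counts", {
  counts <- matrix(c(55, 22, 32, 94), 2,
                   dimnames = list(c("HC", "alMDD"), c("male", "female")))
  expect_warning(ok <- check_count_consistency(counts, c(88, 116)),
                 "HC")
  expect_false(ok)
  counts[1, 2] <- 33
  expect_silent(expect_true(check_count_consistency(counts, c(88, 116))))
})

test_that("one-way ANOVA wrapper agrees with the F formula on 2 groups", {
  set.seed(3)
  x <- rnorm(10); y <- rnorm(10, 1)
  r <- one_way_anova(list(x, y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
})
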