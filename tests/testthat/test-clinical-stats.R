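test_that("cumulative wetting length sums both eyes within bounds", {
  expect_equal(cumulative_wetting(10, 20), 30)
  expect_equal(cumulative_wetting(0, 0), 0)
  expect_equal(cumulative_wetting(35, 35), 70)
  expect_error(cumulative_wetting(-1, 5), "\\[0, 35\\]")
  expect_error(cumulative_wetting(10, 36), "\\[0, 35\\]")
})

test_that("pearson_r matches the covariance-sum formula", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  set.seed(1)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  n <- 50
  r_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(pearson_r(x, y), r_oracle, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("Fisher-z CIs reproduce cor.test and behave correctly", {
  # cross-check against the independent implementation in cor.test
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.4 * x
    ct <- cor.test(x, y)
    ci <- fisher_ci_from_summary(unname(ct$estimate), n)
    expect_equal(unname(ci), as.numeric(ct$conf.int), tolerance = 1e-10)
  }
  # symmetry about 0 and antisymmetry in the sign of r
  ci0 <- fisher_ci_from_summary(0, 20)
  expect_equal(ci0[["ci_low"]], -ci0[["ci_high"]])
  cip <- fisher_ci_from_summary(0.5, 20)
  cin <- fisher_ci_from_summary(-0.5, 20)
  expect_equal(unname(cip), -rev(unname(cin)))
  # bounds strictly inside (-1, 1); width shrinks with n
  expect_true(all(abs(fisher_ci_from_summary(0.99, 5)) < 1))
  w <- function(n) diff(fisher_ci_from_summary(0.6, n))
  expect_true(w(10) > w(50))
  expect_error(fisher_ci_from_summary(1, 10), "inside")
  expect_error(fisher_ci_from_summary(0.5, 3), "at least 4")
})

test_that("correlation p-values follow the t reference distribution", {
  expect_equal(pearson_p(0, 10), 1)
  expect_equal(pearson_p(0.5, 20), pearson_p(-0.5, 20))
  # independent t-CDF route
  r <- 0.91; n <- 7
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(pearson_p(r, n), 2 * (1 - pt(t, n - 2)), tolerance = 1e-12)
  expect_equal(round(pearson_p(0.91, 7), 3), 0.004)
  set.seed(4)
  x <- rnorm(30); y <- rnorm(30) + x
  expect_equal(correlate(x, y)$p, cor.test(x, y)$p.value,
               tolerance = 1e-10)
})

test_that("linear model recovers exact and simulated coefficients", {
  x <- 1:10
  fit <- suppressWarnings( # exact fit: lm warns about perfect residuals
    fit_linear_model(y ~ x, data.frame(x = x, y = 2 * x + 3)))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "x"], 2, tolerance = 1e-10)
  expect_equal(co$estimate[co$term == "(Intercept)"], 3, tolerance = 1e-10)
  expect_lt(fit$sigma, 1e-10)

  # seeded simulation vs the normal-equations oracle
  set.seed(5)
  grp <- factor(rep(c("control", "PD"), each = 30))
  age <- rnorm(60, 70, 8)
  y <- 40 - 12 * (grp == "PD") + 0.1 * age + rnorm(60, 0, 5)
  fit <- fit_linear_model(y ~ grp + age, data.frame(y, grp, age))
  X <- cbind(1, grp == "PD", age)
  beta <- oracle_ols(X, y)
  expect_equal(fit$coefficients$estimate, unname(beta), tolerance = 1e-10)
  expect_error(
    fit_linear_model(y ~ x1 + x2, data.frame(y = 1:5, x1 = 1:5, x2 = 2:6)),
    "singular")
})

test_that("group coefficient CIs cover a planted wetting-length deficit", {
  # planted PD deficit of -10 mm at n = 500 per group; t-based CIs should
  # cover the truth in at least 93 of 100 seeded runs
  covered <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    n <- 500
    grp <- factor(rep(c("control", "PD"), each = n))
    age <- rnorm(2 * n, 70, 8)
    sex <- factor(sample(c("F", "M"), 2 * n, replace = TRUE))
    y <- 35 - 10 * (grp == "PD") - 0.2 * age + rnorm(2 * n, 0, 15)
    fit <- fit_linear_model(y ~ grp + age + sex,
                            data.frame(y, grp, age, sex))
    co <- fit$coefficients[fit$coefficients$term == "grpPD", ]
    covered <- covered + (co$ci_low <= -10 && -10 <= co$ci_high)
  }
  expect_gte(covered, 93)
})

test_that("one-way ANOVA matches the two-group t-test identity", {
  set.seed(6)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  res <- one_way_anova(c(x, y), rep(c("a", "b"), c(12, 15)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  # identical constant groups: no variance anywhere -> F = 0, p = 1
  res0 <- one_way_anova(rep(5, 20), rep(c("a", "b"), 10))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  expect_error(one_way_anova(1:5, c("a", "a", "a", "a", "b")), "n >= 2")
})

test_that("ANOVA type-I error is calibrated under the null", {
  set.seed(8)
  hits <- 0
  n_sim <- 2000
  g <- rep(c("a", "b", "c", "d"), each = 10)
  for (i in seq_len(n_sim)) {
    p <- one_way_anova(rnorm(40), g)$p
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / n_sim, 0.035)
  expect_lt(hits / n_sim, 0.065)
})

test_that("Tukey post hoc handles unequal group sizes", {
  set.seed(9)
  vals <- c(rnorm(10, 0), rnorm(29, 2), rnorm(7, 0), rnorm(10, 0))
  grp <- rep(c("control", "PD", "MSA", "PSP"), c(10, 29, 7, 10))
  res <- one_way_anova(vals, grp)
  expect_equal(nrow(res$pairwise), 6)
  expect_true(all(res$pairwise$p_adj >= 0 & res$pairwise$p_adj <= 1))
  pd_ctrl <- res$pairwise[
    (res$pairwise$group_i == "PD" & res$pairwise$group_j == "control") |
    (res$pairwise$group_i == "control" & res$pairwise$group_j == "PD"), ]
  expect_lt(pd_ctrl$p_adj, 0.01)
})

test_that("Freeman-Halton enumeration matches known and oracle values", {
  # 3 tables share the margins of [[2,0],[0,2]]; two have prob 1/6
  res <- fisher_exact_rxc(matrix(c(2, 0, 0, 2), 2))
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  expect_identical(res$method, "enumeration")
  # identical rows: independence exactly holds
  expect_equal(fisher_exact_rxc(matrix(c(3, 3, 2, 2), 2))$p, 1,
               tolerance = 1e-12)
  # any 2x2 equals the classic hypergeometric two-sided formulation
  set.seed(10)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 4) + 1, 2)
    expect_equal(fisher_exact_rxc(tab)$p, oracle_fisher_2x2(tab),
                 tolerance = 1e-10)
    # and base R's fisher.test as a second, independent implementation
    expect_equal(fisher_exact_rxc(tab)$p, fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
  # r x c case against fisher.test's network algorithm
  set.seed(11)
  for (i in 1:5) {
    tab <- matrix(rpois(8, 3) + 1, 2, 4)
    expect_equal(fisher_exact_rxc(tab)$p, fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("Monte Carlo fallback agrees with enumeration within 3 SE", {
  tab <- matrix(c(5, 3, 4, 6, 2, 7), 2, 3)
  exact <- fisher_exact_rxc(tab)
  expect_identical(exact$method, "enumeration")
  set.seed(12)
  mc <- fisher_exact_rxc(tab, max_tables = 3, mc_samples = 20000)
  expect_identical(mc$method, "monte carlo")
  expect_lt(abs(mc$p - exact$p), 3 * mc$se)
  expect_error(fisher_exact_rxc(matrix(c(1, -1, 2, 3), 2)), "non-negative")
})

test_that("the clinical battery runs end to end on a synthetic cohort", {
  clin <- generate_cohort(cohort_config(seed = 21))
  stats <- clinical_stats_battery(clin)
  expect_true(all(c("conc_vs_wl_overall", "conc_vs_wl_PD", "wl_regression",
                    "anova_age", "exact_sex") %in% names(stats)))
  ov <- stats$conc_vs_wl_overall
  expect_s3_class(ov, "correlation_result")
  expect_equal(ov$n, 56)
  expect_true(ov$ci_low <= ov$r && ov$r <= ov$ci_high)
  # duration analyses exclude controls
  expect_equal(stats$anova_duration$n, 46)
  expect_false("conc_vs_duration_control" %in% names(stats))
  # missing anticholinergic flags drop out pairwise
  expect_lte(stats$exact_anticholinergic$n, 56)
  # round trip through stats.json
  path <- tempfile(fileext = ".json")
  write_clinical_stats(stats, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$conc_vs_wl_overall$n, 56)
})
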