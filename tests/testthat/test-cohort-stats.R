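test_that("median/IQR descriptives follow the declared percentile rule", {
  d <- describe_median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(d$median, 3); expect_equal(d$q25, 2); expect_equal(d$q75, 4)
  d1 <- describe_median_iqr(5)
  expect_equal(d1$median, 5); expect_equal(d1$q25, 5); expect_equal(d1$q75, 5)
  expect_equal(describe_median_iqr(c(1, 2, 3, 4))$median, 2.5)
  expect_error(describe_median_iqr(numeric(0)), "nonempty")
})

test_that("Mann-Whitney exact branch: known small cases", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3)     # 2/6 assignments in the lower tail, doubled
  expect_equal(r$statistic, 0)
  # identical multisets -> perfect overlap, p = 1
  expect_equal(mann_whitney(c(5, 5, 7), c(5, 7, 5))$p_value, 1)
  # exact branch agrees with wilcox.test on tie-free data
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(sample(2:5, 1)); y <- rnorm(sample(2:5, 1))
    expect_equal(mann_whitney(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact branch equals brute-force enumeration with ties", {
  set.seed(31)
  for (i in 1:60) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    vals <- sample(1:4, nx + ny, replace = TRUE)   # heavy ties
    x <- vals[seq_len(nx)]; y <- vals[nx + seq_len(ny)]
    expect_equal(mann_whitney(x, y)$p_value, mw_enumeration_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney large-sample branch: tie-corrected normal approximation", {
  set.seed(41)
  x <- rnorm(200); y <- rnorm(200, 1)
  expect_lt(mann_whitney(x, y)$p_value, 0.001)
  # matches the reference implementation without continuity correction
  xr <- round(rnorm(30), 1); yr <- round(rnorm(25, 0.3), 1)   # some ties
  expect_equal(mann_whitney(xr, yr)$p_value,
               suppressWarnings(wilcox.test(xr, yr, exact = FALSE,
                                            correct = FALSE)$p.value),
               tolerance = 1e-10)
})

test_that("Fisher's exact test matches the hypergeometric enumeration oracle", {
  set.seed(51)
  for (i in 1:80) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, fisher_enumeration_oracle(tab),
                 tolerance = 1e-9)
  }
  expect_warning(r0 <- fisher_exact(matrix(c(0, 5, 0, 7), 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(r0$p_value, 1)
  expect_error(fisher_exact(matrix(c(1, 2, 3), 1)), "2x2")
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("group comparison dispatches by type and handles degenerate variables", {
  co <- generate_cohort(cohort_spec(300, seed = 8))
  tab <- compare_groups(co, "functional_independence",
                        c(age = "continuous", platelet_inhibitor = "binary"))
  expect_equal(tab$test, c("Mann-Whitney U", "Fisher's exact"))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_match(tab$p_display[1], "^0\\.\\d{3}$")

  co$const <- 5
  expect_equal(compare_groups(co, "functional_independence",
                              c(const = "continuous"))$p_value, 1)
  co$multi <- sample(c("a", "b", "c"), nrow(co), replace = TRUE)
  expect_error(compare_groups(co, "functional_independence",
                              c(multi = "binary")), "two-level")
  expect_error(compare_groups(co, "functional_independence",
                              c(age = "ordinal")), "unknown variable type")
  co$all_true <- TRUE
  expect_error(compare_groups(co, "all_true", c(age = "continuous")),
               "nonempty")
})

test_that("null grouping yields approximately uniform p-values", {
  co <- generate_cohort(cohort_spec(200, seed = 13))
  set.seed(61)
  ps <- replicate(60, {
    co$fake <- sample(co$functional_independence)   # permuted labels
    compare_groups(co, "fake", c(age = "continuous"))$p_value
  })
  expect_lt(mean(ps < 0.05), 0.20)     # near-nominal false positives
  expect_gt(mean(ps), 0.30)            # not collapsed toward 0
})

test_that("stepwise with open thresholds reduces to the full-model fit", {
  co <- generate_cohort(cohort_spec(500, seed = 23))
  cands <- c("percent_cbf_difference", "infarct_volume_ml", "age")
  res <- stepwise_logistic(co, cands, "functional_independence",
                           entry_p = 1, removal_p = 1)
  expect_setequal(res$selected$variable, cands)
  full <- glm(functional_independence ~ percent_cbf_difference +
                infarct_volume_ml + age, data = co, family = binomial())
  expect_equal(sort(coef(res$fit)), sort(coef(full)), tolerance = 1e-6)
})

test_that("a single candidate matches the direct one-variable fit", {
  co <- generate_cohort(cohort_spec(500, seed = 29))
  res <- stepwise_logistic(co, "pre_stroke_mrs", "functional_independence")
  direct <- glm(functional_independence ~ pre_stroke_mrs, data = co,
                family = binomial())
  expect_equal(res$selected$coefficient,
               unname(coef(direct)["pre_stroke_mrs"]), tolerance = 1e-8)
  expect_equal(res$selected$or, exp(res$selected$coefficient))
  expect_true(res$selected$ci_low <= res$selected$or &
                res$selected$or <= res$selected$ci_high)
})

test_that("perfect separation raises a diagnostic error naming the variable", {
  d <- data.frame(y = rep(c(FALSE, TRUE), each = 25),
                  sep = c(rnorm(25, -5), rnorm(25, 5)))
  expect_error(stepwise_logistic(d, "sep", "y"), "separation.*sep")
})

test_that("the fitted log-likelihood gradient vanishes at the optimum", {
  co <- generate_cohort(cohort_spec(800, seed = 31))
  res <- stepwise_logistic(co, c("percent_cbf_difference", "infarct_volume_ml",
                                 "pre_stroke_mrs"), "functional_independence",
                           entry_p = 1, removal_p = 1)
  X <- model.matrix(res$fit)
  grad <- t(X) %*% (res$fit$y - fitted(res$fit))
  expect_lt(max(abs(grad)), 1e-6)
})

test_that("the odds-ratio table carries no OR for removed variables", {
  co <- generate_cohort(cohort_spec(1500, seed = 37))
  res <- stepwise_logistic(co, c("pre_stroke_mrs", "age", "nihss_admission"),
                           "functional_independence")
  tab <- odds_ratio_table(res)
  expect_true(all(is.na(tab$or[!tab$selected])))
  expect_true(all(!is.na(tab$p_value)))         # removed rows keep a p-value
  expect_true(all(is.finite(tab$or[tab$selected])))
  expect_equal(nrow(tab), 3)
  expect_equal(res$path$action[1], "enter")
})
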