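test_that("group comparisons run the named two-sided tests", {
  # balanced 2x2 table: no association, statistic 0, p = 1
  d <- data.frame(group = rep(c("asymptomatic", "ms"), each = 20),
                  flag = rep(c(TRUE, FALSE), 20))
  gc <- group_compare(d, "flag", kind = "chi2")
  expect_equal(gc$statistic, 0)
  expect_equal(gc$p.value, 1)

  # rank-sum on fully separated small groups: exact two-sided p = 2/20
  d2 <- data.frame(group = rep(c("a", "b"), each = 3), x = c(1, 2, 3, 4, 5, 6))
  gc2 <- group_compare(d2, "x", kind = "ranksum")
  expect_equal(gc2$p.value, 0.1)

  # t test recovers a large shift
  set.seed(4)
  d3 <- data.frame(group = rep(c("a", "b"), each = 50),
                   x = c(rnorm(50), rnorm(50, 3)))
  expect_lt(group_compare(d3, "x", kind = "t")$p.value, 1e-10)

  expect_error(group_compare(data.frame(group = "a", x = 1), "x", "t"),
               "two non-empty groups")
})

test_that("null group comparisons are calibrated", {
  set.seed(12)
  ps <- replicate(120, {
    d <- data.frame(group = rep(c("a", "b"), each = 30), x = rnorm(60))
    group_compare(d, "x", kind = "ranksum")$p.value
  })
  # the rank-sum statistic is discrete, so repeated p-values tie in ks.test
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("adjusted regression reports the exposure coefficient and errors on bad designs", {
  sim <- generate_cohort(preset_params("strong-effect", n = 250, seed = 31),
                         keep_networks = FALSE)
  tab <- sim$cohort
  r <- adjusted_regression(tab, "percent_no_doctor")
  fit <- stats::lm(msrs_total ~ percent_no_doctor + age + male + married +
                     education, data = tab)
  co <- summary(fit)$coefficients["percent_no_doctor", ]
  expect_equal(r$beta, unname(co[1]))
  expect_equal(r$se, unname(co[2]))
  expect_equal(r$p.value, unname(co[4]))
  expect_equal(r$n, nrow(stats::model.frame(fit)))

  tab$copy_of_age <- tab$age
  expect_error(adjusted_regression(tab, "copy_of_age"), "collinear")
  tab$const <- 1
  expect_error(adjusted_regression(tab, "const"), "no variance")
  expect_error(adjusted_regression(tab, "not_a_column"), "lacks column")
})

test_that("null regressions give uniform p-values across seeds", {
  ps <- vapply(1:150, function(s) {
    x <- generate_cohort(preset_params("null", n = 250, seed = 5000 + s),
                         keep_networks = FALSE)
    adjusted_regression(x$cohort, "percent_negative_influence")$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  # monotone non-decreasing on sorted input
  set.seed(6)
  p <- sort(runif(20))
  expect_true(all(diff(bh_fdr(p)) >= 0))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("Fisher combination matches its closed form and is additive", {
  expect_equal(fisher_combine(c(1, 1, 1)), 0)
  expect_equal(fisher_combine(c(0.05, 0.05)), -4 * log(0.05))
  expect_equal(fisher_combine(exp(-1)), 2)
  a <- c(0.1, 0.4); b <- c(0.03, 0.9, 0.5)
  expect_equal(fisher_combine(c(a, b)),
               fisher_combine(a) + fisher_combine(b))
  expect_warning(fl <- fisher_combine(c(0.5, 0)), "clamped")
  expect_equal(fl, -2 * (log(0.5) + log(1e-300)))
})

test_that("Spearman sensitivity matches the rank formula", {
  d <- data.frame(x = c(1, 2, 3), msrs_total = c(2, 1, 3))
  expect_equal(spearman_sensitivity(d, "x")$rho, 0.5)
  d2 <- data.frame(x = 1:10, msrs_total = (1:10)^3)
  expect_equal(spearman_sensitivity(d2, "x")$rho, 1)
  d3 <- data.frame(x = 1:10, msrs_total = -(1:10))
  expect_equal(spearman_sensitivity(d3, "x")$rho, -1)
  expect_warning(
    r <- spearman_sensitivity(data.frame(x = rep(1, 5), msrs_total = 1:5),
                              "x"), "constant")
  expect_true(is.na(r$rho))
})

test_that("the association table adjusts within category batches", {
  sim <- generate_cohort(preset_params("paper-like", n = 300, seed = 8),
                         keep_networks = FALSE)
  tab <- association_table(sim$cohort)
  expect_equal(nrow(tab), 19L)
  expect_equal(sum(tab$category == "structure"), 6L)
  expect_equal(sum(tab$category == "composition"), 13L)
  for (cat in c("structure", "composition")) {
    sub <- tab[tab$category == cat, ]
    expect_equal(sub$fdr, bh_fdr(sub$p.value))
    expect_true(all(sub$fdr >= sub$p.value))
  }
})
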