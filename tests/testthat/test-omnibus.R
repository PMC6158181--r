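test_that("the omnibus test is deterministic and its statistic matches Fisher", {
  sim <- generate_cohort(preset_params("paper-like", n = 200, seed = 14),
                         keep_networks = FALSE)
  om1 <- omnibus_permutation_test(sim$cohort, COMPOSITION_VARS,
                                  n_perm = 300, seed = 9,
                                  category = "composition")
  om2 <- omnibus_permutation_test(sim$cohort, COMPOSITION_VARS,
                                  n_perm = 300, seed = 9,
                                  category = "composition")
  expect_equal(om1, om2)
  expect_equal(om1$observed_stat, fisher_combine(om1$observed_p))
  expect_equal(dim(om1$perm_pvalues), c(300L, 13L))
  expect_equal(om1$seed, 9L)

  # per-variable observed p equals the standalone regression p
  r <- adjusted_regression(sim$cohort, "percent_kin")
  expect_equal(unname(om1$observed_p["percent_kin"]), r$p.value)

  # corrected rule never returns zero and dominates the plain rule
  expect_gt(om1$empirical_p_corrected, 0)
  expect_gte(om1$empirical_p_corrected,
             om1$empirical_p * om1$n_perm / (om1$n_perm + 1))
})

test_that("an observed statistic above every permutation gives empirical p 0", {
  # strong injected effects at moderate n make the observed statistic extreme
  sim <- generate_cohort(preset_params("strong-effect", n = 500, seed = 23),
                         keep_networks = FALSE)
  om <- omnibus_permutation_test(sim$cohort, COMPOSITION_VARS,
                                 n_perm = 200, seed = 4,
                                 category = "composition")
  expect_true(all(om$perm_stats < om$observed_stat))
  expect_equal(om$empirical_p, 0)
  expect_equal(om$empirical_p_corrected, 1 / 201)
  expect_output(print(om), "< 0.005")
})

test_that("omnibus JSON serialisation is byte-identical under a fixed seed", {
  sim <- generate_cohort(preset_params("paper-like", n = 150, seed = 2),
                         keep_networks = FALSE)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_omnibus(omnibus_permutation_test(sim$cohort, STRUCTURE_VARS,
                                         n_perm = 200, seed = 77,
                                         category = "structure"), f1)
  write_omnibus(omnibus_permutation_test(sim$cohort, STRUCTURE_VARS,
                                         n_perm = 200, seed = 77,
                                         category = "structure"), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("QQ envelopes are ordered, monotone and anchored to order-statistic medians", {
  sim <- generate_cohort(preset_params("null", n = 200, seed = 19),
                         keep_networks = FALSE)
  om <- omnibus_permutation_test(sim$cohort, COMPOSITION_VARS,
                                 n_perm = 400, seed = 3,
                                 category = "composition")
  env <- qq_envelope(om)
  expect_equal(nrow(env), 13L)
  m <- 13
  expected <- sort(-log10(stats::qbeta(0.5, 1:m, m:1)))
  expect_equal(env$expected, expected)
  expect_true(all(diff(env$expected) >= 0))
  expect_true(all(diff(env$observed) >= 0))
  # band ordering and nesting at every rank
  expect_true(all(env$lo95 <= env$lo90))
  expect_true(all(env$hi90 <= env$hi95))
  expect_true(all(env$lo90 <= env$hi90))
  # envelopes monotone in rank and widest at the extreme rank
  expect_true(all(diff(env$hi95) >= 0))
  width <- env$hi95 - env$lo95
  expect_equal(which.max(width), m)
})

test_that("single-variable omnibus degenerates to one QQ point", {
  sim <- generate_cohort(preset_params("null", n = 150, seed = 29),
                         keep_networks = FALSE)
  om <- omnibus_permutation_test(sim$cohort, "density", n_perm = 100,
                                 seed = 8, category = "structure")
  env <- qq_envelope(om)
  expect_equal(nrow(env), 1L)
  expect_equal(env$expected, -log10(stats::qbeta(0.5, 1, 1)))
})

test_that("the omnibus p is stable under row reordering of the cohort table", {
  # permutations attach to outcome values in row order, so reordering rows
  # redraws the Monte Carlo pairing but not the sampling distribution
  sim <- generate_cohort(preset_params("paper-like", n = 250, seed = 44),
                         keep_networks = FALSE)
  om <- omnibus_permutation_test(sim$cohort, COMPOSITION_VARS,
                                 n_perm = 2000, seed = 5)
  shuffled <- sim$cohort[rev(seq_len(nrow(sim$cohort))), ]
  om2 <- omnibus_permutation_test(shuffled, COMPOSITION_VARS,
                                  n_perm = 2000, seed = 5)
  expect_equal(om$observed_stat, om2$observed_stat)
  expect_lt(abs(om$empirical_p - om2$empirical_p), 0.05)
})

test_that("omnibus rejects unusable inputs", {
  sim <- generate_cohort(preset_params("null", n = 100, seed = 1),
                         keep_networks = FALSE)
  expect_error(omnibus_permutation_test(sim$cohort, character(0)),
               "no variables")
  expect_error(omnibus_permutation_test(sim$cohort, "density", n_perm = 0),
               "n_perm")
  bad <- sim$cohort
  bad$const <- 0
  expect_error(omnibus_permutation_test(bad, c("density", "const"),
                                        n_perm = 10),
               "cannot be fit")
})

test_that("the 95% envelope has calibrated pointwise coverage on null draws", {
  hits <- unlist(lapply(1:20, function(seed) {
    sim <- generate_cohort(preset_params("null", n = 150, seed = seed),
                           keep_networks = FALSE)
    om <- omnibus_permutation_test(sim$cohort, COMPOSITION_VARS,
                                   n_perm = 300, seed = 11,
                                   category = "composition")
    env <- qq_envelope(om)
    env$observed >= env$lo95 & env$observed <= env$hi95
  }))
  # each rank should fall inside its pointwise band about 95% of the time
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.995)
})
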