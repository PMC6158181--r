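flagged_net <- function(values, flag = "kin") {
  a <- alter_table(length(values))
  a[[flag]] <- values
  ego_network("e1", length(values), a)
}

test_that("percentages use non-missing denominators", {
  p <- percent_with(flagged_net(c(TRUE, TRUE, FALSE, FALSE)), "kin")
  expect_equal(as.numeric(p), 50)
  expect_equal(attr(p, "n"), 4)

  p2 <- percent_with(flagged_net(c(TRUE, FALSE, FALSE, NA, FALSE), "smokes"),
                     "smokes")
  expect_equal(as.numeric(p2), 25)
  expect_equal(attr(p2, "n"), 4)

  p3 <- percent_with(flagged_net(rep(FALSE, 8), "no_doctor"), "no_doctor")
  expect_equal(as.numeric(p3), 0)

  expect_warning(p4 <- percent_with(flagged_net(rep(NA, 3)), "kin"),
                 "undefined")
  expect_true(is.na(as.numeric(p4)))
  expect_error(percent_with(flagged_net(TRUE), "nonsense"), "unknown")
})

test_that("alter age spread is the sample standard deviation", {
  withage <- function(ages) {
    a <- alter_table(length(ages)); a$age <- ages
    ego_network("e1", length(ages), a)
  }
  expect_equal(age_sd(withage(c(30, 40))), sqrt(50))
  expect_equal(age_sd(withage(c(25, 25, 25))), 0)
  expect_equal(age_sd(withage(c(20, 30, 40))), 10)
  expect_warning(s <- age_sd(withage(c(31, NA))), "undefined")
  expect_true(is.na(s))
})

test_that("the diversity index hits its anchors and hand values", {
  expect_equal(iqv_diversity(c("M", "M", "F", "F"), k = 2), 1)
  expect_equal(iqv_diversity(rep("M", 5), k = 2), 0)
  expect_equal(iqv_diversity(c("M", "M", "M", "F"), k = 2), 0.75)
  # unnormalised Blau option: maximum is 1 - 1/k
  expect_equal(iqv_diversity(c("M", "F"), k = 2, normalize = FALSE), 0.5)
  expect_error(iqv_diversity(c("M"), k = 1), "categories")
  expect_warning(na <- iqv_diversity(c(NA, NA), k = 2), "undefined")
  expect_true(is.na(na))
})

test_that("the diversity index is in [0,1] and maximal at the uniform mix", {
  # brute force over all compositions of <=8 alters into k<=4 categories
  for (k in 2:4) {
    n <- 2 * k                      # uniform mix representable exactly
    grid <- expand.grid(rep(list(0:n), k))
    grid <- grid[rowSums(grid) == n, , drop = FALSE]
    vals <- apply(grid, 1, function(counts) {
      iqv_diversity(rep(letters[1:k], counts), k = k)
    })
    expect_true(all(vals >= 0 & vals <= 1 + 1e-12))
    expect_equal(unname(unlist(grid[which.max(vals), ])), rep(2L, k))
    expect_equal(max(vals), 1)
  }
})

test_that("the four-habit unhealthy composite follows any-true / all-false / missing rules", {
  a <- alter_table(3)
  a$smokes <- c(TRUE, FALSE, NA)
  a$no_exercise <- c(FALSE, FALSE, TRUE)
  a$med_nonadherent <- c(FALSE, FALSE, NA)
  a$no_doctor <- c(FALSE, FALSE, NA)
  net <- ego_network("e1", 3, a)
  expect_equal(unhealthy_flags(net), c(TRUE, FALSE, TRUE))

  allna <- alter_table(1)
  net2 <- ego_network("e2", 1, allna)
  expect_true(is.na(unhealthy_flags(net2)))
})

test_that("percentages are invariant under duplicating every alter", {
  sim <- small_sim(n = 8, seed = 13)
  net <- sim$networks[[which(vapply(sim$networks, n_alters, integer(1))
                             %in% 2:5)[1]]]
  m <- n_alters(net)
  dup <- ego_network("dup", 2 * m,
                     rbind(net$alters, net$alters))
  for (metric in names(egonets::FLAG_METRIC_MAP)) {
    flag <- egonets::FLAG_METRIC_MAP[[metric]]
    expect_equal(as.numeric(percent_with(dup, flag)),
                 as.numeric(percent_with(net, flag)), label = metric)
  }
  expect_equal(iqv_diversity(dup$alters$sex, 2),
               iqv_diversity(net$alters$sex, 2))
})

test_that("the batch table carries all thirteen measures plus denominators", {
  sim <- small_sim(n = 5, seed = 2)
  row <- composition_metrics(sim$networks[[1]])
  expect_true(all(COMPOSITION_VARS %in% names(row)))
  expect_true(all(paste0("n_", names(egonets::FLAG_METRIC_MAP)) %in%
                    names(row)))
  pcts <- unlist(row[grep("^percent_", names(row))])
  expect_true(all(is.na(pcts) | (pcts >= 0 & pcts <= 100)))
})
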