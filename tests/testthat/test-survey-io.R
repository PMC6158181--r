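test_that("generated survey CSVs parse back with zero rejects and equal networks", {
  sim <- small_sim(n = 20, seed = 7, missing_tie_rate = 0.05)
  csv <- withr::local_tempfile(fileext = ".csv")
  emit_survey_csv(sim, survey_config(), csv)
  res <- networks_from_survey(csv)
  expect_equal(length(res$networks), 20L)
  expect_equal(nrow(res$rejects), 0L)
  for (i in seq_along(res$networks)) {
    expect_equal(res$networks[[i]], sim$networks[[i]])
  }
})

test_that("rows violating hard invariants are routed to rejects, never raised", {
  sim <- small_sim(n = 5, seed = 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  emit_survey_csv(sim, survey_config(), csv)
  raw <- utils::read.csv(csv, colClasses = "character", check.names = FALSE)
  raw$msrs_2[2] <- "7"              # outcome item out of range
  raw$named_count[4] <- ""          # missing name-generator count
  raw$tie_1_2[5] <- "9"             # unknown tie code (ego 5 has >1 alter)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, bad, row.names = FALSE)
  out <- parse_survey_csv(bad, survey_config())
  expect_equal(length(out$records) + nrow(out$rejects), out$n_rows)
  expect_match(out$rejects$reason[out$rejects$row == 2], "out of range")
  expect_match(out$rejects$reason[out$rejects$row == 4], "count missing")
})

test_that("name-generator counts above ten keep ten detailed alters", {
  sim <- small_sim(n = 40, seed = 9)
  big <- which(vapply(sim$records, `[[`, integer(1), "named_count") > 10L)[1]
  expect_false(is.na(big))
  rec <- sim$records[[big]]
  expect_equal(nrow(rec$alters), 10L)
  net <- build_ego_network(rec)
  expect_gt(net$total_named, 10L)
  expect_equal(n_alters(net), 10L)
})

test_that("tie matrices are symmetric with ego ties present and missing pairs coded absent", {
  rec <- structure(list(
    id = "e1", age = 40, male = FALSE, married = TRUE, education = 16,
    group = "asymptomatic", msrs = rep(0, 8), msrs_total = 0L,
    named_count = 2L, alters = alter_table(2L), ties = c(2L)
  ), class = "survey_record")
  net <- build_ego_network(rec)
  expect_equal(dim(net$ties), c(3L, 3L))
  expect_equal(net$ties[2, 3], 2L)
  expect_equal(net$ties[1, 2], 2L)       # ego-alter definitionally present
  expect_equal(net$ties, t(net$ties))

  rec$ties <- c(NA_integer_)
  net2 <- build_ego_network(rec)
  expect_equal(net2$ties[2, 3], 0L)
  expect_equal(net2$missing_ties, 1L)

  rec$named_count <- 0L
  rec$alters <- alter_table(0L)
  rec$ties <- integer(0)
  net3 <- build_ego_network(rec)
  expect_equal(n_alters(net3), 0L)
  expect_equal(network_size(net3), 0L)
})

test_that("JSON serialisation round-trips and GraphML carries the graph", {
  sim <- small_sim(n = 6, seed = 21)
  net <- sim$networks[[which.max(vapply(sim$networks, n_alters, integer(1)))]]
  js <- withr::local_tempfile(fileext = ".json")
  write_network(net, js)
  expect_equal(read_network(js), net)

  net3 <- toy_net(3, ties = c(2L, 0L, 1L))
  gm <- withr::local_tempfile(fileext = ".graphml")
  write_network(net3, gm, format = "graphml")
  g <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 5L)    # 3 ego edges + 2 alter-alter
  expect_setequal(igraph::E(g)$strength, c(2, 2, 2, 2, 1))

  solo <- toy_net(0, total = 4)
  gm0 <- withr::local_tempfile(fileext = ".graphml")
  write_network(solo, gm0, format = "graphml")
  g0 <- igraph::read_graph(gm0, format = "graphml")
  expect_equal(igraph::vcount(g0), 1L)
  expect_equal(igraph::ecount(g0), 0L)

  expect_error(write_network(net3, gm, format = "dot"), "arg")

  nets_file <- withr::local_tempfile(fileext = ".json")
  write_networks(sim$networks, nets_file)
  expect_equal(read_networks(nets_file), sim$networks)
})

test_that("configs validate their column map", {
  expect_error(survey_config(age = "record_id"), "unique")
  cfg <- survey_config()
  expect_equal(length(cfg$tie_cols), 45L)
  expect_equal(nrow(cfg$tie_pairs), 45L)
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("id: subject", "named_count: n_named"), yml)
  cfg2 <- read_survey_config(yml)
  expect_equal(cfg2$id, "subject")
  expect_equal(cfg2$named_count, "n_named")
  writeLines("bogus_key: 1", yml)
  expect_error(read_survey_config(yml), "unknown")
})
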