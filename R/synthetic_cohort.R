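#' Simulation parameters for a synthetic survey cohort
#'
#' Defines the marginal structure of a simulated cohort of respondents and
#' their personal networks, plus a linear outcome model through which
#' network effects are injected.  The defaults emulate the published
#' marginals of a large MS-at-risk family cohort: age ~ N(38, 8.4), 19%
#' male, 67% married, ~8% with an MS diagnosis; uncapped network size drawn
#' negative-binomially with quartiles 6 / 8 / 12; per-ego tie density drawn
#' from Beta(1.73, 1) (median 0.67); alter attribute prevalences matched to
#' the reported composition medians; and a 0--32 outcome built as a clamped,
#' rounded linear model of the network metrics, which reproduces the floor
#' effect (right skew) of the real instrument when the intercept sits near
#' the floor.
#'
#' @param n number of egos.
#' @param seed integer seed; all randomness derives from it.
#' @param ms_fraction fraction of egos in the MS group.
#' @param age_mean,age_sd ego age distribution (years).
#' @param male_fraction,married_fraction ego covariate prevalences.
#' @param education_mean,education_sd ego education (years, rounded).
#' @param size_mu,size_dispersion negative-binomial model of the uncapped
#'   name-generator count.
#' @param density_shape1,density_shape2 Beta model for per-ego tie density;
#'   alter pairs are then tied independently with that probability.
#' @param strong_fraction probability a present tie is strong (vs weak);
#'   affects visualisation and serialization only, as metrics binarise ties.
#' @param prevalence named vector of per-alter flag probabilities (names
#'   from `ALTER_FLAGS`).
#' @param alter_male_prob,alter_age_sd,race_homophily alter demographics:
#'   sex mix, age spread around the ego's age, and the probability an alter
#'   shares the ego's predominant race.
#' @param race_levels race category list (also the `k` of race diversity).
#' @param outcome_intercept,outcome_noise_sd outcome model intercept and
#'   residual standard deviation.
#' @param beta named vector of per-unit outcome effects of network metrics
#'   (e.g. `c(percent_negative_influence = 0.017)`); metrics enter centred
#'   at their realised cohort mean, missing metrics contribute zero.
#' @param covariate_beta named vector of effects for `age`, `male`,
#'   `married`, `education` (centred) and `ms` (group indicator).
#' @param missing_attr_rate,missing_tie_rate independent missingness rates
#'   for alter attribute items and pairwise tie items.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n = 300L, seed = 1L,
                       ms_fraction = 0.077,
                       age_mean = 38.3, age_sd = 8.4,
                       male_fraction = 0.193, married_fraction = 0.67,
                       education_mean = 16.3, education_sd = 1.8,
                       size_mu = 9, size_dispersion = 6,
                       density_shape1 = 1.73, density_shape2 = 1,
                       strong_fraction = 0.6,
                       prevalence = c(kin = 0.45, supportive = 0.38,
                                      contact_leq_weekly = 0.65,
                                      known_lt6y = 0.25, gt15mi = 0.35,
                                      smokes = 0.10, no_exercise = 0.33,
                                      med_nonadherent = 0.05,
                                      no_doctor = 0.07,
                                      negative_influence = 0.12),
                       alter_male_prob = 0.45, alter_age_sd = 13.5,
                       race_homophily = 0.93,
                       race_levels = c("white", "black", "asian",
                                       "hispanic", "other"),
                       outcome_intercept = 1.2, outcome_noise_sd = 2.2,
                       beta = numeric(0),
                       covariate_beta = c(age = 0, male = 0, married = 0,
                                          education = 0, ms = 0),
                       missing_attr_rate = 0.02, missing_tie_rate = 0) {
  stopifnot(n >= 1, all(prevalence >= 0 & prevalence <= 1),
            missing_attr_rate >= 0, missing_attr_rate <= 1,
            missing_tie_rate >= 0, missing_tie_rate <= 1)
  if (length(beta) && is.null(names(beta))) {
    stop("beta must be a named vector over metric columns", call. = FALSE)
  }
  bad <- setdiff(names(beta), c(STRUCTURE_VARS, COMPOSITION_VARS,
                                "percent_unhealthy"))
  if (length(bad)) {
    stop("unknown metric(s) in beta: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_params")
}

#' Preset simulation scenarios
#'
#' * `"null"` — outcome is pure noise on the floor-skewed scale; every
#'   network and covariate effect is zero.  Used for calibration checks.
#' * `"paper-like"` — composition effects injected at the magnitudes
#'   reported for the real cohort (`percent_no_doctor` 0.045,
#'   `percent_negative_influence` 0.017, `percent_smoke` 0.006,
#'   `percent_contact_weekly_or_less` -0.009), all structure effects null,
#'   MS group shifted upward, floor-skewed outcome.
#' * `"strong-effect"` — larger composition effects
#'   (`percent_no_doctor` 0.08, `percent_negative_influence` 0.04) with the
#'   outcome centred mid-scale (intercept 10, noise 3) so clamping is
#'   negligible; the regime for clean parameter-recovery and power studies.
#'
#' @param preset preset name.
#' @param ... overrides passed on to [sim_params()].
#' @return a `sim_params` list.
#' @export
preset_params <- function(preset = c("null", "paper-like", "strong-effect"),
                          ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "null" = list(),
    "paper-like" = list(
      beta = c(percent_no_doctor = 0.045,
               percent_negative_influence = 0.017,
               percent_smoke = 0.006,
               percent_contact_weekly_or_less = -0.009),
      covariate_beta = c(age = 0.02, male = 0, married = 0, education = 0,
                         ms = 4.5)
    ),
    "strong-effect" = list(
      beta = c(percent_no_doctor = 0.08,
               percent_negative_influence = 0.04),
      outcome_intercept = 10, outcome_noise_sd = 3
    )
  )
  do.call(sim_params, utils::modifyList(args, list(...)))
}

# Distribute an integer total over 8 items each capped at 4.
allocate_items <- function(total) {
  x <- as.vector(stats::rmultinom(1L, total, rep(1, 8L)))
  excess <- sum(pmax(x - 4L, 0L))
  x <- pmin(x, 4L)
  while (excess > 0L) {
    slack <- which(x < 4L)
    pick <- slack[sample.int(length(slack), 1L)]
    x[pick] <- x[pick] + 1L
    excess <- excess - 1L
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort under a [sim_params()] scenario: ego demographics and
#' group labels, uncapped network sizes with detailed data for the first ten
#' alters, symmetric three-level tie matrices, alter attributes, and a
#' clamped linear outcome with known injected effects.  Returns the cohort
#' metrics table (computed with the same metric definitions as
#' [cohort_metrics()]), the survey-record and network objects, and a truth
#' record with every injected parameter.
#'
#' @param params a [sim_params()] object.
#' @param keep_networks build the per-ego `survey_record` and
#'   [ego_network()] objects (set `FALSE` for large calibration runs that
#'   only need the metrics table).
#' @return list with `cohort` (data.frame), `records`, `networks`, `truth`.
#' @export
generate_cohort <- function(params, keep_networks = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed_local(p$seed, generate_cohort_impl(p, keep_networks))
}

generate_cohort_impl <- function(p, keep_networks) {
  n <- p$n
  ego_id <- sprintf("ego%05d", seq_len(n))
  group <- ifelse(stats::runif(n) < p$ms_fraction, "ms", "asymptomatic")
  age <- round(stats::rnorm(n, p$age_mean, p$age_sd), 1)
  male <- stats::runif(n) < p$male_fraction
  married <- stats::runif(n) < p$married_fraction
  education <- pmax(8L, round(stats::rnorm(n, p$education_mean,
                                           p$education_sd)))
  size <- as.integer(stats::rnbinom(n, mu = p$size_mu, size = p$size_dispersion))
  m <- pmin(size, 10L)
  dens <- stats::rbeta(n, p$density_shape1, p$density_shape2)

  # --- alter attribute grid, one block of rows per ego ---------------------
  total <- sum(m)
  ego_of <- rep.int(seq_len(n), m)
  alter_sex <- ifelse(stats::runif(total) < p$alter_male_prob,
                      "male", "female")
  alter_age <- pmax(0, round(stats::rnorm(total, rep.int(age, m),
                                          p$alter_age_sd)))
  nr <- length(p$race_levels)
  ego_race_idx <- sample.int(nr, n, replace = TRUE,
                             prob = c(0.7, rep(0.3 / (nr - 1), nr - 1)))
  others <- t(vapply(seq_len(nr), function(r) p$race_levels[-r],
                     character(nr - 1L)))        # nr x (nr-1)
  other_race <- others[cbind(ego_race_idx[ego_of],
                             sample.int(nr - 1L, total, replace = TRUE))]
  alter_race <- ifelse(stats::runif(total) < p$race_homophily,
                       p$race_levels[ego_race_idx[ego_of]], other_race)
  flags <- lapply(ALTER_FLAGS, function(f) {
    stats::runif(total) < p$prevalence[[f]]
  })
  names(flags) <- ALTER_FLAGS
  # attribute missingness
  if (p$missing_attr_rate > 0 && total > 0) {
    drop <- function(x) {
      x[stats::runif(length(x)) < p$missing_attr_rate] <- NA
      x
    }
    alter_sex <- drop(alter_sex); alter_age <- drop(alter_age)
    alter_race <- drop(alter_race)
    flags <- lapply(flags, drop)
  }

  # --- ties: per-ego Bernoulli(d_e) over the alter pairs -------------------
  npairs <- (m * (m - 1L)) %/% 2L
  tie_codes <- vector("list", n)      # 0/1/2 per pair, NA = missing item
  for (i in seq_len(n)) {
    if (npairs[i] == 0L) { tie_codes[[i]] <- integer(0); next }
    present <- stats::rbinom(npairs[i], 1L, dens[i])
    strength <- 1L + stats::rbinom(npairs[i], 1L, p$strong_fraction)
    code <- present * strength
    if (p$missing_tie_rate > 0) {
      code[stats::runif(npairs[i]) < p$missing_tie_rate] <- NA_integer_
    }
    tie_codes[[i]] <- code
  }

  # --- metrics (same definitions as the per-network functions) -------------
  ties_obs <- vapply(tie_codes, function(tc) sum(tc > 0L, na.rm = TRUE),
                     numeric(1))
  metr <- data.frame(size = size)
  metr$density <- ifelse(m >= 2L, 100 * ties_obs / pmax(npairs, 1L), NA_real_)
  metr$effective_size <- ifelse(m >= 1L, m - 2 * ties_obs / pmax(m, 1L),
                                NA_real_)
  degs <- lapply(seq_len(n), function(i) pair_degrees(m[i], tie_codes[[i]]))
  metr$constraint <- vapply(seq_len(n), function(i) {
    if (m[i] < 1L) return(NA_real_)
    100 * constraint_kernel(binary_weight_matrix(m[i], tie_codes[[i]]))
  }, numeric(1))
  metr$max_degree <- vapply(degs, function(d) {
    if (is.null(d)) NA_real_ else max(d)
  }, numeric(1))
  metr$mean_degree <- vapply(degs, function(d) {
    if (is.null(d)) NA_real_ else mean(d)
  }, numeric(1))

  pct_by_ego <- function(x) {
    known <- as.numeric(rowsum_safe(!is.na(x), ego_of, n))
    hits <- as.numeric(rowsum_safe(!is.na(x) & x, ego_of, n))
    ifelse(known > 0, 100 * hits / known, NA_real_)
  }
  for (metric in names(FLAG_METRIC_MAP)) {
    metr[[metric]] <- pct_by_ego(flags[[FLAG_METRIC_MAP[[metric]]]])
  }
  unhealthy <- Reduce(`|`, lapply(flags[UNHEALTHY_FLAGS],
                                  function(x) !is.na(x) & x))
  unhealthy[!unhealthy &
              Reduce(`&`, lapply(flags[UNHEALTHY_FLAGS], is.na))] <- NA
  metr$percent_unhealthy <- pct_by_ego(unhealthy)

  age_known <- as.numeric(rowsum_safe(!is.na(alter_age), ego_of, n))
  age_sum <- as.numeric(rowsum_safe(ifelse(is.na(alter_age), 0, alter_age),
                                    ego_of, n))
  age_sq <- as.numeric(rowsum_safe(ifelse(is.na(alter_age), 0, alter_age^2),
                                   ego_of, n))
  metr$sd_age <- ifelse(age_known >= 2,
                        sqrt(pmax(age_sq - age_sum^2 / age_known, 0) /
                               (age_known - 1)), NA_real_)

  sex_known <- as.numeric(rowsum_safe(!is.na(alter_sex), ego_of, n))
  sex_male <- as.numeric(rowsum_safe(!is.na(alter_sex) &
                                       alter_sex == "male", ego_of, n))
  pm <- ifelse(sex_known > 0, sex_male / sex_known, NA_real_)
  metr$diversity_sex <- 4 * pm * (1 - pm)
  race_p2 <- Reduce(`+`, lapply(p$race_levels, function(rl) {
    known <- as.numeric(rowsum_safe(!is.na(alter_race), ego_of, n))
    hits <- as.numeric(rowsum_safe(!is.na(alter_race) & alter_race == rl,
                                   ego_of, n))
    ifelse(known > 0, (hits / known)^2, NA_real_)
  }))
  k <- length(p$race_levels)
  metr$diversity_race <- (1 - race_p2) / (1 - 1 / k)

  # --- outcome: centred linear model, clamped and rounded to 0..32 ---------
  lp <- rep(p$outcome_intercept, n)
  centred_means <- numeric(0)
  for (v in names(p$beta)) {
    x <- metr[[v]]
    mu <- mean(x, na.rm = TRUE)
    centred_means[v] <- mu
    contrib <- p$beta[[v]] * (x - mu)
    contrib[is.na(contrib)] <- 0
    lp <- lp + contrib
  }
  cb <- p$covariate_beta
  lp <- lp + cb[["age"]] * (age - mean(age)) + cb[["male"]] * male +
    cb[["married"]] * married +
    cb[["education"]] * (education - mean(education)) +
    cb[["ms"]] * (group == "ms")
  msrs_total <- as.integer(pmin(32, pmax(0, round(
    lp + stats::rnorm(n, 0, p$outcome_noise_sd)))))

  cohort <- cbind(
    data.frame(ego_id = ego_id, age = age, male = male, married = married,
               education = education, group = group,
               msrs_total = msrs_total, stringsAsFactors = FALSE),
    metr
  )

  records <- networks <- NULL
  if (keep_networks) {
    msrs_items <- lapply(msrs_total, allocate_items)
    offsets <- c(0L, cumsum(m))
    records <- vector("list", n)
    networks <- vector("list", n)
    for (i in seq_len(n)) {
      idx <- if (m[i] > 0L) (offsets[i] + 1L):offsets[i + 1L] else integer(0)
      alters <- new_alter_table(c(
        list(sex = alter_sex[idx], age = as.numeric(alter_age[idx]),
             race = alter_race[idx]),
        lapply(flags, function(x) x[idx])
      ), m[i])
      records[[i]] <- structure(list(
        id = ego_id[i], age = age[i], male = male[i], married = married[i],
        education = education[i], group = group[i],
        msrs = as.numeric(msrs_items[[i]]),
        msrs_total = msrs_total[i], named_count = size[i],
        alters = alters, ties = tie_codes[[i]]
      ), class = "survey_record")
      networks[[i]] <- build_ego_network(records[[i]])
    }
  }

  truth <- list(params = p, beta = p$beta, covariate_beta = p$covariate_beta,
                metric_means = centred_means, seed = p$seed)
  list(cohort = cohort, records = records, networks = networks,
       truth = truth)
}

rowsum_safe <- function(x, g, n) {
  out <- numeric(n)
  if (length(x)) {
    rs <- rowsum(as.numeric(x), g)
    out[as.integer(rownames(rs))] <- rs[, 1L]
  }
  out
}

# degrees on the alter-alter subgraph from a row-major pair code vector
pair_degrees <- function(m, codes) {
  if (m < 1L) return(NULL)
  deg <- numeric(m)
  if (m >= 2L) {
    pr <- pair_index(m)
    present <- !is.na(codes) & codes > 0L
    deg <- tabulate(c(pr[present, 1L], pr[present, 2L]), nbins = m)
  }
  deg
}

pair_index_cache <- new.env(parent = emptyenv())
pair_index <- function(m) {
  key <- as.character(m)
  if (is.null(pair_index_cache[[key]])) {
    idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    pair_index_cache[[key]] <- idx[order(idx[, 1], idx[, 2]), ,
                                   drop = FALSE]
  }
  pair_index_cache[[key]]
}

binary_weight_matrix <- function(m, codes) {
  w <- matrix(0, 1L + m, 1L + m)
  w[1L, -1L] <- w[-1L, 1L] <- 1
  if (m >= 2L) {
    pr <- pair_index(m)
    present <- !is.na(codes) & codes > 0L
    w[cbind(pr[present, 1L] + 1L, pr[present, 2L] + 1L)] <- 1
    w[cbind(pr[present, 2L] + 1L, pr[present, 1L] + 1L)] <- 1
  }
  w
}

#' Emit a cohort as a wide-format survey CSV
#'
#' Writes the cohort in the export dialect described by a [survey_config()],
#' so the file parses through [parse_survey_csv()] /
#' [build_ego_network()] with zero rejects and round-trips every field.
#' Missing items (unused alter slots, injected missing attributes or tie
#' codes) are written as the first configured missing code.
#'
#' @param sim result of [generate_cohort()] (with `keep_networks = TRUE`).
#' @param config a [survey_config()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
emit_survey_csv <- function(sim, config = survey_config(), path) {
  records <- sim$records
  if (is.null(records)) {
    stop("generate_cohort(keep_networks = TRUE) output required",
         call. = FALSE)
  }
  mcode <- config$missing_codes[1]
  fmt <- function(x) ifelse(is.na(x), mcode, as.character(x))
  fmt_flag <- function(x) ifelse(is.na(x), mcode, ifelse(x, "1", "0"))
  n <- length(records)
  cols <- stats::setNames(
    vector("list", length(survey_columns(config))), survey_columns(config))
  cols[[config$id]] <- vapply(records, `[[`, character(1), "id")
  cols[[config$demographics[["age"]]]] <-
    fmt(vapply(records, `[[`, numeric(1), "age"))
  cols[[config$demographics[["sex"]]]] <- vapply(records, function(r) {
    if (is.na(r$male)) mcode else {
      unname(config$sex_levels[[if (r$male) "male" else "female"]])
    }
  }, character(1))
  cols[[config$demographics[["married"]]]] <- vapply(records, function(r) {
    if (is.na(r$married)) mcode else {
      unname(config$married_levels[[if (r$married) "married" else
        "not_married"]])
    }
  }, character(1))
  cols[[config$demographics[["education"]]]] <-
    fmt(vapply(records, `[[`, numeric(1), "education"))
  cols[[config$demographics[["group"]]]] <- vapply(records, function(r) {
    if (is.na(r$group)) mcode else unname(config$group_levels[[r$group]])
  }, character(1))
  for (j in 1:8) {
    cols[[config$msrs_items[j]]] <-
      fmt(vapply(records, function(r) r$msrs[j], numeric(1)))
  }
  cols[[config$named_count]] <-
    as.character(vapply(records, `[[`, integer(1), "named_count"))

  for (i in 1:10) {
    for (f in ALTER_FIELDS) {
      col <- config$alter_cols[[f]][i]
      cols[[col]] <- vapply(records, function(r) {
        if (nrow(r$alters) < i) return(mcode)
        v <- r$alters[[f]][i]
        if (f %in% ALTER_FLAGS) {
          fmt_flag(v)
        } else if (f == "sex" && !is.na(v)) {
          unname(config$sex_levels[[v]])
        } else {
          fmt(v)
        }
      }, character(1))
    }
  }
  code_of <- stats::setNames(names(config$tie_codes), config$tie_codes)
  for (k in seq_len(45L)) {
    i <- config$tie_pairs[k, 1]; j <- config$tie_pairs[k, 2]
    cols[[config$tie_cols[k]]] <- vapply(records, function(r) {
      mi <- nrow(r$alters)
      if (j > mi) return(mcode)
      pos <- pair_pos(mi, i, j)
      v <- r$ties[pos]
      if (is.na(v)) mcode else unname(code_of[[as.character(v)]])
    }, character(1))
  }
  df <- new_alter_table(cols, n)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# position of pair (i, j), i < j <= m, in row-major pair order
pair_pos <- function(m, i, j) {
  (i - 1L) * m - (i * (i - 1L)) %/% 2L + (j - i)
}
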