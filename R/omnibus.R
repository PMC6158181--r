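# Evaluate expr with a private RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Category-level omnibus association test by outcome permutation
#'
#' Tests whether a category of network variables (structure or composition)
#' is associated with the outcome as a group.  Per-variable two-sided
#' p-values from [adjusted_regression()] are combined into a Fisher
#' chi-squared statistic, which is referred to an empirical null built by
#' permuting the outcome across respondents and refitting every regression;
#' permuting the outcome (rather than the predictors) preserves the
#' correlation structure among the network variables.  The empirical
#' p-value is the fraction of permuted statistics strictly greater than the
#' observed one (`p_rule = "greater"`); the bias-corrected estimate
#' `(1 + #\{perm >= obs\}) / (n_perm + 1)` is reported alongside and is the
#' better choice when the p-value itself feeds further inference, since the
#' plain rule can return an exact zero.
#'
#' Permutations shuffle outcome *values* over the rows of the cohort table;
#' each variable's regression then uses its own complete cases.  Rows with a
#' missing outcome or incomplete covariates are dropped before permuting,
#' so the test is invariant to the printed row order of the table.
#'
#' @inheritParams adjusted_regression
#' @param variables character vector: the network variables of the category.
#' @param n_perm number of permutations (10000 for reported results).
#' @param seed integer seed for the permutation stream; recorded in the
#'   result.
#' @param category label stored in the result.
#' @return an `omnibus_result` list: `category`, `variables`, `m`,
#'   `observed_p` (per-variable), `observed_stat`, `perm_stats`,
#'   `perm_pvalues` (`n_perm` x `m`), `empirical_p`,
#'   `empirical_p_corrected`, `n_perm`, `seed`, `n`.
#' @export
omnibus_permutation_test <- function(cohort, variables,
                                     covariates = COVARIATES_FULL,
                                     n_perm = 10000L, seed = 1L,
                                     outcome = "msrs_total",
                                     category = "category") {
  if (length(variables) == 0L) stop("no variables given", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  m <- length(variables)

  # base rows: outcome and covariates complete; permutation acts on these
  base_cols <- c(outcome, covariates)
  base <- cohort[stats::complete.cases(
    as.data.frame(lapply(cohort[base_cols], as.numeric))), , drop = FALSE]
  n <- nrow(base)
  if (n < length(covariates) + 3L) {
    stop("too few complete rows for the omnibus test", call. = FALSE)
  }
  y <- as.numeric(base[[outcome]])

  perm_idx <- with_seed_local(seed, {
    matrix(unlist(lapply(seq_len(n_perm), function(b) sample.int(n))), n,
           n_perm)
  })
  Yperm <- matrix(y[perm_idx], n, n_perm)

  observed_p <- numeric(m)
  perm_p <- matrix(NA_real_, n_perm, m)
  names(observed_p) <- colnames(perm_p) <- variables
  for (j in seq_len(m)) {
    d <- design_for(base, variables[j], covariates, outcome)
    if (d$n < length(covariates) + 3L || stats::var(d$X[, 2L]) == 0) {
      stop("omnibus: regression for '", variables[j],
           "' cannot be fit (too few rows or constant variable)",
           call. = FALSE)
    }
    qx <- qr(d$X)
    if (qx$rank < ncol(d$X)) {
      stop("omnibus: rank-deficient design for '", variables[j], "'",
           call. = FALSE)
    }
    observed_p[j] <- ols_tstat(qx, matrix(d$y, ncol = 1L), 2L)$p
    perm_p[, j] <- ols_tstat(qx, Yperm[d$keep, , drop = FALSE], 2L)$p
  }

  obs_stat <- fisher_combine(observed_p)
  perm_stats <- -2 * rowSums(log(pmax(perm_p, 1e-300)))

  structure(list(
    category = category,
    variables = variables,
    m = m,
    observed_p = observed_p,
    observed_stat = obs_stat,
    perm_stats = perm_stats,
    perm_pvalues = perm_p,
    empirical_p = sum(perm_stats > obs_stat) / n_perm,
    empirical_p_corrected = (1 + sum(perm_stats >= obs_stat)) / (n_perm + 1),
    n_perm = as.integer(n_perm),
    seed = as.integer(seed),
    n = n,
    covariates = covariates,
    outcome = outcome
  ), class = "omnibus_result")
}

#' @export
print.omnibus_result <- function(x, ...) {
  p <- if (x$empirical_p == 0) paste0("< ", format(1 / x$n_perm)) else {
    format(x$empirical_p)
  }
  cat("<omnibus_result> ", x$category, ": m = ", x$m,
      ", observed X^2 = ", signif(x$observed_stat, 5),
      " (df ", 2 * x$m, "), empirical p = ", p,
      " [", x$n_perm, " permutations, seed ", x$seed, "]\n", sep = "")
  invisible(x)
}

#' Quantile-quantile coordinates with permutation confidence envelopes
#'
#' For each rank `i` of the `m` per-variable p-values: the expected value is
#' `-log10` of the median of the `i`-th uniform order statistic
#' (`qbeta(0.5, i, m - i + 1)`), the observed value is the sorted observed
#' `-log10` p, and the envelopes are pointwise quantiles across permutations
#' of each sorted rank's `-log10` p (90% band: 5th--95th percentile; 95%
#' band: 2.5th--97.5th).
#'
#' @param result an `omnibus_result` (with retained permutation p-values).
#' @return data.frame with columns `rank`, `expected`, `observed`, `lo90`,
#'   `hi90`, `lo95`, `hi95`, ordered by increasing expected value.
#' @export
qq_envelope <- function(result) {
  stopifnot(inherits(result, "omnibus_result"))
  m <- result$m
  obs <- sort(-log10(pmax(result$observed_p, 1e-300)), decreasing = FALSE)
  # sorted descending p per permutation -> ascending -log10
  perm_sorted <- apply(result$perm_pvalues, 1L, function(p) {
    sort(-log10(pmax(p, 1e-300)))
  })
  perm_sorted <- matrix(perm_sorted, nrow = m)     # m x n_perm
  qs <- apply(perm_sorted, 1L, stats::quantile,
              probs = c(0.05, 0.95, 0.025, 0.975), names = FALSE)
  i <- seq_len(m)
  data.frame(
    rank = i,
    expected = sort(-log10(stats::qbeta(0.5, i, m - i + 1))),
    observed = obs,
    lo90 = qs[1L, ], hi90 = qs[2L, ],
    lo95 = qs[3L, ], hi95 = qs[4L, ]
  )
}

#' Serialize an omnibus result to JSON
#'
#' Writes every deterministic component (observed per-variable p-values,
#' statistic, permutation statistics, empirical p-values, seed, QQ
#' coordinates), so two runs with the same inputs and seed produce
#' byte-identical files.  The full permutation p-value matrix is omitted to
#' keep files small; regenerate it from the seed if needed.
#'
#' @param result an `omnibus_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_omnibus <- function(result, path) {
  env <- qq_envelope(result)
  out <- result[c("category", "variables", "m", "observed_p",
                  "observed_stat", "perm_stats", "empirical_p",
                  "empirical_p_corrected", "n_perm", "seed", "n",
                  "covariates", "outcome")]
  out$observed_p <- as.list(out$observed_p)
  out$qq <- env
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
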