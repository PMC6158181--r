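# Default covariate sets for the adjusted regressions.  The full set adds
# years of education; the reduced set is the minimal confounder adjustment.
COVARIATES_FULL <- c("age", "male", "married", "education")
COVARIATES_REDUCED <- c("age", "male", "married")

#' Compare a variable between the two diagnosis groups
#'
#' Two-sided descriptive group comparison: Welch t test for approximately
#' normal quantities (age), chi-squared test for dichotomous variables, and
#' the Wilcoxon rank-sum test for skewed quantities (education, outcome
#' scores, network metrics).  The rank-sum test enumerates the exact
#' distribution when both groups have at most 10 observations and no ties;
#' otherwise it uses the normal approximation with mid-ranks and tie
#' correction.
#'
#' @param cohort cohort table with a `group` column.
#' @param variable column name to compare.
#' @param kind `"t"`, `"chi2"`, or `"ranksum"`.
#' @param group grouping column (two levels).
#' @return list with `kind`, `statistic`, `p.value`, and per-group `n`.
#' @export
group_compare <- function(cohort, variable, kind = c("t", "chi2", "ranksum"),
                          group = "group") {
  kind <- match.arg(kind)
  g <- cohort[[group]]
  x <- cohort[[variable]]
  keep <- !is.na(g) & !is.na(x)
  g <- factor(g[keep]); x <- x[keep]
  if (nlevels(g) != 2L || any(table(g) == 0L)) {
    stop("group_compare needs two non-empty groups", call. = FALSE)
  }
  ht <- switch(kind,
    t = stats::t.test(x ~ g),
    chi2 = stats::chisq.test(table(g, x)),
    ranksum = {
      n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
      exact <- n1 <= 10L && n2 <= 10L && !anyDuplicated(x)
      stats::wilcox.test(x ~ g, exact = exact, correct = TRUE)
    }
  )
  list(kind = kind, statistic = unname(ht$statistic),
       p.value = ht$p.value, n = as.vector(table(g)))
}

#' Covariate-adjusted linear association of one network variable
#'
#' Ordinary least squares of the outcome on one network variable plus the
#' adjustment covariates, on the complete cases for that variable.  Reports
#' the variable term's coefficient, standard error and two-sided p-value.
#'
#' @param cohort cohort table (see [cohort_metrics()] / [generate_cohort()]).
#' @param variable network variable column name (the exposure).
#' @param covariates adjustment covariate column names; `COVARIATES_FULL`
#'   (`age, male, married, education`) by default.
#' @param outcome outcome column name.
#' @return an `association_result` list: `variable`, `beta`, `se`,
#'   `p.value`, `n`.
#' @export
adjusted_regression <- function(cohort, variable,
                                covariates = COVARIATES_FULL,
                                outcome = "msrs_total") {
  d <- design_for(cohort, variable, covariates, outcome)
  if (d$n < length(covariates) + 2L) {
    stop("too few complete rows (", d$n, ") for adjusted regression of '",
         variable, "'", call. = FALSE)
  }
  if (stats::var(d$X[, 2L]) == 0) {
    stop("variable '", variable, "' has no variance on the complete cases",
         call. = FALSE)
  }
  qx <- qr(d$X)
  if (qx$rank < ncol(d$X)) {
    bad <- colnames(d$X)[qx$pivot[seq.int(qx$rank + 1L, ncol(d$X))]]
    stop("rank-deficient design for '", variable, "': collinear term(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- ols_tstat(qx, matrix(d$y, ncol = 1L), which = 2L)
  structure(list(variable = variable, beta = fit$beta[1L], se = fit$se[1L],
                 p.value = fit$p[1L], n = d$n, covariates = covariates,
                 outcome = outcome),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> %s: beta = %.4g (SE %.4g), p = %.3g, n = %d\n",
              x$variable, x$beta, x$se, x$p.value, x$n))
  invisible(x)
}

# Complete-case design matrix (intercept, variable, covariates) and outcome.
design_for <- function(cohort, variable, covariates, outcome) {
  cols <- c(outcome, variable, covariates)
  absent <- setdiff(cols, names(cohort))
  if (length(absent)) {
    stop("cohort table lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  d <- cohort[cols]
  for (j in seq_along(d)) d[[j]] <- as.numeric(d[[j]])
  keep <- stats::complete.cases(d)
  X <- cbind(`(Intercept)` = 1, as.matrix(d[keep, -1L, drop = FALSE]))
  list(X = X, y = d[[1L]][keep], n = sum(keep), keep = keep)
}

# t statistics for one coefficient of X across many outcome columns.
# qx: qr(X) (unpivoted full rank); Y: n x B outcomes; which: column of X.
ols_tstat <- function(qx, Y, which) {
  n <- nrow(Y); k <- qx$rank
  Q <- qr.Q(qx); R <- qr.R(qx)
  QtY <- crossprod(Q, Y)                       # k x B
  beta <- backsolve(R, QtY)
  rss <- pmax(colSums(Y^2) - colSums(QtY^2), 0)
  sigma2 <- rss / (n - k)
  vcv_w <- chol2inv(R)[which, which]
  se <- sqrt(sigma2 * vcv_w)
  tval <- beta[which, ] / se
  list(beta = beta[which, ], se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df = n - k))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, capped at 1.
#' Applied within each metric category (structure, composition) by
#' [association_table()].
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value list", call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Fisher's combination of p-values
#'
#' `X^2 = -2 * sum(log(p))`, chi-squared with `2m` degrees of freedom under
#' independence; here it is referred to a permutation null instead, so the
#' statistic is only used as a ranking quantity.  Zero p-values are clamped
#' to `floor` with a warning before taking logs.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param floor smallest admissible p-value.
#' @return the combined chi-squared statistic.
#' @export
fisher_combine <- function(pvalues, floor = 1e-300) {
  if (length(pvalues) == 0L) stop("empty p-value list", call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (any(pvalues < floor)) {
    warning("p-value(s) below floor ", floor, " clamped before log")
    pvalues <- pmax(pvalues, floor)
  }
  -2 * sum(log(pvalues))
}

#' Rank-based sensitivity analysis
#'
#' Spearman correlation between a network variable and the outcome, the
#' non-parametric companion to [adjusted_regression()] for skewed data.
#' Ties are handled by mid-ranks (asymptotic p-value).
#'
#' @inheritParams adjusted_regression
#' @return list with `rho`, `p.value`, `n`.
#' @export
spearman_sensitivity <- function(cohort, variable, outcome = "msrs_total") {
  x <- as.numeric(cohort[[variable]])
  y <- as.numeric(cohort[[outcome]])
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p.value = NA_real_, n = length(x)))
  }
  exact <- !anyDuplicated(x) && !anyDuplicated(y) && length(x) < 1290L
  ht <- stats::cor.test(x, y, method = "spearman", exact = exact)
  list(rho = unname(ht$estimate), p.value = ht$p.value, n = length(x))
}

#' Per-variable association table with within-category FDR
#'
#' Runs [adjusted_regression()] for every network variable and adjusts the
#' p-values by [bh_fdr()] separately within the structure batch (6
#' variables) and the composition batch (13 variables), mirroring how the
#' multiple-testing burden is controlled per metric category.
#'
#' @inheritParams adjusted_regression
#' @param variables named list of character vectors, one element per
#'   category; defaults to the canonical structure/composition split.
#' @return data.frame with `category`, `variable`, `beta`, `se`, `p.value`,
#'   `fdr`, `n`.
#' @export
association_table <- function(cohort,
                              variables = list(structure = STRUCTURE_VARS,
                                               composition = COMPOSITION_VARS),
                              covariates = COVARIATES_FULL,
                              outcome = "msrs_total") {
  out <- lapply(names(variables), function(cat) {
    rows <- lapply(variables[[cat]], function(v) {
      r <- adjusted_regression(cohort, v, covariates, outcome)
      data.frame(category = cat, variable = v, beta = r$beta, se = r$se,
                 p.value = r$p.value, n = r$n, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$fdr <- bh_fdr(tab$p.value)
    tab
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("category", "variable", "beta", "se", "p.value", "fdr", "n")]
}
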