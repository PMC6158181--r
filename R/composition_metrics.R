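#' Compositional metrics of an egocentric network
#'
#' Compositional measures summarise who the alters are.  Every percentage is
#' taken over the alters with a non-missing value for that item (the
#' denominator is reported alongside in the batch table), so unknown habits
#' do not deflate the percentage.  Diversity of sex and race use the index
#' of qualitative variation; the spread of ages is the sample standard
#' deviation.
#'
#' @param net an [ego_network()].
#' @param attribute one of the alter flag names
#'   (`r paste(ALTER_FLAGS, collapse = ", ")`) or `"unhealthy"` for the
#'   four-habit composite.
#' @return scalar metrics; [composition_metrics()] returns a one-row
#'   data.frame of all thirteen measures plus `percent_unhealthy` and the
#'   per-measure denominators (`n_` columns).
#' @name composition-metrics
NULL

pct_kernel <- function(flags) {
  n <- sum(!is.na(flags))
  if (n == 0L) return(c(value = NA_real_, n = 0))
  c(value = 100 * sum(flags, na.rm = TRUE) / n, n = n)
}

#' @rdname composition-metrics
#' @export
percent_with <- function(net, attribute) {
  flags <- if (identical(attribute, "unhealthy")) {
    unhealthy_flags(net)
  } else {
    if (!attribute %in% ALTER_FLAGS) {
      stop("unknown alter attribute '", attribute, "'", call. = FALSE)
    }
    net$alters[[attribute]]
  }
  out <- pct_kernel(flags)
  if (out["n"] == 0) {
    warning("percent_", attribute, " undefined: no non-missing alters")
  }
  structure(out[["value"]], n = out[["n"]])
}

#' @rdname composition-metrics
#' @export
age_sd <- function(net) {
  ages <- net$alters$age[!is.na(net$alters$age)]
  if (length(ages) < 2L) {
    warning("age spread undefined with fewer than 2 known ages")
    return(NA_real_)
  }
  stats::sd(ages)
}

#' Index of qualitative variation
#'
#' `IQV = (1 - sum(p^2)) / (1 - 1/k)` over the non-missing values, where
#' `p` are the observed category proportions and `k` the number of possible
#' categories.  The index is 1 at a perfectly even mix (for sex, equal
#' numbers of men and women) and 0 when every member falls in one category.
#' `normalize = FALSE` drops the `1 - 1/k` normalisation, giving the raw
#' Blau index `1 - sum(p^2)` with maximum `1 - 1/k`.
#'
#' @param values vector of categorical values (`NA` allowed).
#' @param k number of possible categories (at least 2).
#' @param normalize divide by `1 - 1/k` (default `TRUE`).
#' @return index in `[0, 1]` (normalised) or `[0, 1 - 1/k]`.
#' @export
iqv_diversity <- function(values, k, normalize = TRUE) {
  if (k < 2L) stop("iqv_diversity needs at least 2 categories", call. = FALSE)
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    warning("diversity undefined: all values missing")
    return(NA_real_)
  }
  p <- tabulate(factor(values), nbins = nlevels(factor(values)))
  p <- p / sum(p)
  blau <- 1 - sum(p^2)
  if (normalize) blau / (1 - 1 / k) else blau
}

#' Four-habit "unhealthy alter" composite
#'
#' An alter is unhealthy if they do any of: smoke, not exercise, not visit
#' doctors regularly, or not comply with prescription medications.  The
#' composite is `TRUE` as soon as any of the four flags is `TRUE` (even if
#' others are missing), `FALSE` when all non-missing flags are `FALSE` and
#' at least one is observed, and `NA` when all four are missing.
#'
#' @param net an [ego_network()].
#' @return logical vector, one element per alter.
#' @export
unhealthy_flags <- function(net) {
  f <- net$alters[UNHEALTHY_FLAGS]
  any_true <- Reduce(`|`, lapply(f, function(x) !is.na(x) & x))
  all_na <- Reduce(`&`, lapply(f, is.na))
  out <- rep(FALSE, nrow(net$alters))
  out[any_true] <- TRUE
  out[!any_true & all_na] <- NA
  out
}

#' @rdname composition-metrics
#' @param race_k number of race categories of the instrument (the `k` for
#'   race diversity); defaults to the 5-level list of [survey_config()].
#' @param normalize_iqv use the normalised index (see [iqv_diversity()]).
#' @export
composition_metrics <- function(net, race_k = 5L, normalize_iqv = TRUE) {
  suppressWarnings({
    vals <- numeric(0); ns <- numeric(0)
    for (metric in names(FLAG_METRIC_MAP)) {
      p <- percent_with(net, FLAG_METRIC_MAP[[metric]])
      vals[metric] <- as.numeric(p)
      ns[paste0("n_", metric)] <- attr(p, "n")
    }
    unh <- percent_with(net, "unhealthy")
    out <- data.frame(
      percent_kin = vals[["percent_kin"]],
      percent_supportive = vals[["percent_supportive"]],
      sd_age = age_sd(net),
      diversity_sex = iqv_diversity(net$alters$sex, k = 2L,
                                    normalize = normalize_iqv),
      diversity_race = iqv_diversity(net$alters$race, k = race_k,
                                     normalize = normalize_iqv),
      percent_contact_weekly_or_less = vals[["percent_contact_weekly_or_less"]],
      percent_known_lt6y = vals[["percent_known_lt6y"]],
      percent_gt15mi = vals[["percent_gt15mi"]],
      percent_smoke = vals[["percent_smoke"]],
      percent_no_exercise = vals[["percent_no_exercise"]],
      percent_med_nonadherent = vals[["percent_med_nonadherent"]],
      percent_no_doctor = vals[["percent_no_doctor"]],
      percent_negative_influence = vals[["percent_negative_influence"]],
      percent_unhealthy = as.numeric(unh),
      row.names = NULL
    )
    for (nm in names(ns)) out[[nm]] <- unname(ns[nm])
    out$n_unhealthy <- attr(unh, "n")
    out
  })
}
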