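#' @keywords internal
"_PACKAGE"

#' Canonical variable sets
#'
#' `ALTER_FLAGS`: the ten tri-state alter attribute flags (stored as logical
#' columns, `TRUE`/`FALSE`/`NA`); `UNHEALTHY_FLAGS`: the four habit flags of
#' the unhealthy-alter composite; `STRUCTURE_VARS` / `COMPOSITION_VARS`: the
#' six structural and thirteen compositional metric columns, the two
#' multiple-testing batches of the association analyses; `COVARIATES_FULL` /
#' `COVARIATES_REDUCED`: the default and minimal regression adjustment sets.
#'
#' `FLAG_METRIC_MAP` maps each percentage metric to its alter flag.
#'
#' @name variable-sets
#' @aliases ALTER_FLAGS UNHEALTHY_FLAGS STRUCTURE_VARS COMPOSITION_VARS
#'   COVARIATES_FULL COVARIATES_REDUCED FLAG_METRIC_MAP
#' @export ALTER_FLAGS UNHEALTHY_FLAGS STRUCTURE_VARS COMPOSITION_VARS
#' @export COVARIATES_FULL COVARIATES_REDUCED FLAG_METRIC_MAP
NULL

# The ten tri-state flags are stored as logical columns (TRUE/FALSE/NA);
# sex and race are character, age numeric.
ALTER_FLAGS <- c(
  "kin", "supportive", "contact_leq_weekly", "known_lt6y", "gt15mi",
  "smokes", "no_exercise", "med_nonadherent", "no_doctor",
  "negative_influence"
)
ALTER_FIELDS <- c("sex", "age", "race", ALTER_FLAGS)

# The four habit flags entering the "unhealthy alter" composite.
UNHEALTHY_FLAGS <- c("smokes", "no_exercise", "med_nonadherent", "no_doctor")

# Metric column names, grouped as reported: six structural measures and the
# thirteen compositional measures that form the two FDR batches.
STRUCTURE_VARS <- c(
  "size", "density", "constraint", "effective_size", "max_degree",
  "mean_degree"
)
COMPOSITION_VARS <- c(
  "percent_kin", "percent_supportive", "sd_age", "diversity_sex",
  "diversity_race", "percent_contact_weekly_or_less", "percent_known_lt6y",
  "percent_gt15mi", "percent_smoke", "percent_no_exercise",
  "percent_med_nonadherent", "percent_no_doctor", "percent_negative_influence"
)

# flag metric name -> alter flag column
FLAG_METRIC_MAP <- c(
  percent_kin                    = "kin",
  percent_supportive             = "supportive",
  percent_contact_weekly_or_less = "contact_leq_weekly",
  percent_known_lt6y             = "known_lt6y",
  percent_gt15mi                 = "gt15mi",
  percent_smoke                  = "smokes",
  percent_no_exercise            = "no_exercise",
  percent_med_nonadherent        = "med_nonadherent",
  percent_no_doctor              = "no_doctor",
  percent_negative_influence     = "negative_influence"
)

#' Survey column-mapping configuration
#'
#' Describes how one wide-format survey export (one row per respondent)
#' encodes the fields the pipeline needs: respondent demographics, the eight
#' outcome domain items, the uncapped name-generator count, the per-alter
#' attribute grid for the first ten alters, and the 45 pairwise tie-strength
#' items among those ten slots.  All column names, category encodings and
#' missing-value codes live here so the parser is not bound to a single
#' export dialect.
#'
#' @param id column holding the pseudonymous respondent id.
#' @param age,sex,married,education,group demographic column names.
#' @param msrs_items character vector of the 8 outcome item columns, each an
#'   integer score in 0--4 (total 0--32).
#' @param named_count column with the total number of persons named
#'   (uncapped; detailed alter data cover at most the first ten).
#' @param alter_prefix prefix for alter attribute columns; attribute `f` of
#'   alter slot `i` is `<alter_prefix><i>_<f>` with `f` one of
#'   `r paste(ALTER_FIELDS, collapse = ", ")`.
#' @param tie_prefix prefix for pair tie columns; the tie between slots
#'   `i < j` is column `<tie_prefix><i>_<j>`.
#' @param tie_codes named integer vector mapping the raw cell values to tie
#'   levels 0 (stranger/absent), 1 (weak), 2 (strong).
#' @param sex_levels,married_levels,group_levels named character vectors
#'   mapping canonical levels (`male`/`female`, `married`/`not_married`,
#'   `asymptomatic`/`ms`) to the raw codes used in the export.
#' @param race_levels character vector of race categories used by the
#'   instrument; its length is the category count for race diversity.
#' @param missing_codes raw cell values treated as missing.
#' @param missing_tie_policy how to handle a missing pairwise tie item:
#'   `"absent"` (default) codes it 0 and counts it in the missingness
#'   report; `"reject"` routes the row to the rejects report.
#'
#' @return an object of class `survey_config`.
#' @export
survey_config <- function(id = "record_id",
                          age = "age", sex = "sex", married = "married",
                          education = "education", group = "group",
                          msrs_items = paste0("msrs_", 1:8),
                          named_count = "named_count",
                          alter_prefix = "alter",
                          tie_prefix = "tie_",
                          tie_codes = c("0" = 0L, "1" = 1L, "2" = 2L),
                          sex_levels = c(male = "male", female = "female"),
                          married_levels = c(married = "married",
                                             not_married = "not married"),
                          group_levels = c(asymptomatic = "asymptomatic",
                                           ms = "MS"),
                          race_levels = c("white", "black", "asian",
                                          "hispanic", "other"),
                          missing_codes = c("", "NA"),
                          missing_tie_policy = c("absent", "reject")) {
  stopifnot(length(msrs_items) == 8L)
  missing_tie_policy <- match.arg(missing_tie_policy)

  alter_cols <- lapply(ALTER_FIELDS, function(f) {
    paste0(alter_prefix, 1:10, "_", f)
  })
  names(alter_cols) <- ALTER_FIELDS

  pairs <- which(upper.tri(matrix(0, 10, 10)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  tie_cols <- paste0(tie_prefix, pairs[, 1], "_", pairs[, 2])

  cfg <- structure(list(
    id = id,
    demographics = c(age = age, sex = sex, married = married,
                     education = education, group = group),
    msrs_items = msrs_items,
    named_count = named_count,
    alter_cols = alter_cols,
    tie_cols = tie_cols,
    tie_pairs = pairs,
    tie_codes = tie_codes,
    sex_levels = sex_levels,
    married_levels = married_levels,
    group_levels = group_levels,
    race_levels = race_levels,
    missing_codes = missing_codes,
    missing_tie_policy = missing_tie_policy
  ), class = "survey_config")
  validate_survey_config(cfg)
  cfg
}

validate_survey_config <- function(cfg) {
  cols <- c(cfg$id, cfg$demographics, cfg$msrs_items, cfg$named_count,
            unlist(cfg$alter_cols, use.names = FALSE), cfg$tie_cols)
  if (anyDuplicated(cols)) {
    stop("survey_config: mapped column names must be unique; duplicated: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(cfg$tie_cols) != 45L) {
    stop("survey_config: tie columns must cover exactly the 45 unordered ",
         "pairs of 10 alter slots", call. = FALSE)
  }
  invisible(cfg)
}

#' All mapped column names of a configuration, in export order
#' @param cfg a [survey_config()].
#' @return character vector of column names.
#' @export
survey_columns <- function(cfg) {
  alter_grid <- unlist(lapply(1:10, function(i) {
    vapply(ALTER_FIELDS, function(f) cfg$alter_cols[[f]][i], character(1))
  }), use.names = FALSE)
  c(cfg$id, unname(cfg$demographics), cfg$msrs_items, cfg$named_count,
    alter_grid, cfg$tie_cols)
}

#' Read a survey configuration from a YAML file
#'
#' The YAML file may set any argument of [survey_config()]; omitted keys keep
#' their defaults.  `tie_codes` is given as a mapping from raw code to level.
#'
#' @param path YAML file path.
#' @return a `survey_config`.
#' @export
read_survey_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(survey_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown survey_config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in c("tie_codes", "sex_levels", "married_levels", "group_levels")) {
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  }
  if (!is.null(raw$tie_codes)) storage.mode(raw$tie_codes) <- "integer"
  do.call(survey_config, raw)
}

#' @export
print.survey_config <- function(x, ...) {
  cat("<survey_config>\n",
      "  id column:    ", x$id, "\n",
      "  demographics: ", paste(x$demographics, collapse = ", "), "\n",
      "  outcome items:", length(x$msrs_items), "columns\n",
      "  alter grid:   10 slots x", length(ALTER_FIELDS), "fields\n",
      "  tie columns:  ", length(x$tie_cols), "\n",
      "  race levels:  ", paste(x$race_levels, collapse = ", "), "\n")
  invisible(x)
}
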