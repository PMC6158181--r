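#' Flatten a cohort of ego networks into a tidy metrics table
#'
#' One row per ego, with the six structural and the compositional metrics in
#' a fixed column order, plus the per-metric denominators.  When the
#' matching survey records are supplied, ego demographics (regression
#' covariates), group label and outcome total are prepended, yielding the
#' cohort table the association analyses consume.
#'
#' @param networks list of [ego_network()] objects.
#' @param records optional list of `survey_record`s aligned with `networks`.
#' @param race_k,normalize_iqv passed to [composition_metrics()].
#' @param weighted passed to [structure_metrics()].
#' @return a data.frame, one row per ego.
#' @export
cohort_metrics <- function(networks, records = NULL, race_k = 5L,
                           normalize_iqv = TRUE, weighted = FALSE) {
  rows <- lapply(seq_along(networks), function(i) {
    net <- networks[[i]]
    row <- cbind(
      data.frame(ego_id = net$ego_id, stringsAsFactors = FALSE),
      structure_metrics(net, weighted = weighted),
      composition_metrics(net, race_k = race_k,
                          normalize_iqv = normalize_iqv)
    )
    row$missing_ties <- net$missing_ties
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(records)) {
    if (length(records) != length(networks)) {
      stop("records and networks must align", call. = FALSE)
    }
    demo <- do.call(rbind, lapply(records, function(r) {
      data.frame(age = r$age, male = r$male, married = r$married,
                 education = r$education, group = r$group,
                 msrs_total = r$msrs_total, stringsAsFactors = FALSE)
    }))
    out <- cbind(out[, "ego_id", drop = FALSE], demo,
                 out[, setdiff(names(out), "ego_id")])
  }
  rownames(out) <- NULL
  out
}

#' Write / read the cohort metrics table as CSV
#' @param table data.frame from [cohort_metrics()] or [generate_cohort()].
#' @param path CSV file path.
#' @return `path` (write) or the table (read).
#' @export
write_metrics <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
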