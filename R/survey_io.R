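#' Parse a wide-format personal-network survey export
#'
#' Reads a CSV export (RFC 4180, UTF-8, header row; one row per respondent)
#' and maps it to validated survey records using a [survey_config()].  Rows
#' violating hard invariants (outcome item outside 0--4, missing or negative
#' name-generator count, unrecognised tie code) are routed to a rejects
#' report with the reason; they are never silently dropped and the parser
#' never raises on malformed rows.
#'
#' @param path CSV file path.
#' @param config a [survey_config()].
#' @return a list with elements `records` (list of `survey_record`),
#'   `rejects` (data.frame with `row`, `id`, `reason`), and `n_rows`.
#' @export
parse_survey_csv <- function(path, config = survey_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  needed <- survey_columns(config)
  absent <- setdiff(needed, names(raw))
  if (length(absent)) {
    stop("survey export lacks mapped columns: ",
         paste(utils::head(absent, 8L), collapse = ", "),
         if (length(absent) > 8L) ", ...", call. = FALSE)
  }
  miss <- function(x) {
    x[x %in% config$missing_codes] <- NA_character_
    x
  }
  records <- vector("list", nrow(raw))
  rej_row <- integer(0); rej_id <- character(0); rej_reason <- character(0)
  n_ok <- 0L
  for (r in seq_len(nrow(raw))) {
    id <- raw[[config$id]][r]
    res <- tryCatch(
      parse_survey_row(raw[r, , drop = FALSE], config, miss),
      survey_reject = function(e) e
    )
    if (inherits(res, "survey_reject")) {
      rej_row <- c(rej_row, r); rej_id <- c(rej_id, id)
      rej_reason <- c(rej_reason, conditionMessage(res))
    } else {
      n_ok <- n_ok + 1L
      records[[n_ok]] <- res
    }
  }
  list(
    records = records[seq_len(n_ok)],
    rejects = data.frame(row = rej_row, id = rej_id, reason = rej_reason,
                         stringsAsFactors = FALSE),
    n_rows = nrow(raw)
  )
}

reject <- function(...) {
  stop(structure(class = c("survey_reject", "condition"),
                 list(message = paste0(...), call = NULL)))
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

parse_flag <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("1", "TRUE", "true", "yes")] <- TRUE
  out[x %in% c("0", "FALSE", "false", "no")] <- FALSE
  out
}

decode_level <- function(x, levels) {
  hit <- match(x, levels)
  if (is.na(x) || is.na(hit)) NA_character_ else names(levels)[hit]
}

parse_survey_row <- function(row, config, miss) {
  cell <- function(col) miss(row[[col]])

  # outcome items: hard invariant, each in [0, 4] when present
  msrs <- vapply(config$msrs_items, function(col) {
    v <- cell(col)
    if (is.na(v)) return(NA_real_)
    x <- num_or_na(v)
    if (is.na(x)) reject("non-numeric outcome item in column '", col, "'")
    if (x < 0 || x > 4 || x != round(x)) {
      reject("outcome item ", x, " in column '", col, "' out of range [0,4]")
    }
    x
  }, numeric(1))
  msrs_total <- if (anyNA(msrs)) NA_integer_ else as.integer(sum(msrs))

  nc_raw <- cell(config$named_count)
  named <- num_or_na(nc_raw)
  if (is.na(named) || named < 0 || named != round(named)) {
    reject("name-generator count missing or invalid ('",
           if (is.na(nc_raw)) "" else nc_raw, "')")
  }
  named <- as.integer(named)
  m <- min(named, 10L)

  alters <- alter_table(m)
  if (m > 0L) {
    for (i in seq_len(m)) {
      alters$sex[i] <- decode_level(cell(config$alter_cols$sex[i]),
                                    config$sex_levels)
      alters$age[i] <- num_or_na(cell(config$alter_cols$age[i]))
      race <- cell(config$alter_cols$race[i])
      alters$race[i] <- if (!is.na(race) && race %in% config$race_levels) {
        race
      } else {
        NA_character_
      }
      for (f in ALTER_FLAGS) {
        alters[[f]][i] <- parse_flag(cell(config$alter_cols[[f]][i]))
      }
    }
  }

  # observed tie pairs: both slots within the detailed alters
  keep <- config$tie_pairs[, 2] <= m
  ties <- rep(NA_integer_, sum(keep))
  cols <- config$tie_cols[keep]
  for (k in seq_along(cols)) {
    v <- cell(cols[k])
    if (is.na(v)) {
      if (config$missing_tie_policy == "reject") {
        reject("missing tie code in column '", cols[k], "'")
      }
      next
    }
    code <- config$tie_codes[match(v, names(config$tie_codes))]
    if (is.na(code)) reject("unrecognised tie code '", v, "' in column '",
                            cols[k], "'")
    ties[k] <- code
  }

  sex <- decode_level(cell(config$demographics[["sex"]]), config$sex_levels)
  marr <- decode_level(cell(config$demographics[["married"]]),
                       config$married_levels)
  structure(list(
    id = row[[config$id]],
    age = num_or_na(cell(config$demographics[["age"]])),
    male = if (is.na(sex)) NA else sex == "male",
    married = if (is.na(marr)) NA else marr == "married",
    education = num_or_na(cell(config$demographics[["education"]])),
    group = decode_level(cell(config$demographics[["group"]]),
                         config$group_levels),
    msrs = msrs,
    msrs_total = msrs_total,
    named_count = named,
    alters = alters,
    ties = ties
  ), class = "survey_record")
}

#' Build an ego network from a parsed survey record
#'
#' Pairs with a missing tie code are coded 0 (absent) and counted in the
#' network's `missing_ties` field, so cohort-level missingness can be
#' audited.  The uncapped name-generator count is preserved as
#' `total_named`.
#'
#' @param record a `survey_record` from [parse_survey_csv()].
#' @return an [ego_network()].
#' @export
build_ego_network <- function(record) {
  ties <- record$ties
  n_missing <- sum(is.na(ties))
  ties[is.na(ties)] <- 0L
  net <- ego_network(record$ego_id %||% record$id, record$named_count,
                     record$alters, ties, missing_ties = n_missing)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a survey export straight to ego networks
#'
#' Convenience wrapper chaining [parse_survey_csv()] and
#' [build_ego_network()], with a cohort-level tie missingness report.
#'
#' @inheritParams parse_survey_csv
#' @return list with `networks`, `records`, `rejects`, and
#'   `missing_tie_rate` (missing pairwise items / observed pairwise items).
#' @export
networks_from_survey <- function(path, config = survey_config()) {
  parsed <- parse_survey_csv(path, config)
  nets <- lapply(parsed$records, build_ego_network)
  n_pairs <- sum(vapply(parsed$records, function(r) length(r$ties),
                        integer(1)))
  n_miss <- sum(vapply(nets, function(n) n$missing_ties, integer(1)))
  list(
    networks = nets,
    records = parsed$records,
    rejects = parsed$rejects,
    missing_tie_rate = if (n_pairs > 0L) n_miss / n_pairs else 0
  )
}

#' Serialize an ego network
#'
#' JSON round-trips losslessly through [read_network()]; GraphML (via
#' igraph) carries tie strength as an edge attribute and alter attributes as
#' node attributes, for use in external network tools.
#'
#' @param net an [ego_network()].
#' @param path output file path.
#' @param format `"json"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(network_to_list(net), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  } else {
    g <- as_igraph(net)
    for (f in ALTER_FLAGS) {  # graphml has no tri-state logical; emit 0/1
      g <- igraph::set_vertex_attr(g, f,
        value = as.numeric(igraph::vertex_attr(g, f)))
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

network_to_list <- function(net) {
  m <- n_alters(net)
  list(
    ego_id = net$ego_id,
    total_named = net$total_named,
    missing_ties = net$missing_ties,
    alters = as.list(net$alters),
    ties = net$ties[upper.tri(net$ties)][order(.ut_colmajor_order(1L + m))]
  )
}

network_from_list <- function(x) {
  null2na <- function(v, na) {
    vapply(v, function(e) if (is.null(e)) na else e, na)
  }
  n <- length(x$alters$sex %||% list())
  alters <- alter_table(n)
  if (n > 0L) {
    alters$sex <- null2na(x$alters$sex, NA_character_)
    alters$age <- null2na(x$alters$age, NA_real_)
    alters$race <- null2na(x$alters$race, NA_character_)
    for (f in ALTER_FLAGS) alters[[f]] <- null2na(x$alters[[f]], NA)
  }
  full <- unlist(x$ties)            # row-major pairs over {ego} U alters
  tm <- matrix(0L, 1L + n, 1L + n)
  tm[upper.tri(tm)] <- as.integer(full)[.ut_colmajor_order(1L + n)]
  tm[lower.tri(tm)] <- t(tm)[lower.tri(tm)]
  ego_network(x$ego_id, x$total_named, alters, tm,
              missing_ties = x$missing_ties %||% 0L)
}

#' Read an ego network from JSON
#' @param path JSON file written by [write_network()].
#' @return an [ego_network()].
#' @export
read_network <- function(path) {
  network_from_list(jsonlite::read_json(path))
}

#' Write / read a whole cohort of networks as one JSON file
#' @param nets list of [ego_network()] objects.
#' @param path JSON file path.
#' @return `path` (write) or list of networks (read).
#' @export
write_networks <- function(nets, path) {
  jsonlite::write_json(lapply(nets, network_to_list), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_networks
#' @export
read_networks <- function(path) {
  lapply(jsonlite::read_json(path), network_from_list)
}
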