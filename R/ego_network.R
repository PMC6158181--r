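# Fast data.frame constructor for alter tables: all columns pre-typed and of
# equal length, so we can skip data.frame()'s coercion overhead (the
# synthetic generator builds hundreds of thousands of these).
new_alter_table <- function(cols, n) {
  structure(cols, class = "data.frame", row.names = .set_row_names(n))
}

#' Empty alter attribute table
#'
#' @param n number of alters (rows).
#' @return a data.frame with one row per alter and the canonical columns:
#'   `sex`, `race` (character), `age` (numeric) and the ten tri-state logical
#'   flags (`TRUE`/`FALSE`/`NA`).
#' @export
alter_table <- function(n = 0L) {
  cols <- c(
    list(sex = rep(NA_character_, n), age = rep(NA_real_, n),
         race = rep(NA_character_, n)),
    stats::setNames(rep(list(rep(NA, n)), length(ALTER_FLAGS)), ALTER_FLAGS)
  )
  new_alter_table(cols, n)
}

#' Construct an egocentric network
#'
#' An `ego_network` holds one respondent's personal network: the ego, the
#' detailed alters (at most ten, the slots the instrument collects pairwise
#' tie and attribute data for), a symmetric tie matrix over ego and alters
#' with entries 0 (stranger/absent), 1 (weak), 2 (strong), and the uncapped
#' total number of persons named.  Ego--alter ties are definitionally present
#' (the ego named each alter) and are coded strong (2) in the matrix; all
#' structural metrics except constraint ignore them.
#'
#' @param ego_id pseudonymous id.
#' @param total_named uncapped name-generator count (network size).
#' @param alters alter attribute table as from [alter_table()]; at most 10
#'   rows.
#' @param ties either a full symmetric `(1+m) x (1+m)` integer matrix (ego
#'   first), or a length `m(m-1)/2` vector of alter-pair codes in row-major
#'   upper-triangle order, or `NULL` for no alter-alter ties.
#' @param missing_ties number of pairwise tie items that were missing and
#'   coded 0 under the absent-tie policy (kept for the missingness report).
#' @return an object of class `ego_network`.
#' @export
ego_network <- function(ego_id, total_named, alters = alter_table(0L),
                        ties = NULL, missing_ties = 0L) {
  m <- nrow(alters)
  if (m > 10L) stop("at most 10 detailed alters are supported", call. = FALSE)
  if (total_named < m) {
    stop("total_named (", total_named, ") smaller than number of detailed ",
         "alters (", m, ")", call. = FALSE)
  }
  if (is.matrix(ties)) {
    tm <- ties
    storage.mode(tm) <- "integer"
  } else {
    tm <- matrix(0L, 1L + m, 1L + m)
    if (m > 0L) {
      tm[1L, -1L] <- tm[-1L, 1L] <- 2L
      if (!is.null(ties)) {
        if (length(ties) != m * (m - 1L) / 2L) {
          stop("tie vector must have length m(m-1)/2", call. = FALSE)
        }
        sub <- matrix(0L, m, m)
        sub[upper.tri(sub)] <- as.integer(ties)[.ut_colmajor_order(m)]
        sub[lower.tri(sub)] <- t(sub)[lower.tri(sub)]
        tm[-1L, -1L] <- sub
      }
    }
  }
  dimnames(tm) <- list(c("ego", alter_ids(m)), c("ego", alter_ids(m)))
  net <- structure(list(
    ego_id = ego_id,
    total_named = as.integer(total_named),
    alters = alters,
    ties = tm,
    missing_ties = as.integer(missing_ties)
  ), class = "ego_network")
  validate_ego_network(net)
  net
}

alter_ids <- function(m) if (m > 0L) paste0("a", seq_len(m)) else character(0)

# row-major (i<j by i then j) pair order -> positions in column-major
# upper.tri order, so a row-major pair vector can fill upper.tri directly
.ut_colmajor_order <- function(m) {
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  order(order(idx[, 1], idx[, 2]))
}

validate_ego_network <- function(net) {
  tm <- net$ties
  m <- nrow(net$alters)
  if (!is.matrix(tm) || nrow(tm) != 1L + m || ncol(tm) != 1L + m) {
    stop("tie matrix must be (1+alters) square", call. = FALSE)
  }
  if (any(tm != t(tm))) stop("tie matrix must be symmetric", call. = FALSE)
  if (any(diag(tm) != 0L)) stop("tie matrix diagonal must be 0", call. = FALSE)
  if (any(!tm %in% 0:2)) stop("tie codes must be 0, 1 or 2", call. = FALSE)
  invisible(net)
}

#' @export
print.ego_network <- function(x, ...) {
  m <- nrow(x$alters)
  cat("<ego_network ", x$ego_id, ">  size ", x$total_named,
      " (", m, " detailed alter", if (m != 1L) "s", "), ",
      sum(x$ties[-1L, -1L][upper.tri(x$ties[-1L, -1L])] > 0L),
      " alter-alter ties\n", sep = "")
  invisible(x)
}

#' Number of detailed alters (at most ten)
#' @param net an `ego_network`.
#' @return integer count of alters with detailed data.
#' @export
n_alters <- function(net) nrow(net$alters)

# Binary alter-alter adjacency (presence = weak or strong).
alter_adjacency <- function(net) {
  m <- n_alters(net)
  sub <- net$ties[-1L, -1L, drop = FALSE]
  (sub > 0L) + 0L
}

#' Convert an ego network to an igraph graph
#'
#' Vertices are the ego plus the detailed alters, with alter attributes as
#' vertex attributes; edges carry the tie strength (`strength`: 1 weak, 2
#' strong; ego--alter edges are coded 2) as an edge attribute.
#'
#' @param net an `ego_network`.
#' @return an [igraph::igraph] object.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net$ties, mode = "undirected",
                                           weighted = "strength")
  igraph::V(g)$role <- c("ego", rep("alter", n_alters(net)))
  for (f in ALTER_FIELDS) {
    vals <- net$alters[[f]]
    g <- igraph::set_vertex_attr(g, f, value = c(NA, vals))
  }
  g
}
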