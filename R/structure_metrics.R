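#' Structural metrics of an egocentric network
#'
#' Six measures summarise network structure.  *Size* is the uncapped number
#' of persons named, excluding the ego.  The remaining five are computed on
#' the detailed alters (at most ten) for which pairwise tie data exist, with
#' ties binarised (present iff weak or strong) unless noted:
#'
#' * **density** — percent of possible alter--alter ties present, the ego's
#'   own (definitional) ties excluded;
#' * **constraint** — Burt's constraint of the ego on the graph including
#'   the ego, scaled by 100;
#' * **effective size** — Burt's count of non-redundant alters, `n - 2t/n`
#'   on a binary graph with `n` alters and `t` alter--alter ties;
#' * **max / mean degree** — highest and average number of alter--alter ties
#'   per alter (ego ties excluded).
#'
#' Metrics that are undefined for very small networks (density needs two
#' alters; constraint, effective size and degrees need one) are returned as
#' `NA` and propagate as missing into downstream regressions.
#'
#' @param net an [ego_network()].
#' @param weighted for [burt_constraint()]: if `TRUE` use tie strengths
#'   (weak = 1, strong = 2) as weights instead of binary presence.
#' @return [structure_metrics()] returns a one-row data.frame with columns
#'   `size`, `density`, `constraint`, `effective_size`, `max_degree`,
#'   `mean_degree`; the individual functions return scalars.
#' @name structure-metrics
NULL

#' @rdname structure-metrics
#' @export
network_size <- function(net) net$total_named

#' @rdname structure-metrics
#' @export
net_density <- function(net) {
  m <- n_alters(net)
  if (m < 2L) {
    warning("density undefined for networks with fewer than 2 alters")
    return(NA_real_)
  }
  a <- alter_adjacency(net)
  100 * sum(a[upper.tri(a)]) / (m * (m - 1) / 2)
}

#' @rdname structure-metrics
#' @export
burt_constraint <- function(net, weighted = FALSE) {
  m <- n_alters(net)
  if (m < 1L) {
    warning("constraint undefined for networks with no alters")
    return(NA_real_)
  }
  w <- net$ties
  if (!weighted) w <- (w > 0L) + 0
  100 * constraint_kernel(w)
}

# Burt constraint of vertex 1 on a symmetric weight matrix (vertex 1 = ego):
# C = sum_j (p_1j + sum_q p_1q p_qj)^2 over j != 1, q != 1, j.
constraint_kernel <- function(w) {
  p <- w / rowSums(w)           # proportional tie investment per vertex
  pe <- p[1L, -1L]              # ego -> alters
  ind <- as.vector(pe %*% p[-1L, -1L, drop = FALSE])  # sum_q p_eq p_qj
  sum((pe + ind)^2)
}

#' @rdname structure-metrics
#' @export
effective_size <- function(net) {
  m <- n_alters(net)
  if (m < 1L) {
    warning("effective size undefined for networks with no alters")
    return(NA_real_)
  }
  a <- alter_adjacency(net)
  m - 2 * sum(a[upper.tri(a)]) / m
}

#' @rdname structure-metrics
#' @export
degree_stats <- function(net) {
  m <- n_alters(net)
  if (m < 1L) {
    warning("degrees undefined for networks with no alters")
    return(c(max_degree = NA_real_, mean_degree = NA_real_))
  }
  deg <- colSums(alter_adjacency(net))
  c(max_degree = max(deg), mean_degree = mean(deg))
}

#' @rdname structure-metrics
#' @export
structure_metrics <- function(net, weighted = FALSE) {
  suppressWarnings({
    d <- degree_stats(net)
    data.frame(
      size = network_size(net),
      density = net_density(net),
      constraint = burt_constraint(net, weighted = weighted),
      effective_size = effective_size(net),
      max_degree = unname(d["max_degree"]),
      mean_degree = unname(d["mean_degree"])
    )
  })
}
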