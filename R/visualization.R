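#' Sociogram plotting specification
#'
#' @param mode `"structure"` colours edges by tie strength (strong red,
#'   weak blue, ego--alter grey); `"health"` colours alters by the
#'   four-habit unhealthy composite (unhealthy red, healthy white, unknown
#'   grey).
#' @param order_by montage ordering key: `"size"` (smallest network first)
#'   or `"unhealthy"` (least unhealthy percent first); networks with an
#'   undefined key sort last, ties broken by ego id.
#' @param seed layout seed (force-directed layouts are deterministic under
#'   a fixed seed).
#' @param width,height,dpi raster output geometry (inches / dots per inch).
#' @param ncol montage grid columns (`NULL`: near-square grid).
#' @return a `plot_spec` list.
#' @export
plot_spec <- function(mode = c("structure", "health"),
                      order_by = c("size", "unhealthy"),
                      seed = 42L, width = 7, height = 7, dpi = 150,
                      ncol = NULL) {
  structure(list(mode = match.arg(mode), order_by = match.arg(order_by),
                 seed = as.integer(seed), width = width, height = height,
                 dpi = dpi, ncol = ncol), class = "plot_spec")
}

# Node/edge geometry + colour assignment for one network.
sociogram_data <- function(net, spec) {
  m <- n_alters(net)
  g <- as_igraph(net)
  coords <- with_seed_local(spec$seed, {
    if (m == 0L) matrix(0, 1L, 2L) else igraph::layout_with_fr(g)
  })
  if (m > 0L) {  # pin the ego at the centroid of its alters
    coords[1L, ] <- colMeans(coords[-1L, , drop = FALSE])
  }
  node_color <- if (spec$mode == "structure") {
    c("black", rep("white", m))
  } else {
    unh <- if (m > 0L) unhealthy_flags(net) else logical(0)
    c("black", ifelse(is.na(unh), "grey70", ifelse(unh, "red", "white")))
  }
  nodes <- data.frame(
    id = c("ego", alter_ids(m)),
    role = c("ego", rep("alter", m)),
    x = coords[, 1L], y = coords[, 2L],
    color = node_color, stringsAsFactors = FALSE
  )
  el <- igraph::as_edgelist(g, names = TRUE)
  strength <- igraph::E(g)$strength
  if (is.null(strength)) strength <- numeric(0)
  ego_edge <- el[, 1L] == "ego" | el[, 2L] == "ego"
  edge_color <- if (spec$mode == "structure") {
    ifelse(ego_edge, "grey60", ifelse(strength == 2, "red", "blue"))
  } else {
    rep("grey60", nrow(el))
  }
  edges <- data.frame(
    from = el[, 1L], to = el[, 2L],
    strength = strength, ego_edge = ego_edge,
    color = edge_color, stringsAsFactors = FALSE
  )
  list(ego_id = as.character(net$ego_id), nodes = nodes, edges = edges)
}

sociogram_layer <- function(dat) {
  ed <- dat$edges
  nd <- dat$nodes
  ed$x <- nd$x[match(ed$from, nd$id)]
  ed$y <- nd$y[match(ed$from, nd$id)]
  ed$xend <- nd$x[match(ed$to, nd$id)]
  ed$yend <- nd$y[match(ed$to, nd$id)]
  list(
    if (nrow(ed)) {
      ggplot2::geom_segment(
        data = ed,
        ggplot2::aes(x = x, y = y, xend = xend,
                     yend = yend),
        colour = ed$color, linewidth = 0.4)
    },
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = x, y = y),
      fill = nd$color, shape = 21, size = ifelse(nd$role == "ego", 4, 3),
      colour = "black")
  )
}

#' Plot one ego network as a sociogram
#'
#' The ego is a black circle pinned at the centroid of its alters (white
#' circles).  In structure mode, strong ties are red and weak ties blue; in
#' health mode, alters flagged by the four-habit unhealthy composite are
#' red.  A JSON sidecar (`<file>.json`) records node coordinates and every
#' colour assignment so figures can be checked and re-rendered without
#' reading pixels.
#'
#' @param net an [ego_network()].
#' @param spec a [plot_spec()].
#' @param file output image path (`.png` or `.svg`).
#' @return the sidecar data, invisibly.
#' @export
plot_ego_network <- function(net, spec = plot_spec(), file) {
  dat <- sociogram_data(net, spec)
  pl <- ggplot2::ggplot() + sociogram_layer(dat) +
    ggplot2::coord_equal() + ggplot2::theme_void() +
    ggplot2::ggtitle(dat$ego_id)
  ggplot2::ggsave(file, pl, width = spec$width, height = spec$height,
                  dpi = spec$dpi)
  jsonlite::write_json(dat, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dat)
}

montage_key <- function(nets, spec) {
  if (spec$order_by == "size") {
    vapply(nets, network_size, numeric(1))
  } else {
    vapply(nets, function(n) {
      suppressWarnings(as.numeric(percent_with(n, "unhealthy")))
    }, numeric(1))
  }
}

#' Plot a montage of sociograms
#'
#' Grid of [plot_ego_network()] panels ordered by the spec's key (network
#' size ascending, or percent of unhealthy alters ascending), ties broken
#' by ego id; networks with an undefined key come last.  The sidecar lists
#' the cell order and per-cell geometry.
#'
#' @param nets list of [ego_network()] objects.
#' @inheritParams plot_ego_network
#' @return the sidecar data (with `order`: ego ids in cell order),
#'   invisibly.
#' @export
plot_montage <- function(nets, spec = plot_spec(), file) {
  if (length(nets) == 0L) stop("no networks to plot", call. = FALSE)
  key <- montage_key(nets, spec)
  key[is.na(key)] <- Inf
  ids <- vapply(nets, function(n) as.character(n$ego_id), character(1))
  ord <- order(key, ids)
  dats <- lapply(nets[ord], sociogram_data, spec = spec)
  cells <- lapply(seq_along(dats), function(i) {
    d <- dats[[i]]
    d$nodes$cell <- i
    d$edges$cell <- i
    d
  })
  # offset each cell into a grid position so one coord system carries all
  # panels (cheaper and more controllable than facetting here)
  ncol <- spec$ncol %||% ceiling(sqrt(length(cells)))
  normed <- lapply(seq_along(cells), function(i) {
    d <- cells[[i]]
    rng <- function(v) if (diff(range(v)) == 0) 1 else diff(range(v))
    d$nodes$x <- (d$nodes$x - min(d$nodes$x)) / rng(d$nodes$x) * 0.8 + 0.1 +
      ((i - 1) %% ncol)
    d$nodes$y <- (d$nodes$y - min(d$nodes$y)) / rng(d$nodes$y) * 0.8 + 0.1 -
      ((i - 1) %/% ncol)
    d
  })
  pl <- Reduce(`+`, lapply(normed, sociogram_layer),
               ggplot2::ggplot())
  pl <- pl + ggplot2::coord_equal() + ggplot2::theme_void()
  ggplot2::ggsave(file, pl, width = spec$width, height = spec$height,
                  dpi = spec$dpi)
  side <- list(order = vapply(dats, `[[`, character(1), "ego_id"),
               ncol = ncol, cells = normed)
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(side)
}

#' Quantile-quantile plot of observed versus expected p-values
#'
#' Expected against observed `-log10` p-values for one omnibus category,
#' with the pointwise permutation envelopes shaded (dark grey: 90% band,
#' the chance range at a threshold of 0.10; light grey: 95% band, at
#' 0.05).  The plotted coordinates are also written as a CSV sidecar
#' (`<file>.csv`).
#'
#' @param result an `omnibus_result` from [omnibus_permutation_test()].
#' @param file output image path.
#' @param spec a [plot_spec()] (geometry only).
#' @return the [qq_envelope()] coordinates, invisibly.
#' @export
plot_qq <- function(result, file, spec = plot_spec()) {
  env <- qq_envelope(result)
  pl <- ggplot2::ggplot(env, ggplot2::aes(x = expected)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo95, ymax = hi95),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo90, ymax = hi90),
                         fill = "grey65") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = observed)) +
    ggplot2::labs(x = "expected -log10(p)", y = "observed -log10(p)",
                  title = result$category) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file, pl, width = spec$width, height = spec$height,
                  dpi = spec$dpi)
  utils::write.csv(env, paste0(file, ".csv"), row.names = FALSE)
  invisible(env)
}

utils::globalVariables(c("x", "y", "xend", "yend", "expected", "observed",
                         "lo90", "hi90", "lo95", "hi95"))
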