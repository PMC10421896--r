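#' Build a thresholded functional network
#'
#' An undirected weighted graph over all atlas regions, with an edge wherever
#' the correlation is positive and its p-value is below the threshold. Edge
#' weight is the correlation coefficient `r`; a Fisher-transformed `zweight`
#' is attached too (coefficients numerically at 1 are clamped just below 1
#' before transforming). Isolated regions stay in the node set and are
#' flagged; significant negative correlations are counted as a diagnostic but
#' never become edges.
#'
#' @param corr A `fos_corr`.
#' @param p_threshold Significance threshold in (0, 1); default 0.05.
#' @return Object of class `fcnet`: list with the igraph `graph`, `condition`,
#'   `p_threshold`, `regions`, `isolates`, `n_negative_significant`.
#' @export
build_network <- function(corr, p_threshold = 0.05) {
  stopifnot(inherits(corr, "fos_corr"))
  if (!is.numeric(p_threshold) || length(p_threshold) != 1 ||
      p_threshold <= 0 || p_threshold >= 1) {
    stop("p_threshold must be a single number in (0, 1)")
  }
  regions <- corr$regions
  sig <- !is.na(corr$r) & !is.na(corr$p) & corr$p < p_threshold
  pos <- sig & corr$r > 0
  neg <- sig & corr$r < 0
  adj <- corr$r
  adj[!pos] <- 0
  adj[is.na(adj)] <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) {
    w <- igraph::E(g)$weight
    igraph::E(g)$zweight <- atanh(pmin(w, 1 - 1e-12))
  }
  deg <- igraph::degree(g)
  structure(
    list(graph = g, condition = corr$condition, p_threshold = p_threshold,
         regions = regions, isolates = regions[deg == 0],
         n_negative_significant = sum(neg[upper.tri(neg)])),
    class = "fcnet"
  )
}

#' @export
print.fcnet <- function(x, ...) {
  g <- x$graph
  cat("Functional network '", x$condition, "' (p < ", x$p_threshold, "): ",
      igraph::vcount(g), " regions, ", igraph::ecount(g), " edges, ",
      length(x$isolates), " isolated\n", sep = "")
  if (x$n_negative_significant > 0) {
    cat(x$n_negative_significant, "significant negative correlation(s) excluded\n")
  }
  invisible(x)
}

#' @export
plot.fcnet <- function(x, atlas = NULL, ...) {
  g <- x$graph
  if (!is.null(atlas)) {
    grp <- atlas$group[match(igraph::V(g)$name, atlas$code)]
    igraph::V(g)$color <- grDevices::rainbow(length(anatomical_groups()))[
      match(grp, anatomical_groups())]
  }
  deg <- igraph::degree(g)
  plot(g, vertex.size = 3 + 10 * deg / max(1, max(deg)),
       vertex.label.cex = 0.6,
       edge.width = if (igraph::ecount(g) > 0)
         2 * igraph::E(g)$weight / max(igraph::E(g)$weight) else 1, ...)
  invisible(x)
}

# unweighted shortest-path distance matrix of a network
net_distances <- function(net) {
  igraph::distances(net$graph, weights = NA)
}

#' Graph-level summary measures
#'
#' Density over connected (non-isolated) nodes and over all nodes; average
#' degree, average weighted degree (sum of r weights), average unweighted
#' local clustering coefficient (nodes with degree < 2 contribute 0), global
#' efficiency (mean of nodal efficiencies, unreachable pairs contributing 0),
#' per-node nodal efficiency `(1/(N-1)) * sum_j 1/d_ij`, average unweighted
#' shortest-path length over reachable pairs, and the maximum eccentricity
#' among connected nodes. Shortest paths count the minimum number of edges;
#' weights enter only the weighted degree.
#'
#' @param net A `fcnet`, or a bare igraph graph.
#' @return Object of class `fcnet_summary` (a list; node-level vectors under
#'   `nodal_efficiency`).
#' @export
graph_summary <- function(net) {
  g <- if (inherits(net, "fcnet")) net$graph else net
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  n_conn <- sum(deg > 0)
  dens <- function(k) if (k >= 2) m / (k * (k - 1) / 2) else NA_real_
  wdeg <- if (m > 0) igraph::strength(g) else stats::setNames(rep(0, n),
                                                              igraph::V(g)$name)
  cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  d <- igraph::distances(g, weights = NA)
  diag(d) <- Inf
  inv <- 1 / d
  nodal_eff <- if (n > 1) rowSums(inv) / (n - 1) else stats::setNames(0, igraph::V(g)$name)
  names(nodal_eff) <- igraph::V(g)$name
  reach <- is.finite(d)
  apl <- if (any(reach)) mean(d[reach]) else NA_real_
  ecc <- if (n_conn > 0) {
    dd <- d
    dd[!is.finite(dd)] <- NA
    max(apply(dd[deg > 0, deg > 0, drop = FALSE], 1, max, na.rm = TRUE))
  } else NA_real_
  structure(
    list(n_nodes = n, n_connected = n_conn, n_edges = m,
         density = dens(n_conn), density_all = dens(n),
         avg_degree = mean(deg), avg_weighted_degree = mean(wdeg),
         avg_clustering = if (n > 0) mean(cl) else NA_real_,
         global_efficiency = if (n > 0) mean(nodal_eff) else NA_real_,
         nodal_efficiency = nodal_eff,
         avg_path_length = apl, max_eccentricity = ecc,
         n_negative_significant = if (inherits(net, "fcnet"))
           net$n_negative_significant else NA_integer_),
    class = "fcnet_summary"
  )
}

#' @export
print.fcnet_summary <- function(x, ...) {
  cat(sprintf("nodes %d (connected %d), edges %d\n", x$n_nodes, x$n_connected,
              x$n_edges))
  cat(sprintf("density %.3f (all-node %.3f) | avg degree %.2f | avg wdeg %.2f\n",
              x$density, x$density_all, x$avg_degree, x$avg_weighted_degree))
  cat(sprintf("clustering %.3f | global eff %.3f | path length %.3f | ecc %s\n",
              x$avg_clustering, x$global_efficiency, x$avg_path_length,
              format(x$max_eccentricity)))
  invisible(x)
}

#' Node-level vectors of a summary measure
#'
#' @param net A `fcnet`.
#' @param measure One of `"degree"`, `"weighted_degree"`, `"clustering"`,
#'   `"nodal_efficiency"`.
#' @return Named numeric vector over nodes.
#' @export
node_measure <- function(net, measure = c("degree", "weighted_degree",
                                          "clustering", "nodal_efficiency")) {
  measure <- match.arg(measure)
  g <- net$graph
  switch(measure,
    degree = igraph::degree(g),
    weighted_degree = if (igraph::ecount(g) > 0) igraph::strength(g) else
      stats::setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name),
    clustering = stats::setNames(
      igraph::transitivity(g, type = "localundirected", isolates = "zero"),
      igraph::V(g)$name),
    nodal_efficiency = graph_summary(net)$nodal_efficiency
  )
}

#' Compare a summary measure between two networks
#'
#' Welch t on the node-level means and/or a two-sample Kolmogorov-Smirnov test
#' on the node-level distributions. Scalar-only measures (density, path
#' length) have no node-level vector; only their difference is reported.
#'
#' @param netA,netB `fcnet` objects.
#' @param measure A node-level measure name (see [node_measure()]), or
#'   `"density"` / `"avg_path_length"` for scalar-only comparison.
#' @param method Character subset of `c("welch", "ks")`.
#' @return List with `measure`, `mean_A`, `mean_B`, `difference` and, for
#'   node-level measures, `welch_p`, `ks_D`, `ks_p`.
#' @export
compare_summaries <- function(netA, netB, measure = "degree",
                              method = c("welch", "ks")) {
  node_level <- c("degree", "weighted_degree", "clustering", "nodal_efficiency")
  if (measure %in% node_level) {
    a <- node_measure(netA, measure)
    b <- node_measure(netB, measure)
    out <- list(measure = measure, mean_A = mean(a), mean_B = mean(b),
                difference = mean(a) - mean(b))
    if ("welch" %in% method) {
      out$welch_p <- tryCatch(stats::t.test(a, b)$p.value,
                              error = function(e) NA_real_)
    }
    if ("ks" %in% method) {
      ks <- suppressWarnings(stats::ks.test(a, b))
      out$ks_D <- unname(ks$statistic)
      out$ks_p <- ks$p.value
    }
    out
  } else {
    sa <- graph_summary(netA)
    sb <- graph_summary(netB)
    if (!measure %in% names(sa)) stop("unknown measure '", measure, "'")
    list(measure = measure, mean_A = sa[[measure]], mean_B = sb[[measure]],
         difference = sa[[measure]] - sb[[measure]])
  }
}

#' Export a network as GraphML and a weighted edge list
#'
#' @param net A `fcnet`.
#' @param prefix Path prefix; writes `<prefix>.graphml` and
#'   `<prefix>_edges.csv` (columns `src`, `dst`, `r`).
#' @return The two paths, invisibly.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "fcnet"))
  graphml <- paste0(prefix, ".graphml")
  igraph::write_graph(net$graph, graphml, format = "graphml")
  el <- igraph::as_edgelist(net$graph)
  edges <- data.frame(src = el[, 1], dst = el[, 2],
                      r = if (igraph::ecount(net$graph) > 0)
                        igraph::E(net$graph)$weight else numeric(0),
                      stringsAsFactors = FALSE)
  csv <- paste0(prefix, "_edges.csv")
  utils::write.csv(edges, csv, row.names = FALSE, quote = FALSE)
  invisible(c(graphml, csv))
}
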