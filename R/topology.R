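#' Community detection by modularity optimization
#'
#' Partitions a functional network into communities. The default algorithm is
#' multilevel (Louvain) modularity optimization on Fisher-Z edge weights;
#' leading-eigenvector is available as an alternative heuristic, and
#' `"exhaustive_small"` enumerates every partition of graphs with at most 10
#' nodes and returns the global modularity maximum (an oracle mode for small
#' graphs). Isolated nodes form singleton communities. An empty graph yields
#' the all-singleton partition with Q = 0.
#'
#' @param net A `fcnet` or igraph graph.
#' @param algorithm `"multilevel_louvain"` (default), `"leading_eigenvector"`
#'   or `"exhaustive_small"`.
#' @param weight_scheme Edge weights used in modularity: `"fisher_z"`
#'   (default), `"r"`, or `"unweighted"`.
#' @param seed Integer seed (heuristics are deterministic given the seed).
#' @return Object of class `fos_partition`: list with `membership` (named
#'   integer vector), `modularity`, `algorithm`, `weight_scheme`, `seed`.
#' @export
detect_communities <- function(net,
                               algorithm = c("multilevel_louvain",
                                             "leading_eigenvector",
                                             "exhaustive_small"),
                               weight_scheme = c("fisher_z", "r", "unweighted"),
                               seed = 1L) {
  algorithm <- match.arg(algorithm)
  weight_scheme <- match.arg(weight_scheme)
  g <- if (inherits(net, "fcnet")) net$graph else net
  w <- edge_weights(g, weight_scheme)
  if (igraph::ecount(g) == 0) {
    memb <- stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
    return(structure(list(membership = memb, modularity = 0,
                          algorithm = algorithm, weight_scheme = weight_scheme,
                          seed = seed),
                     class = "fos_partition"))
  }
  if (algorithm == "exhaustive_small") {
    res <- exhaustive_modularity(g, w)
    memb <- res$membership
    q <- res$modularity
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    comm <- if (algorithm == "multilevel_louvain") {
      igraph::cluster_louvain(g, weights = w)
    } else {
      igraph::cluster_leading_eigen(g, weights = w)
    }
    memb <- stats::setNames(igraph::membership(comm), igraph::V(g)$name)
    q <- igraph::modularity(g, memb, weights = w)
  }
  structure(list(membership = memb, modularity = q, algorithm = algorithm,
                 weight_scheme = weight_scheme, seed = seed),
            class = "fos_partition")
}

edge_weights <- function(g, weight_scheme) {
  if (igraph::ecount(g) == 0) return(NULL)
  switch(weight_scheme,
         fisher_z = igraph::E(g)$zweight,
         r = igraph::E(g)$weight,
         unweighted = rep(1, igraph::ecount(g)))
}

# enumerate all set partitions (restricted growth strings) of <= 10 nodes and
# return the modularity-maximizing membership
exhaustive_modularity <- function(g, w) {
  n <- igraph::vcount(g)
  if (n > 10) stop("exhaustive_small supports at most 10 nodes (got ", n, ")")
  best_q <- -Inf
  best <- NULL
  a <- integer(n)  # restricted growth string, 0-based
  recurse <- function(i, maxv) {
    if (i > n) {
      q <- igraph::modularity(g, a + 1L, weights = w)
      if (q > best_q) {
        best_q <<- q
        best <<- a + 1L
      }
      return(invisible(NULL))
    }
    for (v in 0:(maxv + 1L)) {
      a[i] <<- v
      recurse(i + 1L, max(maxv, v))
    }
  }
  a[1] <- 0L
  recurse(2L, 0L)
  if (n == 1) best <- 1L
  structure(list(membership = stats::setNames(best, igraph::V(g)$name),
                 modularity = best_q))
}

#' @export
print.fos_partition <- function(x, ...) {
  cat("Partition (", x$algorithm, ", ", x$weight_scheme, " weights): ",
      length(unique(x$membership)), " communities, Q = ",
      round(x$modularity, 4), "\n", sep = "")
  invisible(x)
}

#' Community composition by anatomical group
#'
#' Cross-tabulates community membership against anatomical groups, mirroring
#' per-community composition summaries.
#'
#' @param partition A `fos_partition`.
#' @param atlas A `fos_atlas`.
#' @return A contingency table, communities x anatomical groups.
#' @export
community_composition <- function(partition, atlas) {
  nodes <- names(partition$membership)
  grp <- factor(atlas$group[match(nodes, atlas$code)],
                levels = anatomical_groups())
  table(community = partition$membership, group = grp)
}

# within-community (unweighted) degree of every node
within_degree <- function(g, membership) {
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  adj[adj != 0] <- 1
  same <- outer(membership, membership, "==")
  stats::setNames(rowSums(adj * same), names(membership))
}

#' Within-community degree z-score
#'
#' `z_i = (kappa_i - mean_c) / sd_c`, where `kappa_i` is the node's number of
#' edges inside its own community and mean/sd are taken over the node's
#' community (population SD). Communities with zero SD (including singletons)
#' yield z = 0 by convention.
#'
#' @param net A `fcnet` or igraph graph.
#' @param partition A `fos_partition` covering the network.
#' @return Named numeric vector of z-scores.
#' @export
wc_zscore <- function(net, partition) {
  g <- if (inherits(net, "fcnet")) net$graph else net
  memb <- partition$membership[igraph::V(g)$name]
  if (any(is.na(memb))) stop("partition does not cover every network node")
  kin <- within_degree(g, memb)
  z <- numeric(length(kin))
  names(z) <- names(kin)
  for (cm in unique(memb)) {
    idx <- memb == cm
    k <- kin[idx]
    mu <- mean(k)
    sdp <- sqrt(mean((k - mu)^2))  # population SD
    z[idx] <- if (sdp > 0) (k - mu) / sdp else 0
  }
  z
}

#' Participation coefficient
#'
#' Guimera variant (default): `PC_i = 1 - sum_s (kappa_is / k_i)^2` over
#' communities s, using unweighted degrees. Simple-ratio variant:
#' `PC_i = 1 - kappa_i,own / k_i`. Isolated nodes score 0 in both.
#'
#' @param net A `fcnet` or igraph graph.
#' @param partition A `fos_partition`.
#' @param variant `"guimera"` (default) or `"simple_ratio"`.
#' @return Named numeric vector in `[0, 1]`.
#' @export
participation_coefficient <- function(net, partition,
                                      variant = c("guimera", "simple_ratio")) {
  variant <- match.arg(variant)
  g <- if (inherits(net, "fcnet")) net$graph else net
  memb <- partition$membership[igraph::V(g)$name]
  if (any(is.na(memb))) stop("partition does not cover every network node")
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  adj[adj != 0] <- 1
  k <- rowSums(adj)
  pc <- numeric(length(k))
  names(pc) <- names(memb)
  comms <- unique(memb)
  for (i in seq_along(k)) {
    if (k[i] == 0) next
    kis <- vapply(comms, function(cm) sum(adj[i, memb == cm]), numeric(1))
    if (variant == "guimera") {
      pc[i] <- 1 - sum((kis / k[i])^2)
    } else {
      pc[i] <- 1 - kis[match(memb[i], comms)] / k[i]
    }
  }
  pc
}

#' Classify provincial and connector hubs
#'
#' Provincial hubs have many within-community connections (WC z-score >= 1.5
#' and PC <= 0.3); connector hubs distribute their connections across
#' communities (PC >= 0.8 and WC z-score <= 1.5). Nodes satisfying neither
#' exclusive rule (including those nominally matching both) are `"neither"`.
#'
#' @param wc Named WC z-score vector.
#' @param pc Named participation-coefficient vector (same nodes).
#' @param wc_cut,pc_provincial,pc_connector Classification thresholds.
#' @return data.frame with `node`, `wc_zscore`, `pc`, `role`.
#' @export
classify_roles <- function(wc, pc, wc_cut = 1.5, pc_provincial = 0.3,
                           pc_connector = 0.8) {
  stopifnot(identical(names(wc), names(pc)))
  provincial <- wc >= wc_cut & pc <= pc_provincial
  connector <- pc >= pc_connector & wc <= wc_cut
  role <- ifelse(provincial, "provincial",
                 ifelse(connector, "connector", "neither"))
  data.frame(node = names(wc), wc_zscore = unname(wc), pc = unname(pc),
             role = role, stringsAsFactors = FALSE)
}

#' Four node centrality measures
#'
#' Weighted degree (sum of edge weights), eigenvector centrality (principal
#' eigenvector of the weighted adjacency, computed per connected component and
#' scaled to maximum 1 within each component), betweenness (unnormalized, on
#' unweighted shortest paths) and closeness (number of reachable nodes divided
#' by the sum of unweighted shortest-path distances to them). Isolated nodes
#' score 0 in every measure.
#'
#' @param net A `fcnet` or igraph graph.
#' @param weight_scheme Weights for the weighted degree and eigenvector:
#'   `"r"` (default, the literal sum-of-coefficients definition) or
#'   `"fisher_z"`.
#' @return data.frame of class `fos_centrality` with columns `node`, `wdg`,
#'   `evc`, `bet`, `clo`.
#' @export
centralities <- function(net, weight_scheme = c("r", "fisher_z")) {
  weight_scheme <- match.arg(weight_scheme)
  g <- if (inherits(net, "fcnet")) net$graph else net
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  w <- edge_weights(g, weight_scheme)
  wdg <- if (igraph::ecount(g) > 0) {
    igraph::strength(g, weights = w)
  } else rep(0, n)
  # eigenvector centrality per connected component
  evc <- rep(0, n)
  comp <- igraph::components(g)
  adj <- matrix(0, n, n)
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    for (e in seq_len(nrow(el))) {
      adj[el[e, 1], el[e, 2]] <- w[e]
      adj[el[e, 2], el[e, 1]] <- w[e]
    }
  }
  for (cm in seq_len(comp$no)) {
    idx <- which(comp$membership == cm)
    if (length(idx) < 2) next
    sub <- adj[idx, idx, drop = FALSE]
    es <- eigen(sub, symmetric = TRUE)
    v <- abs(es$vectors[, 1])
    evc[idx] <- v / max(v)
  }
  bet <- igraph::betweenness(g, weights = NA, normalized = FALSE)
  d <- igraph::distances(g, weights = NA)
  diag(d) <- Inf
  clo <- apply(d, 1, function(row) {
    reach <- is.finite(row)
    if (!any(reach)) 0 else sum(reach) / sum(row[reach])
  })
  out <- data.frame(node = nodes, wdg = unname(wdg), evc = evc,
                    bet = unname(bet), clo = unname(clo),
                    stringsAsFactors = FALSE)
  class(out) <- c("fos_centrality", "data.frame")
  attr(out, "weight_scheme") <- weight_scheme
  out
}

#' Identify centrality hubs
#'
#' Per measure, flags the top `floor(N * top_fraction)` nodes by value
#' (descending; ties ordered by value then lexicographic node code, and ties
#' at the cutoff value expand the flagged list, with the expansion reported).
#' A node flagged in at least `min_measures` measures is a hub.
#'
#' @param table A `fos_centrality`.
#' @param top_fraction Fraction of nodes per measure list (default 0.25).
#' @param min_measures Minimum number of measures (default 3).
#' @return List of class `fos_hubs`: `hubs` (character), `flags` (logical
#'   matrix nodes x measures), `n_flagged` (per measure, including tie
#'   expansion), `top_n` (nominal list length), `ranks` (matrix of descending
#'   ranks).
#' @export
identify_hubs <- function(table, top_fraction = 0.25, min_measures = 3) {
  stopifnot(inherits(table, "fos_centrality"))
  measures <- c("wdg", "evc", "bet", "clo")
  n <- nrow(table)
  top_n <- floor(n * top_fraction)
  flags <- matrix(FALSE, n, length(measures),
                  dimnames = list(table$node, measures))
  ranks <- flags
  storage.mode(ranks) <- "double"
  for (msr in measures) {
    val <- table[[msr]]
    ord <- order(-val, table$node)
    ranks[, msr] <- order(ord)  # descending rank, ties by code
    if (top_n >= 1) {
      cutoff <- val[ord[top_n]]
      flags[, msr] <- val >= cutoff
    }
  }
  hubs <- rownames(flags)[rowSums(flags) >= min_measures]
  structure(
    list(hubs = sort(hubs), flags = flags, n_flagged = colSums(flags),
         top_n = top_n, ranks = ranks, top_fraction = top_fraction,
         min_measures = min_measures),
    class = "fos_hubs"
  )
}

#' @export
print.fos_hubs <- function(x, ...) {
  cat("Hubs (top", x$top_n, "per measure, >=", x$min_measures, "measures):",
      if (length(x$hubs) > 0) paste(x$hubs, collapse = ", ") else "(none)", "\n")
  expanded <- x$n_flagged[x$n_flagged > x$top_n]
  if (length(expanded) > 0) {
    cat("tie expansion in:", paste(names(expanded), "(", expanded, ")"), "\n")
  }
  invisible(x)
}

#' Stable hubs across thresholds
#'
#' Intersection of two or more hub sets (e.g., the hub sets of the same
#' condition's networks at different p thresholds).
#'
#' @param ... Character vectors of hub codes, `fos_hubs` objects, or a single
#'   list of either.
#' @return Sorted character vector.
#' @export
stable_hubs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "fos_hubs")) {
    sets <- sets[[1]]
  }
  sets <- lapply(sets, function(s) if (inherits(s, "fos_hubs")) s$hubs else
    as.character(s))
  if (length(sets) < 2) stop("need at least two hub sets")
  sort(Reduce(intersect, sets))
}
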