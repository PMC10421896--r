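# Brute-force graph oracles, written independently of the package internals.
# All take a symmetric weighted adjacency matrix (0 = no edge).

bf_distances <- function(adj) {
  # Floyd-Warshall on unweighted edges
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj != 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

bf_betweenness <- function(adj) {
  # count all shortest paths by DFS enumeration of simple paths
  n <- nrow(adj)
  d <- bf_distances(adj)
  bet <- numeric(n)
  paths_through <- function(src, dst) {
    # enumerate all shortest src->dst paths, return interior-node counts
    res <- numeric(n)
    total <- 0
    walk <- function(node, visited, len) {
      if (node == dst) {
        total <<- total + 1
        interior <- setdiff(visited, c(src, dst))
        res[interior] <<- res[interior] + 1
        return(invisible(NULL))
      }
      if (len >= d[src, dst]) return(invisible(NULL))
      for (nb in which(adj[node, ] != 0)) {
        if (nb %in% visited) next
        if (d[src, nb] == len + 1 && d[nb, dst] == d[src, dst] - len - 1) {
          walk(nb, c(visited, nb), len + 1)
        }
      }
    }
    walk(src, src, 0)
    list(counts = res, total = total)
  }
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      if (!is.finite(d[s, t]) || d[s, t] == 0) next
      pt <- paths_through(s, t)
      if (pt$total > 0) bet <- bet + pt$counts / pt$total
    }
  }
  bet
}

bf_closeness <- function(adj) {
  d <- bf_distances(adj)
  diag(d) <- Inf
  apply(d, 1, function(row) {
    reach <- is.finite(row)
    if (!any(reach)) 0 else sum(reach) / sum(row[reach])
  })
}

bf_evc <- function(adj) {
  # power iteration per connected component, max 1 within each component
  n <- nrow(adj)
  d <- bf_distances(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[is.finite(d[i, ])] <- cid
    }
  }
  evc <- numeric(n)
  for (cm in unique(comp)) {
    idx <- which(comp == cm)
    if (length(idx) < 2) next
    sub <- adj[idx, idx, drop = FALSE]
    # spectral shift keeps the Perron vector but makes the dominant
    # eigenvalue unique (power iteration oscillates on bipartite graphs)
    shift <- max(rowSums(sub)) + 1
    sub <- sub + diag(shift, length(idx))
    v <- rep(1, length(idx))
    for (it in 1:200000) {
      v2 <- as.vector(sub %*% v)
      v2 <- v2 / sqrt(sum(v2^2))
      if (max(abs(v2 - v)) < 1e-15) break
      v <- v2
    }
    v <- abs(v)
    evc[idx] <- v / max(v)
  }
  evc
}

bf_clustering <- function(adj) {
  # unweighted local clustering; degree < 2 scores 0
  a <- (adj != 0) * 1
  n <- nrow(a)
  sapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(a[nb, nb]) / (k * (k - 1))
  })
}

bf_efficiency <- function(adj) {
  d <- bf_distances(adj)
  diag(d) <- Inf
  n <- nrow(adj)
  nodal <- rowSums(1 / d) / (n - 1)
  list(nodal = nodal, global = mean(nodal))
}

bf_path_length <- function(adj) {
  d <- bf_distances(adj)
  diag(d) <- Inf
  mean(d[is.finite(d)])
}

bf_wc_zscore <- function(adj, membership) {
  a <- (adj != 0) * 1
  kin <- sapply(seq_len(nrow(a)), function(i) sum(a[i, membership == membership[i]]))
  z <- numeric(length(kin))
  for (cm in unique(membership)) {
    idx <- membership == cm
    mu <- mean(kin[idx])
    sdp <- sqrt(mean((kin[idx] - mu)^2))
    z[idx] <- if (sdp > 0) (kin[idx] - mu) / sdp else 0
  }
  z
}

bf_pc <- function(adj, membership, variant = "guimera") {
  a <- (adj != 0) * 1
  k <- rowSums(a)
  sapply(seq_len(nrow(a)), function(i) {
    if (k[i] == 0) return(0)
    kis <- tapply(a[i, ], membership, sum)
    if (variant == "guimera") 1 - sum((kis / k[i])^2)
    else 1 - kis[[as.character(membership[i])]] / k[i]
  })
}

# modularity from the definition: Q = sum_c (e_c / m - (deg_c / 2m)^2), weights
bf_modularity <- function(adj, membership) {
  w <- adj
  m2 <- sum(w)  # 2m for symmetric matrix
  if (m2 == 0) return(0)
  q <- 0
  for (cm in unique(membership)) {
    idx <- membership == cm
    e_in <- sum(w[idx, idx])          # counts both directions
    deg <- sum(w[idx, ])
    q <- q + e_in / m2 - (deg / m2)^2
  }
  q
}

# all set partitions of n elements as membership vectors (restricted growth)
bf_partitions <- function(n) {
  out <- list()
  a <- integer(n)
  rec <- function(i, maxv) {
    if (i > n) {
      out[[length(out) + 1]] <<- a + 1L
      return(invisible(NULL))
    }
    for (v in 0:(maxv + 1L)) {
      a[i] <<- v
      rec(i + 1L, max(maxv, v))
    }
  }
  rec(2L, 0L)
  out
}

bf_best_partition <- function(adj) {
  parts <- bf_partitions(nrow(adj))
  qs <- vapply(parts, function(p) bf_modularity(adj, p), numeric(1))
  list(membership = parts[[which.max(qs)]], modularity = max(qs))
}

# random connected-ish weighted graph as adjacency matrix
random_adj <- function(n, p_edge = 0.4, weighted = TRUE) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) {
        w <- if (weighted) stats::runif(1, 0.2, 1) else 1
        a[i, j] <- a[j, i] <- w
      }
    }
  }
  a
}

# wrap an adjacency matrix as an fcnet-compatible igraph for package calls
graph_from_adj <- function(adj) {
  rownames(adj) <- colnames(adj) <- paste0("n", sprintf("%02d", seq_len(nrow(adj))))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$zweight <- atanh(pmin(igraph::E(g)$weight, 1 - 1e-12))
  }
  g
}

# small expression fixture: n animals per condition, given region count
make_expr <- function(n_regions = 6, conds = c("A", "B"), n = 6, seed = 1,
                      groups = NULL) {
  set.seed(seed)
  if (is.null(groups)) {
    groups <- rep(anatomical_groups(), length.out = n_regions)
  }
  atl <- fos_atlas(data.frame(code = paste0("R", seq_len(n_regions)),
                              name = paste0("region ", seq_len(n_regions)),
                              group = groups))
  vals <- matrix(stats::rlnorm(n * length(conds) * n_regions, 4, 0.3),
                 n * length(conds), n_regions,
                 dimnames = list(NULL, atl$code))
  fos_expression(vals, rep(conds, each = n), atl)
}
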