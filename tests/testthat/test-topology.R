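test_that("two cliques joined by one edge are recovered by both heuristic and oracle", {
  adj <- matrix(0, 10, 10)
  adj[1:5, 1:5] <- 1
  adj[6:10, 6:10] <- 1
  diag(adj) <- 0
  adj[5, 6] <- adj[6, 5] <- 1
  g <- graph_from_adj(adj)
  louvain <- detect_communities(g, "multilevel_louvain", seed = 1)
  exact <- detect_communities(g, "exhaustive_small")
  truth <- rep(1:2, each = 5)
  expect_equal(unname(as.integer(factor(louvain$membership))), truth)
  expect_equal(unname(as.integer(factor(exact$membership))), truth)
  expect_equal(louvain$modularity, exact$modularity, tolerance = 1e-12)
  # and the exhaustive optimum agrees with the test-local enumeration
  bf <- bf_best_partition(adj)
  expect_equal(exact$modularity, bf$modularity, tolerance = 1e-9)
})

test_that("exhaustive modularity maximization matches brute-force enumeration", {
  set.seed(303)
  for (rep in 1:12) {
    n <- sample(4:7, 1)
    adj <- random_adj(n, p_edge = 0.5)
    if (all(adj == 0)) next
    exact <- detect_communities(graph_from_adj(adj), "exhaustive_small",
                                weight_scheme = "r")
    bf <- bf_best_partition(adj)
    expect_equal(exact$modularity, bf$modularity, tolerance = 1e-9)
    expect_equal(bf_modularity(adj, exact$membership), exact$modularity,
                 tolerance = 1e-9)
  }
})

test_that("forced single community has Q = 0; empty graph gives singletons", {
  adj <- random_adj(6, p_edge = 0.5)
  expect_equal(bf_modularity(adj, rep(1, 6)), 0)
  g <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g)$name <- paste0("R", 1:4)
  part <- detect_communities(g, "multilevel_louvain")
  expect_equal(part$modularity, 0)
  expect_equal(length(unique(part$membership)), 4)
})

test_that("partition modularity is at least the one-community baseline", {
  for (s in 1:8) {
    expr <- make_expr(n_regions = 10, conds = "A", n = 11, seed = 600 + s)
    net <- build_network(correlation_matrix(expr, "A"), 0.05)
    if (igraph::ecount(net$graph) == 0) next
    part <- detect_communities(net, seed = 1)
    expect_gte(part$modularity, 0)
  }
})

test_that("community detection recovers planted correlation blocks (ARI >= 0.9)", {
  skip_if_not_installed("mclust")
  atl <- default_atlas()
  blocks <- split(atl$code, rep(1:3, c(16, 16, 17)))
  truth <- rep(1:3, c(16, 16, 17))
  ari <- vapply(1:10, function(s) {
    spec <- cohort_spec(condition_design("A", 11, "A"), atl, 100, 30,
                        coupling_blocks = lapply(1:3, function(k)
                          list(condition = "A", regions = blocks[[k]],
                               rho = 0.8)),
                        rho0 = 0.1, seed = s)
    net <- build_network(correlation_matrix(generate_cohort(spec), "A"), 0.05)
    part <- detect_communities(net, seed = 1)
    mclust::adjustedRandIndex(part$membership[atl$code], truth)
  }, numeric(1))
  expect_gte(mean(ari >= 0.9), 0.9)
})

test_that("WC z-score matches hand computation and the sd = 0 convention", {
  # star inside community {1,2,3,4}: within-degrees 3,1,1,1
  adj <- matrix(0, 6, 6)
  adj[1, 2:4] <- adj[2:4, 1] <- 1
  adj[5, 6] <- adj[6, 5] <- 1
  g <- graph_from_adj(adj)
  part <- structure(list(membership = stats::setNames(c(1, 1, 1, 1, 2, 2),
                                                      igraph::V(g)$name)),
                    class = "fos_partition")
  z <- wc_zscore(g, part)
  expect_equal(unname(z[1]), 1.732, tolerance = 1e-3)      # (3-1.5)/0.866
  expect_equal(unname(z[2]), -0.577, tolerance = 1e-3)
  expect_equal(unname(z[5]), 0)  # equal within-degrees -> sd 0 -> z 0
  # adding an edge between the two other communities leaves node 1 unchanged
  adj2 <- adj
  adj2[4, 5] <- adj2[5, 4] <- 1
  z2 <- wc_zscore(graph_from_adj(adj2), part)
  expect_equal(z2[1], z[1])
})

test_that("WC z-scores and PC match brute-force oracles on random graphs", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    adj <- random_adj(n, p_edge = 0.5)
    g <- graph_from_adj(adj)
    memb <- sample(1:3, n, replace = TRUE)
    part <- structure(list(membership = stats::setNames(memb,
                                                        igraph::V(g)$name)),
                      class = "fos_partition")
    expect_equal(unname(wc_zscore(g, part)), bf_wc_zscore(adj, memb),
                 tolerance = 1e-9)
    expect_equal(unname(participation_coefficient(g, part, "guimera")),
                 unname(bf_pc(adj, memb, "guimera")), tolerance = 1e-9)
    expect_equal(unname(participation_coefficient(g, part, "simple_ratio")),
                 unname(bf_pc(adj, memb, "simple_ratio")), tolerance = 1e-9)
  }
})

test_that("participation coefficient closed forms hold", {
  # degree 4: two edges in own community, one in each of two others
  adj <- matrix(0, 7, 7)
  adj[1, 2:5] <- adj[2:5, 1] <- 1
  g <- graph_from_adj(adj)
  memb <- c(1, 1, 1, 2, 3, 2, 3)
  part <- structure(list(membership = stats::setNames(memb, igraph::V(g)$name)),
                    class = "fos_partition")
  pc_g <- participation_coefficient(g, part, "guimera")
  pc_s <- participation_coefficient(g, part, "simple_ratio")
  expect_equal(unname(pc_g[1]), 0.625)
  expect_equal(unname(pc_s[1]), 0.5)
  # all edges inside own community -> 0 in both variants
  memb_all <- rep(1, 7)
  part_all <- structure(list(membership = stats::setNames(memb_all,
                                                          igraph::V(g)$name)),
                        class = "fos_partition")
  expect_true(all(participation_coefficient(g, part_all, "guimera") == 0))
  expect_true(all(participation_coefficient(g, part_all, "simple_ratio") == 0))
  # edges spread equally over m communities -> guimera PC = 1 - 1/m
  adj_m <- matrix(0, 4, 4)
  adj_m[1, 2:4] <- adj_m[2:4, 1] <- 1
  gm <- graph_from_adj(adj_m)
  part_m <- structure(list(membership = stats::setNames(c(1, 2, 3, 4),
                                                        igraph::V(gm)$name)),
                      class = "fos_partition")
  pcm <- participation_coefficient(gm, part_m, "guimera")
  expect_equal(unname(pcm[1]), 1 - 1 / 3)
})

test_that("role classification follows the exclusive threshold rules", {
  wc <- c(a = 0.670, b = 1.835, c = 1.6, d = 0.2)
  pc <- c(a = 0.912, b = 0.000, c = 0.9, d = 0.5)
  roles <- classify_roles(wc, pc)
  expect_equal(roles$role, c("connector", "provincial", "neither", "neither"))
  # boundary values belong to the rules (>= / <=)
  r2 <- classify_roles(c(x = 1.5), c(x = 0.3))
  expect_equal(r2$role, "provincial")
})

test_that("centralities match closed forms on the 5-node star", {
  adj <- matrix(0, 5, 5)
  adj[1, 2:5] <- adj[2:5, 1] <- 0.5
  ct <- centralities(graph_from_adj(adj))
  expect_equal(ct$bet[1], 6)
  expect_equal(ct$clo[1], 1)
  expect_equal(ct$clo[2], 4 / 7)
  expect_equal(ct$evc[1], 1)
  expect_equal(ct$wdg[1], 2)
})

test_that("regular graphs have all-equal eigenvector centrality 1", {
  ring <- matrix(0, 6, 6)
  for (i in 1:6) {
    j <- i %% 6 + 1
    ring[i, j] <- ring[j, i] <- 1
  }
  ct <- centralities(graph_from_adj(ring))
  expect_equal(ct$evc, rep(1, 6))
})

test_that("all four centralities match brute-force oracles on random graphs", {
  set.seed(505)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    adj <- random_adj(n, p_edge = runif(1, 0.25, 0.7))
    ct <- centralities(graph_from_adj(adj))
    expect_equal(ct$wdg, rowSums(adj), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(ct$evc, bf_evc(adj), tolerance = 1e-9)
    expect_equal(ct$bet, bf_betweenness(adj), tolerance = 1e-9)
    expect_equal(ct$clo, bf_closeness(adj), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("hub rule flags top-quartile membership in >= 3 measures", {
  expr <- make_expr(n_regions = 12, conds = "A", n = 11, seed = 888)
  net <- build_network(correlation_matrix(expr, "A"), 0.05)
  ct <- centralities(net)
  hubs <- identify_hubs(ct, top_fraction = 0.25, min_measures = 3)
  expect_equal(hubs$top_n, 3)  # floor(12 * 0.25)
  expect_equal(sum(rowSums(hubs$flags) >= 3), length(hubs$hubs))
  # a node flagged in only 2 measures is not a hub
  two <- rownames(hubs$flags)[rowSums(hubs$flags) == 2]
  expect_true(all(!two %in% hubs$hubs))
  # N = 49 gives 12-node lists
  expect_equal(floor(49 * 0.25), 12)
  # a node ranked first everywhere is always a hub
  best <- ct
  best[best$node == "R1", c("wdg", "evc", "bet", "clo")] <-
    apply(ct[, c("wdg", "evc", "bet", "clo")], 2, max) + 1
  expect_true("R1" %in% identify_hubs(best)$hubs)
})

test_that("hub identification is invariant to node relabeling", {
  expr <- make_expr(n_regions = 10, conds = "A", n = 11, seed = 999)
  net <- build_network(correlation_matrix(expr, "A"), 0.05)
  ct <- centralities(net)
  hubs1 <- identify_hubs(ct)
  perm <- sample(nrow(ct))
  ct2 <- ct[perm, ]
  hubs2 <- identify_hubs(ct2)
  expect_setequal(hubs1$hubs, hubs2$hubs)
})

test_that("stable hubs are set intersections", {
  expect_setequal(stable_hubs(c("A", "B", "C"), c("B", "C", "D")), c("B", "C"))
  expect_length(stable_hubs(c("A"), c("B")), 0)
  expect_setequal(stable_hubs(c("A", "B"), c("A", "B")), c("A", "B"))
  expect_error(stable_hubs(c("A")), "at least two")
})

test_that("a globally coupled region becomes a centrality hub", {
  atl <- default_atlas()
  star <- "BLAa"
  others <- setdiff(atl$code, star)
  blocks <- lapply(others, function(r)
    list(condition = "A", regions = c(star, r), rho = 0.55))
  hits <- vapply(1:10, function(s) {
    spec <- cohort_spec(condition_design("A", 11, "A"), atl, 100, 30,
                        coupling_blocks = blocks, rho0 = 0.3, seed = s)
    net <- build_network(correlation_matrix(generate_cohort(spec), "A"), 0.05)
    star %in% identify_hubs(centralities(net))$hubs
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("community composition cross-tabulates membership by group", {
  expr <- make_expr(n_regions = 6, conds = "A", n = 11, seed = 123,
                    groups = rep(c("AMY", "TAL"), each = 3))
  net <- build_network(correlation_matrix(expr, "A"), 0.05)
  part <- detect_communities(net, seed = 1)
  comp <- community_composition(part, expr$atlas)
  expect_equal(sum(comp), 6)
  expect_equal(unname(colSums(comp)[c("AMY", "TAL")]), c(3, 3))
})
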