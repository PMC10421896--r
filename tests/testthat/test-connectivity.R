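test_that("correlation matrix matches the t-transform p-values", {
  expr <- make_expr(n_regions = 5, conds = "A", n = 11, seed = 1)
  corr <- correlation_matrix(expr, "A")
  expect_true(isSymmetric(corr$r))
  expect_true(isSymmetric(corr$p))
  expect_true(all(corr$n == 11))
  # independent check of one pair against cor.test
  ct <- cor.test(expr$values[, 1], expr$values[, 2])
  expect_equal(corr$r[1, 2], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(corr$p[1, 2], ct$p.value, tolerance = 1e-12)
  # at n = 11, r = 0.6021 sits exactly at the two-sided p = 0.05 boundary
  r_crit <- 0.6021
  t <- r_crit * sqrt(9) / sqrt(1 - r_crit^2)
  expect_equal(2 * pt(-t, 9), 0.05, tolerance = 1e-3)
})

test_that("an exact linear copy of a region correlates at r = 1", {
  expr <- make_expr(n_regions = 4, conds = "A", n = 8, seed = 2)
  expr$values[, 2] <- 3 * expr$values[, 1] + 5
  corr <- correlation_matrix(expr, "A")
  expect_equal(corr$r[1, 2], 1, tolerance = 1e-12)
  expect_equal(corr$p[1, 2], 0)
})

test_that("null correlations reject at the nominal 5% rate", {
  set.seed(71)
  n <- 11
  r_crit <- sqrt(qt(0.975, n - 2)^2 / (qt(0.975, n - 2)^2 + n - 2))
  hits <- replicate(5000, abs(cor(rnorm(n), rnorm(n))) > r_crit)
  expect_lt(abs(mean(hits) - 0.05), 0.01)
})

test_that("zero-variance regions are marked undefined with a warning", {
  expr <- make_expr(n_regions = 4, conds = "A", n = 8, seed = 3)
  expr$values[, 3] <- 42
  expect_warning(corr <- correlation_matrix(expr, "A"), "R3")
  expect_true(corr$undefined[["R3"]])
  expect_true(all(is.na(corr$r[3, ])))
  expect_false(any(is.na(corr$r[-3, -3][upper.tri(diag(3))])))
})

test_that("missing values use pairwise-complete observations with recorded n", {
  expr <- make_expr(n_regions = 4, conds = "A", n = 10, seed = 4)
  expr$values[1:2, 2] <- NA
  corr <- correlation_matrix(expr, "A")
  expect_equal(corr$n[1, 2], 8)
  expect_equal(corr$n[1, 3], 10)
  keep <- !is.na(expr$values[, 2])
  expect_equal(corr$r[1, 2],
               cor(expr$values[keep, 1], expr$values[keep, 2]),
               tolerance = 1e-12)
})

test_that("correlations are invariant under per-region affine rescaling", {
  expr <- make_expr(n_regions = 5, conds = "A", n = 9, seed = 5)
  scaled <- expr
  scaled$values <- sweep(sweep(expr$values, 2, c(2, 3, 0.5, 10, 1), "*"),
                         2, c(0, 5, 1, 2, 0), "+")
  expect_equal(correlation_matrix(scaled, "A")$r,
               correlation_matrix(expr, "A")$r, tolerance = 1e-10)
})

test_that("fisher_z is the closed-form inverse hyperbolic tangent", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.981), 0.5 * log(1.981 / 0.019), tolerance = 1e-12)
  expect_equal(fisher_z(0.981), 2.323, tolerance = 1e-3)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1), ">= 1")
  expect_error(fisher_z(-1.2), ">= 1")
})

test_that("edge_difference reproduces the reported amygdala pair", {
  # the strongest between-condition edge change: r = 0.981 vs r = 0.345
  ed_raw <- edge_difference(0.981, 11, 0.345, 11, mode = "raw")
  expect_equal(ed_raw$statistic, 1.96, tolerance = 0.01)
  # the raw difference sits just under the literal >= 2 cutoff
  expect_false(ed_raw$significant)
  ed_std <- edge_difference(0.981, 11, 0.345, 11, mode = "standardized")
  expect_equal(ed_std$statistic, 3.93, tolerance = 0.01)
  expect_true(ed_std$significant)
})

test_that("edge_difference is null at equality and antisymmetric", {
  for (mode in c("raw", "standardized")) {
    ed <- edge_difference(0.5, 11, 0.5, 11, mode = mode)
    expect_equal(ed$statistic, 0)
    expect_false(ed$significant)
    a <- edge_difference(0.7, 11, 0.2, 12, mode = mode)
    b <- edge_difference(0.2, 12, 0.7, 11, mode = mode)
    expect_equal(a$statistic, -b$statistic)
  }
  expect_error(edge_difference(1, 11, 0.3, 11), "|r| < 1")
  expect_error(edge_difference(0.5, 3, 0.3, 11), "n1, n2 > 3")
})

test_that("standardized edge difference is calibrated under the null", {
  set.seed(5150)
  rho <- 0.3
  n <- 11
  L <- chol(matrix(c(1, rho, rho, 1), 2))
  rej <- replicate(5000, {
    r1 <- cor(matrix(rnorm(2 * n), n, 2) %*% L)[1, 2]
    r2 <- cor(matrix(rnorm(2 * n), n, 2) %*% L)[1, 2]
    edge_difference(r1, n, r2, n)$significant
  })
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("group connectivity enumerates the right scopes and pair counts", {
  spec <- reference_cohort_spec(seed = 17)
  expr <- generate_cohort(spec)
  corr <- correlation_matrix(expr, "CFC")
  gc <- group_connectivity(corr, spec$atlas)
  expect_equal(sum(gc$scope == "internal"), 9)
  expect_equal(sum(gc$scope == "external"), 9)
  expect_equal(sum(gc$scope == "pairwise"), 36)
  sizes <- table(spec$atlas$group)
  for (g in names(sizes)) {
    expect_equal(gc$n_pairs[gc$scope == "internal" & gc$group1 == g],
                 unname(sizes[g] * (sizes[g] - 1) / 2))
    expect_equal(gc$n_pairs[gc$scope == "external" & gc$group1 == g],
                 unname(sizes[g] * (49 - sizes[g])))
  }
  expect_equal(gc$n_pairs[gc$scope == "pairwise" & gc$group1 == "AMY" &
                          gc$group2 == "DH"], 11 * 3)
  # brute-force check of one internal mean
  amy <- spec$atlas$code[spec$atlas$group == "AMY"]
  sub <- corr$r[amy, amy]
  expect_equal(gc$mean_r[gc$scope == "internal" & gc$group1 == "AMY"],
               mean(sub[upper.tri(sub)]), tolerance = 1e-12)
})

test_that("a constant correlation matrix gives every scope that mean", {
  expr <- make_expr(n_regions = 6, conds = "A", n = 8, seed = 6,
                    groups = rep(c("AMY", "TAL", "DH"), each = 2))
  corr <- correlation_matrix(expr, "A")
  corr$r[] <- 0.4
  diag(corr$r) <- NA
  gc <- group_connectivity(corr, expr$atlas)
  expect_true(all(abs(gc$mean_r - 0.4) < 1e-12))
})

test_that("identical matrices compare as not different; planted AMY difference rejects", {
  expr <- make_expr(n_regions = 6, conds = "A", n = 10, seed = 7,
                    groups = rep(c("AMY", "TAL"), each = 3))
  corr <- correlation_matrix(expr, "A")
  cmp <- compare_group_connectivity(corr, corr, expr$atlas,
                                    method = "coefficient_permutation",
                                    n_perm = 199, seed = 1)
  expect_true(all(cmp$p > 0.9, na.rm = TRUE))
  cmp_w <- compare_group_connectivity(corr, corr, expr$atlas)
  expect_true(all(cmp_w$p > 0.99, na.rm = TRUE))

  atl <- default_atlas()
  amy <- atl$code[atl$group == "AMY"]
  des <- condition_design(c("A", "B"), c(11, 11), "A")
  hits <- vapply(1:20, function(s) {
    spec <- cohort_spec(des, atl, base_mean = 100, base_sd = 30,
                        coupling_blocks = list(
                          list(condition = "A", regions = amy, rho = 0.9),
                          list(condition = "B", regions = amy, rho = 0.3)),
                        rho0 = 0.2, seed = s)
    expr2 <- generate_cohort(spec)
    cmp2 <- compare_group_connectivity(correlation_matrix(expr2, "A"),
                                       correlation_matrix(expr2, "B"), atl)
    p <- cmp2$p[cmp2$scope == "internal" & cmp2$group1 == "AMY"]
    a <- cmp2$mean_A[cmp2$scope == "internal" & cmp2$group1 == "AMY"]
    b <- cmp2$mean_B[cmp2$scope == "internal" & cmp2$group1 == "AMY"]
    !is.na(p) && p < 0.05 && a > b
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("activity-connectivity association has calibrated p and exact extremes", {
  # r_ij = (m_i + m_j) scaled makes each region's mean r affine in its mean
  # expression, so the across-region correlation is exactly 1
  expr <- make_expr(n_regions = 8, conds = "A", n = 10, seed = 8)
  corr <- correlation_matrix(expr, "A")
  mean_expr <- colMeans(condition_values(expr, "A"))
  corr$r <- outer(mean_expr, mean_expr, "+") / (4 * max(mean_expr))
  rownames(corr$r) <- colnames(corr$r) <- corr$regions
  diag(corr$r) <- NA
  assoc <- activity_connectivity_association(corr, expr)
  expect_equal(assoc["mean_r", "estimate"], 1, tolerance = 1e-10)
  # the reported weak association: n = 49 regions, r = 0.057 -> p ~ 0.70
  t <- 0.057 * sqrt(47) / sqrt(1 - 0.057^2)
  expect_equal(2 * pt(-abs(t), 47), 0.70, tolerance = 0.01)
})

test_that("independent expression and connectivity show no association", {
  assoc_r <- vapply(1:30, function(s) {
    expr <- make_expr(n_regions = 10, conds = "A", n = 12, seed = 100 + s)
    corr <- correlation_matrix(expr, "A")
    activity_connectivity_association(corr, expr)["mean_r", "estimate"]
  }, numeric(1))
  expect_lt(abs(mean(assoc_r)), 0.15)
})
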