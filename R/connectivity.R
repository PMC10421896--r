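#' Per-condition inter-regional correlation matrix
#'
#' Pearson correlation of regional expression across the animals of one
#' condition, with two-sided p-values from the exact t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom, and
#' the pairwise-complete animal count per pair. Regions with zero variance
#' (or fewer than 4 complete observations against every partner) are marked
#' undefined (`NA` row/column) with a warning, never silently set to 0.
#'
#' @param expr A `fos_expression`.
#' @param condition Condition label (needs n >= 4 animals).
#' @return Object of class `fos_corr`: list with `condition`, `regions`,
#'   symmetric matrices `r`, `p`, `n` (diagonal `NA` for r/p), and
#'   `undefined`, a logical vector marking zero-variance regions.
#' @export
correlation_matrix <- function(expr, condition) {
  stopifnot(inherits(expr, "fos_expression"))
  vals <- condition_values(expr, condition)
  if (nrow(vals) < 4) stop("condition '", condition, "' needs at least 4 animals")
  regions <- colnames(vals)
  obs <- !is.na(vals)
  n <- crossprod(obs)                       # pairwise-complete counts
  v <- apply(vals, 2, stats::var, na.rm = TRUE)
  undefined <- !is.finite(v) | v == 0
  if (any(undefined)) {
    warning("zero-variance region(s) marked undefined: ",
            paste(regions[undefined], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(vals, use = "pairwise.complete.obs"))
  r[undefined, ] <- NA_real_
  r[, undefined] <- NA_real_
  df <- n - 2
  p <- matrix(NA_real_, length(regions), length(regions),
              dimnames = dimnames(r))
  ok <- !is.na(r) & df >= 2
  rr <- pmin(pmax(r[ok], -1), 1)
  tt <- rr * sqrt(df[ok]) / sqrt(pmax(1 - rr^2, 0))
  pv <- 2 * stats::pt(-abs(tt), df[ok])
  pv[abs(rr) >= 1] <- 0
  p[ok] <- pv
  diag(r) <- NA_real_
  diag(p) <- NA_real_
  structure(
    list(condition = condition, regions = regions, r = r, p = p, n = n,
         undefined = stats::setNames(undefined, regions)),
    class = "fos_corr"
  )
}

#' @export
print.fos_corr <- function(x, ...) {
  m <- x$r[upper.tri(x$r)]
  cat("Correlation matrix for condition '", x$condition, "': ",
      length(x$regions), " regions\n", sep = "")
  cat("mean r =", round(mean(m, na.rm = TRUE), 3),
      "| undefined regions:", sum(x$undefined), "\n")
  invisible(x)
}

#' Fisher Z transformation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`; strictly increasing and odd.
#' Errors on `|r| >= 1` (infinite transform). `NA`s propagate.
#'
#' @param r Numeric vector of correlation coefficients with `|r| < 1`.
#' @return Fisher-transformed values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    stop("fisher_z is undefined for |r| >= 1")
  }
  atanh(r)
}

#' Compare one correlation coefficient between two conditions
#'
#' Fisher-transforms both coefficients and reports either the raw difference
#' `z1 - z2` (flagged when `|z1 - z2| >= 2`) or the standardized difference
#' `(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` (flagged when `|.| >= 1.96`,
#' two-sided alpha = 0.05). The standardized mode is the default: its critical
#' value 1.96 corresponds to the nominal alpha the raw `|z| >= 2` rule
#' approximates.
#'
#' @param r1,r2 Correlation coefficients, `|r| < 1`.
#' @param n1,n2 Sample sizes (standardized mode needs `n > 3`).
#' @param mode `"standardized"` (default) or `"raw"`.
#' @return List of class `edge_difference` with `r1`, `r2`, `z1`, `z2`,
#'   `statistic`, `mode`, `significant`.
#' @export
edge_difference <- function(r1, n1, r2, n2, mode = c("standardized", "raw")) {
  mode <- match.arg(mode)
  if (any(!is.finite(c(r1, r2))) || abs(r1) >= 1 || abs(r2) >= 1) {
    stop("edge_difference needs finite correlations with |r| < 1")
  }
  z1 <- fisher_z(r1)
  z2 <- fisher_z(r2)
  if (mode == "standardized") {
    if (any(!is.finite(c(n1, n2))) || n1 <= 3 || n2 <= 3) {
      stop("standardized mode needs n1, n2 > 3")
    }
    stat <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
    sig <- abs(stat) >= 1.96
  } else {
    stat <- z1 - z2
    sig <- abs(stat) >= 2
  }
  structure(list(r1 = r1, r2 = r2, n1 = n1, n2 = n2, z1 = z1, z2 = z2,
                 statistic = stat, mode = mode, significant = sig),
            class = "edge_difference")
}

#' @export
print.edge_difference <- function(x, ...) {
  cat(sprintf("Fisher-Z edge difference (%s): %.3f (r1 = %.3f, r2 = %.3f)%s\n",
              x$mode, x$statistic, x$r1, x$r2,
              if (x$significant) " *" else ""))
  invisible(x)
}

# enumerate the coefficient list of one connectivity scope
scope_coefficients <- function(corr, atlas, scope, g1, g2 = NULL) {
  codes <- corr$regions
  grp <- stats::setNames(atlas$group[match(codes, atlas$code)], codes)
  if (scope == "internal") {
    idx <- which(grp == g1)
    if (length(idx) < 2) return(numeric(0))
    corr$r[idx, idx][upper.tri(diag(length(idx)))]
  } else if (scope == "external") {
    idx <- which(grp == g1)
    as.vector(corr$r[idx, which(grp != g1), drop = FALSE])
  } else {
    as.vector(corr$r[which(grp == g1), which(grp == g2), drop = FALSE])
  }
}

#' Anatomical-group connectivity summaries
#'
#' Means (and SEs) of the raw correlation coefficients within each anatomical
#' group (internal connectivity, `|g|(|g|-1)/2` coefficients), between each
#' group and all other regions (external connectivity) and between every pair
#' of groups (`|a| * |b|` coefficients). Undefined coefficients are excluded
#' from the means with the exclusion count reported.
#'
#' @param corr A `fos_corr`.
#' @param atlas A `fos_atlas` covering all regions of `corr`.
#' @return data.frame with columns `scope`, `group1`, `group2`, `n_pairs`,
#'   `n_used`, `mean_r`, `se_r`.
#' @export
group_connectivity <- function(corr, atlas) {
  stopifnot(inherits(corr, "fos_corr"), inherits(atlas, "fos_atlas"))
  if (!all(corr$regions %in% atlas$code)) {
    stop("atlas does not cover all regions of the correlation matrix")
  }
  groups <- intersect(anatomical_groups(),
                      unique(atlas$group[match(corr$regions, atlas$code)]))
  rows <- list()
  add <- function(scope, g1, g2) {
    cf <- scope_coefficients(corr, atlas, scope, g1, g2)
    used <- cf[!is.na(cf)]
    rows[[length(rows) + 1]] <<- data.frame(
      scope = scope, group1 = g1, group2 = if (is.null(g2)) NA_character_ else g2,
      n_pairs = length(cf), n_used = length(used),
      mean_r = if (length(used) > 0) mean(used) else NA_real_,
      se_r = if (length(used) > 1) stats::sd(used) / sqrt(length(used)) else NA_real_,
      stringsAsFactors = FALSE)
  }
  for (g in groups) add("internal", g, NULL)
  for (g in groups) add("external", g, NULL)
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2)
    for (q in seq_len(ncol(pairs))) add("pairwise", pairs[1, q], pairs[2, q])
  }
  do.call(rbind, rows)
}

#' Compare group connectivity between two conditions
#'
#' For every connectivity scope, compares the two sets of coefficients: either
#' a Welch t test on the Fisher-transformed coefficients (`"welch_on_z"`) or a
#' two-sided permutation test shuffling coefficients between the two sets
#' (`"coefficient_permutation"`).
#'
#' @param corrA,corrB `fos_corr` objects over the same atlas.
#' @param atlas A `fos_atlas`.
#' @param method `"welch_on_z"` or `"coefficient_permutation"`.
#' @param n_perm Permutations for the permutation method.
#' @param seed Seed for the permutation method.
#' @return data.frame with per-scope means and the comparison p-value.
#' @export
compare_group_connectivity <- function(corrA, corrB, atlas,
                                       method = c("welch_on_z",
                                                  "coefficient_permutation"),
                                       n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  if (!identical(corrA$regions, corrB$regions)) {
    stop("the two correlation matrices must share the same region set")
  }
  ga <- group_connectivity(corrA, atlas)
  if (method == "coefficient_permutation") {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  out <- ga[, c("scope", "group1", "group2")]
  out$mean_A <- NA_real_
  out$mean_B <- NA_real_
  out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    g2 <- if (is.na(out$group2[i])) NULL else out$group2[i]
    ca <- scope_coefficients(corrA, atlas, out$scope[i], out$group1[i], g2)
    cb <- scope_coefficients(corrB, atlas, out$scope[i], out$group1[i], g2)
    ca <- ca[!is.na(ca)]; cb <- cb[!is.na(cb)]
    if (length(ca) < 2 || length(cb) < 2) next
    out$mean_A[i] <- mean(ca)
    out$mean_B[i] <- mean(cb)
    if (method == "welch_on_z") {
      za <- atanh(pmin(pmax(ca, -1 + 1e-12), 1 - 1e-12))
      zb <- atanh(pmin(pmax(cb, -1 + 1e-12), 1 - 1e-12))
      if (stats::sd(za) == 0 && stats::sd(zb) == 0) {
        out$p[i] <- if (mean(za) == mean(zb)) 1 else 0
      } else {
        out$p[i] <- tryCatch(stats::t.test(za, zb)$p.value,
                             error = function(e) NA_real_)
      }
    } else {
      obs <- abs(mean(ca) - mean(cb))
      pool <- c(ca, cb)
      na <- length(ca)
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        idx <- sample.int(length(pool), na)
        if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs) cnt <- cnt + 1L
      }
      out$p[i] <- (1 + cnt) / (1 + n_perm)
    }
  }
  out
}

#' Association between regional activity and connectivity
#'
#' Across regions, correlates each region's mean correlation coefficient (mean
#' of its coefficients to all partners) and mean squared coefficient with its
#' mean expression, reporting Pearson r and the two-sided t-based p
#' (df = number of regions - 2).
#'
#' @param corr A `fos_corr`.
#' @param expr A `fos_expression` (the matching condition's animals are used).
#' @return data.frame with rows `mean_r` and `mean_r2`: columns `estimate`,
#'   `p`, `n_regions`.
#' @export
activity_connectivity_association <- function(corr, expr) {
  stopifnot(inherits(corr, "fos_corr"), inherits(expr, "fos_expression"))
  vals <- condition_values(expr, corr$condition)
  mean_expr <- colMeans(vals, na.rm = TRUE)[corr$regions]
  mean_r <- rowMeans(corr$r, na.rm = TRUE)
  mean_r2 <- rowMeans(corr$r^2, na.rm = TRUE)
  one <- function(x) {
    ok <- is.finite(x) & is.finite(mean_expr)
    n <- sum(ok)
    r <- stats::cor(x[ok], mean_expr[ok])
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    data.frame(estimate = r, p = 2 * stats::pt(-abs(t), n - 2), n_regions = n)
  }
  out <- rbind(one(mean_r), one(mean_r2))
  rownames(out) <- c("mean_r", "mean_r2")
  out
}

#' Write the r/p/n layers of a correlation result as square CSVs
#'
#' @param corr A `fos_corr`.
#' @param prefix Path prefix; writes `<prefix>_r.csv`, `<prefix>_p.csv`,
#'   `<prefix>_n.csv`.
#' @return The three paths, invisibly.
#' @export
write_correlation <- function(corr, prefix) {
  stopifnot(inherits(corr, "fos_corr"))
  paths <- paste0(prefix, "_", c("r", "p", "n"), ".csv")
  utils::write.csv(corr$r, paths[1], na = "NA")
  utils::write.csv(corr$p, paths[2], na = "NA")
  utils::write.csv(corr$n, paths[3], na = "NA")
  invisible(paths)
}
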