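#' Permutation test for between-network centrality differences
#'
#' Compares each region's centrality between the functional networks of two
#' conditions. Animal group labels are shuffled (without replacement,
#' preserving group sizes); each resample rebuilds the two correlation
#' matrices, thresholded networks and centrality tables, and records the
#' per-region differences. The p-value is the one-sided exceedance frequency
#' `count(resampled difference > observed difference) / n_perm` (the
#' strict-exceedance convention, which can be exactly 0); the floored convention
#' `(count + 1) / (n_perm + 1)` is reported alongside as `p_corrected`.
#' Swapping the two conditions negates the observed differences and maps the
#' upper-tail p to the complementary tail.
#'
#' @param expr A `fos_expression` containing both conditions.
#' @param condition_a,condition_b The two condition labels; observed
#'   differences are `A - B`.
#' @param p_thresholds Numeric vector of network thresholds
#'   (default `c(0.05, 0.01)`).
#' @param measures Subset of `c("wdg", "evc", "bet", "clo")`.
#' @param n_perm Number of resamples (default 1000; < 100 warns).
#' @param seed Integer seed; results are reproducible bit-for-bit.
#' @param weight_scheme Passed to [centralities()].
#' @param alpha Level used for the cross-threshold `stable` flag.
#' @return Object of class `fos_permutation`: list with `results` (long
#'   data.frame: `region`, `measure`, `threshold`, `observed`, `count`,
#'   `p_strict`, `p_corrected`, `direction`), `stable` (data.frame of
#'   region/measure pairs significant at every threshold), `n_perm`, `seed`.
#' @export
permutation_centrality_test <- function(expr, condition_a, condition_b,
                                        p_thresholds = c(0.05, 0.01),
                                        measures = c("wdg", "evc", "bet", "clo"),
                                        n_perm = 1000, seed = 1L,
                                        weight_scheme = "r", alpha = 0.05) {
  stopifnot(inherits(expr, "fos_expression"))
  measures <- match.arg(measures, several.ok = TRUE)
  keep <- expr$animals$condition %in% c(condition_a, condition_b)
  if (sum(expr$animals$condition == condition_a) < 4 ||
      sum(expr$animals$condition == condition_b) < 4) {
    stop("both conditions need at least 4 animals")
  }
  if (n_perm < 100) warning("n_perm < 100 gives very coarse p-values")
  vals <- expr$values[keep, , drop = FALSE]
  labels <- expr$animals$condition[keep]
  n_a <- sum(labels == condition_a)
  atlas <- expr$atlas

  cent_tables <- function(lab) {
    sub <- fos_expression(vals, lab, atlas, scale = expr$scale)
    out <- list()
    for (thr in p_thresholds) {
      for (cc in c(condition_a, condition_b)) {
        corr <- suppressWarnings(correlation_matrix(sub, cc))
        net <- build_network(corr, thr)
        ct <- centralities(net, weight_scheme)
        out[[paste(cc, thr)]] <- ct
      }
    }
    out
  }

  diff_array <- function(tabs) {
    # measures x regions x thresholds array of A - B differences
    regions <- tabs[[1]]$node
    arr <- array(NA_real_, c(length(measures), length(regions),
                             length(p_thresholds)),
                 dimnames = list(measures, regions, as.character(p_thresholds)))
    for (ti in seq_along(p_thresholds)) {
      a <- tabs[[paste(condition_a, p_thresholds[ti])]]
      b <- tabs[[paste(condition_b, p_thresholds[ti])]]
      for (m in measures) arr[m, , ti] <- a[[m]] - b[[m]]
    }
    arr
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  observed <- diff_array(cent_tables(labels))
  count <- array(0L, dim = dim(observed), dimnames = dimnames(observed))
  for (b in seq_len(n_perm)) {
    perm_lab <- rep(condition_b, length(labels))
    perm_lab[sample.int(length(labels), n_a)] <- condition_a
    d <- diff_array(cent_tables(perm_lab))
    count <- count + (d > observed)
  }
  p_strict <- count / n_perm
  p_corr <- (count + 1) / (n_perm + 1)

  res <- do.call(rbind, lapply(seq_along(p_thresholds), function(ti) {
    do.call(rbind, lapply(measures, function(m) {
      data.frame(region = dimnames(observed)[[2]], measure = m,
                 threshold = p_thresholds[ti],
                 observed = observed[m, , ti], count = count[m, , ti],
                 p_strict = p_strict[m, , ti], p_corrected = p_corr[m, , ti],
                 direction = ifelse(observed[m, , ti] >= 0, condition_a,
                                    condition_b),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))

  sig <- res$p_strict <= alpha
  key <- paste(res$region, res$measure)
  stable_keys <- names(which(tapply(sig, key, all)))
  stable <- unique(res[paste(res$region, res$measure) %in% stable_keys,
                       c("region", "measure")])
  rownames(stable) <- NULL

  structure(
    list(results = res, stable = stable, n_perm = n_perm, seed = seed,
         conditions = c(condition_a, condition_b), alpha = alpha,
         p_thresholds = p_thresholds, measures = measures),
    class = "fos_permutation"
  )
}

#' @export
print.fos_permutation <- function(x, ...) {
  cat("Permutation centrality test:", x$conditions[1], "vs", x$conditions[2],
      "|", x$n_perm, "resamples, seed", x$seed, "\n")
  nsig <- sum(x$results$p_strict <= x$alpha)
  cat(nsig, "of", nrow(x$results), "(region, measure, threshold) comparisons",
      "significant at p <=", x$alpha, "\n")
  if (nrow(x$stable) > 0) {
    cat("stable across thresholds:",
        paste(x$stable$region, x$stable$measure, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Write permutation results as long-format CSV plus a JSON manifest
#'
#' @param perm A `fos_permutation`.
#' @param prefix Path prefix; writes `<prefix>.csv` and
#'   `<prefix>_manifest.json`.
#' @return The two paths, invisibly.
#' @export
write_permutation <- function(perm, prefix) {
  stopifnot(inherits(perm, "fos_permutation"))
  csv <- paste0(prefix, ".csv")
  utils::write.csv(perm$results, csv, row.names = FALSE, quote = TRUE)
  manifest <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(
    list(conditions = perm$conditions, n_perm = perm$n_perm, seed = perm$seed,
         p_thresholds = perm$p_thresholds, measures = perm$measures,
         alpha = perm$alpha),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, manifest))
}
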