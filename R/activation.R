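#' Per-region between-condition activation analysis
#'
#' For every atlas region, tests whether mean expression differs across
#' conditions (omnibus Welch ANOVA by default, permutation F optionally) and,
#' when the omnibus test passes the gate, computes all pairwise contrasts
#' (Welch two-sample t, or permutation differences of means). Effect sizes are
#' standardized mean differences (difference of group means over the pooled
#' SD of the two groups).
#'
#' Regions in which every group has zero within-group variance have an
#' undefined omnibus p; they are flagged (`undefined`) rather than dropped.
#'
#' @param expr A `fos_expression` (raw or percent-of-baseline scale).
#' @param design Optional `condition_design`; defaults to the conditions found
#'   in the data.
#' @param method `"welch"` (Welch ANOVA + Welch pairwise t) or
#'   `"permutation"` (label-permutation F and pairwise mean differences).
#' @param mcc Multiple-testing correction across regions for the omnibus p:
#'   `"none"` (default) or `"bh"` (Benjamini-Hochberg).
#' @param alpha Gate level for computing pairwise contrasts.
#' @param gatekeep If `TRUE` (default), pairwise contrasts are only computed
#'   for regions whose (corrected) omnibus p is below `alpha`.
#' @param n_perm Number of permutations for `method = "permutation"`.
#' @param seed Seed for the permutation method.
#' @return An object of class `fos_activation`: list with `means`, `se`
#'   (condition x region matrices), `omnibus` (data.frame with `region`, `p`,
#'   `p_adj`, `undefined`, `gated`), `pairwise` (long data.frame with `region`,
#'   `group1`, `group2`, `p`, `effect`, `higher`), and the call parameters.
#' @export
compare_activation <- function(expr, design = NULL,
                               method = c("welch", "permutation"),
                               mcc = c("none", "bh"),
                               alpha = 0.05, gatekeep = TRUE,
                               n_perm = 999, seed = 1L) {
  stopifnot(inherits(expr, "fos_expression"))
  method <- match.arg(method)
  mcc <- match.arg(mcc)
  conds <- if (!is.null(design)) design$conditions else
    unique(expr$animals$condition)
  conds <- conds[conds %in% expr$animals$condition]
  if (length(conds) < 2) stop("need at least two conditions")
  tab <- table(expr$animals$condition)[conds]
  if (any(tab < 3)) stop("every condition needs at least 3 animals")
  regions <- colnames(expr$values)
  grp <- factor(expr$animals$condition, levels = conds)
  keep <- !is.na(grp)
  vals <- expr$values[keep, , drop = FALSE]
  grp <- grp[keep]

  means <- matrix(NA_real_, length(conds), length(regions),
                  dimnames = list(conds, regions))
  se <- means
  for (cc in conds) {
    m <- vals[grp == cc, , drop = FALSE]
    means[cc, ] <- colMeans(m, na.rm = TRUE)
    nn <- colSums(!is.na(m))
    se[cc, ] <- apply(m, 2, stats::sd, na.rm = TRUE) / sqrt(nn)
  }

  if (method == "permutation") {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }

  omni_p <- rep(NA_real_, length(regions))
  undefined <- rep(FALSE, length(regions))
  for (j in seq_along(regions)) {
    y <- vals[, j]
    ok <- !is.na(y)
    v <- tapply(y[ok], grp[ok], stats::var)
    if (all(is.na(v) | v == 0)) {
      undefined[j] <- TRUE
      next
    }
    if (method == "welch") {
      omni_p[j] <- tryCatch(
        stats::oneway.test(y[ok] ~ grp[ok], var.equal = FALSE)$p.value,
        error = function(e) NA_real_)
    } else {
      omni_p[j] <- perm_anova_p(y[ok], grp[ok], n_perm)
    }
    if (is.na(omni_p[j])) undefined[j] <- TRUE
  }
  p_adj <- if (mcc == "bh") stats::p.adjust(omni_p, method = "BH") else omni_p
  gated <- !undefined & !is.na(p_adj) & (!gatekeep | p_adj < alpha)

  pairs <- utils::combn(conds, 2)
  pw <- vector("list", sum(gated) * ncol(pairs))
  k <- 0L
  for (j in which(gated)) {
    y <- vals[, j]
    for (q in seq_len(ncol(pairs))) {
      g1 <- pairs[1, q]; g2 <- pairs[2, q]
      y1 <- y[grp == g1 & !is.na(y)]
      y2 <- y[grp == g2 & !is.na(y)]
      p <- if (method == "welch") {
        tryCatch(stats::t.test(y1, y2)$p.value, error = function(e) NA_real_)
      } else {
        perm_t_p(y1, y2, n_perm)
      }
      sp <- sqrt(((length(y1) - 1) * stats::var(y1) +
                  (length(y2) - 1) * stats::var(y2)) /
                 (length(y1) + length(y2) - 2))
      eff <- if (sp > 0) (mean(y1) - mean(y2)) / sp else NA_real_
      k <- k + 1L
      pw[[k]] <- data.frame(
        region = regions[j], group1 = g1, group2 = g2, p = p,
        effect = eff,
        higher = if (mean(y1) >= mean(y2)) g1 else g2,
        stringsAsFactors = FALSE)
    }
  }
  pairwise <- if (k > 0) do.call(rbind, pw[seq_len(k)]) else
    data.frame(region = character(0), group1 = character(0),
               group2 = character(0), p = numeric(0), effect = numeric(0),
               higher = character(0), stringsAsFactors = FALSE)

  structure(
    list(means = means, se = se,
         omnibus = data.frame(region = regions, p = omni_p, p_adj = p_adj,
                              undefined = undefined, gated = gated,
                              stringsAsFactors = FALSE),
         pairwise = pairwise, conditions = conds, alpha = alpha,
         method = method, mcc = mcc, gatekeep = gatekeep,
         scale = expr$scale),
    class = "fos_activation"
  )
}

# permutation F: Welch F statistic under label shuffles, p = (1+#>=obs)/(1+B)
perm_anova_p <- function(y, g, n_perm) {
  obs <- tryCatch(stats::oneway.test(y ~ g, var.equal = FALSE)$statistic,
                  error = function(e) NA_real_)
  if (is.na(obs)) return(NA_real_)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    st <- tryCatch(stats::oneway.test(y ~ sample(g), var.equal = FALSE)$statistic,
                   error = function(e) NA_real_)
    if (!is.na(st) && st >= obs) cnt <- cnt + 1L
  }
  (1 + cnt) / (1 + n_perm)
}

perm_t_p <- function(y1, y2, n_perm) {
  obs <- abs(mean(y1) - mean(y2))
  pool <- c(y1, y2)
  n1 <- length(y1)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(pool), n1)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs) cnt <- cnt + 1L
  }
  (1 + cnt) / (1 + n_perm)
}

# significant directed contrast: p < alpha and group a has the higher mean
sig_higher <- function(pw, a, b, alpha) {
  row <- pw[(pw$group1 == a & pw$group2 == b) |
            (pw$group1 == b & pw$group2 == a), , drop = FALSE]
  if (nrow(row) == 0) return(FALSE)
  any(!is.na(row$p) & row$p < alpha & row$higher == a)
}

not_different <- function(pw, a, b, alpha) {
  row <- pw[(pw$group1 == a & pw$group2 == b) |
            (pw$group1 == b & pw$group2 == a), , drop = FALSE]
  if (nrow(row) == 0) return(TRUE)  # never gated => no evidence of difference
  all(is.na(row$p) | row$p >= alpha)
}

#' Classify per-region engagement
#'
#' Applies the three-clause decision rule over pairwise contrast significance:
#' \describe{
#'   \item{target-specific}{the focal condition is significantly higher than
#'     every other condition;}
#'   \item{both-conditionings}{the focal and partner conditioning groups do not
#'     differ, each is higher than the shock-only or baseline group, and
#'     either each beats its own context control or the context controls do
#'     not differ from the shock-only and baseline groups;}
#'   \item{contextual}{the four context-exposed groups (both conditionings and
#'     both context controls) do not differ among themselves and each is
#'     higher than the shock-only or baseline group;}
#'   \item{other}{some significant contrast, but no rule above applies;}
#'   \item{none}{no significant contrast.}
#' }
#'
#' @param table A `fos_activation`.
#' @param focal Focal conditioning condition (default `"CFC-5s"`).
#' @param partner The overlapping-conditioning partner (default `"CFC"`).
#' @param contexts Context controls for `partner` and `focal`, in that order
#'   (default `c("CT", "CT-5s")`).
#' @param aversive Shock-only control (default `"US"`).
#' @param baseline Baseline condition (default `"HC"`).
#' @param alpha Contrast significance level.
#' @return data.frame with `region` and `category`.
#' @export
classify_engagement <- function(table, focal = "CFC-5s", partner = "CFC",
                                contexts = c("CT", "CT-5s"), aversive = "US",
                                baseline = "HC", alpha = table$alpha) {
  stopifnot(inherits(table, "fos_activation"))
  conds <- table$conditions
  need <- c(focal, partner, contexts, aversive, baseline)
  if (!all(need %in% conds)) {
    stop("classification needs conditions: ", paste(need, collapse = ", "))
  }
  regions <- table$omnibus$region
  others <- setdiff(conds, focal)
  ctx_groups <- c(partner, focal, contexts)
  out <- character(length(regions))
  for (i in seq_along(regions)) {
    pw <- table$pairwise[table$pairwise$region == regions[i], , drop = FALSE]
    if (nrow(pw) == 0 || all(is.na(pw$p) | pw$p >= alpha)) {
      out[i] <- "none"
      next
    }
    target <- all(vapply(others, function(o) sig_higher(pw, focal, o, alpha),
                         logical(1)))
    if (target) {
      out[i] <- "target-specific"
      next
    }
    above_floor <- function(g) {
      sig_higher(pw, g, aversive, alpha) || sig_higher(pw, g, baseline, alpha)
    }
    both <- not_different(pw, focal, partner, alpha) &&
      above_floor(focal) && above_floor(partner) &&
      ((sig_higher(pw, partner, contexts[1], alpha) &&
        sig_higher(pw, focal, contexts[2], alpha)) ||
       all(vapply(contexts, function(ct) {
         not_different(pw, ct, aversive, alpha) &&
           not_different(pw, ct, baseline, alpha)
       }, logical(1))))
    if (both) {
      out[i] <- "both-conditionings"
      next
    }
    ctx_pairs <- utils::combn(ctx_groups, 2)
    ctx_same <- all(vapply(seq_len(ncol(ctx_pairs)), function(q) {
      not_different(pw, ctx_pairs[1, q], ctx_pairs[2, q], alpha)
    }, logical(1)))
    contextual <- ctx_same && all(vapply(ctx_groups, above_floor, logical(1)))
    out[i] <- if (contextual) "contextual" else "other"
  }
  data.frame(region = regions, category = out, stringsAsFactors = FALSE)
}

#' @export
print.fos_activation <- function(x, ...) {
  cat("Activation analysis (", x$method, ", mcc = ", x$mcc, ", scale = ",
      x$scale, ")\n", sep = "")
  cat(sum(x$omnibus$gated), "of", nrow(x$omnibus),
      "regions pass the omnibus gate at alpha =", x$alpha, "\n")
  if (any(x$omnibus$undefined)) {
    cat("undefined (zero-variance) regions:",
        paste(x$omnibus$region[x$omnibus$undefined], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export an activation table as a wide CSV
#'
#' One row per region: per-condition mean and SE, omnibus p, and significance
#' codes per contrast partner.
#'
#' @param table A `fos_activation`.
#' @param path Output CSV path.
#' @param alpha Significance level for the contrast codes.
#' @return `path`, invisibly.
#' @export
write_activation <- function(table, path, alpha = table$alpha) {
  stopifnot(inherits(table, "fos_activation"))
  regions <- table$omnibus$region
  out <- data.frame(region = regions, stringsAsFactors = FALSE)
  for (cc in table$conditions) {
    out[[paste0("mean_", cc)]] <- table$means[cc, regions]
    out[[paste0("se_", cc)]] <- table$se[cc, regions]
  }
  out$omnibus_p <- table$omnibus$p
  out$omnibus_p_adj <- table$omnibus$p_adj
  sig <- vapply(regions, function(rg) {
    pw <- table$pairwise[table$pairwise$region == rg & !is.na(table$pairwise$p) &
                         table$pairwise$p < alpha, , drop = FALSE]
    if (nrow(pw) == 0) return("")
    paste(sprintf("%s>%s", pw$higher,
                  ifelse(pw$higher == pw$group1, pw$group2, pw$group1)),
          collapse = ";")
  }, character(1))
  out$significant_contrasts <- sig
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
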