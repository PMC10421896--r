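#' Specification of a synthetic cohort
#'
#' Describes the statistical structure of a simulated c-Fos cohort: a condition
#' design, an atlas, per-region mean and SD targets on the observed count
#' scale, multiplicative activation effects per condition, block-structured
#' latent correlation per condition and a background correlation. Counts are
#' sampled from a lognormal family by default, so they are strictly positive
#' and right-skewed like real cell counts; correlation targets apply on the
#' latent (log) scale, and the observed-scale Pearson r is very slightly
#' attenuated.
#'
#' Multiplicative mean shifts scale the region SD along with the mean
#' (constant coefficient of variation), so activation effects do not perturb
#' the latent correlation structure.
#'
#' @param design A `condition_design`.
#' @param atlas A `fos_atlas`.
#' @param base_mean Per-region mean count target: scalar or named/plain vector
#'   of length `nrow(atlas)`.
#' @param base_sd Per-region SD target, recycled like `base_mean`.
#' @param activation_effects List of `list(condition=, regions=, shift=)`
#'   entries; `shift` multiplies the mean (and SD) of those regions in that
#'   condition.
#' @param coupling_blocks List of `list(condition=, regions=, rho=)` entries;
#'   `rho` is the within-block latent correlation in that condition.
#' @param rho0 Background latent correlation between all region pairs,
#'   in `[0, 1)`.
#' @param family `"lognormal"` (default) or `"truncated_normal"`.
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(design, atlas, base_mean = 100, base_sd = 30,
                        activation_effects = list(), coupling_blocks = list(),
                        rho0 = 0.2, family = c("lognormal", "truncated_normal"),
                        seed = 1L) {
  stopifnot(inherits(design, "condition_design"), inherits(atlas, "fos_atlas"))
  family <- match.arg(family)
  p <- nrow(atlas)
  expand <- function(v, nm) {
    if (length(v) == 1) v <- rep(v, p)
    if (length(v) != p) stop("'", nm, "' must be scalar or length nrow(atlas)")
    v <- as.numeric(v)
    if (any(!is.finite(v)) || any(v <= 0)) stop("'", nm, "' must be positive")
    stats::setNames(v, atlas$code)
  }
  base_mean <- expand(base_mean, "base_mean")
  base_sd <- expand(base_sd, "base_sd")
  if (!is.numeric(rho0) || rho0 < 0 || rho0 >= 1) stop("rho0 must be in [0, 1)")
  check_effect <- function(e, what) {
    if (!all(c("condition", "regions") %in% names(e))) {
      stop(what, " entries need 'condition' and 'regions'")
    }
    if (!e$condition %in% design$conditions) {
      stop(what, ": unknown condition '", e$condition, "'")
    }
    bad <- setdiff(e$regions, atlas$code)
    if (length(bad) > 0) {
      stop(what, ": region(s) not in atlas: ", paste(bad, collapse = ", "))
    }
  }
  for (e in activation_effects) {
    check_effect(e, "activation_effects")
    if (is.null(e$shift) || e$shift <= 0) stop("activation shift must be positive")
  }
  for (b in coupling_blocks) {
    check_effect(b, "coupling_blocks")
    if (is.null(b$rho) || b$rho < 0 || b$rho >= 1) {
      stop("coupling rho must be in [0, 1)")
    }
  }
  spec <- structure(
    list(design = design, atlas = atlas, base_mean = base_mean,
         base_sd = base_sd, activation_effects = activation_effects,
         coupling_blocks = coupling_blocks, rho0 = rho0, family = family,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
  # fail early: every per-condition correlation target must be PSD
  for (cc in design$conditions) latent_correlation(spec, cc)
  spec
}

# Per-condition latent correlation target: rho0 everywhere, overwritten
# within each coupling block of that condition. Rejects non-PSD targets
# (eigenvalue tolerance 1e-10).
latent_correlation <- function(spec, condition) {
  codes <- spec$atlas$code
  p <- length(codes)
  C <- matrix(spec$rho0, p, p, dimnames = list(codes, codes))
  for (b in spec$coupling_blocks) {
    if (b$condition != condition) next
    idx <- match(b$regions, codes)
    C[idx, idx] <- b$rho
  }
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("latent correlation target for condition '", condition,
         "' is not positive semi-definite (min eigenvalue ", signif(min(ev), 3), ")")
  }
  C
}

# Per-condition observed mean targets after applying activation shifts.
condition_means <- function(spec, condition) {
  m <- spec$base_mean
  for (e in spec$activation_effects) {
    if (e$condition != condition) next
    m[e$regions] <- m[e$regions] * e$shift
  }
  m
}

condition_sds <- function(spec, condition) {
  s <- spec$base_sd
  for (e in spec$activation_effects) {
    if (e$condition != condition) next
    s[e$regions] <- s[e$regions] * e$shift
  }
  s
}

# Draw n rows from N(0, C) via the symmetric eigen square root (tolerates
# exactly singular PSD targets).
rmvn_eigen <- function(n, C) {
  es <- eigen(C, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  L <- es$vectors %*% (sqrt(lam) * t(es$vectors))
  matrix(stats::rnorm(n * ncol(C)), n, ncol(C)) %*% L
}

#' Generate a synthetic cohort
#'
#' Samples one animal per row according to the design. For the lognormal
#' family, region j in condition c is `exp(mu_cj + sigma_j * z_j)` with latent
#' `z ~ N(0, C_c)`; `mu` and `sigma` are chosen so the observed mean and SD
#' converge to the spec targets. The truncated-normal family samples
#' `mean + sd * z` and redraws any animal with a negative value.
#'
#' @param spec A `cohort_spec`.
#' @return A raw-scale `fos_expression`; deterministic given `spec$seed`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  codes <- spec$atlas$code
  rows <- list()
  conds <- character(0)
  for (cc in spec$design$conditions) {
    n <- spec$design$n[[cc]]
    C <- latent_correlation(spec, cc)
    m <- condition_means(spec, cc)
    s <- condition_sds(spec, cc)
    if (spec$family == "lognormal") {
      sigma2 <- log(1 + (s / m)^2)
      mu <- log(m) - sigma2 / 2
      z <- rmvn_eigen(n, C)
      vals <- exp(sweep(sweep(z, 2, sqrt(sigma2), "*"), 2, mu, "+"))
    } else {
      vals <- matrix(NA_real_, n, length(codes))
      todo <- seq_len(n)
      for (iter in 1:100) {
        z <- rmvn_eigen(length(todo), C)
        cand <- sweep(sweep(z, 2, s, "*"), 2, m, "+")
        ok <- apply(cand >= 0, 1, all)
        vals[todo[ok], ] <- cand[ok, , drop = FALSE]
        todo <- todo[!ok]
        if (length(todo) == 0) break
      }
      if (length(todo) > 0) {
        stop("truncated-normal rejection sampling failed; mean/sd targets ",
             "put too much mass below zero")
      }
    }
    colnames(vals) <- codes
    rows[[cc]] <- vals
    conds <- c(conds, rep(cc, n))
  }
  values <- do.call(rbind, rows)
  rownames(values) <- sprintf("%s_%02d", conds, unlist(lapply(
    spec$design$conditions, function(cc) seq_len(spec$design$n[[cc]]))))
  fos_expression(values, conds, spec$atlas, scale = "raw")
}

#' Machine-readable record of the planted effects
#'
#' Returns the activation effects and coupling blocks planted by a spec, plus
#' the implied hub regions (regions belonging to blocks whose coupling exceeds
#' the background correlation), for recovery scoring of downstream analyses.
#'
#' @param spec A `cohort_spec`.
#' @return List with elements `activations`, `coupling_blocks`,
#'   `implied_hubs`.
#' @export
planted_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  acts <- Filter(function(e) e$shift != 1, spec$activation_effects)
  blocks <- spec$coupling_blocks
  elevated <- Filter(function(b) b$rho > spec$rho0, blocks)
  hubs <- sort(unique(unlist(lapply(elevated, `[[`, "regions"))))
  list(
    activations = lapply(acts, function(e)
      list(condition = e$condition, regions = e$regions, shift = e$shift)),
    coupling_blocks = lapply(blocks, function(b)
      list(condition = b$condition, regions = b$regions, rho = b$rho)),
    implied_hubs = if (length(hubs) > 0) hubs else character(0)
  )
}

#' Reference cohort specification
#'
#' A cohort spec that mimics the study conditions of the six-group design:
#' eleven focal regions (PL, IL, BLAp, LAv, MEAa, vCA1, vSUB, PER, POR, DIENT,
#' VIENT) strongly and specifically activated in CFC-5s, six fear-conditioning
#' regions activated in both CFC and CFC-5s, elevated amygdala-block coupling
#' in CFC-5s relative to CFC, and a moderate background correlation. Counts
#' are lognormal with coefficient of variation 0.3; region base means vary
#' deterministically over a realistic 40-220 cells range.
#'
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
reference_cohort_spec <- function(seed = 1L) {
  atlas <- default_atlas()
  design <- default_design()
  p <- nrow(atlas)
  base_mean <- 40 + 180 * (seq_len(p) - 1) / (p - 1)  # deterministic spread
  base_sd <- 0.3 * base_mean
  focal <- c("PL", "IL", "BLAp", "LAv", "MEAa", "vCA1", "vSUB",
             "PER", "POR", "DIENT", "VIENT")
  fear <- c("AC", "BLAa", "CEA", "M2", "vDG", "RSDp")
  amy <- atlas$code[atlas$group == "AMY"]
  acts <- c(
    list(list(condition = "CFC-5s", regions = focal, shift = 3.0)),
    lapply(c("CFC", "CT", "CT-5s", "US"), function(cc)
      list(condition = cc, regions = focal, shift = 1.4)),
    lapply(c("CFC", "CFC-5s"), function(cc)
      list(condition = cc, regions = fear, shift = 2.2)),
    lapply(c("CT", "CT-5s", "US"), function(cc)
      list(condition = cc, regions = fear, shift = 1.2))
  )
  blocks <- list(
    list(condition = "CFC-5s", regions = amy, rho = 0.75),
    list(condition = "CFC", regions = amy, rho = 0.35)
  )
  cohort_spec(design, atlas, base_mean = base_mean, base_sd = base_sd,
              activation_effects = acts, coupling_blocks = blocks,
              rho0 = 0.25, family = "lognormal", seed = seed)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", sum(x$design$n), "animals,",
      nrow(x$atlas), "regions,", x$family, "family, rho0 =", x$rho0, "\n")
  cat(length(x$activation_effects), "activation effect(s),",
      length(x$coupling_blocks), "coupling block(s), seed", x$seed, "\n")
  invisible(x)
}
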