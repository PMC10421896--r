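#' Condition design
#'
#' Declares the experimental conditions, their per-condition sample sizes and
#' which condition is the baseline used for normalization (the homecage group
#' in the default design). Sample sizes must be at least 4 so that correlation
#' p-values (df = n - 2) are defined.
#'
#' @param conditions Character vector of condition names.
#' @param n Integer vector of per-condition sample sizes (same length).
#' @param baseline Name of the baseline condition; must appear in `conditions`.
#' @return An object of class `condition_design`.
#' @examples
#' default_design()
#' @export
condition_design <- function(conditions, n, baseline) {
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions)) stop("duplicated condition names")
  if (length(n) != length(conditions)) {
    stop("'n' must have one entry per condition")
  }
  n <- as.integer(n)
  if (any(is.na(n)) || any(n < 4)) {
    stop("all per-condition sample sizes must be >= 4")
  }
  if (!baseline %in% conditions) {
    stop("baseline condition '", baseline, "' is not among the conditions")
  }
  structure(
    list(conditions = conditions, n = stats::setNames(n, conditions),
         baseline = baseline),
    class = "condition_design"
  )
}

#' Default six-condition design
#'
#' Homecage baseline (HC, n = 12), contextual fear conditioning (CFC, n = 11),
#' contextual fear conditioning with a 5-s interval (CFC-5s, n = 11), context
#' only (CT, n = 11), context with interval (CT-5s, n = 12) and immediate
#' shock (US, n = 11).
#'
#' @return A `condition_design`.
#' @export
default_design <- function() {
  condition_design(
    conditions = c("HC", "CFC", "CFC-5s", "CT", "CT-5s", "US"),
    n = c(12L, 11L, 11L, 11L, 12L, 11L),
    baseline = "HC"
  )
}

#' @export
print.condition_design <- function(x, ...) {
  cat("Condition design (baseline:", x$baseline, ")\n")
  print(x$n)
  invisible(x)
}
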