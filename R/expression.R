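#' Animal-by-region expression matrix
#'
#' Holds per-animal c-Fos-positive cell counts (or percent-of-baseline values
#' after normalization) for every atlas region, together with a condition label
#' per animal. Values are non-negative; missing entries are explicit `NA`s
#' (lost tissue), never silent zeros.
#'
#' @param values Numeric matrix, animals x regions, with column names equal to
#'   atlas region codes and (optionally) row names as animal ids.
#' @param condition Character vector of condition labels, one per row.
#' @param atlas A `fos_atlas`; columns are reordered to atlas order.
#' @param scale One of `"raw"` or `"percent_of_baseline"`.
#' @return An object of class `fos_expression`: list with elements `values`
#'   (matrix), `animals` (data.frame with `animal_id`, `condition`), `atlas`,
#'   and `scale`.
#' @export
fos_expression <- function(values, condition, atlas,
                           scale = c("raw", "percent_of_baseline")) {
  scale <- match.arg(scale)
  stopifnot(inherits(atlas, "fos_atlas"))
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("expression values need region column names")
  if (nrow(values) == 0) stop("expression matrix has no animals")
  storage.mode(values) <- "double"
  unknown <- setdiff(colnames(values), atlas$code)
  if (length(unknown) > 0) {
    stop("expression column(s) not in atlas: ", paste(unknown, collapse = ", "))
  }
  absent <- setdiff(atlas$code, colnames(values))
  if (length(absent) > 0) {
    stop("atlas region(s) missing from expression table: ",
         paste(absent, collapse = ", "))
  }
  values <- values[, atlas$code, drop = FALSE]
  if (any(values < 0, na.rm = TRUE)) stop("negative expression values are not allowed")
  if (any(is.infinite(values))) stop("expression values must be finite")
  condition <- as.character(condition)
  if (length(condition) != nrow(values)) {
    stop("'condition' must have one label per animal")
  }
  ids <- rownames(values)
  if (is.null(ids)) ids <- sprintf("animal_%03d", seq_len(nrow(values)))
  rownames(values) <- ids
  structure(
    list(values = values,
         animals = data.frame(animal_id = ids, condition = condition,
                              stringsAsFactors = FALSE),
         atlas = atlas, scale = scale),
    class = "fos_expression"
  )
}

#' Read an expression table
#'
#' Expects a wide delimited table with columns `animal_id`, `condition`, then
#' one column per atlas region code. Any region column absent from the atlas is
#' an error, as is any atlas region absent from the file.
#'
#' @param path CSV path.
#' @param atlas A `fos_atlas` to validate against.
#' @param sep Field separator.
#' @return A `fos_expression` with `scale = "raw"`.
#' @export
read_expression <- function(path, atlas, sep = ",") {
  x <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      comment.char = "", quote = "\"", check.names = FALSE),
    error = function(e) stop("failed to parse expression file '", path, "': ",
                             conditionMessage(e))
  )
  if (nrow(x) == 0) stop("expression file '", path, "' contains no animals")
  if (!all(c("animal_id", "condition") %in% names(x))) {
    stop("expression file must start with 'animal_id' and 'condition' columns")
  }
  vals <- as.matrix(x[, setdiff(names(x), c("animal_id", "condition")), drop = FALSE])
  rownames(vals) <- as.character(x$animal_id)
  fos_expression(vals, x$condition, atlas, scale = "raw")
}

#' Write an expression table to CSV
#'
#' Round-trips losslessly with [read_expression()] (values, animal ids,
#' condition labels and missingness are preserved).
#'
#' @param expr A `fos_expression`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "fos_expression"))
  out <- data.frame(animal_id = expr$animals$animal_id,
                    condition = expr$animals$condition,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(expr$values, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Subset the animals of one condition
#'
#' @param expr A `fos_expression`.
#' @param condition Condition label.
#' @return Numeric matrix (animals of that condition x regions).
#' @export
condition_values <- function(expr, condition) {
  stopifnot(inherits(expr, "fos_expression"))
  keep <- expr$animals$condition == condition
  if (!any(keep)) stop("no animals with condition '", condition, "'")
  expr$values[keep, , drop = FALSE]
}

#' Normalize expression to the baseline-condition mean
#'
#' Divides every value by the baseline-condition mean of its region and
#' multiplies by 100, so the baseline group's per-region mean becomes exactly
#' 100 (percent of baseline). Pearson correlations are invariant under this
#' per-region linear rescaling; normalization only affects the activation
#' scale.
#'
#' @param expr A raw-scale `fos_expression`.
#' @param design A `condition_design` naming the baseline condition, or a
#'   baseline condition label.
#' @return A `fos_expression` with `scale = "percent_of_baseline"`.
#' @export
normalize_to_baseline <- function(expr, design) {
  stopifnot(inherits(expr, "fos_expression"))
  if (expr$scale != "raw") stop("expression is already normalized")
  baseline <- if (inherits(design, "condition_design")) design$baseline else
    as.character(design)
  base_vals <- condition_values(expr, baseline)
  base_mean <- colMeans(base_vals, na.rm = TRUE)
  zero <- !is.finite(base_mean) | base_mean == 0
  if (any(zero)) {
    stop("zero (or undefined) baseline mean in region(s): ",
         paste(names(base_mean)[zero], collapse = ", "))
  }
  out <- expr
  out$values <- sweep(expr$values, 2, base_mean, "/") * 100
  out$scale <- "percent_of_baseline"
  out
}

#' @export
print.fos_expression <- function(x, ...) {
  cat("c-Fos expression matrix:", nrow(x$values), "animals x",
      ncol(x$values), "regions (scale:", x$scale, ")\n")
  print(table(x$animals$condition))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(n_na, "missing value(s)\n")
  invisible(x)
}

#' @export
summary.fos_expression <- function(object, ...) {
  conds <- unique(object$animals$condition)
  means <- t(vapply(conds, function(cc) {
    colMeans(condition_values(object, cc), na.rm = TRUE)
  }, numeric(ncol(object$values))))
  rownames(means) <- conds
  means
}
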