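#' Region atlas
#'
#' An atlas maps short region codes to full anatomical names and to one of nine
#' anatomical groups (PFC, mPFC, RSC, TAL, AMY, DH, VH, SUB, PHC). The atlas
#' defines the node universe of every downstream network: expression tables are
#' validated against it and functional networks carry one node per atlas region.
#'
#' @param x data.frame with columns `code`, `name`, `group`.
#' @return An object of class `fos_atlas`: a data.frame with columns
#'   `code`, `name`, `group`, validated for unique non-empty codes and known
#'   group labels.
#' @examples
#' atl <- default_atlas()
#' nrow(atl)                      # 49 regions
#' table(atl$group)               # 9 anatomical groups
#' @export
fos_atlas <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("code", "name", "group")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("atlas is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- x[, required]
  x$code <- as.character(x$code)
  x$name <- as.character(x$name)
  x$group <- as.character(x$group)
  if (any(is.na(x$code)) || any(!nzchar(x$code))) {
    stop("atlas region codes must be non-empty")
  }
  dup <- unique(x$code[duplicated(x$code)])
  if (length(dup) > 0) {
    stop("duplicated atlas region code(s): ", paste(dup, collapse = ", "))
  }
  bad <- unique(x$group[!(x$group %in% anatomical_groups())])
  if (length(bad) > 0) {
    stop("unknown anatomical group label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(anatomical_groups(), collapse = ", "), ")")
  }
  rownames(x) <- NULL
  class(x) <- c("fos_atlas", "data.frame")
  x
}

#' The nine anatomical group labels
#'
#' @return Character vector of the nine group labels in canonical order.
#' @export
anatomical_groups <- function() {
  c("PFC", "mPFC", "RSC", "TAL", "AMY", "DH", "VH", "SUB", "PHC")
}

#' Default 49-region atlas
#'
#' The default node universe: 49 rat brain regions spanning prefrontal,
#' retrosplenial, thalamic, amygdalar, hippocampal, subicular and
#' parahippocampal territories, grouped into nine anatomical groups. The
#' region-to-group mapping is user-overridable by supplying any other atlas.
#'
#' @return A `fos_atlas` with 49 rows and 9 distinct groups.
#' @export
default_atlas <- function() {
  atl <- data.frame(
    code = c(
      "DLO", "LO", "MO", "VO", "M2",
      "AC", "PL", "IL",
      "RSDa", "RSDp", "RSGab", "RSGca", "RSGcp",
      "AD", "AM", "AV", "MD", "PVT", "RE",
      "BLAa", "BLAp", "BLAv", "BMEa", "BMEp", "CEA", "ITC", "LAd", "LAv",
      "MEAa", "MEAp",
      "dCA1", "dCA3", "dDG",
      "vCA1", "vCA3", "vDG",
      "dSUB", "vSUB", "PAS", "PRES", "POST",
      "PER", "POR", "ECT", "CENT", "DIENT", "DLENT", "MENT", "VIENT"
    ),
    name = c(
      "dorsolateral orbital cortex", "lateral orbital cortex",
      "medial orbital cortex", "ventral orbital cortex",
      "secondary motor cortex",
      "cingulate cortex", "prelimbic cortex", "infralimbic cortex",
      "retrosplenial dysgranular cortex, anterior A30",
      "retrosplenial dysgranular cortex, posterior",
      "retrosplenial granular cortex, A29ab",
      "retrosplenial granular cortex, anterior A29c",
      "retrosplenial granular cortex, posterior A29c",
      "anterodorsal thalamic nucleus", "anteromedial thalamic nucleus",
      "anteroventral thalamic nucleus", "mediodorsal thalamic nucleus",
      "paraventricular thalamic nucleus", "reuniens thalamic nucleus",
      "basolateral amygdaloid nucleus, anterior",
      "basolateral amygdaloid nucleus, posterior",
      "basolateral amygdaloid nucleus, ventral",
      "basomedial amygdaloid nucleus, anterior",
      "basomedial amygdaloid nucleus, posterior",
      "central amygdaloid nucleus", "intercalated amygdaloid nucleus",
      "lateral amygdaloid nucleus, dorsal",
      "lateral amygdaloid nucleus, ventral",
      "medial amygdaloid nucleus, anterior",
      "medial amygdaloid nucleus, posterior",
      "dorsal CA1 region of the hippocampus",
      "dorsal CA3 region of the hippocampus", "dorsal dentate gyrus",
      "ventral CA1 region of the hippocampus",
      "ventral CA3 region of the hippocampus", "ventral dentate gyrus",
      "dorsal subiculum", "ventral subiculum", "parasubiculum",
      "presubiculum", "postsubiculum",
      "perirhinal cortex", "postrhinal cortex", "ectorhinal cortex",
      "caudomedial entorhinal cortex",
      "dorsal intermediate entorhinal cortex",
      "dorsal lateral entorhinal cortex", "medial entorhinal cortex",
      "ventral intermediate entorhinal cortex"
    ),
    group = c(
      rep("PFC", 5), rep("mPFC", 3), rep("RSC", 5), rep("TAL", 6),
      rep("AMY", 11), rep("DH", 3), rep("VH", 3), rep("SUB", 5), rep("PHC", 8)
    ),
    stringsAsFactors = FALSE
  )
  fos_atlas(atl)
}

#' Read an atlas from a delimited text file
#'
#' @param path Path to a CSV file with header columns `code`, `name`, `group`.
#' @param sep Field separator (default `,`).
#' @return A validated `fos_atlas`.
#' @export
read_atlas <- function(path, sep = ",") {
  x <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      comment.char = "", quote = "\"", fill = FALSE),
    error = function(e) stop("failed to parse atlas file '", path, "': ",
                             conditionMessage(e))
  )
  fos_atlas(x)
}

#' Write an atlas to CSV
#' @param atlas A `fos_atlas`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "fos_atlas"))
  utils::write.csv(as.data.frame(atlas), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.fos_atlas <- function(x, ...) {
  cat("Region atlas:", nrow(x), "regions in",
      length(unique(x$group)), "anatomical groups\n")
  print(table(factor(x$group, levels = anatomical_groups())))
  invisible(x)
}
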