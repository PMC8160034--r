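#' Cross-condition Venn classification
#'
#' Partitions two upregulated-unit sets into the three Venn groups used when
#' comparing a perturbation across cell systems: `C1 = A \ B` (up only in
#' condition/system A), `C2 = A` intersect `B` (up in both), `C3 = B \ A`
#' (up only in B). For any inputs `|C1| + |C2| = |A|` and `|C2| + |C3| = |B|`.
#'
#' @param set_a,set_b character vectors of unit ids from one universe.
#' @return Object of class `venn_groups`: list with `labels` (`data.frame`
#'   id/group), `counts` (named C1/C2/C3 sizes) and the input sets.
#' @export
venn_classify <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  c2 <- intersect(set_a, set_b)
  c1 <- setdiff(set_a, set_b)
  c3 <- setdiff(set_b, set_a)
  ids <- c(c1, c2, c3)
  labels <- data.frame(id = ids,
                       group = factor(rep(c("C1", "C2", "C3"),
                                          c(length(c1), length(c2),
                                            length(c3))),
                                      levels = c("C1", "C2", "C3")),
                       stringsAsFactors = FALSE)
  labels <- labels[order(labels$id), , drop = FALSE]
  rownames(labels) <- NULL
  structure(list(labels = labels,
                 counts = c(C1 = length(c1), C2 = length(c2),
                            C3 = length(c3)),
                 set_a = set_a, set_b = set_b),
            class = "venn_groups")
}

#' @export
print.venn_groups <- function(x, ...) {
  cat("venn_groups: |A| =", length(x$set_a), ", |B| =", length(x$set_b),
      "-> C1 =", x$counts["C1"], ", C2 =", x$counts["C2"],
      ", C3 =", x$counts["C3"], "\n")
  invisible(x)
}

#' Define a reference-state-related unit set by fold change
#'
#' Units whose expression in the positive population exceeds the negative
#' population by more than `lfc_min` in log2 (strict inequality, pseudocount
#' on both means) — the construction used to call 2-cell-stage-related genes
#' and retrotransposons from sorted reporter-positive vs reporter-negative
#' expression tables.
#'
#' @param expr_pos,expr_neg named numeric expression vectors (FPKM or RPM)
#'   over one unit universe.
#' @param lfc_min log2 fold-change cutoff (default 1).
#' @param pseudocount added to both means (default 0.5, shared with the
#'   subfamily log2FC convention).
#' @return Sorted character vector of unit ids.
#' @export
define_2c_sets <- function(expr_pos, expr_neg, lfc_min = 1,
                           pseudocount = 0.5) {
  if (is.null(names(expr_pos)) || is.null(names(expr_neg)) ||
      !identical(sort(names(expr_pos)), sort(names(expr_neg)))) {
    stop("expr_pos and expr_neg must be named over the same unit universe")
  }
  expr_neg <- expr_neg[names(expr_pos)]
  lfc <- log2((expr_pos + pseudocount) / (expr_neg + pseudocount))
  sort(names(expr_pos)[lfc > lfc_min])
}

#' Cross-stage pipeline summary table
#'
#' Joins per-subfamily differential results, Venn group labels and mean
#' signal change into one deterministic table (rows in lexicographic
#' subfamily order). All inputs must cover the differential universe; missing
#' ids raise an error naming them.
#'
#' @param diff result of [differential_units()] (column `unit` is the key).
#' @param venn optional `venn_groups` object; units outside all groups get
#'   `"none"`.
#' @param signal optional `data.frame` with columns `unit` and `log2fc`
#'   (e.g. mean ChIP signal change per subfamily); must cover every unit.
#' @param enrichment optional `data.frame` with columns `unit`/`feature` and
#'   `ratio`; must cover every unit.
#' @return `data.frame`, one row per unit.
#' @export
summarize_pipeline <- function(diff, venn = NULL, signal = NULL,
                               enrichment = NULL) {
  out <- diff[order(diff$unit), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(venn)) {
    grp <- setNames(as.character(venn$labels$group), venn$labels$id)
    out$venn_group <- factor(
      ifelse(out$unit %in% names(grp), grp[out$unit], "none"),
      levels = c("C1", "C2", "C3", "none"))
  }
  add_col <- function(tab, value_col, new_name) {
    key <- if ("unit" %in% names(tab)) "unit" else "feature"
    missing <- setdiff(out$unit, tab[[key]])
    if (length(missing)) {
      stop("mismatched universes: ids absent from ", new_name, ": ",
           paste(utils::head(missing, 10), collapse = ", "))
    }
    out[[new_name]] <<- tab[[value_col]][match(out$unit, tab[[key]])]
  }
  if (!is.null(signal)) add_col(signal, "log2fc", "signal_log2fc")
  if (!is.null(enrichment)) add_col(enrichment, "ratio", "enrichment_ratio")
  out
}
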