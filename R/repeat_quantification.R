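#' Per-subfamily genomic regions after coding-gene exclusion
#'
#' For each repeat subfamily, merges its element intervals and removes every
#' base overlapped by a coding gene span (exons plus introns, merged before
#' subtraction), so that repeat expression is not confounded by host-gene
#' transcription. Subfamilies whose entire span lies inside coding genes are
#' retained with an empty region set and a warning.
#'
#' @param repeats `GRanges` of repeat elements with a `subfamily` column.
#' @param gm optional [gene_models]; when `NULL` no exclusion is applied.
#' @return Named `GRangesList`, one merged region set per subfamily.
#' @export
build_subfamily_regions <- function(repeats, gm = NULL) {
  validate_regions(repeats, "repeats")
  if (is.null(repeats$subfamily)) stop("repeats must carry a subfamily column")
  excl <- if (!is.null(gm)) gene_spans(gm, coding_only = TRUE)
    else GenomicRanges::GRanges()
  subs <- sort(unique(as.character(repeats$subfamily)))
  flat0 <- GenomicRanges::granges(repeats)
  GenomicRanges::strand(flat0) <- "*"
  grl <- GenomicRanges::reduce(S4Vectors::split(
    flat0, factor(as.character(repeats$subfamily), levels = subs)))
  if (length(excl)) {
    flat <- unlist(grl, use.names = FALSE)
    sub_of <- factor(rep(names(grl), S4Vectors::elementNROWS(grl)),
                     levels = subs)
    h <- .harmonize(flat, excl)
    pieces <- suppressWarnings(
      GenomicRanges::subtract(h$a, h$b, ignore.strand = TRUE))
    res_flat <- unlist(pieces, use.names = FALSE)
    res_sub <- rep(sub_of, S4Vectors::elementNROWS(pieces))
    grl <- S4Vectors::split(res_flat, res_sub)
  }
  empty <- S4Vectors::elementNROWS(grl) == 0L
  if (any(empty)) {
    warning(sum(empty), " subfamily(ies) with zero residual length after ",
            "coding-gene exclusion: ", paste(subs[empty], collapse = ", "))
  }
  grl
}

#' Quantify repeat subfamily expression
#'
#' Counts reads overlapping each subfamily's region set (a read is counted
#' once per subfamily; a read on two subfamilies increments both) and
#' normalizes to reads per million using the full library size.
#'
#' @param reads `GRanges` of read placements.
#' @param regions named `GRangesList` from [build_subfamily_regions()].
#' @param library_total total mapped reads; must be > 0 and at least the
#'   number of supplied reads.
#' @return `data.frame` with `subfamily`, `count`, `rpm`.
#' @export
quantify_subfamilies <- function(reads, regions, library_total) {
  validate_regions(reads, "reads")
  if (!is.numeric(library_total) || library_total <= 0) {
    stop("library_total must be > 0")
  }
  if (library_total < length(reads)) {
    stop("library_total is smaller than the number of supplied reads")
  }
  flat <- suppressWarnings(unlist(regions, use.names = FALSE))
  sub_of <- rep(seq_along(regions), S4Vectors::elementNROWS(regions))
  h <- .harmonize(reads, flat)
  hits <- GenomicRanges::findOverlaps(h$a, h$b, ignore.strand = TRUE)
  pair <- unique(data.frame(read = S4Vectors::queryHits(hits),
                            sub = sub_of[S4Vectors::subjectHits(hits)]))
  counts <- tabulate(pair$sub, nbins = length(regions))
  data.frame(subfamily = names(regions), count = counts,
             rpm = counts / (library_total / 1e6),
             stringsAsFactors = FALSE)
}

#' Fragments per kilobase per million mapped reads
#'
#' `fpkm = count * 1e9 / (length * mapped)`.
#'
#' @param counts per-transcript read counts.
#' @param lengths effective transcript lengths in bases; must be > 0.
#' @param mapped total mapped reads in the library; must be > 0.
#' @param ids optional transcript/gene ids.
#' @return `data.frame` with `id`, `count`, `length`, `fpkm`.
#' @export
fpkm <- function(counts, lengths, mapped, ids = NULL) {
  if (any(lengths <= 0)) stop("transcript length must be > 0")
  if (mapped <= 0) stop("mapped must be > 0")
  if (is.null(ids)) ids <- paste0("t", seq_along(counts))
  data.frame(id = ids, count = counts, length = lengths,
             fpkm = counts * 1e9 / (lengths * as.numeric(mapped)),
             stringsAsFactors = FALSE)
}

#' Differential expression of quantified units
#'
#' Calls differential repeat subfamilies (or any counted units) between two
#' conditions. The log2 fold change is computed on replicate-mean RPM with a
#' 0.5 pseudocount on each mean. The p-value is a two-sided conditional
#' binomial exact test of the replicate-summed counts of condition A against
#' condition B, with library sizes as offsets (`binom.test` of `k_a` out of
#' `k_a + k_b` against `p = lib_a / (lib_a + lib_b)`). This models technical
#' sampling only and is not a replacement for a dispersion-aware test such as
#' edgeR on biologically variable replicates.
#'
#' Categories follow strict inequalities: `up` when `log2fc > up_lfc` and
#' `p < p_max`; `down` symmetric; `unchanged` when `|log2fc| < unchanged_band`;
#' otherwise `neither`. Units with zero counts in both conditions get `p = 1`
#' and `neither`.
#'
#' @param counts_a,counts_b numeric matrices (units x replicates) or vectors
#'   of raw counts per condition; rows must correspond.
#' @param lib_a,lib_b per-replicate library sizes (recycled if scalar).
#' @param up_lfc log2FC threshold for up/down calls (default 0.3).
#' @param p_max p-value threshold (default 0.05).
#' @param unchanged_band half-width of the unchanged band (default 0.1).
#' @param ids optional unit ids (defaults to rownames or an index).
#' @return `data.frame` with `unit`, `count_a`, `count_b`, `rpm_a`, `rpm_b`,
#'   `log2fc`, `p`, `category`.
#' @export
differential_units <- function(counts_a, counts_b, lib_a, lib_b,
                               up_lfc = 0.3, p_max = 0.05,
                               unchanged_band = 0.1, ids = NULL) {
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  if (nrow(counts_a) != nrow(counts_b)) {
    stop("counts_a and counts_b must have the same number of units")
  }
  if (up_lfc <= 0 || p_max <= 0 || unchanged_band <= 0) {
    stop("thresholds must be positive")
  }
  lib_a <- rep_len(lib_a, ncol(counts_a))
  lib_b <- rep_len(lib_b, ncol(counts_b))
  if (is.null(ids)) {
    ids <- rownames(counts_a)
    if (is.null(ids)) ids <- paste0("unit_", seq_len(nrow(counts_a)))
  }
  rpm_a <- rowMeans(sweep(counts_a, 2, lib_a / 1e6, "/"))
  rpm_b <- rowMeans(sweep(counts_b, 2, lib_b / 1e6, "/"))
  lfc <- log2((rpm_b + 0.5) / (rpm_a + 0.5))
  ka <- rowSums(counts_a)
  kb <- rowSums(counts_b)
  p0 <- sum(lib_a) / (sum(lib_a) + sum(lib_b))
  p <- vapply(seq_along(ka), function(i) {
    n <- ka[i] + kb[i]
    if (n == 0) return(1)
    stats::binom.test(round(ka[i]), round(n), p = p0)$p.value
  }, numeric(1))
  cat_ <- ifelse(ka + kb == 0, "neither",
          ifelse(lfc > up_lfc & p < p_max, "up",
          ifelse(lfc < -up_lfc & p < p_max, "down",
          ifelse(abs(lfc) < unchanged_band, "unchanged", "neither"))))
  data.frame(unit = ids, count_a = ka, count_b = kb,
             rpm_a = rpm_a, rpm_b = rpm_b, log2fc = lfc, p = p,
             category = factor(cat_, levels = c("up", "down", "unchanged",
                                                "neither")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Define differentially expressed genes from FPKM tables
#'
#' Genes with averaged FPKM below `min_fpkm` across the two conditions are
#' removed first; the survivors are classified by fold change (strict
#' inequality) with a small pseudocount guarding zero denominators.
#'
#' @param fpkm_a,fpkm_b named numeric vectors of FPKM over one gene universe.
#' @param fold fold-change cutoff (default 2).
#' @param min_fpkm low-expression floor on the two-condition average
#'   (default 0.1).
#' @param pseudocount added to both FPKM values in the ratio (default 0.01,
#'   an order below the expression floor).
#' @return List with `up`, `down` (gene id vectors, B relative to A) and
#'   `tested` (ids surviving the expression filter).
#' @export
define_degs <- function(fpkm_a, fpkm_b, fold = 2, min_fpkm = 0.1,
                        pseudocount = 0.01) {
  if (is.null(names(fpkm_a)) || is.null(names(fpkm_b)) ||
      !identical(sort(names(fpkm_a)), sort(names(fpkm_b)))) {
    stop("fpkm_a and fpkm_b must be named over the same gene universe")
  }
  fpkm_b <- fpkm_b[names(fpkm_a)]
  keep <- (fpkm_a + fpkm_b) / 2 >= min_fpkm
  a <- fpkm_a[keep] + pseudocount
  b <- fpkm_b[keep] + pseudocount
  list(up = sort(names(a)[b / a > fold]),
       down = sort(names(a)[a / b > fold]),
       tested = sort(names(a)))
}
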