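#' High-confidence peaks from two replicates
#'
#' Peaks called in both replicates (>= `min_overlap` shared bases) are kept.
#' By default each retained replicate-1 peak is clipped to the span covered by
#' its intersections with replicate-2 peaks; `clip = FALSE` keeps the full
#' replicate-1 coordinates instead (both behaviours are consistent with
#' replicate-intersection peak filtering; the clipped span is the default).
#' The replicate-1 fold-enrichment score is carried through.
#'
#' @param rep1,rep2 peak `GRanges` from two replicates of one condition
#'   (a `score` column, when present, is preserved from `rep1`).
#' @param clip clip locations to the intersected span (default `TRUE`).
#' @param min_overlap minimum shared bases (default 1).
#' @return `GRanges` of high-confidence peaks (subset of `rep1`).
#' @export
high_confidence_peaks <- function(rep1, rep2, clip = TRUE, min_overlap = 1L) {
  if (!length(rep1) || !length(rep2)) {
    warning("empty replicate peak list; no high-confidence peaks")
    return(rep1[0])
  }
  validate_regions(rep1, "rep1")
  validate_regions(rep2, "rep2")
  hits <- GenomicRanges::findOverlaps(rep1, rep2, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  out <- rep1[keep]
  if (clip && length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    int_start <- pmax(GenomicRanges::start(rep1)[q],
                      GenomicRanges::start(rep2)[s])
    int_end <- pmin(GenomicRanges::end(rep1)[q], GenomicRanges::end(rep2)[s])
    new_start <- vapply(keep, function(k) min(int_start[q == k]), numeric(1))
    new_end <- vapply(keep, function(k) max(int_end[q == k]), numeric(1))
    GenomicRanges::ranges(out) <- IRanges::IRanges(new_start, new_end)
  }
  out
}

#' Classify peaks by knockout sensitivity
#'
#' A wild-type peak with zero base-pair overlap against every knockout peak is
#' `sensitive` (the mark vanishes when the writer is removed); a peak
#' overlapping at least one knockout peak is `insensitive` (the mark
#' persists). Every WT peak receives exactly one label.
#'
#' @param peaks_wt high-confidence peak `GRanges` from the wild-type
#'   condition.
#' @param peaks_ko high-confidence peak `GRanges` from the knockout condition.
#' @param min_overlap minimum shared bases that counts as "retained"
#'   (default 1).
#' @return `peaks_wt` with an added `sensitivity` factor column
#'   (`sensitive`/`insensitive`).
#' @export
classify_sensitivity <- function(peaks_wt, peaks_ko, min_overlap = 1L) {
  validate_regions(peaks_wt, "peaks_wt")
  retained <- if (length(peaks_ko)) {
    IRanges::overlapsAny(peaks_wt, peaks_ko, minoverlap = min_overlap,
                               ignore.strand = TRUE)
  } else {
    rep(FALSE, length(peaks_wt))
  }
  peaks_wt$sensitivity <- factor(ifelse(retained, "insensitive", "sensitive"),
                                 levels = c("sensitive", "insensitive"))
  peaks_wt
}

#' Label elements by the kinds of marks they carry
#'
#' Each element (e.g. a repeat transcript) is labelled by which peak classes
#' overlap it: `sensitive-only`, `insensitive-only`, `both`, or `none`.
#' The four labels are mutually exclusive and exhaustive.
#'
#' @param elements `GRanges` of elements/transcripts.
#' @param sensitive,insensitive peak `GRanges` of the two classes.
#' @param min_overlap minimum shared bases (default 1).
#' @return Factor vector, one label per element.
#' @export
label_transcripts <- function(elements, sensitive, insensitive,
                              min_overlap = 1L) {
  validate_regions(elements, "elements")
  hit_s <- if (length(sensitive)) {
    IRanges::overlapsAny(elements, sensitive, minoverlap = min_overlap,
                               ignore.strand = TRUE)
  } else rep(FALSE, length(elements))
  hit_i <- if (length(insensitive)) {
    IRanges::overlapsAny(elements, insensitive,
                               minoverlap = min_overlap, ignore.strand = TRUE)
  } else rep(FALSE, length(elements))
  lab <- ifelse(hit_s & hit_i, "both",
         ifelse(hit_s, "sensitive-only",
         ifelse(hit_i, "insensitive-only", "none")))
  factor(lab, levels = c("sensitive-only", "insensitive-only", "both", "none"))
}

#' Classify regions by signal change between two conditions
#'
#' For each region, `log2fc = log2((mean_b + eps) / (mean_a + eps))` of
#' depth-normalized signal; regions with `log2fc` strictly below
#' `lfc_threshold` are `decreased`, the rest `other` (the convention used for
#' calling corepressor peaks that lose occupancy in a knockout, threshold
#' -0.2).
#'
#' @param regions `GRanges`.
#' @param track_a,track_b depth-normalized [signal_track]s (condition A =
#'   reference, condition B = perturbed).
#' @param lfc_threshold log2 fold-change cutoff; must be negative for the
#'   `decreased` semantics (default -0.2).
#' @param eps pseudocount in RPM-equivalents (default 1).
#' @return `data.frame` with `chrom`, `start`, `end`, `mean_a`, `mean_b`,
#'   `log2fc`, `category` (`decreased`/`other`).
#' @export
classify_signal_change <- function(regions, track_a, track_b,
                                   lfc_threshold = -0.2, eps = 1) {
  validate_regions(regions)
  if (any(GenomicRanges::width(regions) < 1L)) stop("zero-length region")
  ma <- region_means(track_a, regions)
  mb <- region_means(track_b, regions)
  lfc <- log2((mb + eps) / (ma + eps))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    mean_a = ma, mean_b = mb, log2fc = lfc,
    category = factor(ifelse(lfc < lfc_threshold, "decreased", "other"),
                      levels = c("decreased", "other")),
    stringsAsFactors = FALSE
  )
}

#' Percentage of regions classified as decreased
#'
#' @param changes result of [classify_signal_change()], or any object with a
#'   `category` column.
#' @return Percentage (0-100) of regions in the `decreased` category.
#' @export
percent_decreased <- function(changes) {
  100 * mean(changes$category == "decreased")
}

#' Define RIP target genes
#'
#' A gene is a RIP target when at least one peak with fold enrichment strictly
#' above `min_fold` overlaps its exons or introns (i.e. its transcript span).
#'
#' @param gm [gene_models].
#' @param rip_peaks peak `GRanges` with a `score` (fold enrichment) column.
#' @param min_fold fold-enrichment cutoff, strict inequality (default 5).
#' @param coding_only restrict to coding genes (default `TRUE`).
#' @return Character vector of gene ids.
#' @export
define_rip_targets <- function(gm, rip_peaks, min_fold = 5,
                               coding_only = TRUE) {
  stopifnot(inherits(gm, "gene_models"))
  validate_regions(rip_peaks, "rip_peaks")
  if (is.null(rip_peaks$score)) stop("rip_peaks must carry a score column")
  strong <- rip_peaks[rip_peaks$score > min_fold]
  spans <- transcript_spans(gm)
  if (coding_only) spans <- spans[spans$biotype == "coding"]
  hit <- IRanges::overlapsAny(spans, strong, ignore.strand = TRUE)
  sort(unique(spans$gene_id[hit]))
}
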