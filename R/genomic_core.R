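#' @import methods
#' @importFrom stats phyper binom.test rnbinom rpois runif rnorm setNames
#' @importFrom utils read.table write.table
NULL

#' Build a region set from BED-style coordinates
#'
#' Convenience constructor turning 0-based half-open (BED convention)
#' coordinates into the `GRanges` objects used throughout the package.
#' All file formats are converted at the I/O boundary so that every
#' in-memory interval follows one convention.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive starts.
#' @param end integer vector, exclusive ends; must satisfy `end > start`.
#' @param strand strand codes; `"."` (unstranded) is mapped to `"*"`.
#' @param ... further per-interval metadata columns (e.g. `score`).
#' @param seqlengths optional named vector of chromosome lengths.
#' @return A `GRanges` with one range per input interval.
#' @examples
#' region_set("chr1", 0, 100)
#' @export
region_set <- function(chrom, start, end, strand = "*", ...,
                       seqlengths = NULL) {
  if (length(chrom) == 0L) {
    return(GenomicRanges::GRanges(seqlengths = seqlengths))
  }
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  bad <- which(is.na(chrom) | !nzchar(chrom) | is.na(start) | is.na(end) |
                 start < 0 | end <= start)
  if (length(bad)) {
    stop("malformed interval at record ", bad[1], ": ",
         chrom[bad[1]], ":", start[bad[1]], "-", end[bad[1]],
         " (need chrom non-empty, start >= 0, end > start)")
  }
  strand <- as.character(strand)
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = strand
  )
  extra <- list(...)
  if (length(extra)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(extra)
  }
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

#' Validate a region set
#'
#' Checks that an object is a `GRanges` with strictly positive widths.
#' Used by all operations that accept user-supplied intervals.
#'
#' @param regions object to validate.
#' @param what label used in error messages.
#' @return The input, invisibly, if valid.
#' @export
validate_regions <- function(regions, what = "regions") {
  if (!methods::is(regions, "GRanges")) {
    stop(what, " must be a GRanges object")
  }
  bad <- which(GenomicRanges::width(regions) < 1L)
  if (length(bad)) {
    stop("malformed interval in ", what, " at record ", bad[1],
         ": zero or negative width")
  }
  invisible(regions)
}

.harmonize <- function(a, b) {
  ## setdiff/intersect need one seqinfo; union the levels, drop lengths
  lev <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lev
  GenomeInfoDb::seqlevels(b) <- lev
  list(a = a, b = b)
}

#' Merge a region set into its minimal disjoint cover
#'
#' Strand-blind union of intervals (bedtools `merge` semantics): overlapping
#' or bookended intervals on one chromosome collapse into one. Idempotent and
#' base-coverage preserving.
#'
#' @param regions `GRanges`.
#' @return Merged, sorted `GRanges` on the `*` strand.
#' @export
merge_regions <- function(regions) {
  validate_regions(regions)
  GenomicRanges::reduce(GenomicRanges::granges(regions), ignore.strand = TRUE)
}

#' Subtract one region set from another
#'
#' Returns the bases covered by `a` and not by `b` (strand-blind, bedtools
#' `subtract` semantics).
#'
#' @param a,b `GRanges`.
#' @return Merged `GRanges` covering `a \ b`.
#' @export
subtract_regions <- function(a, b) {
  validate_regions(a, "a")
  validate_regions(b, "b")
  h <- .harmonize(GenomicRanges::granges(a), GenomicRanges::granges(b))
  suppressWarnings(GenomicRanges::setdiff(h$a, h$b, ignore.strand = TRUE))
}

#' Intersect two region sets
#'
#' Bases covered by both sets; symmetric and strand-blind.
#'
#' @param a,b `GRanges`.
#' @return Merged `GRanges` covering `a` intersected with `b`.
#' @export
intersect_regions <- function(a, b) {
  validate_regions(a, "a")
  validate_regions(b, "b")
  h <- .harmonize(GenomicRanges::granges(a), GenomicRanges::granges(b))
  suppressWarnings(GenomicRanges::intersect(h$a, h$b, ignore.strand = TRUE))
}

#' Total bases covered by a region set
#'
#' @param regions `GRanges`; merged first so overlaps are not double counted.
#' @return Integer number of covered bases.
#' @export
region_length <- function(regions) {
  sum(as.numeric(GenomicRanges::width(merge_regions(regions))))
}

#' Count reads per target interval
#'
#' Under `mode = "any"` a read overlapping at least `min_overlap` bases of a
#' target is counted once for that target; a read spanning two targets
#' increments both. Under `mode = "contained"` only reads lying entirely
#' inside the target are counted. Reads on chromosomes absent from the target
#' set are skipped with a warning summarising how many were dropped.
#'
#' @param reads `GRanges` of read placements.
#' @param targets `GRanges` of target intervals.
#' @param mode `"any"` (default) or `"contained"`.
#' @param min_overlap minimum shared bases for `"any"` mode (default 1).
#' @return Integer vector of counts, one per target interval.
#' @export
count_reads <- function(reads, targets, mode = c("any", "contained"),
                        min_overlap = 1L) {
  mode <- match.arg(mode)
  validate_regions(reads, "reads")
  validate_regions(targets, "targets")
  known <- unique(as.character(GenomicRanges::seqnames(targets)))
  rchrom <- as.character(GenomicRanges::seqnames(reads))
  unknown <- !(rchrom %in% known)
  if (any(unknown)) {
    warning(sum(unknown), " read(s) on chromosome(s) absent from targets (",
            paste(unique(rchrom[unknown]), collapse = ", "),
            ") were skipped")
    reads <- reads[!unknown]
  }
  h <- .harmonize(reads, targets)
  if (mode == "any") {
    GenomicRanges::countOverlaps(h$b, h$a, minoverlap = min_overlap,
                                 ignore.strand = TRUE)
  } else {
    hits <- GenomicRanges::findOverlaps(h$a, h$b, type = "within",
                                        ignore.strand = TRUE)
    tabulate(S4Vectors::subjectHits(hits), nbins = length(targets))
  }
}
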