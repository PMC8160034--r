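#' Signal track
#'
#' Per-base step function of non-negative coverage, one run-length-encoded
#' vector per chromosome, with the library size used for depth normalization
#' recorded. Positions beyond a chromosome's stored extent have value 0.
#'
#' @param coverage `RleList`, one numeric `Rle` per chromosome.
#' @param library_total library size used for normalization (`NA` when the
#'   track was read pre-normalized).
#' @return Object of class `signal_track`.
#' @export
signal_track <- function(coverage, library_total = NA_real_) {
  stopifnot(methods::is(coverage, "RleList"))
  structure(list(coverage = coverage, library_total = library_total),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track over", length(x$coverage), "chromosome(s);",
      "library_total =", x$library_total, "\n")
  invisible(x)
}

#' Depth-normalized coverage from read placements
#'
#' Per-base read depth scaled to reads per million (RPM): depth times
#' `1e6 / library_total` (bedtools `genomecov` followed by depth
#' normalization).
#'
#' @param reads `GRanges` of read placements.
#' @param library_total total mapped reads in the library; must be > 0.
#' @param chrom_sizes optional named chromosome lengths fixing track extent.
#' @return A [signal_track].
#' @export
coverage_from_reads <- function(reads, library_total, chrom_sizes = NULL) {
  validate_regions(reads, "reads")
  if (!is.numeric(library_total) || library_total <= 0) {
    stop("library_total must be > 0")
  }
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlevels(reads) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(reads) <- chrom_sizes
  }
  cov <- GenomicRanges::coverage(reads) * (1e6 / library_total)
  signal_track(cov, library_total = library_total)
}

#' Mean track value over regions
#'
#' Length-weighted mean of the step function over each region; bases outside
#' the stored track extent count as 0.
#'
#' @param track [signal_track].
#' @param regions `GRanges`.
#' @return Numeric vector, one mean per region.
#' @export
region_means <- function(track, regions) {
  stopifnot(inherits(track, "signal_track"))
  validate_regions(regions)
  cov <- track$coverage
  chrom <- as.character(GenomicRanges::seqnames(regions))
  starts <- GenomicRanges::start(regions)
  ends <- GenomicRanges::end(regions)
  vapply(seq_along(regions), function(i) {
    if (!(chrom[i] %in% names(cov))) return(0)
    r <- cov[[chrom[i]]]
    lo <- max(starts[i], 1L)
    hi <- min(ends[i], length(r))
    tot <- if (hi >= lo) sum(as.numeric(S4Vectors::window(r, lo, hi))) else 0
    tot / (ends[i] - starts[i] + 1)
  }, numeric(1))
}

#' IP over input signal intensity for one region
#'
#' The ratio (IP/input) of mean depth-normalized coverage, each mean
#' stabilized with a pseudocount so zero-coverage regions stay finite:
#' `(mean_ip + eps) / (mean_input + eps)`.
#'
#' @param ip,input [signal_track]s, both depth-normalized.
#' @param region single-range `GRanges`.
#' @param eps pseudocount in RPM-equivalents (default 1).
#' @return Numeric ratio.
#' @export
region_signal <- function(ip, input, region, eps = 1) {
  if (length(region) != 1L) stop("region must be a single interval")
  validate_regions(region, "region")
  (region_means(ip, region) + eps) / (region_means(input, region) + eps)
}

## exact length-weighted mean of a per-base vector over `bins` equal
## fractions, allowing fractional bin boundaries
.bin_means <- function(v, bins) {
  n <- length(v)
  cs <- c(0, cumsum(v))
  edges <- seq(0, n, length.out = bins + 1)
  integral <- function(x) {
    f <- floor(x)
    val <- cs[f + 1]
    if (f < n) val <- val + (x - f) * v[f + 1]
    val
  }
  upper <- vapply(edges, integral, numeric(1))
  diff(upper) / diff(edges)
}

.region_vector <- function(cov, chrom, start, end) {
  v <- numeric(end - start + 1)
  if (chrom %in% names(cov)) {
    r <- cov[[chrom]]
    lo <- max(start, 1L)
    hi <- min(end, length(r))
    if (hi >= lo) {
      v[(lo - start + 1):(hi - start + 1)] <-
        as.numeric(S4Vectors::window(r, lo, hi))
    }
  }
  v
}

#' Metagene body profile over elements
#'
#' Rescales each element body to `body_bins` equal fractions, takes the
#' length-weighted mean of the track within each fraction (exact on step
#' functions), orients minus-strand elements so bin 1 is always the 5' end,
#' optionally adds fixed-width flanks, and averages across elements.
#'
#' @param track [signal_track].
#' @param elements stranded `GRanges`; elements shorter than `body_bins`
#'   bases are skipped with a warning.
#' @param body_bins number of body bins (default 100).
#' @param flank flank width in bases on each side (default 0 = body only).
#' @param flank_bins bins per flank (default 0).
#' @return Object of class `metagene_profile`: list with `profile` (numeric,
#'   `flank_bins + body_bins + flank_bins` values), `n_elements`, `body_bins`,
#'   `flank_bins`.
#' @export
metagene_body_profile <- function(track, elements, body_bins = 100L,
                                  flank = 0L, flank_bins = 0L) {
  stopifnot(inherits(track, "signal_track"))
  validate_regions(elements, "elements")
  if (flank > 0 && flank_bins < 1) stop("flank > 0 requires flank_bins >= 1")
  short <- GenomicRanges::width(elements) < body_bins
  if (any(short)) {
    warning(sum(short), " element(s) shorter than body_bins were skipped")
    elements <- elements[!short]
  }
  if (!length(elements)) stop("no elements long enough to profile")
  cov <- track$coverage
  chrom <- as.character(GenomicRanges::seqnames(elements))
  starts <- GenomicRanges::start(elements)
  ends <- GenomicRanges::end(elements)
  minus <- as.character(GenomicRanges::strand(elements)) == "-"
  nb <- body_bins + 2L * flank_bins
  acc <- numeric(nb)
  for (i in seq_along(elements)) {
    v <- .region_vector(cov, chrom[i], starts[i] - flank, ends[i] + flank)
    if (minus[i]) v <- rev(v)
    if (flank > 0) {
      w <- length(v)
      row <- c(.bin_means(v[seq_len(flank)], flank_bins),
               .bin_means(v[(flank + 1):(w - flank)], body_bins),
               .bin_means(v[(w - flank + 1):w], flank_bins))
    } else {
      row <- .bin_means(v, body_bins)
    }
    acc <- acc + row
  }
  structure(list(profile = acc / length(elements),
                 n_elements = length(elements),
                 body_bins = body_bins, flank_bins = flank_bins),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile:", x$body_bins, "body bins,", x$flank_bins,
      "flank bins,", x$n_elements, "elements; peak bin",
      which.max(x$profile), "\n")
  invisible(x)
}
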