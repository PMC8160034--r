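## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's interval machinery: membership is computed on plain
## per-base logical vectors, counts by nested scans, tails by direct
## summation of the probability mass. Calls are namespace-qualified so the
## helpers work identically under every test runner.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

ORACLE_CHROMS <- c("chrA", "chrB", "chrC")
ORACLE_LEN <- 3000L

## random 1-based-closed intervals as a GRanges
rand_regions <- function(n, chroms = ORACLE_CHROMS, len = ORACLE_LEN,
                         max_width = 80L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(len - max_width - 1L, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = width))
}

## per-base membership mask: list of logical vectors, one per chromosome
mask_of <- function(gr, chroms = ORACLE_CHROMS, len = ORACLE_LEN) {
  out <- lapply(chroms, function(ch) {
    v <- logical(len)
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    for (i in seq_along(g)) {
      v[seq(GenomicRanges::start(g)[i],
            min(GenomicRanges::end(g)[i], len))] <- TRUE
    }
    v
  })
  names(out) <- chroms
  out
}

masks_equal <- function(a, b) {
  all(vapply(names(a), function(ch) identical(a[[ch]], b[[ch]]), logical(1)))
}

## nested-scan read counting per target
oracle_count <- function(reads, targets, mode = "any") {
  rs <- GenomicRanges::start(reads); re <- GenomicRanges::end(reads)
  rc <- as.character(GenomicRanges::seqnames(reads))
  vapply(seq_along(targets), function(i) {
    ts <- GenomicRanges::start(targets)[i]
    te <- GenomicRanges::end(targets)[i]
    tc <- as.character(GenomicRanges::seqnames(targets))[i]
    same <- rc == tc
    if (mode == "any") {
      sum(same & rs <= te & re >= ts)
    } else {
      sum(same & rs >= ts & re <= te)
    }
  }, integer(1))
}

## direct mass summation of the hypergeometric upper tail on log scale
oracle_hyper_tail <- function(universe, set_a, set_b, overlap) {
  ks <- seq(overlap, min(set_a, set_b))
  if (!length(ks)) return(0)
  sum(exp(lchoose(set_a, ks) + lchoose(universe - set_a, set_b - ks) -
            lchoose(universe, set_b)))
}

## regex-free nested-loop IUPAC scan (sense strand, overlaps allowed)
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracle_motif_count <- function(seq, motif) {
  s <- strsplit(toupper(gsub("U", "T", seq)), "")[[1]]
  m <- strsplit(toupper(gsub("U", "T", motif)), "")[[1]]
  k <- length(m)
  if (length(s) < k) return(0L)
  n <- 0L
  for (i in seq_len(length(s) - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(s[i + j - 1L] %in% IUPAC_SETS[[m[j]]])) { ok <- FALSE; break }
    }
    if (ok) n <- n + 1L
  }
  n
}
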