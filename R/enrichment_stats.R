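#' Genomic feature classes for enrichment analysis
#'
#' Builds the named region sets used by [relative_enrichment()]: `PROMPT`
#' (promoter-upstream-transcript window, by default the strand-aware 2 kb
#' immediately upstream of each TSS, truncated at chromosome boundaries),
#' `exon`, `intron`, and `retrotransposon`.
#'
#' @param gm [gene_models].
#' @param repeats `GRanges` of repeat elements.
#' @param prompt_span upstream window size in bases (default 2000).
#' @param chrom_sizes optional named chromosome lengths used to truncate
#'   windows at chromosome ends.
#' @return Named list of merged `GRanges`.
#' @export
feature_classes <- function(gm, repeats, prompt_span = 2000L,
                            chrom_sizes = NULL) {
  stopifnot(inherits(gm, "gene_models"))
  tx <- transcript_spans(gm)
  pr <- GenomicRanges::promoters(tx, upstream = prompt_span, downstream = 0L)
  GenomicRanges::start(pr) <- pmax(GenomicRanges::start(pr), 1L)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[as.character(GenomicRanges::seqnames(pr))]
    GenomicRanges::end(pr) <- pmin(GenomicRanges::end(pr), unname(lim))
  }
  pr <- pr[GenomicRanges::width(pr) > 0]
  list(PROMPT = merge_regions(pr),
       exon = exon_regions(gm),
       intron = intron_regions(gm),
       retrotransposon = merge_regions(repeats))
}

#' Relative enrichment of peaks over genomic features
#'
#' For each feature class, the fraction of peaks falling on the feature is
#' divided by the fraction of input reads falling on the same feature; a
#' ratio of 1 indicates no enrichment. Under the default `mode = "multi"` a
#' peak (or read) counts toward every feature it overlaps, matching read
#' counting elsewhere in the package; `mode = "priority"` assigns each peak
#' to the single first feature it overlaps in the order given (useful when
#' the classes are meant to be near-exclusive).
#'
#' @param peaks peak `GRanges`.
#' @param features named list of feature `GRanges` (see [feature_classes()]).
#' @param input_reads `GRanges` of input-library read placements; non-empty.
#' @param mode `"multi"` (default) or `"priority"`.
#' @return `data.frame` with `feature`, `peak_fraction`, `input_fraction`,
#'   `ratio`, and `undefined` (TRUE where the feature received no input reads,
#'   in which case `ratio` is `NA` rather than infinite).
#' @export
relative_enrichment <- function(peaks, features, input_reads,
                                mode = c("multi", "priority")) {
  mode <- match.arg(mode)
  validate_regions(peaks, "peaks")
  if (!length(input_reads)) stop("input_reads must be non-empty")
  validate_regions(input_reads, "input_reads")
  frac <- function(query) {
    if (mode == "multi") {
      vapply(features, function(f) {
        h <- .harmonize(query, f)
        mean(IRanges::overlapsAny(h$a, h$b, ignore.strand = TRUE))
      }, numeric(1))
    } else {
      assigned <- rep(NA_integer_, length(query))
      for (i in seq_along(features)) {
        h <- .harmonize(query, features[[i]])
        hit <- IRanges::overlapsAny(h$a, h$b, ignore.strand = TRUE)
        assigned[is.na(assigned) & hit] <- i
      }
      vapply(seq_along(features),
             function(i) sum(assigned == i, na.rm = TRUE), numeric(1)) /
        length(query)
    }
  }
  pf <- frac(peaks)
  inf <- frac(input_reads)
  undef <- inf == 0
  data.frame(feature = names(features),
             peak_fraction = pf, input_fraction = inf,
             ratio = ifelse(undef, NA_real_, pf / inf),
             undefined = undef,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least `overlap` common members between two
#' sets of sizes `set_a` and `set_b` drawn from a universe of `universe`
#' units: `P(X >= overlap)` for `X ~ Hypergeometric(universe, set_a, set_b)`.
#' The universe size is an explicit argument and is recorded in the result.
#'
#' @param universe number of units in the universe.
#' @param set_a,set_b sizes of the two sets; each at most `universe`.
#' @param overlap observed overlap; at most `min(set_a, set_b)`.
#' @return List of class `hyper_overlap` with `p.value`, `expected` overlap
#'   under independence, and the input counts.
#' @export
hypergeometric_overlap <- function(universe, set_a, set_b, overlap) {
  if (set_a > universe || set_b > universe || overlap > min(set_a, set_b) ||
      overlap < 0 || any(c(universe, set_a, set_b) < 0)) {
    stop("inconsistent counts: need overlap <= min(set_a, set_b) and ",
         "set sizes <= universe")
  }
  if (overlap < set_a + set_b - universe) {
    stop("inconsistent counts: overlap below the forced minimum ",
         set_a + set_b - universe)
  }
  p <- stats::phyper(overlap - 1, set_a, universe - set_a, set_b,
                     lower.tail = FALSE)
  structure(list(p.value = p,
                 expected = set_a * set_b / universe,
                 universe = universe, set_a = set_a, set_b = set_b,
                 overlap = overlap),
            class = "hyper_overlap")
}

#' @export
print.hyper_overlap <- function(x, ...) {
  cat("hypergeometric overlap test\n",
      " universe =", x$universe, "; |A| =", x$set_a, "; |B| =", x$set_b,
      "; overlap =", x$overlap, "\n",
      " expected overlap =", signif(x$expected, 4),
      "; P(X >= overlap) =", format(x$p.value, digits = 4), "\n")
  invisible(x)
}

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Built-in IUPAC motif presets
#'
#' `RRACH` is the writer-complex consensus (R = A/G, H = A/C/U); `ABAG`
#' (B = C/G/U) and `ACAGAGA` relate to the U6-snRNA-recognition consensus of
#' the alternative methyltransferase.
#'
#' @param name one of `"RRACH"`, `"ABAG"`, `"ACAGAGA"`.
#' @return The motif string.
#' @export
motif_preset <- function(name = c("RRACH", "ABAG", "ACAGAGA")) {
  match.arg(name)
}

#' Sense-strand IUPAC motif density
#'
#' Counts motif occurrences in each sequence by sliding window with overlaps
#' allowed (sense strand only: the targets are RNA-derived sequences, so the
#' reverse complement is not scanned) and reports occurrences per kilobase.
#' `T` and `U` are equivalent.
#'
#' @param sequences `DNAStringSet`, `RNAStringSet`, or character vector
#'   (optionally named).
#' @param motif IUPAC motif string, e.g. `"RRACH"`.
#' @return `data.frame` with `id`, `length`, `occurrences`, `density`
#'   (occurrences per kb).
#' @export
motif_density <- function(sequences, motif) {
  motif <- toupper(gsub("U", "T", motif))
  bad <- setdiff(strsplit(motif, "")[[1]], names(.IUPAC))
  if (length(bad)) {
    stop("invalid IUPAC symbol in motif: ", paste(bad, collapse = ", "))
  }
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(toupper(gsub("U", "T", sequences)))
  } else if (methods::is(sequences, "RNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq_", seq_along(sequences))
  occ <- Biostrings::vcountPattern(motif, sequences, fixed = FALSE)
  len <- Biostrings::width(sequences)
  data.frame(id = ids, length = len, occurrences = occ,
             density = occ / len * 1000,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percent spliced in
#'
#' `psi = inclusion / (inclusion + exclusion)`, the fraction of transcripts
#' including a designated exon. When both counts are zero PSI is undefined
#' and flagged rather than returned as NaN silently.
#'
#' @param inclusion,exclusion non-negative read counts (vectorized).
#' @param ids optional exon ids.
#' @return `data.frame` with `id`, `inclusion`, `exclusion`, `psi`,
#'   `defined`.
#' @export
psi <- function(inclusion, exclusion, ids = NULL) {
  if (any(inclusion < 0) || any(exclusion < 0)) {
    stop("counts must be non-negative")
  }
  n <- max(length(inclusion), length(exclusion))
  inclusion <- rep_len(inclusion, n)
  exclusion <- rep_len(exclusion, n)
  if (is.null(ids)) ids <- paste0("exon_", seq_len(n))
  tot <- inclusion + exclusion
  data.frame(id = ids, inclusion = inclusion, exclusion = exclusion,
             psi = ifelse(tot == 0, NA_real_, inclusion / tot),
             defined = tot > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}
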