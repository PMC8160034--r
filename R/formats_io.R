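#' Read a BED file
#'
#' Parses 3- to 6-column BED. Columns 1-3 become intervals (converted from
#' the file's 0-based half-open convention), column 4 a `name`, column 5 a
#' numeric `score` interpreted as MACS2-style fold enrichment (real valued,
#' not the UCSC 0-1000 display score), column 6 the strand.
#'
#' @param path file path.
#' @param chrom_sizes optional named vector of chromosome lengths; when given,
#'   records on undeclared chromosomes raise an error naming the line.
#' @return `GRanges`, with `name`/`score` metadata columns when present.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED line ", lineno[which(nf < 3L)[1]], ": fewer than 3 columns")
  }
  col <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  }, character(1))
  chrom <- col(1)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) {
    stop("BED line ", lineno[bad[1]], ": non-integer coordinates")
  }
  if (!is.null(chrom_sizes)) {
    bad <- which(!(chrom %in% names(chrom_sizes)))
    if (length(bad)) {
      stop("BED line ", lineno[bad[1]], ": chromosome '", chrom[bad[1]],
           "' not in the declared chrom-sizes table")
    }
  }
  extra <- list()
  if (max(nf) >= 4L) extra$name <- col(4)
  if (max(nf) >= 5L) {
    score <- suppressWarnings(as.numeric(col(5)))
    nb <- which(is.na(score) & !is.na(col(5)))
    if (length(nb)) stop("BED line ", lineno[nb[1]], ": non-numeric score")
    extra$score <- score
  }
  strand <- if (max(nf) >= 6L) col(6) else "*"
  strand[is.na(strand)] <- "*"
  do.call(region_set, c(list(chrom = chrom, start = start, end = end,
                             strand = strand, seqlengths = chrom_sizes),
                        extra))
}

#' Write a region set as BED
#'
#' Emits 0-based half-open coordinates; `name`, `score` and strand columns
#' are written when present on the object. Scores are printed with enough
#' digits to round-trip through [read_bed()].
#'
#' @param regions `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  validate_regions(regions)
  mc <- S4Vectors::mcols(regions)
  n <- length(regions)
  cols <- list(as.character(GenomicRanges::seqnames(regions)),
               GenomicRanges::start(regions) - 1L,
               GenomicRanges::end(regions))
  has_strand <- any(as.character(GenomicRanges::strand(regions)) != "*")
  has_score <- "score" %in% names(mc)
  if (has_score || has_strand) {
    nm <- if ("name" %in% names(mc)) as.character(mc$name) else
      paste0("region_", seq_len(n))
    sc <- if (has_score) sprintf("%.15g", mc$score) else rep("0", n)
    st <- as.character(GenomicRanges::strand(regions))
    st[st == "*"] <- "."
    cols <- c(cols, list(nm, sc, st))
  } else if ("name" %in% names(mc)) {
    cols <- c(cols, list(as.character(mc$name)))
  }
  write.table(do.call(data.frame, c(cols, stringsAsFactors = FALSE)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Gene models container
#'
#' Bundles per-transcript exon structures with a transcript table. The TSS is
#' the start of the first exon on the `+` strand and the end of the last exon
#' on the `-` strand; introns are the within-transcript gaps between exons.
#'
#' @param exons named `GRangesList`, one element per transcript, exons sorted
#'   and non-overlapping within a transcript.
#' @param transcripts `data.frame` with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `biotype` (`"coding"`/`"noncoding"`).
#' @return Object of class `gene_models`.
#' @export
gene_models <- function(exons, transcripts) {
  stopifnot(methods::is(exons, "GRangesList"),
            all(transcripts$transcript_id %in% names(exons)))
  ## normalize to a compressed list on one seqinfo so downstream ops never
  ## re-merge per-element Seqinfo objects
  lens <- S4Vectors::elementNROWS(exons)
  grp0 <- factor(rep(names(exons), lens), levels = names(exons))
  flat0 <- suppressWarnings(unlist(exons, use.names = FALSE))
  GenomeInfoDb::seqlevels(flat0) <- sort(unique(transcripts$chrom))
  exons <- S4Vectors::split(flat0, grp0)
  exons <- exons[transcripts$transcript_id]
  flat <- unlist(exons, use.names = FALSE)
  grp <- factor(rep(names(exons), S4Vectors::elementNROWS(exons)),
                levels = names(exons))
  tx_start <- as.integer(min(S4Vectors::splitAsList(
    GenomicRanges::start(flat), grp)))
  tx_end <- as.integer(max(S4Vectors::splitAsList(
    GenomicRanges::end(flat), grp)))
  transcripts$tss <- ifelse(transcripts$strand == "-", tx_end, tx_start)
  transcripts$tx_start <- tx_start
  transcripts$tx_end <- tx_end
  structure(list(exons = exons, transcripts = transcripts),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes (",
      sum(x$transcripts$biotype == "coding"), "coding )\n")
  invisible(x)
}

#' Transcript spans of a gene model set
#'
#' @param gm `gene_models`.
#' @return Stranded `GRanges`, one range per transcript (exons + introns),
#'   named by transcript id, with `gene_id` and `biotype` columns.
#' @export
transcript_spans <- function(gm) {
  tx <- gm$transcripts
  gr <- GenomicRanges::GRanges(tx$chrom,
                               IRanges::IRanges(tx$tx_start, tx$tx_end),
                               strand = tx$strand)
  names(gr) <- tx$transcript_id
  gr$gene_id <- tx$gene_id
  gr$biotype <- tx$biotype
  gr
}

#' Merged gene spans (exons plus introns)
#'
#' @param gm `gene_models`.
#' @param coding_only keep only coding-biotype transcripts.
#' @return Merged unstranded `GRanges`.
#' @export
gene_spans <- function(gm, coding_only = FALSE) {
  gr <- transcript_spans(gm)
  if (coding_only) gr <- gr[gr$biotype == "coding"]
  if (!length(gr)) return(GenomicRanges::GRanges())
  merge_regions(gr)
}

#' Merged exonic regions of a gene model set
#' @param gm `gene_models`.
#' @return Merged unstranded `GRanges`.
#' @export
exon_regions <- function(gm) {
  merge_regions(unlist(gm$exons, use.names = FALSE))
}

#' Merged intronic regions of a gene model set
#'
#' Intron bases are transcript-span bases that are not exonic in any
#' transcript.
#' @param gm `gene_models`.
#' @return Merged unstranded `GRanges`.
#' @export
intron_regions <- function(gm) {
  subtract_regions(gene_spans(gm), exon_regions(gm))
}

#' Read gene models from a GTF file
#'
#' Uses `rtracklayer` for parsing; exon features are grouped by
#' `transcript_id` and 1-based closed GTF coordinates become the internal
#' convention. A `gene_biotype`/`gene_type` attribute (when present) is
#' collapsed to a coding/noncoding flag; absent attributes default to coding.
#'
#' @param path GTF file path.
#' @param chrom_sizes optional named chromosome-length vector for validation.
#' @return A [gene_models] object.
#' @export
read_gtf <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[tolower(gr$type) == "exon"]
  if (!length(ex)) stop("GTF contains no exon features")
  if (is.null(ex$transcript_id) || anyNA(ex$transcript_id)) {
    stop("GTF exon feature without transcript_id attribute")
  }
  if (!is.null(chrom_sizes)) {
    bad <- setdiff(unique(as.character(GenomicRanges::seqnames(ex))),
                   names(chrom_sizes))
    if (length(bad)) {
      stop("GTF chromosome(s) not in the declared chrom-sizes table: ",
           paste(bad, collapse = ", "))
    }
  }
  bio <- if (!is.null(ex$gene_biotype)) ex$gene_biotype
    else if (!is.null(ex$gene_type)) ex$gene_type
    else rep("protein_coding", length(ex))
  bio[is.na(bio)] <- "protein_coding"
  first <- !duplicated(ex$transcript_id)
  tx <- data.frame(
    transcript_id = ex$transcript_id[first],
    gene_id = ex$gene_id[first],
    chrom = as.character(GenomicRanges::seqnames(ex))[first],
    strand = as.character(GenomicRanges::strand(ex))[first],
    biotype = ifelse(bio[first] %in% c("protein_coding", "coding"),
                     "coding", "noncoding"),
    stringsAsFactors = FALSE
  )
  exl <- GenomicRanges::reduce(
    S4Vectors::split(GenomicRanges::granges(ex), ex$transcript_id))
  gene_models(exl, tx)
}

#' Write gene models as GTF
#'
#' Emits transcript and exon features with `gene_id`/`transcript_id`/
#' `gene_biotype` attributes, 1-based closed coordinates.
#'
#' @param gm `gene_models`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gm, path) {
  tx <- gm$transcripts
  lines <- character(0)
  attr_str <- function(g, t, b) {
    sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
            g, t, if (b == "coding") "protein_coding" else "lincRNA")
  }
  for (i in seq_len(nrow(tx))) {
    ex <- gm$exons[[tx$transcript_id[i]]]
    a <- attr_str(tx$gene_id[i], tx$transcript_id[i], tx$biotype[i])
    lines <- c(lines,
      paste(tx$chrom[i], "retromark", "transcript", tx$tx_start[i],
            tx$tx_end[i], ".", tx$strand[i], ".", a, sep = "\t"),
      paste(tx$chrom[i], "retromark", "exon", GenomicRanges::start(ex),
            GenomicRanges::end(ex), ".", tx$strand[i], ".", a, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BedGraph file into a signal track
#'
#' Intervals must be non-overlapping per chromosome; the per-base value is
#' defined everywhere (0 outside listed intervals).
#'
#' @param path BedGraph path.
#' @param chrom_sizes optional named chromosome-length vector; declares track
#'   extent and validates chromosome naming.
#' @param library_total optional library size recorded on the track.
#' @return A [signal_track] object.
#' @export
read_bedgraph <- function(path, chrom_sizes = NULL, library_total = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(chrom_sizes)) {
    bad <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                   names(chrom_sizes))
    if (length(bad)) {
      stop("BedGraph chromosome(s) not in the declared chrom-sizes table: ",
           paste(bad, collapse = ", "))
    }
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- chrom_sizes
  }
  if (length(gr) &&
      any(GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE) > 1L)) {
    stop("overlapping BedGraph intervals in ", path)
  }
  cov <- GenomicRanges::coverage(gr, weight = "score")
  signal_track(cov, library_total = library_total)
}

#' Write a signal track as BedGraph
#'
#' Zero-valued runs are omitted (they are implicit in the format).
#'
#' @param track [signal_track].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  gr <- methods::as(track$coverage, "GRanges")
  gr <- gr[gr$score != 0]
  df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr),
                   sprintf("%.15g", gr$score))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chrom-sizes table
#'
#' Two tab-separated columns: chromosome name, length.
#' @param path file path.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "size"),
                   colClasses = c("character", "integer"))
  setNames(df$size, df$chrom)
}

#' Write a chrom-sizes table
#' @param chrom_sizes named integer vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(data.frame(names(chrom_sizes), unname(chrom_sizes)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
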