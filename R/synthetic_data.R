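.default_subfamilies <- function() {
  data.frame(
    subfamily = c("L1Md_T", "L1Md_A", "L1Md_Gf", "Lx5",
                  "MERVL-int", "MT2_Mm", "MMETn-int", "ETnERV3-int",
                  "IAPEz-int", "MuRRS-int", "B1_Mus1", "MTA_Mm"),
    family = c("L1", "L1", "L1", "L1",
               "ERVL", "ERVL", "ERVK", "ERVK",
               "ERVK", "ERV1", "Alu", "ERVL-MaLR"),
    repclass = c("LINE", "LINE", "LINE", "LINE",
                 "LTR", "LTR", "LTR", "LTR",
                 "LTR", "LTR", "SINE", "LTR"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator, with defaults scaled
#' so that a full pipeline run takes seconds: 3 chromosomes of 1 Mb, 150
#' genes, 600 repeat elements over 12 mouse-named subfamilies. The seed fully
#' determines every generator output.
#'
#' @param seed integer master seed.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes number of genes; gene lengths are drawn from
#'   `gene_length`, exon counts from `exons_per_gene`, and a
#'   `coding_fraction` of genes is flagged coding.
#' @param gene_length,exons_per_gene,coding_fraction see above.
#' @param subfamilies `data.frame` with `subfamily`, `family`, `repclass`.
#' @param n_elements total repeat elements, split evenly across subfamilies.
#' @param element_genic_fraction fraction of elements planted inside gene
#'   spans (exercising coding-gene exclusion).
#' @param truncated_fraction fraction of short (truncated) element copies;
#'   lengths from `truncated_length`, the rest from `full_length`
#'   (LINE1-like full-length copies).
#' @param truncated_length,full_length length ranges in bases.
#' @param library_size reads per replicate library.
#' @param n_replicates replicates per condition.
#' @param dispersion negative-binomial dispersion of per-subfamily counts
#'   (0 = Poisson).
#' @param repeat_fraction fraction of each library expected on repeats.
#' @param lfc named per-subfamily planted log2 fold changes (condition B over
#'   A); unnamed subfamilies default to 0.
#' @param read_length simulated read length in bases.
#' @param p_sensitive,p_insensitive per-element probability of carrying a
#'   knockout-sensitive 5'-end peak / a knockout-insensitive body peak.
#' @param jitter replicate peak-boundary jitter in bases.
#' @param peak_score range of fold-enrichment scores.
#' @param frac_decreased planted fraction of signal-losing regions for the
#'   ChIP simulation.
#' @param chip_delta planted log2 change of decreased regions (< -0.2).
#' @param chip_noise_sd log-normal noise sd on region signal levels.
#' @param chip_base baseline IP signal level (RPM-equivalents).
#' @param motif_rate_high,motif_rate_low planted motif insertion rates per
#'   kilobase for the enriched/depleted sequence class.
#' @param n_seq_per_class,seq_length motif-simulation sequence set shape.
#' @param background_alphabet characters used for background sequence.
#' @param make_genome also generate a random genome sequence (FASTA-ready).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 3L, chrom_length = 1e6,
                       n_genes = 150L,
                       gene_length = c(2000L, 10000L),
                       exons_per_gene = c(2L, 8L),
                       coding_fraction = 0.8,
                       subfamilies = .default_subfamilies(),
                       n_elements = 600L,
                       element_genic_fraction = 0.3,
                       truncated_fraction = 0.8,
                       truncated_length = c(300L, 1500L),
                       full_length = c(5000L, 7000L),
                       library_size = 2e5,
                       n_replicates = 2L,
                       dispersion = 0.1,
                       repeat_fraction = 0.3,
                       lfc = NULL,
                       read_length = 75L,
                       p_sensitive = 0.5,
                       p_insensitive = 0.7,
                       jitter = 0L,
                       peak_score = c(5, 30),
                       frac_decreased = 0.759,
                       chip_delta = -1,
                       chip_noise_sd = 0.05,
                       chip_base = 5,
                       motif_rate_high = 10,
                       motif_rate_low = 2,
                       n_seq_per_class = 100L,
                       seq_length = 500L,
                       background_alphabet = c("A", "C", "G", "T"),
                       make_genome = TRUE) {
  full_lfc <- setNames(numeric(nrow(subfamilies)), subfamilies$subfamily)
  if (!is.null(lfc)) {
    unknown <- setdiff(names(lfc), names(full_lfc))
    if (length(unknown)) stop("lfc names not in the subfamily catalog: ",
                              paste(unknown, collapse = ", "))
    full_lfc[names(lfc)] <- lfc
  }
  stopifnot(frac_decreased >= 0, frac_decreased <= 1,
            p_sensitive >= 0, p_sensitive <= 1,
            p_insensitive >= 0, p_insensitive <= 1,
            element_genic_fraction >= 0, element_genic_fraction <= 1,
            repeat_fraction > 0, repeat_fraction < 1,
            dispersion >= 0, seed == floor(seed))
  structure(list(
    seed = as.integer(seed), n_chroms = n_chroms,
    chrom_length = chrom_length, n_genes = n_genes,
    gene_length = gene_length, exons_per_gene = exons_per_gene,
    coding_fraction = coding_fraction, subfamilies = subfamilies,
    n_elements = n_elements,
    element_genic_fraction = element_genic_fraction,
    truncated_fraction = truncated_fraction,
    truncated_length = truncated_length, full_length = full_length,
    library_size = library_size, n_replicates = n_replicates,
    dispersion = dispersion, repeat_fraction = repeat_fraction,
    lfc = full_lfc, read_length = read_length,
    p_sensitive = p_sensitive, p_insensitive = p_insensitive,
    jitter = as.integer(jitter), peak_score = peak_score,
    frac_decreased = frac_decreased, chip_delta = chip_delta,
    chip_noise_sd = chip_noise_sd, chip_base = chip_base,
    motif_rate_high = motif_rate_high, motif_rate_low = motif_rate_low,
    n_seq_per_class = n_seq_per_class, seq_length = seq_length,
    background_alphabet = background_alphabet, make_genome = make_genome
  ), class = "sim_config")
}

.runif_int <- function(n, range) {
  as.integer(floor(runif(n, range[1], range[2] + 1)))
}

#' Generate a miniature annotated genome
#'
#' Places non-overlapping genes (2-8 exons each) and mutually non-overlapping
#' repeat elements — partly inside gene spans, partly intergenic, with
#' LINE1-like truncated and full-length copies — on a small multi-chromosome
#' genome, optionally with a random sequence. All outputs are deterministic
#' functions of the config seed.
#'
#' @param config [sim_config].
#' @return List of class `sim_annotation`: `chrom_sizes`, `genes`
#'   ([gene_models]), `repeats` (`GRanges` with `name`, `subfamily`,
#'   `family`, `repclass`), `genome` (`DNAStringSet` or `NULL`), and
#'   `ledger` (per-element truth table).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_sizes <- setNames(rep(as.integer(config$chrom_length),
                              config$n_chroms), chroms)

  ## --- genes: sequential left-to-right placement with random gaps
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  tx_rows <- list()
  ex_list <- list()
  gi <- 0L
  for (ch in chroms) {
    cursor <- .runif_int(1, c(1000L, 5000L))
    for (k in seq_len(per_chrom)) {
      if (gi >= config$n_genes) break
      len <- .runif_int(1, config$gene_length)
      if (cursor + len + 1000L > chrom_sizes[ch]) {
        stop("infeasible packing: too many genes for the genome")
      }
      gi <- gi + 1L
      gid <- sprintf("gene_%03d", gi)
      tid <- sprintf("tx_%03d", gi)
      n_ex <- .runif_int(1, config$exons_per_gene)
      nseg <- 2L * n_ex - 1L
      w <- runif(nseg, 0.5, 1.5)
      seg <- pmax(60L, as.integer(floor(w / sum(w) * len)))
      bounds <- cursor + c(0L, cumsum(seg))
      ex_idx <- seq(1L, nseg, by = 2L)
      ex_list[[tid]] <- IRanges::IRanges(start = bounds[ex_idx],
                                        end = bounds[ex_idx + 1L] - 1L)
      tx_rows[[tid]] <- data.frame(
        transcript_id = tid, gene_id = gid, chrom = ch,
        strand = sample(c("+", "-"), 1),
        biotype = if (runif(1) < config$coding_fraction) "coding"
                  else "noncoding",
        stringsAsFactors = FALSE)
      cursor <- bounds[nseg + 1L] + .runif_int(1, c(1500L, 6000L))
    }
  }
  tx <- do.call(rbind, tx_rows)
  n_ex_per_tx <- lengths(ex_list)
  flat_ex <- GenomicRanges::GRanges(
    factor(rep(tx$chrom, n_ex_per_tx[tx$transcript_id]), levels = chroms),
    do.call(c, unname(ex_list)),
    strand = rep(tx$strand, n_ex_per_tx[tx$transcript_id]))
  exl <- S4Vectors::split(
    flat_ex, factor(rep(tx$transcript_id, n_ex_per_tx[tx$transcript_id]),
                    levels = tx$transcript_id))
  gm <- gene_models(exl, tx)
  tx <- gm$transcripts

  ## --- repeat elements: non-overlapping with each other; a planted
  ##     fraction sits inside gene spans, the rest is intergenic
  subs <- config$subfamilies
  n_sub <- nrow(subs)
  assign_sub <- rep(seq_len(n_sub), length.out = config$n_elements)
  n_trunc <- round(config$truncated_fraction * config$n_elements)
  lens <- integer(config$n_elements)
  trunc_idx <- sample(config$n_elements, n_trunc)
  lens[trunc_idx] <- .runif_int(n_trunc, config$truncated_length)
  lens[-trunc_idx] <- .runif_int(config$n_elements - n_trunc,
                                 config$full_length)
  genic <- runif(config$n_elements) < config$element_genic_fraction
  gene_span_gr <- gene_spans(gm)
  span_chrom <- as.character(GenomicRanges::seqnames(gene_span_gr))
  gs <- split(GenomicRanges::start(gene_span_gr), span_chrom)
  ge <- split(GenomicRanges::end(gene_span_gr), span_chrom)
  occ_s <- setNames(rep(list(numeric(0)), length(chroms)), chroms)
  occ_e <- occ_s
  el_chrom <- character(config$n_elements)
  el_start <- integer(config$n_elements)
  ## long (full-length) copies are placed first: packing a crowded genome
  ## succeeds far more often when the big blocks go in before the short ones
  for (i in order(lens, decreasing = TRUE)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      if (genic[i]) {
        j <- sample(nrow(tx), 1)
        ch <- tx$chrom[j]
        lo <- tx$tx_start[j]
        hi <- max(lo, tx$tx_end[j] - lens[i])
      } else {
        ch <- sample(chroms, 1)
        lo <- 1L
        hi <- chrom_sizes[ch] - lens[i]
      }
      s <- .runif_int(1, c(lo, hi))
      e <- s + lens[i] - 1L
      if (any(occ_s[[ch]] <= e & occ_e[[ch]] >= s)) next
      if (!genic[i] && !is.null(gs[[ch]]) &&
          any(gs[[ch]] <= e & ge[[ch]] >= s)) next
      occ_s[[ch]] <- c(occ_s[[ch]], s)
      occ_e[[ch]] <- c(occ_e[[ch]], e)
      el_chrom[i] <- ch
      el_start[i] <- s
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible packing: could not place element ", i,
                      " (genome too crowded)")
  }
  repeats <- GenomicRanges::GRanges(
    el_chrom, IRanges::IRanges(el_start, width = lens),
    strand = sample(c("+", "-"), config$n_elements, replace = TRUE))
  repeats$name <- sprintf("el_%04d", seq_len(config$n_elements))
  repeats$subfamily <- subs$subfamily[assign_sub]
  repeats$family <- subs$family[assign_sub]
  repeats$repclass <- subs$repclass[assign_sub]
  GenomeInfoDb::seqlevels(repeats) <- chroms
  GenomeInfoDb::seqlengths(repeats) <- chrom_sizes

  genome <- NULL
  if (config$make_genome) {
    genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
      rawToChar(as.raw(c(65L, 67L, 71L, 84L)[
        sample.int(4L, chrom_sizes[ch], replace = TRUE)]))
    }, character(1)))
    names(genome) <- chroms
  }
  ledger <- data.frame(name = repeats$name,
                       subfamily = repeats$subfamily,
                       chrom = el_chrom, start0 = el_start - 1L,
                       end = el_start + lens - 1L,
                       width = lens, genic = genic,
                       stringsAsFactors = FALSE)
  structure(list(chrom_sizes = chrom_sizes, genes = gm, repeats = repeats,
                 genome = genome, ledger = ledger, config = config),
            class = "sim_annotation")
}

#' @export
print.sim_annotation <- function(x, ...) {
  cat("sim_annotation:", length(x$chrom_sizes), "chromosomes,",
      nrow(x$genes$transcripts), "genes,", length(x$repeats),
      "repeat elements over",
      length(unique(x$repeats$subfamily)), "subfamilies\n")
  invisible(x)
}

#' Write a simulated annotation to disk
#'
#' Emits `genome.fa` (when generated), `genes.gtf`, `repeats.bed` (6-column,
#' name = element id) and `chrom.sizes`.
#'
#' @param ann `sim_annotation`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_annotation <- function(ann, dir) {
  stopifnot(inherits(ann, "sim_annotation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(ann$genome)) {
    Biostrings::writeXStringSet(ann$genome, file.path(dir, "genome.fa"))
  }
  write_gtf(ann$genes, file.path(dir, "genes.gtf"))
  rep_bed <- ann$repeats
  rep_bed$name <- paste(ann$repeats$name, ann$repeats$subfamily,
                        ann$repeats$family, ann$repeats$repclass, sep = "|")
  rep_bed$score <- rep(0, length(rep_bed))
  write_bed(rep_bed, file.path(dir, "repeats.bed"))
  write_chrom_sizes(ann$chrom_sizes, file.path(dir, "chrom.sizes"))
  invisible(dir)
}

#' Simulate condition-dependent repeat-derived read libraries
#'
#' Per-subfamily read counts are drawn with negative-binomial noise around
#' expected proportions (`repeat_fraction` of the library, split evenly
#' across subfamilies); condition-B expectations are scaled by the planted
#' `2^log2FC`. Reads fall uniformly within the subfamily's elements; the
#' remainder of each library is background placed outside repeat elements,
#' so each replicate emits exactly `library_size` reads.
#'
#' @param config [sim_config].
#' @param ann [generate_annotation()] output.
#' @return List with `reads` (`$cond_a`, `$cond_b`: lists of per-replicate
#'   read `GRanges`), `truth` (per-subfamily planted proportion and log2FC)
#'   and `library_size`.
#' @export
simulate_reads <- function(config, ann) {
  stopifnot(inherits(config, "sim_config"), inherits(ann, "sim_annotation"))
  set.seed(config$seed + 101L)
  subs <- config$subfamilies$subfamily
  prop <- config$repeat_fraction / length(subs)
  mu_a <- rep(prop * config$library_size, length(subs))
  mu_b <- mu_a * 2^config$lfc[subs]
  el_sub <- match(ann$repeats$subfamily, subs)
  el_chrom <- as.character(GenomicRanges::seqnames(ann$repeats))
  el_start <- GenomicRanges::start(ann$repeats)
  el_avail <- GenomicRanges::width(ann$repeats) - config$read_length + 1L
  idx_by_sub <- split(seq_along(el_sub), el_sub)
  genome_gr <- GenomicRanges::GRanges(
    names(ann$chrom_sizes),
    IRanges::IRanges(1L, unname(ann$chrom_sizes)))
  bg_regions <- subtract_regions(genome_gr, merge_regions(ann$repeats))
  bg_chrom <- as.character(GenomicRanges::seqnames(bg_regions))
  bg_start <- GenomicRanges::start(bg_regions)
  bg_avail <- GenomicRanges::width(bg_regions) - config$read_length + 1L
  bg_keep <- bg_avail > 0L
  draw <- function(mu) {
    if (config$dispersion == 0) rpois(length(mu), mu)
    else rnbinom(length(mu), size = 1 / config$dispersion, mu = mu)
  }
  one_rep <- function(mu_vec) {
    counts <- draw(mu_vec)
    total_rep <- sum(counts)
    if (total_rep > config$library_size) {
      stop("repeat read counts exceed library_size; lower repeat_fraction")
    }
    el_idx <- unlist(lapply(seq_along(counts), function(i) {
      cand <- idx_by_sub[[as.character(i)]]
      cand <- cand[el_avail[cand] > 0L]
      if (!length(cand)) return(integer(0))
      cand[sample.int(length(cand), counts[i], replace = TRUE,
                      prob = el_avail[cand])]
    }), use.names = FALSE)
    n_bg <- config$library_size - length(el_idx)
    bg_idx <- which(bg_keep)[sample.int(sum(bg_keep), n_bg, replace = TRUE,
                                        prob = bg_avail[bg_keep])]
    chrom <- c(el_chrom[el_idx], bg_chrom[bg_idx])
    base <- c(el_start[el_idx], bg_start[bg_idx])
    avail <- c(el_avail[el_idx], bg_avail[bg_idx])
    start <- base + floor(runif(length(base)) * avail)
    out <- GenomicRanges::GRanges(
      factor(chrom, levels = names(ann$chrom_sizes)),
      IRanges::IRanges(start, width = config$read_length))
    GenomeInfoDb::seqlengths(out) <- ann$chrom_sizes
    out
  }
  reads <- list(
    cond_a = lapply(seq_len(config$n_replicates), function(r) one_rep(mu_a)),
    cond_b = lapply(seq_len(config$n_replicates), function(r) one_rep(mu_b)))
  truth <- data.frame(subfamily = subs, prop = prop,
                      lfc = unname(config$lfc[subs]),
                      mu_a = mu_a, mu_b = mu_b, stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, library_size = config$library_size)
}

#' Simulate knockout-sensitive and -insensitive peak sets
#'
#' Each repeat element carries, with configured probabilities, a
#' "sensitive" peak confined to the first 10% of its body (5'-end, strand
#' aware) that is emitted only in the wild-type condition, and/or an
#' "insensitive" peak placed in the body (past the 25% point) emitted in both
#' wild type and knockout. Two replicates per condition are emitted with
#' boundary jitter of at most `config$jitter` bases; planted labels are
#' returned as ground truth.
#'
#' @param config [sim_config].
#' @param ann [generate_annotation()] output.
#' @return List with `wt`/`ko` (each `$rep1`, `$rep2` peak `GRanges` with
#'   `name`, `score`, `condition`, `replicate`) and `truth`
#'   (`data.frame` of planted peaks and labels).
#' @export
simulate_peaks <- function(config, ann) {
  stopifnot(inherits(config, "sim_config"), inherits(ann, "sim_annotation"))
  set.seed(config$seed + 202L)
  el <- ann$repeats
  w <- GenomicRanges::width(el)
  minus <- as.character(GenomicRanges::strand(el)) == "-"
  has_s <- runif(length(el)) < config$p_sensitive
  has_i <- runif(length(el)) < config$p_insensitive
  rows <- list()
  for (i in seq_along(el)) {
    s0 <- GenomicRanges::start(el)[i]
    e0 <- GenomicRanges::end(el)[i]
    if (has_s[i]) {
      ws <- max(50L, as.integer(round(0.10 * w[i])))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(el))[i],
        start = if (minus[i]) e0 - ws + 1L else s0,
        end = if (minus[i]) e0 else s0 + ws - 1L,
        name = paste0(el$name[i], "_sens"), label = "sensitive",
        stringsAsFactors = FALSE)
    }
    if (has_i[i]) {
      wi <- max(50L, as.integer(round(0.15 * w[i])))
      fr <- runif(1, 0.25, max(0.2501, 1 - wi / w[i]))
      off <- as.integer(floor(fr * w[i]))
      ps <- if (minus[i]) e0 - off - wi + 1L else s0 + off
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(el))[i],
        start = max(s0, ps), end = min(e0, ps + wi - 1L),
        name = paste0(el$name[i], "_ins"), label = "insensitive",
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  truth$score <- runif(nrow(truth), config$peak_score[1],
                       config$peak_score[2])
  emit <- function(tab, condition, replicate) {
    if (!nrow(tab)) return(GenomicRanges::GRanges())
    j <- config$jitter
    d1 <- if (j > 0) .runif_int(nrow(tab), c(-j, j)) else 0L
    d2 <- if (j > 0) .runif_int(nrow(tab), c(-j, j)) else 0L
    s <- pmax(1L, tab$start + d1)
    e <- pmax(s + 20L, tab$end + d2)
    gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(s, e))
    gr$name <- tab$name
    gr$score <- tab$score
    gr$condition <- condition
    gr$replicate <- replicate
    gr
  }
  ins <- truth[truth$label == "insensitive", , drop = FALSE]
  list(wt = list(rep1 = emit(truth, "WT", 1L), rep2 = emit(truth, "WT", 2L)),
       ko = list(rep1 = emit(ins, "KO", 1L), rep2 = emit(ins, "KO", 2L)),
       truth = truth)
}

#' Disjoint fixed-width windows over a genome
#'
#' Evenly spaced non-overlapping windows, a convenient stand-in for a peak
#' universe when simulating signal tracks.
#'
#' @param chrom_sizes named chromosome lengths.
#' @param n number of windows.
#' @param width window width in bases.
#' @return `GRanges` of `n` disjoint windows.
#' @export
disjoint_windows <- function(chrom_sizes, n, width = 500L) {
  per <- ceiling(n / length(chrom_sizes))
  out <- list()
  for (ch in names(chrom_sizes)) {
    step <- floor((chrom_sizes[ch] - width - 1) / per)
    if (step <= width) stop("too many windows for the genome")
    starts <- 1L + step * (seq_len(per) - 1L)
    out[[ch]] <- GenomicRanges::GRanges(ch,
      IRanges::IRanges(starts, width = width))
  }
  head(suppressWarnings(do.call(c, unname(out))), n)
}

#' Simulate IP/input signal tracks with a planted decreased fraction
#'
#' A configured fraction of the supplied regions has its condition-B IP
#' signal scaled by `2^chip_delta` (with `chip_delta < -0.2` these regions
#' are truly "decreased"); the remainder keeps its baseline level. Log-normal
#' noise multiplies every region level independently per condition. Input
#' tracks are flat at 1 and identical across conditions by construction.
#'
#' @param config [sim_config].
#' @param regions non-overlapping `GRanges` (e.g. a peak universe).
#' @param chrom_sizes named chromosome lengths for track extent; defaults to
#'   the regions' `seqlengths` when set.
#' @return List with [signal_track]s `ip_a`, `ip_b`, `input_a`, `input_b`
#'   and `truth` (`data.frame` of planted categories).
#' @export
simulate_chip <- function(config, regions, chrom_sizes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_regions(regions)
  if (any(GenomicRanges::countOverlaps(regions, regions,
                                       ignore.strand = TRUE) > 1L)) {
    stop("regions must be non-overlapping")
  }
  if (is.null(chrom_sizes)) {
    sl <- GenomeInfoDb::seqlengths(regions)
    if (anyNA(sl)) {
      sl <- vapply(split(GenomicRanges::end(regions),
                         as.character(GenomicRanges::seqnames(regions))),
                   max, numeric(1))
    }
    chrom_sizes <- sl
  }
  set.seed(config$seed + 303L)
  n <- length(regions)
  n_dec <- round(config$frac_decreased * n)
  dec <- rep(FALSE, n)
  dec[sample.int(n, n_dec)] <- TRUE
  lvl_a <- config$chip_base * exp(rnorm(n, 0, config$chip_noise_sd))
  lvl_b <- config$chip_base * 2^(config$chip_delta * dec) *
    exp(rnorm(n, 0, config$chip_noise_sd))
  mk_track <- function(values) {
    gr <- GenomicRanges::granges(regions)
    gr$score <- values
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- chrom_sizes
    signal_track(GenomicRanges::coverage(gr, weight = "score"),
                 library_total = NA_real_)
  }
  flat <- GenomicRanges::GRanges(names(chrom_sizes),
                                 IRanges::IRanges(1L, unname(chrom_sizes)),
                                 score = 1)
  GenomeInfoDb::seqlengths(flat) <- chrom_sizes
  input <- signal_track(GenomicRanges::coverage(flat, weight = "score"),
                        library_total = NA_real_)
  truth <- data.frame(
    region = paste0("reg_", seq_len(n)),
    category = factor(ifelse(dec, "decreased", "other"),
                      levels = c("decreased", "other")),
    level_a = lvl_a, level_b = lvl_b, stringsAsFactors = FALSE)
  list(ip_a = mk_track(lvl_a), ip_b = mk_track(lvl_b),
       input_a = input, input_b = input, truth = truth)
}

.realize_motif <- function(motif) {
  letters <- strsplit(toupper(gsub("U", "T", motif)), "")[[1]]
  paste(vapply(letters, function(ch) {
    opts <- strsplit(.IUPAC[[ch]], "")[[1]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

#' Embed degenerate motifs into synthetic sequence classes
#'
#' Two sequence classes emulating knockout-sensitive vs -insensitive peak
#' sequences: class 1 receives RRACH insertions at `motif_rate_high` per kb
#' and ABAG at `motif_rate_low`; class 2 is reversed. Insertions replace
#' background bases at well-separated positions (no two insertions closer
#' than 8 bases), so each insertion contributes one occurrence on top of the
#' background rate of the alphabet.
#'
#' @param config [sim_config].
#' @return List with `sequences` (`DNAStringSet`, names carry the class) and
#'   `truth` (`data.frame` of planted per-sequence rates).
#' @export
embed_motifs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 404L)
  len <- config$seq_length
  slots <- seq(1L, len - 8L, by = 8L)
  gen_class <- function(class_id, rate_rrach, rate_abag) {
    lapply(seq_len(config$n_seq_per_class), function(i) {
      bases <- sample(config$background_alphabet, len, replace = TRUE)
      k_r <- rpois(1, rate_rrach * len / 1000)
      k_a <- rpois(1, rate_abag * len / 1000)
      k <- min(k_r + k_a, length(slots))
      pos <- sample(slots, k)
      kinds <- c(rep("RRACH", min(k_r, k)),
                 rep("ABAG", max(0, k - min(k_r, k))))
      for (j in seq_len(k)) {
        inst <- .realize_motif(kinds[j])
        bases[pos[j]:(pos[j] + nchar(inst) - 1L)] <-
          strsplit(inst, "")[[1]]
      }
      list(seq = paste(bases, collapse = ""),
           id = sprintf("class%d_seq%03d", class_id, i),
           n_rrach = min(k_r, k), n_abag = max(0, k - min(k_r, k)))
    })
  }
  c1 <- gen_class(1L, config$motif_rate_high, config$motif_rate_low)
  c2 <- gen_class(2L, config$motif_rate_low, config$motif_rate_high)
  all <- c(c1, c2)
  seqs <- Biostrings::DNAStringSet(vapply(all, `[[`, character(1), "seq"))
  names(seqs) <- vapply(all, `[[`, character(1), "id")
  truth <- data.frame(
    id = names(seqs),
    class = rep(c(1L, 2L), each = config$n_seq_per_class),
    rrach_rate = rep(c(config$motif_rate_high, config$motif_rate_low),
                     each = config$n_seq_per_class),
    abag_rate = rep(c(config$motif_rate_low, config$motif_rate_high),
                    each = config$n_seq_per_class),
    n_rrach = vapply(all, `[[`, numeric(1), "n_rrach"),
    n_abag = vapply(all, `[[`, numeric(1), "n_abag"),
    stringsAsFactors = FALSE)
  list(sequences = seqs, truth = truth)
}
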