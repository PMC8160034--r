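test_that("PROMPT windows are strand-aware 2-kb upstream spans", {
  ex <- suppressWarnings(as(
    list(tp = GRanges("chrA", IRanges(5001, 6000), strand = "+"),
         tm = GRanges("chrB", IRanges(3001, 5000), strand = "-")),
    "GRangesList"))
  gm <- gene_models(ex, data.frame(
    transcript_id = c("tp", "tm"), gene_id = c("gp", "gm"),
    chrom = c("chrA", "chrB"), strand = c("+", "-"), biotype = "coding",
    stringsAsFactors = FALSE))
  reps <- region_set("chrA", 8000, 8500, subfamily = "S")
  fc <- feature_classes(gm, reps, prompt_span = 2000)
  ## + strand TSS 5001 -> [3001,5000]; - strand TSS 5000 -> [5001,7000]
  pr <- sort(fc$PROMPT)
  expect_equal(start(pr), c(3001L, 5001L))
  expect_equal(end(pr), c(5000L, 7000L))
  ## truncation at the chromosome start
  ex2 <- as_grl(list(t0 = GRanges("chrA", IRanges(501, 900), strand = "+")))
  gm2 <- gene_models(ex2, data.frame(
    transcript_id = "t0", gene_id = "g0", chrom = "chrA", strand = "+",
    biotype = "coding", stringsAsFactors = FALSE))
  fc2 <- feature_classes(gm2, reps, prompt_span = 2000)
  expect_equal(start(fc2$PROMPT), 1L)
  expect_equal(end(fc2$PROMPT), 500L)
})

test_that("relative enrichment is 1 in the null and scales arithmetically", {
  feats <- list(S1 = GRanges("chrA", IRanges(1, 1000)),
                S2 = GRanges("chrB", IRanges(1, 1000)))
  ## peaks distributed identically to input reads: both 50/50
  peaks <- gr_c(GRanges("chrA", IRanges(sample(1:900, 20), width = 50)),
             GRanges("chrB", IRanges(sample(1:900, 20), width = 50)))
  en <- relative_enrichment(peaks, feats, peaks)
  expect_equal(en$ratio, c(1, 1))
  ## 10/100 peaks on a feature that receives 5% of input reads -> 2.0
  pk <- gr_c(GRanges("chrA", IRanges(rep(10, 10), width = 10)),
          GRanges("chrC", IRanges(rep(10, 90), width = 10)))
  inp <- gr_c(GRanges("chrA", IRanges(rep(10, 5), width = 10)),
           GRanges("chrC", IRanges(rep(10, 95), width = 10)))
  en2 <- relative_enrichment(pk, list(S1 = feats$S1), inp)
  expect_equal(en2$ratio, 2)
})

test_that("zero-input features are flagged undefined, not infinite", {
  feats <- list(S1 = GRanges("chrA", IRanges(1, 100)),
                empty = GRanges("chrB", IRanges(5000, 5100)))
  pk <- GRanges("chrA", IRanges(10, 20))
  en <- relative_enrichment(pk, feats, pk)
  expect_true(en$undefined[en$feature == "empty"])
  expect_true(is.na(en$ratio[en$feature == "empty"]))
})

test_that("enrichment is invariant to uniform input-library scaling", {
  set.seed(4)
  feats <- list(S = GRanges("chrA", IRanges(1, 1500)))
  pk <- rand_regions(60)
  inp <- rand_regions(200)
  a <- relative_enrichment(pk, feats, inp)$ratio
  b <- relative_enrichment(pk, feats, rep(inp, 5))$ratio
  expect_equal(a, b)
})

test_that("planted 3x enrichment on one subfamily is recovered", {
  set.seed(12)
  feats <- list(hot = GRanges("chrA", IRanges(1, 1000)),
                cold = GRanges("chrB", IRanges(1, 1000)))
  ## input: uniform across the two features; peaks: 3:1 toward hot
  inp <- gr_c(GRanges("chrA", IRanges(sample(900, 500, TRUE), width = 20)),
           GRanges("chrB", IRanges(sample(900, 500, TRUE), width = 20)))
  pk <- gr_c(GRanges("chrA", IRanges(sample(900, 300, TRUE), width = 20)),
          GRanges("chrB", IRanges(sample(900, 100, TRUE), width = 20)))
  en <- relative_enrichment(pk, feats, inp)
  expect_lt(abs(en$ratio[en$feature == "hot"] - 1.5), 0.05)
  ## with peaks at 3x the input rate on hot only
  pk3 <- gr_c(GRanges("chrA", IRanges(sample(900, 300, TRUE), width = 20)),
           GRanges("chrB", IRanges(sample(900, 100, TRUE), width = 20)))
  en3 <- relative_enrichment(pk3, list(hot = feats$hot),
                             gr_c(GRanges("chrA", IRanges(sample(900, 250, TRUE),
                                                       width = 20)),
                               GRanges("chrB", IRanges(sample(900, 750, TRUE),
                                                       width = 20))))
  expect_lt(abs(en3$ratio - 3), 0.15)
})

test_that("hypergeometric tail handles boundaries and monotonicity", {
  expect_equal(hypergeometric_overlap(50, 50, 50, 50)$p.value, 1)
  ps <- vapply(5:20, function(k) {
    hypergeometric_overlap(611, 61, 33, k)$p.value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(hypergeometric_overlap(100, 60, 60, 10), "inconsistent")
  expect_error(hypergeometric_overlap(100, 10, 20, 15), "inconsistent")
})

test_that("hypergeometric tail equals direct mass summation", {
  p <- hypergeometric_overlap(611, 61, 33, 13)$p.value
  expect_equal(p, oracle_hyper_tail(611, 61, 33, 13), tolerance = 1e-12)
})

test_that("motif scanning counts degenerate matches on the sense strand", {
  expect_equal(motif_density("GGACU", "RRACH")$occurrences, 1L)
  expect_equal(motif_density("CCCCC", "RRACH")$occurrences, 0L)
  expect_error(motif_density("ACGT", "RRXCH"), "IUPAC")
  ## overlapping occurrences are all counted
  expect_equal(motif_density("AAACAACA", "AAC")$occurrences, 2L)
  ## reverse complement changes counts (sense-strand semantics)
  s <- "GGACTGGACTGGACT"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_false(motif_density(s, "RRACH")$occurrences ==
                 motif_density(rc, "RRACH")$occurrences)
})

test_that("motif counts agree with the nested-loop oracle", {
  set.seed(6)
  seqs <- vapply(1:25, function(i) {
    paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  }, character(1))
  for (motif in c("RRACH", "ABAG")) {
    got <- motif_density(seqs, motif)$occurrences
    want <- vapply(seqs, oracle_motif_count, integer(1), motif = motif,
                   USE.NAMES = FALSE)
    expect_equal(got, want)
  }
})

test_that("PSI is the inclusion fraction with undefined zeros flagged", {
  expect_equal(psi(30, 10)$psi, 0.75)
  expect_equal(psi(5, 0)$psi, 1.0)
  expect_equal(psi(7, 7)$psi, 0.5)
  z <- psi(0, 0)
  expect_true(is.na(z$psi))
  expect_false(z$defined)
  expect_error(psi(-1, 5), "non-negative")
})
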