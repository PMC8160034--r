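test_that("generation is deterministic and honours requested copy numbers", {
  cfg <- sim_config(seed = 42L, make_genome = FALSE)
  again <- generate_annotation(cfg)
  expect_identical(again$ledger, shared_ann$ledger)
  tab <- table(shared_ann$repeats$subfamily)
  expect_equal(unname(as.integer(tab)),
               rep(shared_cfg$n_elements / nrow(shared_cfg$subfamilies),
                   nrow(shared_cfg$subfamilies)))
  ## element lengths within the configured LINE1-like ranges
  w <- width(shared_ann$repeats)
  expect_true(all(w >= 300 & w <= 7000))
  ## elements are mutually non-overlapping
  expect_equal(region_length(shared_ann$repeats), sum(as.numeric(w)))
})

test_that("written annotation survives a round trip through the readers", {
  dir <- withr::local_tempdir()
  write_annotation(shared_ann, dir)
  sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(sizes, shared_ann$chrom_sizes)
  reps <- read_bed(file.path(dir, "repeats.bed"), chrom_sizes = sizes)
  expect_equal(length(reps), length(shared_ann$repeats))
  expect_true(all(start(reps) >= 1 & end(reps) <= sizes[
    as.character(seqnames(reps))]))
  expect_equal(as.data.frame(granges(reps))[, 1:3],
               as.data.frame(granges(shared_ann$repeats))[, 1:3])
  gm <- read_gtf(file.path(dir, "genes.gtf"), chrom_sizes = sizes)
  expect_equal(nrow(gm$transcripts), shared_cfg$n_genes)
})

test_that("each replicate library emits exactly library_size reads", {
  rd <- simulate_reads(shared_cfg, shared_ann)
  for (cond in rd$reads) {
    for (rep in cond) expect_equal(length(rep), shared_cfg$library_size)
  }
  ## determinism from (config, seed)
  rd2 <- simulate_reads(shared_cfg, shared_ann)
  expect_identical(as.data.frame(rd$reads$cond_b[[2]]),
                   as.data.frame(rd2$reads$cond_b[[2]]))
})

test_that("a planted twofold subfamily effect is recovered as up", {
  cfg <- sim_config(seed = 5L, lfc = c("MMETn-int" = 1, "MERVL-int" = 1),
                    dispersion = 0, make_genome = FALSE)
  ann <- generate_annotation(cfg)
  rd <- simulate_reads(cfg, ann)
  regs <- suppressWarnings(build_subfamily_regions(ann$repeats, ann$genes))
  ca <- sapply(rd$reads$cond_a, function(r)
    quantify_subfamilies(r, regs, cfg$library_size)$count)
  cb <- sapply(rd$reads$cond_b, function(r)
    quantify_subfamilies(r, regs, cfg$library_size)$count)
  dr <- differential_units(ca, cb, cfg$library_size, cfg$library_size,
                           ids = names(regs))
  expect_equal(as.character(dr$category[dr$unit == "MMETn-int"]), "up")
  expect_equal(as.character(dr$category[dr$unit == "MERVL-int"]), "up")
  ## unplanted subfamilies are not systematically up
  others <- dr[!(dr$unit %in% c("MMETn-int", "MERVL-int")), ]
  expect_lt(mean(others$category == "up"), 0.2)
})

test_that("knockout files contain no sensitive peaks by construction", {
  expect_false(any(grepl("_sens$", shared_peaks$ko$rep1$name)))
  expect_false(any(grepl("_sens$", shared_peaks$ko$rep2$name)))
  ## every emitted peak has a truth entry
  expect_true(all(shared_peaks$wt$rep1$name %in% shared_peaks$truth$name))
  ## sensitive peaks sit in the first 10% of the element body (5' aware)
  el <- shared_ann$repeats
  tr <- shared_peaks$truth[shared_peaks$truth$label == "sensitive", ]
  idx <- match(sub("_sens$", "", tr$name), el$name)
  frac_start <- ifelse(as.character(strand(el)[idx]) == "-",
                       (end(el)[idx] - tr$end) / width(el)[idx],
                       (tr$start - start(el)[idx]) / width(el)[idx])
  expect_true(all(frac_start >= 0 & frac_start < 0.01))
})

test_that("input tracks from the signal simulation are identical", {
  w <- disjoint_windows(shared_ann$chrom_sizes, 200, 400)
  ch <- simulate_chip(shared_cfg, w)
  expect_identical(ch$input_a$coverage, ch$input_b$coverage)
  ## planted zero fraction: decreased calls stay at the noise floor
  cfg0 <- sim_config(seed = 9L, frac_decreased = 0, make_genome = FALSE)
  ch0 <- simulate_chip(cfg0, w)
  sc0 <- classify_signal_change(w, ch0$ip_a, ch0$ip_b)
  expect_lte(mean(sc0$category == "decreased"), 0.02)
})

test_that("planted motif rates are recovered on a motif-free background", {
  ## background without A cannot spell RRACH or ABAG; each insertion
  ## contributes its occurrences on an otherwise clean slate
  cfg <- sim_config(seed = 13L, motif_rate_low = 0,
                    background_alphabet = c("C", "G", "T"),
                    make_genome = FALSE)
  em <- embed_motifs(cfg)
  md <- motif_density(em$sequences, "RRACH")
  c1 <- em$truth$class == 1
  kb1 <- sum(md$length[c1]) / 1000
  planted_rate <- sum(em$truth$n_rrach[c1]) / kb1
  expect_lt(abs(mean(md$density[c1]) - planted_rate), 1e-9)
  expect_lt(abs(planted_rate - cfg$motif_rate_high),
            5 * sqrt(cfg$motif_rate_high / kb1))
  ## rate-zero class: only incidental matches formed at the junctions of
  ## the other motif's insertions remain, far below the planted rate
  expect_lt(mean(md$density[!c1]), 1.5)
  ## determinism
  em2 <- embed_motifs(cfg)
  expect_identical(as.character(em$sequences), as.character(em2$sequences))
})

test_that("motif class contrast holds under the default background", {
  em <- embed_motifs(sim_config(seed = 21L, make_genome = FALSE))
  rr <- motif_density(em$sequences, "RRACH")
  ab <- motif_density(em$sequences, "ABAG")
  c1 <- em$truth$class == 1
  expect_gt(mean(rr$density[c1]), mean(rr$density[!c1]))
  expect_gt(mean(ab$density[!c1]), mean(ab$density[c1]))
})

test_that("full pipeline recovers planted labels across stages", {
  ## peak sensitivity
  hc_wt <- high_confidence_peaks(shared_peaks$wt$rep1, shared_peaks$wt$rep2)
  hc_ko <- high_confidence_peaks(shared_peaks$ko$rep1, shared_peaks$ko$rep2)
  cl <- classify_sensitivity(hc_wt, hc_ko)
  truth <- setNames(shared_peaks$truth$label, shared_peaks$truth$name)
  expect_gte(mean(as.character(cl$sensitivity) == truth[cl$name]), 0.95)
  ## signal change
  w <- disjoint_windows(shared_ann$chrom_sizes, 500, 400)
  ch <- simulate_chip(shared_cfg, w)
  sc <- classify_signal_change(w, ch$ip_a, ch$ip_b)
  expect_gte(mean(as.character(sc$category) ==
                    as.character(ch$truth$category)), 0.95)
  ## element mark labels: elements with a planted sensitive peak are
  ## labelled sensitive-only or both
  sens <- cl[cl$sensitivity == "sensitive"]
  ins <- cl[cl$sensitivity == "insensitive"]
  lab <- label_transcripts(shared_ann$repeats, sens, ins)
  has_sens <- shared_ann$repeats$name %in%
    sub("_sens$", "", grep("_sens$", shared_peaks$truth$name, value = TRUE))
  expect_gte(mean((lab %in% c("sensitive-only", "both")) == has_sens), 0.95)
})
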