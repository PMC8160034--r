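test_that("coding-gene exclusion trims subfamily regions", {
  gm <- tiny_gene_models()
  ## element fully inside the coding gene span [101,500] -> empty
  ## element [1,1000] overlapping it -> residuals [1,100] and [501,1000]
  reps <- region_set(c("chrA", "chrA"), c(150, 0), c(450, 1000),
                     subfamily = c("SubA", "SubB"))
  expect_warning(regs <- build_subfamily_regions(reps, gm), "SubA")
  expect_equal(length(regs[["SubA"]]), 0L)
  expect_equal(start(regs[["SubB"]]), c(1L, 501L))
  expect_equal(end(regs[["SubB"]]), c(100L, 1000L))
})

test_that("residual subfamily lengths match the per-base oracle", {
  set.seed(17)
  reps <- rand_regions(120, max_width = 300L)
  reps$subfamily <- sample(c("S1", "S2", "S3"), 120, replace = TRUE)
  ex <- as_grl(list(t1 = GRanges("chrA", IRanges(500, 1500), strand = "+"),
                t2 = GRanges("chrB", IRanges(100, 900), strand = "+")))
  gm <- gene_models(ex, data.frame(
    transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
    chrom = c("chrA", "chrB"), strand = "+", biotype = "coding",
    stringsAsFactors = FALSE))
  regs <- suppressWarnings(build_subfamily_regions(reps, gm))
  gene_mask <- mask_of(gene_spans(gm, coding_only = TRUE))
  for (s in names(regs)) {
    m <- mask_of(reps[reps$subfamily == s])
    want <- sum(vapply(ORACLE_CHROMS,
                       function(ch) sum(m[[ch]] & !gene_mask[[ch]]),
                       numeric(1)))
    expect_equal(region_length(regs[[s]]), want)
  }
})

test_that("subfamily RPM normalizes by the library total", {
  regs <- as_grl(list(S1 = GRanges("chrA", IRanges(1, 1000)),
                  S2 = GRanges("chrB", IRanges(1, 10))))
  reads <- region_set("chrA", seq(0, 900, by = 100), seq(50, 950, by = 100))
  q <- quantify_subfamilies(reads, regs, library_total = 1e6)
  expect_equal(q$count, c(10L, 0L))
  expect_equal(q$rpm, c(10, 0))
  expect_error(quantify_subfamilies(reads, regs, 0), "library_total")
})

test_that("simulated reads recover planted subfamily proportions", {
  rd <- simulate_reads(shared_cfg, shared_ann)
  regs <- suppressWarnings(
    build_subfamily_regions(shared_ann$repeats, NULL))
  q <- quantify_subfamilies(rd$reads$cond_a[[1]], regs,
                            shared_cfg$library_size)
  expect_equal(length(rd$reads$cond_a[[1]]), shared_cfg$library_size)
  planted <- shared_cfg$repeat_fraction / nrow(shared_cfg$subfamilies)
  observed <- q$count / shared_cfg$library_size
  ## within 5 sd of the planted count noise (negative binomial)
  mu <- planted * shared_cfg$library_size
  tol <- 5 * sqrt(mu + shared_cfg$dispersion * mu^2) /
    shared_cfg$library_size
  expect_true(all(abs(observed - planted) < tol))
})

test_that("FPKM follows the closed form", {
  u <- fpkm(100, 1000, 1e6)
  expect_equal(u$fpkm, 100)
  expect_equal(fpkm(0, 500, 1e6)$fpkm, 0)
  set.seed(3)
  counts <- rpois(50, 200); lens <- sample(200:5000, 50); mapped <- 2.5e6
  got <- fpkm(counts, lens, mapped)$fpkm
  expect_equal(got, counts * 1e9 / (lens * mapped))
  expect_error(fpkm(1, 0, 1e6), "length")
})

test_that("differential calls follow thresholds and planted effects", {
  ## identical conditions: log2fc 0, unchanged
  same <- differential_units(matrix(c(100, 100), 1), matrix(c(100, 100), 1),
                             1e6, 1e6)
  expect_equal(same$log2fc, 0)
  expect_equal(as.character(same$category), "unchanged")
  ## planted 2-fold up with deep counts
  up <- differential_units(matrix(c(500, 500), 1), matrix(c(1000, 1000), 1),
                           1e6, 1e6)
  expect_equal(as.character(up$category), "up")
  expect_lt(up$p, 1e-10)
  ## all-zero unit: p = 1, neither
  zero <- differential_units(matrix(0, 1, 2), matrix(0, 1, 2), 1e6, 1e6)
  expect_equal(zero$p, 1)
  expect_equal(as.character(zero$category), "neither")
})

test_that("swapping conditions maps up to down and preserves p exactly", {
  set.seed(8)
  ca <- matrix(rpois(60, 300), ncol = 2)
  cb <- matrix(rpois(60, 360), ncol = 2)
  fwd <- differential_units(ca, cb, 1e6, 1e6)
  rev <- differential_units(cb, ca, 1e6, 1e6)
  expect_equal(rev$p, fwd$p)
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(as.character(rev$category)[fwd$category == "up"],
               rep("down", sum(fwd$category == "up")))
})

test_that("DEG definition filters low expression then applies fold change", {
  a <- c(g1 = 0.05, g2 = 1.0, g3 = 4.0, g4 = 2.0)
  b <- c(g1 = 0.05, g2 = 2.5, g3 = 1.0, g4 = 3.0)
  degs <- define_degs(a, b, fold = 2, min_fpkm = 0.1)
  expect_false("g1" %in% degs$tested)  # low in both, ignored
  expect_equal(degs$up, "g2")          # 1.0 -> 2.5 exceeds 2-fold
  expect_equal(degs$down, "g3")
  set.seed(19)
  ra <- setNames(round(runif(200, 0, 5), 2), paste0("g", 1:200))
  rb <- setNames(round(runif(200, 0, 5), 2), paste0("g", 1:200))
  degs2 <- define_degs(ra, rb)
  keep <- (ra + rb) / 2 >= 0.1
  expect_equal(degs2$up,
               sort(names(ra)[keep & (rb + 0.01) / (ra + 0.01) > 2]))
  expect_equal(degs2$down,
               sort(names(ra)[keep & (ra + 0.01) / (rb + 0.01) > 2]))
})
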