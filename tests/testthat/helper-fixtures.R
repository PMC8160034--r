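## combine GRanges built on different chromosomes without seqinfo chatter
gr_c <- function(...) suppressWarnings(c(...))
as_grl <- function(lst) suppressWarnings(methods::as(lst, "GRangesList"))

## One shared synthetic dataset, generated once per test run. The genome
## sequence is skipped here; motif tests build their own sequence sets.
shared_cfg <- sim_config(seed = 42L, make_genome = FALSE)
shared_ann <- generate_annotation(shared_cfg)
shared_peaks <- simulate_peaks(shared_cfg, shared_ann)

## a tiny hand-built gene model set: two genes on chrA
## gene_001 (+, coding): exons [101,200] and [401,500] (intron [201,400])
## gene_002 (-, noncoding): single exon [1001,1400], TSS at 1400
tiny_gene_models <- function() {
  ex <- as_grl(list(
    tx_a = GenomicRanges::GRanges(
      "chrA", IRanges::IRanges(c(101, 401), c(200, 500)), strand = "+"),
    tx_b = GenomicRanges::GRanges(
      "chrA", IRanges::IRanges(1001, 1400), strand = "-")
  ))
  gene_models(ex, data.frame(
    transcript_id = c("tx_a", "tx_b"),
    gene_id = c("gene_001", "gene_002"),
    chrom = "chrA", strand = c("+", "-"),
    biotype = c("coding", "noncoding"),
    stringsAsFactors = FALSE))
}
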