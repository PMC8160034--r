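---
title: "retromark: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retromark: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific setting

Chromatin-associated RNAs (caRNAs) carry N6-methyladenosine (m6A) marks
that are read by nuclear proteins and feed back onto chromatin state. A
recurring experimental design in this area compares a wild-type cell line
against a writer or reader knockout across several sequencing modalities:
MeRIP/m6A-seq peak calls, caRNA-seq read counts over repeat elements,
RIP-seq peaks for a reader protein, and ChIP-seq for a corepressor
(e.g. KAP1/TRIM28) or a histone mark (H3K9me3). `retromark` packages the
downstream computations these designs share, so that each one is a tested,
reusable function instead of a one-off script:

* knockout-**sensitivity classification** of modification peaks
  (a peak present in wild type but absent in the knockout is *sensitive*;
  one that persists is *insensitive*);
* **repeat-subfamily quantification**: reads falling on the merged genomic
  copies of each subfamily, after excluding bases covered by coding genes,
  depth-normalized to reads per million (RPM);
* **differential calling** of subfamilies between conditions with the
  printed thresholds (`log2FC > 0.3` and `P < 0.05` for "up";
  `|log2FC| < 0.1` for "unchanged");
* **relative enrichment** of a peak set over genomic feature classes
  (fraction of peaks on the feature divided by the fraction of input reads
  on the feature);
* **ChIP signal intensity** as the IP/input ratio of depth-normalized
  coverage, and peak-change classification at `log2FC < -0.2`;
* **metagene body profiles** over repeat element bodies;
* **IUPAC motif density** (RRACH, ABAG, ACAGAGA presets), **PSI**
  (percent spliced in), and **hypergeometric set-overlap** testing;
* cross-system **Venn classification** (up only in system A / in both /
  only in system B).

All coordinates are handled as `GRanges`; plain-text formats (BED,
BedGraph, GTF, FASTA) are converted at the I/O boundary, so BED's 0-based
half-open convention never leaks into analysis code.

## Conventions and numerical choices

**Overlap.** "A overlaps B" means at least one shared base, everywhere;
the minimum overlap is exposed as a parameter on every classification
function. Overlap arithmetic is strand-blind (matching bedtools defaults);
only PROMPT construction, metagene orientation and motif scanning are
strand-aware.

**Strict inequalities.** Every published threshold is applied exactly as
printed: fold enrichment `> 5` for RIP targets, `log2FC > 0.3`,
`P < 0.05`, `|log2FC| < 0.1`, `log2FC > 1` for reference-state sets,
`log2FC < -0.2` for decreased ChIP peaks, average FPKM `< 0.1` for the
low-expression filter, fold change `> 2` for DEGs. Boundary cases are
excluded, and the tests pin this down.

**Pseudocounts.** Three distinct scales demand three constants, each
chosen once:

* ratios of depth-normalized coverage (ChIP signal, signal change) add
  1 RPM-equivalent to each mean (`eps = 1`), so zero-coverage regions are
  finite and shrink toward no change;
* subfamily log2 fold changes add 0.5 to each condition's mean RPM — a
  symmetric half-count that avoids infinities without drowning real
  effects; the same 0.5 is reused for reference-state (2C-like) set
  definitions so set membership is consistent across stages;
* DEG fold-change ratios on FPKM add 0.01, an order of magnitude below
  the 0.1 expression floor. A 0.5 pseudocount on the FPKM scale would
  swallow genuine two-fold changes of low-expressed genes (1.0 vs 2.5
  FPKM would no longer exceed two-fold), so the FPKM pathway uses the
  smaller guard.

**Replicate intersection.** High-confidence peaks are replicate-1 peaks
that overlap a replicate-2 peak. Whether the retained peak keeps its full
span or is clipped to the intersected span is not determined by the
definition; `high_confidence_peaks()` clips by default and offers
`clip = FALSE`, and the sensitivity classification is invariant to the
choice whenever peaks overlap at all.

**Metagene bins.** Each element body is rescaled to `body_bins` equal
fractions and the bin value is the *length-weighted mean* of the coverage
step function over the (generally fractional) bin — computed exactly from
cumulative sums rather than by midpoint sampling, so a constant track
yields a constant profile to machine precision. Minus-strand elements are
reversed before binning so bin 1 is always the 5' end. Defaults are 100
body bins and no flanks; flanks are supported.

**Hypergeometric overlap.** `P(X >= k)` is computed with `phyper` on the
upper tail; the universe size is a required argument and is recorded in
the result, because overlap significance is meaningless without it. For
a repeat-subfamily universe a value near 611 (46 reference-state
subfamilies plus 565 controls) is the natural choice in the motivating
design. The tests verify agreement with direct summation of the
probability mass to 1e-12 for universes up to 2,000.

## The differential test

The motivating analyses use edgeR for subfamily p-values. Reproducing
edgeR's dispersion machinery is out of scope here; `differential_units()`
instead applies a *conditional binomial exact test*: with replicate-summed
counts `k_a`, `k_b` and library sizes `L_a`, `L_b`, it tests
`k_a ~ Binomial(k_a + k_b, L_a / (L_a + L_b))` two-sided. This is the
exact conditional version of comparing two Poisson rates with offsets.

Two properties follow and are tested: swapping conditions maps up-calls to
down-calls with identical p-values, and under Poisson sampling the test is
calibrated (type-I error at `p < 0.05` lands in the binomial band around
0.05 over 600 null units). The deliberate limitation: the test models
*technical* (counting) noise only. With biologically overdispersed
replicates it is anti-conservative, as any Poisson-family test without a
dispersion estimate must be — which is why the calibration and power
experiments in the acceptance suite run the generator in its Poisson
regime (`dispersion = 0`), and why results on real replicated data should
be read as descriptive rather than inferential. The categories
(`up`/`down`/`unchanged`/`neither`) additionally require the log2FC
thresholds, which dominate the calls at deep coverage.

## What the synthetic-data generator emulates

`sim_config()` defaults define a miniature study: 3 chromosomes of 1 Mb,
150 genes of 2–8 exons, and 600 repeat elements across 12 subfamilies
named after the mouse families that motivate the design (L1Md_T, MERVL,
MMETn, ETnERV3, ...). Element lengths mix truncated (300–1,500 bp, 80%)
and full-length (5,000–7,000 bp) copies, mirroring the length structure of
LINE1 annotations. About 30% of elements are planted inside gene spans so
that coding-gene exclusion is actually exercised. These sizes make a full
pipeline run take seconds while every stage sees non-trivial input.

* `simulate_reads()` draws per-subfamily counts with negative-binomial
  noise (dispersion 0.1 by default, the conventional overdispersion scale
  for sequencing counts; 0 gives Poisson) around planted proportions, and
  scales condition B by planted `2^log2FC`. Background reads fill each
  library to exactly its configured size and are placed outside repeat
  elements.
* `simulate_peaks()` plants *sensitive* peaks in the first 10% of element
  bodies (5'-end, strand-aware), emitted only in wild type, and
  *insensitive* peaks in the body past the 25% point, emitted in both
  conditions; replicates jitter boundaries by at most the configured
  number of bases. Because elements are mutually non-overlapping and the
  two peak classes are separated within each element, zero-jitter label
  recovery is exact by construction — which is what makes the recovery
  rate a meaningful test statistic rather than a tautology at positive
  jitter.
* `simulate_chip()` scales a planted fraction (default 0.759) of region
  signals by `2^delta` (default `delta = -1`) in condition B, with
  log-normal noise (sd 0.05) on every level; input tracks are flat and
  identical across conditions.
* `embed_motifs()` plants RRACH and ABAG instances at configurable
  per-kilobase rates into two sequence classes. On the default uniform
  ACGT background the background RRACH rate (~11.7/kb) and motif
  cross-talk at insertion junctions are substantial, so exact rate
  recovery is tested on a motif-free C/G/T background, and the default
  background is used only for the class-contrast property.

What the generator does **not** emulate, and what passing tests therefore
do not establish: mappability and multi-mapping ambiguity of young repeat
copies (every simulated read has one true origin), fragment-length
effects, GC and amplification bias, biological replicate variability in
the ChIP tracks, and peak-caller behaviour (peaks are planted, not
called). Results on real data depend on all of these.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
interval-algebra oracles use 200 intervals on 3 chromosomes across 100
seeds; sensitivity recovery uses the default 600-element genome (~700
planted peaks); calibration and power use 600 single-element subfamilies
at 200,000 reads per replicate, two replicates per condition; the
signal-change recovery uses 1,000 disjoint windows; metagene checks use
~300 elements. These sizes were chosen so the acceptance properties have
tight sampling error while a complete run stays within seconds to a
couple of minutes.

## Known limitations

* The sensitivity classifier is binary presence/absence by overlap; it
  does not model partial peak attenuation (a strongly reduced but still
  called peak is "insensitive").
* Subfamily counts assign a read to every subfamily it overlaps; regions
  of different subfamilies that genuinely overlap are double-counted by
  design (documented bedtools-style behaviour), though the generator's
  elements never overlap.
* PSI accepts inclusion/exclusion counts as given; no junction-length
  normalization is applied.
* The conditional binomial test is not an edgeR replacement (see above).
* Motif scanning is sense-strand only, by design, since its targets are
  RNA-derived peak sequences.
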