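---
title: "Models and methods behind mtscatac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtscatac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtscatac)
library(dplyr)
```

`mtscatac` analyses experiments that read out chromatin accessibility and
mitochondrial DNA from the same single cells. This vignette explains the
statistical models and conventions the package uses, the defaults and why
they were chosen, what the synthetic-data generator does and does not
emulate, and the numerical decisions a maintainer should know about.

## Coordinate conventions

Nuclear intervals (fragments, peaks, gene windows) are 0-based half-open,
as in BED and the 10x fragments format. Mitochondrial variant positions are
1-based (`m.<pos>`), the universal convention for mtDNA alleles; the gene
tables bundled for the mouse (16,299 bp) and human (16,569 bp)
mitochondrial genomes use 1-based inclusive coordinates. Tests assert the
conversion between the two frames. The bundled mitochondrial reference
sequences are synthetic (seeded random draws at the true lengths) but
anchored at a handful of loci carrying well-characterised variants, so that
annotation of those variants yields the expected calls (for example mouse
m.15219 sits at the first base of CYTB codon 359, Phe/TTC, so a T>C there
is c.T1075C / p.F359L). Coordinates, not sequence content, drive every
statistic; only the annotation of specific known variants depends on the
anchored bases.

## Per-cell quality control

**TSS enrichment.** The score is the Tn5 insertion density (both fragment
ends count as insertions) per bp within ±100 bp of any TSS, divided by the
density in distal flanks (the 100 bp windows ending 2,000 bp away on each
side), with a pseudocount of one flank insertion so empty flanks give a
finite, window-normalised score. This is the standard scATAC construction;
the retention gate of 1.2 then has its usual meaning. Cells with no
fragments score 0 with a warning rather than erroring, so cohort tables
stay rectangular.

**Retention gate.** A cell passes QC iff TSS enrichment ≥ 1.2, unique
nuclear fragment count in [2,000, 50,000] (both ends inclusive — "between"),
and FRiP strictly greater than 0.2 ("higher than"). The boundary semantics
are deliberate and tested. A fragment is "in a peak" iff it overlaps any
peak by at least one base — the simplest verifiable rule, checked against a
per-base membership oracle.

**Chromatin complexity.** Where a fixed number of top cells is needed
(e.g. aggregate coverage summaries), cells are ranked by unique nuclear
fragment count, the only per-cell complexity measure in this data model,
with lexicographic barcode ties so selection is order-stable.

**Barnyard classification.** In a two-species mixing experiment a barcode
is a singlet iff its major-species nuclear fraction reaches the purity
threshold (default 0.95), otherwise a collision. Among singlets,
contamination — foreign-species mtDNA under a clean nuclear barcode — is
called when the minor-species share of mito reads reaches 0.05. Both
thresholds are configurable because descriptions of such experiments
usually say only "uniquely mapped"; 0.95/0.05 are conservative defaults
that tolerate stray misassigned reads without masking true mixing.

## Mitochondrial genotyping

**Read and base filters.** A mito read contributes to the allele-count
tensor iff MAPQ ≥ 30 and it has at most two mismatches; every base of a
passing read additionally requires base quality ≥ 20. Counting is
strand-resolved per cell, implemented in C++ (the one hot loop in the
package) and verified exactly against a plain R per-read oracle. Reads
overhanging the mitochondrial end are clipped with a warning; the
simulator never emits origin-spanning reads, a documented limitation.

**Per-cell VAF.** VAF = alt/(alt + ref) summed over strands. Cells with
site coverage below 10 are *missing*, not zero — imputing zeros would
deflate every downstream heteroplasmy statistic (VMR, burden, mean VAF),
which is why the low-coverage mask propagates as `NA` throughout.

**Informative variants.** For every non-reference allele the package
computes: number of cells with alt evidence, pseudo-bulk VAF, mean
per-cell site coverage, strand concordance (Pearson correlation of plus-
and minus-strand alt counts across covered cells; cells with zero alt
reads enter as exact zeros via sufficient sums, and degenerate cases are
defined as 0), and the variance-to-mean ratio of per-cell VAF. Candidates
need concordance ≥ 0.65 and VMR ≥ 0.01. These two defaults follow the
conventions of established mtDNA single-cell genotypers; they are
configurable because only the low-coverage threshold is a hard published
constant. A perfectly homoplasmic site has VMR 0 and is correctly treated
as uninformative for cell-level analyses.

**The filtering cascade.** Candidates are then flagged against:
(1) a ≥ 5-fold pseudo-bulk depth difference between the two alleles,
(2) not more than 90% of alt reads on one strand, (3) bulk site depth
≥ 250, (4)–(6) the base-quality/MAPQ/mismatch limits (guaranteed upstream
by the read filters and recorded as passes for audit), (7) ≥ 50 cells
exhibiting the SNP, and (8) absence from a species-keyed blacklist
(human m.310, a poly-C artifact; no mouse positions by default). All flags
are computed independently and retained even on failure, which makes the
cascade order-independent and monotone under threshold tightening — both
properties are tested against a brute-force reimplementation. Filter (1)
read literally rejects alleles with bulk VAF between 1/6 and 5/6; since
mid-frequency heteroplasmies do occur, the ratio filter can be disabled
via `allele_depth_ratio = NA`. The literal reading is the default; the
switch exists because the filter's intent (alleles vs strands) is
ambiguous in common usage.

**"Cells exhibiting a SNP."** The detection rule is ≥ 1 passing alt read
(configurable `min_alt_reads`), applied consistently in the cascade's
filter (7), in mutation burden, and in carrier assignment.

**Annotation.** Protein-gene positions get a cDNA offset
(c.N = pos − start + 1 on plus-strand genes, mirrored on minus-strand
genes), the affected codon on the coding strand, and the amino-acid change
under the vertebrate mitochondrial genetic code. Genes whose length is not
a multiple of three are trimmed to the last complete codon (mitochondrial
stop codons are completed post-transcriptionally); a variant in the
trimmed tail is reported without an amino-acid call. Overlapping genes
(e.g. mouse ATP8/ATP6) produce one annotation row each.

**qPCR anchor.** Copies = 2 × 2^ΔCt with ΔCt = Ct(nuclear) − Ct(mito); the
factor 2 reflects the two nuclear gene copies per diploid cell.

## Cohort statistics

**Wilcoxon rank-sum.** When both groups have at most `exact_max` (default
10) observations the two-sided p-value is computed by exhaustive
enumeration of all group assignments of the pooled ranks — exact in the
presence of ties, which base R's exact path cannot handle. Larger samples
use the tie-corrected normal approximation with continuity correction,
which on 8-vs-8 draws agrees with the exact answer to well within 0.01.
Pairwise mtDNA-content matrices report raw p-values at α = 0.01 without
multiplicity correction — the field convention for these significance
heatmaps — and the summary bookkeeping (n significant / C(k,2), also
rounded to two decimals as conventionally printed) is exposed separately
so it can be verified in isolation.

**Burden and mean VAF.** A variant counts toward a cell's burden iff the
cell has ≥ `min_alt_reads` alt reads there; missing entries are excluded
from both numerator and denominator, so low-coverage cells do not appear
artificially mutation-free. Burden is non-increasing in the detection
threshold (tested).

**Gene activity and signatures.** Gene activity is the fragment count over
the gene body plus 2 kb upstream on the strand-oriented 5′ side, the common
accessibility proxy for expression. Signature scores are means of per-gene
z-scores across cells; zero-variance genes contribute 0 so constant
background genes cannot move a score. The membership of any particular
signature set is a configuration input; tests use synthetic sets.

**Aggregate profiles.** Replicate concordance is the Pearson correlation
of per-peak aggregate counts, log1p-transformed by default to tame count
heteroscedasticity; the raw scale is available (and is the scale on which
the correlation is exactly invariant to a global depth factor).

## Carrier contrasts and motifs

**Carrier assignment.** Given a designated variant set, a cell is a
carrier with detected alt evidence at ≥ 1 designated site, wild-type if
covered and clean at all covered designated sites, and unassigned if all
designated sites are missing. The summary reports the fraction of carriers
with two or more designated variants.

**Differential accessibility.** Accessibility is binarized per peak
(detected iff ≥ 1 fragment) and tested by a likelihood-ratio test of
`detected ~ group + log(total fragments)` against the covariate-only
logistic model; this mirrors the default of the dominant single-cell
chromatin toolkit. A Fisher-exact mode exists for tiny datasets where the
asymptotic test is unreliable (and for the degenerate single-peak case,
where the depth covariate would be collinear with the outcome — the
`depth` argument also accepts an externally computed covariate for that
reason). P-values are BH-adjusted across peaks; significance requires
q < 0.01 and a ≥ 1.25-fold change in either direction. Fold change is the
ratio of detection rates normalised by group mean depth with pseudocount
1/n_cells, without which FC on sparse binary data is undefined. The test
is label-symmetric (swapping groups negates log2FC and preserves q,
tested). One caveat the tests quantify: when a large *fraction* of all
peaks carries a real group effect, the total-fragment covariate becomes
confounded with group membership and null peaks inflate slightly; with a
realistic affected fraction (≲ 10% of peaks) the false-positive rate stays
below 1%.

**Permutation control.** Labels are permuted preserving group sizes (the
carrier-to-WT ratio), the full differential analysis is re-run per
replicate (default 100), and the distribution of significant-peak counts
is reported. On data without planted effects the median count is 0 and
fewer than 5% of replicates show any significant peak.

**Motifs.** PWMs are scanned by sliding the log-odds score (pseudocount
0.01, uniform background by default) over both strands; a peak is a hit if
its best window reaches the threshold, by default 75% of the motif's
maximum achievable score. Enrichment in the differential set versus all
tested peaks is the hypergeometric upper tail, BH-adjusted. GC-matched
backgrounds are out of scope because the sequences here are synthetic; with
real peaks a matched background would be preferable.

## The synthetic-data generator

The generator's defaults encode the experimental regime the pipeline
targets: log-normal unique-fragment counts with median ≈ 6,400 per cell;
mitochondrial content Beta-distributed per cell type and age group (young
mean 0.55 with concentration 20, aged mean 0.45 with concentration 8 —
higher and tighter content in young cells, cohort average near 50%);
collision rate 2% and contamination rate 0.5%; and per-cell heteroplasmy
from a zero-inflated Beta — with probability π = 0.8 a cell carries none
of a variant, otherwise VAF ~ Beta(0.5, 50), giving the mostly sub-1%
spectrum typical of tissue heteroplasmy — plus a few near-homoplasmic
sites. The empirical shape of real per-cell VAF distributions is not
published in a reusable form, so the zero-inflated Beta is an explicit
stand-in, exposed in the configuration.

Reads are simulated with binomial alt sampling at each cell's true VAF,
i.i.d. per-base qualities (5% of bases at Phred 15, the rest at Phred 37)
with errors injected at each base's Phred-implied rate, and MAPQ /
mismatch-count fields populated so configurable fractions of reads fail
each read-level filter. Contamination is modelled as reads whose genotype
is drawn from a donor cell under the recipient's barcode — foreign mtDNA
inside a singlet — rather than whole-cell mixing. TSS-proximal insertion
enrichment is planted by a calibrated mixture weight: a TSS-assigned
fragment puts its start insertion inside the ±100 bp window and, for
fragments shorter than ~200 bp, occasionally its other end as well; the
closed-form weight accounts for both so the realised enrichment matches
the target (tests recover 5× within [4, 6]).

The nuclear genome is toy-scale (2 × 1 Mb default, smaller in tests): all
downstream statistics are scale-free, and a desk-scale genome keeps the
whole suite in CPU-minutes. What the generator does **not** emulate:
indels, soft-clips, duplicate structure, origin-spanning mito reads,
GC-dependent coverage, doublet-specific fragment-count inflation, and any
aligner behaviour. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not robustness to
alignment artifacts in real data.

Determinism: every simulation entry point takes a seed and is
byte-reproducible under it; dataset writes include a flat-text manifest
recording the seed.

## Validation studies and problem sizes

Three seeded studies ship with the package (exported, reused by the test
suite and the acceptance script):

- **Planted-variant recovery** — 120 cells on a 1,500 bp toy mito genome
  at ~100× per-cell coverage, eight planted variants (six low-frequency,
  two near-homoplasmic), ten seeds. Recovery is scored over planted
  variants with true bulk VAF ≥ 0.5% and ≥ 50 carrier cells; the pipeline
  achieves recall ≥ 0.9 with per-cell VAF RMSE ≤ 0.05. The near-homoplasmic
  variants are planted at a 5% wild-type residual so their bulk VAF
  (~0.93) clears the literal allele-ratio filter; mid-frequency alleles
  would require disabling that filter, as discussed above.
- **Permutation-null calibration** — 300 cells × 150 peaks with no planted
  effect, 100 random splits: median significant count 0.
- **Barnyard recovery** — 5,000 cells with 2% planted collisions and 0.5%
  contamination, recovered within binomial 99% intervals.

These sizes were chosen so each study runs in about a minute on a single
core while keeping the binomial/normal error bands narrow enough for the
assertions to be meaningful.

## Known limitations

- The variant caller targets SNVs only; indels, haplogroups and clonal
  lineage trees are out of scope.
- The allele-ratio filter read literally excludes mid-frequency alleles
  (see above); keep the switch in mind for datasets where such alleles
  matter.
- The differential test binarizes accessibility; count-level effects
  within detected cells are invisible to it.
- Motif identities found on synthetic sequences carry no biological
  meaning; the enrichment machinery, not any specific motif call, is the
  tested artifact.
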