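---
title: "MSAP band-type analysis of sperm DNA methylation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSAP band-type analysis of sperm DNA methylation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimsap)
```

## The assay and its readout

Methylation-sensitive amplification polymorphism (MSAP) is an AFLP variant
that reads CCGG methylation from band presence/absence. Genomic DNA is
digested twice in parallel — once with EcoRI + MspI, once with EcoRI +
HpaII — ligated to adapters, selectively amplified, and sized by capillary
electrophoresis. MspI and HpaII are isoschizomers of 5'-CCGG-3' with
different methylation sensitivity: MspI cuts C^CGG whether or not the
internal CpG cytosine carries 5mC, while HpaII is blocked by internal CpG
methylation. Each locus in each sample is therefore a presence pair over
the (MspI lane, HpaII lane):

| type | (M, H) | interpretation (mammalian CpG model)         |
|------|--------|----------------------------------------------|
| I    | (1,1)  | unmethylated CCGG                            |
| II   | (1,0)  | internal CpG methylated on both strands      |
| III  | (0,1)  | nested CCGG pair with an internal CmCGG site |
| IV   | (0,0)  | site absent, or a non-amplifying nested configuration |

In plants type III is usually read as hemimethylation; in vertebrates CpG
methylation dominates, so the package follows the mammalian
reinterpretation: type III arises when two CCGG sites sit between the same
EcoRI sites and only the inner one is methylated, so the long fragment
survives HpaII but is destroyed by MspI. `classify_transition()` encodes
the resulting twelve-row model of ordered band-type changes: three
transitions are hypermethylation (IV→II, I→II, I→III: each gains a CmCGG),
three are hypomethylation (II→IV, II→I, III→I: each loses one), the
IV↔III pair is ambiguous (either direction is a move between nested-pair
configurations that cannot be resolved from two lanes) and scores
methylation-unchanged, and the rest are pure sequence mutations or
compound events with no net methylation verdict. Identity transitions are
representable and classify as no change, so whole matrices are processed
uniformly.

Band types are stored internally as the (msp, hpa) bit pair; the Roman
numeral is presentation only. The model also follows the source table
literally in one asymmetric corner: a IV→I change is scored as pure
mutation (new CCGG) while IV→II is mutation plus epimutation, although a
type IV baseline cannot itself distinguish a truly absent site from a
nested-pair configuration.

## The methylation-ratio statistic

The per-sample methylation level is the fully methylated fraction of
CpG-informative bands,

$$\mathrm{ratio} = 100 \cdot \frac{n_{II}}{n_I + n_{II}}\,,$$

with types III and IV excluded from both numerator and denominator.
Percentages throughout the package are rounded half-up to two decimals:
that convention reproduces every checkable printed value of the study this
package models (e.g. 1042/1523 → 68.42), whereas R's default half-even
rounding does not in general. Genotype comparisons of the per-replicate
ratios use Welch's two-sample t-test at α = 0.05 (Student's is available
by flag); the noise-free simulator produces identical replicates, and that
degenerate zero-variance case is defined explicitly as statistic 0 / p = 1
when the means agree.

## The synthetic cohort

Because no sequence data are deposited for the study, the package carries
a first-class generative model of the whole experiment:

* **Genome** — `generate_genome()` assembles chromosomes from repeating
  units `GAATTC | spacer | CCGG [| spacer | CCGG] | spacer`, so every site
  coordinate is known exactly (0-based half-open; both motifs are
  palindromic so a single-strand scan suffices). A configurable fraction
  of inter-EcoRI intervals carries a nested CCGG pair, which is the only
  source of type III/IV nested behaviour. Spacers are motif-free and the
  assembled sequence is re-scanned to scrub accidental motifs created at
  junctions.
* **Methylome** — one status per CCGG site, `unmethylated` or
  `internal_methylated`, symmetric on both strands. Non-CpG methylation,
  external-C methylation and hemimethylation are deliberately outside the
  mammalian model. The default methylated fraction (0.55) puts simulated
  sperm ratios in the >50% regime the assay reports.
* **Digestion and amplification** — `digest()` applies the enzyme rules
  above; `enumerate_amplicons()` reports, per lane, every fragment that
  spans one EcoRI cut end and one MspI/HpaII cut end with no internal cut
  in that lane, matches the selective primer suffixes at both ends, and
  has detected size strictly inside the 50–500 bp window. Detected size is
  restriction-fragment length plus a constant adapter/primer offset
  (default 0 and configurable, since the mapping from sizing traces to
  restriction lengths is instrument-specific). The default panel of
  4 × 16 = 64 primer pairs (one EcoRI-side selective base, two HM-side)
  mirrors the study's 64 selective combinations; it also keeps
  same-length fragments from different primer pairs apart, which matters
  because loci are identified by primer pair + size.
* **Genotype effects** — `apply_genotype_effects()` plants
  hypermethylation, hypomethylation, CCGG gain and CCGG loss events on the
  base state. Each event is tagged shared-by-both offspring genotypes
  (probability `shared_fraction`) or private to one, which is the planted
  ground truth for the inheritance partition. Defaults (6% hyper, 4.5%
  hypo, 2% gain, 2% loss, 42% shared) approximate the changed-locus load
  and the ~42% offspring-shared fraction of the study's cohort. Gains are
  planted between an EcoRI site and its first CCGG, at a position fixed
  once on the base sequence so shared gains land identically in both
  carriers; a gain truncates the pre-existing fragment, so it is observed
  as one new locus appearing plus one old locus vanishing — both real,
  both in the truth table.
* **Peak emission** — `emit_peak_tables()` writes the replicate peak
  tables. The default noise model is exact (no dropout, no spurious
  peaks, no jitter, constant 5000 RFU heights), so the scored matrix
  reproduces `truth_band_types()` byte-for-byte; the analysis workflow
  uses a realistic preset (5% dropout, 2 spurious peaks per lane, 0.15 bp
  sizing jitter, log-normal heights with sdlog 0.6 so a tail falls below
  the 1000 RFU filter).

What the generator does *not* emulate: electropherogram signal shape, PCR
competition/bias, partial digestion, size-dependent amplification decay,
and homoplasy beyond exact size collision. Passing round-trip tests
therefore show the scoring and classification machinery is exact on its
own terms, not that the laboratory assay is error-free.

## Scoring rules

`filter_peaks()` applies the study's filters strictly: height > 1000 RFU
and 50 bp < size < 500 bp. `bin_loci()` clusters sizes within each primer
pair by single linkage at ±0.5 bp (typical capillary sizing precision; the
source is silent, so this is a package choice), keeping chains but
splitting any cluster wider than twice the tolerance at its largest
internal gap; with equal gaps the first maximum wins, which is documented
tie-break behaviour. The locus universe is every bin seen in at least one
sample × lane after filtering — a locus must be seen somewhere to exist,
and a locus absent from both lanes of a sample codes IV there. A sample
missing an entire lane is a named error rather than a silent IV column.

Two consensus rules coexist, following the study's two stated criteria:
the total-locus analysis (count tables, ratio statistics) uses the
majority rule — the modal band type if it reaches ⌈2n/3⌉ of n replicates,
ties to excluded — while the inheritance analysis uses strict unanimity.
Strict consensus is always a subset of majority consensus on retained
loci.

## The inheritance partition

With wild-type (WT), transgene-negative (NEG) and transgene-positive
(POS) consensus calls per locus, a differentially amplified locus (DAL) is
any locus where the three calls are not all equal. Changed loci partition
into `only_negative` (NEG differs, POS equals WT), `only_positive`,
`both` (NEG and POS share the same changed type — the candidate
intergenerationally inherited class), and `inconsistent` (changed in both
offspring but to different types). The source tables never mention the
inconsistent case; this package reports it separately and counts it in no
sharing column, which is the conservative reading of "the same band types
in both". DML verdicts apply the twelve-row model per locus;
`count_dml()` reports every fraction with an explicit numerator and
denominator because the published figures mix denominators (DALs, DMLs,
and the shared column). The reproduction scripts flag, and do not
reproduce, printed figures that are not derivable from the count tables
(a 34.26% and 75.07% share, a wild-type mean ratio of 59.01, and in-text
type-II averages that contradict the per-replicate counts).

## BSP cross-validation

`bisulfite_convert()` implements the conversion chemistry (unmethylated C
→ T via U; methylated C unchanged; optional per-C conversion-failure
rate), `call_clones()` reads per-CpG methylated fractions from cloned
sequences (C methylated, T unmethylated, anything else uncallable and out
of the denominator), and `concordance()` compares the clone-fraction
difference between genotypes with the MSAP hyper/hypo direction at a
default threshold of 0.2 — about two clones of the ten per replicate the
study sequenced; no numeric criterion is stated in the source, only
consistency. Only the sense strand is simulated, since strand bookkeeping
collapses after PCR and T-vector cloning. In noise-free simulations the
MSAP call and the BSP call agree at 100% of callable CCGG-internal CpGs,
which is the designed cross-check of the two code paths.

## Feature annotation

Gene models load from GFF3 or BED12 through `rtracklayer` into a
precedence index: promoter > 5'UTR > 3'UTR > exon > intron > intergenic,
any overlap counts, promoters are a strand-aware 2 kb window upstream of
the TSS (configurable; the source never defines "promoter"). Introns are
derived as gene body minus exons, and BED12 UTRs from the thick/CDS
interval, so the two formats of the same gene annotate identically. The
5'UTR class is kept separate; merging it into exon recovers the 5-way
split used in the study's figures. Coordinates are 0-based half-open
internally and converted at the format boundary.

## Problem sizes and numerical choices

The test suite runs the exact round trip at a realistic scale — one
1.25 Mb chromosome, ~5000 loci over the 64 primer pairs, 3 genotypes × 3
replicates — and the sharing-recovery property over ten 40 kb cohorts,
checking the pooled recovered shared fraction against the exact binomial
95% interval of the planted fraction. The analysis workflow under
`analysis/` uses two 200 kb chromosomes (~1600 loci) with the noisy
emission preset. These sizes are the package's choice of a demonstration
scale: every engine is size-independent, and the acceptance computations
on the published count tables involve no simulation at all.

Ties, degenerate inputs, and other corners defined explicitly: the
undefined methylation ratio (no type I or II bands) is an error, not NA;
empty cut sets produce empty fragment sets; majority-consensus ties
exclude the locus; binning of an empty peak table is an empty matrix;
`sample(x, 1)` scalar traps are avoided by dedicated integer samplers; and
all generator stages are deterministic functions of their seed.

## Known limitations

* Locus identity is primer pair + binned size, so two co-migrating
  fragments from the same primer pair merge, in the simulator truth and in
  scoring alike — exactly the homoplasy limit of real AFLP/MSAP.
* The twelve-row model reads each transition independently per locus; it
  cannot see coupled changes at nested pairs (one methylation event can
  legitimately move two loci), which is why recovery tests on sharing
  structure use nest-free genomes.
* Methylation is modelled only at CCGG-internal CpGs; CHG/CHH and
  hemimethylated states, and plant-style type III semantics, are out of
  scope.
* BSP simulation covers conversion and clone calling, not primer design,
  amplification bias across converted templates, or alignment of real
  Sanger traces.
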