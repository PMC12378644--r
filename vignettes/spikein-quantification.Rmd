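---
title: "Absolute quantification from spike-in metagenomes: model and methods"
author: "spikequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute quantification from spike-in metagenomes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikequant)
```

## The problem and the model

Shotgun metagenome read counts are compositional: they tell you what
fraction of the sequenced DNA came from each organism, not how many
organisms were in the water. Two ingredients turn counts into absolute,
volumetric abundances:

1. **Genomic internal standards (spike-ins).** A known number of copies of
   one or more foreign genomes is added to each sample before library
   preparation. Whatever fraction of those copies survives extraction,
   library preparation and sequencing — the *recovery ratio* — applies, to
   a first approximation, to every other genome in the same tube.
2. **Single-copy marker genes.** A gene present exactly once per haploid
   genome (*recA* in bacteria, its homolog *radA* in archaea, *psbO* in
   cyanobacteria and eukaryotic phytoplankton) makes a gene count a genome
   count.

The calculus, per sample:

$$S_r = \frac{S_s}{S_p}, \qquad R = \frac{S_r}{S_a}, \qquad
  G_a = \frac{G_s}{R}, \qquad
  \text{abundance} = \frac{G_a}{V} \;\; [\text{haploid genome equivalents } L^{-1}]$$

where $S_s$ is the number of reads matching any protein-coding gene of a
standard, $S_p$ the number of protein-coding genes in that standard's
genome, $S_a$ the genome copies added, $G_s$ the reads assigned to a
taxon's marker gene, and $V$ the liters of water filtered. Cell counts
follow by dividing haploid genome equivalents by ploidy (diatoms are
typically diploid; many dinoflagellates haplontic; some filamentous
cyanobacteria polyploid). With several standards spiked per sample,
`combine_recoveries()` merges their per-standard ratios — geometric mean
by default (recovery losses act multiplicatively), with arithmetic and
pooled ($\sum S_s / \sum S_p S_a$) alternatives; a max/min dispersion
above 2 flags a likely failed spike.

**Key assumption.** $G_a = G_s/R$ treats each marker-gene copy as
yielding reads at the same per-copy rate as each standard gene. That
holds when the marker and the standards' genes present comparable target
lengths to the read classifier. The calculus does not length-normalize —
neither does the field protocol it mirrors, which works because bacterial
single-copy markers and typical bacterial protein-coding genes are all of
order 1 kb.

### The cross-domain (cyanobacteria-anchored) estimator

*psbO* annotation is less sensitive than *recA* annotation in practice
(sparser reference databases), so direct *psbO* quantification
undercounts phototrophs. Because cyanobacteria carry *both* genes, they
calibrate the undercount internally:

$$G_{euk} = G_{recA}^{cyano} \times \frac{psbO_{euk}}{psbO_{cyano}}$$

Any annotation sensitivity common to cyanobacterial and eukaryotic
*psbO* cancels in the ratio; the estimate inherits the accuracy of the
cyanobacterial *recA* count. This is exactly what the package's
acceptance test demonstrates: with a shared *psbO* sensitivity of 0.72
the direct estimator recovers ~0.72 of truth while the anchored
estimator stays within a few percent of it. The estimator fails
gracefully: with zero cyanobacterial *psbO* reads it is undefined, the
record is flagged, and the direct estimate is the fallback.

A symbol-level ambiguity deserves a note: the anchor
$G_{recA}^{cyano}$ can be read either as raw cyanobacterial *recA*
reads or as the recovered absolute abundance. We implement it as the
recovered abundance ($G_a$ applied to cyanobacterial *recA*), which
gives $G_{euk}$ the same unit as the anchor; the ratio
$psbO_{euk}/psbO_{cyano}$ is unit-free either way.

## Detection limits

A taxon observed at zero reads is not "absent"; it is below the
sample's resolution. `detection_limit()` reports the abundance that one
annotated read would represent, $1/(R \times V)$, and
`abundance_table()` attaches it to every record — zero-count rows carry
abundance 0 *and* an explicit upper bound. Sequencing $d\times$ deeper
multiplies $R$ by $d$ and divides the limit by $d$; the acceptance
suite verifies the 13-fold version of this scaling empirically — the
coverage gain a typical resequencing effort buys for rare-phytoplankton
detection.

## The synthetic world

`build_transect()` + `simulate_reads()` generate everything the pipeline
consumes, so parameter recovery is checkable without downloads. The
generator's defaults encode the stated experimental conditions; where a
value was not stated we chose once, as follows, and did not revisit:

| parameter | default | why |
|---|---|---|
| standards | 3 genomes, dosed at ~1% of total DNA mass | the field protocol spikes three genomic standards targeting ~1% |
| dosing model | mass $\propto$ copies $\times$ genome length | simplest mass model; the protocol states only the ~1% target |
| abundance span | $10^7$–$10^9$ cells L$^{-1}$, log-spaced roster | matches the >100-fold station-to-station variation of surface communities |
| per-sample variation | common log10-scale SD 0.3 (+ optional per-taxon jitter 0.15) | emulates a productivity gradient along a transect |
| reads | 250 b merged fragments, substitution rate 0.002 | one count per merged fragment is the counting unit; ~Illumina-scale error |
| genome lengths | 0.1 Mb (prokaryote), 0.2 Mb (eukaryote) | desk-scale stand-ins (~20x below real genomes) so that 100k reads give informative marker coverage; the calculus depends only on copies x length, so the scaling is neutral |
| marker/standard gene lengths | all 1000 b | the calculus assumes equal per-copy read yield per gene (see assumption above); unequal lengths would inject a deterministic bias the method does not correct |
| marker divergence | per-copy mutation rate 0.15 from a family ancestor, enforced pairwise divergence >= 0.20 | keeps the 80/95/98% identity tiers cleanly separating taxa, families and standards |
| annotation sensitivity | 1.0 per marker; set `psbO = 0.72` to emulate the observed *psbO* undercount | sensitivity is a property of annotation databases, so it is modeled at the annotation layer, not in the sequence |

Reads are drawn in two steps: source genome $\propto$ copies $\times$
genome length, start position uniform over the positions where the read
fits (genomes are linear; no reverse strand by default — a
`both_strands` matcher flag exists). A read is a *latent* hit of a locus
iff its overlap is at least half the read length; the latent hit is
*annotated* with the marker's sensitivity. `expected_counts()` gives the
exact closed-form expectations, against which simulation output is
tested at 3 sigma.

What the generator does **not** emulate — hence what a green test does
not establish: extraction/lysis bias between taxa, GC or length-dependent
library bias, chimeras, quality-score structure, paired-end merging
artifacts, real *psbO* database incompleteness (only its aggregate
sensitivity), taxonomic mis-annotation between related taxa, and ploidy
variation within a taxon. A green suite establishes that the *calculus
and its software are faithful*, not that the wet-lab assumptions hold.

## The read matcher

The BLAST/DIAMOND stages of the field protocol are replaced by a
deterministic k-mer-seeded, ungapped matcher (`match_read()`,
`count_hits()`), because the synthetic references are close copies of
the read sources and gapped alignment statistics would add nothing
testable. Filter thresholds mirror the protocol: standards 95% identity
with a 98% confirmation pass (the nucleotide-space collapse of a
two-stage BLASTn-then-BLASTx identification), *recA*/*radA*/*psbO* 80%,
all with a 50%-of-read alignment-length rule and best-hit-only counting
(the `-k 1` convention). E-value and bit-score filters are deliberately
not reproduced — they are statistics of BLAST's scoring system, and the
identity + length rules carry the selectivity at desk scale.

Numerical choices that make results platform-independent: identity
comparisons use exact integer cross-multiplication (never floating
ratios); ties break by longer aligned span, then lexicographically
smallest reference id; reads that tie across strands keep the forward
orientation. A read whose best accepted hit is a standard gene but fails
the 98% confirmation is dropped, not reassigned — how multi-class
conflicts were resolved in the original protocol is not documented, so
global best-hit is our stated choice. The matcher is verified against a
brute-force all-offsets oracle that scores every (read, reference,
offset) alignment exhaustively.

Note the seed-based candidate search is exact only up to seeding: a true
hit with no shared 15-mer is invisible to the matcher. At the simulated
error rate (0.002/base, ~0.5 errors per 250 b read) the probability of
an accepted hit lacking an exact 15-mer is negligible, and the oracle
equivalence test confirms it at the tested seeds.

## Degenerate inputs and guardrails

* $S_p = 0$, $S_a \le 0$, $R \le 0$, volume $\le 0$, ploidy $< 1$:
  errors, never silent zeros.
* $R > 1$ (more standard recovered than added): warning — possible under
  count noise; $R \ge 2$: the sample is flagged and its abundances are
  reported as missing rather than nonsense.
* Zero marker reads: abundance 0 with the detection limit attached.
* Zero cyanobacterial *psbO*: anchored estimator flagged, direct
  estimator reported.

## Validation statistics

`paired_comparison()` reports Pearson's *r* and a slope under
least-squares through the origin (default), OLS with intercept, or
standardized major axis — the field reports "slope" without stating the
model, so the default is the one under which "slope = 1" means numeric
equivalence of two counting methods, and `slope_model = "all"` prints
every variant. `braycurtis_pcoa()` computes Bray–Curtis dissimilarity
and classical PCoA; negative eigenvalues (Bray–Curtis is non-Euclidean)
are clipped at zero for the variance-explained fraction by default, with
a Cailliez correction behind a flag. `fold_range()` and
`filaments_to_cells()` (default 100 cells per filament, the standard
microscopy conversion for filamentous cyanobacteria) support the
comparisons against reference counting methods.

## Known limitations

* The matcher is a desk-scale stand-in: no gapped alignment, no protein
  translation, no taxonomy inference; taxon labels come from reference
  ids.
* Recovery combination across standards assumes the spikes behave
  exchangeably; a failed spike is only *flagged* (dispersion > 2), not
  down-weighted.
* No uncertainty propagation beyond what the simulator provides
  empirically; counts are treated as point estimates.
* Statistical caveat recorded during design: at an expected marker count
  of exactly 50 reads the multinomial coefficient of variation is ~14%,
  so a per-sample 10% error band cannot hold with high probability at
  that boundary; recovery properties are therefore asserted for the mean
  across samples (acceptance) or at counts where the band is attainable
  (unit property tests).
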