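---
title: "Comparing affinity-based 5hmC enrichment techniques on synthetic tiling arrays"
author: "hmcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing affinity-based 5hmC enrichment techniques on synthetic tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmcompare)
```

## The problem

5-hydroxymethylcytosine (5hmC) is mapped genome-wide by enriching
5hmC-marked DNA fragments and comparing enriched to input material, most
cheaply on two-channel tiling microarrays that report per-probe
log2(IP/input) ratios. Three affinity strategies are in common use:
antibody immunoprecipitation (hmeDIP), βGT-glucosylation followed by
chemical biotin capture (hMeSeal), and JBP-1 protein affinity for
glucosylated DNA. They differ in recovery, noise and sequence biases,
and those differences propagate into every downstream claim about where
5hmC sits. `hmcompare` implements the comparative analysis — from
normalization through peak calling, genomic annotation, correlation and
profile diagnostics, bias-region detection, chromatin-state overlap and
gRES-qPCR validation — and pairs it with a synthetic data generator in
which each technique is an explicit, parameterized transfer function.
Because the generator knows the truth, every analysis component can be
tested for recovery of known structure rather than merely for internal
consistency.

## The synthetic epigenome

`build_genome()` writes a small mammalian-flavoured genome: by default 2
chromosomes of 5 Mb carrying 200 non-overlapping genes (5–30 kb), a
promoter CpG island for ~70% of genes (1 kb, spanning 300 bp upstream to
700 bp downstream of the TSS) plus orphan islands, 60 intergenic
enhancers, and 250 repeat blocks per class for six repeat classes
(Line1, LTR, SINE, and literal (CA)n, (TC)n and other simple tandem
motifs), about 13% of the genome — deliberately repeat-rich, as
mammalian genomes are. Background sequence is CpG-depleted by simulated
deamination (~85% of background CpGs become TpG, observed/expected ≈
0.15–0.25), islands are GC-rich and undepleted (o/e ≈ 1), and
interspersed-repeat consensus sequences are themselves CpG-depleted, as
aged repeats are. A minority (~30%) of gene bodies additionally carry
2–4 intermediate-CpG-content (ICP) patches of 300–500 bp with o/e ≈ 0.6
— CpG-denser than bulk DNA but far below island density.

`assign_true_modifications()` turns the annotation into per-CpG ground
truth for a tissue: 5hmC probability is high across expressed gene
bodies and enhancers, essentially zero within ±100 bp of TSSs and inside
CpG islands, and low over repeats; 5mC is high everywhere except
islands. Within ICP patches the per-CpG 5hmC probability is reduced so
that the summed 5hmC of a patch stays near the level of the surrounding
gene body — denser CpGs, less modification per CpG — which matters for
the antibody bias below. The map is scaled so its mean equals the
tissue's global 5hmC level: 0.7% for the brain-like profile and 0.07%
for the liver-like one, a 10-fold contrast, with 5mC (4.5%) equal
between tissues. The two default tissue profiles share half of their
expressed genes, which is what makes tissues separate in clustering
while techniques agree within a tissue.

## Technique transfer functions

`simulate_probe_track()` evaluates, per probe,

signal = gain × density + cpg_bias × max(0, o/e − o/e₀) + repeat_bias +
proximal_boost + TSS_artifact + noise,

with density the summed per-CpG 5hmC probability over a 300 bp window
(the mean sonication fragment size) centred on the probe, divided by its
genome-wide mean — an IP/input ratio responds to relative, not absolute,
enrichment, so tissue-level differences live in the truth map rather
than in the track scale. The defaults encode the observed technique
phenotypes:

| parameter | hmedip | hmeseal | jbp1 | meaning |
|---|---|---|---|---|
| gain | 0.8 | 0.9 | 0.03 | log2 units per unit density |
| noise_sd | 0.45 | 0.22 | 0.45 | log2 noise per replicate |
| cpg_bias_coeff | 1.8 | 0 | 0 | CpG-composition bias |
| repeat_bias (Line1/CA/TC) | 1.3/1.4/1.4 | 0 | 0 | additive, per class |
| promoter_proximal_boost | 0 | 0.4 | 0 | 100 bp–1 kb upstream |
| tss_artifact | 0 | 0 | 0.9 | ±100 bp of TSS |

The protein-affinity model is deliberately noise-dominated (gain near
zero) with a spurious TSS signal — its defining failure mode. The
antibody's composition bias uses the fragment window's CpG o/e, with a
guard: windows whose o/e is estimated from fewer than 10 C or 10 G bases
(deep inside AT-rich simple repeats) contribute no bias, since a ratio
built on a handful of bases measures noise, not CpG density. The
magnitudes of gain, biases and noise are not reported quantities
anywhere; they were fixed once so that the default study reproduces the
qualitative regime the comparison establishes — replicate correlations
around 0.9 exceeding cross-technique correlations (>0.7 within tissue),
cross-technique exceeding cross-tissue, protein affinity nearly
uncorrelated (<0.25) with everything — and were not revisited
afterwards.

Why the ICP patches matter: the antibody and the chemical capture select
fragments by 5hmC content alike, and 5hmC rides on CpGs, so both peak
sets are mildly CpG-enriched relative to the array. The antibody's extra
composition affinity only becomes visible where CpG density and 5hmC
content decouple — the ICP patches — which is where its peak set gains
fragments the chemical capture does not, raising its mean fragment CpG
o/e. A single flat CpG-bias term large enough to produce the same shift
without ICPs would instead light up promoter CpG islands and erase the
antibody's TSS trough, which the real technique clearly retains.

## Normalization

Tracks are normalized as two-channel arrays are: a robust loess fit of M
(log2 ratio) on A (mean log intensity) removes intensity trend
(`limma::loessFit`, span 0.3, three robustness iterations), then scale
normalization divides each sample by its median absolute deviation and
multiplies by the geometric mean of all samples' MADs, equalizing spread
across samples. Simulated tracks carry log2 ratios directly and no
A-values, so the loess step degrades to an announced no-op and
normalization reduces to the scale step — which is exactly idempotent.
A genuine robust loess is not a projection, so a second application
moves residuals slightly; the tests document near-stability rather than
exact idempotence on that path.

## Peak calling and annotation

The peak threshold is the 95th percentile (linear interpolation between
order statistics) of a sample's probe values genome-wide; a sliding
window of four consecutive probes passes when at least three reach the
threshold (ties count), windows never span chromosome ends or tiling
gaps above 1 kb, and peak probes are the union of probes in passing
windows, merged into peaks over adjacent runs. Sliding (rather than
disjoint) windows are used; the window oracle in the test suite
enumerates every window explicitly and agrees on hundreds of random
instances, and segments shorter than the window yield no peaks by
definition. Raising the percentile can only shrink the peak set
(monotonicity, also tested).

Each probe is assigned by its midpoint, strand-aware, to promoter core
(TSS ±100 bp), promoter proximal (100 bp–1 kb upstream), promoter distal
(1–2 kb upstream), intra-genic or inter-genic; the upstream reading of
"proximal" follows the direction the comparative results describe.
Within one gene the promoter categories outrank the body; a probe
claimed by two different genes is non-uniquely mapping and excluded from
distributions. CpG-island accounting counts any ≥1 bp overlap of a peak
probe with an island and splits islands into promoter (within 2 kb
upstream through the core of a TSS) and orphan.

## Profiles, correlation and bias detection

Correlation clustering samples up to 500,000 probes without replacement
(the desk-scale array has 40,000, so all are used, with a notice),
computes Pearson correlations and clusters with Ward linkage on
1 − r; the dendrogram is also serialized as newick. Autocorrelation at
probe lag k uses all within-segment pairs; 40 probes at the default
250 bp spacing span ~10 kb. Gene scores are the mean of probes mapping
to the gene divided by gene length in bp; genes without probes are
missing, not zero. Metagene profiles rescale each gene to unit length
with 25% flanks (25 + 100 + 25 bins), orient by strand, assign probes to
bins by midpoint and average per-gene bin means across genes; empty bins
stay missing so sparse genes do not drag the profile toward zero.

The Δ5hmC track is hMeSeal − hmeDIP on replicate-averaged tracks;
technique-biased regions are maximal runs of ≥3 consecutive probes all
beyond ±1.5 log2 units spanning ≥200 bp (strict per-probe rule; the
alternative per-replicate confirmation mode is available through the
replicate tracks). Repeat-class comparisons use the two-sided Wilcoxon
rank-sum test — exact when both groups have ≤25 tie-free values,
otherwise the normal approximation with tie and continuity correction —
delegated to `stats::wilcox.test` and cross-checked in the tests against
full enumeration of all rank assignments for small samples.

## gRES-qPCR

Glucosylation-sensitive restriction qPCR interrogates one CCGG site:
MspI cuts C, 5mC and 5hmC but is blocked by glucosyl-5hmC; HpaII cuts
only unmodified C. With ideal doubling, the intact template fraction of
a digest is 2^(Ct_uncut − Ct_digest), capped at 1; a reaction that takes
≥50 cycles is treated as fully cut (the simulator writes a sentinel of
55 cycles for zero template). Then 5hmC = intact(MspI,+βGT) −
intact(MspI,−βGT), total blocked = intact(HpaII,−βGT), 5mC = blocked −
5hmC, C = 1 − blocked; negatives are clamped and the three marks scaled
to sum to exactly 100%. The kit vendor's worksheet is not public, so
these formulas are reconstructed from the stated enzyme chemistry; each
digest is referenced to the uncut tube of its own βGT branch (controls
for treatment losses), the −βGT HpaII tube is authoritative and the +βGT
tube serves as a consistency check that warns beyond 10 percentage
points. The noiseless simulate→compute round trip is exact on a full
grid of fraction triples, which is the designed-in invariant of the
pair.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open everywhere inside the package;
conversions happen only in the readers/writers. Quantiles use linear
interpolation (type 7). Probes tie-break into bins by `floor` of
fractional position. Fewer than 50 probes refuse a loess fit; a zero-MAD
sample, a constant sample in correlation, an empty replicate group, an
empty interval set in midpoint profiling, and probe-layout mismatches in
Δ-track construction are all hard errors naming the offending input.
Interval subtraction drops fragments under 50 bp as slivers; active
enhancers exclude H3K4me3-overlapping H3K4me1 peaks by default so
promoter H3K4me1 is not misread (the mark-pair-only behaviour is
selectable).

## Problem sizes and what the tests show

The default study — 2 × 5 Mb, 40,000 probes, 2 tissues × 2 techniques ×
2 replicates plus one protein-affinity sample — was chosen as the
smallest scale at which percentile thresholds, correlation structure and
repeat statistics are stable; it simulates and analyses end to end in
about a minute. The test suite validates oracle equivalences on smaller
random instances and runs the default study once for the comparative
findings. Passing tests show that the analysis recovers the structure
the generator encodes: they validate the pipeline's correctness and the
internal consistency of the technique models, not the biology of any
real tissue. Real arrays add probe-specific affinity, dye and
amplification effects, unmappable and copy-variable regions, and
antibody lots that differ between batches; none of these are modelled,
and conclusions about a real data set still require the package's
validation arms (gRES-qPCR, cross-technique concordance) on that data
set.

## Known limitations

The generator's nucleotide model is deliberately minimal (CpG and repeat
structure only); loess normalization is exercised mainly through its
no-op path on synthetic ratio data; dendrogram stability is not
bootstrapped; and peak calling has no FDR control — it reproduces the
percentile-rule definition, whose statistical properties are inherited
from that choice, not improved upon.
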