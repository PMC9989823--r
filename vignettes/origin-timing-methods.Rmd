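---
title: "Models and methods behind oriRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oriRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriRT)
```

# Scope and scientific background

Budding-yeast replication origins (ARSs) span a wide range of
replication times (RT) and firing efficiencies: early-efficient (EE)
origins such as ARS305 fire in most cells early in S-phase, while
late-inefficient (LI) origins such as ARS316 fire late and in a minority
of cells. oriRT implements the computational layer used to characterise
such origins from four angles:

1. **Sequence**: counting degenerate origin elements (ACS, eACS, B1, B2,
   B3) at each origin and asking whether their abundance correlates with
   RT or efficiency.
2. **Copy number**: turning binned G1- and S-phase sequencing counts
   into smoothed log2 S/G1 RT profiles and calling regions whose RT
   differs between two conditions.
3. **qPCR arithmetic**: spike-in normalised recovery, fold enrichment
   over a reference locus, and purity of purified origin chromatin.
4. **Proteomics**: scoring which proteins are enriched at a purified
   origin relative to control purifications.

A fifth module, the origin-firing simulator, generates all of these
inputs with known ground truth; every pipeline stage is validated
against it.

# Coordinates and containers

All genomic coordinates are 0-based, half-open (BED convention),
everywhere. Readers for 1-based tables convert at the boundary and
nothing downstream re-converts; this single-convention rule is why
interval containers are plain data.frames rather than 1-based range
classes. The central S4 containers are `GenomeAnnotation` (chromosomes,
origin catalog, centromeres, mitochondrial name set), `BinnedTrack`
(per-chromosome fixed-width bin vectors with a pipeline-stage tag) and
`MotifDef` (an IUPAC consensus with mismatch budget, per-motif flank and
optional positional anchoring).

# Degenerate motif scanning

A genome base matches a consensus letter X iff it lies in IUPAC(X); an
ambiguous genome base counts as a mismatch unless the consensus letter
is N. A motif instance is any window, on either strand, with at most
`maxMismatches` violations (default 2). Minus-strand hits are computed
against the reverse complement and reported in plus-strand coordinates.
Overlapping instances are all counted — no greedy masking — and for a
palindromic consensus the identical two-strand hit at one locus is
counted once.

Two motifs have special rules. The B1 element (consensus WTW) is not
scanned freely: it is searched only in the three 3-mers starting 17, 18
and 19 bp 3' of each ACS hit, on the ACS's T-rich strand (for a
minus-strand ACS, 3' runs leftward on the plus strand). The B3 element
(an Abf1 binding site) is scanned with 200 bp of extra flank on each
side of the origin window, since Abf1 can act outside the
nucleosome-free region.

Design choices that were genuinely open:

* The ACS, eACS and B3 consensus strings are not fixed by the analysis
  being reproduced; `defaultMotifs()` ships literature defaults (ACS
  11-mer `WTTTAYRTTTW`, eACS 17-mer `WWWWTTTAYRTTTWGTT`, B3
  `RTCRYNNNNNACG`) and every definition is configuration via
  `motifDef()`.
* Both strands are scanned for all motifs, and the origin window
  defaults to the annotated interval (or midpoint ± 250 bp); both are
  exposed rather than hard-coded because neither is uniquely determined.
* Count-vs-RT association uses Spearman rank correlation with a seeded
  permutation p-value (motif counts are small, skewed integers, so a
  rank statistic with an exact-style null is safer than a parametric
  correlation test).

The scanner is tested for exact agreement with a brute-force
position-by-position set-membership oracle on 100 random 1-kb sequences
with planted motifs at budgets 0–2, plus reverse-complement symmetry and
budget monotonicity properties.

# Copy-number RT profiling

Read-pair fragments with mapping quality ≥ 12 are assigned to one
fixed-width bin (500 bp default, 1000 bp supported) by their midpoint —
midpoint assignment is the one rule that gives each pair exactly one bin
and conserves totals. Mitochondrial contigs are excluded by name.
Tracks are normalised by total mapped count (scaled by 1e6 for readable
bedgraphs; the constant cancels in ratios), smoothed with a centered
rolling mean, and combined per replicate into log2(S/G1) ratios. Before
the log transformation the lowest 5th percentile of normalised bin
values — evaluated per sample, masking a bin if *either* member of the
S/G1 pair fails — is removed; the symmetric mask is what prevents
division blow-ups in near-empty bins. Smoothing is applied before the
ratio, matching the stated order of the emulated workflow (tracks are
smoothed, then ratioed per replicate), with any further smoothing of the
replicate average left to display code.

The smoothing window (5 bins) is a package default, not a reproduced
value: at 500-bp bins it visibly suppresses shot noise without erasing
single-origin peaks, and it is configurable.

# Differential RT calling

For every bin with at least two unmasked replicate values per condition,
treated and control log2 ratios are compared with Welch's unequal
variance t-test (`stats::t.test`; the wrapper only adds the
zero-variance contracts the textbook formula cannot express). A bin is
significant when p < 0.05 **and** the mean difference is at least 0.1
log2 units; no multiple-testing correction is applied by default, in
fidelity to the per-bin gate being reproduced, with Benjamini–Hochberg
available as an opt-in (`adjust = "BH"`). Maximal runs of adjacent
significant bins with a common sign become regions (gap tolerance 0,
minimum one bin — the simplest faithful reading of per-bin calling);
regions are classified as CEN, ORI or inter-origin by strict
boundary-to-point distance under 5 kb, with CEN taking precedence over
ORI because centromeres sit atop centromeric origins.

Two honest caveats. First, the merging rule of the reproduced analysis
is not spelled out, so genome-wide region *counts* are not an exact
reproduction target; the percentage arithmetic (29 of 224 delayed
regions near origins = 13%; 80 of 236 advanced = 34%) is what the
package reproduces exactly. Second, Welch's test at three replicates per
side is intrinsically conservative: its true type-I error at nominal
0.05 is ≈ 0.035 (a property of the Welch–Satterthwaite approximation
visible on pure Gaussian 3v3 draws, not of this implementation). The
null-calibration test therefore checks that the rejection rate never
*exceeds* nominal and that the effect-size gate removes essentially
everything under the null; a two-sided equality with 5% cannot hold at
n = 3.

Null calibration is assessed with smoothing disabled: the rolling mean
correlates neighbouring bins, which invalidates pooled binomial bounds,
while the per-bin test's marginal calibration is the property of
interest. Region-count and recovery checks run the default smoothed
pipeline. Replicate outliers are excluded manually by sample id
(`excludeReplicates`), mirroring by-name removal rather than inventing
an automated criterion.

# qPCR arithmetic

Recovery normalises each locus to a spike-in plasmid added in equal
amount to every assayed sample and corrects for the fraction of each
sample loaded (0.1% for extract/pellet/input/flowthrough vs 1–2.5% for
beads/elution in the emulated design). Fold enrichment is
(target/reference) in elution over the same in input, with PDC1 as the
conventional reference. Purity uses the competitive-fraction form

$$\mathrm{purity} = 100\cdot\frac{F\,L}{F\,L + (G - L)}$$

with fold enrichment $F$, target length $L \approx 1$ kb and genome
size $G \approx 12{,}000$ kb: the enriched target competes against the
remaining genome at single-copy level. This is the only dimensionally
consistent combination of those three printed ingredients, and it maps
the printed 30,000–150,000-fold enrichment range to 71.4–92.6% purity,
consistent with the reported ≈60–90% band. RT time courses normalise
each locus to its own G1 value before taking the early/late ratio, so
global qPCR scale factors cancel and the ratio is 1 at t = 0 by
construction.

# Proteomic enrichment

Abundance columns are normalised to equal totals (loading correction);
each protein's enrichment is the median over target replicates divided
by the median over control replicates, with absences treated as missing
rather than zero. Proteins absent from the control but present in the
target are given the table's 1st-percentile abundance as a control floor
and flagged as imputed lower bounds — such proteins are reportable as
enriched, so the division must be defined. Significance comes from a
background-variance test: the central 80% of log2 ratios estimates the
background location (median) and scale (MAD, rescaled by the
normal-consistency factor for the trimming — without that factor an 80%
truncation understates a Gaussian background's sigma by ~22% and
inflates false positives), and each protein is scored by its
standardised deviation. Tables under 30 proteins fall back to
per-protein Welch tests with a warning. The enrichment gate is
inclusive ≥1.4-fold with p ≤ 0.05; both gates are exposed because the
emulated headline counts do not state whether the p gate was applied
jointly. Complex stoichiometry (e.g. MCM2-7 over canonical histones)
averages member-level enrichments and Welch-tests across members.

# The simulator: what it emulates and what it does not

Each origin fires independently with probability `efficiency` at a
Normal(`firingTime`, `firingSd`) time; forks move at `forkSpeed` and a
locus is replicated at the first fork arrival, giving the closed form

$$E[\mathrm{copy}](x,t) = 2 - \prod_i \left(1 - e_i\,
\Phi\!\left(\frac{t - d_i/v - \mu_i}{\sigma_i}\right)\right)$$

checked against an explicit Monte Carlo cell simulation
(`monteCarloCopyNumber`), which is the reference implementation. HU
mode caps fork travel at 5 kb, confining replication to ~5 kb around
early origins as under 200 mM hydroxyurea. Counts are Poisson with a
log-normal per-bin bias shared between the G1 and S samples of a
replicate — exactly the structure that makes the percentile filter and
the bias-cancelling S/G1 ratio meaningfully testable.

Defaults are the emulated study conditions where stated (G1 at t = 0, S
at 24 min, HU 60 min with 5 kb cap, 3 replicates) and literature-typical
otherwise, chosen once: fork speed 1.5 kb/min, firing-time SD 3 min,
bin bias SD 0.05, and sequencing depth 2000 read pairs per 500-bp bin —
the depth at which per-bin copy-number noise after smoothing is a few
percent, as in published sorted S/G1 profiles. Pipeline tests use a
two-origin 500-kb chromosome (1000 bins): large enough for distinct
early/late domains and masked tails, small enough that a 50-seed null
study and a 10-seed recovery study run in seconds.

The simulator does **not** model fork collisions beyond first-arrival,
replication-checkpoint feedback, GC or mappability bias (no GC
correction exists in the pipeline either), or mechanistic regulators
(Rif1, Fkh, chromatin state). Passing recovery tests therefore show the
caller detects localized timing shifts of the modeled kind at realistic
depth and replicate numbers — not that it is robust to every artefact of
real sequencing data.

# Numerical details worth knowing

* Motif hits are sorted by (offset, strand) with plus before minus,
  independent of collation locale.
* `welchTest` contracts: both groups constant and equal means gives
  t = 0, p = 1; both constant with unequal means gives p → 0 flagged
  degenerate.
* The percentile mask uses strict `<` against the per-sample quantile;
  a zero G1 value that still survives is masked with a warning rather
  than yielding an infinite ratio.
* Rolling means have hard NA edges — no partial windows — and NA inputs
  propagate; replicate averaging then uses pairwise deletion.
* `nearestFeatureDistance` returns `Inf` when a chromosome has no
  feature, which classification treats as "not near".
* Percentages in class summaries are integer-rounded, matching the
  printed style of the figures being reproduced.

# Reproducibility

All simulation entry points take explicit seeds. `scripts/acceptance.R`
re-derives every headline quantity from scratch — the class-summary
percentages, the purity band endpoints, scanner-vs-oracle agreement,
null calibration and region counts, perturbation recovery, closed-form
vs Monte Carlo copy-number agreement, HU confinement and proteomic
recovery — from a single `--seed`, and writes them as JSON. Problem
sizes match those quoted above and are printed with each value.
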