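---
title: "Dissecting UV damage and repair at TF binding sites with uvmotif"
author: "uvmotif authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting UV damage and repair at TF binding sites with uvmotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Melanomas carry an unusually high rate of UV-induced C>T mutations at
active transcription factor binding sites (TFBS). Two mechanisms can
produce such a local excess: the bound protein can *increase the
formation* of cyclobutane pyrimidine dimers (CPDs) at particular
dipyrimidines it distorts, and it can *impair nucleotide excision
repair* (NER) by blocking access to lesions under its footprint.
`uvmotif` implements the machinery to separate these two contributions
from three data layers mapped at single-nucleotide resolution:

* somatic SNVs from a UV-exposed tumour cohort,
* CPD formation maps immediately after irradiation (cellular and
  deproteinized "naked" DNA), and
* CPD maps at two timepoints (0 h and 48 h) sequenced at a
  predetermined depth per timepoint (Damage-seq style).

All three layers are stacked into a common coordinate system: for every
binding motif of a TF, each active genomic instance contributes a
2001-bp window centered on the motif and oriented along the motif
strand. Four concentric regions partition every window: the **motif**
(21 bp in protein contact), the **TFBS** (101 bp, containing the
motif), the **DHS flanks** (200 bp per side of mostly protein-free open
chromatin), and the outer **flanks** (750 bp per side), which serve as
the local background.

# Models and procedures

## Binding-site catalog

Motif instances are located by a log2-odds PWM scan
(`buildPWM()`, `scanMotif()`) inside ChIP-seq peak intervals, on both
strands, reporting hits above a configurable fraction of the maximum
attainable score (default 0.85). A fraction-of-max threshold was chosen
over a p-value threshold because it is reproducible without a
background-distribution algorithm; overlapping hits within a peak are
resolved by score (ties: leftmost, then plus strand). A site is called
*active* when it overlaps a DNase I hypersensitive site in **every**
supplied DHS set — one per cell type, so activity means open chromatin
in all of them — and *inactive* otherwise (`classifyActivity()`). The
center of a motif of length $L$ is `start + floor(L/2)`, giving a
deterministic single-base anchor for window alignment; `jaccardOverlap()`
quantifies the genomic overlap of two active-site sets after expanding
each site to its center ±50 nt (bedtools-jaccard semantics).

## Window stacking and inclusion filters

`buildWindowStack()` extracts the oriented windows (minus-strand motifs
are reverse-complemented; windows crossing a chromosome end are
discarded rather than truncated, so every column keeps equal depth).
Events are mapped by `mapEvents()`: mutations as points, CPD records at
the oriented position of the dipyrimidine (anchored at the smaller
oriented offset of its two bases) with the strand re-expressed relative
to the motif. Events under two overlapping windows count once per
window — stacking is per window, then columns are summed.

A motif type enters the analysis only if it has at least 5000 active
sites *and* the median of its 2001 per-position mutation counts is at
least 2 (`filterMotifs()`); both thresholds act exactly at their
boundaries (4999 fails, 5000 passes; median 1 fails, 2 passes).

## Expected mutations from sequence context

Per-sample UV dominance is enforced by keeping samples with at least
70% C>T substitutions (G>A counted as C>T on the other strand) and
discarding non-C>T records within kept samples (`filterCohort()`).
`fitSubstitutionModel()` then estimates a pyrimidine-centered k-mer
mutability table (k = 3 by default, k = 5 as a switch): mutations
observed at genome occurrences of the k-mer divided by the occurrence
count, with every genomic position counted once on its
pyrimidine-bearing strand. Contexts containing N are excluded rather
than imputed.

The per-offset expectation (`expectedProfile()`) conditions on each
window's observed mutation total $m_w$ and redistributes it over the
window's offsets proportionally to the context mutabilities — the
analytic mean of the "randomize mutations within each sequence"
procedure, so each window's expectation sums *exactly* to $m_w$. A
seeded Monte-Carlo mode (`mcExpectedProfile()`) exists to verify the
analytic form. The observed mutation profile of the *inactive* sites of
the same motif, scaled to the active total, is available as an
alternative background (`inactiveBackgroundProfile()`).

## Relative repair from fixed-depth maps

Because each timepoint's map is sequenced to a predetermined depth,
comparing raw counts across timepoints cannot reveal what fraction of
lesions was removed; only the *redistribution* of CPDs is identifiable.
`relativeRepairProfile()` therefore normalises each timepoint (by
window totals, or genome-wide totals) and subtracts:
$\mathrm{repair}_i = \mathrm{rel0}_i - \mathrm{rel48}_i$. Under window
scope this profile is zero-sum by construction — a deliberate property,
not a defect. Region summaries (`regionRepairRatio()`) compare *means*
of per-position repair so regions of different widths are comparable,
in log2 relative to the flanks or the DHS flanks; negative per-position
repair (apparent relative CPD gain) is retained, never clipped. The
significance of a region's redistribution is a G-test of independence
on the 2×2 table (region vs reference) × (0 h vs 48 h).

For the within-motif comparison the same change is expressed as a
*percent change* of genome-normalised counts after 48 h, and reported
as the difference between the site and its matched flanks in
percentage points (`withinMotifRepair()`): with fixed-depth maps these
percent changes are identifiable only relative to the genome-average
survival, which the synthetic generator pins to 1 (below).

## Within-motif dipyrimidine analysis

`conservedDipyrimidines()` reports motif positions where one specific
dipyrimidine type (TT, TC, CT, CC — read on either motif-relative
strand, since CPDs are strand-specific) is present in at least 50% of
the motif's instances. Requiring a *specific* type (not merely any
pyrimidine pair) is what makes the null well-defined, because the
expectation is matched on the full tetranucleotide. For each site, each
carrier window contributes one uniformly drawn flank position sharing
that window's own 5′ base + dipyrimidine + 3′ base (both flank strands
eligible); the track counts at the drawn positions are summed and the
procedure is repeated 50 times and averaged (`drawMatchedSamples()`,
`evaluateDraws()`). Drawing once per window per iteration makes
"without replacement within an iteration" automatic. The same draws are
reused across tracks, so 0 h vs 48 h comparisons sit on identical
sampled positions. Observed mutation counts sum both bases of the
dimer; observed CPD counts use the strand-specific records anchored at
the site. Deviations are reported as
`100 * (observed - expected) / expected`, with a Poisson
likelihood-ratio G statistic (df = 1) as the per-site significance
call — a one-cell comparison, so a multi-cell goodness-of-fit does not
apply.

## Predicting the 48 h landscape and the mutation correlation

`predictCpds48h()` transfers the 0→48 h redistribution learned from one
dataset onto an independently measured 0 h profile:
$f_i = \mathrm{rel}(\text{ref48})_i / \mathrm{rel}(\text{ref0})_i$,
prediction $\propto \mathrm{rel}(\text{target0})_i \cdot f_i$,
renormalised. The transform is scale-invariant in all three inputs and
reproduces the identities `target0 = ref0 → rel(ref48)` and
`ref48 = ref0 → rel(target0)` exactly; to keep those identities exact,
pseudocounts (0.5 on both reference tracks) are applied only when the
reference has zero cells under positive target support, and the
optional moving-average smoothing of $f$ (5-bp bandwidth) is off by
default. Both knobs are exposed.

`correlateDamageMutation()` closes the loop: across motifs, the log2
TFBS-to-flanks ratio of mutations is correlated (Pearson) with the same
ratio of a damage track — observed 0 h, or predicted 48 h. If mutation
rate is shaped by the damage that *survives* repair, the predicted-48 h
ratios must correlate better than the 0 h ratios; that contrast is a
planted, recoverable truth in the synthetic panel.

## Statistics

`chisqGof()` (Pearson, df = cells − 1), `gTest()`
(G = 2ΣO·ln(O/E)), and `chisqHomogeneity()` (2×k contingency) follow
their textbook forms, with deterministic left-to-right pooling of cells
whose expected count falls below 5. Region-level significance in
`summarizeRegions()` and `damageVsNakedSummary()` is computed on the
two-cell partition (inside region, rest of window) so that a uniform
excess over a region is detected even when its internal shape matches
the expectation; a goodness-of-fit across the region's positions with
the expectation rescaled to the region total would test shape only and
assign p ≈ 1 to a uniform doubling. P-values are reported raw
(significance at P < 0.05, uncorrected), with a Benjamini–Hochberg
column emitted alongside for users who want it.

# The synthetic study and what it does (and does not) emulate

`simulateStudy()` builds a self-contained study with recorded truth:

* **Genome and sites.** An i.i.d. genome (default GC 0.4, the
  human-like value) with 6000 active and 1000 inactive implanted
  consensus instances at 2100-bp spacing, so windows are disjoint.
  Instances are the consensus sequence (a `fidelity` parameter can
  degrade them); peaks cover all sites, two DHS "cell types" cover the
  active ones only.
* **Damage.** Per-dipyrimidine 0 h intensity is a per-type baseline
  (TT 1.0, TC 0.6, CT 0.4, CC 0.3 — TT dimers form most readily),
  times a 2× spike at the consensus TT (motif offsets −8/−7, plus
  strand), emulating the Tryptophan-cluster behaviour of locally
  increased photoproduct formation. Naked-DNA intensity is the baseline
  alone.
* **Repair.** 48 h intensity multiplies the 0 h intensity by a
  region-wise survival fraction (motif 0.8, TFBS 0.7, DHS flank 0.55,
  flank 0.4), *expressed relative to the genomic background, whose
  survival is the reference unit 1*. Fixed-depth maps make only
  survival-relative-to-background identifiable, so this is a
  parameterisation, not a biological claim that background DNA escapes
  repair.
* **Maps.** Each timepoint is a fixed-depth draw over all genomic
  dipyrimidines — 48 h at the *same* depth as 0 h, deliberately
  destroying absolute-repair information so the pipeline must work with
  relative repair, as with the real protocol. The draw is an exact
  multinomial when the depth fits a 32-bit integer and independent
  Poisson sampling (the standard large-depth limit of the multinomial)
  beyond that. `backgroundWeight` (default 220) multiplies the
  intensity of background dipyrimidines so that the windows hold ~2% of
  the total CPD mass: in real data the stacked windows are a tiny
  fraction of a 3-Gb genome, and genome-total normalisation behaves
  accordingly without simulating gigabases. With the windows at ~2% of
  the mass, the intensity-weighted mean survival is ≈0.99, and the
  recoverable within-motif repair contrast is 100·(0.8 − 0.4)/0.99 ≈
  +40.4 percentage points.
* **Mutations.** Per sample, C>T records land on cytosines inside
  dipyrimidines with probability proportional to the *48 h-surviving*
  intensity (mutations arise from unrepaired lesions; `from = "0h"` is
  the negative-control switch), plus a `1 − ctFraction` share of
  uniform non-C>T noise. Defaults: 40 samples × 5000 mutations at 90%
  C>T.

`simulatePanel()` extends this to 10 motifs with random consensus
sequences and independently drawn per-motif damage multipliers
(0.7–1.6, over the whole TFBS) and TFBS survivals (0.3–0.9), a
reference 0 h/48 h map pair, an independent target 0 h map, and a
cohort drawn from the 48 h law — the setting in which predicted-48 h
damage should out-correlate 0 h damage.

**What passing these tests shows — and what it does not.** The
generator reproduces the statistical structure the methods rely on:
fixed-depth multinomial sampling, strand-specific dipyrimidine
placement, context-driven mutation placement, disjoint oriented
windows. It does *not* emulate replication timing, nucleosome
positioning, transcription-coupled repair, antibody bias of the damage
assay, overlapping or clustered binding sites, or cell-type mismatch
between damage and mutation data. Green tests therefore certify the
estimators against their own model assumptions, not the biology of any
particular real dataset.

# Numerical choices and degenerate inputs

* All internal coordinates are 1-based closed `GRanges`/`IRanges`;
  conversion to the 0-based half-open file conventions happens exactly
  once, in each reader/writer.
* Window sequences are stored with a 2-base margin so pentanucleotide
  contexts and tetranucleotide matching are defined at every offset;
  flank pairs whose tetranucleotide would leave the stored window are
  excluded from the candidate pool.
* CPD records failing the dipyrimidine check against the reference are
  dropped (not errored), tolerating reference-version mismatches; the
  drop count is attached to the returned object and warned.
* A window with observed mutations but all-zero context mutability is
  an error (it indicates a genome/cohort mismatch), as is a k-mer with
  mutations but no genome occurrences.
* Zero-total tracks error in normalisation; regions with non-positive
  mean repair are reported missing rather than log-transformed; a
  non-positive *reference* mean repair is an error.
* Tie-breaks in the scan are deterministic (score, then leftmost, then
  plus strand), and all sampling is seeded; `runPipeline()` re-runs
  byte-identically from (inputs, config, seed).

# Problem sizes used in the validation suite

The shipped tests validate at desk scale, chosen to keep planted
effects many standard errors wide: the oracle comparison for the
expected-mutation profile uses 500 windows × 10^4 Monte-Carlo
redistributions; repair recovery uses the full default study (6000
sites, 10^4 expected 0 h reads per window); spike recovery uses 20
seeds × 800 sites; the correlation contrast uses 20 replicates of the
10-motif panel; test calibration uses 10^4 multinomial null draws.
`scripts/acceptance.R` re-runs the default study and a 10-replicate
panel from scratch under a caller-supplied seed.

# Known limitations

* Absolute repair rates are out of reach by design: fixed-depth maps
  identify redistribution only, and every repair quantity here is
  relative (to the window, the genome total, or matched flanks).
* The fraction-of-max scan threshold is not calibrated to a match
  p-value; results at marginal sites depend on it, which is why it is a
  single exposed parameter.
* The per-region significance calls share the real analysis's
  assumption that the expectation is noise-free; when the expectation
  itself is estimated from a sampled track (naked DNA, matched flanks),
  the tests are mildly anti-conservative at very high depth.
* `runPipeline()` treats each motif independently; co-occurring or
  overlapping motifs of different TFs are stacked separately, so their
  windows can share genomic territory.
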