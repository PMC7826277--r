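# uvmotif

UV light leaves cyclobutane pyrimidine dimers (CPDs) at adjacent
pyrimidines; unrepaired dimers become the C>T mutations that dominate
melanoma genomes. At active transcription factor binding sites (TFBS)
the local mutation rate is often far from the sequence-context
expectation, and two mechanisms compete to explain it: the bound
protein can **increase CPD formation** at specific dipyrimidines it
distorts, and it can **impair nucleotide excision repair (NER)** by
blocking access to lesions under its footprint. `uvmotif` is an R
package for separating these contributions from nucleotide-resolution
data: somatic SNVs from a UV-exposed cohort, CPD maps immediately after
irradiation (cellular and naked DNA), and fixed-depth CPD maps at 0 h
and 48 h.

It is aimed at computational biologists working on regional mutation
rates, DNA damage/repair maps, or regulatory-region analyses.

## The core quantities

Every binding motif instance contributes a 2001-bp window centered on
the motif and oriented along the motif strand; windows of one motif
type are stacked and partitioned into **motif** (21 bp), **TFBS**
(101 bp, containing the motif), **DHS flanks** (2 × 200 bp) and
**flanks** (2 × 750 bp). On the stack, per motif type:

* **Expected mutations** — each window's observed mutation total *m* is
  redistributed over its offsets by pyrimidine-centered trinucleotide
  (or pentanucleotide) mutabilities fitted genome-wide on the
  UV-dominated cohort (samples with ≥ 70% C>T; non-C>T discarded).
  Region deviation is reported as log2(observed/expected) with a G-test.
* **Relative repair** — with maps sequenced to a predetermined depth per
  timepoint, only the redistribution of CPDs is identifiable:
  `repair_i = rel0_i − rel48_i` after normalising each timepoint.
  Region summaries compare mean per-position repair against the flanks
  (log2), and a within-motif analysis expresses the 48 h change at
  conserved motif dipyrimidines as percentage points relative to
  tetranucleotide-matched flank positions (50 sampled iterations).
* **48 h prediction** — the 0→48 h redistribution learned from one
  dataset is applied to an independent 0 h map, and the TFBS-to-flanks
  damage ratios are correlated with the mutation ratios across motifs.

A fully synthetic study generator (`simulateStudy()`,
`simulatePanel()`) plants known damage spikes, region-wise repair
impairment and a UV cohort, so every estimator is validated by
parameter recovery — no external downloads are needed anywhere.

## Worked example

A small synthetic study: 120 active sites of one motif, a planted 2×
damage spike at the motif's TT dimer, motif/flank CPD survival 0.8/0.4,
and a cohort of 8 samples whose mutations arise from 48 h-surviving
damage.

```r
library(uvmotif)
cfg <- analysisConfig()
study <- simulateStudy(seed = 3, nActive = 120, nInactive = 30,
                       depthPerWindow = 2000, backgroundWeight = 50,
                       nSamples = 8, mutsPerSample = 8000)

stack <- buildWindowStack(study$sites, study$genome, cfg)
cohort <- filterCohort(study$mutations)
stack <- mapEvents(stack, cohort$muts, "mutations")
for (tp in names(study$maps))
  stack <- mapEvents(stack, study$maps[[tp]], paste0("cpd_", tp))

model <- fitSubstitutionModel(cohort$muts, study$genome, k = 3)
stack <- expectedProfile(stack, model)
summarizeRegions(stackProfile(stack, "mutations"),
                 expectedMutations(stack), cfg, motifId = "SYN1")
#>      region observed_sum expected_sum log2_ratio  p_value
#> 1     motif           30         20.3      0.565 4.24e-02
#> 2      tfbs          124         85.4      0.537 5.64e-05
#> 3 dhs_flank          401        323.3      0.311 2.62e-06
#> 4     flank         1099       1215.3     -0.145 1.01e-10
```

Mutations are enriched over the trinucleotide expectation inside the
motif and TFBS (positive log2 ratios) and depleted in the flanks, as
planted. Repair, relative to the flanks (genome-scope normalisation):

```r
totals <- sapply(study$maps, function(m) sum(S4Vectors::mcols(m)$count))
rpg <- relativeRepairProfile(stackProfile(stack, "cpd_0h"),
                             stackProfile(stack, "cpd_48h"), "genome",
                             genomeTotals = unname(totals[c("0h", "48h")]))
regionRepairRatio(rpg, cfg, "flank",
                  cpd0 = stackProfile(stack, "cpd_0h"),
                  cpd48 = stackProfile(stack, "cpd_48h"))
#>      region log2_ratio   p_value
#> 1     motif     -2.028 1.18e-101
#> 2      tfbs     -1.300  0.00e+00
#> 3 dhs_flank     -0.439 2.37e-281
```

The motif is repaired at a quarter of the flank rate (log2 ≈ −2): the
planted NER impairment. Zooming in on conserved dipyrimidines, the
spiked TT stands out while the repair deficit is shared across the
motif:

```r
wm <- withinMotifSummary(stack, tracks = "cpd_0h", seed = 9,
                         genomeTotals = list(cpd_0h = totals[["0h"]],
                                             cpd_48h = totals[["48h"]]))
wm[wm$offset == -8 & wm$strand == "+",
   c("offset", "strand", "type", "observed", "expected",
     "percent_over_expected", "repair_pp_diff", "p_value")]
#>   offset strand type observed expected percent_over_expected repair_pp_diff
#> 2     -8      +   TT      754      368                   105           39.2
#>    p_value
#> 2 4.03e-69
```

The planted 2× spike reads as +105% CPDs over the tetranucleotide-
matched expectation (truth: +100%), and the site was repaired ~39
percentage points less than its matched flanks (truth: +40). The other
motif dipyrimidines show no formation excess — their mutation excess
comes from repair alone.

`runPipeline(inputDir, outDir, config, seed)` runs the same stages over
exchange files (FASTA, BED, JASPAR PFM, mutations TSV, CPD maps) and
writes the catalog, stack, model, repair, within-motif and region
summary tables plus a JSON run manifest, byte-identically for a given
config and seed.

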