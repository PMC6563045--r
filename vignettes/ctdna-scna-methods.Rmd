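---
title: "Copy number profiling and tracking in circulating tumour DNA: models and methods"
author: "scnatrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy number profiling and tracking in circulating tumour DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnatrack)
```

## The problem

Chromosomally unstable (CIN-type) oesophagogastric adenocarcinomas are driven
largely by somatic copy number aberrations (SCNAs) rather than point
mutations. Low-coverage whole-genome sequencing (lcWGS, ~0.1–0.5x) of plasma
cell-free DNA (cfDNA) gives genome-wide read-depth profiles from which the
tumour-derived fraction of cfDNA (the *ctDNA fraction*, `f`), the tumour
ploidy (`phi`, the mean copy number of the tumour genome) and a per-bin
integer copy number profile can be inferred — without a tissue biopsy, and
repeatably over a course of chemotherapy.

`scnatrack` implements the full analysis chain: binned read-depth
normalisation, joint (`f`, `phi`, copy number) inference by a hidden Markov
model, focal-amplification calling at 50 kb resolution, chromosomal
instability and circulating-DNA metrics with tertile survival analysis,
cohort-level gain/loss frequency and group-unique region analysis, and paired
pretreatment-versus-progression copy number differencing. Because no public
patient-level dataset accompanies the study design this package follows, a
first-class synthetic cohort generator produces ground-truthed inputs at the
same scale (30 patients, ~12 million 100 bp reads per sample, 500 kb and
50 kb bins over the hg19 autosomes); every downstream claim in the test suite
is a recovery claim against that ground truth.

## The depth model

Reads are assigned to non-overlapping bins (500 kb for genome-wide analysis;
50 kb for focal events). For a bin with tumour copy number `c` in a sample
with tumour fraction `f`, the cfDNA copy number mixture is

    m(c) = f * c + (1 - f) * 2,

since non-tumour cells contribute two copies everywhere. After correcting
counts for GC content and mappability and dividing by the median corrected
count, the expected log2 ratio of the bin is

    mu(c) = log2( m(c) / (f * phi + (1 - f) * 2) ),

the denominator being the sample-average mixture at ploidy `phi`. The inverse
transform

    acn(r) = ( (f * phi + (1 - f) * 2) * 2^r - (1 - f) * 2 ) / f

recovers continuous absolute tumour copy number from any observed ratio and
is used by the focal caller and by the paired-change analysis.

### Normalisation

GC bias is fitted by loess of count-per-unit-length against GC fraction and
divided out; the fit is done twice, the second pass restricted to bins whose
first-pass residual lies within one MAD of the median, so that
copy-number-aberrant bins (whole arms, which share coherent GC) do not drag
the curve. Bins with mappability below 0.9 (standard practice for binned
read-depth pipelines), zero length or zero count are masked; true zero counts
at this depth indicate unmappable sequence, so no pseudocounts are used.
Ratios are centred in log space, making the median of valid log2 ratios
exactly zero. No panel of normals is used: each sample is its own reference.
The loess span (default 0.3) was chosen so that a bias-free simulation
recovers a flat curve within a few percent.

## The HMM and its fitting

Copy number states 0–5 form a hidden Markov chain along each chromosome
(chromosomes are independent; higher amplifications are deliberately left to
the 50 kb focal caller). Emissions are Gaussian around `mu(c)` with a shared
standard deviation estimated from the data; the self-transition probability
(default 0.9999 per 500 kb bin, i.e. an expected segment length of several
megabases) is the segmentation prior. Viterbi decoding breaks exact ties
toward CN 2 so that near-flat samples do not acquire spurious aberrations.

Fitting alternates forward–backward E-steps with M-steps in which the
emission sd is closed-form and (`f`, `phi`) are updated by bounded 2-D
numerical maximisation of the expected complete-data log-likelihood. The EM
is restarted from a grid of initialisations
(`f` in {0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6} × `phi` in {2, 3}), each restart
boxed around its initialisation so the grid explores genuinely distinct
solution basins.

### Model selection: why it is the hard part

Depth-only copy number inference has two intrinsic pathologies that the
candidate-selection stage must handle, and both shaped this design:

1. **Over-dense state grids.** At low `f` the state levels become closer than
   the noise sd, and the raw bin-level Gaussian likelihood *rewards* such
   solutions: the dense level grid absorbs the slight skew that the log2
   transform leaves in count noise, and residual depth waves. Defences: a
   resolution filter rejects solutions whose per-copy level spacing is below
   0.35 noise sd (this also sets the method's honest tumour-fraction
   detection floor, roughly 5–8% at the default noise level), and candidates
   are compared on a count-level negative-binomial likelihood of their state
   path rather than on the Gaussian bin likelihood. Per-bin deviances are
   winsorised so a handful of extreme bins cannot dominate, and each
   candidate's (`f`, `phi`) is first *polished* against the same count-level
   objective (run from both the EM solution and the original initialisation,
   keeping the better, since coordinate ascent can self-confirm a shrunken
   `f`).

2. **Mirror solutions.** The emission model is *exactly* invariant under
   relabelling all states by ±1 with a compensating change of (`f`, `phi`)
   — a genome called as near-triploid with losses is indistinguishable from
   a near-diploid genome with gains — except where the state space is
   bounded. Two physical anchors break the tie: copy number cannot be
   negative, so data segments sitting below a candidate's homozygous-deletion
   level are evidence against it (scored on a model-free CBS-style
   segmentation, so candidates cannot gerrymander their own segment
   boundaries; segment weight uses genomic length, not bin count, so short
   chromosome-end bins are not over-weighted); and broad segments above the
   top state level indicate a wrong absolute scale (narrow high-level
   amplifications are exempt, as they legitimately exceed the state cap).
   Finally, a small penalty proportional to the aberration load — the
   length-weighted mean |CN − 2| of the path — breaks remaining exact ties
   in favour of the most parsimonious aberration pattern, generalising a
   penalty on the non-neutral genome fraction (which cannot separate
   mirror solutions that relabel single-copy events as two-copy events at
   half the tumour fraction). The weight (default 4) was calibrated on
   simulated mirror-ambiguity cases and sits on a broad plateau.

The synthetic truth generator reflects the same physics: every simulated CIN
genome carries features that real CIN oesophagogastric genomes recurrently
carry and that are precisely the features anchoring the absolute scale —
focal homozygous deletions at CDKN2A and the FHIT/WWOX fragile sites, one
broad high-level (CN 5) arm gain, and a narrow high-level driver
amplification. This is a deliberate modelling statement: without
boundary-state content, absolute ploidy from depth alone is mathematically
unidentifiable, and recovery tests would be testing a coin flip. Near the
detection floor (`f` around 0.10) the anchor evidence amounts to only a few
log-likelihood units and mirror misassignment of ploidy remains possible;
this is a real limitation of lcWGS ctDNA profiling, not of the
implementation, and the recovery tests operate where they operate knowing
it.

A sample is reported as **zero ctDNA** when every resolvable candidate is
rejected by the spacing filter, or when the best-fit fraction falls below
0.03, or when less than 1% of the genome is non-neutral; its profile is then
flat diploid with `f = 0`, mirroring how depth-only callers report
undetectable tumour content.

## Focal amplifications at 50 kb

High-level amplifications are narrow (often well under a megabase) and are
averaged away in 500 kb bins, so they are called on a 50 kb grid: each bin's
ratio is converted to continuous copy number using the sample's 500 kb
(`f`, `phi`) fit, and maximal runs of at least 2 consecutive bins at CN ≥
`phi` + 3, at most 10 Mb wide, are called; runs separated by a single
sub-threshold bin are merged. The +3-copies-over-ploidy, 2-bin, 10 Mb and
single-gap-merge rules are this package's explicit operationalisation of
"narrow high-level amplification" (visual review of heatmaps is replaced by
the rule); all four are configurable. Calls are annotated with a packaged
catalog of ~20 driver loci (approximate hg19 coordinates, a static fixture —
no annotation download).

## Metrics

* **wGII** — for each autosome, the fraction of its valid-bin length at copy
  number different from `round(phi)`; wGII is the unweighted mean of the 22
  fractions, so small chromosomes count equally. Valid-bin length (not raw
  chromosome length) is used so masked regions do not dilute the index.
* **Non-ploidy segment count** — merged segments with CN ≠ `round(phi)`.
* **Circulating DNA metrics** — total cfDNA concentration (ng/mL plasma),
  ctDNA fraction, and their product, the absolute ctDNA concentration.
* **Tertiles** — rank-based thirds (ties broken by stable input order); when
  the count is not divisible by three, extra samples go to the lower
  tertiles first, fixing survival groupings reproducibly.

Survival uses the Kaplan–Meier estimator and the k-group log-rank test; for
ordered tertiles the score-weighted (trend) statistic with scores 1..k is
reported alongside, computed from the log-rank observed/expected/variance
components. Group comparisons use the Mann–Whitney test, exact by enumeration
for combined samples of at most 12 without ties and normal-approximated with
tie and continuity correction otherwise. Raw p-values are reported without
multiple-testing adjustment, matching how such cohort analyses are usually
presented; this is flagged here deliberately.

## Cohort and longitudinal analyses

Profiles are re-expressed on the union of all samples' segment boundaries
(values unchanged within original segments, so each sample's length-weighted
mean CN is preserved exactly). A segment is a gain/loss for a sample iff its
CN is at least one copy above/below that sample's `round(phi)` — all calls
are ploidy-relative. Group-unique regions are maximal runs where one group
has carriers and the other none, filtered at 1 Mb (suppressing single-bin
artefacts), with runs carried by more than a third of the group flagged as
frequent; the minimal consistent region of an aberration is the contiguous
core where the carrier count reaches its maximum (leftmost on ties).

Paired pretreatment/progression differencing compares continuous absolute
copy number (from each sample's own segment-mean ratios and its own
(`f`, `phi`)); segment means rather than raw bins are used because the ±0.8
change threshold is meaningless at bin-level noise. A pair is eligible only
when both fractions exceed 0.10 and their ratio is at most 2.5 ("similar
tumour content" is not quantified in the field; 2.5 is this package's
explicit, configurable choice). A bin is changed iff |delta| **strictly**
exceeds 0.8 — a threshold designed to enrich for aneuploidies acquired by
the bulk of the tumour rather than small subclones — and percent genome
changed is the changed fraction of the jointly valid genome length. An
alternative ploidy-centred differencing (subtracting each sample's `phi`
first) can be obtained by recentring profiles, but the default subtracts raw
absolute copy number, reporting clonal shifts and ploidy changes alike.

## The synthetic cohort

The generator simulates at bin level (the analysis consumes only bin
counts; read-level simulation and fragment-size structure would not change
them). Counts are negative binomial with mean proportional to bin length ×
mixture copy number × a log-quadratic GC curve × mappability, scaled to
12 million reads per sample; the dispersion default (size = 100, giving a
log2-ratio sd of ~0.15 per 500 kb bin) is at the pessimistic end of real
lcWGS overdispersion. Cohort defaults emulate the study conditions: 30
patients with 7 of 30 at zero ctDNA; lognormal tumour fractions stratified
so liver-metastasis patients centre at 18% versus 7% without (and primary-
in-situ patients higher than resected ones); cfDNA concentrations lognormal
with median 8.9 ng/mL; overall survival exponential with tertile-dependent
medians (19.5 / 11.3 / 12.8 months); 20 patients paired with a progression
sample generated by reweighting a two-clone mixture (trunk preserved,
subclone-private arms shifting), responders' progression fractions dropping
(median ratio 0.45) and nonresponders' staying level; three of twenty
progression samples at zero ctDNA. These values are calibrated only to
published medians and counts, so the synthetic cohort is approximate by
construction: it reproduces the *structure* of the study, not its
patients. What passing tests show is that the pipeline recovers known truth
under realistic noise; they cannot show robustness to artefacts the
generator does not model (replication-timing bias, fragment-end effects,
germline CNVs, panel-of-normal residuals).

## Numerical choices and problem sizes

Chromosome chains with fewer than ~50 valid bins are rejected at
normalisation; EM stops at a log-likelihood gain below 1e-3 or 30
iterations, and errors if the likelihood ever decreases materially (a bug
trap, not a tolerance). The Viterbi tie-break is toward CN 2; the model-free
segmentation uses an interval z-threshold of 4 (stricter than a single test
because it scans all intervals). The demonstration pipeline and most unit
tests run on a 1/10-scale genome with the read budget scaled by the same
factor, which leaves per-bin depth and noise identical to the full setting;
recovery and end-to-end validation checks run at full scale (5,776 bins of 500 kb,
57,723 of 50 kb, 12M reads). The test suite states every cohort size it
uses in its own code; none are hidden defaults.

## Known limitations

* Ploidy and tumour fraction are identifiable only through boundary-state
  evidence; samples whose genomes lack homozygous deletions and high-level
  gains can be reported at a mirrored (`f`, `phi`) with relative calls
  intact. Near `f` ≈ 0.1 this can happen even with anchors present.
* Subclonal copy number states are not modelled; subclonal events appear as
  intermediate levels and are rounded to the nearest clonal state.
* Allele-specific copy number, SNV-based fraction estimates and
  matched-normal designs are out of scope.
* The gene catalog is a ~20-locus fixture with approximate coordinates,
  sufficient for annotation of simulated events, not a clinical annotation
  resource.
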