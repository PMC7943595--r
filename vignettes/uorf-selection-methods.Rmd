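---
title: "Detecting selection on translated uORFs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection on translated uORFs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfsel)
```

## The biological question

Many human 5'UTRs contain translated upstream open reading frames (uORFs).
Ribosomes that initiate at a uORF usually repress initiation at the
downstream protein-coding start, so mutations that change how a uORF
terminates or initiates can change expression of the downstream protein.
`uorfsel` implements the statistical machinery for asking whether such
variants are under negative selection in human populations, and whether
carriers show phenotypic consequences:

1. **Reading-frame-aware consequence annotation** of SNVs inside
   translated ORFs (stop-gain / upstream termination codons, stop
   strengthening along the termination-efficiency hierarchy
   UAA > UAG > UGA, start disruption of NUG start codons, missense /
   synonymous, codon-optimality direction).
2. **MAPS**, the mutability-adjusted proportion of singletons, with
   per-trinucleotide-context calibration, bootstrap confidence intervals
   and paired-bootstrap p-values.
3. **Stop-codon usage** of uORFs against the background of stop-matching
   trinucleotides in 5'UTR sequence.
4. **Conserved-base proportions** (phyloP-style scores > 2) for potential
   stop-creating and start-disrupting positions, with CDS-distance-matched
   controls.
5. A **PheWAS / gene-burden association layer**: dated-diagnosis
   case/control derivation, covariate-adjusted logistic regression,
   inverse-variance-weighted (IVW) meta-analysis across ancestry strata,
   and the Bonferroni / FDR significance lines.

Real analyses of this kind require restricted-access population and
biobank data. The package therefore ships a first-class synthetic-data
module that generates every input format with known ground truth, so each
stage has a parameter-recovery test and the full pipeline runs end to end
offline.

## Consequence model

An ORF is a set of strand-aware genomic blocks plus its spliced RNA
sequence in translation orientation (minus-strand features are
reverse-complemented on construction; internally all blocks are 0-based
half-open, VCF positions 1-based). A variant is mapped to its
spliced-sequence index, the affected codon substituted, and exactly one of
eight categories assigned:

* first-codon rules take precedence: mutating position 1 of the NUG start
  keeps an NUG context (`start_maintain`); positions 2-3 destroy it
  (`start_disrupt`);
* otherwise stop-table membership decides `stop_gain` (a new upstream
  termination codon, UTC), `stop_strengthen` / `stop_weaken` (movement
  along UAA > UAG > UGA), or `stop_loss`;
* remaining sense-to-sense changes are `missense` or `synonymous` under
  the standard genetic code.

`stop_weaken` and `stop_loss` are not analysed as selected classes but are
emitted so the eight categories partition all 9 substitutions per codon —
this partition is property-tested against an independent brute-force
oracle over all 64 x 9 codon changes. A variant inside several
overlapping ORFs is classified against each; for class-level statistics it
is counted once with its most severe call (stop_gain > stop_strengthen >
start_disrupt > stop_loss > stop_weaken > missense > synonymous >
start_maintain; the two unanalysed categories are ranked between
start_disrupt and missense as a package convention). The UAA-creating
class is defined as stop gains whose new stop is UAA; a switch
(`uaa_includes_strengthen`) optionally adds UAA-creating
stop-strengthening variants, since published class definitions are
ambiguous on this point.

`find_potential_stop_positions()` enumerates positions where one
substitution yields an in-frame stop. The first (start) codon is excluded
— its mutations are start-codon consequences, keeping the enumeration
consistent with the classifier — as is the terminal stop codon, whose
mutations are weaken/loss events rather than creations.

## MAPS

Negative selection keeps deleterious variants rare, so a selected class is
enriched for singletons (allele count 1). Raw singleton proportions
confound selection with mutability: high-rate contexts (CpG transitions)
recur in the population and are singleton-depleted regardless of
selection. MAPS calibrates the expectation on a neutral class:

* per collapsed trinucleotide context \(c\) (central reference base
  folded to A/C, 96 classes), the neutral singleton proportion \(p_c\)
  is regressed on the context mutation rate \(\mu_c\) by weighted least
  squares (weights = per-context variant counts, intercept included; a
  logit link is available behind a flag);
* for a variant class, `MAPS = (observed singletons − Σ p̂(c_i)) / n`.

The intercept-bearing weighted fit makes the training class score exactly
0 (tested to 1e-9), fitted proportions are clamped to [0, 1], and the
score always lies in `[−expected/n, 1 − expected/n]`. Confidence intervals
resample the class with replacement (default 10,000 iterations; the
default 5th/95th percentile pair is the 90% interval, configurable because
different displays conventionally use 95%). P-values for "class a exceeds
class b" resample **both** classes each iteration and report
`(1 + #{score_a ≤ score_b}) / (n_iter + 1)` — the +1 correction means 0 is
never reported and the attainable floor is `1/(n_iter+1)`. Published
descriptions of this test are ambiguous about whether only the
experimental group is resampled; resampling both is the variant whose
null distribution is symmetric (p ≈ uniform under exchangeability, which
the test suite verifies by KS test), so it is the default here.
Context-matched controls (`match_by_context()`) reproduce the target
class's context histogram exactly, sampling with replacement only when a
context's pool is thinner than its target count (with a warning).

## Stop-codon usage

Terminal codons of translated uORFs are compared against what their host
UTRs offer: per iteration one stop-matching trinucleotide (UGA/UAG/UAA,
scanned in transcript orientation only, overlapping occurrences counted at
every offset) is drawn uniformly from each UTR, and the codon proportions
among draws recorded; UTRs lacking any occurrence contribute nothing that
iteration (each iteration's denominator is the number of contributing
UTRs). Masking translated-uORF bases before scanning gives the
"non-uORF UTR segments" background. Depletion p-values count iterations
where the uORF bootstrap frequency is ≥ the background draw (enrichment:
≤), again with the +1 floor. In the synthetic world each gene has one
transcript, standing in for a canonical-transcript set.

## Conservation

The conserved-base proportion is the fraction of positions with score
strictly greater than 2 ("phyloP > 2" is implemented as a strict
inequality, so a score of exactly 2.0 is *not* conserved — tested at the
boundary). Positions missing from the track are dropped with a reported
count, never scored 0. Controls are matched by distance to the downstream
CDS start in transcript coordinates, binned in 10-bp windows
([0,10), [10,20), ...), sampling one pool candidate per target position
so bin histograms match exactly. For control positions outside any ORF
there is no reading frame, so "stop-creating" is defined in any of the
three local frame alignments (a config switch restricts it if desired).

## Association layer

Case/control status per phenotype code: ≥ 2 distinct diagnosis dates →
case; no occurrence → control; exactly one date → excluded (dated-billing
EHR convention; `min_case_dates = 1` reproduces the single-encounter
biobank convention, and an optional exclusion-code list removes related
diagnoses from controls). Tests require ≥ 5 alternate alleles, ≤ 50%
missing genotypes and ≥ 20 cases, with machine-readable failure reasons.
The model is `case ~ dosage + age + age² + sex + PC1..PC10` (additive
dosage), Wald inference. Quasi-complete separation — common when a handful
of carriers all share a rare phenotype — is detected (non-convergence or
an exploding standard error) and flagged rather than silently returned;
flagged strata are dropped from IVW meta-analysis with a message. A
penalized-likelihood (Firth) fallback is a natural extension but is not
implemented; flagged results are reported for manual review instead.
IVW pooling uses weights 1/se², so the pooled variance never exceeds the
smallest stratum variance. Gene burdens sum dosages of rare
(MAF ≤ 0.1%) variants that are pLOF or missense with REVEL ≥ 0.5
(boundary inclusive). The Bonferroni line is α/(n_variants × n_phenotypes)
and the plotted FDR line fdr_level/n_phenotypes — the only formula
consistent with the conventional plotted thresholds (0.05/8000 = 6.25e-6,
0.1/800 = 1.25e-4); a Benjamini–Hochberg step-up over observed p-values
via `p.adjust(p, "BH")` is available for per-result reporting.

## Synthetic-data model and its limits

The generator is the package's reference study condition; its defaults
were chosen once to emulate the qualitative features of the real data
sources at desk scale:

* ~150 genes on one chromosome, 5'UTRs of 150–400 nt, a short CDS
  anchoring distance computations, both strands equally represented;
  uORFs in ~60% of UTRs, 5–140 codons, non-AUG-skewed start weights
  (AUG/CUG/GUG/UUG = 0.35/0.30/0.20/0.15; published start-usage
  distributions are plotted but not tabulated, so these are illustrative)
  and stop weights UGA/UAG/UAA = 0.45/0.36/0.19 matching the reported
  ~19% UAA usage of translated uORFs;
* context mutation rates log-uniform on [1e-9, 1e-7] over the 96
  collapsed classes; singleton indicators are drawn directly as
  Bernoulli(intercept + slope·μ + δ_class) with intercept 0.55 and slope
  −2e6 (singleton proportions ~0.35–0.55, descending in mutability, the
  range seen in large WGS cohorts). Simulating the singleton indicator
  directly rather than through a coalescent is the minimal sufficient
  generative model: MAPS consumes only (context, singleton). It does not
  emulate allele-frequency spectra, linkage or demography;
* default selection excesses δ: stop_gain 0.05, stop_strengthen 0.04,
  start_disrupt 0.04, missense 0.005, all other classes 0 — a neutral
  synonymous class and UTC-class excess of the observed order;
* ~2–3% of records fail FILTER, carry LCR flags, or have low AN, so the
  QC filters (PASS, non-LCR, AN ≥ 80% of the set-wide maximum AN) have
  work to do;
* conservation scores: background N(0, 1.5²); designated classes exceed
  the threshold with probability q (defaults 0.35 stop-creating, 0.40
  start-disrupting, 0.15 other uORF bases), drawn from disjoint supports
  strictly above/below 2 so q is exactly the conserved fraction;
* biobank: 5,000 individuals, two ancestry strata (0.7/0.3), carrier
  frequency 1%, target odds ratio 3 at 5% prevalence with age/sex
  effects, 2% genotype missingness, and 10% of non-cases receiving
  exactly one diagnosis date to exercise the exclusion rule.

The generator writes uORF variants so that the intended consequence class
is re-derivable from the serialized FASTA/BED/VCF alone; the test suite
asserts this self-consistency, which exercises the whole
coordinate/strand plumbing. Because generated uORFs never overlap and
UTRs are single-block, passing tests do not exercise deep isoform overlap
or splicing complexity beyond the dedicated multi-block unit fixtures.

## Numerical and design choices

* Bootstraps are chunked resamples of per-variant contributions
  (singleton − p̂), so CIs and p-values scale to 10⁴ iterations in
  vectorized R; all entry points accept a seed and are bit-reproducible.
* `run_pipeline()` derives every stage's RNG stream from the single
  configuration seed and records md5 hashes of all outputs in a JSON
  manifest; a rerun with the same configuration is byte-identical
  (tested).
* Default problem sizes in the test suite and demo pipeline (tens of
  genes, 10³–10⁴ bootstrap iterations, 100–200 simulation replicates,
  biobank of 1,200–20,000) were chosen as the smallest sizes at which the
  statistical assertions have adequate power; the package defaults for
  user-facing functions keep the conventional 10⁴ iterations.
* Recovery tests that measure bootstrap-CI coverage calibrate the MAPS
  model once on a large neutral sample: the class bootstrap quantifies
  class-sampling error only, and with a small training set the extra
  (uncaptured) calibration variance would depress coverage below nominal
  — a property of the MAPS method itself worth remembering when training
  classes are small.
* Long/short stratification thresholds default to 118 codons (missense
  analyses) and 20 codons (start-disruption analyses), both configurable.
* The AN quality filter uses the maximum AN within the analysed variant
  set as its base (the simplest reading of "maximum number of sequenced
  alleles"); a per-chromosome base would be a one-line change.
* Methylation-stratified contexts are accepted as an optional third key
  in the rate table but default off; the synthetic generator does not
  emulate methylation.

## Known limitations

* MAPS is a rank statistic for selection strength, not a selection
  coefficient; no LOEUF-style gene-level constraint is computed (a
  per-gene score column can be used for stratified reporting).
* Wald p-values with separation flagging, not Firth/LRT; ORs from
  few-carrier tables should be read with their flags.
* The conservation module consumes per-base scores; it does not recompute
  phyloP from alignments, and bigWig output is out of scope (bedGraph
  only).
* No LiftOver: all inputs must share one assembly.
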