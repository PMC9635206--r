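---
title: "Methods: biobank screening for familial hypercholesterolemia burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biobank screening for familial hypercholesterolemia burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhburden)
```

# The screening problem

Familial hypercholesterolemia (FH) is an autosomal-dominant disorder of
LDL-cholesterol handling, driven mostly by variants in *LDLR*, *APOB* and
*PCSK9*, with rarer recessive phenocopies caused by biallelic variants in
*LDLRAP1*, *ABCG5*, *ABCG8* and *LIPA*. Population biobanks allow FH to be
assessed without the referral bias of lipid clinics, but they bring their
own constraints: lipid levels are measured once, often on treatment;
clinical signs such as tendon xanthomas are not recorded; and events and
medications are self-reported. `fhburden` implements a screening workflow
built for exactly those constraints, together with a synthetic cohort
generator so the whole pipeline can be exercised and tested without access
to restricted data.

# Medication correction and the modified DLCN score

Observed LDL-C in treated participants underestimates the diagnostic
quantity, pre-treatment LDL-C. `correct_ldl()` multiplies observed values
by a medication-class-specific factor; the default map carries the single
universally applicable entry, 1.43 for an unspecified lipid-lowering
medication, which corresponds to an assumed 30% LDL-C reduction
(`correction_factor_from_reduction(0.30)`). Class-specific factor tables
are supplied as two-column delimited files. Participants without an LDL-C
measurement are excluded, never imputed: a score built on an imputed
diagnostic criterion would misstate certainty, and exclusion keeps the
denominator interpretable.

The modified Dutch Lipid Clinic Network score usable with questionnaire
data has four items:

| Item | Points |
|---|---|
| First-degree relative with coronary/vascular disease | 1 |
| Personal premature coronary artery disease | 2 |
| Personal premature cerebral/peripheral vascular disease | 1 |
| LDL-C 4.0–4.9 / 5.0–6.4 / 6.5–8.4 / ≥ 8.5 mmol/L | 1 / 3 / 5 / 8 |

Totals map to classes: definite (> 8), probable (6–8), possible (3–5),
unlikely (< 3). Two boundary choices deserve explanation:

* **LDL bands.** Printed band edges such as "4.0–4.9" and "5.0–6.4" leave
  gaps (4.95 belongs to no printed band). The bands are implemented as
  contiguous half-open intervals `[4.0, 5.0)`, `[5.0, 6.5)`, `[6.5, 8.5)`,
  `[8.5, Inf)`, so every non-negative value falls in exactly one band and
  printed edges keep their printed points.
* **Score 8.** Conventions differ on whether a score of exactly 8 is
  definite or probable. The default here treats 8 as probable (definite
  strictly above 8); `definite_at_8 = TRUE` switches to the other reading.
  Both are legitimate; the package makes the choice explicit and
  configurable rather than silent.
* **Premature events.** "Premature" is implemented as event age strictly
  below 55 for men and 60 for women (`is_premature()`), the standard
  epidemiological convention; cutoffs are arguments, not constants.

The full DLCN items that need clinical examination (tendon xanthomas,
corneal arcus) or a genetic test result are deliberately out of scope:
biobank questionnaires cannot supply them, and silently scoring them as
absent would be indistinguishable from scoring them as examined-and-absent.

# Carriers and estimated clinical penetrance

`carrier_status()` cross-references a curated pathogenicity table
(ClinVar/HGMD-style classifications are *inputs*, not computed) against
cohort genotypes. Variant keys are normalized to a minimal representation
(shared prefix/suffix trimming) before matching, and multi-allelic VCF
records are split to biallelic keys on read — mismatched normalization is
the most common silent failure in this kind of lookup. Missing genotypes
shrink the allele-number denominator rather than counting as reference.

Estimated clinical penetrance is the fraction of a variant's carriers
classified definite, probable or possible:

$$\hat{\pi} = \frac{\#\{\text{carriers classified possible-or-worse}\}}
                  {\#\{\text{carriers}\}}$$

For recessive genes both numerator and denominator are restricted to
homozygotes, since heterozygous carriers of a recessive allele are not
expected to express the phenotype. A zero denominator yields an explicit
undefined marker distinct from an estimated penetrance of zero — "no
carriers to assess" and "carriers assessed, none affected" are different
scientific statements.

This estimator is a crude upper-level summary: it ignores age, treatment
and ascertainment, and with single-digit carrier counts its sampling error
is large. The parameter-recovery test plants a known penetrance and checks
the estimate falls inside the exact central 99% binomial interval, which
is the honest precision claim at these carrier counts.

# Structural-variant consensus

Calls from two SV callers are filtered to lengths in [50 bp, 10 Mb] and
merged per individual when they agree on sample, chromosome and type and
their *reciprocal overlap* — `min(ovl/len_a, ovl/len_b)` on 1-based
inclusive coordinates — is strictly greater than 0.8. Matching is greedy:
candidate pairs are ranked by larger overlap, then smaller start, and each
call is used at most once. In the regime dual-caller data actually
occupies (each true event producing at most one call per caller, with
breakpoint jitter small relative to event spacing), greedy matching
coincides with the exhaustive optimum, which the test suite verifies by
brute force on small instances; adversarially overlapping call stacks
could in principle make greedy sacrifice one pairing, a limitation
accepted for determinism and speed. The consensus interval averages the
two callers' breakpoints (rounded half up) since neither caller's
breakpoints are privileged. BED input is converted from 0-based half-open
to 1-based inclusive on read; breakend (BND) records are excluded with a
logged count. Gene disruption is any-overlap (≥ 1 base) with the gene
span — a deliberately sensitive definition appropriate for flagging, not
for classifying mechanism.

# The LDL-C SNP score and polygenic inheritance

The polygenic score is the raw weighted sum of LDL-raising effect-allele
dosages, `score = Σ dosage_i × β_i`, not divided by the number of SNPs or
alleles: general-population means below 1 on this scale match the
published score distributions this analysis style reports, and a
`normalize` switch provides the per-SNP average for users who want it.
Strand-ambiguous (A/T, C/G) SNPs are rejected at load with an explicit
error rather than silently flipped. Missing genotypes default to
expected-dosage imputation (2 × cohort effect-allele frequency, flagged);
a strict mode drops them. SNPs absent from the genotype set entirely are
skipped for all participants with a notice — the package ships an 11-SNP
default table precisely because one SNP of the standard 12-SNP panel
(rs1800562 in *HFE*) can be absent from a cohort's variant set.

The polygenic-inheritance call uses the bottom quartile of the
unlikely-FH score distribution, computed by linear interpolation between
order statistics (quantile type 7) — the threshold is cohort-dependent by
construction, so no fixed cut-off is hard-coded. Mutation-negative
definite-or-probable individuals with scores above it are consistent with
a polygenic rather than monogenic cause. Group comparisons
(definite-or-probable / possible / unlikely) use classical one-way ANOVA.

The shipped weight table (`inst/extdata/prs_weights_illustrative.tsv`) is
illustrative: real rsIDs from the standard panel, but invented
non-ambiguous alleles and betas calibrated once so the synthetic
general-population score distribution has mean ≈ 0.76 and SD ≈ 0.2.
Production use requires the actual GWAS weights.

# Statistics layer

* `prevalence()` reports a proportion plus the rounded one-in-N form
  clinicians quote (49/6,140 → 0.8%, "1:125").
* `odds_ratio_woolf()` uses the log-scale (Woolf) interval
  $\exp(\ln \text{OR} \pm z\sqrt{1/a+1/b+1/c+1/d})$; it reproduces
  published carrier odds ratios from reconstructed cells, which is why it
  was chosen over exact or score intervals. Zero cells trigger the
  Haldane–Anscombe +0.5 correction, flagged in the result.
* `chi_square_2x2()` is Pearson's test without continuity correction by
  default (Yates available); a zero margin returns an explicit undefined
  marker.
* `comorbidity_crosstab()` emits per-class counts with a pooled
  definite-or-probable column; percentages are rounded half away from
  zero to integers for report parity with clinical tables, with raw
  proportions always retained.

# What the synthetic cohort does and does not emulate

`simulate_cohort()` generates, per participant: baseline LDL-C from a
log-normal distribution (meanlog 0.84, sdlog 0.38 by default) with mild
age (+0.003/year) and sex (+0.02 for men) shifts on the log scale; an
additive polygenic contribution from the 11 PRS SNPs planted in
Hardy–Weinberg proportions; rare pathogenic variants planted at stated
allele frequencies, whose penetrant carriers (dominant: any carrier;
recessive: homozygotes) receive an LDL-C shift of 2.5–3 mmol/L; treatment
assigned to ~13.4% of participants with probability increasing in true
LDL-C, masking observed LDL-C by exactly the configured 30% reduction;
and questionnaire fields (events, family history, self-reported
hypercholesterolemia) drawn from logistic models on true LDL-C and age,
then flipped with 2% symmetric misreport noise. Two SV call sets are
jittered observations (±20 bp breakpoints, 90% per-caller detection) of a
shared set of true events, always including one whole-gene *PCSK9*
duplication, plus caller-specific false positives and two deliberately
out-of-size-range calls that exercise the size filter.

Default sizes and rates mirror the cohort structure this analysis style
assumes: n = 6,140 adults, 57% female, ages 18–88, ~13% treated, rare
dominant variants at allele counts of order 1–6 per cohort with
penetrance 0 to 1. The LDL-C distribution itself is a calibration choice,
not an estimate — population LDL-C band counts constrain but do not
identify a distribution — chosen once so that the ≥ 4 mmol/L and
≥ 4.9 mmol/L band counts are non-trivial at default parameters (several
hundred of 6,140).

Deliberately **not** emulated: sequencing or genotyping error, ancestry
structure and subclusters (treated throughout as pass-through metadata),
relatedness/consanguinity (so recessive homozygotes are rarer than in
founder populations — planting a recessive homozygote requires either a
raised frequency or a manual dosage edit), assay noise in lipid
measurement, and longitudinal follow-up. Consequently, passing
recovery tests demonstrates the estimators are correct under the model's
assumptions; it does not validate those assumptions against real biobank
data.

Randomness uses one master seed spawning fixed-order per-component
substreams (demographics, genotypes, LDL, penetrance, treatment,
questionnaire, SV, ...), so adding a new component appends a stream
without perturbing existing ones, and identical parameters plus seed give
byte-identical output files.

# Numerical and degenerate-input choices

* All proportions validated to [0, 1]; planted allele frequencies to
  (0, 0.5] (they are rare variants); PRS effect-allele frequencies to
  (0, 1), since common LDL-raising effect alleles can be major alleles.
* `n_participants = 0` produces empty, schema-correct tables rather than
  an error.
* Quantile interpolation is type 7 throughout; report rounding is half
  away from zero (`round_half_up()`), matching clinical table
  conventions rather than banker's rounding.
* Equal-variance ANOVA returns F = 0, p = 1 when all groups are
  identical (the 0/0 limit is resolved to "no evidence of difference").
* SV merge ties (equal overlap) break by smaller start; representative
  breakpoints round half up.

# Problem sizes used by the test suite

The suite runs entirely on generated data: cohorts of 120–6,140 for
structure checks, n = 20,000 for the Hardy–Weinberg test (chi-square at
α = 0.001), n = 5,000 with ~200 planted carriers for penetrance recovery,
2,000 null simulations for Woolf-interval coverage (94–96% band), 200
replicates at group sizes 49/334/5,757 for ANOVA power, and exhaustive
small grids for the chi-square and matching oracles. These sizes were
chosen to make each statistical check sharp at conventional error rates
while keeping the default test run in well under a minute.

# Known limitations

* Penetrance estimates carry no confidence intervals in the output
  tables; at the carrier counts involved, users should treat them as
  descriptive.
* The DLCN implementation is the modified four-item score; results are
  not comparable to full-DLCN studies that include clinical signs.
* Greedy SV matching is optimal only in the well-separated regime (see
  above).
* The generator's comorbidity model is a convenience for producing
  realistic-looking cross-tabs; its logistic coefficients are not
  estimates of any real association.
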