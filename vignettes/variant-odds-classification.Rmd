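---
title: "Classifying rare missense variants by prior and posterior odds"
author: "varodds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying rare missense variants by prior and posterior odds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varodds)
```

## The problem

Rare missense variants found by panel sequencing in candidate genes — here
motivated by *LRP5*, the Wnt co-receptor whose loss of function lowers bone
mineral density — mostly land in the "variant of uncertain significance"
bucket. When functional assays are unavailable, the practical question is how
to aggregate weak, heterogeneous computational and annotation evidence into a
defensible pathogenicity ranking. `varodds` implements one such aggregation:
a transparent odds-ratio model over eight binary evidence descriptors, plus
the supporting steps (consequence annotation, rare-missense filtering,
repeat-domain conservation, cohort statistics) and seeded generators for all
of its inputs.

## The model

Each variant carries eight binary descriptors, in fixed order:

| d | descriptor |
|---|------------|
| d1 | sequence conservation at the position |
| d2 | position inside an annotated functional domain |
| d3 | low local sequence complexity |
| d4 | position inside a structured (folded) domain |
| d5 | on or near a functional linear motif |
| d6 | agreement among in-silico predictors |
| d7 | prior annotation in public databases |
| d8 | pathogenic description in the literature |

Three channels feed the score so that no line of evidence is counted twice:

* **Prediction score** `= 1 + (number of damaging calls among the three
  categorical predictors)`, range 1–4. A PolyPhen-2-style call counts as
  damaging when possibly/probably damaging, a SIFT-style call when not
  tolerated, a Pmut-style call when disease. The stability change (ΔΔG) is
  reported but never counted: in the motivating data every variant was
  predicted destabilizing, so it carries no discrimination.
* **Odd score** `= max(1, d1 + d2 + d4 + d5 + d7)`, range 1–5 — the
  structural/annotation descriptors only. d6 already lives in the prediction
  score and d8 in the prior; d3 is reported but does not score (it is a
  context annotation, not a pathogenicity direction by itself).
* **Prior odds ratio**: 19 (95:5) when the literature describes the variant
  as pathogenic, 1.25 (5:4) when it sits in dbSNP at low frequency with no
  functional data, 1 (50:50) otherwise, with precedence
  literature > dbSNP > default.

The merged score is the sum of the two sub-scores (2–9), and

$$\mathrm{posterior\ OR} = \mathrm{merged} \times \mathrm{prior},\qquad
\mathrm{posterior\ OR\%} = \frac{\mathrm{posterior\ OR}}{9}\times 100.$$

The constant 9 is the maximum merged score, so a prior of 1 maps the merged
score linearly onto 22.2–100 %. Five classes are assigned on the percentage:
Pathogenic (≥ 90), Likely Pathogenic (≥ 50), Uncertain (≥ 25), Likely
Neutral (≥ 12.5), Neutral (below). With a prior above 1 the percentage can
exceed 100; it is reported as is, and the class saturates at Pathogenic. The
percentage is rounded half-up to two decimals for reporting; the posterior
OR itself is never rounded. The per-variant `descriptor_agreement`
(positive descriptors / 8) is reported alongside: Pathogenic/Likely
Pathogenic calls in the bundled case study all reach at least 5/8 (62.5 %),
and Neutral-like calls stay below 2/8.

Percentage thresholds and the normalization constant are reconstructions:
the motivating study prints the scored table but not the banding rule, and
these are the unique simple choices that reproduce every published row. The
same holds for the per-variant descriptor binarization shipped in
`inst/extdata/lrp5/evidence_context_reconstructed.tsv` — the file is a
documented reconstruction, not primary data, and is flagged as such in its
header.

```{r}
p <- lrp5_predictor_calls()
e <- lrp5_evidence_context()
res <- classify_batch(p$variant, p, e)
res[, c("variant", "prediction_score", "odd_score", "merged_score",
        "prior_or", "posterior_or", "posterior_or_pct", "meaning")]
```

Two published rows are internally inconsistent (one prediction score that is
not 1 + damage count, one merged score that is not the sum of its
components). `classify()` accepts an external `merged` value and flags the
disagreement via `score_consistent`; `flag_prediction_discrepancies()` does
the same for prediction scores. Nothing is silently matched.

```{r}
flag_prediction_discrepancies(p, lrp5_published_scores())
```

## Consequence annotation

`annotate_consequence()` maps each SNV through a transcript model (1-based
inclusive coordinates throughout, VCF/GFF3 convention; minus-strand alleles
complemented before codon lookup) and emits HGVS one-letter protein labels
(`p.R1135C`, `p.L10=`, `p.R12*`). Positions outside the CDS are labelled
`splice_region` (within 2 nt of a CDS segment boundary, intronic side),
`noncoding` (deeper intronic) or `utr` (inside the transcript span but
outside the CDS extremes) — the span is carried on the transcript because
the CDS alone cannot distinguish UTR from intergenic. Only SNVs are
supported; indels error out loudly rather than being half-handled. The
standard nuclear genetic code is used, with no alternative-code option.

`filter_rare_missense()` keeps heterozygous missense variants in panel genes
with MAF < 1 % — and treats a *missing* MAF as rare, since novel variants
have no frequency record; excluding them would discard exactly the variants
the screen exists to find.

## Repeat-domain self-alignment

Repeat proteins (such as the four β-propellers of LRP5) evolve by internal
duplication, so cross-species conservation understates which positions
matter for the fold. The self-analysis aligns a protein's own repeat units
against each other: units (annotation-supplied boundaries; de-novo repeat
detection is out of scope) are added in input order to a growing profile
under Gotoh global alignment — BLOSUM62 substitution values, affine gaps
where a run of length *k* costs 10 + *k*, deterministic traceback preferring
diagonal, then up, then left. Input-order progressive alignment was chosen
over a guide tree because unit sets are small (≤ 8) and near-equal length;
determinism is worth more than marginal alignment quality here. The
per-column conservation score is the modal non-gap residue frequency
multiplied by the non-gap fraction, so insertion columns present in few
units score low — matching the intuition that lineage-specific insertions
are not part of the conserved repeat scaffold. Modal ties break
alphabetically. The exact scoring behind the motivating study's heat-map is
not disclosed; this profile is the package's own documented scheme,
validated on synthetic fixtures with planted substitution rates.

```{r}
rp <- gen_repeat_protein(sim_config(seed = 2, unit_length = 40,
                                    n_units = 4, unit_mut_rate = 0.2))
prof <- conservation_profile(self_align(rp$units))
mean(prof$scores)
```

## Cohort statistics

`group_compare()` is a two-sided two-sample t-test, pooled-variance Student
form by default because that is the named test in the motivating analysis;
Welch is one flag away. Degenerate inputs (both groups constant) return
`p = 1` on equal means and `p = 0` otherwise instead of erroring mid-pipeline.
`summarize_cohort()` reports mean ± SD per DXA measurement and the carrier
fraction as a percent rounded to one decimal (11/128 → 8.6 %).

## What the generators emulate — and what they do not

`sim_config()` defaults encode the motivating cohort: 128 men, 11 carriers,
age 41.6 ± 8.7 years truncated to 18–60, and the published lumbar/total-hip
BMD and T/Z score means and SDs. Carrier and pathogenic counts are assigned
deterministically (`round(fraction × n)`), not by Bernoulli draws, so
fixture-level counts are exact. Variant truth is planted through
class-conditional probabilities: each damaging call and evidence flag fires
with probability 0.8 for a pathogenic-profile variant and 0.1 for a
benign-profile one — values chosen to make truth recovery non-trivial but
stable at n = 500 (the scale used in the recovery test, where the classifier
separates planted classes with balanced accuracy ≥ 0.85, treating Uncertain
as abstention). One master seed is split into fixed per-generator offsets,
so adding a generator never perturbs existing outputs, and truth labels
live in a separate sidecar that the pipeline inputs never contain.

The generators do **not** emulate: linkage or population structure, realistic
BMD effect sizes of genotypes, correlated predictor errors (real in-silico
predictors fail together on the same structural contexts), or read-level
sequencing noise. Passing recovery tests therefore demonstrate internal
consistency of the scoring machinery, not clinical performance on real
variants.

## Numerical and edge-case choices

* Rounding of reported percentages is half-up at two decimals (base R's
  round-half-even would not reproduce published values).
* An all-gap alignment column scores 0 with consensus `-`.
* A constant column beats ties alphabetically, making consensus strings
  reproducible.
* The both-flags-set evidence state (literature and dbSNP) is rejected at
  validation; `assign_prior()` still defines literature precedence for
  robustness.
* Problem sizes in the shipped tests: every-SNV annotation oracles run on a
  ~100-nt toy transcript (≈ 290 substitutions), aligner oracles on all pairs
  of ≤ 5-mers from a 25-peptide sample, recovery at n = 500 variants, and
  type-I error at 1000 null replicates — sizes chosen to exercise each
  property thoroughly while keeping the default suite under a minute.

## Known limitations

The classifier is an evidence aggregator, not a clinical instrument: class 5
is "maximal computational support", not demonstrated pathogenicity. The
descriptor binarization for the bundled case study is a reconstruction. The
published cohort-wide variant counts and carrier/non-carrier p-values are
not reproducible without the raw per-subject data and are deliberately not
targets of this package's tests.
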