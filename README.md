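# varodds

Bayesian prior/posterior odds classification of rare missense variants.

Panel sequencing of candidate genes routinely surfaces rare heterozygous
missense variants with no functional data — formally "variants of uncertain
significance". `varodds` implements a transparent odds-ratio model for
ranking them, motivated by rare *LRP5* variants found in men with idiopathic
low bone mass, together with every supporting step: SNV consequence
annotation against a transcript model (HGVS p. notation), the rare
heterozygous missense filter (MAF < 1 %, missing MAF counts as rare),
self-alignment conservation profiling of repeat proteins (β-propeller-style
domains), carrier/non-carrier cohort statistics, and seeded synthetic-data
generators for all pipeline inputs.

## The model

Each variant is described by eight binary evidence descriptors d1–d8
(conservation, functional domain, low complexity, structured domain, linear
motif, predictor agreement, database annotation, literature). Three
independent channels combine:

* prediction score = 1 + #(damaging calls among three categorical
  predictors), range 1–4;
* odd score = max(1, d1 + d2 + d4 + d5 + d7), range 1–5;
* prior odds ratio: 19 (literature-described pathogenic), 1.25 (low-frequency
  dbSNP, no functional data), 1 (otherwise).

Then

```
posterior OR  = (prediction + odd) × prior
posterior OR% = posterior OR / 9 × 100
```

with five classes on the percentage: Pathogenic ≥ 90, Likely Pathogenic
≥ 50, Uncertain ≥ 25, Likely Neutral ≥ 12.5, Neutral below. See the
methods vignette (`vignettes/variant-odds-classification.Rmd`) for the
rationale behind each constant and the reconstruction caveats.

## Worked example

The package ships the ten-variant LRP5 case study (predictor calls plus a
reconstructed evidence-context table):

```r
library(varodds)
p <- lrp5_predictor_calls()
e <- lrp5_evidence_context()
res <- classify_batch(p$variant, p, e)
res[, c("variant", "prediction_score", "odd_score", "merged_score",
        "prior_or", "posterior_or", "posterior_or_pct", "meaning")]
```

```
  variant prediction_score odd_score merged_score prior_or posterior_or posterior_or_pct meaning
   p.V99L                1         1            2     1.00         2.00            22.22      LN
  p.G333S                1         1            2     1.00         2.00            22.22      LN
  p.E341K                2         3            5     1.00         5.00            55.56      LP
  p.T443M                2         3            5     1.00         5.00            55.56      LP
 p.R1036Q                2         5            7     1.25         8.75            97.22       P
 p.R1135C                3         5            8     1.25        10.00           111.11       P
 p.R1342P                3         3            6     1.00         6.00            66.67      LP
 p.A1525V                1         3            4     1.25         5.00            55.56      LP
 p.A1537V                2         3            5     1.00         5.00            55.56      LP
 p.S1585L                4         1            5     1.00         5.00            55.56      LP
```

Two variants — p.R1036Q and p.R1135C, both in the fourth β-propeller —
reach the Pathogenic class (posterior OR% ≥ 90); most of the rest are
Likely Pathogenic, and the two variants with no positive evidence are
Likely Neutral. `flag_prediction_discrepancies()` reports where a published
score disagrees with its own components instead of silently matching it.

A toy end-to-end run from standard formats:

```r
cfg <- sim_config(seed = 7)
toy <- gen_toy_transcript(cfg)           # GFF3/FASTA/VCF-writable
ann <- annotate_consequence(toy$variants, toy$transcript)
filter_rare_missense(ann, genes = "TOYG")   # 7 of 20 planted variants pass
```

A thin CLI over the same functions lives at `inst/cli/varodds.R`
(`annotate`, `descriptors`, `classify`, `repeats`, `cohort`, `simulate`
subcommands).

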