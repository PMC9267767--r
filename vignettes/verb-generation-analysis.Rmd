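---
title: "Analyzing auditory verb generation tasks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing auditory verb generation tasks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(verbgen)
library(dplyr)
```

verbgen analyzes the behavioral output of an auditory noun-to-verb generation
task: each participant hears a set of nouns (typically 50, each presented
twice) and produces an associated verb per trial. This vignette is the
methods account of the package — what each component computes, the modeling
assumptions behind it, the parameters that matter and their defaults, and
what the synthetic-data generator does and does not emulate.

## Response coding

Every trial is assigned one of four codes: `related_verb` (the only code
counted correct), `not_a_verb`, `unrelated_verb`, or `missing`. In a clinical
study this judgment is made by human raters; verbgen accepts such
pre-assigned codes and never overwrites them. For synthetic and exploratory
work it provides a transparent rule-based auto-coder
(`code_responses()` with `coding_rules()`):

1. an empty response is `missing`;
2. a per-item rejected phrase (e.g., "to be careful" for *knife*) is
   `unrelated_verb`, and a per-item accepted exception (e.g., "to do" for
   *laundry*) is `related_verb` — these lists carry rater adjudications the
   rules cannot express;
3. otherwise the response's head-verb lemma decides: acceptable for the noun
   (in the reference lexicon) → `related_verb`; a known verb but not
   acceptable for this noun → `unrelated_verb`; not a verb at all →
   `not_a_verb`.

The default reference lexicon is the set of verb lemmas produced by at least
one control for each noun (`reference_lexicon()`), the most defensible
acceptability standard available without new rater time. The "global verb
vocabulary" used for the not-a-verb decision is the lexicon union the
light-verb list union any caller-supplied verbs; it is deliberately
conservative, since a free-text token outside every verb list is far more
likely a noun than an exotic verb. Phrasal responses ("take out") match on
their head verb, after stripping a leading infinitive marker; lemmatization
is a bundled inflection lookup (exhaustive for the light-verb list and common
task verbs) with no suffix heuristics or POS tagging — surface forms outside
the table are treated as their own lemma. Articulatory errors and
phonological paraphasias are upstream concerns: they should arrive either as
pre-assigned codes or as per-item exceptions, because no text rule can
adjudicate them.

## Subject profiles and outlier exclusion

`subject_profiles()` reports the four category percentages over each
subject's trials; by construction they sum to exactly 100. Because each noun
appears twice, two consistency measures are defined: error consistency (the
percentage of a subject's stimulus pairs with both presentations incorrect,
denominator all pairs) and error-type consistency (the percentage of those
consistently-erred pairs where both errors share one type, denominator the
consistently-erred pairs only). A subject with no consistently-erred pairs
has an undefined type consistency, reported `NA` and dropped from group
means — averaging in a placeholder would bias cohorts with mild impairment.
Mean reaction time defaults to correct trials only (an `"all"` option
exists): error and missing trials confound retrieval time with task failure.

`exclude_outliers()` removes subjects whose accuracy lies strictly more than
2 SD from their reference cohort's mean, computed once on the full cohort
(single-pass; the procedure is never iterated, matching standard one-shot
screening practice). "Outside of 2 SD" is read strictly: a subject exactly at
the boundary stays. The default reference cohorts are all patients pooled
versus controls — patient subgroups are usually too small to estimate their
own spread reliably — with a `per_group` mode available.

## Agreement indices

Control responses define, per noun, a response distribution over verb lemmas
(`response_distributions()`). Three indices summarize it:

- **Response entropy** (bits): `E = Σᵢ pᵢ log₂(1/pᵢ)` with `pᵢ` the
  proportion of responses for verb *i*. 0 = perfect agreement; 1 = two verbs
  at equal frequency; `log₂ k` for k equally popular verbs.
- **ASI** (%): the modal response's share — retrieval demand (how strongly
  the noun points at one verb).
- **CSI** (ratio ≥ 1): modal share over second share — competition demand
  (how contested the top choice is). When a noun elicits a single verb the
  second share is imputed as one hypothetical dissenter, `100/n`, keeping the
  index finite; CSI then equals `n` and is deliberately sample-size
  dependent, so single-verb nouns carry "as much competition headroom as the
  sample could show".

Two analysis choices are exposed as flags because the field's practice
varies and neither is self-evident: both presentations are pooled by default
(a subject answering twice counts twice; `responses = "first"` keeps one
response per subject) and unrelated-verb responses are included by default
(the distribution describes what controls *generate*, not what raters
endorse; `include_unrelated = FALSE` restricts to related verbs). Ties for
the modal verb are broken lexicographically for reporting only; all indices
are order-independent.

## Lexico-semantic features

`unique_verb_counts()` measures response dispersion as the number of
distinct related-verb lemmas, per noun within cohort by default (a
per-subject reduction is available). `light_verb_pct()` scores each
subject's related responses against a fixed list of fourteen light verbs
(*be, bring, come, do, get, give, go, have, make, move, put, see, take,
use*), matching on the head lemma so "take out" counts as *take*; subjects
with no related responses get `NA`.

Not-a-verb errors are decomposed (`not_verb_decomposition()`) into stimulus
repetitions (response lemma equals the noun) and semantically related nouns:
non-repetition responses whose embedding cosine similarity to the stimulus is
strictly greater than a threshold, default 0.3, the conventional cut-off;
`calibrate_threshold()` returns the median of the pooled similarity values
across cohorts as a data-driven alternative. Repetitions are excluded from
the related count (their similarity is trivially maximal and they index a
different failure mode). Trials whose noun or response is missing from the
embedding table are counted in `n_uncovered` and flagged with a warning,
never silently dropped — pretrained vocabularies vary and silent coverage
loss would bias the counts. The four parts always partition a subject's
not-a-verb total.

## Cohort statistics

ANOVAs go through `stats::aov`: `oneway_anova()` for accuracy (and for
reaction times across the three variants, since each subject contributes one
mean RT), and `group_by_errortype_anova()` for the 3 group × 3 error-type
design. The latter is fitted as a mixed design — group between subjects,
error type within (each subject contributes all three percentages) — which is
the error structure the data actually have; a fully-between long-format
variant sits behind `design = "between"` for comparison. A single-group
input degenerates to a within-subject one-way design. Tukey HSD
(`tukey_hsd()`, via `stats::TukeyHSD`) provides the pairwise comparisons
using the pooled within-group mean square. When all values are identical the
F statistic is undefined and reported as `NA` rather than 0 or error.

Correlations are Pearson, pairwise-complete (per-measure availability
differs routinely in clinical batteries), with explicit Bonferroni families:
6 by-item predictors (log frequency, phoneme count, semantic neighborhood
density, ASI, CSI, entropy, against per-noun accuracy pooled across one
variant's subjects and both presentations) and 3 by-subject measures
(single-word comprehension, the phonemic/semantic fluency ratio with
zero-denominator subjects excluded, and trails total time). `survives` is
`min(1, m·p) < α` with α = 0.05 by default.

## Classification against an empirical chance level

The diagnostic question — do error patterns alone identify the variant? — is
answered with a depth-2 decision tree (`fit_tree()`) on three features: the
not-a-verb, unrelated-verb and missing percentages. Accuracy is their linear
complement and is excluded as redundant. The tree is standard greedy CART
with Gini impurity: candidate thresholds are midpoints of consecutive sorted
unique feature values; growth stops at depth 2, purity, or fewer than 2 rows.
Zero-gain splits are allowed whenever any candidate exists — Gini is concave
so a split never increases weighted impurity, and refusing equal-impurity
splits would make XOR-like layouts unlearnable at depth 2. Determinism is
guaranteed by explicit tie-breaks: lowest threshold among equal-impurity
splits, then lowest feature index; leaf prediction ties go to the
lexicographically first class.

`cross_validated_score()` uses stratified 5-fold cross-validation (k is
reduced with a warning if the smallest class is smaller), and
`permutation_test()` re-runs the entire CV loop on `n_perm = 1000` random
relabelings, with freshly stratified folds per permutation, to estimate the
chance distribution empirically. The empirical p-value
`(1 + #{null ≥ observed}) / (1 + n_perm)` is never zero; the theoretical
chance level `1/#classes` (33.33% for three variants) is reported alongside.
Folds, permutations and scores are pure functions of the seed. The depth
bound, Gini criterion, fold count and permutation count are defaults of the
reference implementation era for this kind of analysis, not empirical
claims; all are arguments.

## The synthetic-data generator

The generator exists so the full pipeline can be exercised and tested
without patient data. It emulates the statistical structure such studies
report, not the linguistic surface:

- **Stimuli** (`generate_stimuli()`): 50 nouns, norms drawn uniformly within
  ranges typical of published stimulus sets (log frequency 3.4–8.3, phonemes
  2–6, semantic neighborhood 28.7–362.9, Glasgow-style ratings). Each noun
  gets a latent verb-popularity vector: a truncated geometric over a 10-verb
  inventory whose decay is solved (by root finding) so the implied response
  entropy is uniform over the target span, default 0.1–2.7 bits — the range
  control cohorts typically realize.
- **Controls** (`generate_hc_responses()`): 29 subjects sample verbs from
  the popularity vectors, with a 2% missing rate.
- **Patients** (`generate_patient_cohort()`): per-subject error mixes are
  drawn from a truncated normal at the cohort's published means and SDs
  (lvPPA 45.1/37.9/3.9/13.1, svPPA 63.9/17.3/7.6/11.3, nfvPPA
  79.2/7.8/2.1/11.0 for correct/not-verb/unrelated/missing; cohort sizes 19,
  28, 24) and renormalized to 100. The published svPPA and nfvPPA means sum
  to 100.1 (rounding in the source tables), so the defaults shave 0.1 off
  the missing component to satisfy the exact-closure invariant. The truncation location is
  moment-matched — solved so the post-truncation mean equals the planted
  mean — because naive truncation at zero inflates small error components
  and would bias cohort accuracy several points low. Trial outcomes are
  multinomial in the subject's mix; item-level correctness is modulated
  through a logistic link by `frequency_effect · (freq_log − mean)`, with
  the svPPA default 0.12 chosen once so the by-item frequency correlation
  lands in the moderate range reported for that variant (given ~50 items and
  ~28 subjects, item-level binomial noise has SD ≈ 6 percentage points, and
  a slope of 0.12 logits per log-frequency unit produces a comparable
  signal SD). Structural knobs mirror the reported contrasts: svPPA gets the
  widest verb-choice dispersion (popularity flattened by a temperature of 2)
  and the highest light-verb substitution rate (8.7% vs ≈2%), lvPPA the
  highest semantically-related-noun rate among not-a-verb errors (0.5 vs
  0.25), repetition rates equal across variants (no group difference is
  expected), and reaction times lognormal at the published variant means.
- **Embeddings** (`generate_embeddings()`): random unit vectors in 50
  dimensions (unplanted cosines concentrate near 0, SD ≈ 1/√50 ≈ 0.14, so
  essentially never cross the 0.3 threshold); each `(noun, noun_rel)` pair
  is planted at cosine 0.6 by explicit construction
  `b = s·a + √(1−s²)·u⊥`.
- **Covariates** (`generate_subjects()`): the four neuropsychological scores
  drawn from group-typical normals (e.g., trails time 86.2 ± 37.0 s in
  lvPPA vs 23.1 ± 11.3 in controls), semantic fluency truncated at 1 so the
  fluency ratio stays defined, with an optional coupling slope that plants a
  trails–accuracy association (the full-study default −0.5 s per accuracy
  point yields the usual worse-performance–slower-trails pattern).

Every generator is a pure function of (configuration, seed); identical
inputs give bit-identical outputs, and `simulate_study()` derives fixed
sub-seeds for each component.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: real lexical content (tokens are synthetic
strings, so no genuine lemmatization load), rater disagreement and
phonological/articulatory error surface forms, correlations between a
subject's error mix and the per-item difficulty structure beyond the single
frequency link, floor/ceiling effects in neuropsychological scores, and any
dependence between presentations of the same noun within a subject
(consistency levels in synthetic data arise purely from each subject's
marginal error rate, and sit below the ~30–35% published for real
patients, where item-specific difficulty makes errors repeat).

## Numerical choices and degenerate inputs

- Percentages are computed as `100 · count / n`; closure to 100 is exact up
  to float rounding.
- Entropy uses base-2 logarithms; a single-verb distribution is exactly 0.
- The CSI single-verb imputation is the only agreement quantity that is not
  scale-invariant (deliberately; see above).
- A zero embedding vector is a domain error for cosine similarity, not a 0.
- Tree split search tolerates impurity ties at 1e−12 and resolves them
  deterministically.
- Outlier exclusion with a zero-variance reference cohort excludes any
  deviating subject (the band has zero width).
- Problem sizes used in the test suite — e.g., 20 replicate studies at 20
  subjects per variant with 1000-permutation nulls for the recovery check,
  and 200 seeded null runs at 100 permutations for the p-value calibration
  check — were chosen as the smallest sizes at which the quantities under
  test are stable, keeping the default suite fast.

## Known limitations

The auto-coder is a proxy for human rating: it cannot judge interpretability
of paraphasias, and its unrelated/not-a-verb boundary depends on the supplied
verb vocabulary. The mixed ANOVA assumes sphericity (no correction is
applied across the three error types). The permutation p-value is slightly
conservative when cross-validated scores tie, which is common at small n
with discrete accuracies. CSI for single-verb nouns grows with the sample
size by construction. None of these affect the package's intended use —
transparent, reproducible re-analysis and simulation of verb-generation
error patterns — but all matter when interpreting absolute values.
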