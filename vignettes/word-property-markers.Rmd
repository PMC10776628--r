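---
title: "Word-property markers from property-listing tasks: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Word-property markers from property-listing tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pltmarkers)
```

## The task and the analysis problem

In a property-listing task a participant is cued with a concrete concept
("sun") and freely lists its features ("hot", "yellow", "rises in the
morning"). The short phrases that come back are a window into how a person
navigates semantic memory: which words they reach for, how concrete and
imageable those words are, and how far they travel between consecutive
choices. `pltmarkers` turns coded transcripts of such responses into ten
participant-level word-property features and pushes them through the three
analyses used to characterize clinical groups — here Parkinson's disease
(PD) patients, behavioral-variant frontotemporal dementia (bvFTD) patients
as disease controls, and healthy controls (HC): group-level inference,
subject-level classification, and correlations with clinical scores.

The pipeline consumes five inputs: coded transcripts (with human-assigned
validity tags; the package never infers validity), a psycholinguistic norms
table, a word-vector lexicon in word2vec text format, a noun taxonomy rooted
at `entity` with an explicit word-to-node mapping, and a clinical-scores
table.

## The ten features

Per concept, then averaged over a participant's concepts:

* **Concreteness, imageability, familiarity** (1–7 norm scales), **log
  frequency** (log10 per million) and **phoneme length**: arithmetic means of
  the norms of all in-vocabulary content lemmas (nouns, verbs, adjectives,
  adverbs) pooled across the concept's properties.
* **Semantic variability**: the embedding vectors of consecutively produced
  content words form a trajectory; the distances between consecutive vectors
  form a time series, and the feature is that series' sample variance. A
  speaker who stays inside one semantic field produces a flat series (low
  variability); hopping between fields produces an alternating series (high
  variability).
* **Granularity**: mean taxonomy depth (edge-count distance to the root
  `entity`) of the concept's nouns; deeper nodes are more specific concepts.
  Depth is exposed per noun, and the scalar entering the feature matrix is
  the mean — the taxonomy induces a depth distribution, but downstream
  statistics need one value per feature.
* **Property distance flow**: each property is summarized as the mean of its
  word vectors; the feature is the variance of the distances between the
  property vectors and the cue concept's vector.
* **Relevance and distinctiveness**: from the pooled concept-by-property
  production-frequency table, property *j*'s relevance for concept *i* is
  \(k_{ij} = x_{ij}\,\log(I/I_j)\) with \(x_{ij}\) the production frequency,
  \(I\) the number of concepts and \(I_j\) the number of concepts for which
  the property was listed; \(\log(I/I_j)\) is the property's
  distinctiveness. A participant's per-concept values are means over the
  properties they actually listed.

### Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| distance metric | cosine (`1 - cos`) | standard for word embeddings; Euclidean available |
| variance convention | sample (n−1) | fewer than 2 distances gives `NA`, never a fabricated 0 |
| variability adjacency | `concat` | token order concatenates a concept's properties in production order; `reset` restricts pairs to within-property and pools the distances |
| log base (relevance) | natural | the base is a global rescale only |
| polysemy policy | min depth | the least specific defensible sense; `mean` available |
| production-frequency unit | pooled over the analysis set, repetitions counted | property identity is the sorted lemma multiset |
| OOV policy | skip with warning | imputation would fabricate data; a cell is missing only when a feature is undefined for every concept |

Lookups are lemma-based, case-folded and accent-preserving (Spanish norms
distinguish `papa`/`papá`).

## Group statistics

Per feature, on the pooled sample: values outside `[Q1 - 3*IQR, Q3 + 3*IQR]`
(type-7 quartiles computed once on the full input) are removed; a one-way
ANCOVA tests the group factor with years of education as covariate, using
the standard linear-model decomposition (group sum of squares = residual
drop from adding group to the covariate-only model; partial eta squared =
SS_group / (SS_group + SS_error)); Tukey–Kramer post hocs (studentized range
with unequal-n standard errors) and Cohen's d with the pooled two-group SD
(no small-sample correction) follow. Raw p-values are reported across the
ten features; multiple-testing correction is left to configuration, since
the analysis this mirrors applied none.

Clinical correlations pool each patient group with controls (PD–HC and
bvFTD–HC tandems) to widen the score range, then use Pearson's r if both
variables pass Shapiro–Wilk at 0.05 and Spearman's rho otherwise; a
configured covariate is partialled out by residualizing both variables
(rank-transforming everything first in the Spearman branch).

### A numerical edge case worth knowing

With a covariate whose coefficient is exactly zero in-sample, the ANCOVA's
group and error sums of squares coincide with the plain ANOVA's, but the F
statistics still differ by the structural error-df factor
\((N-g)/(N-g-1)\) (≈ 2% at N = 60) because the covariate consumes one
degree of freedom whether or not it explains anything. The test suite
asserts the sharp version of this identity (equal sums of squares; F equal
after the df factor) rather than pretending the factor away.

## Classification

Subject-level discrimination restricts the feature matrix to one pairing
(PD–HC, bvFTD–HC, PD–bvFTD) and repeats, for each of `n_iterations` random
stratified 5-fold partitions: median imputation and min-max normalization
fitted on the training folds only; a small gradient-boosting grid
(`max_depth` {1, 2} × `colsample_bytree` {0.5, 1}, `eta` 0.1, `subsample`
0.8, 60 rounds — shallow, feature-subsampled trees, because with a few
dozen subjects and mostly-uninformative columns deeper trees latch onto
noise) tuned per outer fold by
an inner stratified 3-fold search; out-of-fold decision scores pooled into
one AUC per iteration (rank-based, tie-aware). The report carries the full
AUC vector, its mean ± SD, per-subject mean scores, and every chosen
configuration. Fitting the normalizer inside the folds avoids leakage;
`paper_mode = TRUE` fits it once on the full sample for faithfulness
comparisons. Whether tuning should be global or per fold is unspecified in
the original description; per-fold is the default here because it keeps the
test fold untouched by any training decision.

One behavior of boosted trees is worth flagging: with a perfectly
separating continuous feature, the split threshold lands adjacent to the
extreme training value of one class, so a test point just outside the
training range of its class is misclassified — at these sample sizes that
costs a few AUC points no matter how wide the margin is. This is a property
of tree learners, not of the pipeline.

## The synthetic cohort generator

The generator exists so that every downstream stage can be exercised, and
its detection properties measured, without any external data. Its defaults
are the study conditions this package was built around: groups of 20/16/26
(PD/bvFTD/HC), ten concrete Spanish cue words (one to three syllables, mean
2.1), group means of 6.3/6.0/8.3 valid properties per concept
(negative-binomial with size 8, truncated at 1; overdispersed counts are
realistic and only the means are pinned), 1 + Poisson(1.3) content tokens
per property, and an 8% admixture of non-valid properties carrying the
three non-valid tags.

Vocabulary is a clustered unit-vector lexicon (480 words, 8 dimensions, 4
clusters around orthonormal centroids, within-cluster dispersion 0.15)
crossed with independent high/low strata for concreteness and imageability
(norms uniform on [5,7] vs [1,3]). Three latent traits per participant
drive generation:

* `p_conc`, `p_imag` — probability of drawing each token from the high-norm
  stratum (HC mean 0.5, trait SD 0.10);
* `stay` — probability that the next token remains in the current vector
  cluster (HC mean 0.6, trait SD 0.05). Raising `stay` compresses the
  distance series and lowers semantic variability monotonically (for
  `stay` > 0.5).

Injected effects are specified as signed standardized shifts (Cohen's d at
the participant level; defaults +0.78 concreteness and +0.74 imageability
for PD, −1.04 semantic variability for both patient groups — the magnitudes
this design is calibrated to). The generator maps d to trait shifts itself:
analytically for the strata (a stratum-probability shift of Δp moves the
feature by 4Δp; the feature SD combines the trait SD with the
token-sampling variance of the mixture, using E[1/m] over the design's
token-count distribution because short property lists dominate the
sampling error) and by a Monte-Carlo secant iteration for `stay` (simulated
pseudo-participants run the actual cluster-stay chain over the actual
lexicon, so token-sharing between consecutive distances and unequal list
lengths are represented rather than approximated). Across replicate
cohorts the mean recovered d sits within ~0.05 of the injected value for
concreteness/imageability and overshoots by ~0.15–0.20 for semantic
variability (the per-cohort Cohen's d of a right-skewed feature is
inflated by small-sample SD estimation), inside the generator's ±0.3
contract.

Education (years) is drawn from one common distribution (mean 12.4, SD 4.5)
for all groups and explains ~30% of the within-group trait variance in
concreteness/imageability (capped by trait capacity for `stay`), with signs
chosen so more educated speakers produce less concrete, more variable
vocabulary. Two deliberate departures from strict realism follow from the
generator's purpose: (a) a group-balanced education distribution — with
unequal group education and an effect not mediated by education, covariate
adjustment would bias the adjusted contrast away from the injected d, making
recovery experiments uninterpretable; (b) under the *null* condition
(`null_effects = TRUE` in the validation experiments) the per-group
production rates are also equalized, because group-specific property counts
are themselves a group difference that classifiers and production-frequency
features legitimately detect (leaving them in place yields null AUC ≈ 0.63
— a detection, not a false positive).

Clinical scores are linear in the latent traits plus Gaussian noise, with
the signs of the reported associations: MoCA decreases with the
concreteness/imageability traits, Hayling increases with `stay` (i.e.
decreases with semantic variability); PDQ-39 is generated for PD only and
linked to nothing.

What the generator does *not* emulate: real Spanish phrases (tokens are
synthetic word ids), correlated norm dimensions beyond the two strata,
participant-level production-rate/trait correlations, or any linguistic
structure inside a property. Passing recovery tests therefore shows that
the pipeline detects the modeled kinds of group differences at the modeled
sizes — not that real transcripts carry them.

## Validation experiments and problem sizes

`recovery_experiment()` simulates 50 cohorts under the injected-effect and
null conditions and runs the ANCOVA stage on each (the three injected
features are flagged in well over 70% of effect replicates; no feature
exceeds a 10% flag rate under the null). `classification_experiment()` runs
200 cross-validation iterations per condition (null AUC sits in the
0.45–0.55 chance band; injected effects push it past 0.65; 200 iterations
estimates the mean AUC to ±0.01 while keeping the experiment at desk
scale — the analysis default remains 1000). `ancova_null_calibration()`
checks the omnibus test's empirical size at 0.05 over 1000 Gaussian null
datasets of the study's dimensions. `scripts/acceptance.R` reruns all of
these from scratch and writes the numbers as JSON.

The classification experiment divides its iteration budget over eight
independent cohorts rather than running one, because a single simulated
cohort of 46 subjects carries chance group separation (in either
direction) that cross-validation legitimately estimates — cohort-level
null AUC has an SD near 0.1 — and detection statements are about the
expectation over cohort realizations. The chance-level (null) condition
goes one step further and is a permutation null: within each of four
exchangeable null cohorts, the PD/HC labels are freshly permuted between
blocks of iterations, integrating over the label assignment; this pins the
null mean AUC within about ±0.01 of its theoretical chance level where a
fixed assignment would wander by ±0.1.

## Known limitations

* Validity coding and part-of-speech tagging are consumed, not performed;
  the dictionary tagger is for pre-lemmatized or test data, and real
  transcripts should arrive pre-tagged (`lemma_seq`/`pos_seq` columns).
* Relevance/distinctiveness couple participants through the pooled
  production table, so their ANCOVA p-values are mildly anticonservative;
  the coupling is intrinsic to the feature's definition.
* The syllabifier implements orthographic nucleus rules (diphthongs,
  accented-weak hiatus, silent `u`); it is intended for stimulus validation,
  not exhaustive Spanish phonology.
* η_p² is reported from the standard SS ratio and is bounded by 1 by
  construction; it cannot reproduce out-of-range values reported elsewhere.
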