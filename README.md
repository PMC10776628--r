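# pltmarkers

Lexico-semantic markers of semantic memory navigation from property-listing
tasks.

In a property-listing task, a participant reads a cue concept ("sun") and
freely lists its features ("hot", "yellow", ...). The words people choose
carry measurable signatures of how they navigate semantic memory, and those
signatures shift in neurodegenerative disease: Parkinson's disease (PD)
patients tend toward more concrete, more imageable vocabulary and reduced
semantic variability, a pattern that also appears (for variability) in
behavioral-variant frontotemporal dementia (bvFTD). `pltmarkers` implements
the full analysis pipeline for such studies:

* **Ingest** — parse coded transcripts (UTF-8 CSV/TSV), drop non-valid
  responses (examiner-directed, personal-experience, metacognitive), isolate
  lemmatized content words (nouns, verbs, adjectives, adverbs) via pre-tagged
  columns or a pluggable tagger.
* **Ten word-property features** per participant:
  five psycholinguistic norm means (concreteness, imageability, familiarity,
  log frequency, phoneme length); *semantic variability*, the variance of
  the distance series between consecutive word embeddings; *granularity*,
  mean taxonomy depth below the root `entity`; *property distance flow*, the
  variance of property-to-concept embedding distances; and
  *relevance*/*distinctiveness* from production frequencies,
  k<sub>ij</sub> = x<sub>ij</sub> log(I / I<sub>j</sub>), where
  x<sub>ij</sub> is the production frequency of property *j* for concept
  *i*, *I* the number of concepts and *I<sub>j</sub>* the number of concepts
  listing property *j*.
* **Group statistics** — 3×IQR outlier fencing, one-way ANCOVA with an
  education covariate (partial η² = SS<sub>group</sub> /
  (SS<sub>group</sub> + SS<sub>error</sub>)), Tukey–Kramer post hocs,
  Cohen's d.
* **Classification** — repeated stratified 5-fold cross-validation with
  min-max normalization and tuned gradient-boosted trees (xgboost); AUC
  mean ± SD over random repartitions.
* **Clinical correlations** — patient+control tandems, Pearson or Spearman
  gated by Shapiro–Wilk, optional partial correlation.
* **Synthetic cohorts** — a generator that emulates the study design
  (groups of 20/16/26, ten Spanish cue words, overdispersed property
  counts) with calibrated standardized group shifts, so the whole pipeline
  is testable without any external data.

## Worked example

Simulate a cohort with the default injected effects (+0.78 SD concreteness
and +0.74 SD imageability in PD, −1.04 SD semantic variability in both
patient groups), then run the full pipeline:

```r
library(pltmarkers)

spec <- cohort_spec(seed = 1)
sim  <- simulate_cohort(spec, dir = "demo")

cfg <- run_config(
  inputs = list(
    transcripts      = "demo/transcripts.csv",
    norms            = "demo/norms.csv",
    vectors          = "demo/vectors.vec",
    taxonomy_edges   = "demo/taxonomy_edges.tsv",
    taxonomy_mapping = "demo/taxonomy_mapping.tsv",
    participants     = "demo/participants.csv",
    clinical         = "demo/clinical.csv"
  ),
  outdir = "demo/out",
  classifier = list(n_iterations = 50, seed = 1)
)
res <- run_pipeline(cfg)

cmp <- res$comparisons
cmp[cmp$significant, c("feature", "F", "p", "eta_p2")]
#> # A tibble: 2 × 4
#>   feature                  F        p eta_p2
#>   <chr>                <dbl>    <dbl>  <dbl>
#> 1 concreteness          7.58 0.00119   0.207
#> 2 semantic_variability  8.89 0.000429  0.235

cmp$posthoc[[which(cmp$feature == "semantic_variability")]]
#> # A tibble: 3 × 6
#>   pair         diff       p      d    n1    n2
#>   <chr>       <dbl>   <dbl>  <dbl> <int> <int>
#> 1 bvFTD-HC -0.0227  0.0210  -0.856    16    26
#> 2 bvFTD-PD  0.00306 0.934    0.102    16    20
#> 3 HC-PD     0.0257  0.00410  1.20     26    20

res$classifiers[["PD-vs-HC"]]
#> <plt_classifier_report> PD-vs-HC: AUC 0.589 +/- 0.052 over 50 iterations

head(res$correlations[!is.na(res$correlations$p) & res$correlations$p < 0.05,
                      c("tandem", "feature", "score", "method", "estimate", "p")])
#>   tandem  feature              score   method estimate        p
#> 1 PD-HC   concreteness         moca   spearman   -0.53  0.00017
#> 2 PD-HC   concreteness         hayling spearman    0.40  0.0060
#> 3 PD-HC   semantic_variability moca    pearson     0.63  2.6e-06
#> 4 PD-HC   semantic_variability hayling spearman   -0.32  0.031
```

Reading the output: the education-adjusted ANCOVA flags concreteness and
semantic variability (imageability, injected at d = 0.74, misses the 0.05
cutoff in this particular cohort — single-cohort power is around 80%, and
the replicated experiments below aggregate over 50 cohorts); the post hocs
show both patient groups below controls in semantic variability (HC−PD
d = 1.20, HC−bvFTD d = 0.86, single-cohort estimates of the injected 1.04)
with no PD–bvFTD difference; the PD-vs-HC classifier sits above chance
using all ten features jointly (cohort-level AUC varies roughly 0.55–0.77
across simulated cohorts); and the tandem-pooled clinical correlations
recover the built-in associations — concreteness negative against MoCA,
semantic variability negative against Hayling — with the method column
recording which coefficient the normality gate selected.

A thin CLI wrapping the same functions ships in `inst/cli/pltmarkers.R`
(`simulate`, `extract`, `stats`, `classify`, `correlate`, `run-all`
subcommands).

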