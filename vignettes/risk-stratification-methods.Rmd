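---
title: "Methods: stratifying asymptomatic Alzheimer's disease risk from CSF peptide panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratifying asymptomatic Alzheimer's disease risk from CSF peptide panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymadstrat)
```

## The problem

A long asymptomatic phase precedes clinical Alzheimer's disease: CSF
amyloid-beta 42 (Abeta42) falls and total tau (tTau) rises years before
cognitive symptoms appear. Cognitively normal individuals whose CSF
biomarkers already indicate pathology — "AsymAD", operationally CN/BM+ —
are a heterogeneous group: some resemble biomarker-negative controls,
others resemble symptomatic patients, and only the latter are plausibly
near conversion. `asymadstrat` implements a pipeline that (i) gates
subjects into Control / AsymAD / AD groups from biomarker positivity,
(ii) selects a small discriminative peptide panel from a targeted CSF
proteomics assay, (iii) sub-types AsymAD subjects by proximity to the two
reference groups in a low-dimensional embedding, and (iv) corroborates the
sub-typing with an event-based model (EBM) of disease progression fitted
to cross-sectional data.

Because the motivating cohort data are access-restricted, the package
ships a synthetic-cohort generator whose statistical structure matches
what the analysis assumes. Every stage is validated by recovery
experiments against the generator's ground truth.

## Biomarker gating

**Ratio cut-off.** The tTau:Abeta42 ratio is strongly bimodal in mixed
cohorts (biomarker-negative values cluster near 0.12, positive values
spread upward past 0.3). `fit_ratio_mixture()` fits a two-component
Gaussian mixture by EM and places the positivity threshold where the
posterior probability of the upper component crosses 0.5. EM details the
literature leaves open were fixed for reproducibility: initialisation by
quantile split, tolerance 1e-6 on the log-likelihood, at most 500
iterations, best of five deterministic restarts with widening quantile
pairs. Degenerate fits (component weight below 0.01, collapsed SD, no
crossing between the means) are flagged and produce no cut-off. The
mixture is fitted on the raw ratio by default, since published thresholds
of this kind (around 0.24) are quoted on the raw scale; `use_log = TRUE`
fits on the log scale and back-transforms, which is what `run_pipeline()`
uses because per-group ratio distributions are approximately log-normal
and the raw-scale Gaussian fit is unstable under the heavy right tail.

**ROC cut-off.** For PET SUVR scalars, `youden_cutoff()` maximises
J = sensitivity + specificity − 1 over all midpoints between consecutive
sorted unique scores. Ties in J favour higher sensitivity, then the
smaller threshold. Positivity is a strict inequality in both gating
modes, matching how such thresholds are quoted (e.g. AV45 > 1.226,
FDG < 1.191).

**Matching.** `match_groups()` builds 1:1:1 Control-AsymAD-AD triplets by
greedy nearest-age matching inside exact sex and race strata, with an age
caliper (default 5 years) for both pairs and an education caliper
(default 3 years) for the Control pair only, mirroring designs in which
symptomatic cases are matched on age/sex/race and the two CN groups
additionally on education. Greedy matching was chosen over optimal
matching for simplicity and reproducibility; unmatched subjects are
reported, not dropped silently.

## Panel selection

Selection uses only Control and AD subjects. A stratified 80/20 split
reserves the held-out 20% for validation; held-out rows never touch the
scaler, the selection, or classifier training. Training abundances are
log-transformed (targeted MS intensities are right-skewed), mean-centred
and scaled to unit variance; zero-variance peptides are excluded and
logged.

Recursive feature elimination is run independently under two
L2-regularised linear classifiers — logistic regression and a
squared-hinge linear SVM, both fitted by BFGS from a zero start with a
fixed regularisation strength (0.01) — eliminating the single feature
with the smallest absolute weight per iteration until 14 remain.
Weight-magnitude ties eliminate the lower peptide index first. The final
panel is the **intersection** of the two 14-peptide sets. (One step per
iteration maximises the fidelity of the elimination order; fixed
regularisation favours determinism over tuning.)

The panel is quantified three ways:

* **Held-out metrics.** A logistic classifier restricted to the panel is
  trained on the training rows and evaluated on the held-out rows
  (confusion counts, sensitivity, specificity, rank-based ROC-AUC).
* **Permutation null.** `permutation_test()` draws uniform random peptide
  subsets of the panel's size (100 000 by default), trains the same
  classifier per draw, and reports per-metric p-values as the plain
  fraction of draws performing at least as well as the panel. Draws may
  coincide with the observed panel (excludable by flag), and a
  (r+1)/(N+1) variant is available by flag.
* **Cognition ranking.** Kendall tau-b (tie-corrected, because MoCA is an
  integer 0–30 score with heavy ties) of every peptide against MoCA
  across all groups; discriminative peptides should occupy the extremes
  of the sorted coefficients.

Volcano statistics (`volcano_stats()`) use log2 fold changes of
linear-scale group means — the conventional display scale — with
two-sided Mann-Whitney p-values.

## AsymAD sub-typing

`stability_stratify()` embeds the standardised log-scale panel values of
all Control, AD and AsymAD subjects into 2-D with exact t-SNE and labels
each AsymAD subject by the majority of its k = 5 nearest Control/AD
neighbours (Euclidean distance in the embedding; AsymAD points are never
neighbours; distance ties break to the lower subject index). Because
t-SNE depends on its random initialisation, the embed-and-vote step is
repeated (100 times by default) with repeat seeds derived from the master
seed; `p_adlike` is the exact fraction of repeats voting `ADLike` and the
consensus is the majority, with the `p_adlike = 0.5` tie resolved to
`ADLike` — the risk-conservative direction — and flagged.

t-SNE details: perplexity 30 by default (shrunk with a warning for small
cohorts), learning rate 200, 500 gradient-descent iterations with early
exaggeration 12 for the first 100, momentum 0.5 switching to 0.8. The
implementation is the standard exact O(n²) algorithm (cohorts here are a
few hundred subjects, so no tree approximation is needed). Exact
duplicate rows are collapsed before embedding and share the resulting
coordinate — reference implementations either refuse duplicates or place
them unpredictably, and sharing the coordinate is the only behaviour
consistent with treating copies as the same measurement.

APOE enrichment between the sub-types is tested primarily on a 2x2
allele-count table (two alleles per subject, epsilon-4 vs other) with
two-sided Fisher's exact test; a genotype-level 2x3 table with Pearson
chi-square is also reported, since "allele frequency" comparisons are the
convention but genotype tables are sometimes wanted.

## Event-based disease progression model

The scaled EBM groups the panel biomarkers into `n_clusters = 4` clusters
of `cluster_size = 2` that become abnormal together, yielding 5 stages
(0 = no event). Per biomarker, a two-component Gaussian mixture is fitted
by constrained EM on the pooled Control + AD values: the normal component
is initialised from Controls, the abnormal from AD cases, means stay
ordered in the abnormality direction (the sign of the initial AD-minus-
Control difference handles non-monotone panel members), and SDs are
floored at 1e-3 of the data SD. All panel peptides enter the model; the
direction field absorbs those whose change is not cleanly monotone.

The joint state — cluster order **and** balanced biomarker-to-cluster
assignment — is inferred by Metropolis MCMC with symmetric proposals
(uniformly: swap two order positions, or swap two biomarkers between
clusters) and acceptance `min(1, exp(delta logL))`. The likelihood
marginalises each subject's stage under a uniform prior over 0..K (the
classic EBM choice). The chain runs 5e5 iterations with the first 3e5
discarded as burn-in, initialised by greedy search from 30 random starts
of 800 iterations each (each iteration proposes a sampled set of candidate
moves and accepts the best only if it improves). A `"fast"` profile (5e4
iterations, 3e4 burn-in, 10 x 200 greedy) is provided for tests; the full
schedule remains the default. The `implicit_feature_exclusion`
hyperparameter is accepted at its stated value 0, where it is a no-op;
other values are rejected because their semantics are not defined for
this pipeline.

Summaries use the modal sampled state (ties broken by likelihood), which
drives staging: each subject's posterior over stages under the modal
state, with `ml_stage` the argmax (ties to the lower stage — again the
conservative direction for a severity scale read from stage 0 upward).
Positional-variance matrices (cluster x position frequencies, and the
biomarker-level analogue) summarise ordering uncertainty; rows sum to 1
exactly. Subjects with missing biomarker values are staged over their
observed biomarkers and flagged. `recalibrate()` re-fits only the mixture
parameters on an external cohort (ordering and assignment held fixed),
either anchored by external Control/AD labels or by unconstrained EM
warm-started from the training parameters — both modes exist because
published descriptions of cross-cohort recalibration do not say whether
external labels were used. Note that the unlabelled mode is only a fixed
point of the labelled fit when run on the same rows the mixtures were
fitted on; on data with many intermediate-stage subjects the unconstrained
optimum can differ.

Cluster identities are arbitrary labels, so ordering recovery is measured
at the biomarker level: `event_order_distance()` places each planted
cluster at the mean inferred position of its biomarkers and counts
inverted pairs (a Kendall distance; 0 means exact recovery up to
relabelling).

## The synthetic world

`generate_cohort()` simulates the cohort structure the pipeline assumes.
Key choices, and what they do and do not emulate:

* **Severity.** Each subject has a latent severity in [0, 1]: Controls
  Uniform(0, 0.2), AD Uniform(0.8, 1), AsymAD Uniform(0.15, 0.85) so that
  both sub-types occur; the true sub-type is `ADLike` iff severity
  exceeds 0.5.
* **Peptides.** 75 peptide columns; log-scale abundance = fixed baseline
  + effect x severity + N(0, 1) noise, exported on the linear scale.
  Eight informative peptides carry signed effects of magnitude **3
  residual SDs per unit severity**. This is the one deliberately
  calibrated default: the magnitude is not reported peptide-wise anywhere,
  so it was chosen to reproduce the qualitative regimes a strongly
  discriminative panel exhibits — Control/AD held-out AUC around
  0.98–1.00 and clearly separated embedding clusters. At substantially
  smaller effects (e.g. 1.5 SD) the Bayes-optimal sub-type accuracy over
  the AsymAD severity span is only about 0.75, i.e. no method could
  recover sub-types at the fidelity the strong-panel regime implies, and
  at much larger effects the classification tasks trivialise. Effects mix
  signs (five up, three down) as real panels do.
* **CSF analytes.** Per-group log-normal Abeta42/tTau/pTau with location
  and scale derived from published group medians and IQRs, giving a
  bimodal tTau:Abeta42 ratio for the gate.
* **APOE.** Allele draws at per-group epsilon-4 frequencies 0.08 / 0.40 /
  0.50; the residual allele mass is split 90/10 between epsilon-3 and
  epsilon-2.
* **Cognition.** MoCA = 26.8 − 10.4 x severity + N(0, 2.3), rounded and
  clamped to [0, 30], so the AD band mean lands near 17.4 with
  control-like means near 26.8. This makes MoCA informative across the
  whole severity continuum — in real AsymAD cohorts cognition is normal
  by definition, so a green Kendall-ranking test here establishes the
  machinery, not the clinical effect size.
* **Demographics.** Age ~ N(66, 6), 74.6% female, race 92.5/6.7/0.8%,
  education ~ N(16.7, 2.1) — matched-cohort values, drawn independently of
  group so the generator does not emulate confounding.
* **Missingness.** Off by default; an MCAR mask rate is available for
  robustness tests.
* **Not emulated.** Batch effects, censoring at detection limits, between-
  peptide correlation beyond the shared severity factor, longitudinal
  follow-up, and within-group APOE-severity linkage: epsilon-4 frequency
  varies by diagnostic group only, so the two AsymAD sub-types have equal
  allele frequencies by construction and `apoe_enrichment()` is null on
  generator output (its power is tested on directly planted allele
  tables instead). Green recovery tests therefore establish algorithmic
  correctness under the stated generative model, not clinical validity.

`generate_event_cascade()` is the EBM's own oracle: subjects receive a
true stage, and biomarkers in clusters ordered at or before that stage
are drawn from their abnormal component. Earlier clusters are abnormal in
a larger fraction of the population — exactly the premise the EBM
exploits.

## Numerical and degenerate-input policy

* All seeds are explicit; repeat/stage seeds are derived from the master
  seed below 2^31. Reruns are bit-identical, including the pipeline
  report hash.
* Classifier fits start from zero weights with analytic gradients;
  non-convergence triggers one refit at 10x regularisation, logged.
* Tie-breaks are all deterministic and documented: lower peptide index in
  RFE, lower subject index in k-NN distance ties, higher sensitivity then
  smaller threshold in Youden scans, `ADLike` at a consensus tie, the
  lower stage at a staging tie, likelihood at a modal-state tie.
* Degenerate inputs produce flags or typed errors, never silent numbers:
  degenerate mixtures carry no cut-off, single-class held-out sets have
  `NA` AUC with a flag, empty panel intersections error, zero-margin
  APOE tables return p = 1 with a flag.

## Worked example

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_config(seed = 1))
res <- select_panel(cohort$table, selection_config(seed = 1))
strat <- stability_stratify(cohort$table, res$final_panel,
                            embedding_config(n_repeats = 25, seed = 1),
                            scaler = res$scaler)
fit <- fit_ebm(cohort$table, res$final_panel[1:8],
               ebm_config(profile = "fast", seed = 1))
stages <- stage_subjects(fit, cohort$table)
```

The README shows a complete run with the numbers it prints.

## Known limitations

* The synthetic severity model is one-dimensional; real AsymAD
  heterogeneity is plausibly multi-factorial, which would lower all
  recovery numbers.
* The EBM assumes predominantly monotone biomarkers; the direction field
  handles sign, not non-monotone shapes.
* The permutation null retrains only the classifier per draw, not the RFE
  selection (the conventional design; a selection-inclusive null would be
  far more expensive and answer a different question).
* Greedy matching is not optimal matching; with tight calipers it can
  leave matchable subjects unmatched.
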