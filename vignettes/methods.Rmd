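---
title: "Embedding-based summaries of ordinal symptom questionnaires: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding-based summaries of ordinal symptom questionnaires: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psychembed)
```

## The scoring model

Self-report psychiatric instruments ask ordinal questions ("I felt scared
without any good reason", answered 0--3). Classical scoring treats every item
as an exchangeable unit. This package instead places each question in a word
embedding space, so that items phrased differently but meaning similar things
contribute similar directions.

Three linear steps produce a patient's survey-level vector:

1. **Word vectors.** Each vocabulary token $w$ has a $d$-dimensional vector
   $v_w$, trained by skip-gram with negative sampling on a large text corpus
   (or loaded from a pretrained word2vec-format file). The training defaults —
   $d = 500$, window 10, 10 negative samples, minimum total frequency 100,
   5 epochs — are standard large-corpus settings for this family of models.
2. **Question vectors.** A question with tokens $\{w\}$ becomes
   $q_j = \sum_w \mathrm{idf}(w)\, v_w$, the inverse-document-frequency
   weighted sum, with repeated tokens counted per occurrence. IDF uses the
   classic $\ln(N/\mathrm{df})$ form (a smoothed variant is available);
   weights are used raw, not renormalized within a question.
3. **Survey vectors.** Patient $i$'s vector for a survey is
   $s_i = \sum_j a_{ij}\, q_j$ with $a_{ij}$ the ordinal answer. The map is
   linear in the answers: raising one answer from 1 to 2 adds exactly one
   extra copy of that question's vector, and an answer of 0 contributes
   nothing. This asymmetry is inherited from the native 0-based codings of
   the instruments and is deliberate — recoding would change the model.

Tokens missing from the embedding vocabulary or IDF table are skipped (they
contribute the zero vector), mirroring the minimum-frequency vocabulary cut.

## Derived scores

**Principal components.** Each survey's patient-by-$d$ matrix is
column-centred and decomposed; the leading one or two score columns per
survey are the compact features (9 or 18 columns for a nine-instrument
battery). Component signs are fixed by making the largest-magnitude loading
positive, so bootstrap replicates are comparable.

**Canonical correlation.** To orient the reduction toward *symptoms* rather
than generic variance, each survey's leading PCs are canonically correlated
with the 13-column DSM-style self-rated symptom matrix, and the first
canonical variable (CCV) of the PC block is kept. The number of PCs entering
is data-adaptive: the smallest count explaining 80% of variance, capped at
10. Both blocks are z-scored and the block covariances carry a ridge of
$10^{-8}$ purely for rank safety; the ridge is orders of magnitude below any
data eigenvalue and does not move $\rho_1$ at the reported precision.

**RDoC scores.** A domain's reference vector is the IDF-weighted average of
its seed words' vectors. A patient's domain-specific vector is a weighted
average of *all* question vectors pooled across the battery, with weight
$w_{ij} = a_{ij} \cos(q_j, d_k)$ — the answer times the question's cosine
similarity to the domain. Because cosine weights can be negative, the
normalizer is $\sum_j |w_{ij}|$; a plain sum could vanish and flip signs.
The score is the cosine between patient and domain vectors, defined as 0
when either vector is zero so all-zero responders propagate no NaN. Pooling
questions across surveys is the default (a per-survey mode exists) — the
domains are transdiagnostic constructs, so restricting a domain to one
instrument would reintroduce the instrument boundaries the scores are meant
to cross. A placeholder seed list for the five original domains ships in
`inst/extdata/`; it should be replaced by a curated list matched to the
user's vocabulary.

## Evaluation machinery

Diagnostic contrasts (cases vs. controls+supercontrols, cases+controls vs.
supercontrols) are evaluated over bootstrap replicates (reference analyses
use $B = 500$; the examples here use $B = 50$, which bounds the Monte Carlo
error of a bootstrap mean AUC near 0.01). Resampling is stratified by class
so no replicate loses a class.

* **Gaussian mixture.** Two components, full covariance first with fallback
  to constrained structures on degeneracy, fitted by EM via `mclust` with
  its deterministic model-based hierarchical initialization (we rely on
  that instead of random restarts precisely because it is reproducible).
  Cluster labels are arbitrary, so posteriors are oriented to make the
  in-sample AUC at least 0.5; ties keep cluster 1 as the case cluster.
  Metrics are in-sample per replicate by default. Note the orientation step
  makes in-sample AUC $\ge 0.5$ *by construction*, so for null-calibration
  questions the out-of-bag mode (`outOfBag = TRUE`) is the meaningful one:
  orientation is chosen in-bag and the AUC measured on out-of-bag patients,
  and only there can a null cohort's AUC interval straddle 0.5.
* **Logistic regression.** Ridge-regularized (small fixed penalty for
  stability under separation), 10-fold cross-validated inside each
  replicate, with z-scoring parameters estimated on training folds only.
  All copies of a resampled patient are assigned to the same fold —
  otherwise duplicates leak across the train/test split and out-of-fold
  metrics are inflated even for pure-noise features. Fold assignment hashes
  sorted patient identity, so metrics do not depend on row order.
* **Metrics.** ACC/FPR/FNR from the confusion matrix at probability
  threshold 0.5, AUC by the tie-averaged rank statistic (exactly the
  pairwise-enumeration definition). Intervals are percentile 2.5/97.5 over
  replicates. Feature sets are compared by a two-sided permutation test on
  replicate-level metric means; treating bootstrap replicates as
  exchangeable samples is a simplification (replicates share data), so the
  p-value ranks feature sets rather than testing an independent-samples
  hypothesis.
* **t-SNE.** The two-dimensional display of the 18 PC features uses an
  exact $O(n^2)$ t-SNE (perplexity calibration by bisection, early
  exaggeration, momentum gradient descent) — appropriate at cohort scale
  and deterministic under a seed.

## Outcome association

Spearman matrices (tie-corrected, pairwise-complete, two-sided p-values
with 0.1/0.05/0.01 stars) relate predictors to neurocognitive outcomes.
Skewed outcomes (|sample skewness| > 1) are log-transformed as
$\ln(x - \min(x) + 1)$; the shift guards nonpositive values, and the
threshold of 1 is the conventional cut for marked skew. Joint prediction
uses LASSO with the penalty chosen to minimize
$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2\,\mathrm{df}$, df being the
support size (the standard LARS-style estimate). Predictivity is summarized
as the cross-validated Spearman correlation between out-of-fold predictions
and observations, bootstrap-averaged. Worth knowing: with this AIC the
deviance gain needed to admit a feature is 2, which a spurious feature
clears with probability $\approx 0.16$; across 18 null features roughly
three false inclusions are expected, so the null model is *small* but not
reliably empty. Missingness is pairwise in correlations and listwise in
regressions.

## The synthetic study generator

No clinical data ship with the package; the generator reproduces the
statistical structure the method assumes so that every stage is testable.

* **Embedding space.** Tokens partition into domain topics around
  orthonormal centroids; a token's vector is its centroid plus isotropic
  noise (per-coordinate sd $0.7/\sqrt d$, giving within-topic cosines near
  0.67 against near-zero between-topic cosines). IDF weights are
  log-uniform on $[0.5, 5]$; seed words are the tokens nearest each
  centroid.
* **Cohort.** Latent severities $z_{ik} \sim N(\mu_g, 1)$ with
  $\mu = \Delta, \Delta/2, 0$ for cases, controls, supercontrols. Question
  texts are drawn from their domain's topic; answers discretize
  $z + \varepsilon$ through fixed population thresholds (a graded-threshold
  model — chosen because the scoring multiplies by the ordinal level, so a
  monotone severity-response link is precisely the structure the method
  presumes). The DSM-style matrix is a noisy linear map of $z$; outcomes
  are linear in one domain each, plus a pure-noise negative control.
* **Defaults as study conditions.** 310 patients; group proportions
  0.64/0.12/0.24 (the reference cohort has 198 cases among 310; the split
  of the 112 remaining into controls and supercontrols is not published, so
  we assign two thirds to supercontrols as the larger no-lifetime-diagnosis
  pool); nine 10-question instruments over five domains; 5 ordinal levels;
  $\Delta = 2$; answer noise sd 1. The embedding space defaults to $d = 50$
  and a 500-token vocabulary so that a full pipeline — simulation through
  bootstrap evaluation — runs in well under a minute; $d = 500$ is a
  configuration change, not a code change.
* **What it does not emulate.** Real question language (topics are token
  clouds, not sentences), reverse-scored items, instrument-specific response
  styles, missingness mechanisms, and correlated latent domains (topics are
  orthogonal by construction). Passing tests therefore demonstrate that the
  machinery recovers structure *of the assumed form*; they cannot certify
  construct validity on real cohorts.

## Numerical conventions, in one place

* Cosine of a zero vector is 0 (never NaN).
* PC and canonical directions sign-fixed by largest-|loading| positive.
* Missing answers: per-question median imputation (rounded, in range) by
  default; "zero" and "drop-patient" alternatives.
* Patients ordered lexicographically by id unless a roster fixes the order;
  every output carries explicit id columns.
* Embedding file I/O: word2vec text format, 9 significant digits so a
  write/read round trip stays within $10^{-6}$ per component.
* All stochastic stages consume explicit seeds; embedding training is
  single-threaded with an internal RNG and is bit-reproducible.
* EM degeneracy (a cluster with fewer than 2 patients) warns; covariance
  structure falls back VVV → VVI → EEE → EII.

## A short example

```{r example, eval = FALSE}
cfg <- simConfig(nPatients = 150, effectSize = 2, seed = 1)
st  <- simulateStudy(cfg)
features <- featureMatrix("2PC", st$surveys)
labels   <- contrastLabels(st$cohort$groups, "C_vs_CS")
ev <- bootstrapEvaluate(features, labels, method = "logistic", B = 50, seed = 1)
ev$summary
```

## Known limitations

Survey vectors are unnormalized sums, so patients who endorse more items
have longer vectors; PCA partly absorbs this, but severity and verbosity of
the instrument are entangled by design. The permutation comparison of
feature sets inherits the dependence between bootstrap replicates. The
AIC-tuned LASSO is a liberal selector (see above); users wanting
conservative supports should swap in BIC externally. And the synthetic
generator's orthogonal domains make the RDoC discriminant check easier than
real, correlated psychopathology would be.
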