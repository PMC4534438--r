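---
title: "PulmoScreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PulmoScreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PulmoScreen)
```

## The problem

Rare paediatric pulmonary diseases — primary ciliary dyskinesia (PCD) above
all — are diagnosed late because their early presentation overlaps with
common conditions such as asthma or protracted bacterial bronchitis.
PulmoScreen implements a questionnaire-based triage model for seven
diagnosis groups: CF, AS, PCD, PM, AB, PBB and healthy controls (CTRL), in
that fixed canonical order. A patient is described by a parent-completed
questionnaire of 45 items, each answered on a six-level ordinal agreement
scale (1 = does not apply at all … 6 = applies completely). The ordinal
answers are interpreted numerically by all classifiers.

## The model

**Classifier bank.** Eight deliberately heterogeneous classifiers are
trained on the same labelled cohort: an RBF-kernel support vector machine
with post-hoc probability calibration, a single-hidden-layer neural network
(16 units, softmax output), a fuzzy rule-based classifier, a 500-tree
random forest, L2-penalised multinomial logistic regression,
shrinkage-regularised linear discriminant analysis, categorical naive
Bayes with Laplace smoothing (α = 1), and a distance-weighted k = 5
nearest-neighbour vote. Each member emits a posterior probability vector
over the seven classes. Classes absent from a training partition receive
probability exactly 0, so the fusion stage can never credit a diagnosis no
member could have learned.

**Fusion.** For a query with member posteriors $p^{(m)}$, the score of
class $c$ is $S_c = \sum_{m} p^{(m)}_c$ and the relative score is
$\tilde S_c = S_c / \sum_{c'} S_{c'}$. The top class is proposed only if
its relative score strictly exceeds a confidence limit; otherwise the
result is a *no-call* that still reports the ranked top-3 shortlist.
Argmax ties break towards the earlier canonical class.

**Evaluation.** Stratified k-fold cross-validation (default k = 10)
retrains all eight members per fold; the imputation reference is recomputed
from each training partition so validation records never leak into it.
Sensitivity of class $c$ is correct($c$)/count($c$); no-calls count as
errors because the evaluation design reports a single correct/incorrect
tally with no abstention column. ROC analysis is one-vs-rest on the fused
relative scores pooled across validation folds; the AUC is the trapezoidal
area, identical to the concordant-pair statistic with ties scored 1/2.
Fused scores could alternatively be replaced by each member's own scores;
the per-member argmax predictions are retained in the report and surfaced
by `sensitivityTable()`, but the default ROC output shows the fusion.

**Discrimination analysis.** For an ordered diagnosis pair $(d_1, d_2)$,
question $q$ and answer level $a$, the heat-map statistic is
$\Delta_{qa} = \hat f(a \mid q, d_1) - \hat f(a \mid q, d_2)$ with relative
frequencies computed within each class over non-missing answers, so every
entry lies in $[-1, 1]$ and each question's six entries sum to zero.
Question usefulness is also ranked globally by information gain
$IG(q) = H(\text{class}) - \sum_a \hat p(a)\, H(\text{class} \mid a)$ in
bits (base 2 is conventional; the base affects only scale, never the
ranking).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `limit` | 0.25 | no-call threshold on the top relative score; ≈1.75× the 1/7 chance level. Applied to the *relative* score for scale invariance. |
| `k` | 10 | cross-validation folds; on 170 records this gives validation folds of 17 and training partitions of 153. |
| `separation` | — | generator knob in [0, 1]: mixture weight of class-specific triangular answer peaks against the uniform background. |
| `missingRate` | 0 | generator probability of replacing an answer with the missing marker. |
| per-kind hyperparameters | `defaultHyperparameters()` | one overridable config block; see below. |

The study behind the design reports no classifier hyperparameters, network
architecture, SVM kernel, k for the nearest neighbour, or fuzzy rule
system, so the defaults above are this package's own choices, held in one
config block and overridable per call. Published stand-alone sensitivities
of that study consequently cannot be expected to reproduce numerically
here, and the package treats them as qualitative ordering context only.

## Design choices where the design was genuinely open

* **Fuzzy classifier instantiation.** Only the method family is named in
  the source design, not its rules. The implementation uses one rule per
  class: histogram membership functions equal to the Laplace-smoothed
  class-conditional answer frequencies rescaled to maximum 1, combined by
  the geometric mean over the 45 questions and normalised — the simplest
  Mamdani-style reading consistent with a probability-vector output.
* **Missing answers.** The data model permits them (the study design is
  silent). They are imputed with the per-question rounded median of the
  training partition: the median preserves the ordinal scale and cannot
  invent off-scale values. Halves round up; an all-missing question falls
  back to the scale midpoint 3.
* **Confidence limit.** Unquantified in the source design; the default
  0.25 on the relative score was fixed a priori at about 1.75× chance and
  is configurable. Reported case percentages are normalised relative
  scores, the assumption being documented here because raw-versus-relative
  is not stated in the source design.
* **Equal-weight summation.** The fusion is a plain probability sum: the
  phrase "weighted majority voting" is read as the probability-sum rule
  (member confidence acts as the implicit weight); no learned per-member
  weights exist.
* **Fold remainders.** Records are dealt to folds by one continuous
  round-robin across classes in canonical order, so per-class imbalance is
  ≤ 1, overall fold sizes differ by ≤ 1, and larger folds come first —
  deterministically in (cohort order, k, seed).
* **LDA regularisation.** With 45 features and ~20 records per class the
  pooled covariance is singular; it is shrunk towards a scaled identity,
  $(1-\gamma)S + \gamma\,(\mathrm{tr}\,S/p)I$ with $\gamma = 0.25$.
* **Nearest-neighbour ties.** All training points tied with the k-th
  smallest distance are included in the vote, which makes predictions
  invariant under permutation of the training set; exact matches
  (distance 0) take the entire vote.

## The synthetic cohort generator

`defaultCohortSpec(separation, seed)` reproduces the study cohort
composition exactly — CF 33, AS 27, PCD 24, PM 21, AB 23, PBB 18, CTRL 24,
total 170 — with class-conditional, question-independent categorical answer
distributions. Questions 1–42 are split into seven six-question blocks; a
class peaks at level 6 on its own block and at level 1 on every other
block (triangular peak of half-width two levels), mixed with the uniform
distribution by the `separation` weight; questions 43–45 stay uniform.
Draws consume one seeded stream per class in record-major, question-minor
order, so changing one class's count never perturbs another class's
records.

What the generator emulates: class-specific modal answer profiles over a
6-level ordinal scale, exact class counts, controllable difficulty and
missingness. What it does not emulate: inter-question correlation,
ordinal response styles (acquiescence, extreme responding), age or
centre effects, and the real questionnaire's marginals — it makes no
attempt to fit the real dataset. Passing recovery tests on generated
cohorts therefore demonstrates that the pipeline is implemented correctly
and can exploit class-conditional signal, not that real questionnaires are
this separable; headline accuracies measured here are properties of the
synthetic conditions.

## Numerical choices and degenerate inputs

* Probability vectors are validated to sum to 1 within 1e-9; member
  outputs are clipped at 0 and renormalised after the absent-class
  expansion.
* Fuzzy and LDA posteriors are computed in log space (log-mean /
  log-density plus softmax) to avoid underflow over 45 factors.
* A single-class training cohort yields, for every kind, the degenerate
  model that returns probability 1 for that class.
* Information gain clamps tiny negative float round-off to 0; the
  `0 log 0 = 0` convention applies throughout.
* Heat-map denominators are each class's non-missing count per question;
  a class with no non-missing answers on a question yields `NA` for that
  question's row rather than a silent 0.
* ROC requires at least one positive and one negative; the all-tied score
  vector gives AUC 0.5 by the tie convention.

## Problem sizes used by the shipped checks

The test suite and reference checks run the full eight-member, 10-fold
cross-validation on 170-record synthetic cohorts (the study composition)
at separation 0.95 (recovery: overall accuracy ≥ 0.95 and fusion overall
sensitivity within 0.02 of the best stand-alone member) and at separation
0 (chance control: accuracy within three binomial standard errors of 1/7,
all information gains under the 0.25-bit sampling-bias bound, which is the
χ²(df = 30) mean-plus-3-sd bias at N = 170). Oracle equivalences (AUC
versus concordant pairs, naive Bayes versus the smoothed-frequency
product, information gain versus the contingency-table entropy) run on
cohorts of at most 12 records where brute force is exact.

## Known limitations

* The question registry ships synthetic placeholder texts; item wording is
  metadata only.
* No spreadsheet ingest: cohorts are read from the canonical CSV dialect
  (`record_id,diagnosis,q01,...,q45`, missing = empty cell).
* No repeated or nested cross-validation, no significance testing between
  members, no learned fusion weights or stacking, and no handling of
  correlated questions in the generator.
* A question-ablation analysis ("does each question add reliability?") is
  out of scope; `rankQuestions()` orders questions but does not retrain
  without them.
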