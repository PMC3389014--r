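---
title: "Classifying brains by regional volume: the nested leave-one-out SVM elimination pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying brains by regional volume: the nested leave-one-out SVM elimination pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given structural-MRI morphometry — one volume in mm³ per segmented brain
region per subject, as produced by FreeSurfer's `aseg`/`aparc` pipelines —
can a classifier tell which of two groups a single subject belongs to, and
which regions carry the discriminative information? `morphclass` implements
the classical answer for small two-group cohorts: a linear support vector
machine (SVM) wrapped in a *two-level* leave-one-subject-out (LOO)
procedure that performs feature selection without ever letting the test
subject influence any fitted quantity.

The motivating setting is a cohort of regular meditators versus
non-meditators (19 vs 20 subjects, 121 regional volumes), but nothing in
the package is specific to it: any subjects-by-regions volume table with
age, sex and a two-level group label fits.

## The model and the procedure

The classifier is the standard linear soft-margin SVM: given training pairs
$(x_i, y_i)$ with $y_i \in \{\pm 1\}$,

$$\min_{w, b}\; \tfrac{1}{2}\lVert w\rVert^2 +
  C \sum_i \max\bigl(0,\, 1 - y_i(w \cdot x_i + b)\bigr),$$

with decision function $w \cdot x + b$. The relevance of feature $j$ is
$|w_j|$: a small absolute hyperplane coefficient means the feature
contributes little to the decision. The package solves the dual with a
sequential-minimal-optimization solver written for this pipeline (the
elimination loop below performs tens of thousands of fits per cohort, so
the solver warm-starts each fit from the previous solution along the
elimination path); its optima are verified in the test suite against both
libSVM (`e1071`) and a brute-force active-set enumeration of the dual QP.

For each **outer fold**, one subject is held out and the remaining $n - 1$
form the training fold:

1. *Covariate removal.* Each feature is regressed on age and sex
   (ordinary least squares with intercept) and replaced by its residual.
2. *Standardisation.* Each residual feature is scaled to mean 0, variance 1
   (sample variance, $n-1$ denominator).
3. *Inner LOO elimination.* For each inner fold, another subject is left
   out; the SVM is trained on the rest with all $P$ features, the features
   are ranked once by $|w_j|$, and the least-relevant feature is removed one
   at a time — retraining and predicting the inner held-out subject at every
   count $P-1, \dots, 1$. Pooled accuracy across inner folds yields an
   accuracy-versus-count curve, and $Q$ is the count maximising it.
4. *Final fold model.* The SVM is retrained on the full training fold, the
   $Q$ most discriminant features (by the full-model ranking) are kept, and
   the SVM is retrained on that subset.
5. *Prediction.* The held-out subject is transformed with the training-fold
   covariate model and scaler — never refitted — and classified.

Outer accuracy is the fraction of held-out subjects classified correctly;
its significance is the exact binomial upper tail
$P(X \ge n_\text{correct})$, $X \sim \mathrm{Bin}(n, \text{chance})$. The
**consensus regions** — selected in *every* outer fold — are the
discriminative-region map. $Q$ legitimately differs between folds; the
per-fold values and the per-region selection frequencies are part of the
report.

Everything from step 1 onward is deterministic given the input table: there
is no randomness anywhere in the procedure, and rerunning it reproduces the
result bit for bit.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cost` | 1 | SVM soft-margin cost $C$; 1 is the customary default of libSVM front-ends. The pipeline standardises features upstream, so no internal rescaling is done (and none would be leak-free). |
| `rerank` | `FALSE` | `FALSE` ranks once per fold from the full model and eliminates along that fixed ranking; `TRUE` re-ranks after every elimination (classic recursive feature elimination). Both are exact to the independent oracle in the tests. |
| `q_tie` | `"max"` | tie rule among accuracy-maximising counts (below). |
| `correct_covariates` | `TRUE` | age/sex residualization per training fold. Disabling it is only sensible to demonstrate why it exists (see the confound experiment below). |
| `chance` | 0.5 | binomial null for the p-value. 0.5 is the conventional two-class reading; the majority-class proportion (e.g. 20/39 ≈ 0.513) is a stricter alternative and is a one-argument change. |
| `tolerance` | 1e-6 | dual KKT stopping tolerance; tighter than libSVM's 1e-3 default. Results in the regression suite are identical from 1e-4 to 1e-8. |

### Why `q_tie = "max"`

Pooled inner accuracy over $n-1$ folds has resolution $1/(n-1)$ (about
0.026 at $n = 40$), so the accuracy-versus-count curve ties across wide
ranges of counts. Picking the *smallest* maximising count (maximal
parsimony) then collapses $Q$ to a handful of features and the all-fold
intersection to one or two regions, which defeats the purpose of the
consensus map. The default keeps the *largest* maximising count — every
feature whose removal does not improve inner accuracy is retained — which
yields materially more stable and interpretable consensus sets. The
parsimonious rule remains available as `q_tie = "min"`.

## The synthetic cohort generator

No MRI data ships with the package; `generate_cohort()` emulates the
structure the pipeline assumes. Region $j$ of subject $i$ is

$$x_{ij} = \mu_j + \beta^{\text{age}}_j \,\text{age}_i
          + \beta^{\text{sex}}_j \,\text{sex}_i
          + d \,\sigma_j \,[i \in \text{positive group, } j \text{ planted}]
          + \varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0, \sigma_j^2).$$

Defaults mirror the motivating cohort: 19 vs 20 subjects; 121 regions with
baselines $\mu_j$ log-uniform in 500–20,000 mm³ (thalamus-to-lobe scale);
noise $\sigma_j = 8\%$ of baseline (test–retest-scale variability);
ages $N(45.47, 9.47^2)$ vs $N(43.80, 9.35^2)$ truncated at 18; a mild
age slope of $-0.2\%$ of baseline per year and a $+0.5\%$ sex offset;
5 planted regions at standardized effect $d = 2.0$. Because the effect is
planted in units of the within-group noise sd, `effect_size` *is* the
population Cohen's d after confound removal, and the generator's
consistency tests verify exactly that.

What the generator deliberately does **not** emulate: anatomical
correlation between regions (real volumes co-vary strongly), non-Gaussian
tails, scanner/site effects, or nonlinear age trajectories. Passing tests
on synthetic cohorts therefore demonstrate the *procedure's* correctness
and calibration — not that any particular accuracy is attainable on real
morphometry.

## What the procedure can and cannot recover

Simulation at the planted-effect conditions (20+20 subjects, 30 regions, 5
planted at $d = 2$) shows mean outer accuracy above 0.9, chance-level
accuracy on matched null cohorts, and well-calibrated binomial p-values.
The *exact* consensus map is a harder target: the all-fold intersection
requires every one of the 40 folds to select all 5 planted regions, but
per-fold $Q$ is the argmax of a noisy curve (standard error ≈ 0.05 against
between-count differences of one inner subject), so $Q$ varies widely
across folds and a weak planted region falls out of a minority of folds.
In our replicates the planted regions reach selection frequencies of
0.9–1.0, yet the strict intersection equals the planted set in only a
minority of cohorts — under either ranking schedule or tie rule. The
selection-frequency table is therefore the more faithful region map, and
the consensus set should be read as its frequency-1.0 stratum.

## The confound experiment

Why regress age and sex out per training fold? Plant *no* group effect but
make the groups differ in age (means 55 vs 38 years, sd 6) with a strong
age slope ($-1\%$ of baseline per year — exaggerated on purpose): every
region is now an age proxy. Without residualization the pipeline classifies
this null cohort well above chance — it has learned age, not group. With
residualization it returns to chance. The acceptance suite runs exactly
this contrast.

## Numerical choices and degenerate inputs

* Decision value exactly 0 predicts the positive class (fixed tie rule).
* Ranking ties in $|w_j|$ break by ascending feature index (stable).
* Zero-variance features are flagged and scaled to 0 — not dropped — so
  feature indexing stays aligned across folds.
* A rank-deficient covariate design (constant age *and* sex) falls back to
  the minimum-norm solution with a warning; residuals then reduce to
  centred features.
* An inner training subset that loses a class entirely is excluded from the
  pooled accuracy with a warning.
* With fewer than ~6 subjects the age+sex regression consumes most degrees
  of freedom and results are largely meaningless; `run_outer_loocv()`
  refuses fewer than 4 subjects or fewer than 2 per class.
* On cohorts where a fold's optimum is the degenerate corner $w = 0$ (a
  lone subject of one class inside the other's hull), feature ranking is
  undefined in principle; the package's tie rules make it deterministic,
  but no scientific meaning should be attached to selections from such
  folds.

## Problem sizes in the test suite

The regression suite verifies the full procedure against an independently
written naive implementation (explicit loops over folds, `lm()` residuals,
libSVM fits) on cohorts of 6–8 subjects and 2–4 features — small enough
that the brute-force QP oracle for the SVM dual (3ⁿ active-set
enumeration) is also exact — and runs the planted/null calibration studies
at 20+20 subjects × 30 regions with 25 replicates each. The analysis
scripts demonstrate the full study geometry, 39 subjects × 121 regions.
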