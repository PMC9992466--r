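---
title: "Temporal robustness of EHR foundation-model representations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal robustness of EHR foundation-model representations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Clinical prediction models trained on electronic health record (EHR) data
degrade as clinical practice changes between development and deployment.
This package studies one proposed remedy at desk scale: pretrain an
autoregressive sequence model over coded patient timelines (a clinical
language model–based representation, CLMBR), freeze it, and train small
logistic heads on its representations, instead of training logistic
regression directly on count-based code features. The hypothesis is that
the self-supervised model, by mapping codes into an ontology and learning
patient-state structure, produces representations whose relationship to
outcomes is more stable over calendar time than raw code indicators.

Because real hospital data of this kind is access-restricted, the package
pairs the modeling pipeline with a synthetic EHR generator whose temporal
shift mechanism is controllable and whose ground truth is known. Every
claim the analysis makes is therefore a claim about a *mechanism* — what
kind of shift hurts which representation — not a reproduction of any
hospital's numbers.

## The synthetic study population

`generate_population()` simulates patients over a calendar (default
2009–2021; the analysis scripts use 2009–2016 to keep runs small) with:

* **A two-level code ontology.** Parent codes are clinical concepts;
  leaf codes are the concrete codes practitioners record. The default
  ontology has four domains (condition, drug, procedure, measurement).
  The package default is about 200 leaves; the analysis scripts use
  8 parents × 6 leaves (48 leaves) so that head fitting is
  well-conditioned at a few hundred training admissions.
* **Chronic condition structure.** Each patient carries
  `chronic_parents_per_patient = 3` persistent parent concepts (drawn
  with probability proportional to concept frequency). Each code draw
  comes from the patient's chronic concepts with probability
  `chronic_share = 0.6`, otherwise from the background concept
  distribution. Chronic concepts recur across a patient's event days;
  they are what an autoregressive model can genuinely learn to track,
  and they carry the outcome signal.
* **Concentrated coding.** Within a parent, leaf log-frequencies are
  N(0, `within_group_logit_sd` = 2.5), so each concept has one or two
  dominant codes at any time — one canonical way of coding a concept —
  which is precisely why changes of coding practice matter for
  leaf-level models.
* **Leaf-level temporal shift, invisible at the parent level.** Two
  knobs, both operating strictly within sibling groups so that
  parent-level marginals are time-invariant by construction:
  `drift_magnitude` (an AR(1) on within-sibling log-frequencies with
  year-on-year correlation `exp(-drift_magnitude)`; the stationary
  marginal is unchanged, so there is no artifactual concentration over
  time) and `code_replacement_rate` (per-year probability that a leaf
  swaps identity with a random sibling — episodic recoding in the
  spirit of vocabulary migrations). Defaults: 0.3 and 0.1.
* **Outcomes with a recoverable ground truth.** Four inpatient outcomes
  (hospital mortality, long length of stay ≥ 7 days, 30-day
  readmission, ICU transfer) are Bernoulli draws from a logistic model
  whose linear score is a fixed function of *parent-level* indicators
  over a 30-day lookback window plus demographics, with admission-level
  noise (sd 0.5). Coefficients are drawn once per seed. Mortality's
  demographic coefficients are zero: tying death to persistent
  demographics would selectively remove high-risk patients over
  calendar time and break the designed time-invariance of the signal.
  Intercepts are self-calibrated: a Monte-Carlo initializer is refined
  against the realized risk scores of a pilot generation pass (up to
  1,500 patients), and the readmission intercept absorbs the competing
  risk of in-hospital death. Reference-period prevalences (defaults:
  mortality 0.03, long LOS 0.25, readmission 0.15, ICU 0.08) are
  recovered within binomial error at n = 5,000.
* **Admissions.** A sequential process with mean rate `admission_rate`
  (0.3 per patient-year); 30-day readmissions shorten the next gap, and
  the non-readmission gap is calibrated so the marginal rate holds. ICU
  transfer days cluster early in the stay, with ~15% on the admission
  day itself (those are excluded from the ICU task, since the transfer
  precedes the prediction time).

What the generator deliberately does **not** model: patient-level
code co-occurrence beyond the chronic-concept mixture, free text,
intra-day timing, visit-type taxonomies, and staggered enrollment.
Passing tests therefore show that the pipeline behaves as designed under
*this* shift mechanism; they cannot show how large the robustness gap is
on any real hospital's data, where the shift mechanism is unknown.

## Cohorts and labels

`build_pretraining_cohort()` includes patients with at least 3 distinct
event days inside the pretraining year range and truncates timelines to
that range; task validation/test patients are excluded from every
pretraining cohort, and `assert_no_leakage()` enforces this before any
training. `build_task_cohort()` keeps adult (≥ 18 years at admission)
inpatient admissions, drops same-day discharges, and selects one index
admission per patient uniformly at random. Interpretations chosen where
the rules have an open boundary: length of stay counts both endpoints
(so "seven or more days" means `discharge_day - admit_day >= 6`);
readmission gaps of 1–30 days are positive, a gap of 0 makes the patient
ineligible; a first-day ICU transfer makes the patient ineligible.
Prediction time is "11:59 PM", i.e. events with `day <= prediction day`
are visible; the prediction day is the admission day except for
readmission (discharge day).

## The two representations

**Count features** (`featurize_cohort()`): binary indicators of each
code's occurrence in four clinical time bins relative to the prediction
day (the prediction day itself; 1–7; 8–30; 31+ days prior), plus
abnormal-direction indicators for measurements and demographics with
5-year age bins. Features seen fewer than `min_count` times in the
training rows are pruned (package default 25, as appropriate for large
cohorts; the desk-scale analyses use 10). These features see *leaf*
codes only — that is the point.

**CLMBR representations** (`pretrain()`, `extract_representations()`):
each event day becomes the mean embedding of its ancestor-extended code
set concatenated with time features (scaled age, time delta, first-day
flag, and log transforms; the transformer also receives concatenated
sinusoidal day-offset and age encodings). A GRU or causal transformer
maps the day sequence to per-day representations through a final linear
layer (`representation_dim`, default 800; the analyses use 48). The
next day's code set is predicted from the previous day's representation
through a hierarchical-sigmoid objective: the probability of a code is
the product of `sigmoid(<node embedding, representation>)` along its
root path, and the training loss is mean binary cross-entropy over the
decision nodes induced by the observed set (all children of every node
whose subtree intersects it). On a depth-1 ontology this reduces
exactly to independent per-code sigmoids. Demographics enter as
synthetic codes on the first day. Training: Adam with gradient-norm
clipping, an 80/20 patient-level split, early stopping on validation
loss (patience 5).

Numerical and optimization choices that desk scale forced, each
verified in the test suite:

* **Analytic gradients.** Both encoders are implemented with
  hand-derived backpropagation, checked against central finite
  differences to a relative 1e-4.
* **Discriminative learning rates.** The hierarchical output node
  embeddings train at `output_lr_scale` (50) times the encoder's
  learning rate (2e-4). At these model sizes, uniformly fast training
  lets the encoder collapse onto regime-level summaries of the loss and
  destroys the linear decodability of patient state from the frozen
  representation; small encoder steps preserve it while the output side
  still learns the conditional structure (validation loss beats the
  marginal-frequency baseline, and planted day-to-day transitions are
  recovered).
* **Code-token dropout** (`code_dropout = 0.3`) drops individual input
  codes during training, pushing information onto the ever-present
  ancestors.
* **Ontology-informed initialization** starts each code's embedding at
  its primary parent's embedding plus a small offset, so codes
  differentiate from their ancestors only as data demands.
* **Truncation** keeps the most recent `max_sequence_days` event days —
  recency is what matters for next-day prediction.
* BCE is computed on logits in log-space (finite for any magnitude),
  probabilities are clipped at 1e-15 before any logit, and the ACE
  recalibration treats a perfectly separated fit (deviance ≈ 0) as a
  valid degenerate solution.

## Adaptation and evaluation

Heads are L2-penalized logistic regressions (glmnet) over a grid of
penalties from 1e-6 to 1e2 by powers of ten, selected on validation
binary cross-entropy with ties broken toward stronger regularization.
CLMBR representations are z-scored with training-split statistics before
the head (penalties are scale-sensitive; binary count features are left
raw). Per-year oracles refit vocabulary and head within each OOD year.
The end-to-end (ETE) baseline trains the same encoder architecture
directly on a task label with a sigmoid head and no next-day objective.

Metrics: AUROC (rank statistic); AUPRC_C, the area under the
precision–recall curve with precision recomputed at a fixed reference
prevalence via `pi*TPR / (pi*TPR + (1-pi)*FPR)` and right-continuous
step integration over recall, which makes the metric invariant to
prevalence change in later years (the reference is the ID-period
prevalence); and ACE, the mean absolute gap between predictions and a
logistic recalibration curve fitted to the logits of the predictions.
Uncertainty: patient-level percentile bootstrap (default 1,000
resamples); paired comparisons resample the same rows for both models
and call a difference significant when the 95% interval excludes zero.
Scaling slopes regress performance on log10(pretraining patients).
Reclassification uses thresholds 0.05–0.95 by 0.05.

## Scale choices

The analyses and acceptance computations run at sizes a single CPU
handles in minutes, chosen once: populations of 2,000–2,500 patients
over 2009–2016 (ID 2009–2012, OOD 2013–2016), a 48-leaf/8-parent
vocabulary, pretraining cohorts capped at 500–800 patients, encoders
with embedding 24 / hidden 32 / representation 48, 6–10 epochs,
sequence truncation at 20 days, and 12 drift-on plus 6 drift-off
replicates (two tasks each) for the robustness contrast, with OOD
evaluation on the pooled validation and test splits (both are excluded
from pretraining, and OOD rows play no role in head selection). The
prevalence check uses n = 5,000. Concept frequencies are moderately
skewed (Dirichlet-like with shape 6) and each task's parent effect
vector is standardized to a fixed root-mean-square (0.9), so replicates
share the same total signal strength. With these sizes a single replicate of the full pipeline
(generate → cohorts → featurize → pretrain → adapt → evaluate) takes
roughly a minute.

## Known limitations

The robustness contrast is a designed property of the generator — leaf
drift with parent-invariant signal — so the package demonstrates the
mechanism, not its magnitude in any real system. Desk-scale heads on a
few hundred training rows leave count-LR well below the Bayes ceiling,
and single-seed comparisons are noisy (AUROC standard errors of a few
points at the evaluation sizes used); conclusions are drawn only from
means over replicates. The hierarchical loss enumerates all sibling
negatives, which is exact but would not scale to real vocabularies; the
paper-scale solution (sampling) is out of scope. Only the logistic
adaptation head is implemented; gradient-boosted heads are not.
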