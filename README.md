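# ehrshift

Do EHR foundation models make clinical prediction models more robust to
temporal distribution shift? This package implements, at desk scale, the
full pipeline needed to study that question when the real hospital data
is out of reach: a synthetic electronic-health-record generator with a
controllable, ontology-respecting shift mechanism; an autoregressive
day-sequence foundation model over coded patient timelines (CLMBR-style:
GRU or causal transformer encoders trained with a hierarchical-sigmoid
next-day code objective); count-based featurization with clinical time
bins; frozen-representation logistic adaptation heads; and evaluation
with AUROC, prevalence-calibrated AUPRC (AUPRC_C), absolute calibration
error (ACE) and patient-level bootstrap inference.

It is written for methods researchers in clinical machine learning and
biostatistics who want a fully inspectable, reproducible sandbox in
which "representation models survive coding-practice drift that breaks
count models" is a *designed, testable property* rather than an
anecdote.

## The core model

A patient is a time-ordered sequence of days, each a set of medical
codes drawn from an ontology (leaves = recorded codes, parents =
concepts). The foundation model embeds each day as the mean embedding of
its ancestor-extended code set plus time features, encodes the sequence
with a GRU or causal transformer, and predicts the next day's code set
through a hierarchical factorization

p(code | h) = prod over nodes v on the code's root path of
sigmoid(<n_v, h>),

trained with binary cross-entropy over the decision nodes induced by
each observed day-set. Adaptation freezes the encoder and fits
L2-penalized logistic regression on the day-of-prediction
representation; the baseline fits the same head on time-binned binary
code indicators. Temporal shift in the generator moves *leaf* code
frequencies and identities (stationary AR(1) log-frequency mixing plus
sibling replacement) while the parent-level signal that drives all four
inpatient outcomes (mortality, long LOS, 30-day readmission, ICU
transfer) is time-invariant by construction.

## A worked example

```r
library(ehrshift)

# a small synthetic study: 8 parent concepts, 48 leaf codes,
# leaf-level drift on, 2009-2016
gen <- generator_config(n_patients = 2000, year_range = c(2009, 2016),
                        ontology = make_synthetic_ontology(2, 6), seed = 1)
cfg <- experiment_config(
  generator = gen, id_years = c(2009, 2012),
  ood_year_groups = list(c(2013, 2016)),
  split_fractions = c(train = 0.65, val = 0.15, test = 0.2),
  pretrain_cap = 600L,
  encoder = pretrain_config(architecture = "gru", code_embed_dim = 24,
                            hidden_dim = 32, representation_dim = 48,
                            max_epochs = 8, max_sequence_days = 20),
  architectures = "gru", tasks = "long_los", n_boot = 200,
  min_count = 10, seed = 42)

res <- run_experiment1(cfg, with_ete = FALSE, with_correlation = FALSE)
d <- res$decays[res$decays$metric == "auroc", ]
d$decay <- d$ood_value - d$id_value
d[, c("model", "id_value", "ood_value", "decay")]
```

One seed of this run prints (your numbers will vary by a few points —
evaluation sets are a few hundred admissions):

```
          model  id_value ood_value       decay
       count-LR 0.6657418 0.5984730 -0.06726875
   CLMBR-LR-gru 0.6949686 0.6652785 -0.02969005
```

Read: in distribution the frozen-representation head (`CLMBR-LR-gru`)
is about three points of AUROC ahead of the count-feature baseline; out
of distribution — after four years of leaf-level coding drift — count-LR
has lost roughly seven points while the representation model, which sees
the drifting leaves mostly through their stable ancestors, has lost
three.
Averaged over replicates (see the acceptance script) this ordering is
the package's headline result; with drift disabled both decays center
on zero.

The numbered scripts under `analysis/` run the full study — population
generation and descriptives, the count-LR baseline with per-year
oracles, Experiment 1 (ID/OOD comparison incl. end-to-end baselines and
the pretraining/downstream correlation), Experiment 2 (pretraining-size
scaling and reclassification) and report generation — writing tidy CSVs
under `results/`:

```sh
Rscript analysis/01_generate_population.R
Rscript analysis/02_baseline.R
Rscript analysis/03_experiment1.R
Rscript analysis/04_experiment2.R
Rscript analysis/05_report.R
```

## Package layout

- `R/` — generator, ontology, cohorts, count features, encoder
  (forward/backward, pretraining, extraction), adaptation heads,
  metrics, experiment orchestration
- `analysis/` — the numbered study drivers
- `vignettes/temporal-robustness.Rmd` — the methods account: model,
  assumptions, parameter choices, limitations
- `tests/testthat/` — unit, property and acceptance tests (gradients
  are checked against finite differences; metrics against brute-force
  oracles)
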