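# canrecall

Simulations of immediate free recall with a
**categorization–activation–novelty (CAN) network**: a limited-capacity
lexical activation buffer coupled to a semantic-features layer with
adaptation, a fast-Hebbian categorization layer, a novelty ("surprise")
detector, and a single-unit list context.  The categorization and novelty
components stand for prefrontal contributions to memory; disabling them
(`frontal = FALSE`) simulates a frontal patient.  The package is for
computational memory researchers who want to study how semantic
clustering of categorized lists and the Von Restorff (isolation) effect
can arise — or fail to arise — from competitive buffer dynamics plus fast
category learning gated by novelty.

## The model in brief

Every layer follows a discrete leaky update with the saturating rate
function *F*(v) = v/(1+v) (v > 0).  The buffer:

```
x_i(t) = λ x_i(t−1) + (1−λ)[ α F(x_i) − β_x Σ_j F(x_j) + I_i(t)
                             + ξ Σ_j W_ij F(y_j) + N(0, σ) ]
```

Self-excitation α against global inhibition β_x keeps 3–4 items
co-active.  The semantic layer adds adaptation `a(t) = λ_a a(t−1) +
(1−λ_a) F(y(t−1))`, which doubles as the network's prediction of its own
state: a summed mismatch `Σ|F(y) − a|` crossing a threshold latches a
"surprise" that boosts the sensory input and the Hebbian rate for the
current item.  Categorization units compete for the semantic pattern and,
above a learning threshold, learn it fast (`W += δ F(z)ᵀF(y)`, with each
unit's incoming norm conserved).  At retrieval the list context drives
all layers, recalled items are reset, and a monitor resets the
categorization layer after more than two unsuccessful retrievals
(repetitions + intrusions), letting recall move between categories.

Study designs: CVLT-like 16-item/4-category lists (no two adjacent
same-category), Von Restorff isolate lists, same-category baselines, and
unrelated lists.  Metrics: serial-position recall and first-recall
curves, the chance-corrected semantic clustering index
(observed adjacent same-category pairs − Σ r_c(r_c−1)/R), isolate
advantage measures, and lag-CRP.

## Worked example

```r
library(canrecall)

params <- can_params()                       # calibrated default profile
trial  <- run_trial("cvlt", params, seed = 7)
trial$study_list
#> <can_study_list> design = cvlt ( 16 items )
#>   d15 b6 c12 d16 a4 b8 d13 c9 b5 c11 a2 c10 a1 d14 a3 b7
trial$recall
#> <can_recall> 9 correct, 579 repetitions, 0 intrusions; 177 categorization resets

ev  <- trial$recall$events
cor <- ev[ev$classification == "correct", ]
paste0(trial$study_list$categories[cor$serial_position], cor$serial_position)
#> "b16" "d4" "d1" "d7" "d14" "a11" "a13" "a15" "a5"
clustering_index(ev, trial$study_list)
#> 3.333333
```

Recall starts with the last-presented item (`b16`, still in the buffer),
then proceeds in category runs — four `d` items, four `a` items — giving
a clustering index of 3.33: the recall order contains 3.33 more adjacent
same-category pairs than a random permutation of the same recalls would.

Aggregating over runs, with the frontal mechanisms disabled:

```r
lesioned <- run_condition("cvlt", params, frontal = FALSE, n_runs = 25, seed = 11)
lesioned
#> <can_condition> design = cvlt  | frontal = FALSE | runs = 25
#>   mean correct recalls: 8.84
#>   mean clustering index: 2.42
round(lesioned$curve$p_recall, 2)
#>  [1] 1.00 0.36 0.44 0.72 0.48 0.36 0.60 0.72 0.60 0.44 0.48 0.32 0.48 0.44 0.40 1.00
```

The serial-position curve is U-shaped: strong recency (the buffer's
surviving items are recalled first) with a primacy edge at position 1.
`run_condition()` returns the pooled transcripts, per-run summaries and
curves; `report_run()` writes them out as CSV/JSON plus plots, and
`vr_measures()`, `lag_crp()` and `recall_probability()` score any
transcript set — simulated or empirical — in the same CSV schema.

A command-line front end is installed with the package
(`system.file("cli", "can-recall", package = "canrecall")`), with
subcommands `simulate cvlt|vr|baseline|unrelated`, `sweep` and `report`.

See the vignette (`vignettes/can-model.Rmd`) for the full model
description, the calibration of the default parameters, and an honest
account of which reference phenomena this implementation reproduces and
which it does not (the intact-model clustering level and the late-list
isolate advantage fall short; the vignette explains the structural
reason).

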