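---
title: "The CAN model: buffer, categorization and novelty in free recall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CAN model: buffer, categorization and novelty in free recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canrecall)
```

## The model

`canrecall` simulates immediate free recall with a
categorization-activation-novelty (CAN) network.  Four components interact:

1. **A lexical activation buffer.**  Each of `n_lex = 50` lexical units
   stands for one word; 12 (16 in the CVLT design) serve as list items.
   Units excite themselves and inhibit everyone through a global
   inhibition term, so only a few units can stay active at once — a
   limited-capacity short-term buffer of 3–4 items.  The update is the
   discrete map

   $$x_i(t) = \lambda x_i(t-1) + (1-\lambda)\big[\alpha F(x_i) -
   \beta_x \textstyle\sum_j F(x_j) + I_i(t) + \xi \sum_j W^{xy}_{ij} F(y_j)
   + \mathcal N(0, \sigma)\big]$$

   with the saturating rate function $F(v) = v/(1+v)$ for $v>0$, else 0.
   All right-hand side activations are the previous step's values (the
   update is an explicit map), and the result is floored at zero.  The
   global-inhibition sum includes the unit's own term; $\alpha$ is
   therefore the self-excitation net of self-inhibition.

2. **A semantic-features layer** (`n_sem = 45`), reciprocally and
   symmetrically connected to the lexical layer through a binary matrix
   $W^{xy}$.  A word's row in $W^{xy}$ is its distributed semantic
   representation.  The layer has its own global inhibition $\beta_y$ and
   an *adaptation* term $a_i(t) = \lambda_a a_i(t-1) + (1-\lambda_a)
   F(y_i(t-1))$ — a leaky average of the layer's activation history that
   is subtracted from the input current with gain $\kappa$ and doubles as
   the network's *prediction* of its own semantic state.

3. **A categorization layer** (`n_cat = 10`) with strong competition
   ($\beta_z$), driven by the semantic layer through plastic weights
   $W^{yz}$, initialized at random (U(0,1)).  Units that cross a learning
   threshold undergo fast Hebbian learning,
   $W^{yz} \mathrel{+}= \delta\, F(z)^\top F(y)$, after which the updated
   unit's incoming weight vector is renormalized: each unit has a fixed
   synaptic budget, so learning one category's features is paid for by
   unlearning everything else.  This layer and the novelty mechanism are
   the model's stand-in for prefrontal contributions to memory; the
   *frontal-lesion* mode (`frontal_enabled = FALSE`) disables both.

4. **A single list-context unit**, Hebbian-bound during encoding to all
   three layers (`Cx`, `Cy`, `Cz` grow by the current $F$ of each layer
   every step).  At retrieval the context weights are frozen and drive
   the layers with gains $\mu_x, \mu_y, \mu_z$.

**Novelty ("surprise").**  Each encoding step the model compares the
semantic layer's current activation to its prediction:
$m = \sum_i |F(y_i) - a_i|$.  When $m$ crosses `theta_surprise`, a
surprise is latched for the remainder of the current item: the sensory
input rises from `input_base` to `input_surprise` and the Hebbian rate
from `delta` to `delta_surprise`.  The boost is withdrawn at item offset
and never carries into the next item.  An optional variant divides the
score by $\mathrm{var}(F(B)) + 1$, the variance of recent semantic
activation, which damps spurious surprises in unrelated lists where the
activation varies a lot anyway (`surprise_variant =
"variance_normalized"`).

**Encoding** clamps each list item's unit for `T_enc = 25` steps, and at
each step performs, in order: adaptation update, surprise check, lexical
update, semantic update, categorization update, context learning, fast
Hebbian category learning.  **Retrieval** runs `T_ret = 700` steps in
which the context drives all three layers, the categorization layer feeds
the semantic layer with gain $\varpi$, and the semantic-to-categorization
gain drops from `phi_enc` to `phi_ret`.  A lexical unit crossing
`theta_retrieve` is *recalled* and reset to zero; the first recall of a
list item is correct, re-retrievals are repetitions, non-list items are
intrusions.  A monitor counts unsuccessful retrievals (repetitions plus
intrusions); when the count exceeds `max_unsuccessful = 2` it resets the
categorization layer, permanently inhibits the units active since the
last reset, and restarts its counter — which is what lets recall move on
to a different category.

## List designs and what the generator emulates

`build_design()` constructs the four study conditions:

* `"cvlt"` — 16 items, 4 categories of 4; each category has a dedicated
  band of `n_shared = 5` semantic features set to 1 for all members, plus
  item-specific features drawn at `p_conn = 16%` outside all bands; the
  presentation order is a uniformly random permutation with no two
  adjacent same-category items (rejection sampling gives exact uniformity
  on the constrained support), resampled every run.
* `"von_restorff"` — 11 items of one category plus a single isolate from a
  second category at a chosen serial position.
* `"same_category"` — the matched baseline: the critical serial position
  is occupied by an item of the list's own (single) category.
* `"unrelated"` — independent Bernoulli(16%) features for every item
  (7.2 features per word in expectation; the reference description
  rounds this to "6–7").

Non-item lexical units carry random features outside the category bands
and are the model's potential intrusion sources.  The generator emulates
the *structure* of categorized word lists — shared versus distinctive
features, category bands, constrained orders — not lexical frequency,
word length, phonology, or inter-category semantic similarity, all of
which real word norms contain.  Passing tests therefore speak to the
model's dynamics under idealized semantic structure, not to fits of any
behavioral dataset.

## Parameters and calibration

No reference parameter values exist for this model, so the package ships
a calibrated default profile (`can_params()`).  Calibration proceeded in
stages against the model's qualitative signatures: (i) buffer capacity of
3–4 co-active items and primacy in the activation peaks, which constrain
$\alpha, \beta_x, I, \lambda$; (ii) reliable separation of the
prediction-mismatch score between a mid-list category isolate and a
matched same-category item, which constrains $\chi, \kappa, \lambda_a$
and places `theta_surprise`; (iii) category capture by the fast Hebbian
rule, which places `phi_enc`, `theta_learn`, $\beta_z$ and the learning
rates; (iv) retrieval behavior — recency-first output, category runs,
plateaued recall within `T_ret` — which constrains the retrieval gains
$\mu_x, \mu_y, \mu_z, \varpi$, `phi_ret` and `theta_retrieve`.  Search
ranges were roughly $\lambda \in [0.8, 0.98]$, inhibition gains
$[0.05, 2.5]$, coupling gains $[0.05, 3.5]$, context gains
$[5\times10^{-4}, 0.025]$, and thresholds located from measured
activation and mismatch distributions.

Choices worth knowing about:

* `T_enc = 25` steps per item matches the timing of the reference
  simulations (an item at serial position $k$ is active during steps
  $25(k-1)$–$25k$).
* `lambda_ = 0.8` makes the within-item transient fast enough that a
  novel item's semantic features develop within its own 25-step window —
  with slower dynamics the mismatch score never separates isolates from
  ordinary items before item offset.
* `noise_sd = 0.2` is the reference value; noise is resampled per unit
  and per step, at retrieval as well as encoding (retrieval variability
  is what makes recall stochastic).
* `theta_buffer = 0.45` (in $F$-units) is a *diagnostic* threshold used
  only to report buffer occupancy.  Under the calibrated dynamics,
  weakly supported "floater" units sit at $F \approx 0.33$–$0.52$ and
  sustained units at $F \gtrsim 0.68$ with the currently clamped item
  near saturation; 0.45 sits at the shoulder between the bands.  It
  plays no role in the dynamics.
* Initial $W^{yz}$ columns are drawn U(0,1) and then rescaled to a
  common norm ($\sqrt{n_{sem}/3}$, the expected norm of such a column).
  The normalization rule that holds after every learning step is thereby
  applied from the start; without it, units that randomly draw globally
  larger columns win every item regardless of direction and competitive
  learning cannot assign categories.
* Euclidean norm preservation is the default normalization
  (`norm_mode = "preserve"`); `"unit"` is available, and the norm type
  only rescales the same direction.
* Context learning applies at encoding only; retrieval uses the frozen
  end-of-encoding context weights.
* The unsuccessful-retrieval counter restarts at zero after every
  categorization reset.
* "Reset after recall" sets the recalled unit's activation to zero with
  no refractory clamp, so items can re-cross the threshold and be logged
  as repetitions — the reference output sequences contain such
  repetitions.
* The clustering index scores correct recalls only by default;
  `scope = "with_repetitions"` is available, but with long repetition
  runs the chance correction term grows pathologically, so the
  correct-only convention (as in CVLT scoring) is the default.
* Serial positions are 1-based throughout.

## Degenerate inputs and numerical behavior

All activations are floored at zero after each full update (the floor is
applied to the result, not to individual input terms).  `lambda_ = 1`
freezes a layer; `p_conn` of 0 or 1 gives empty or complete
connectivity; fewer than two scored recalls leave the clustering index
undefined and raise a condition of class `can_undefined_metric`;
`run_condition()` records `NA` for such runs.  With `noise_sd = 0` and
fixed seeds, encoding and retrieval are bit-reproducible.  Ties at the
retrieval threshold within one time step are emitted in decreasing order
of activation.

## What reproduces, and what does not

The shipped profile reproduces, and the test suite checks:

* a 3–4 item activation buffer during late list presentation
  (the measured mean sits at the top of that range, ≈ 3.9–4.0);
* primacy in peak lexical activation (items 1–3 exceed mid-list items)
  and recency in recall (last two positions ≈ 0.8 recall probability
  versus ≈ 0.5 mid-list), with first recalls coming from the recency
  positions;
* above-chance semantic clustering of CVLT-like lists (index ≈ 2.2–2.5,
  consistent with the frontal-patient reference value 2.8 ± 1.8);
* lesion invariances: the frontal-off model never changes $W^{yz}$ and
  never signals novelty (bit-level checks);
* novelty selectivity: a mid- or late-list isolate produces a larger
  prediction mismatch than a matched same-category item, the
  variance-normalized variant lowers unrelated-list surprise rates, and
  a position-1 isolate has *no* advantage — notably, in a same-category
  list the first item recruits its whole category through shared-feature
  resonance, while a position-1 isolate has no partners to recruit, an
  emergent asymmetry in the direction the theory predicts;
* the isolate disadvantage at position 1 and a non-decreasing advantage
  gradient from position 1 to 9 with the frontal mechanisms on, and a
  poorly recalled isolate at every position with them off.

Two reference results do **not** reproduce under this implementation,
and their acceptance tests are left failing rather than weakened:

* **The intact-model clustering level (5.4) and the intact-lesioned
  contrast.**  Both models cluster at ≈ 2.2–2.5.  The diagnosis, stable
  across a wide parameter search: the categorization layer has no
  recurrent self-excitation, so its "competition" is a global
  subtraction applied to units whose inputs are nearly identical —
  the semantic snapshot at any moment superposes the 3–4 buffer-resident
  items, which in a CVLT order belong to different categories.  Fast
  Hebbian learning then either converges several units onto one shared
  blended column or fails to separate categories, and the retrieval-time
  categorization feedback is too diffuse to reorganize recall order
  beyond what lexical–semantic resonance already provides both models.
  The clustering both models do show is resonance-driven, which is
  exactly the mechanism the theory assigns to the lesioned model.
* **A positive isolate advantage at position 9.**  The isolate's novelty
  is detected and its input boosted, but with a 25-step item window and
  fast dynamics the boost decays before retrieval begins, the isolate
  cannot self-sustain in a buffer whose other occupants support each
  other through shared features, and no categorization unit becomes
  selectively associated with the isolate's category band (the main
  category's residual activation contaminates the learning step).  The
  advantage therefore stays negative at all positions, though it
  *increases* monotonically from position 1 to 9.

Both failures trace to one structural fact — under interleaved or
embedded category structure, the moment-to-moment semantic state is a
blend, and the printed categorization dynamics have no mechanism to
unblend it.  A regime with much slower integration (hundreds of steps
per item, as in the antecedent activation-buffer models) or recurrent
categorization dynamics might recover the reference behavior; both are
outside this implementation's scope.

## Problem sizes

The packaged simulations use 100 runs per CVLT condition and 100
unrelated-list encodings in the acceptance script, and up to 200 runs
per cell for the isolate-advantage conditions in the test suite; at the
default layer sizes one encode–retrieve run takes roughly a quarter of a
second.

## A short session

```{r example, eval = FALSE}
library(canrecall)

params <- can_params()                 # calibrated defaults
trial <- run_trial("cvlt", params, seed = 1)
trial$recall                           # one run's recall events

intact <- run_condition("cvlt", params, frontal = TRUE,
                        n_runs = 100, seed = 1)
lesioned <- run_condition("cvlt", params, frontal = FALSE,
                          n_runs = 100, seed = 1)
mean(intact$per_run$clustering, na.rm = TRUE)
mean(lesioned$per_run$clustering, na.rm = TRUE)

report_run(list(intact = intact, lesioned = lesioned), "cvlt-report")
```
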