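---
title: "Nearest-neighbor reasoning cues for sepsis treatment decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nearest-neighbor reasoning cues for sepsis treatment decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the approach

Sepsis management in the ICU revolves around two coupled decisions made
every few hours: how to manage intravascular *volume* (give an IV fluid
bolus, do nothing, or actively remove fluid with diuretics) and how to
manage *vasopressors* (start or increase, maintain, or wean). Outcome
models alone answer neither question directly; what a clinician often wants
to know is *what happened to patients like this one, and what did their
clinicians do?*

`sepsiscues` implements a case-based decision-support engine around that
question. Rather than fitting one predictive model per question, a single
denoising autoencoder learns a per-timestep embedding of patient states;
the 100 nearest cohort states of a query state then supply every quantity
the engine reports. Eight *reasoning cues* are computed from the neighbor
pool:

* **R1 / R2** — the up-to-three features on which the case most agrees
  with / most deviates from its neighbors;
* **R3** — the outcome frequency among neighbors, read as a risk score and
  banded low / moderate / high (for two targets: vasopressor use 12 h
  ahead, and death within the admission);
* **R4** — whether neighbors who received a particular treatment plan had
  a *significantly different* risk than the remaining neighbors (two-sided
  Fisher exact test on the 2x2 outcome table);
* **R5** — how frequently each action was taken among neighbors, with a
  support gate: a plan observed in fewer than 10 of 100 neighbors never
  yields a conditional risk or a recommendation;
* **R6** — whether one action reaches consensus, i.e. strictly more than
  60% of neighbors;
* **R7 / R8** — the mention of a concrete plan, and a plan positioned as
  "best" either by peer behaviour (modal actions) or by risk (the
  significantly safest supported plan).

Seven interface payloads compose these cues in fixed combinations
(`interface_cue_map()`), from a purely descriptive *case features* view to
a bare *treatment recommendation*. Payloads are machine-readable JSON; the
package deliberately stops short of rendering a UI.

## The cohort pipeline

The engine consumes relational EHR event tables in a documented CSV schema
(patients, stays, timed measurements, timed treatments). The cohort rules
are: a patient is *suspected septic* if an antibiotic administration and a
microbial culture occur within 24 h of each other; stays under 12 h
(inclusive threshold: 12.0 h qualifies) are excluded; data beyond the
cohort-level 95th percentile of stay length is removed (linear-interpolation
percentile, computed on the eligible cohort before the train/evaluation
split); and all timesteps at or after a comfort-measures-only order are
censored, since treatment intent changes there.

States are binned on a 4-hour grid with half-open bins, so an event at
exactly a boundary belongs to the later bin and is never counted twice.
Vitals are averaged within bins; labs carry their most recent value
forward; values carried into a bin (or imputed from the cohort median
before a first observation) are flagged, and flagged query features are
never surfaced by R1/R2. Per-bin actions are the summed fluid volume and
vasopressor/diuretic activity flags. Two labels are attached per state:
vasopressor activity in the bin starting 12 h later (undefined when the
admission ends before that bin exists — discharge and death are both
treated as end-of-observation, because recording "no vasopressor" for a
patient who died would read as reassurance), and death within the
admission.

The train/evaluation split is at patient level, `floor(0.5 n)` training
patients, seeded. All normalisation statistics (z-scores for embeddings
and for feature discrepancies) come from the training split only.

## The embedding

The encoder is a small causal self-attention network written directly in R
matrix algebra: an input projection plus sinusoidal positions, two blocks
of multi-head attention (4 heads) and a tanh feed-forward layer with
residual connections, and a linear reconstruction head; embedding dimension
32. Layer normalisation is omitted — at this scale (tens of features,
hundreds of trajectories) training is stable without it and the gradient
code stays small enough to verify against finite differences, which the
test suite does. Training corrupts each trajectory by masking feature
entries independently at rate 0.3 (a sentinel the input encoder maps to
the feature's neutral value) and minimises reconstruction error of the
uncorrupted sequence — squared error on continuous channels, cross-entropy
on binary ones. Optimisation is Adam, one trajectory per step, fully
seeded.

Attention is masked left-to-right, so a state's embedding depends only on
its own past. This is a deliberate design choice: cues are meant to be
available *at decision time*, and a bidirectional encoder would leak the
patient's future into the neighborhood definition.

A model-free fallback, `baseline_embed()`, is the z-scored raw state
vector. It shares the exact downstream contract of the autoencoder
embedding, which keeps every retrieval and cue operation testable against
deterministic inputs; the calibration experiments below use it for
that reason.

## Retrieval

Cue statistics are computed over only `k = 100` neighbors, so retrieval is
exact by contract: the index answers every query identically to a
brute-force scan (verified against an independently coded oracle on fuzzed
inputs), distances are computed with plain coordinate-wise differences so
exactly tied distances stay exactly tied, and ties are broken
lexicographically by `(patient_id, bin_index)`. By default all states of
the query's own patient are excluded, so a patient's own history cannot
vote in their cue statistics. Euclidean distance is the default with
cosine switchable; nothing in the cue layer depends on the choice.

## Statistical choices in the cue layer

*Significance of a plan-conditional difference* (R4) is operationalised as
a two-sided Fisher exact test at `alpha = 0.05` on the outcome table of
plan-takers versus the rest. Counts in a 100-neighbor pool are small
enough that exactness matters; the test suite checks the p-values against
a full enumeration of the hypergeometric distribution at `1e-9`. The
comparison is each-plan-versus-rest, not all-pairs.

*Consistency* for R1 requires both agreement and tightness: a feature
qualifies only if the neighbors' dispersion on it is below the median
dispersion across eligible features, and candidates are then ranked by the
absolute z-score gap between query and neighbor mean. R2 is simply the
largest gaps. Ties break alphabetically, so cues are reproducible.

*Risk bands* sit at 1/3 and 2/3, giving the three-level low / moderate /
high phrasing with "as likely as not" in the middle band; comparisons are
strict on both edges.

*The observed plan of a neighbor* is read over the three bins after the
decision bin (12 h, matching the vasopressor label horizon): any fluid and
no diuretic is `give_fluids`, any diuretic is `give_diuretics` (simultaneous
fluid and diuretic counts as fluids and is flagged), and the pressor action
compares activity at the window end with the current bin. Windows reaching
past the end of a trajectory are computed on what exists and flagged
partial.

## What the synthetic cohort emulates

The bundled simulator exists so every stage is testable with known ground
truth; it emulates the *regime* of an ICU EHR extract, not physiology. One
latent severity per patient follows a mean-reverting bounded AR(1) on
[0, 1]; 8 vitals and 8 labs are linear-Gaussian emissions of severity at
irregular, partially missing times; 4 demographic features are constant. A
softmax clinician policy chooses one plan per bin, preferring
severity-appropriate actions (fluids and pressors when sick, diuresis and
weaning when recovering) with a temperature that controls how concentrated
peers are — low temperature produces R6-style consensus, high temperature
an uninformative policy. Death follows a per-bin logistic hazard in
severity plus a configurable additive log-odds shift per plan; comfort-care
orders arrive with a small per-bin hazard and freeze active treatment;
suspicion events are planted for a configurable fraction of patients.

Ground truth is closed-form: per state, the simulator records the latent
severity, the per-bin hazard under each of the nine plans, the
admission-mortality probability under each plan and under the policy
(computed by dynamic programming over a discretized severity grid jointly
with the pressor status), and the probability of vasopressor activity
three bins ahead. Configured plan effects apply to the mortality hazard
only; the vasopressor outcome responds to plans mechanically through the
policy's status dynamics, where an additive log-odds shift has no coherent
definition.

Defaults describe a mixed-acuity cohort chosen once: ~4-day mean stays
(gamma, shape 2), hazard intercept −5.3 and severity slope 2.2 (per-bin
death probabilities around 1–4%, admission mortality around 20–30%),
measurement noise at 0.6 population SDs, 30% missingness, policy
temperature 0.7 (consensus emerges at severity extremes but not mid-range),
and modest protective effects for fluids and pressor initiation.

What the simulator does *not* reproduce: organ-system structure,
treatment-measurement feedback (measurements do not become denser when
patients deteriorate), multi-stay patients, and informative missingness.
Tests passing on this cohort therefore demonstrate the *machinery* —
filters, binning, retrieval exactness, estimator calibration — not
clinical validity on real data.

## Calibration experiments and their design

Three design points deserve explanation because the obvious reading would
be wrong.

**The sharp null needs an unconfounded policy.** With zero configured plan
effects the *causal* null holds, but the severity-driven policy still makes
plan assignment depend on severity, and severity drives outcomes — the
*observational* null that a binomial or Fisher calibration check assumes is
false by design. The null-calibration and type-I experiments therefore set
the policy temperature high enough to make plans severity-independent;
with assignment independent of outcomes, the hypergeometric null is exact
regardless of any label correlation, and the flag rate lands within 3
binomial SDs of `alpha` (Fisher's conservatism keeps it slightly below).
This is an experimental-design requirement decided before running the
experiments, not a tuning knob.

**Power is evaluated at the support boundary the gate defines.** Replicate
neighbor pools draw the focal plan's count from Bin(100, 1/3) conditioned
on the `n_plan >= 30` region, with risks 0.2 on-plan versus 0.5 off-plan.
The exact two-sided Fisher power at the hardest point (30 vs 70) is 0.816;
over the conditioned region the detection rate is ~0.83.

**Consistency is checked on the per-state outcome.** The neighbor risk
estimator is compared with ground-truth state probabilities on the
vasopressor-at-12h target across cohorts of roughly 500, 2,000 and 8,000
states (fixed seeds; 200 queries each): mean absolute error decreases
strictly as the cohort grows. The admission-mortality target cannot show
this cleanly: its label is constant across a patient's states, so a
100-neighbor pool contains far fewer independent labels than neighbors and
the estimator's variance floor stops shrinking with cohort size. That
clustering is a real property of admission-level outcomes, and a known
limitation of neighbor-pool risk estimates of them.

## Numerical and degenerate-input choices

Percentiles use linear interpolation between order statistics. Zero-variance
features contribute zero coordinates to embeddings and are excluded from
discrepancy scores. A risk score with no defined labels is an error, not a
zero. A plan partition with an empty side leaves the p-value undefined and
the flag unset; below the support gate the conditional risk and p-value are
reported as undefined rather than computed and hidden. Modal-action ties
defeat consensus and break alphabetically where an action must still be
named. Seeds flow explicitly through every stochastic operation, and the
RNG state of the caller is always restored.

## Problem sizes

The test suite and the acceptance script run the experiments at the sizes
stated above — cohorts of a few hundred patients (500–8,000 states), 200
trajectories for autoencoder training with the default 32-dimensional,
2-block encoder, 500 replicates for the calibration and power checks, and
100 fuzzed queries for the retrieval oracle. These sizes were chosen so the
full verification cycle completes on a single CPU in minutes while leaving
every statistical check adequately powered.

## Known limitations

Plan-conditional risks are observational contrasts among similar patients,
not causal effects; the package deliberately performs no confounding
adjustment, matching the decision-support design it implements. The
autoencoder is desk-scale; it demonstrates the denoising-objective
pipeline, not a state-of-the-art clinical representation. The simulator's
ground-truth dynamic program ignores the (rare, default 1% per bin)
comfort-care transition, a second-order approximation documented here so
that exact-match expectations are set correctly.
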