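# sepsiscues

Nearest-neighbor reasoning cues for sepsis treatment decisions in the ICU.

Sepsis management repeatedly poses two coupled questions: manage *volume*
(IV fluid bolus, nothing, or diuresis) and manage *vasopressors* (start or
increase, maintain, or wean). `sepsiscues` implements a case-based
decision-support engine for these decisions: ICU stays are converted into
4-hour state trajectories, embedded per-timestep with a denoising
autoencoder (a small causal self-attention encoder), and each query state
is answered from its 100 exact nearest cohort states.

From a neighbor pool the engine computes eight **intelligent reasoning
cues**:

| cue | meaning |
|-----|---------|
| R1 / R2 | up to three features most consistent with / most unusual against the neighbors (z-score discrepancy `d_f = |z(x_f) - mean z(neighbors_f)|`) |
| R3 | neighbor outcome frequency as a risk score, banded low / moderate / high at 1/3 and 2/3 |
| R4 | plan-conditional risk difference, two-sided Fisher exact test at α = 0.05 |
| R5 | peer action frequencies, with a support gate at 10 of 100 neighbors |
| R6 | consensus action: one action in strictly more than 60% of neighbors |
| R7 / R8 | plan mention, and a plan positioned "best" by peers or by risk |

Two risk targets are supported: vasopressor use 12 h ahead (a severity
proxy) and death within the current admission. The cues compose into seven
machine-readable interface payloads (`interface_names()`), from a purely
descriptive case-features view to a bare treatment recommendation; the
`prior_clinician_actions` interface contains peer behaviour only and no
outcome numbers.

Because the cohort the method was designed around requires credentialed
access, the package ships a synthetic EHR simulator (`simulate_cohort()`)
with closed-form ground truth: a latent severity process, linear-Gaussian
vitals/labs, a softmax clinician policy over the 3 × 3 plan grid, and a
logistic per-bin mortality hazard with configurable additive plan effects.
Every downstream stage is tested against it. The cohort reader accepts any
extract reshaped to the documented CSV schema (`patients.csv`,
`icustays.csv`, `events.csv`, `treatments.csv`; hours from ICU admission).

## Worked example

```r
library(sepsiscues)

sim    <- simulate_cohort(sim_config(n_patients = 60, seed = 1))
ts     <- build_trajectories(sim$records)      # filters + 4-hour binning
split  <- split_cohort(ts)                     # patient-level halves
stats  <- cohort_stats(ts, split$train)        # train-split z-statistics
model  <- train_encoder(ts$trajectories[split$train],
                        encoder_config(embed_dim = 16, n_layers = 1,
                                       n_heads = 2, epochs = 4, seed = 2),
                        stats = stats)
emb    <- embed_cohort(ts, model = model)
engine <- cue_engine(ts, stats, emb, eval_ids = split$eval)

q  <- emb[emb$patient_id %in% split$eval & emb$bin_index == 2][1]
ns <- nearest_states(engine$index, q, neighbor_query_config(k = 100))
ns
#> <neighbor_set for P0002/bin 2: k=100, d in [2.3, 3.81]>

risk_score(ns, "mortality_in_admission", engine$ts)
#> mortality risk: 0.36 (moderate, 36/100 neighbors)

plan_conditional_risk(ns, treatment_plan("give_fluids", "maintain"),
                      "mortality_in_admission", engine$ts)
#> plan give_fluids+maintain: n_plan=53 risk=0.36 vs rest=0.36 p=1.000
#> significant=FALSE

fv <- action_frequencies(ns, "volume", engine$ts)
round(fv$frequencies, 2)
#>    give_fluids           none give_diuretics
#>           0.65           0.22           0.13
consensus(fv)
#> volume consensus: TRUE (modal give_fluids at 0.65)
```

Read: this patient's neighbors died in 36 of 100 admissions (moderate
band); neighbors who received fluids and maintained pressors had the same
mortality as the rest (p = 1.000 — equipoise, so no R4 flag and no
risk-based recommendation), yet 65% of peer clinicians gave fluids, which
crosses the 60% consensus threshold. A payload bundles such cues per
interface:

```r
p <- build_payload(engine, "prior_clinician_actions", q$patient_id, q$bin_index)
validate_payload(p)    # exact cue composition, outcome-free peer view
payload_json(p)
#> {"interface_name":"prior_clinician_actions","patient_id":"P0002", ...
```

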