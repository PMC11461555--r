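---
title: "Methods: CKD screening as a finite-horizon POMDP"
author: "ckdscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CKD screening as a finite-horizon POMDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model, its assumptions, the parameter choices
and the numerical decisions behind `ckdscreen`, in enough detail that a
reader can judge what the package's passing tests do and do not
establish.

## The decision problem

A diagnosed diabetic, age 30, is seen quarterly. Each quarter the
physician either orders a CKD screen (proteinuria testing plus eGFR) or
waits. Kidney health is one of ten states: Normal (eGFR ≥ 60, no
proteinuria); CKD 1 and 2 (proteinuria with eGFR ≥ 90 and 60–89); CKD 3,
4, 5 (eGFR 30–59, 15–29, < 15, each with and without proteinuria); and
death. eGFR bands are half-open on the left ( [15, 30), [30, 60),
[60, 90), [90, ∞) ), the usual KDIGO convention, so that the
(eGFR, proteinuria) → state map is a partition; this is tested at each
boundary. A patient with eGFR 60–89 and no proteinuria is *Normal*, not
latent CKD 2 — kidney-damage markers are required for a stage 1–2 label.

Waiting reveals only vital status. Screening, in the base case, reveals
the state exactly; the identity observation matrix reflects the
assumption that confirmatory testing corrects errors within a quarter. A
screen showing CKD 3+ starts treatment and ends the decision process
with a lump-sum terminal reward; results of Normal/CKD 1/CKD 2 leave the
patient in the process with their proteinuria status known. We follow
the stage-3+ stopping rule; the alternative reading (any observed CKD
stage stops the process) appears once in the published literature but
contradicts both the terminal-reward definition (states 4–9 only) and
the "repeats until … stage 3 or above" description, so it is not
implemented as a default behavior.

Rewards are net monetary benefit: NMB = λ·QALYs − costs, λ = $150,000
per QALY, discounted at 3% annually via the quarterly factor
γ = (1.03)^(−1/4). Stage rewards accrue each quarter's health value
(quarterly QALY weight × λ − quarterly state cost) under both actions;
the screening cost is the only difference between actions and is charged
immediately. Waiting would otherwise be valueless and the comparison
meaningless; the action-difference identity is asserted by a test. No
testing disutility is applied (none is established for this cheap,
noninvasive screen).

## Microsimulation

The agent-level engine advances a cohort quarterly with a fixed event
order: (1) mortality draw at the quarterly hazard of the current state
(annual hazards converted by q = 1 − (1 − p)^(1/4), the constant-hazard
assumption); (2) eGFR decline by a quarter of the annual decrement for
the agent's age band and proteinuria status; (3) proteinuria onset
(irreversible once acquired); (4) ESRD entry from CKD 5 at a quarterly
hazard (ESRD is a flagged sub-state used for case counting, not a
separate reward state); (5) aging by 0.25 years and discounted accrual
of the quarter's cost and QALY weight on the end-of-quarter state. Dead
agents accrue nothing. Treatment multiplies the eGFR decrement by
1 − 0.327, the quarterly proteinuria-onset probability by 1 − 0.55 and
the quarterly mortality hazard by 1 − 0.23. The event order is a
convention fixed for reproducibility; nothing in the source material
prescribes one.

The POMDP accrues stage rewards on the beginning-of-quarter state
(that is what the belief at *t* refers to), the microsimulation on the
end-of-quarter state (accrual follows progression in the event order).
This is a boundary-convention difference only; totals differ by one
epoch's accrual at the ends of life, not systematically.

Randomness is drawn from counter-derived substreams keyed by (cohort
seed, epoch, purpose), indexed by agent. Consequences: results are
independent of iteration order; two policies simulated with the same
seed share every natural-history draw (common random numbers), so policy
deltas are low-variance and a policy compared with itself gives exactly
zero; and health draws do not shift when screening behavior changes.

### Screening algorithm

With perfect tests the screen observes the true state (the concurrent
proteinuria + eGFR procedure). With imperfect proteinuria tests the
two-test algorithm is used: two proteinuria tests; if at least one is
positive, eGFR is measured exactly and the observed state combines the
measured band with the positive proteinuria report; if both are
negative, no eGFR is measured and the patient is reported as state 1 —
so proteinuria-negative reports can miss low-eGFR disease. The perfect
case is *not* the ε → 0 limit of the two-test algorithm (which would
never measure eGFR in proteinuria-negative patients); it is the stated
base-case assumption that the combined procedure observes the CKD stage,
and it is what makes the identity observation matrix of the solver
consistent with the simulator. Imperfect characteristics (0.76
sensitivity, 0.96 specificity per test) are a sensitivity analysis: the
policy is still solved under perfect observation and evaluated in the
imperfect world.

### Transition tensor and terminal rewards

Quarterly 10×10 transition matrices per epoch and treatment arm are
empirical frequencies from simulated untreated/treated cohorts with no
screening. Rows are normalized; the death row is absorbing; proteinuria
reversal is a structural zero (enforced, not estimated); rows visited
fewer than `min_visits` times keep an identity row and are flagged
unobserved. Identity filling is neutral but biased toward stasis — at
default scale it affects only rarely-occupied cells (e.g. CKD 5 at young
ages).

Terminal rewards R^t(s) — the value of starting treatment at epoch *t*
in state *s* — are computed by default by backward recursion over the
*treated* transition matrices:
R^t(s) = r(s) + γ Σⱼ P^trt,t(s, j) R^{t+1}(j), boundary zero. The
alternative Monte-Carlo estimator simulates treated agents from each
(epoch, state) cell and interpolates across an epoch grid. The Markov
recursion is the default because it values treated and untreated
prospects from the same family of estimated matrices: the Monte-Carlo
estimator sees semi-Markov within-band detail that the 10-state process
cannot represent, which systematically depresses R(s) relative to the
Markov continuation value and distorts the screen/wait margin. When the
Monte-Carlo estimator is used, initial eGFR is resampled from the
empirical within-state occupancy distribution of an untreated run
("occupancy"), again for consistency with the tensor; uniform-in-band
initialization is available.

Everything — stage accrual, terminal rewards, cohort outcomes — is
measured within ages 30–85: the horizon boundary reward is zero for all
states. A patient alive at 85 therefore contributes no value beyond 85
under either policy. This truncation follows from defining the model on
a fixed age range; it compresses the value of late-life screening
symmetrically across policies.

## Solver

Starting from the single initial belief, the reachable set is expanded
breadth-first over both actions and all positive-probability
observations. With perfect observation, each node is exactly a pair
(last observed state a ∈ {initial, 1, 2, 3}, epochs since that
observation), so the graph has O(3·T²/2) ≈ 7·10⁴ nodes at the full
horizon. Beliefs are deduplicated within an epoch by rounding to the
dedup tolerance (default 10⁻⁹, max-norm scale): with perfect observation
duplicates are exact and the tolerance only absorbs float noise;
grid-rounding can in principle fail to merge two beliefs straddling a
rounding boundary, which is why the tolerance is not meaningful for
aggressive merging. Backward induction then fills values per Bellman's
recursion; screen observations of 4–9 contribute the expected terminal
reward under the observation's posterior (exactly R^{t+1}(k) for a
perfect test), Dead contributes zero. Ties within 10⁻⁹ break toward
Wait, minimizing intervention at equal value. Values are kept in USD
(magnitude ~10⁶, well within double precision; the oracle comparisons
run at unit scale with 10⁻⁹ absolute tolerance).

The solver is validated against two independent oracles on randomized
processes of ≤ 4 states and ≤ 4 epochs: literal enumeration of every
history-dependent policy, each evaluated by explicit path summation
(horizons 2–3, where the policy space is enumerable), and a
history-space recursion over unnormalized state weights computed by
direct path summation (horizon 4). Neither forms beliefs, normalizes,
nor shares code with the solver.

The policy is defined only on reachable histories. When the simulated
world produces a history the model assigns probability zero (possible
only with imperfect tests or model/simulation mismatch), the policy
waits; re-rooting the solve from an arbitrary epoch/belief is possible
by constructing a spec with that initial belief.

## Synthetic parameter defaults

Values printed in the published literature are used as-is: discount 0.03,
λ = $150,000/QALY, treatment effects 32.7% / 55% / 23%, perfect
base-case tests, ages 30–85, and annual CKD-stage costs
$12,505 / $17,049 / $18,263 / $25,048 / $76,153 (stages 1–4 and
5+ESRD). The remaining inputs emulate the *structure* of the
survey-derived tables the model family uses, with magnitudes chosen once
to be clinically plausible for diagnosed diabetics:

* eGFR decrements 1.0–2.3 (no proteinuria) and 2.0–4.0 (proteinuria)
  mL/min/1.73m²/yr, rising with age band; ×1.25 for Black profiles,
  ×0.9 for women. Non-negative, non-decreasing in age,
  proteinuria ≥ non-proteinuria, Black ≥ White — all enforced and
  property-tested.
* Proteinuria onset 1–4%/yr rising with age; ×1.4 for Black profiles.
* Mortality: diabetic baseline 0.3–7.5%/yr by age band, multiplied
  1.0–3.5 by CKD severity; ×1.15 for men, ×1.08 for Black profiles.
* Quarterly QALY weights = annual utilities (0.90 Normal down to 0.56
  CKD 5 with proteinuria) / 4, no half-cycle correction.
* Initial prevalence at 30: ~90% Normal, ~7.5% CKD 1–2, ~2.5% CKD 3–4,
  none in CKD 5 or dead; Black profiles carry more baseline proteinuria.
* Screening cost $60; quarterly ESRD entry hazard 0.05 from CKD 5;
  eGFR initialized uniformly within a state's band, with open-ended
  bands capped at 120.

`sample_parameters()` jitters every default multiplicatively and repairs
the invariants, giving a generator of admissible worlds for
property-based testing.

What the generator does *not* emulate: estimation from real survey
microdata; comorbidity attributes (hypertension, smoking, cardiovascular
disease) as explicit agent state — they are implicit in the hazard and
cost schedules, mirroring the decision process, with the parameter set
as the natural extension point; kidney transplant and dialysis modality
detail; diabetes onset (all agents are diagnosed diabetics); and
calibration to registry targets. Passing tests therefore establish the
machinery — staging, simulation invariants, estimator convergence, exact
solving, evaluation accounting — not clinical magnitudes. Headline
comparisons (NMB deltas, averted cases) under these defaults are
illustrative; their published counterparts depend on appendix-level
inputs that are out of scope here.

A further structural caveat: a 10-state quarterly Markov model is an
aggregation of the continuous-eGFR process that generates it. Within-band
heterogeneity means estimated transition rows mix recent entrants with
long-dwellers, so model-optimal policies are optimal *for the aggregated
model*; their simulated advantage over the status quo at agent level is
smaller than the in-model value difference and can be near zero under
these defaults. This is the familiar hazard of Markov cohort
approximations, and it is why the package always reports simulated
policy comparisons rather than solver values alone.

## Evaluation conventions

*Screening frequency.* "Screens per person-year" restricts the
denominator to in-process person-time — alive, undiagnosed, and within
the age bin — counted over *completed* process-years (4-epoch blocks
fully in process). Partial blocks at death, diagnosis or bin edges drop
from numerator and denominator alike. Under this convention the annual
status-quo policy scores exactly 1 in every bin with person-time, which
is the anchor the comparison tables assume; realized-event accounting
with partial person-time would sit slightly above 1 because exits
mid-year strand fractional years.

*Threshold ages* ("starts screening at least every X years") use
sustained attainment: the earliest age from which every later
recommended inter-screen gap stays within the threshold, scanned from
the policy tree's Wait-run profile for an example patient whose screens
all return Normal.

*National policy form.* Age-binned frequencies (bins 30–40, 41–50,
51–60, 61–70, 71–80 by block start age) plus earliest/latest screening
ages; the earliest age is reported from realized screens in the
simulated cohort.

*Population scaling* is the linear identity
totals = population × diabetic share × Σ group-share × per-person delta.

## Sensitivity engine

Levers and levels: treatment effectiveness {0.20, 0.327, 0.40}; cost set
{base, USRDS, Honeycutt}; eGFR decrement ×{1.0, 1.1}; WTP {$50k, $100k,
$150k}; QALY-weight set {base, alternative}; test characteristics
{perfect, (0.76, 0.96)}. The USRDS set maps its aggregated "stage 4–5"
figure ($41,976) to all four stage-4/5 states and its stage 1–2 figure
to both CKD 1 and 2; the Honeycutt set has no stage-5/ESRD estimate, so
base-case costs are retained there. The alternative QALY set assigns
smaller decrements between successive stages. One-way scenarios
re-evaluate the *fixed* base-case policy and the status quo in the
perturbed world on a shared seed — the policy is solved once and
stress-tested, not re-solved (a `resolve` would answer a different
question). The simultaneous analysis draws each lever uniformly and
independently per replicate (WTP fixed at $150k), 72 replicates by
default — the size of the full level grid — with 95% normal-theory CIs
from between-replicate variation; the per-replicate cohort size is
configuration (no authoritative value exists).

## Problem sizes and tolerances in the shipped tests

The test-suite exercises the full horizon where the property demands it
(status-quo frequency, dominance checks at n = 2,000–4,000; the
closed-form kernel check at n = 100,000 on a one-year horizon) and a
31–40 age window elsewhere, with cohort sizes of a few hundred — sizes
chosen so Monte-Carlo margins (3 standard errors) are decisive while the
suite stays fast. Stochastic assertions always use seeded draws and
explicit MC-error margins; exact assertions (probability conservation,
NMB identity, structural zeros) use 10⁻¹⁰–10⁻¹² tolerances.

```{r example-pipeline}
library(ckdscreen)
params   <- default_parameters(demographic_profile("White", "Male"))
tensor   <- estimate_transition_tensor(params, n = 20000, seed = 1)
terminal <- estimate_terminal_rewards(params, tensor = tensor, seed = 1)
tree     <- solve_pomdp(assemble_pomdp(params, tensor, terminal))
evaluate_policy_pair(params, policy_from_tree(tree), n = 5000, seed = 1)
```

## Known limitations

* Ten states cannot carry within-band eGFR position; see the aggregation
  caveat above.
* Terminal rewards and transition matrices estimated at finite n carry
  sampling noise into the solver; decisions near value ties can flip
  between seeds. The default n = 10,000–20,000 keeps this small relative
  to the screen/wait margin except very near the horizon.
* Mortality, onset and decrement schedules move in 10-year age bands, so
  the policy inherits mild staircase artifacts at band edges.
* The approximate national policy is a population summary of a
  belief-based rule; individuals with unusual test histories are better
  served by the tree itself.
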