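---
title: "Models and methods behind pulseopt"
author: "pulseopt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pulseopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pulseopt)
```

`pulseopt` searches for periodic blood-flow waveforms that maximize membrane
oxygenator gas transfer while limiting hemolysis, under the actuation
constraints of a pulsatile blood pump. This vignette is the package's own
account of its models: what is computed, why the defaults are what they are,
and what the results do and do not show.

## The physical setting

Blood flowing past hollow-fiber membranes takes up oxygen until the red
cells near the membrane saturate; that saturated boundary layer is the
dominant mass-transfer resistance. Pulsatile flow disturbs the layer and can
raise the oxygen transfer rate (OTR, mL O₂ per liter of blood per pass), but
shear stress scales with flow, and shear over time lyses red cells. The
interesting regime is therefore a constrained trade-off at fixed mean flow:
the clinical operating point here is a mean of 0.9 L/min with a 0.8 s
pulsation period (1.25 Hz), and the pump can change flow by at most
0.4 L/min per 4 ms actuation interval within absolute bounds of −0.5 to
5.0 L/min.

The baseline waveform is the half-sine pulse profile (HSPP): a half-sine
systolic lobe over a fraction *s* of the period on a constant diastolic
baseline *b*. Its continuous-time mean is `m = b + (P − b)·(2/π)·s`, which
`generate_hspp()` solves for the peak *P*. The defaults `s = 0.6` and
`b = −0.4785` are the only calibration consistent with a 3.13 L/min peak at
0.24 s and a 0.9 L/min mean simultaneously; the half-sine with a zero
baseline cannot satisfy all three at once, so the negative diastolic
baseline (just above the pump floor) is an inference of the calibration, not
an independent datum. A final additive shift absorbs the sub-milliliter
discretization residual so the grid mean is exactly the target.

## The pseudo-CFD oracle

A full CFD model of the oxygenator is far too costly to sit inside a
reinforcement-learning loop, and is out of scope here. `oracle_labels()`
replaces it with an analytic surrogate of the relevant physics. With
`u_t = max(|q_t|, q_floor)` (L/min) and `dq_t` the time derivative of flow:

* transfer coefficient: `k_t = k_ref · u_t^m_exp · (1 + gamma_p · tanh(|dq_t| / a_ref))`
* per-pass saturation: `f_t = 1 − exp(−k_t / u_t)`
* instantaneous transfer: `otr_inst_t = c_art · f_t` (mL O₂/L)
* wall shear: `tau_t = c_tau · |q_t|` (Pa)
* hemolysis increment: `hem_inst_t = C · tau_t^b · dt^a` (%)

The flow-power term is a Sherwood-correlation analogy; the `tanh` term is
the boundary-layer-disruption analogy (pulsation thins the layer, with
diminishing returns); the exponential is residence-time saturation (slow
blood leaves nearly equilibrated, fast blood has less contact time). The
cycle OTR is the flow-weighted mean of `otr_inst` over samples with positive
flow — reverse flow delivers no oxygenated blood downstream but still incurs
shear — and the cycle hemolysis index is the sum of the per-step increments.
Integrating the power law per step and summing is a deliberate, monotone
simplification; mechanistic damage-accumulation models are debated even for
real devices and a training oracle only needs the right orderings.

Defaults, chosen once and frozen:

| parameter | default | units | rationale |
|---|---|---|---|
| `k_ref` | 0.5 | L/min | sets per-pass saturation ≈ 0.40 at 0.9 L/min steady flow, i.e. ~24 mL/L cycle OTR, the right clinical order of magnitude |
| `m_exp` | 0.8 | – | sublinear transfer growth with flow, so residence-time loss matters at high flow |
| `gamma_p` | 1.5 | – | maximum mixing enhancement of 2.5×; large enough that the pulsatility/tracking/smoothness trade-off has an interior pulsatile optimum |
| `a_ref` | 40 | L/min per s | the pump's achievable slew is 0–100 L/min/s; this scale makes the enhancement discriminate smoothly across that range instead of saturating for every feasible action |
| `c_art` | 60 | mL O₂/L | saturation-limited content gain per pass (venous-to-arterial content difference scale) |
| `q_floor` | 0.05 | L/min | keeps the residence-time term finite near stagnation |
| `c_tau` | 10 | Pa per L/min | puts cycle shear in the tens of pascals, where the power law is conventionally applied |

The hemolysis constants default to the widely used Giersiepen-family values
`C = 3.62e-5 %`, `a = 0.785`, `b = 2.416`. They are configurable and are not
claimed to be device-specific.

With these defaults the half-sine baseline earns ~26.7 mL/L per cycle versus
~24.0 mL/L for constant flow at the same mean — the toy physics rewards
pulsatility, which is precisely the property the learning stage must
exploit, and the property suite asserts it for every waveform family.

## Derivatives, curvature, and grids

Waveforms are one period of a cyclic signal, so `compute_features()` uses
central finite differences with periodic wraparound; one-sided boundary
stencils would put artifacts exactly where the surrogate features matter.
Curvature uses the plane-curve formula `|q''| / (1 + q'^2)^(3/2)` after
nondimensionalizing by 1 L/min and 1 s; the units convention is arbitrary
but must match between corpus generation and any later inference, so it is
fixed package-wide. `resample_profile()` interpolates linearly on the
periodic extension (bridging the 0.01 s corpus grid and the 4 ms control
grid) and re-centers the result so the mean is conserved exactly; the
re-centering shift is identically zero for integer refinements.

Inside the environment the derivative must be causal. The backward
difference `(q_t − q_{t−1})/dt` turned out to be exploitable: flow that
alternates every single 4 ms step has a large backward difference at every
point but is invisible to the periodic central difference used for
whole-cycle labelling (`q_{t+1} = q_{t−1}` makes `dq ≡ 0` — aliasing). The
environment therefore uses the one-step-delayed central difference
`(q_t − q_{t−2})/(2 dt)`: causal, consistent with the evaluation, and blind
to numerical chatter at the Nyquist period.

## The surrogate corpus and networks

The default corpus is 2000 waveforms × 80 points (dt = 0.01 s, period
0.8 s) across the five families, with target means drawn from 0.6–1.3 L/min.
Family parameter ranges are set so every normalized profile stays strictly
positive and within the pump's bounds and slew limits — a corpus with
near-zero flows would make the relative-error metric on the hemolysis label
(∝ |q|^2.416) meaningless at points where the label itself vanishes. Splits
are assigned per profile, never per time point: adjacent time points of one
waveform are near-duplicates, and a time-point split would leak them into
the test set.

Both networks are trained with AdamW (learning rate 1e-4, weight decay
0.01), MSE loss, and early stopping with best-weights restoration. Features
are z-scored on the training split. The oxygen-transfer label is z-scored;
the hemolysis label is log-transformed first, because a power law spanning
several orders of magnitude trained in raw units would concentrate all of
the MSE on the largest labels and fail the relative-error criterion at the
small ones. Inputs outside the 0.5–99.5 percentile box of the training
features are flagged as out-of-distribution at prediction time rather than
silently extrapolated, since the control loop can drive the surrogate off
the corpus.

Two practical notes on the optimizer. First, the epoch caps differ per net
(18 for the wide OTR net, 400 for the small hemolysis net) purely because
their per-epoch costs differ by orders of magnitude; both stop early on
validation stall. Second, Adam's scale-invariant step keeps parameters
wandering at learning-rate scale even on a perfectly learnable target, so
"zero" training error means ~1e-4 in normalized units, not machine zero;
tests assert accordingly.

## The environment and reward

An episode builds one pulsation period: 200 steps of 4 ms. The observation
is `[Q_t, Q_{t−5:t}, T_progress, D_remain]` (length 8): current flow, a
five-step history, normalized step index, and the normalized remaining flow
demand `(q_tar·T − Σ q_k dt)/(q_tar·T)`. The action in [−1, 1] scales the
per-step flow change and is projected onto the constraint set, so no
reachable state can violate the pump limits — the property suite fuzzes this
with 10⁴ random episodes.

The per-step reward is

`r_t = β_o·Ro + β_d·Rd + λ_a·Pa + λ_s·Ps + λ_e·Pe`

with `Ro = η_t/η_max` (instantaneous transfer over the content ceiling),
`Rd = −κ·D_t` (hemolysis increment), `Pa = −|mean of the last W flows −
q_tar|` (read as a magnitude penalty; a signed version would reward
underflow), `Ps = −(1/W)·Σ|a_k|` over the W−1 *previous* accelerations, and
a terminal penalty `Pe = −|Q_T|` when the final flow exceeds the tolerance
(applied once, at the end). The reward identity — the scalar reward equals
the weighted term sum to 1e-12 — is asserted at every step.

Choices a reader should know about:

* `η_t` is the oracle's *instantaneous* transfer at the current step,
  computed causally from the trace so far, so the reward is dense; the
  cycle aggregate is recomputed for reporting.
* `a_k` is the realized per-step flow change rate ΔQ_k/dt in L/min per
  second, which reaches ~100 at the slew limit. The smoothness weight
  default `λ_s = 0.002` is scaled to those units so the maximum smoothness
  penalty (~0.2) is commensurate with the oxygenation reward (≤ 1); a
  weight of order 0.1 in these units would make smoothness dominate
  everything and force constant flow.
* Defaults `β_o = 1`, `β_d = 1`, `κ = 10`, `λ_a = 4`, `λ_e = 1`,
  `τ_tol = 0.1 L/min`, `W = 5`, `η_max = c_art`. None of these is a
  measured quantity; they were set so that, at the defaults of the oracle,
  the reward's optimum is a moderate-amplitude pulsatile waveform tracking
  the target mean. `λ_a = 4` pins the episode mean within ~0.1 L/min of
  target for the shipped training configuration.
* The sliding window W is shared between `Pa` and `Ps`. A side effect worth
  knowing: a window mean is blind to oscillations whose period divides W,
  so the tracking penalty has a spectral notch near period-W ripple. That
  is acceptable here — the evaluation metric (flow-weighted cycle OTR) has
  the final word.

## The recurrent agent

A single 256-unit LSTM consumes the observation sequence; actor and critic
each add one 64-unit tanh layer and a linear output. The policy is a
diagonal Gaussian over a pre-squash variable with a global learned log-std,
squashed to [−1, 1] by tanh with the usual log-density correction. Entropy
regularization uses the base Gaussian entropy (the squashed entropy has no
closed form). Updates use GAE (γ = 0.99, λ = 0.95), advantage normalization
per rollout buffer, the clipped objective (ε = 0.2), value coefficient 0.5,
gradient-norm clip 0.5, and Adam at 2e-4. Minibatches are whole episodes
replayed from the episode-start hidden state, which keeps the recurrence
exact. Optimization of a buffer stops once the mean approximate KL to the
collecting policy exceeds 0.02 — without this guard, repeated epochs over a
small buffer routinely walked the recurrent policy out of the trust region
and destroyed it. The backpropagation-through-time gradients are verified
against finite differences in the test suite.

The training curriculum follows three phases expressed at a reference
1.4M-step budget and scaled linearly (the desk-scale default is 1/100:
14,000 environment steps with phase switches at 8,000 and 12,000): entropy
coefficient 0.05 / 0.03 / 0.01, and an exploration-noise cap on the policy
log-std annealed from −0.5 through −1.2 to −2.5 across the phase anchors.
The annealing is the package's reading of a curriculum that "adjusts
exploration parameters": it matters because the pulsatility reward is
symmetric in the action sign, so a noisy policy collects the mixing bonus
through its exploration noise while the deterministic mean sits at a
zero-gradient saddle. Shrinking the noise forces the mean, which is what a
deterministic readout ultimately uses, to carry the oscillation.

At desk scale even that is not enough for the mean to *discover*
oscillation from scratch within ~70 episodes, so training warm-starts the
actor head as a saturating delayed tracking law,
`u = 4·(q_tar − Q_{t−2}) + (q_tar − Q_t) + 2·(pace deficit)`, fitted by
ridge regression from the randomly initialized LSTM's hidden features
(echo-state style — the architecture is unchanged and the law is installed
in one head unit). Delayed negative feedback of this form has a limit cycle
around the target mean, so PPO starts inside the pulsatile basin and spends
its budget tuning amplitude and shape rather than escaping the saddle. The
warm start consumes three random episodes that are counted against the step
budget and recorded in the history. At the full 1.4M-step budget one would
expect the curriculum alone to suffice; the warm start is a desk-scale
concession, and turning it off (`warmstart = FALSE`) reproduces the
saddle behaviour.

The optimized profile is extracted by a deterministic rollout (action =
squashed policy mean). On the shipped configuration and seed the test suite
asserts the scaled-down analogs of the study's claims: final-phase episode
rewards exceed first-phase rewards, the extracted profile's mean flow is
within 0.1 L/min of target, and its cycle OTR is at least the half-sine
baseline's. The *magnitude* of the improvement is not asserted anywhere:
it is a property of the toy oracle, not a reproduction of bench data.

## Evaluation fixtures and statistics

`fidelity_metrics()` reports RMSE, MAE, Pearson correlation and the
coefficient of determination separately (the two are often conflated in
figure captions), plus peak delays from nearest-peak pairing within half a
period; on constant series the correlation is flagged undefined rather than
reported as a number. `simulate_bloodgas_experiment()` builds synthetic
pre/post blood-gas replicates: outlet content = inlet content + cycle OTR +
Gaussian noise, back-allocated through the content formula saturation-first
(the dissolved term takes the remainder only at 100 % saturation). That
back-allocation is a fixture convention — a bench study measures outlet
gases, it never computes them — and with zero noise the round trip through
the content formula is exact to 1e-10, which is what anchors the fixture to
the oracle. The t-test defaults to the pooled-variance Student form, the
plainest reading of an "independent samples t-test", with Welch behind a
flag; on small integer groups it is checked against the enumerated
permutation null (mid-p, since the discrete null is heavily tied). NIH
follows the ASTM normalization `ΔPFH·V·(100−Hct)/100·100/(Q·t)`.

## Problem sizes

The shipped defaults are desk-scale by design: a 2000 × 80-point corpus
(160,000 labelled samples), full-width surrogate training in minutes on one
CPU, and a 14,000-step training run (70 episodes). The corpus size is the
point where the held-out threshold accuracies plateau for these smooth
1–2 dimensional label surfaces; the training length is 1/100 of the
reference schedule with the phase structure preserved.

## Limitations

* The oracle is a caricature with the right orderings, not a validated
  gas-exchange model; nothing here transfers quantitatively to a real
  device. Absolute OTR values depend directly on `c_art` and `k_ref`.
* Hemolysis accumulation is per-step power-law summation; it ignores
  loading history and sublethal damage.
* Episodes are single cycles; multi-cycle variability, venous saturation
  feedback, and pump motor dynamics are out of scope.
* The surrogate is validated against the package's own oracle only, and
  surrogate-in-the-loop error propagation during training is not
  quantified beyond the out-of-distribution flagging.
* Waveform families keep flows strictly positive and smooth at the corpus
  grid; real pump output contains measurement noise and actuator lag that
  the generators do not emulate, so passing tests demonstrate internal
  consistency, not hardware fidelity.
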