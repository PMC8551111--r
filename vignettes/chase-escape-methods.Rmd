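---
title: "Chase-escape behavior and opponent-motion prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chase-escape behavior and opponent-motion prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chasepred)
```

## The scientific problem

In one-on-one interception, a pursuer (defender) must touch an evasive
target (attacker) despite a sensorimotor delay of several hundred
milliseconds. Compensating for that delay requires *predicting* the
target's near-future state. Two broad predictive strategies are usually
contrasted:

* **Linear extrapolation** — the target is assumed to keep its current
  velocity; the pursuer can only be *reactive* to a sudden reversal.
* **Nonlinear extrapolation through an internal model** — a learned mapping
  from the current state to the future state; this can produce
  *anticipatory* responses (reversals of the pursuer that precede, or
  follow unusually quickly, a reversal of the target).

`chasepred` implements the complete computational tool chain for studying
this question on 2-D chase-escape trajectories recorded on a bounded pitch:
behavioral statistics that diagnose anticipation, a family of learned
predictors of the attacker's next displacement, and closed-loop multi-step
evaluation — all driven by an agent-based simulator so that every stage is
testable without any recorded data.

## The task world

Two disks of diameter 1 cm move on a pitch of height 15 cm and width 7.5,
15 or 30 cm (conditions *narrow*, *square*, *wide*), both speed-capped at
5.5 cm/s, sampled at 120 Hz. The attacker starts at the top middle, the
defender at the center; the attacker tries to reach the end line behind the
defender, the defender to touch the attacker (center distance <= 1 cm). A
trial ends at a catch, an end-line crossing, the attacker leaving the
pitch, or a time limit (such censored trials are labelled `timeout` and are
excluded from outcome proportions).

The package coordinate frame puts the origin at the pitch center, X along
the width, Y along the height, end line at Y = -height/2. Velocities are
stored as cm per sample interval (the models operate on per-step
displacements; multiply by the rate for cm/s).

## Behavioral statistics

All event-level analyses run on the raw 120 Hz data:

* **Directional change**: the X velocity crossing zero. A zero sample
  inherits the previous nonzero sign, so "touching" zero is not an event;
  an event requires a strict sign flip. This avoids double counting
  numerical jitter at rest, and makes consecutive events of one agent
  alternate in sign by construction.
* **Response time**: for each attacker event, the earliest unmatched
  defender event of the *same* sign within [0, 500] ms (greedy, one-to-one
  matching in time order; responses beyond 500 ms are treated as given-up
  pursuit and dropped). Responses faster than 150 ms are classified
  **short-latency** (anticipatory) — 150 ms being the empirical lower bound
  of simple visuomotor reaction.
* **Change ratio**: total defender events over total attacker events, per
  defender participant. A purely reactive defender can at most answer each
  attacker event once, so the ratio cannot exceed 1; erroneous
  anticipatory reversals push it above 1.
* **Spatial statistics**: the pitch is divided into 4/8/16 equal-width X
  columns (constant 1.875 cm column width across conditions); per column we
  report occupancy time, event counts and events per second of occupancy.
  Columns never visited are flagged missing and excluded from summaries.
  The same logic is available binned by interpersonal distance (default
  1 mm bins).
* **Heading-change entropy** runs at 20 Hz (50 ms steps, closer to the
  timescale of human perception): per step, the signed change in movement
  direction, wrapped to (-180, 180] with counterclockwise positive, is
  histogrammed at 5 degrees (72 bins) and summarized by Shannon entropy in
  bits. Base 2 is a package convention; the comparisons are ordinal, so
  the base only scales values.
* **Inter-switch intervals**: within-trial intervals between attacker
  events. A memoryless (Poisson) switching process has an exponential
  interval tail; we fit the tail beyond 0.5 s (past the refractory-induced
  mode) by maximum likelihood. When trial end times are supplied, the open
  interval from the last event to the trial end enters as right-censored
  exposure — ignoring that censoring biases the rate upward, which matters
  for trials only a few mean intervals long.
* **Speed saturation**: the fraction of samples above 90% of the speed cap.
  In data of this kind it exceeds 90% for both agents, which is what
  licenses the focus on movement *direction* rather than speed.

## Predictors of opponent motion

All models predict the attacker's displacement over the next 50 ms step
from the 6-vector state `x_t = (v_a, v_d, r)`: attacker velocity, defender
velocity, and the range vector from defender to attacker. Inputs carry no
explicit information about the walls and no accelerations.

Parameter-free baselines:

* **L** (linear): repeat the latest displacement.
* **C** (curvilinear): rotate the latest displacement by the latest angular
  change (constant speed and turn rate, i.e. a circular arc). For
  collinear context C coincides with L exactly.

Networks share a three-weight-layer skeleton 6 → 64 → 128 → 5 and differ in
the middle: **LN** all linear; **NN** ReLU; **RNN** a tanh recurrence at
width 128; **LSTM** an LSTM cell in the same position; **DNN/DRNN/DLSTM**
insert a second 128-wide hidden layer of the same type. Prose
descriptions of this architecture family leave the recurrent wiring
ambiguous; we keep the common three-layer skeleton and place the
recurrence in the middle layer, the reading consistent with all other
kinds.

The 5-vector head output parameterizes a bivariate Gaussian over the next
displacement via `mu = (h1, h2)`, `sigma = exp(h3, h4)`, `rho = tanh(h5)`
(the transform used by the pedestrian-trajectory literature this
architecture descends from; it guarantees a valid density for any real
head output). Training minimizes the negative log-likelihood of observed
displacements with Adam at learning rate 3e-4 and batch size 16 — adopted
constants, not tuned here. Feedforward kinds batch over shuffled
time-steps; recurrent kinds batch over shuffled trials with full-sequence
unrolling, zero initial state per trial, and right-padding masked out of
the loss. Epoch count is not an adopted constant; the package default is
100 with the lowest-training-NLL epoch retained (no validation data is
taken from the held-out participant). All analytic gradients — the
Gaussian head and every layer's backward pass, including backpropagation
through time — are verified against central finite differences in the test
suite.

Evaluation proceeds in two regimes:

* **One-step**: the Gaussian mean is the predicted displacement; predicted
  and actual displacements are converted to directions relative to the
  pursuer (0 = straight at the pursuer, positive = left) and compared by
  absolute wrapped angular error. Steps are stratified by the actual
  heading change: straight (< 20 degrees), gentle curve (20-60), sharp
  curve (> 60).
* **Rollout**: closed-loop sequential prediction up to 5 steps (250 ms):
  the predicted displacement is fed back as the attacker-state input, while
  defender inputs are read from the recorded defender trajectory (own
  state assumed known up to 250 ms ahead via the internal model of one's
  own motion). Recurrent kinds first warm their hidden state on 2.5 s
  (50 steps) of observed inputs. Errors are Euclidean distances to the
  actual positions: ADE (mean over horizons) and FDE (final horizon).
  Rollouts start at every step with sufficient context (a start-step
  stride is available purely as a compute knob) and never cross trial
  boundaries.

Evaluation is by **leave-one-participant-out cross-validation** over
defender participants: train on all others, evaluate on the held-out one;
summaries are mean ± s.e.m. across held-out participants. With a single
fold the s.e.m. is reported as `NA` rather than 0.

## The synthetic world

`simulate_trialset()` generates trial sets with the statistical structure
the analyses assume, so that a green test establishes the *pipeline*, not
any fact about human behavior:

* The **attacker** is heading-controlled at 95% of the speed cap (joystick
  tilt maps to velocity, so velocity control is the faithful abstraction).
  It runs toward an aim point just beyond the nearer side wall at the end
  line; its lateral sign reverses as a memoryless Bernoulli hazard outside
  a hard 0.45 s refractory window (producing the secondary interval mode
  near 0.5 s). An outward run turns back at a randomized turn point, after
  a committed near-vertical "dive" of exponential mean duration; this pair
  of mechanisms is what makes switch frequency per unit occupancy time
  flat across pitch columns, as in the data the simulator emulates (a
  fixed wall-margin turn would concentrate switches, and hence switch
  frequency, in the outermost columns). A `descent` parameter caps the
  vertical heading component; per-condition reference values make narrow
  trials fast and direct and wide trials shallow and long.
* The **defender** perceives the attacker's state with a pure 250 ms delay
  and linearly extrapolates it. Laterally it matches the perceived
  attacker velocity plus a proportional position correction (with a small
  hysteresis band so it does not dither the stick around zero); vertically
  it guards a 1.4 cm buffer below the attacker, retreating as the attacker
  advances, and lunges once laterally aligned and vertically close.
  Commands are low-pass filtered (~60 ms) and perturbed by AR(1) angular
  noise (~100 ms correlation time): white per-sample noise would flip the
  X-velocity sign many times whenever it sweeps through zero, creating
  spurious direction-change events no human joystick produces.
  Anticipation is modelled phenomenologically: with some probability per
  attacker reversal the defender pre-empts it at a latency drawn uniform
  on [0, 150) ms, and independent "false alarms" (brief, self-corrected
  reversals) occur at a low rate — the latter are what push the change
  ratio above 1. This is a stand-in for testing the analysis, not a
  cognitive model.

Reference configurations (`reference_configs()`) freeze one calibration of
these parameters per condition such that heading-change entropy,
short-latency proportion and change ratio are each ordered
narrow > square > wide, speed saturation exceeds 0.9 for both agents, and
mean durations order narrow < square < wide. The calibration was performed
once against those qualitative orderings and is not revisited by tests.

What the generator does **not** emulate: strategic adaptation between
opponents, fatigue or learning across trials, the true distribution of
human anticipation (no quantitative rate is available to target), or
out-of-bounds escapes (the simulated attacker's wall avoidance makes the
`out_of_bounds` outcome essentially unreachable). Green tests therefore
establish correctness of detection, matching, information-theoretic and
model-evaluation machinery on data with the *stated* structure — not
reproduction of human descriptive statistics, which require ingesting the
deposited experimental data through the CSV adapter.

## Numerical choices and edge cases

* Event time is the time of the first velocity sample carrying the new
  sign; event location is the agent's position at that sample.
* Downsampling is decimation (keep every k-th sample), not averaging, so
  consecutive 20 Hz samples are exactly 50 ms apart.
* Zero-speed steps are skipped (and counted) in heading analyses; zero
  displacements make relative direction undefined (`NA`, with a warning).
* The curvilinear model defines the turn angle as 0 when the earlier
  displacement vanishes and returns the current position when the latest
  displacement vanishes.
* The interval-tail MLE is `n / total exposure`, with right-censored
  exposure from trial ends when available; fewer than 10 tail intervals
  set a `low_confidence` flag.
* A defender-participant grouping averages per-participant proportions
  (equal weight per participant, matching mean ± s.e.m. reporting), not
  pooled events.
* Where the attribution of a response location is ambiguous (defender's
  vs. attacker's position), the package uses the defender's own position
  at its change event and also stores the attacker-side position in the
  response record.
* Spec'd interface examples use YAML-ish config files; this implementation
  uses JSON (`jsonlite`), the equivalent structured format available here.

## Worked example

```{r example, eval = FALSE}
library(chasepred)

ts <- simulate_trialset(reference_configs("square", n_pairs = 4,
                                          trials_per_pair = 25))
behavior_summary(ts)

spec <- model_spec("NN", epochs = 20, seed = 1)
folds <- loo_cv(spec, ts, max_folds = 2, rollout_stride = 5)
aggregate_folds(folds)
```

The README shows the numbers this prints on the package authors' machine;
all quantitative claims above are recomputed by the test suite
(`tests/testthat/`, in particular `test-acceptance.R`).

## Known limitations

* Training is pure R; it is fast enough for the package's scaled analyses
  (a 20-epoch NN fold on ~20k steps takes ~20 s on one CPU) but not for
  large hyperparameter sweeps — which are out of scope anyway (the
  learning rate and batch size are adopted constants).
* Narrow-condition reference trials are short (~2 s), so recurrent-model
  rollouts (which need 2.5 s of warm-up) find few valid start points
  there; square/wide sets are the right substrate for rollout studies.
* The figshare ingestion command is a documented stub: the deposit's file
  layout is not machine-readable from the publication, so the adapter
  must be written against the actual download (convert to the package's
  CSV + JSON-manifest dialect and use `read_trialset()`).
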