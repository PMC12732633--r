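---
title: "Adaptive cognitive training in cogadapt: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive cognitive training in cogadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogadapt)
```

`cogadapt` implements the computational core of an adaptive cognitive
intervention for older adults — difficulty adaptation, ability tracking,
cognitive-load monitoring, persona coordination, safety rules, protocol
scheduling and instrument scoring — together with a participant simulator
that lets the full six-week feasibility protocol run end-to-end on
synthetic data. This vignette explains the models, the parameters that
matter, the numerical choices, and what the simulated results do and do
not show.

## The adaptive engine

### Success model

Task success is modeled with the two-parameter logistic (2PL) of item
response theory:

$$P(\text{success}\mid\theta, b) = \frac{1}{1 + e^{-a(\theta - b)}}$$

with ability $\theta$ and difficulty $b$ on a common logit scale and
discrimination $a > 0$. The model is strictly increasing in $\theta$ and
strictly decreasing in $b$; at $\theta = b$ success is exactly 50%.

### Difficulty control

After each trial the difficulty moves towards the level that would hold
the modeled success probability at the target $P^\* = 0.85$ (the
optimal-challenge target: high enough success to protect self-efficacy,
enough failure to preserve challenge):

$$b_{t+1} = \mathrm{clip}_{[b_{\min}, b_{\max}]}\big(b_t + \eta\,(P_t - P^\*)\big)$$

When $P_t$ equals the target, $b$ is an exact fixed point. The
deterministic fixed point of the coupled system is
$b^\* = \theta - \mathrm{logit}(P^\*)/a$, i.e. difficulty settles about
1.73 logits below ability at the defaults, where the true success
probability is 85%.

$P_t$ here is the **model probability** computed from the current
smoothed ability estimate, not the realized 0/1 outcome. Both readings
are defensible; the model-probability form gives the update the
deterministic fixed point written above, whereas the outcome form turns
the update into a noisier stochastic approximation of the same target.
The outcome form remains available via
`difficulty_policy(update_from_outcome = TRUE)`.

### Ability estimation and smoothing

$\hat\theta_t$ maximizes the Bernoulli 2PL log-likelihood of the recent
(difficulty, outcome) history over $[\theta_{\min}, \theta_{\max}]$
(`stats::optimize`, tolerance 1e-6; the log-likelihood is concave in
$\theta$, so the interior maximum is unique). All-correct and
all-incorrect histories have no interior maximum and return the upper or
lower bound. The running estimate is then exponentially smoothed,

$$\theta_{t+1} = \lambda\,\theta_t + (1 - \lambda)\,\hat\theta_t,$$

which keeps the estimate between its previous value and the fresh MLE
and damps day-to-day variability.

### Cognitive load

Per-trial load is the weighted composite

$$L = w_1\,\max\!\Big(0, \frac{t_{\text{resp}} - \bar t_{\text{base}}}{\bar t_{\text{base}}}\Big) + w_2\,e + w_3\,\sigma^2,$$

clipped to $[0, 2]$, with default weights $(0.4, 0.35, 0.25)$ that
prioritize processing speed, the dominant mediator of age-related
performance change. Two choices are worth flagging:

- The response-time deviation is floored at zero: faster-than-baseline
  responses indicate spare capacity, not negative load, and the metric's
  declared floor is 0.
- $\sigma^2$ (attention variance) is supplied by the logger/simulator as
  the variance of normalized within-session inter-response intervals;
  the metric itself does not prescribe its estimator.

The baseline $\bar t_{\text{base}}$ is the mean response time of the
participant's first completed (calibration) session and is frozen
thereafter, so later slowing registers as load rather than silently
re-normalizing.

Load values are banded (`classify_load`) at 0.5 and 1.2 — plumbing
constants for strategy selection (the boundary goes to the upper band),
not clinically validated thresholds.

### Parameter defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| $P^\*$ | 0.85 | probability | optimal-challenge target; a design constant of the intervention |
| $w_1, w_2, w_3$ | 0.4, 0.35, 0.25 | — | load weights; design constants |
| $a$ | 1.0 | — | logit scaling convention; $a$ is not estimated from data |
| $\eta$ | 0.5 | logits/unit | one step moves at most 0.5·|P−P*| ≈ 0.08 logits: fast enough to track, small enough not to oscillate |
| $\lambda$ | 0.8 | — | estimate half-life ≈ 3 trials of MLE innovations; favors stability |
| $b$ range | [−3, 3] | logits | covers success probabilities ≈ 5–95% for a median learner |
| $\theta$ range | [−4, 4] | logits | wider than $b$ so boundary estimates stay representable |
| MLE window | 100 trials | trials | see below |

**Why a 100-trial window.** The estimation window must be long enough
that degenerate (all-correct) histories are rare: at the 85% success
target an all-correct window of length $n$ occurs with probability
$0.85^n$, which is ≈ 0.20 at $n = 10$ but ≈ 9×10⁻⁸ at $n = 100$. Because
degenerate windows pin $\hat\theta$ to the ±4 bound, a short window
injects large, asymmetric jumps into the smoothed estimate and biases
the whole control loop off its target: in simulation a 10-trial window
drives the long-run success rate to ≈ 0.81 with an ability estimate
drifting more than two logits high, while a 100-trial window (about
three sessions of recent performance — still "recent" on the time scale
of day-to-day variability, whose tracking is anyway delegated to the
$\lambda$-smoothing) holds the loop at ≈ 0.845–0.85 across seeds. The
window remains configurable (`difficulty_policy(mle_window = )`).

## Persona coordination

Routing is a total deterministic function of the event kind: activity
planning → coach, cognitive task → teacher, emotional cue → companion;
in single-agent fallback mode every event goes to the fallback persona
(companion by default). Fallback is entered when a week's
agent-recognition answers are majority-incorrect or the participant
prefers fewer agents — the majority rule is this package's decision; the
protocol defines the question but not the decision rule.

Conflicting action proposals are resolved by a fixed
safety-conservative total order (rest < suggest_break < empathize <
encourage < remind < train < suggest_activity; lower is chosen), with
ties broken by persona order then action name so the outcome is
invariant to proposal order. A staff alert fires when two proposals form
a declared contradiction pair; the default set is
{activity × break, train × rest, activity × rest}, covering the
canonical conflict of one persona urging activity while another detects
fatigue. Both the order and the pair set are config-overridable — the
safety-conservative *principle* is the constraint, the particular order
is an engineering choice.

The conversational context is a strict FIFO window of the 5 most recent
utterances. Reminders escalate visual → auditory (+15 min) → haptic
(+30 min); a logged response cancels the tiers at or after it. The
valence–arousal emotion state is tracked with a componentwise EWMA
(rate 0.3, clipped to [−1, 1]); the protocol names the valence–arousal
representation but no update law, so a deliberately simple one was
chosen. A teacher session opening under negative valence starts
Δb = 0.5 logits easier.

## Safety monitoring

Discontinuation rules are exact window scans: negative affect ≥
baseline + 1.5 SD on two *consecutive* weekly assessments (flag at the
first week completing the run), and fatigue ≥ 7/10 on three consecutive
completed sessions. Two underdetermined points were resolved as
follows: a skipped session *breaks* a fatigue run (the rule reads
"consecutive sessions", and counting across gaps would conflate
non-attendance with sustained fatigue); and the baseline SD for the
affect rule is caller-supplied — the cohort-level baseline by default in
the simulator — because nothing in the protocol fixes
individual-versus-cohort baselines.

The response filter honors a block + fallback + notify contract: any
candidate response matching a configured pattern category (medical
advice, financial guidance) is replaced verbatim by the fixed fallback
message and raises a `blocked_response` alert. Pattern matching is a
deliberate stub for semantic plausibility checking, which is out of
scope; the contract, not the classifier, is what downstream code relies
on. Fidelity sampling draws round(0.10·N) logs (half-away-from-zero,
minimum one) without replacement, reproducibly under a seed and without
disturbing the caller's RNG stream. Every alert carries a contact
deadline exactly 24 h after it is raised.

## Protocol and instruments

The schedule places `weeks × sessions_per_week` slots on consecutive
weekdays starting the Monday on or after the start date (the protocol
fixes counts, not a weekday pattern; Monday–Friday is the natural
reading of five sessions per week). Cognitive blocks anchor at 09:00 and
social blocks at 15:00, a circadian morning/afternoon rule with the
anchors as config constants. Defaults give 30 sessions and 900 minutes.

Adherence metrics: completion rate = 100·completed/scheduled; mean
duration over completed sessions only (reported as absent, not zero,
when nothing was completed — a 0 would be indistinguishable from
instant sessions); task completion from terminal trial status;
per-persona user-initiated interaction counts; and the least-squares
slope of per-session mean response latency. Feasibility passes iff
completion ≥ 70%, SUS ≥ 70, and no sustained-negative-affect
discontinuation; the check is monotone in each criterion.
`enrollment_size(k, r)` returns the smallest n with
floor((1−r)·n) ≥ k — 14 enrolled for 12 completers at 10% attrition.

Instrument scoring uses the published rules (SUS odd/even items scaled
×2.5 to 0–100; PANAS 10+10 sums; BPNS 7/6/8 subscale means with 6−x
reversal; UEQ-S items −4 to a −3..+3 scale, 4+4 pragmatic/hedonic;
MDPQ-16 item mean × 8; CARS item mean). Every item-to-subscale map and
reversal set is an argument with the published default, so
population-specific variants are data, not code. The BPNS reversal set
defaults to empty because the protocol does not identify the reversed
items for its translation.

## The participant simulator

The simulator emulates exactly the population the protocol describes,
with one latent learner per participant:

- **Responses**: Bernoulli draws from the *same* 2PL the engine assumes
  — deliberately well-specified so parameter-recovery tests have a true
  value to recover. A guessing floor (`guessing = 0.1`) is available as
  a misspecification probe.
- **Ability drift**: a Gaussian random walk across calendar days
  (day_sd = 0.1 logits/day by default); the protocol motivates
  day-to-day variability but prescribes no process, and a random walk
  is the minimal model with that property.
- **Response times**: lognormal (median 2.5 s, shape 0.4 — typical
  item-response latencies for older adults on simple cognitive tasks),
  inflated multiplicatively by within-session fatigue. Each trial also
  consumes a 60 s presentation overhead, giving ≈ 28 trials per
  30-minute session.
- **Affect**: weekly PANAS-NA follows an AR(1) around baseline 15 with
  SD 4 and autocorrelation 0.5, clipped to the 10–50 instrument range.
  With the 1.5 SD threshold this puts ~7% of participant-weeks above
  threshold, so sustained-elevation flags occur in a minority of
  cohorts — the safety rules are exercised, not vacuous.
- **Adherence**: sessions are skipped independently with probability
  0.1; with probability 0.10 a participant drops out from a uniformly
  drawn mid-study week onwards. Expected completers for n = 14 are
  12.6.
- **End-of-study instruments**: SUS responses are generated from a
  latent usability score ~ Normal(75, 10) — a plausible mean for a
  carefully onboarded cohort, chosen once, not fit to anything.

A single global RNG (one `set.seed` per cohort run) makes entire cohort
runs — logs, instruments, verdicts, serialized files — byte-reproducible
from the seed.

**What passing simulations do and do not show.** They show the control
loop is correct: the difficulty update holds a stationary 2PL learner
at the 0.85 target, the estimator recovers the generating ability in
expectation, and the protocol/safety arithmetic is exact. They do not
show that real older adults behave like 2PL learners, that real
response times are lognormal, or that the load weights are clinically
optimal — those are exactly the questions the real feasibility study
exists to answer.

## Numerical choices and degenerate inputs

- The MLE search uses golden-section `optimize` (tol 1e-6) on a concave
  log-likelihood; tests verify agreement with a two-stage exhaustive
  grid (resolution 1e-4) to within 1e-3 on histories up to 20 trials.
- Degenerate histories (all correct / all incorrect) return the ability
  bound exactly, not a large finite value.
- `update_difficulty` clips *after* the step, so the bound is attained
  exactly (a 2.99 + 0.075 step yields 3.0, not an error).
- Sample sizes for fidelity sampling round half-away-from-zero (base R
  `round` is half-to-even, which would take 10% of 15 to 1, not 2).
- Enrollment arithmetic adds a 1e-9 slack inside `floor` to absorb
  binary-representation error in (1−r)·n.
- Load-band boundaries assign the cut value to the upper band; ties in
  conflict resolution are broken deterministically (persona order, then
  action name).

## Problem sizes in the test suite

The shipped tests run the tracking loop for 5,000 trials, the recovery
check at 20 replicates × 200 trials, the estimator-versus-grid and
discontinuation-versus-scan oracles at 1,000 random cases each, and one
full 14-participant × 6-week cohort twice (for byte-identity). These
sizes give stable Monte-Carlo margins for every asserted tolerance
while keeping a full suite run in the low minutes on one core.

**Recovery is asserted in expectation.** At the 0.85 operating point the
per-trial Fisher information is $a^2 P(1-P) \approx 0.1275$, so 200
trials bound any unbiased estimator's SD below by
$1/\sqrt{200 \times 0.1275} \approx 0.198$ (Cramér–Rao). Individual
200-trial replicates therefore *cannot* all land within ±0.2 of the
truth; the meaningful 200-trial recovery statement — and the one the
test makes — is that the estimator is unbiased: the mean smoothed
estimate across 20 seeded replicates lands within ±0.2 (measured bias
≈ +0.02).

## Known limitations

- The discrimination parameter $a$ is fixed, not estimated; there is no
  multidimensional IRT and no item bank — difficulty is a continuous
  scalar.
- The response filter is pattern-based; it honors the blocking contract
  but is not a content classifier.
- Utterance payloads are canned templates; no language generation or
  speech processing of any kind is included.
- Scheduling uses naive local dates: no time zones, no makeup sessions
  (the protocol is silent on both).
- MMSE, TMT and Digit Span enter only as opaque recorded totals; their
  item content is out of scope.
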