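---
title: "Models and methods behind marmopull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind marmopull}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marmopull)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the choices made where the design was
genuinely open, and what the synthetic-data tests do and do not establish
about real recordings.

## The task and its contingencies

Two marmosets sit in adjacent enclosures, each with a lever. A pull
registers when the lever position passes a positional threshold read from
a potentiometer. Two contingencies exist:

* **Self-Reward** — every registered pull earns the pulling animal a small
  liquid reward (default 0.1 ml) at pull time, fully independently across
  the two animals.
* **Mutual Cooperation** — a pull pair, one per animal, with
  leader-to-follower latency inside the cooperation window (final stage
  1 s; training staircases through 3, 2, 1.5, 1 s) triggers a tone at the
  follower's pull time and one larger reward (default 0.2 ml) to *each*
  animal after a fixed delay (default 1 s). Unpaired pulls earn nothing.

`run_session()` applies these rules to pull events or to a raw lever
trace. Rewards whose delivery time lands past the session end are still
logged at their scheduled time and counted in an `n_truncated_rewards`
attribute, since a real pump would already be committed.

### Pull detection

`detect_pulls()` timestamps a pull at the *first* sample at or above the
threshold — the observable a real-time controller reacts to — rather than
at the position peak. A two-threshold hysteresis (re-arm at
`rearm_fraction × threshold`, default 0.5) prevents sensor noise that
wobbles around the threshold from registering chatter pulls; the
re-arm rule is this package's choice, since the apparatus description
does not define when a lever may register its next pull.

### Pairing policy

Overlapping pull sequences admit several defensible matchings. The
implemented rule is greedy, chronological and one-to-one: scanning pulls
in time order, an unmatched pull becomes the follower of the *earliest*
unmatched opposite-animal pull within the window; matched pulls are
consumed. This is the simplest policy a causal real-time controller can
implement, and it is what the conservation law `2|pairs| + |unpaired| =
|pulls|` and the window-monotonicity property are tested against (an
alternative latest-leader preference is selectable). Boundary choices,
also deliberate: the window is closed (latency exactly `w` succeeds),
simultaneous pulls designate M1 as leader with latency 0, and no
refractory period follows a reward (the task is unconstrained; a lockout
parameter exists, default 0).

## The dyadic agent model

No behavioral model accompanies the original apparatus; the simulator's
leader–follower point process is the minimal generative structure that
spans chance-level to proficient cooperation:

* spontaneous pulls: Poisson with rate `base_rate_hz`, optionally decaying
  with half-life `motivation_halflife_ms` (waning motivation);
* responses: each *spontaneous* partner pull is answered with probability
  `respond_prob` after a latency drawn from a uniform or exponential
  distribution. Responses do not trigger responses, so there is no echo
  chain and `respond_prob` stays interpretable as a per-opportunity
  answer rate.

Expected dyadic pulls per session are `(1 + p)(b1 + b2)T`. The shipped
presets fix `b1 = 0.06` Hz, `b2 = 0.0185` Hz and latency uniform on
[100, 700] ms; with `p = 0.55` (proficient) this gives ≈146 pulls per
20-minute session — the throughput regime reported for real automated
dyads — with success rate ≈0.7, while `p = 0.10` (naive) gives ≈103
pulls at success ≈0.25. The asymmetric base rates encode a common
leader/follower role division. These presets were fixed analytically from
the target regime, once, and the tests assert them.

Parameter recovery is validated in the one-sided design (`b2 = 0`,
follower only responds): paired followers divided by leader pulls is then
an exactly binomial estimate of `respond_prob`, and the suite checks
recovery inside the pooled binomial 95% CI for p ∈ {0.2, 0.5, 0.8}.

### Synthetic lever traces

`synthesize_lever_trace()` renders each pull as a short excursion: a
sub-threshold approach ramp (≤ 0.7 × threshold), an overshoot to 1.6 ×
threshold whose first suprathreshold sample sits at the pull time (±½
sample), and a linear decay back through the re-arm level, plus Gaussian
sensor noise (default SD 1% of threshold). The margins are many noise
standard deviations wide by construction, which is why the round-trip
guarantee — detection recovers every pull within one sample period, F1
= 1 — is testable at scale. Pulls packed tighter than the excursion
footprint are compressed with a warning; generators in the tests keep
≥ 200 ms spacing, matching plausible motor constraints.

## Gaze from six facial keypoints

Markerless trackers provide six 3D points per head: two ear tufts, two
eyes, central blaze, mouth (world frame, cm; coordinates are assumed
right-handed). The face plane is fit through the eyes and the blaze —
the only forehead-region marker among the six — and gaze direction is
the plane's outward unit normal with origin at the eye midpoint. The
normal's sign is set to point away from the ear-tuft midpoint (ears lie
behind the face plane), falling back to the mouth side (the template
mouth sits slightly anterior) when both ear tufts are missing; with
neither cue the frame is invalid with a reason, never an error.

A target is gazed at when it lies in front of the face and within a
closed cone about the axis. The quoted 15° "solid angle" is dimensionally
a cone aperture, read here as the **half-angle** (the apex-angle reading
is selectable via `angle_interpretation`). Per frame the label is the hit
target nearest in angle; the partner target is the partner's per-frame
eye midpoint when partner poses are available, else a fixed point.

Bouts are maximal single-target runs bridging gaps of at most 1 frame,
kept at ≥ 3 frames (≈100 ms at 30 fps) — invented defaults, exposed as
parameters, chosen so a single dropped frame does not split a fixation.
Because whether one should count bouts or frames is itself a judgment
call, `gaze_target_counts()` reports both.

**Sensitivity to keypoint noise.** The plane is fit to three points
roughly 1–1.6 cm apart, so the normal's angular error grows quickly with
keypoint jitter: at 0.05 cm isotropic noise recovery of scripted gaze
targets stays above 95% with the default cone, but at 0.2 cm the normal
wanders ≈10° RMS and roughly half the frames leave a 15° cone. Keypoint
pipelines feeding this analysis should deliver sub-millimeter
post-triangulation precision, or use a wider cone.

## Peri-event analyses

`align_events()` counts points per trial in sliding bins (defaults:
150 ms bins, 50 ms steps — the published geometry — over ±5 s; the
window extent is not printed anywhere authoritative, so it is a
parameter). Bins are half-open `[lo, hi)`: a point exactly on a boundary
belongs to the bin whose left edge it is. Trials whose window leaves the
recording are kept and flagged (droppable via `drop_partial`). PSTH rates
are counts divided by the bin width in seconds, events/s, averaged across
trials with s.e.m. = SD/√n (0 by convention for a single trial).

`compare_conditions()` runs a two-sided Wilcoxon rank-sum test per bin on
the per-trial counts. Counts are heavily tied, so the implementation is
tie-aware throughout: for small samples (both groups ≤ 10, total ≤ 20)
the p-value is the exhaustive permutation tail of the rank-sum statistic,
which is exact even under ties; otherwise the tie-corrected normal
approximation (no continuity correction; verified against
`wilcox.test(correct = FALSE)`). All-equal bins give p = 1. Significance
is marked at uncorrected p < alpha (default 0.05), matching the
conventional per-bin marking of PSTH figures; a Benjamini–Hochberg
option exists but is off by default. A consequence worth stating
plainly: with ~40 bins per window, a handful of isolated significant
bins is expected under the null, so localization claims should rest on
runs of significant bins inside a hypothesized window, which is how the
package's own tests phrase them (power ≥ 0.9 inside an injected
elevation, marking rate ≈ alpha elsewhere).

## Data formats and determinism

All interchange is UTF-8 CSV with mandatory headers and integer
milliseconds from session start (millisecond precision is the stated
resolution of the apparatus; exact integer arithmetic avoids float
drift). The event stream (`t_ms, actor, kind, value, ref_id`) is the
normative serialization of a session; pulls and cooperation pairs are
recoverable from it, and writers emit canonical formatting so write∘read
is byte-identical. Validation is total — a reader returns a fully valid
object or raises a typed error naming the offending line and column.
Keypoints below the confidence threshold (default 0.6; tracking
pipelines filter by likelihood without a published cutoff) are kept as
explicitly missing, never interpolated.

Every stochastic function takes an explicit seed and restores the
caller's RNG state; `run_demo()` derives all stage seeds from one master
seed and writes a manifest with the seed, configuration and tool version
— deliberately no wall-clock timestamp, so identical seeds produce
byte-identical output trees.

## Problem sizes used in the test-suite

The suite validates against independent oracles at sizes chosen to make
the checked properties sharp yet quick to regenerate: 1,000 random pull
sets (≤50 pulls) against the exhaustive pairing oracle; 500 synthesized
traces for detection round-trips; 100 random logs against a 1 ms
grid-scan of working time; 50 sessions per response-probability level for
parameter recovery; 1,000 random rigid transforms for gaze invariance;
and 500 null replicates (49 trials per condition, a typical per-session
trial count) for the rank-sum false-positive calibration, which lands at
the nominal 0.05.

## Known limitations

* The simulator is a point-process caricature: no satiety dynamics beyond
  exponential rate decay, no turn-taking strategy, no learning within or
  across sessions. Passing tests demonstrate the *analyses* are correct
  on data with known structure, not that real marmosets behave like the
  model.
* Head direction is the gaze proxy (as in the underlying tracking
  approach); eye-in-head rotation is not modeled, and the partner target
  is a point, not a volumetric head.
* The engine is an offline reference implementation of the contingency
  logic, not a real-time controller: servo control, force calibration and
  hardware I/O are out of scope.
* Spike sorting, call detection and 2D→3D triangulation are consumed as
  inputs (spike times, call times, keypoints), never performed.
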