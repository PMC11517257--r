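# marmopull

Cooperative lever-pulling sessions for marmoset dyads, in software: the
task's reward contingencies, a generative dyad simulator with known ground
truth, and the analysis stack used to quantify such sessions — performance
metrics, 3D gaze-cone target classification, and event-aligned peri-event
time histograms with bin-wise rank-sum comparison.

## Who this is for

Automated dyadic pulling setups let two animals earn rewards either
independently (*Self-Reward*: each pull earns that animal 0.1 ml) or only
by coordinating (*Mutual Cooperation*: pulls by both animals within a 1 s
window trigger a tone and deliver 0.2 ml to each animal 1 s later).
`marmopull` is for researchers building or analyzing such paradigms who
need (i) a reference implementation of the contingency logic, (ii) fully
synthetic sessions with known generative parameters to validate analysis
code before any animal data exist, and (iii) the standard analyses in one
tested place.

## The model and statistics

**Pull detection.** A pull registers when the lever position first passes
the positional threshold; the lever re-arms only after returning below
`rearm_fraction × threshold` (two-threshold hysteresis).

**Cooperation.** Pulls are paired greedily in time order: a pull becomes
the *follower* of the earliest unmatched opposite-animal pull within the
window `[0, w]` (w = 1000 ms at the final training stage; the staircase
3 s → 2 s → 1.5 s → 1 s is expressible through `coop_window_ms`). Each
pull joins at most one pair. Success rate = successful pulls / all pulls
= `2·|pairs| / |pulls|`; 50% is the customary proficiency bound.

**Dyad simulator.** Each agent pulls spontaneously as a Poisson process
with rate `b` (optionally decaying with a motivation half-life) and
answers each spontaneous partner pull with probability `p` after a random
latency. Expected pulls per session ≈ `(1+p)(b₁+b₂)T`; the shipped
presets put a proficient dyad near 146 pulls / 20 min with success rate
above 0.5, and a naive dyad below it.

**Gaze.** Per video frame, the face plane is fit through the two eyes and
the blaze (forehead) marker; gaze direction is the outward unit normal,
and a target (partner head, lever, juice tube) is "looked at" when it
falls inside a closed cone of half-angle 15° around that axis. Runs of one
target are segmented into bouts (≥ 3 frames, bridging 1-frame gaps).

**Peri-event analysis.** Point events (calls, spikes) are aligned on task
events and counted in 150 ms bins slid by 50 ms; the PSTH reports mean ±
s.e.m. rate across trials, and two conditions are compared bin-wise with a
two-sided Wilcoxon rank-sum test at uncorrected p < 0.05 (exact by
exhaustive permutation for small samples, tie-corrected normal
approximation otherwise).

## Worked example

```r
library(marmopull)

pre   <- dyad_preset("proficient")
pulls <- simulate_pulls(pre$m1, pre$m2, duration_ms = 1200000, seed = 42)
cfg   <- session_config("mutual_cooperation")
log   <- run_session(pulls, cfg)
log
#> <session_log> mutual_cooperation | 160 pulls, 57 pairs, 114 rewards
#>   provenance: run_session

session_metrics(log)
#> <session_metrics> mutual_cooperation
#>   pulls: 160 (114 successful, 46 unsuccessful)
#>   success rate: 0.713
#>   rewards/working min: 6.07 (working time 1127.5 s)
#>   mean inter-pull time: 3277 ms
```

The simulated dyad pulled 160 times in 20 minutes; 57 pull pairs fell
inside the 1 s window, so 114 of the 160 pulls were successful
(rate 0.71, a proficient dyad). Each pair delivered two 0.2 ml rewards,
and the 114 rewards over the 1127 s in which the dyad was actively
pulling (a pull within the trailing 30 s) give 6.1 rewards per working
minute. The mean time from each pull to the partner's nearest pull was
about 3.3 s.

`run_demo("demo_out", seed = 7)` regenerates a complete synthetic suite —
both conditions, naive and proficient presets, gaze clip, PSTH comparison
— with a manifest that makes the tree byte-reproducible.
`inst/cli/marmopull.R` exposes the same pipeline as a command-line tool
(`engine`, `metrics`, `gaze`, `psth`, `demo` subcommands).

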