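---
title: "Collective and individual movement metrics from positional tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective and individual movement metrics from positional tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teamdyn)
```

# The data model

`teamdyn` works on long-form tables of fixed-rate 2-D tracking samples:
`(time_s, player_id, team, x_m, y_m)` on a rectangular pitch with the origin
at one corner, `x` longitudinal in `[0, length]` (toward the analysed
attacking goal), `y` transverse in `[0, width]`, both in meters. The default
pitch is 105 × 68 m (standard full-size dimensions) and the default rate
10 Hz, the common resolution of optical player tracking; a 45-minute half is
then 27,000 samples per player.

Import (`read_positional_csv()` / `positional_dataset()`) makes three
repairs, each of which reflects how real tracking data misbehaves:

* **Grid alignment.** All players are snapped to the sampling grid anchored
  at the first player's first stamp. Because nearest-point snapping always
  finds a grid point within half a sampling period, the operative failure is
  not "too far off the grid" but two samples landing on the *same* grid
  point, which is rejected as a duplicate.
* **Gap interpolation.** Interior gaps in a player's samples (dropped
  frames) are filled linearly up to `max_gap` (default 0.5 s, i.e. 5 frames
  at 10 Hz — long enough for momentary occlusions, short enough that linear
  interpolation cannot invent much movement). Longer gaps are an error: the
  analyst should slice around them rather than trust fabricated positions.
* **Bound clamping.** Samples slightly outside the pitch (tracking jitter at
  the touchlines) are clamped to the boundary with a warning; a strict mode
  rejects them instead.

Pace classes are discretised **once, at import**, and cached with the
dataset. This mirrors how discretisation is treated as part of data import
rather than analysis; analysing under a different pace scheme means
re-importing with that scheme, which keeps every downstream view of the same
dataset consistent.

# Collective metrics

For a caller-defined group `G` of `n` players with positions `pᵢ(t)`:

* **Centroid** `c(t) = (1/n) Σ pᵢ(t)` — every member contributes equally.
  Group composition is entirely the caller's: excluding goalkeepers,
  analysing "3 forwards vs 4 defenders", etc., is done by selecting ids, and
  the only hard constraint is a minimum group size (2 for centroid, stretch
  index and length/width; 3 for hull areas, since a polygon needs three
  vertices).
* **Stretch index** `SI(t) = (1/n) Σ ‖pᵢ(t) − c(t)‖`, the mean radial
  distance, and its rate `dSI/dt` by centered finite differences at interior
  frames (exact for linear growth) and one-sided differences at the ends.
* **Effective playing space**: the convex hull area of the group's
  positions, in field m². The hull uses a Graham scan — at ≤ ~10 points per
  frame, recomputed for thousands of frames, a simple `O(n log n)` scan is
  the right tool. Tie-breaking: the pivot is the lowest-y (then lowest-x)
  point; collinear candidates sort by distance from the pivot; collinear
  mid-edge points are dropped from the vertex list (the area is unaffected
  either way). A fully collinear frame yields a flagged degenerate hull with
  area 0 rather than an error, since momentarily collinear formations are
  legitimate data. Overlap of two groups' hulls is computed by
  Sutherland–Hodgman clipping, which is exact for convex inputs.
* **Team length / width**: max−min member spread along x / y. These are
  axis-aligned by definition and therefore *not* rotation-invariant, unlike
  the stretch index and hull area (a property the test suite asserts on
  rotated fixtures).

# Coordination metrics

**Relative phase.** Each signal (typically a player's distance to the group
centroid) is mean-centered — the analytic-signal phase of a non-centered
oscillation is distorted — and its instantaneous phase taken as the argument
of the analytic signal, built by the standard FFT construction (negative
frequencies zeroed, positive doubled). The relative phase of a pair is the
wrapped difference in `(−180°, 180°]`: 0° = in-phase, 180° = anti-phase. Two
practical caveats are built in:

* **Edge effects.** The analytic signal is unreliable near the series ends,
  so the first and last 5% of frames (configurable `edge_trim`) are flagged
  and excluded from circular summaries.
* **Circular summaries.** Series are summarised by the circular mean and
  resultant length; an (anti-podal) angle set with resultant ≈ 0 has no
  defined mean and is reported as `NA` rather than an arbitrary angle.

**Approximate Entropy.** `ApEn(m, r) = Φᵐ(r) − Φᵐ⁺¹(r)` with
`Φᵏ(r) = (N−k+1)⁻¹ Σᵢ ln Cᵢᵏ(r)`, `Cᵢᵏ` the fraction of length-`k` windows
within Chebyshev distance `r` of window `i`, **self-matches included** (the
classic convention, which avoids `log 0` and keeps the statistic
non-negative in practice). Defaults `m = 2`, `r = 0.2 × SD` of the series
are the field-standard choice; both are exposed. A constant series gives
exactly 0; typical tracking-derived signals land in roughly the 0–2 range,
which is an empirical expectation, not a bound — only `ApEn ≥ 0` is treated
as an invariant. Note that ApEn is **not monotone in `r`**: it rises to a
peak (around `0.5 × SD` for white noise) and falls on either side, because a
very tight tolerance leaves mostly self-matches at both lengths. The test
suite therefore asserts the decreasing branch beyond the peak only.

# Individual kinematics

Speed at frame `i` is the Euclidean step distance over the step duration
(the first value duplicated so the series aligns with the samples), then
smoothed with a centered moving average, default window 0.5 s. Raw 10 Hz
differentiation is dominated by tracking jitter — 0.2 m of noise at 10 Hz
alone implies ~2–3 m/s of spurious speed — so some smoothing is essential
for sensible pace classification; the window shrinks symmetrically at the
series ends, and `smoothing_window = 0` gives raw differences for exact
conservation arithmetic.

The five pace classes are bounded at 0.2 / 2.1 / 3.8 / 6.1 m/s. The
intervals are **half-open `[lower, upper)`**: interval descriptions like
"between 0.2 and 2.1" and "between 2.1 and 3.8" would otherwise both own
2.1 m/s, and assigning boundaries upward makes the classification a total,
monotone step function of speed. Distance per pace accrues each inter-frame
step (speed × duration) to the class of that step's speed, so the per-class
distances sum to the total distance exactly.

Heat maps bin samples on a regular grid (default 1 m) covering exactly the
pitch; the last row/column may be a partial bin clipped at the boundary, and
samples exactly on the far boundary fall in the last bin. Occupancy mode
counts samples (the grand total is the sample count); pace mode accrues one
sampling period of time per sample at the requested cached pace.

# The synthetic generator

`generate_dataset()` builds match-like data from prescribed kinematics:
anchored agents with per-axis sinusoidal oscillation (amplitude, frequency,
phase offset), optional piecewise-linear waypoint drift, optional
piecewise-constant speed shuttles (reflecting off the pitch ends, so a
profile can span all five paces), plus additive i.i.d. Gaussian position
noise applied before clamping — a reasonable model of optical tracking
jitter. Defaults emulate one half: 2700 s at 10 Hz on 105 × 68 m, two teams
of 10 outfield agents with 0.2 m jitter (typical of optical tracking).
Randomness is keyed by a single seed with per-agent substreams derived from
a hash of the agent id, so adding an agent never perturbs the others —
important when comparing group compositions.

Three scenarios inject recoverable ground truth: `goal_buildup` (linear
centroid drifts crossing at a computable time), `coordination_break` (a pair
oscillating radially in phase except for an anti-phase window, entered and
left through 2 s linear phase ramps to avoid discontinuities) and
`expansion_contraction` (uniform scaling about the group centre, so the
stretch-index rate has a known sign in each phase).

What the generator does **not** emulate: tactical interaction (agents do not
react to each other or to a ball), heavy-tailed or autocorrelated tracking
error, occlusion-induced identity switches, or realistic effort pacing.
Passing recovery tests therefore demonstrates that the *metrics* correctly
measure what was injected — not that real matches look like the synthetic
ones.

# Scope and sizes used in testing

The example scripts treat |relative phase| > 90° sustained for ≥ 2 s as a
"low coordination" illustration; the threshold is illustrative, not
normative. Whether a centroid crossover is tactically meaningful is left to
the analyst: the package reports the first crossover time, nothing more.

The test suite exercises the hull against a brute-force point-elimination
oracle on 1,000 random 3–10 point sets (exact to 1e-9 relative), ApEn
against a literal double-loop reference, phase-offset recovery at
δ ∈ {0°, 45°, 90°, 135°, 180°} with and without 0.3 m noise, and the
conservation/invariance properties on generated data of 20–60 s; the
full-half sample-count check generates 2700 s for a reduced set of four
agents. These sizes keep the default suite quick while covering every code
path at realistic parameter values.

# Known limitations

* Relative phase is pairwise only; no cluster-phase or wavelet coherence.
* No ball data, passing networks, Voronoi/Delaunay dominance areas, or
  biomechanical signals.
* Hull-based metrics require non-degenerate geometry; collinear frames
  return area 0 (flagged) and the overlap of a degenerate hull is 0.
* Linear gap interpolation underestimates movement inside gaps; keep
  `max_gap` short.
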