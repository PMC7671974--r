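---
title: "Motion analysis of surgical tool-tip kinematics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion analysis of surgical tool-tip kinematics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgkin)
```

## The problem

Objective assessment of robot-assisted surgical skill commonly rests on
three kinematic parameters extracted from the tool-tip trajectory of each
trial: the **task time**, the **path length** (PL) and the **number of
movements**. Observer-based global rating scales (GRS, modified-OSATS
style: six items scored 1–5, totals 6–30) provide a human reference, and
participants are grouped by self-declared experience into novices
(< 10 h), intermediates (10–100 h) and experts (> 100 h). surgkin
implements the full chain: reading 76-column kinematic recordings (19
channels × 4 manipulators at 30 Hz), computing the three metrics,
comparing them across skill groups and correlating them with GRS scores.

## The metrics

**Time.** Recordings run at a fixed rate, so time is the frame count
divided by the rate: `trial_time(n, rate) = n / rate` seconds.

**Path length.** For consecutive samples A and B,
\(d_{AB} = \sqrt{(x_B-x_A)^2 + (y_B-y_A)^2 + (z_B-z_A)^2}\), and
\(\mathrm{PL} = \sum_i d_i\) over the whole trial. PL is computed on the
raw, unsmoothed positions: the defining sum is over measured partial
distances, and smoothing before summation would silently shorten every
trajectory. (A sensitivity variant — smoothing first — can be had by
passing `smooth_gaussian`-filtered positions explicitly.)

**Movements.** A movement is a displacement burst whose velocity rises to
a single maximum and returns near zero. The counter takes the per-interval
displacement signal \(d_i\) (speed × Δt), smooths it with a Gaussian
filter, and counts local high peaks. We count peaks of the *displacement
per interval*, not of the cumulative distance: cumulative distance is
monotone and has no peaks, so the velocity-peak definition forces this
choice.

### Peak detection parameters

The original analysis software never published its smoothing or peak
parameters, so these are explicit, defaulted, and recorded in every run
manifest:

| parameter | default | units | rationale |
|---|---|---|---|
| `sigma_samples` | 5 | samples (≈ 0.17 s at 30 Hz) | suppresses tremor-scale jitter while leaving sub-second surgical movements intact |
| `min_peak_height` | 10 % of the smoothed signal's maximum | m/interval | adaptive per trial; scales with how vigorously the subject moves |
| `min_peak_separation` | `2 * sigma_samples` | samples | two bells closer than the smoothing scale are not resolvable anyway |

Peaks are strict local maxima above the threshold; of two peaks closer
than the separation the higher wins, and an exact height tie keeps the
earlier peak. Smoothing uses a truncated (radius 4σ), unit-sum kernel with
reflective edge padding, so constants are preserved exactly and no
spurious boundary peaks appear.

## Statistics

Group summaries are mean ± sample (n−1) SD — the conventional choice for
trial data; singleton groups report no SD. Pairwise skill comparisons use
the two-sided Mann–Whitney U test with U = min(U_a, U_b): exact (integer
count recursion, equivalent to full enumeration) for tie-free samples of
at most 8 per group, otherwise the normal approximation with midrank tie
correction and a 0.5 continuity correction — the group sizes here (8–19
trials) always take the latter branch. Significance is α = 0.05 with raw
p-values; a Holm-correction flag exists but is off by default because the
reference analysis reports uncorrected p-values. Kinematics–GRS
associations use Pearson's r (p from the t transform, n−2 df); skill–GRS
uses Spearman's ρ computed as Pearson on midranks with the same t-based p,
with skill coded novice = 1, intermediate = 2, expert = 3. Correlation
magnitudes are banded with strict thresholds: |r| > 0.7 strong, > 0.5
moderate, > 0.3 weak, else negligible; the sign is reported separately.

## The synthetic world

`generate_trial()` builds a trial as K discrete movements with
**minimum-jerk** displacement profiles
\(x(t) = A(10\tau^3 - 15\tau^4 + 6\tau^5)\), the canonical bell-velocity
reach (peak speed 1.875·A/T at mid-movement, zero at both ends) — any
smooth unimodal-velocity profile would satisfy the movement definition;
this one is standard in the motor-control literature and is swappable.
Successive movements head along directions drawn uniformly on the sphere
(avoids degenerate collinear trajectories), separated by stationary
pauses, sampled at 30 Hz, with i.i.d. Gaussian position noise per axis per
sample added afterwards. Ground truth (movement count, noiseless PL = sum
of amplitudes, time, peak times) is returned alongside.

The recovery-suite world (`sample_trial_spec()`) draws amplitudes from
U(0.04, 0.12) m and durations from U(0.4, 0.8) s — centimeter-scale,
sub-second point-to-point motions typical of suturing — pauses from
U(0.5, 1.0) s, and **position noise sd from U(0, 5 × 10⁻⁵) m**.

### Why the noise is sub-0.1 mm

The noise level deserves its own paragraph because it is a genuine
limitation of the peak-counting definition, not an arbitrary choice.
Position noise enters the displacement signal through a norm,
\(d_i = \lVert u_i + \Delta n_i \rVert\), and therefore *rectifies*: even
zero-mean noise produces a strictly positive floor
(≈ 2.26 × noise sd per interval) under the whole signal, pauses included.
The adaptive threshold is 10 % of the smoothed maximum, so as soon as the
noise floor exceeds roughly 0.3 % of amplitude per duration-second, the
entire pause baseline clears the threshold and every smoothed noise wiggle
becomes a countable peak — the count then grows without bound rather than
degrading gracefully. Real da Vinci kinematics are encoder-derived with
sub-0.1 mm jitter, far below this instability, and the generator's default
follows the instrument, not the breaking point. Recovery under heavy
(several percent of amplitude) position noise would require a
baseline-subtracting or prominence-based peak criterion, which would be a
different counting rule than the one this package sets out to reproduce.

`generate_cohort()` assembles JIGSAWS-shaped cohorts: participants B–I
(4 novices, 2 intermediates, 2 experts), up to 5 repetitions of up to
three exercises, written as 76-column files plus metadata so the entire
pipeline runs on the output unchanged. Per-skill distributions are
calibrated to the *direction and scale* of the published left-hand
suturing group means — novice ≈ 137 s, 3.0 m, 40 movements; intermediate
≈ 88 s, 3.1 m, 60; expert ≈ 100 s, 1.7 m, 15 — and GRS totals are rounded
normals truncated to 6–30 with the published suturing group means
(novices 17.5, intermediates 25.1, experts 16.3). Each hand draws its own
movement schedule independently (the shorter hand rests until the trial
ends): the published ~10× left/right PL asymmetry is unexplained, and the
implementation deliberately contains no hand-specific scaling. Slave arms
mirror the masters with a configurable motion-scale factor (default 1).

What a green synthetic test does **not** establish: the generator has no
tremor spectrum, no temporal noise correlation, no tissue interaction, no
gesture structure, and its movements never overlap — so passing recovery
tests demonstrates correctness of the metric definitions, not performance
on adversarial real recordings.

## Numerical and design choices

- **Column order.** The 76 columns are read as four 19-channel blocks in
  the order left master, right master, left slave, right slave (the
  dataset documentation's convention); the order is configurable via
  `jigsaws_layout()` because secondary descriptions list the controllers
  differently.
- **Hour boundaries.** 10 h and 100 h both map to intermediate
  ("10–100 h" read inclusively).
- **Metadata cross-check.** A skill letter that contradicts the fixed
  participant→skill mapping is a hard error, not a warning: it indicates a
  corrupted join, and every downstream statistic keys on it.
- **Corrupt trials.** Unreadable trial files are skipped with a warning
  and listed in the manifest (the source dataset itself lost trials to
  corruption); `--strict` promotes this to an error.
- **Exact vs approximate U.** The exact branch uses an integer-count
  recursion with one final division, so it is bit-identical to brute-force
  enumeration; the approximation matches the standard
  continuity-corrected, tie-corrected normal form.
- **Determinism.** Everything stochastic flows from a single seed through
  a save/restore RNG guard; a report re-run with its archived
  configuration reproduces every output byte for byte (manifests carry no
  timestamps for exactly this reason).
- **Reference comparison.** `diff_report()` judges only parameter-free
  quantities (trial counts, time means/SDs, GRS summaries and statistics)
  at printed rounding; path-length and movement columns are displayed
  with deltas but flagged informational, because the original smoothing
  parameters are unpublished and those values are not exactly recoverable
  by any reimplementation.

## Known limitations

- Movement counts under strong position noise overcount, by the
  rectification mechanism above; the threshold rule is kept faithful to
  the velocity-peak definition rather than hardened.
- The Spearman p uses the t approximation, not the exact permutation
  distribution; for n ≥ 28 (the smallest exercise here) the difference is
  negligible.
- Only position channels carry information in synthetic files; rotation,
  velocity and gripper channels are valid placeholders.
- The CLI accepts cohort specs as JSON only.
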