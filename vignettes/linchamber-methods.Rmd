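---
title: "Methods and design choices in linchamber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in linchamber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(linchamber)
```

# The paradigm and its coordinate conventions

A linear-chamber experiment is a 5-minute rest period followed by three
10-minute corridor sessions (E-E, first S-O, second S-O) in a 45 × 10 cm
arena whose two faces hold the side chambers. All times in the package are
seconds on a single experiment clock starting at the rest onset; all
intervals are half-open `[start, end)`; all coordinates are cm in the
chamber frame with the corridor axis as x (faces at x = 0 and x = 45).
Behavioral intervals derived from tracking convert maximal runs of member
frames to `[t_first, t_last + 1/fps)`, so an isolated member frame still
contributes one frame duration.

# Behavioral event model

Sniffing is defined by perpendicular distance of the nose to the face plane
(nose x within 3 cm of either end), not radial distance to a point: the
sniffing zone is a band spanning the corridor width. Radial distance to the
face-center point is used only for object proximity, which is how the
proximal/distal classification is defined for objects. In-zone and
center-zone membership use the body center computed as the geometric
midpoint of the tracked nose and tail base — the tracked `body_center` point
is deliberately ignored so the rule matches its stated definition exactly.
The center zone is the middle of five equal 9-cm sections, x ∈ [18, 27).

Valid-trial filtering scans in time order: intervals shorter than the
duration threshold are dropped first, then any interval whose gap from the
end of the previously *retained* interval is below the gap threshold. This
greedy rule is idempotent and guarantees both constraints hold in the
output. Sniffing uses (1 s, 2 s), in-zone and center (0.5 s, 0.5 s),
proximal/distal trials (1 s, no gap constraint).

Frames whose pose likelihood falls below 0.9 are filled by carrying the last
well-tracked coordinate forward. No orientation gating is applied to
sniffing: the source procedure defines sniffing purely by nose position, so
a head-averted nose within 3 cm still counts.

# The synthetic world

The generator's job is to produce experiments with the statistical structure
the analyses assume, not realistic rodent kinematics.

*Trajectories* are piecewise schedules: dwell at a face (1.5–4 s, nose
jittering inside the sniffing band), travel at 15 cm/s, dwell near the
center (1–2.5 s), alternating left and right. This guarantees, by
construction, tens of valid sniffing trials per face and ample center-zone
occupancy per session; the generator still verifies that every one of the
six targets accrues at least 20 s of valid sniffing (the 40-bin encoding
requirement) and redraws the session up to five times before failing with
the offending target named. Body parts sit at fixed offsets along the
heading (nose 2 cm ahead of the body center, tail base 2 cm behind); the
tracking likelihood column is written as 1.0 (an optional jitter model was
considered and rejected — tracking noise is not what any downstream
contract measures).

*Spike trains* are thinned homogeneous Poisson processes: a homogeneous
train at the unit's maximum rate is thinned by `rate(t)/rate_max`, where
`rate(t)` is the rest rate during rest, baseline × gain while the nose
occupies a target's sniffing zone, and baseline elsewhere. Thinning makes
the expected count over any zone-constant span exactly `rate × duration`,
which is what the calibration tests assert. Bursts are inserted post hoc:
each spike spawns, with the unit's burst propensity, one or two extra
spikes at 5-ms spacing. Each unit's stream is seeded from
`(experiment seed, unit index)` so bundles are bit-identical under a fixed
seed and units are reproducible independently of evaluation order.

*Genotype presets* follow the contrasts the analyses are meant to expose:
relative to wild type, the knockout preset raises the resting rate by ~30%,
halves the burst propensity, and reduces the fraction of social-modulated
units by 40%. These magnitudes are free parameters of the synthetic world,
chosen once as plausible effect sizes — they are not measurements, and no
test treats them as such. "Strong" modulation means a 3× sniff-zone gain
for increasing units and 1/3× for decreasing units (70%/30% by default).

A green test on this world establishes that the *procedures* behave as
specified — calibrated nulls, recoverable planted effects, monotone
responses to separation — not that any biological claim holds: real mPFC
units have non-Poisson history dependence, rate drift, correlated noise
across simultaneously recorded units, and tracking dropouts, none of which
the generator emulates.

# Encoding: auROC and the permutation null

Instantaneous rates are spike counts in consecutive 0.5-s bins laid from
each valid trial's start; a trailing remainder shorter than one bin is
discarded so every rate sample is identically distributed (the alternative —
rescaling a short bin — would make tail bins noisier than the rest).

The auROC is computed exactly as printed: thresholds sweep the pooled
min–max range in 100 steps, the curve plots P(sniff > θ) against
P(center > θ), is closed at (0,0) and (1,1), and is integrated by
trapezoids. This agrees with the exhaustive rank-statistic AUC (ties counted
half) to within 0.01 on well-conditioned continuous samples. The sweep is
exactly invariant under positive affine transforms (the grid maps along) but
only approximately invariant under nonlinear monotone transforms: when one
group's spread is small relative to the pooled range its samples crowd a few
grid cells and the discretization error grows. With the 40-bin minimum the
error stays well inside 0.02 for mildly skewed data; the rank AUC is the
reference whenever exactness matters. When the pooled samples are all equal
the auROC is defined as 0.5.

The null distribution re-partitions the pooled bins into groups of the
original sizes 1000 times and recomputes the sweep auROC each time — a label
permutation, which is the exchangeable null for "no target dependence".
Because the threshold grid depends only on the pooled samples, it is fixed
across shuffles, and the permutation loop reduces to cumulative counts per
grid cell (implemented in C++; ~1 ms per unit). A unit is responsive when
its observed auROC lies strictly above the 99.5% or strictly below the 0.5%
interpolated quantile of the shuffled distribution. The strict comparison
and finite shuffle count make the realized false-positive rate on null data
slightly above the nominal 1% (about 1.2% in calibration runs of 10,000
null units); the calibration suite therefore accepts 1% ± 0.5 percentage
points, fixed before measurement.

Sniff bins pool the E-E session's two faces for the empty target and both
S-O sessions for social and object; center bins pool all three sessions.
Spike density functions use 250-ms bins from −1.5 to +3 s around valid
sniff onsets, averaged across trials; group averages normalize each unit by
its maximum across its three target SDFs jointly, so cross-target amplitude
relations survive averaging (per-target normalization would erase them).
z-scores standardize a target's mean rate by the center-zone bin statistics
(sample SD); per-trial z-scores use each trial's own rate over its full
duration, and trial consistency is the percentage of trials whose z-score
carries the unit's response sign, zeros counting against.

# Decoding

No SVM implementation ships with the environment's R stack, so the linear
soft-margin SVM is solved in C++ by sequential minimal optimization with a
deterministic second-choice heuristic — box constraint C = 1, linear
kernel, no feature standardization, mirroring the defaults of the MATLAB
routine the procedure references. On 18 one- or few-dimensional training
points the solver converges in a handful of sweeps.

Each repetition samples 10 trials per class without replacement;
leave-one-out cross-validation holds out the i-th trial of each class,
trains on the remaining 18, and tests the 2 held-out trials; accuracy is
correct/20 over the 10 folds, and 100 repetitions are averaged.
Pseudo-populations concatenate the i-th sampled trial of every selected unit
into one feature vector — units come from different experiments, so pairing
by sampling index is the only structure available. Label shuffles permute
the 20 selected trials' labels within each repetition. A decision value of
exactly zero is counted incorrect, keeping the tie-break deterministic and
conservative.

# Dynamics

The 30-minute epoch yields exactly 1800 windows: a 3-s window is anchored
at every whole second, and the final two windows are truncated at the epoch
end, with rates computed over the actual window length. (Anchoring whole
windows only would give 1798; the printed count of 1800 forces the
truncation convention.) Sigma is the *sample* standard deviation of the
1800 rates — the source defines only "1 SD", and with n = 1800 the
distinction is negligible, but the choice is fixed and tested. Per-session
statistics assign each window to the session containing its start.
Normalized-rate histograms divide by the series maximum and use bins
[0, 0.1), …, [0.9, 1.0], the top bin closed so the maximum itself lands in
it. The sigma-vs-mean comparison regresses log10(sigma) on log10(mean) per
group and applies the slope/elevation test below.

# Slope and elevation comparison

The two-group regression comparison is the classic ANCOVA-style pair of
tests: slope equality by `t = (b1 − b2)/SE` with pooled residual variance
on `n1 + n2 − 4` degrees of freedom; if slopes are homogeneous at α = 0.05,
a common slope is fitted and elevations are compared on `n1 + n2 − 3`
degrees of freedom. The implementation is by explicit sums of squares and
is verified in the tests against the algebraically equivalent
interaction/additive linear-model formulation, which serves as the
independent oracle.

# Bursts

Burst spikes are all spikes participating in at least one ISI at or below
the threshold (every member of a chain counts), so burst and tonic
elimination partition the train exactly — an invariant asserted for
thousands of random trains. ISIs are never computed across the rest/chamber
boundary: epoch restriction precedes differencing. The ISI histogram uses
1-ms bins up to 200 ms (fine enough to resolve peaks a few ms apart) and
normalizes per-unit by the total ISI count, so the proportions sum to the
fraction of ISIs within range.

# Intrinsic excitability

AP threshold is the membrane potential at the last upward crossing of
dV/dt = 5 mV/ms before each peak (central differences, linear
interpolation); searching backward for the *last* crossing ties the
threshold to the upstroke of that spike rather than to recovery segments of
a preceding spike. Peaks are local maxima above 0 mV; the AHP trough is
searched within 20 ms after the peak and FWHM is measured at threshold plus
half the amplitude, both windows being unstated in the source and fixed
here. Input resistance divides the deflection of the −100 pA sweep
(baseline minus the mean over the final 100 ms of the step) by the current.

The sweep simulator builds subthreshold responses as single-exponential RC
steps and inserts stereotyped APs: a slow 2 mV/ms ramp into the threshold,
a linear upstroke and downstroke of slope amplitude/FWHM, a trough at
threshold − AHP, and a 3 mV/ms recovery. The slow ramp places the 5 mV/ms
crossing at the generator's threshold parameter and the symmetric
upstroke/downstroke slopes make the FWHM exact by construction, which is
what lets the recovery suite demand 2% agreement. During spiking sweeps the
RC plateau is clamped 3 mV below threshold. Doublets (8-ms ISI) model
bursting within the 10-ms burst criterion.

# Numerical choices and degenerate inputs

- Spike counting in half-open windows uses sorted-train bisection
  (`findInterval`), so interval work is O(log n) per bound.
- ISI histogram edges absorb floating-point noise with a 1e-9-bin
  tolerance, so a mathematically exact 10-ms ISI never straddles bins.
- Empty membership yields empty interval sets, not errors; empty interval
  sets yield empty rate-sample vectors; classification with under 40 bins
  returns `insufficient_data` rather than a call.
- Degenerate inputs that would silently corrupt statistics fail loudly:
  zero-duration zones in the maximum-Δ computation, zero center-zone SD in
  z-scores, all-zero series in normalized histograms, negative rates in the
  generator.
- All stochastic entry points accept a seed; bundle-level operations derive
  per-unit streams from `(experiment seed, unit index)` (kept below 2^31),
  so results are independent of iteration order.

# Known limitations

- The half-valley-width threshold is applied to stored feature values
  as-is; the printed unit of the 200 threshold is physiologically
  implausible for extracellular waveforms (plausibly µs), so no unit
  conversion is attempted.
- The trajectory model has no turning kinematics, grooming, or tracking
  dropouts; likelihood gating is therefore exercised only by fixtures.
- Pseudo-population decoding assumes exchangeable trials across units; real
  simultaneous recordings would carry noise correlations the generator does
  not model.
- The SMO solver is tuned for the tiny problems this design produces
  (tens of trials, ensembles up to ~50 units); it is not a general-purpose
  SVM.
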