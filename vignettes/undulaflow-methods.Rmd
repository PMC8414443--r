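---
title: "Methods: kinematics and EMG analysis of undulatory swimming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematics and EMG analysis of undulatory swimming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(undulaflow)
```

# What the package measures

undulaflow analyses experiments in which an elongate fish (the motivating
system is the bichir *Polypterus senegalus*) swims in water whose dynamic
viscosity has been raised from 1 cP to as much as 40 cP, while ventral-view
high-speed video (250 fps) and multichannel EMG (10 kHz) are recorded.
The scientific question behind such experiments is how sensory feedback
retunes the swimming motor program when the mechanical environment is
dampened: a fish that merely kept its motor output constant would slow
down, so maintained speed with increased muscle effort is the signature of
active compensation.

The pipeline has four stages, each usable on its own:

1. **Midline extraction** (`extract_midline()`): binarized frames to
   ordered, arc-length-resampled midlines.
2. **Kinematics** (`compute_curvature()`, `segment_cycles()`,
   `wave_speed()`, `body_frequency()`, `swim_speed()`,
   `reynolds_number()`, fin metrics): the eight per-trial variables.
3. **EMG** (`condition_signal()`, `detect_bursts()`, `compute_ria()`,
   `duty_factor()`, `phase_lag()`): burst timing and intensity metrics.
4. **Inference** (`swim_lmm()`): linear mixed-effects models on trial
   averages with conservative degrees of freedom, estimated marginal
   means, Bonferroni-corrected pairwise comparisons, connecting letters
   and pseudo-R².

A synthetic-swimmer forward model (`swimmer_spec()`, `generate_midlines()`,
`rasterize_frames()`, `generate_emg()`, `simulate_trial_summary()`)
generates every input with recorded ground truth, so the whole pipeline is
testable without any animal data.

# Conventions

All derived quantities use body lengths (BL) for length, seconds for time
and 0-based frame indices in files; pixels appear only at the image
boundary. Images follow the x-right / y-down convention; kinematics flips
to y-up. The fish's *heading* is the unit vector from the 20% BL point
(the approximate pectoral girdle) to the nose; the fish's *right* is the
heading rotated −90° in the y-up frame. Signed curvature is positive when
the body is concave toward the fish's **left**; a left-side muscle is
therefore associated with maxima of +κ and a right-side muscle with maxima
of −κ. A tail-beat cycle starts (0%) when the tail tip starts moving
toward the fish's right; 50% is the start of leftward motion.

# The synthetic swimmer

The forward model is an inextensible body of unit arc length carrying a
lateral traveling wave

$$y(s,t) = A(s)\,\sin\!\big(2\pi(f t - s/\lambda)\big), \qquad
A(s) = A_\mathrm{head} + (A_\mathrm{tail}-A_\mathrm{head})\,s^p,$$

with $s$ the arc-length fraction from the nose. The longitudinal
coordinate is recovered from $x'(s) = \sqrt{1-y'(s)^2}$ (this requires
$|y'|<1$, which the constructor enforces), so every frame has total arc
length exactly 1 BL — the "arc-length renormalization" is built into the
construction rather than applied afterwards. The body is advected forward
at $U$ BL/s. The ground-truth wave speed is $c = f\lambda$ and the
curvature of the generated midline is analytically
$\kappa = y''/\sqrt{1-y'^2}$, which the tests exploit.

Defaults describe plain-water swimming: $f = 3.7$ Hz, $U = 0.65$ BL/s,
body length 136.33 mm, fin frequency 5.7 Hz, fin angles 1.48/1.25 rad at
adduction/abduction starts. No published amplitude or wavelength exists
for this species, so $\lambda = 0.65$ BL and
$A_\mathrm{head},A_\mathrm{tail} = 0.02, 0.08$ BL (exponent $p = 2$,
amplitude growing tailward) were fixed once from the anguilliform
literature range and the observed product $f\lambda$ falling inside the
measured wave-speed interval; they are placeholders for a plausible
swimmer, not species estimates.

The width profile used for rasterization is a head-heavy fusiform taper
(maximum half-width 0.035 BL near one-third of the body, thin caudal
peduncle, pointed at both tips). The fore–aft asymmetry is what allows
nose/tail disambiguation without a user hint. The default image scale is
800 px/BL (8 px per 1% BL) so skeletonization is not pixel-starved.

Synthetic EMG places one burst per cycle and electrode: amplitude-modulated
Gaussian noise under a raised-cosine envelope whose onset sits a
configurable percentage of the cycle before or after the local same-side
curvature maximum, with duration a configurable duty factor (default 35%
of the cycle, onset 8% before the maximum — values in the physiological
range for undulatory swimmers). The raised cosine was chosen because it
has unambiguous onset and offset instants, which makes annotation-free
detection testable. Baseline Gaussian noise (SD 0.02 of burst peak) and an
optional 60 Hz contaminant complete the trace. Because the carrier is
stochastic, single-burst onset estimates jitter by a few milliseconds even
without baseline noise; recovery statements are about means.

For the fin adductor electrode, the generator locks bursts to fin
adduction starts, with duration a fraction of the *fin* cycle; the
analysis stage, following the uniform definition of duty factor, reports
all burst durations as percentages of the *tail-beat* cycle. The fin
channel's recovered duty factor therefore differs from the generator's
parameter by the ratio of the two periods — deliberate, and worth knowing
when reading test output.

# Midline extraction

Per frame: 8-connected components are labelled and the largest kept (a
second component at least half its size is an error, not a silent choice);
Zhang–Suen thinning produces a one-pixel skeleton; the longest weighted
geodesic between skeleton endpoints (double-Dijkstra diameter on the
pixel graph) is the midline, which implicitly prunes spurs. Because
thinning erodes the tapered tips, each end is extended by a
centerline-following walk: step one pixel along the current direction,
re-center laterally on the foreground run, update the direction — this
follows a curved tail around its bend where a straight-tangent
extrapolation would exit the silhouette early. A body whose diameter path
is shorter than three times its estimated width (a disk, a blob) has no
unique elongated axis and is rejected, as is a skeleton shorter than half
the expected body length.

The nose is the endpoint nearest the user hint in frame 0 (or nearest the
previous frame's nose afterwards); without a hint, the endpoint with the
wider surroundings wins. The raw path is smoothed with a short moving
average (window scaled to px/BL) and resampled to equal arc length. Body
length is the median of the *smoothed* per-frame path lengths: the raw
8-connected path overestimates length through its staircase steps.

Round-trip accuracy against the generator's ground truth is sub-pixel
(RMS < 1 px at 800 px/BL); the validation suite checks translation and
90°-rotation equivariance and nose stability across frames.

# Curvature and the smoothing ladder

`compute_curvature()` evaluates the parametric signed curvature
$\kappa = (x'y'' - y'x'')/(x'^2+y'^2)^{3/2}$ from spline derivatives over
arc length normalized by BL, sampled at the centers of 100 equal-length
segments, with the outer 5% BL at each end flagged unreliable and masked
from downstream estimates (curvature at the head and tail tip is dominated
by digitizing/skeleton noise).

For clean midlines (synthetic, or digitized landmark files) an
interpolating cubic spline is used directly: on the generator's output it
agrees with the closed-form curvature to better than 0.1%. For extracted
midlines, sub-pixel skeleton noise would dominate the second derivative,
so two symmetric filters are applied first: a temporal moving average
(default 40 ms) of each point's coordinates — midline motion is
band-limited far below the frame rate, while skeleton noise is
frame-independent, so this removes noise without biasing wave phase — and
a fixed-roughness smoothing spline over arc length (default 30 equivalent
df), fitted on data padded at both ends by quadratic extrapolation so the
spline's free-end bias falls outside the body. Cross-validated smoothing
is deliberately *not* used: GCV tracks the pixel noise. The residual
curvature ripple on extracted midlines is ~10–15% of the wave amplitude,
which the time-domain estimators below are designed to tolerate.

# Cycles, wave speed, frequencies

**Cycles.** The tail tip's lateral displacement (positive toward the
fish's right) is differentiated with a 5-frame smoothed derivative;
upward zero crossings are cycle starts. Incomplete edge cycles are
discarded and trials with fewer than three complete cycles are rejected —
the same inclusion rule used when curating video.

**Wave speed.** The traveling crest of same-sign curvature passes a body
position exactly when the curvature time series at that position peaks.
Each half-cycle transit through a section (35–55, 55–75, 75–95% BL) is
therefore timed from the same-sign curvature peak at the entry position to
the matching peak at the exit position, with parabolic sub-frame
refinement; speed = section width / transit time, and the per-cycle value
averages the two half-waves. This time-domain formulation was chosen over
per-frame argmax crest tracking after both were implemented: peak *times*
at fixed positions are far more robust to the curvature ripple of
extracted midlines than crest *positions* at fixed times, and on clean
synthetic waves the two coincide. Three guards reject degenerate cases: a
transit must take at least 1.5 frame periods (simultaneous peaks are not
propagation), must be shorter than 0.9 periods, and the crest must pass
the section midpoint at an intermediate time — which is what rules out
standing waves, whose antiphase endpoint peaks would otherwise mimic a
half-period transit. When a section endpoint coincides with the masked
boundary (95% BL), the outermost unmasked segment center is used and the
width shortened accordingly.

With a uniform amplitude envelope the estimate equals $f\lambda$ to
numerical precision; with a growing envelope the measured crest runs
slightly ahead of the phase speed (the estimate sits 1–3% above
$f\lambda$ with the default envelope), which is a property of the
quantity, not an estimator error.

**Frequencies.** Body wave frequency is the mean reciprocal interval
between successive same-sign curvature peaks at a position; peaks are
found on a 40 ms-smoothed series and peaks closer than 0.6 of the
crossing-estimated period are merged (the higher wins) so frame noise
cannot double-count. Fin frequency is the mean reciprocal interval between
adduction starts.

**Swim speed** is the net displacement of the 20% BL point over the
integer number of complete cycles, divided by elapsed time. The 20% BL
point, not the nose, suppresses head-yaw oscillation; the nose remains
available via the `s_point` argument for comparison with nose-digitized
datasets.

**Reynolds number** is $Re = U L^2 \rho / (\mu \times 10^{-3})$ with $U$
in BL/s — exactly linear in speed and inversely linear in viscosity, which
the tests assert as an invariant.

**Maximum body curvature** per trial is the mean over cycles of the
per-cycle maximum of $|\kappa|$ at each position (not the trial-wide
single maximum — the per-cycle mean is stabler and is stated here as the
package's definition). Ties between equal discrete peaks resolve to the
earlier time.

# EMG metrics

Conditioning mirrors standard acquisition settings digitally: a 40–4000 Hz
4th-order Butterworth band-pass and a 60 Hz notch (biquad, Q = 30), both
applied forward–backward so burst onsets suffer no group delay, on a
reflection-padded signal so filter start-up transients fall outside the
data; the result is mean-centered.

`find_expmax()` computes each electrode's maximum rectified conditioned
amplitude across all trials of one individual (EMG~ExpMax~). The scope is
per electrode *per individual*: electrodes are not comparable across fish.
RIA is the trapezoidal integral of the rectified signal over a burst,
reported as a percentage of the theoretical maximum RIA
(EMG~ExpMax~ × burst duration); a half-sine burst at full amplitude scores
exactly $200/\pi \approx 63.66\%$, one of the frozen closed-form tests.
Duty factor is burst duration as a percentage of the cycle containing the
onset.

Phase lag is the signed time from the nearest same-side curvature maximum
(at the electrode's body position, within ±0.75 cycles) to the burst
onset, as a percentage of the cycle, wrapped into (−50, 50]:
**negative means the muscle turns on before the body reaches maximum
curvature**. The sign convention and wrapping interval are stated here
prominently because they are easy to get backwards: an onset 30 ms before
the maximum in a 300 ms cycle is −10%.

Annotation-free detection (for synthetic pipelines; manual windows load
via `load_burst_annotations()`) uses an RMS envelope (10 ms window), a
threshold at the baseline median + 3 MAD — the baseline being the quietest
quartile of the envelope located by 50 ms windows, so the pooled sample
keeps its natural spread — runs ≥ 15 ms, gaps < 10 ms merged, a 6-MAD peak
confirmation (two-threshold detection, which keeps pure-noise false
positives below 5% of runs), one burst per cycle (largest rectified
integral), and onset/offset refinement from the envelope foot: walk out
from the peak to the 20% crossing and extrapolate along the local slope,
bounded by the raw run edge ± 2 ms. End-to-end on the default synthetic
conditions, recovered duty factor and phase lag sit within ~1 percentage
point of truth per electrode.

# The inference stage

`swim_lmm()` fits the study's models with nlme: per-trial means as
observations; viscosity (and body position plus, optionally, their
interaction) as fixed effects; random intercepts for individual, with body
point nested in individual when positions are present; optional
per-position residual variances (`varIdent`). The interaction is included
either on demand or when it lowers the AIC of maximum-likelihood fits of
the two nested fixed structures; the refit for the F table is REML.
Singular (near-zero variance) random effects are flagged on the object,
never silently simplified — the user chooses how to proceed.

Denominator degrees of freedom follow the conservative inner–outer
(containment) counting rule, which `anova_df_conservative()` implements
independently of the fitter and the tests cross-check against
`anova.lme`: each term is tested at the innermost grouping level at which
it varies, with df $m_i - m_{i-1} - p_i$. Under the package's default
design — six individuals, half swimming all four viscosities and half only
the extremes, two trials per cell plus a third 1 cP trial for the first
two individuals, 38 trials in all — viscosity on a position-free variable
is tested at (3, 29) and position (three sections nested in six
individuals) at (2, 10).

Estimated marginal means come from emmeans; for log-transformed responses
(used for Reynolds number, whose residuals are otherwise right-skewed)
they are back-transformed with the SE reported as a multiplicative factor.
The Bonferroni family is the union the study reports: all viscosity pairs
within each position plus all position pairs within each viscosity
($P\binom{V}{2} + V\binom{P}{2}$ comparisons; just $\binom{V}{2}$ without
positions), and adjusted p-values are $\min(1, m p)$. Connecting letters
are assigned by insert-and-absorb — every significant pair splits the
groups containing both members, subsets are absorbed — with groups ordered
by estimated marginal mean so reports are reproducible and invariant to
cell relabeling. Pseudo-R² follows the variance-components decomposition:
$R^2_m$ uses the variance of the fixed-effect predictions over the summed
fixed, random and residual variances; $R^2_c$ adds the random variance to
the numerator; under `varIdent` the residual variance is averaged over
strata.

# What the synthetic tests do and do not show

The generator emulates: a sinusoidal traveling wave with a smooth
monotone amplitude envelope, an inextensible body, clean binarized
silhouettes, EMG bursts with stereotyped envelopes strictly phase-locked
to curvature, and Gaussian trial-to-trial variation with the published
design's structure. Real data differ in ways the suite does not probe:
non-sinusoidal and cycle-to-cycle-variable waves, glides and burst
swimming, segmentation errors in real video (shadows, fin overlap,
surface glare), electrode cross-talk and movement artifacts, and
non-Gaussian trial variation. Passing tests therefore demonstrate that the
estimators are *correct* (they recover known truth under the stated
conditions at the stated tolerances), not that real recordings meet those
conditions; the masked zones, inclusion rules and rejection errors exist
precisely because real data often do not.

Problem sizes used by the validation suite and the acceptance script were
chosen to exercise every stage at desk scale: 2 s trials at 250 fps for
clean kinematics, a 1.2 s stationary swimmer at 125 fps and 800 px/BL for
the image round trip, 10–20 seeds for the EMG sweeps, and 100–200
simulated designs for mixed-model coverage.

# Known limitations

* Wave speed from a growing amplitude envelope intentionally measures the
  crest of maximum curvature, which travels slightly faster than the
  phase speed; comparisons across conditions are unaffected, absolute
  comparisons with $f\lambda$ are only exact for uniform envelopes.
* Curvature within 5% BL of the ends is never reported; sections touching
  95% BL use the outermost unmasked segment center.
* The burst detector is tuned for one burst per cycle per electrode;
  co-contraction (two same-cycle bursts) keeps only the stronger one.
* `extract_midline()` assumes one fish, fully inside the frame, on a
  clean background; it refuses rather than guesses when that fails.
* The refit of published summary tables requires the corresponding
  trial-average dataset as a CSV; the package ships no animal data.
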