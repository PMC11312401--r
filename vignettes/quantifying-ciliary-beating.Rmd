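---
title: "Quantifying ciliary beating from high-speed video: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ciliary beating from high-speed video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliabeat)
```

## The measurement problem

A single airway cilium — a ~10 µm, 100 nm-thick filament anchored at one end
— beats with a stereotyped asymmetric cycle: a fast *effective stroke*, a
slower *recovery stroke*, and a variable *rest interval* during which the
axonemal dyneins are presumed inactive. Recorded at 250 frames per second
(4 ms/frame), the beat is quantified by placing a scan line across the beat
envelope and reducing each frame to the position at which the filament
crosses the line. From the resulting position-versus-time wave one reads:

* **CBF** (ciliary beat frequency, Hz): the number of peaks counted over a
  2 s record, divided by the duration;
* **CBD** (ciliary bend distance, µm): the mean peak-to-preceding-trough
  distance over ten waves — an index of beat amplitude;
* **stroke durations** (ms): frames counted from the start to the end of
  each stroke, times 4 ms — never sub-frame interpolated;
* **inter-beat intervals** (ms): the rest time between the end of one
  recovery stroke and the start of the next effective stroke.

Demembranated cilia reactivated with ATP plus a cAMP analogue respond
strongly to pH: between pH 7.0 and 8.0 the beat frequency rises roughly
linearly (≈3→15 Hz) and the bend distance rises to a plateau
(≈0.6→1.3–1.5 µm, flat above pH 7.6), while the recovery stroke stays
constant (37–40 ms) and the rest intervals shrink (≈234→31 ms). ATP alone
sustains only slow, sparse beating (≈0.4–1.4 Hz).

`ciliabeat` implements this measurement pipeline together with a seeded
generator of synthetic recordings whose presets encode those condition-level
values, so the whole chain — trajectory, rendering, trace extraction, peak
detection, stroke segmentation, cohort statistics — can be validated by
parameter recovery without any external data.

## The generative beat model

`beat_params()` describes one condition. Within a beat, the crossing
position follows a raised-cosine ramp in each stroke
(`stroke_waveform()`): position rises smoothly and monotonically from the
baseline to the amplitude $A$ over the effective stroke $T_{\mathrm{eff}}$
and returns over the recovery stroke $T_{\mathrm{rec}}$,

$$x(t) = \frac{A}{2}\left(1 - \cos \frac{\pi t}{T_{\mathrm{eff}}}\right),
  \qquad 0 \le t \le T_{\mathrm{eff}},$$

with the mirror-image cosine on the recovery side. The measured quantities
constrain only the durations and the amplitude, not the intra-stroke
velocity profile; the raised cosine is the smoothest ramp with zero
endpoint velocity, and every downstream estimate is validated against the
generator's event log rather than against the ramp shape itself.

Rest intervals are lognormal, parameterized by their **arithmetic mean**
$m$ and log-scale spread $\sigma$ (`meanlog` $= \log m - \sigma^2/2$), with
$\sigma = 0.45$ throughout: with $m = 234$ ms this puts the central 95% of
draws at roughly 90–520 ms, matching the observed 112–584 ms spread of
intervals at pH 7.0 at the printed mean. $\sigma = 0$ gives deterministic
intervals, used for closed-form tests.

A trajectory (`build_trajectory()`) concatenates draws of
rest → effective → recovery on the 4 ms acquisition grid. Stroke durations
and interval draws are quantized to whole frames, so every true stroke
boundary lies on the grid, exactly as a frame-counting observer would see
it. A 37 ms nominal stroke therefore realizes as 36 ms; all recovery
checks use the 37–40 ms band with a ±1 frame allowance.

### Two matching modes

The printed condition-level values are mutually inconsistent: at pH 8.0 the
stroke and interval components sum to ~106 ms per cycle (≈9.4 Hz) while the
printed CBF is 15.4 Hz. Rather than guess a reconciliation, the generator
offers two modes:

* **rate-matched** — all three components are rescaled by a common factor so
  the expected cycle equals $1/\mathrm{CBF}$; after frame quantization of
  the strokes, the rest mean is re-solved so the expectation is exact. Used
  wherever beat frequencies, bend distances or their ratios are the target.
* **component-matched** — the printed durations are used verbatim (up to
  frame quantization). Used wherever stroke durations or interval means are
  the target. The emergent beat rate is then
  $1000/(T_{\mathrm{eff}} + T_{\mathrm{rec}} + \bar I)$ Hz — e.g. ≈2.45 Hz
  at pH 7.0, deliberately not the printed 3.4 Hz.

Each printed number is honored in the regime where it was measured.

### Recording protocol and start-up bias

Trajectories begin with a full rest interval at $t = 0$ (an "ordinary
renewal" start), which makes short deterministic constructions exactly
countable. Counting peaks over a short window from such a fresh start is,
however, negatively biased by about half a beat relative to recording a
cilium that is already beating — which is what a microscopist does. The
cohort simulator therefore discards a warm-up of 1 s or two mean beat
cycles (whichever is longer) before the record, making the recorded window
approximately stationary even for sparse slow beaters whose cycle exceeds
a second. With this protocol the cohort-mean CBF estimator
is unbiased (e.g. 3.40 ± 0.20 Hz across seeds for the pH 7.0 preset's
3.4 Hz target).

For sparse regimes (ATP-only presets, ≈0.4–1.4 beats/s) a 2 s record
contains only ~1–3 events and the integer peak count makes the cohort mean
noisy; the package quantifies those cohorts over 6 s records, as one would
record longer when events are rare. All other cohorts use the standard 2 s.

### Null conditions

Non-beating conditions (unstimulated, ATPγS, PKI-pretreated) are modeled as
an Ornstein–Uhlenbeck baseline fluctuation (correlation time 300 ms) with
no beat train. The fluctuation scale is calibrated against the quantifier:
with sd 0.04 µm, ≥95% of 2 s traces yield zero detected beats at the
default 0.2 µm prominence, and the rare detected excursion has a
peak-to-trough size of ≈0.2 µm — i.e. the quantifier reports essentially
zero CBF and an undefined (NA) CBD for null recordings, cleanly separated
from the smallest stimulated response (0.57 µm). Larger fluctuation scales
(e.g. 0.08 µm) cross the prominence threshold in most records and would
blur that separation, so they are not used.

## The synthetic microscope

`render_stack()` turns a trajectory into a 16-bit grayscale multi-page
stack. The filament is a circular arc pinned at the anchor, tangent to its
base orientation; the curvature is chosen in closed form so that the arc
crosses the scan line at exactly the trajectory's displacement. (A material
point at a fixed arc length cannot stay on a fixed straight line while the
filament bends — any bend shortens the axial extent — so the crossing
position is the quantity the generator controls; it is also the quantity
the measurement reads, which is what makes recovery exact.) The centerline
is integrated onto the pixel grid by bilinear splatting of dense arc
samples (brightness per µm of filament is conserved to <1%), blurred with a
Gaussian PSF, and optionally corrupted with Poisson shot noise and Gaussian
read noise.

Defaults — 0.1 µm/px, PSF sd 0.15 µm, background 200, filament
4000 grayscale·µm⁻¹, read noise sd 4 — make the 100 nm filament
sub-resolution (as in real DIC/phase HSVM) with a beat excursion of 5–15 px
and a peak contrast of ≈100 counts. The renderer refuses configurations
sampled at fewer than 6 frames per beat cycle; at 250 fps even the fastest
preset (15.4 Hz) retains ≥16 frames per cycle. The beat is rendered
strictly in-plane: the original videos are 2-D projections and CBD is
defined in the image plane, so out-of-plane components are out of scope.

## Trace extraction and beat detection

`extract_trace()` samples intensity along the scan line by bilinear
interpolation, removes the static background by subtracting the spatial
median of each frame's profile (robust because the filament occupies a
small fraction of the line; a temporal background estimate would erase a
filament that rests at one position most of the cycle), and estimates the
crossing position as the intensity centroid of the dominant peak refined by
a Gaussian fit — a parabola on log intensity over the peak top. The
refinement matters: it reaches ≈0.001 µm accuracy on noise-free renders
(centroid alone: ≈0.005 µm, limited by profile asymmetry and 16-bit
quantization), well inside the half-pixel (0.05 µm) contract, and positions
are invariant to uniform intensity rescaling and background level by
construction. A line that never crosses the filament (flat profile in
every frame) is an error, not a silent zero trace.

`detect_beats()` keeps local maxima with topographic prominence
≥0.2 µm and pairwise separation ≥20 ms. The prominence default sits below
the smallest stimulated CBD (0.57 µm) and above the null-fluctuation scale;
the separation default (5 frames) is below the shortest plausible cycle
(~65 ms at 15.4 Hz). A beat whose rise or fall is clipped by the record
edge still counts: a prominence side whose valley floor sits exactly on the
edge, with a near-monotone ramp from the edge to a nearby peak, does not
constrain the prominence (without this, a peak 40 ms after the window start
loses most of its measured prominence and a real beat goes uncounted). Each
peak is matched to its preceding trough; a wave whose trough is cut off by
the record edge still counts toward CBF but is excluded from CBD, which
averages the first ten complete waves.

## Stroke segmentation

The original frame counting was done by eye; `segment_strokes()` replaces
it with a reproducible velocity-threshold rule, validated against the
generator's event log. For each beat, with velocity from central
differences on the 4 ms grid:

* the **effective start** is found by walking backward from the fastest
  rising frame through the contiguous run of frames with speed above 10% of
  that beat's maximum rising speed; the boundary is the last frame before
  the crossing at which the cilium was already moving (isolated noise
  spikes earlier in the rest phase cannot capture the start);
* the **recovery end** is the first frame after the peak at which the
  position has returned to within 10% of the beat amplitude above the local
  rest baseline *and* the forward-difference speed has fallen below the
  threshold — forward differences localize the stop exactly on a piecewise
  linear (trapezoidal) test waveform, where a central difference smears the
  corner by one frame;
* the **interval** is the time from one beat's recovery end to the next
  beat's effective start (rest phase only), absent for the last beat.

On noise-free renders every boundary lands within ±1 frame of the event
log across the slow (136 ms), intermediate (44 ms) and fast (36 ms)
effective-stroke presets; sum consistency
($T_{\mathrm{eff}} + T_{\mathrm{rec}} + I$ = spacing of consecutive starts)
holds exactly on the grid. If the next beat begins before the recovery
criterion is met, the beats are merged and flagged, never silently dropped.
One known quirk: for the slowest stroke (136 ms) the 10% velocity crossing
falls 4.35 ms after the true start, so the measured duration is 132 ms —
one frame short, and well within the ±8 ms (2-frame) acceptance band.

## Cohorts, ratios and tests

`simulate_cohort()` derives one seed per cilium from a single master seed
(`derive_seed(master, label, index)`), so any cilium is independently
replayable. `summarize_condition()` reports arithmetic means and sample
SDs (SD 0 by convention for a single cilium, flagged by `n_cilia = 1`);
`normalize_to_reference()` forms CBF/CBD ratios against the pH 7.4
condition, simulated at the study's cohort sizes (4, 4, 11, 6, 6, 4 cilia
for pH 7.0–8.0). Interval statistics pool beats across cilia, as in the
original 3-cilium pooling.

Contrasts use an unpaired Welch *t*-test (`welch_t_test()`, Satterthwaite
degrees of freedom) for two-condition comparisons and fixed-effects one-way
ANOVA (`one_way_anova()`) across the pH series; both are thin wrappers over
the standard R implementations with defined outputs in degenerate cases
(zero variance with equal means gives $t = 0$, $p = 1$), checked against
closed-form textbook formulas in the tests. No multiple-testing correction
is applied, matching the unadjusted reporting convention of the original
analyses; per-figure contrast families are written out so a user can adjust
afterwards if desired. Cohort SDs are emergent from counting statistics and
measurement noise only — inter-cilium biological variability is not modeled
— so only means, never SDs, are recovery targets.

`reproduce_paper(master_seed, out_dir)` runs the whole loop for all bundled
presets in both modes and writes tidy CSVs, figure-analogue plots and a
recovered-vs-target report; a fixed master seed gives byte-identical
outputs.

## Problem sizes and determinism

The standard validation runs at desk scale: a 2 s, 128×128, 500-frame stack
renders and quantifies in a few seconds; the pH-series cohorts comprise 35
cilia; interval pooling uses 3 cilia with records sized to collect 60–110
intervals; stroke-duration checks use single noise-free renders of 12
beats. `reproduce_paper()` over all presets completes in under ten
minutes on one core. All randomness flows from one integer master seed
through named streams (trajectory, imaging noise, per-cilium), and
noise-free rendering is bit-reproducible.

## Known limitations

* Presets are phenomenological: no dynein kinetics, phosphorylation
  signaling, or axonemal mechanics; condition labels (pH, ATP, inhibitors)
  select parameter sets and nothing more.
* Single isolated cilia only — no metachrony or inter-cilium coupling.
* The synthetic microscope does not model illumination drift, stage drift,
  uneven background, or out-of-plane motion; passing recovery tests
  therefore demonstrates correctness of the measurement chain on idealized
  recordings, not robustness to every real-world artifact. Scan-line
  placement on real videos remains a user decision.
* The unstimulated condition reports ≈0 Hz rather than the small nonzero
  cohort mean (0.38 ± 0.40 Hz) seen in vivo, a direct consequence of
  requiring null traces to produce no detected beats; the two cannot hold
  simultaneously under a fixed prominence threshold.
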