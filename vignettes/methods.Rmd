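---
title: "Methods: detecting microdomain Ca2+ transients and quantifying their coupling to tracheal filopodia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting microdomain Ca2+ transients and quantifying their coupling to tracheal filopodia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`filocal` quantifies two linked phenomena in two-channel time-lapse
fluorescence recordings of the larval *Drosophila* CNS: spatially
restricted, near-membrane microdomain Ca2+ transients in astrocyte
processes (imaged with a membrane-tethered indicator such as myr-GCaMP),
and the extension/retraction dynamics of tracheal filopodia (imaged with a
membrane marker such as myr-tdTomato). The scientific question the
coupling statistics address is whether filopodial retraction onsets follow
Ca2+ event peaks at a short, consistent latency when — and only when — the
filopodial tip sits inside the event's spatial domain.

Because raw recordings of this kind are rarely shareable, the package
includes a synthetic-movie generator with full ground truth. Every
analysis stage is validated by parameter recovery against that ground
truth, and the generator's defaults encode the acquisition and biology the
analysis targets.

## The event model and dF/F0

Fluorescence is modelled per pixel as `F_t = F0 * (1 + a * w(t) * k(x, y))
+ noise`, where `a` is the event amplitude as a fraction of baseline,
`w(t)` a unit-peak waveform, and `k` a spatial kernel. `compute_dff()`
inverts this with the textbook fractional change `(F_t - F0) / F0`. The
baseline `F0` is, by default, the per-pixel 20th temporal percentile:
transients are sparse in time, so a low percentile sees essentially only
baseline frames, and it is robust to a drifting mean in a way a plain
minimum is not. A global-constant baseline is available for fixtures and
for recordings where the per-pixel percentile is unreliable (very short
movies). Pixels whose baseline is not positive are masked out rather than
producing infinities.

`detect_events()` segments the thresholded dF/F0 volume into
spatiotemporal connected components using the 4-neighbourhood in space and
same-pixel adjacency across consecutive frames; no diagonal space-time
links are used, so two events that recur at the same hotspot but are
separated by sub-threshold frames stay distinct. The detection cutoff is
5% dF/F0 and *inclusive*: a transient whose footprint-averaged trace peaks
at exactly 5.0% is reported. Components shorter than 2 frames or smaller
than 4 pixels are discarded as shot noise. After segmentation each
candidate is confirmed on its footprint-averaged trace (ROI-mean
semantics); per-pixel thresholding plus ROI-mean confirmation is our
automated stand-in for manual ROI selection followed by post hoc
verification, and both behaviours are configurable.

One practical detail matters at realistic noise levels: an event's
footprint is spatially coherent, so read noise makes the whole
suprathreshold region blink across the cutoff during the rise and fall,
splitting one transient into several components. `close_time_gaps = 1`
bridges single-frame gaps at pixels suprathreshold on both sides. On
noise-free input the waveforms are unimodal and the closing is exactly a
no-op, which is why the brute-force flood-fill equivalence tests hold bit
for bit.

Per-event metrics follow the conventions of the imaging literature:
amplitude is the peak of the footprint-averaged dF/F0 trace in percent;
FWHM is the time between the two half-maximum crossings found by linear
interpolation around the peak (events whose trace never falls below half
maximum inside the recording are flagged censored and excluded from FWHM
summaries rather than reported as numbers); and the aligned trace is the
41-sample window with the peak at index 20 (t = 0..40 convention),
boundary-padded and flagged when the peak is within 20 frames of an edge.

Two small caveats are worth stating. For amplitudes below twice the
cutoff, the half-maximum lies below the detection threshold, so the FWHM
legitimately spans more frames than the suprathreshold support. And event
counts are monotone in the cutoff only while footprints cannot merge;
with disjoint hard-disk events (our generator's geometry) monotonicity is
exact.

## Field statistics

`count_events_in_windows()` reproduces the standard counting scheme: a
100 um x 100 um crop at 1/3 um/px spans 300 x 300 px and tiles into nine
side-to-side 100 x 100 px windows; every event is assigned to exactly one
window by its centroid, with exact-boundary centroids going to the
lower-index window, and the field frequency is reported per minute.
`hotspot_recurrence()` clusters event centroids by single linkage at a
3 um merge radius to recover recurrence foci; with the default generator
settings the modal focus produces 1-3 events per 6-minute recording.
`cross_channel_coincidence()` matches events across two indicator
channels greedily by normalized spatiotemporal distance, one-to-one, for
dual-indicator experiments spanning astrocyte-astrocyte boundaries.
`count_puncta()` applies the same threshold-and-label logic in 3D
(26-connectivity) for punctate stains such as oxidized ROS indicators.

## Filopodium tracking and motility

The trachea channel is binarized with Otsu's threshold computed on the
first frame (the foreground/background mixture is stationary), after a
3-frame temporal majority vote that removes single-frame flicker of
pixels sitting on the anti-aliased line edge. Each connected structure is
skeletonized (Zhang-Suen thinning) and its skeleton endpoints and
junctions located. A structure is one filopodium plus its parent branch;
the branch-filopodium junction anchors the base, and the base position is
estimated as the midpoint of the two static branch-arm endpoints (median
over frames), which is robust to the spurious junction pixels thinning
produces at staircase kinks. The tip is the remaining endpoint, linked
across frames by nearest-neighbour continuity and localized to sub-pixel
precision by finding the half-intensity point of the profile along the
skeleton direction (the rendered/imaged line tapers over about one pixel
past its true end, which is subtracted). Length is the Euclidean
base-to-tip distance; filopodia are rendered straight, and arc length
along a curved path is a noted extension point. A precomputed tip table
can be supplied instead of a movie, in which case all imaging steps are
skipped.

Motility onsets are scored with a hysteresis rule: a retraction onset
requires a cumulative length decrease of at least 0.5 um over at least 3
frames (both configurable), and symmetric for extension. The *reported*
onset time is not the confirmation frame — that would be systematically
late by `min_change / rate`, about 10 s at 3 um/min — but the corner of a
local two-segment least-squares fit around the run's starting extremum,
which is unbiased for both sharp corners and plateau-then-ramp traces and
lands within one frame of the injected onset under test noise. Runs
separated by a stall (no new run extremum for at least `min_stall_s`,
default 5 s) are scored as distinct onsets; the stall criterion is
expressed in seconds, not frames, because at 300 ms sampling the
per-frame motion of a slow filopodium is below measurement noise and a
frame-count stall would trigger constantly. Classification follows the
four-category convention: extension only, retraction only, both, or
stationary. Rates are endpoint slopes over the motile segments bounded by
onsets, reported in um/min, with retraction as a positive magnitude.

## Coupling statistics

Overlap uses the maximum-domain definition: a filopodial tip overlaps an
event if, at any frame, the tip falls within the union of the event's
suprathreshold pixels over its lifetime (a pixel-set membership test in
calibrated coordinates, not a fitted circle; a convex-hull variant was
considered and rejected as it inflates concave domains). The entry time
is the first such frame. `pair_latencies()` pairs each onset of an
overlapping filopodium with the nearest *preceding* event peak within a
120 s window among the events containing that tip, breaking peak-time
ties toward the larger amplitude; unpaired onsets are kept with a null
pairing. The lag window default (120 s) comfortably brackets the ~26 s
retraction latencies and ~145 s extension intervals the analysis is meant
to resolve, and is configurable.

`onset_peak_regression()` is ordinary least squares of retraction-onset
times on paired peak times, reporting slope, intercept and R^2
explicitly. For the simulation surrogate of the published correlation we
regress each filopodium's *first* retraction onset, one point per
filopodium, mirroring the per-filopodium framing of the original
analysis; later repeats of a long retraction would otherwise re-pair with
the same peak and contaminate the fit. `bystander_control()` implements
the spatial null: events whose domain never contains the tip and whose
centroid stays at least 7.5 um from the tip (minimum over frames) are
paired by the same rule, and the onset-peak correlation of those
bystander records carries a bootstrap interval that, under the null of no
long-range coupling, covers zero. `coupling_summary()` collects the
fraction of tips with at least one overlap (counted per filopodium, the
reading we adopt of the published percentage), latency and interval
means with SEM, the regression block and the bystander block.

## The synthetic-data generator as a study design

Defaults encode the target acquisition: 360 s single-plane recordings at
0.3 s/frame, 1/3 um/px, a constant baseline of 1000 16-bit units (so a 5%
transient is 50 units, far above quantization), and additive Gaussian
read noise with SD 10 (1% of baseline; Poisson shot noise is available
but off — no noise model is published for the target data). Events recur
at hotspots (1-3 each), with amplitudes 10-30% dF/F0, FWHM drawn from a
normal with mean 5.5 s and SD 2.26 s truncated to what the recording can
hold, and hard-disk footprints of 1.5-3 um radius; the spatial size of
real microdomains is not established, so the radius range is an explicit
free parameter rather than a biological claim. The default waveform is an
asymmetric fast-rise/slow-decay kernel (half-Gaussian rise, twice-slower
half-Gaussian decay) scaled to the requested FWHM; symmetric triangle and
Gaussian kernels are provided because their FWHM geometry is analytic,
which the tests exploit.

Filopodia draw their category from the published population proportions
(1.7% extension, 20.7% retraction, 75.3% extension-and-retraction, 2.3%
stationary), start 4-7 um long, extend at 2 um/min and retract at
3 um/min by default (rates of this order are what the target system
shows; they are configurable), and are anchored to a 5 um parent branch
drawn perpendicular through the base so the base is visible to the
tracker as a skeleton junction. Retraction floors at 2.2 um because a
shorter stub attached to a 2 px branch is erased by thinning. With
coupling enabled, each extension-and-retraction filopodium is steered so
its tip reaches the centre of a dedicated event at that event's peak and
begins retracting at peak + 25.9 s + Gaussian jitter (SD 2.18 s); a
filopodium for which no event is reachable inside the field is rendered
uncoupled and flagged. Two identifiability constraints are part of the
design: structures keep 1.2 um clear of each other, and a filopodium's
path keeps at least `radius + 1` um clear of every event footprint except
its own target, so each detected onset has one unambiguous preceding
event. A drug epoch, when configured, multiplies the event-time density
after its onset (default usage: application at 3 min, emulating bath
application halfway through the recording).

What the generator does *not* emulate — optics and PSF blur,
photobleaching, drift and motion artifacts, curved or branching
filopodia, out-of-focus signal, inhomogeneous background — bounds what
passing tests show: recovery results demonstrate the analysis is correct
and well-calibrated on data satisfying its geometric assumptions, not
that it is robust to every artifact of real microscopy.

## Numerical choices and problem sizes

All randomness flows from a single integer seed per configuration;
sub-streams for events, noise and filopodia are derived deterministically
from it, so every output is a pure function of the configuration. The
detection cutoff comparison subtracts 1e-12 before testing `>=` so that
an amplitude of exactly 5% survives floating-point division. Breakpoint
refinement treats residual sums within 1e-10 as tied and takes the
earliest candidate, so exactly linear traces anchor their onset at the
first frame. Window assignment resolves exact-boundary centroids to the
lower-index window; event ordering breaks peak-time ties by centroid row
then column; pairing breaks peak-time ties by amplitude.

The test-suite and acceptance problem sizes were chosen to give the
statistical checks adequate power while keeping a full run comfortable on
one CPU: the coupled cohort uses ten 6-minute two-channel movies at
128 x 128 px (about 70 coupled pairs), FWHM recovery uses five 192 x 192
px movies (about 300 events), and the drug-epoch and overlap-fraction
recoveries run on generator ground truth directly, where rendering adds
nothing to the quantity under test.

## Known limitations

Tracking assumes one filopodium per branch structure and no crossings;
the generator enforces this, real data need not. The latency pairing is
temporal-precedence only and makes no causal claim. The bystander
correlation is a null check, not an effect-size estimate. FWHM censoring
at recording edges biases the FWHM summary slightly downward for long
events in short recordings; censored events are therefore counted and
reported separately.
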