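# filocal

Quantitative analysis of astrocyte microdomain Ca²⁺ transients and their
spatiotemporal coupling to tracheal filopodial dynamics in two-channel
time-lapse fluorescence movies — with a synthetic-movie generator that
provides full ground truth, so every stage of the analysis can be
validated by parameter recovery.

## The problem

Astrocytes show spatially restricted, near-membrane microdomain Ca²⁺
transients in their fine processes. In the larval *Drosophila* CNS these
transients sit next to tracheal branches — the insect's gas-exchange
tubules — which continuously probe the neuropil with actin-rich
filopodia. The analytical question: when a filopodial tip enters the
spatial domain of a Ca²⁺ transient, does retraction follow the event peak
at a short, consistent latency, and is that coupling absent for
"bystander" events the tip never touches?

`filocal` implements the full measurement chain:

1. **Event detection.** Per-pixel dF/F₀ = (F_t − F₀)/F₀ with a
   percentile baseline; spatiotemporal connected-component segmentation
   at the inclusive 5% dF/F₀ cutoff; per-event amplitude (% dF/F₀, peak
   of the footprint-averaged trace), FWHM (interpolated half-maximum
   crossings, censoring-aware), and a 41-sample aligned trace with the
   peak at t = 20 of t = 0..40.
2. **Field statistics.** Nine-window (100×100 px) event counting with
   events/min, single-linkage hotspot recurrence histograms, two-channel
   event coincidence matching, and 3D puncta counting for ROS stains.
3. **Filopodia.** Skeleton-based tip tracking with sub-pixel tip
   localization, hysteresis onset detection with unbiased two-line
   breakpoint refinement, four-category motility classification
   (extension / retraction / both / stationary), and rate / max-length /
   epoch-ratio summaries.
4. **Coupling.** Maximum-domain overlap (tip inside the union footprint),
   entry times, onset–peak latency pairing (nearest preceding peak), OLS
   regression of retraction onsets on paired peaks (slope, intercept,
   R²), and a 7.5 µm bystander null with a bootstrap interval.
5. **Pipeline.** `run_pipeline()` chains simulate → detect → track →
   couple → report deterministically from one seed, writing tidy CSVs, a
   JSON summary, a markdown report and a maximum-intensity projection;
   `inst/cli/filocal.R` wraps it for the shell.

All tabular results are tibbles; fitted objects support
`generics::tidy()` / `glance()`; `plot_*()` functions cover the standard
figures.

## Worked example

Simulate a coupled two-channel recording (240 s at 0.3 s/frame, 45 µm
field), run the chain, and summarise the coupling:

```r
library(filocal)

cfg <- sim_config(duration_s = 240, field_size_um = c(45, 45),
                  n_hotspots = 6, events_per_hotspot_range = c(1, 2),
                  n_filopodia = 4, category_proportions = c(0, 0, 1, 0),
                  coupling_enabled = TRUE, seed = 42)
ca      <- generate_ca_movie(cfg)
trachea <- generate_trachea_movie(cfg, ca$events)

events  <- detect_events(compute_dff(ca$movie))
tracks  <- track_tips(trachea$movie)
records <- pair_latencies(events, tracks)
coupling_summary(records, tracks, events)
#> <coupling_summary> 100.0% of 4 tips overlap an event domain
#>   retraction latency 27.38 +/- 0.55 s (n = 4)
#>   extension interval NA +/- NA s (n = 0)
#> <onset_peak_fit> onset = 0.993 * peak + 28.14 s, R^2 = 0.9997 (n = 4)
```

All four filopodia were steered into an event (injected latency
25.9 ± 2.18 s); the recovered mean latency is 27.4 ± 0.6 s and the
onset–peak regression has slope ≈ 1 with R² ≈ 1, i.e. onsets track peaks
at a fixed lag. The detected events themselves carry the per-event
metrics:

```r
head(events[, c("event_id", "peak_time_s", "x_um", "y_um",
                "amplitude_pct", "fwhm_s")], 4)
#>   event_id peak_time_s      x_um      y_um amplitude_pct   fwhm_s
#> 1        1        51.6 39.485944 38.429719      15.75839 2.865163
#> 2        2        53.4 16.812325 25.299720      21.49082 2.793160
#> 3        3        84.3  9.174041 35.817109      28.31763 6.033787
#> 4        4       130.8 36.856918  4.190252      28.22891 2.506384

hotspot_recurrence(events)
#> <hotspot_recurrence> 7 events at 6 foci
#> # A tibble: 2 x 2
#>   events_per_focus n_foci
#>              <int>  <int>
#> 1                1      5
#> 2                2      1
```

`amplitude_pct` is the footprint-averaged peak dF/F₀ in percent,
`fwhm_s` the interpolated full width at half maximum in seconds, and the
recurrence histogram counts how many foci produced 1, 2, ... events.

The columns of `events.csv` written by the pipeline are, in order:
`event_id, hotspot_id, onset_frame, offset_frame, peak_frame,
peak_time_s, x_um, y_um, amplitude_pct, fwhm_s, fwhm_censored,
edge_flagged, area_px, duration_s` (µm and seconds throughout).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the event
model, the tracking and onset estimators, the coupling definitions, the
generator's design (and what it deliberately does not emulate), numerical
choices, and known limitations.
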