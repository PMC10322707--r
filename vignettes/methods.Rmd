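---
title: "Models and methods for quantifying two-stage octopus sleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantifying two-stage octopus sleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephalosleep)
```

# The system and the measurements

Octopuses alternate between two sleep stages. Quiet sleep (QS) shows a flat
posture and a uniformly white skin pattern, punctuated by brief (~7 s)
"colour flashes" -- subtle darkenings of mean skin brightness. Roughly every
hour of daytime sleep, a ~75 s active sleep (AS) bout interrupts QS with
rapid transitions through macroscopic skin patterns, eye and body movements
and elevated, irregular breathing. This package implements the quantitative
pipeline around three data modalities:

* **Skin-brightness traces** -- the per-frame mean brightness of the
  segmented animal (8-bit units, ~24 fps). Because the resting pattern is
  white, both AS bouts and QS flashes appear as brightness *decreases*; all
  detectors therefore operate on the negated, z-scored signal.
* **Multi-channel LFP** -- channels x samples arrays (uV, 2.5 kHz
  acquisition) with per-channel atlas coordinates, region labels and an
  out-of-brain flag used for common-mode re-referencing.
* **Skin-pattern feature trajectories** -- one feature vector per video
  frame (512 dimensions by default), one trajectory per AS bout.

Raw recordings of live animals are not distributable, so the package pairs
every analysis path with a synthetic generator that emulates the statistical
structure of the corresponding modality and emits ground truth. All
parameter-recovery and acceptance tests run against these generators.

# Behavioural detectors

**Flash detection** (`detect_flashes()`, `detect_flashes_qs()`): band-pass
0.005--2 Hz (three-pole Butterworth, applied forward--backward so event
times are not shifted), negate, z-score, then peak detection with minimum
height 2 z, minimum topographic prominence 0.5 z and minimum separation
10 s. Two numerical choices matter:

* The trace is demeaned before filtering; otherwise the filter's startup
  transient on the ~200-unit brightness offset dominates the variance.
* Detection runs *per QS interval* (`detect_flashes_qs()`), with AS/wake
  annotations supplied as inputs. Filtering across deep AS excursions
  injects slow ringing up to ~150 s from bout edges that would otherwise
  register as spurious flashes; QS-restricted detection is also how the
  original analysis was performed.

**Flash duration** (`flash_duration()`): a window from 500 frames before
the peak to 1000 frames after is z-scored; the duration runs between the
last 2 z crossing before the peak and the first after it (on the negated
signal -- the darkening convention; the alternative orientation is not
meaningful for white-resting animals). Sides without a crossing clamp to
the window edge and are flagged.

**Bout duration** (`estimate_bout_duration()`): a window 10 s before to
100 s after the AS start is z-scored and low-pass filtered at 0.1 Hz
(two-pole); the duration is the longest contiguous run below -0.2 z.
Two failure modes are surfaced rather than hidden: windows with no
sub-threshold sample return 0 with `flagged = TRUE`, and runs ending within
half a filter time constant (5 s) of the window edge set
`truncated = TRUE` -- with bouts distributed as ~N(75, 28) s, roughly a
quarter outlast the 110-s analysis window and their durations are lower
bounds, not measurements. Recovery statistics in the tests are computed
over non-truncated estimates. A residual failure mode remains when a bout
fills the entire window: the z-score contrast collapses and the run can
fragment; this is inherent to the published windowed procedure.

**Bout starts** (`detect_bout_starts()`): bout onsets were annotated
manually in the original protocol; this convenience detector thresholds
the low-pass-filtered negated z trace at 3.5 z with a 20-s minimum run.
The threshold sits between low-passed flashes (~2.6 z at the generator's
defaults) and bouts (~9 z); it has no published counterpart.

**Circadian structure** (`circadian_rate()`, `rayleigh_test()`): 2-h
histograms; a continuous rate from a 0.1-h binning convolved with a
Gaussian kernel of SD 40 bins (4 h) with reflective edges, so total event
mass is conserved; and a kernel density estimate of 5-min-binned times
(Silverman bandwidth -- the estimator is named in the source protocol, the
bandwidth is not). The Rayleigh statistic uses phases
$2\pi (t \bmod P)/P$, $\bar R = |\mathrm{mean}(e^{i\theta})|$,
$Z = n\bar R^2$, and the finite-$n$ corrected approximation
$p = \exp\{\sqrt{1+4n+4(n^2-nZ)} - (1+2n)\}$. Monte-Carlo checks hold the
type-I error within [0.04, 0.06] at $\alpha = 0.05$ for $n \in \{10, 50,
100\}$ and power above 0.9 for von Mises concentration $\kappa = 1$ at
$n = 50$.

**Temperature model** (`fit_temperature_model()`): OLS of inter-bout
interval (minutes) on temperature with intercept, reporting slope, $R^2$,
the F statistic against the constant model and its p value -- the same
reporting tuple used for the real-data result (slope about -5 min/degC,
$R^2 = 0.55$, $F = 291$, $n = 243$; those numbers require the original
recordings and are not reproduced here). `tidy()` and `glance()` methods
expose the fit in the usual tabular forms.

**Movement metrics**: `reaction_magnitude()` is the mean movement
magnitude over 1 s after a stimulation minus the mean over 1 s before.
`breathing_metrics()` smooths the residual movement trace with a 10-frame
centred moving average (half-weight ends, so even-length windows introduce
no half-sample delay), z-scores, detects peaks at prominence 0.05 and
linearly interpolates the instantaneous rate to the frame rate; CV is
SD/mean of the inter-peak intervals.

# Electrophysiology

**Preprocessing** (`preprocess_lfp()`): polyphase resampling to 1 kHz,
zero-phase band-pass 0.1--150 Hz (three-pole Butterworth), then per-sample
subtraction of the median of the out-of-brain channels. Because the
reference channels pass through identical linear steps, any common-mode
component cancels exactly (machine precision). The bundled resampler
(`resample_poly()`, Blackman-windowed sinc) is flat to <0.01% in its
passband; the general-purpose alternative in the `signal` package has ~7%
passband ripple, which is why the package carries its own. Note the band
edges themselves shape the spectrum: a 100 Hz tone retains ~94% of its
amplitude after the zero-phase pass (the analytic Butterworth response,
squared), and 200 Hz is attenuated ~16 dB -- properties of the published
filter, verified against its analytic magnitude response.

**Band intensity** (`band_intensity()`): per segment and channel,
band-pass (0.1--10 or 20--150 Hz), analytic envelope via a 151-tap FIR
Hilbert transformer (an even "150-tap" design cannot be the required
odd-length type III; the one-tap deviation is deliberate), mean envelope
over filter-valid samples, a 5-channel sliding median across the channel
axis (shrunken windows at the array edges), then averaging over segments.
A 0.15-s transformer spans less than one period below ~7 Hz, so the
low-band envelope of very slow tones is underestimated (0.85x at 5 Hz);
this is a property of the published filter length and is left intact --
the tone-amplitude checks use high-band frequencies where the transformer
is valid.

**State segments** (`extract_state_segments()`, `extract_qs_chunks()`):
60 s from each AS/wake onset; the 60 s before each AS onset as QS; 0.7-s
windows centred on flashes; and long (up to 1200 s) pre-AS QS windows for
oscillatory-event scanning, with wake intervals excised. Segments exceeding
the record bounds are dropped with a warning.

**Spindle-like events** (`detect_osc_events()`): per channel and QS
segment, band-pass 4--40 Hz, z-score per segment (matching the chunked
loading of the original analysis; a global z is the plausible alternative
and would differ only when segments have very different variances), then
peaks with height 2 z, prominence 2 z, separation 1 s. Rates are events
per second per segment, averaged with equal weight (chunk weighting was
left open in the source; equal weighting is the simpler choice), then
median-filtered across channels. The fixed 2 z threshold presupposes a
nearly silent background punctuated by large events -- the regime of the
recorded brain region. The generator reproduces it: spindle amplitudes
default to 200--700 uV against a few-uV background, with log-normal
inter-event intervals (the simplest heavy-tailed family).

**Spectra**: `wavelet_spectrogram()` implements a complex Morlet CWT
(bandwidth 1.5, centre frequency 1.0; 100 log-spaced frequencies in
1--100 Hz; kernels L1-normalized so a pure tone excites every scale
equally), magnitude-normalized to a maximum of 1.
`multitaper_spectrum()` uses DPSS tapers (time-bandwidth 5, 9 tapers)
on non-overlapping 1-s chunks; the tapers are computed from the standard
symmetric tridiagonal eigenproblem and cached, and the one-sided density
integrates to the signal variance (Parseval check in the tests).

**Region aggregation** (`region_aggregate()`): channel means per region,
excluding regions sampled by fewer than two probes; optional
anterior/posterior split at the midpoint (min + max)/2 of the region's
A--P coordinate span, with the coordinate column and its polarity as
explicit arguments rather than hard-coded.

# Skin-pattern trajectories

Distances: `intra_distance()` (mean consecutive-frame Euclidean distance),
`inter_distance()` (mean element-wise distance at zero lag, up to the end
of the shorter trajectory), `nearest_distances()` (per-frame minima,
irrespective of time), and `dtw_align()`/`dtw_ratio()` -- full
dynamic-programming DTW with Euclidean local cost, symmetric unit-weight
steps and no window, validated against exhaustive path enumeration on
small instances. The DTW ratio divides the mean alignment cost by the
zero-lag inter distance; the source description is ambiguous about the
divisor, so the cumulative path length is available as an option
(`divisor = "path_length"`).

`align_start()` computes the first principal component per trajectory
(the per-trajectory reading of the feature-by-frame matrix) and returns
the first frame whose PC1 score changes by more than 0.1 between
neighbours, with an explicit no-start signal distinct from frame 1.

`parallel_analysis()` estimates dimensionality as the number of leading
sample-correlation eigenvalues exceeding the 95th percentile of
column-permuted surrogates (permutation preserves marginals while
destroying correlations; Horn's mean criterion is available via
`method = "mean"`). `silhouette_by_animal()` is the standard Euclidean
silhouette with animal identity as the label, on a seeded subsample
without replacement. `wake_in_as_test()` reports, for each waking
feature vector, the nearest distance to any AS frame against the
distribution of intra-trajectory steps (bound: a configurable quantile,
default 0.95).

The default featurizer (`default_featurizer()`) is a deterministic
filter bank: 4 wavelengths x 8 orientations of complex Gabor kernels with
exactly zero DC response, local energy pooled over a 4 x 4 grid -- 512
dimensions. It stands on its own as a pattern descriptor; pretrained-network
featurizers plug in through the same `featurizer()` interface but are never
required.

# Image warping

`align_mantle()` fits second-moment ellipses to the mantle masks and maps
one image onto the other by the similarity transform carrying centre and
major axis across, with the 180-degree axis ambiguity resolved by an
explicit anterior flag; output is cropped to the reference mask and
downsampled to 20% with a uniform grey background. `mls_warp()` is
similarity-variant moving least squares (rotation + isotropic scale per
query point, inverse-square distance weights) -- the similarity variant
avoids the shear artifacts an affine fit produces on elongated mantles --
computed in closed form via complex arithmetic, applied by backward
mapping with bilinear sampling. It interpolates control points exactly
and reduces to the global similarity transform when one exists.
`threshold_match()` inverts both greyscale images, binarizes at an
image-specific threshold (Otsu, clipped to the 180--230 interval used in
the source protocol) and scores intersection-over-union.

# What the generators emulate, and what they do not

`gen_brightness_trace()` produces: Gaussian frame noise (`noise_sd`, white)
plus a slow in-band background fluctuation (0.01--0.05 Hz, `slow_sd`);
AS bouts as sustained negative excursions (duration ~N(75, 28) s truncated
at 10 s, 2-s raised-cosine transitions); QS colour flashes as 7.1-s Hann
dips whose rate decays linearly from 0.4 to 0.1 events/min across each QS
stretch; bout timing as a renewal process with start-to-start intervals
~N(60 + (-5)(T - 22), 16.4) min run in an "operational time" that advances
at full rate during the subjective day (06:00--18:00) and at 1/8 rate at
night (30-min cosine taper), so realized daytime intervals average the
configured mean while night sleep is suppressed and labelled wake.
Overlapping events are resampled, keeping the schedule disjoint. Under
these defaults a 24-h day contains ~13 bouts -- at the upper edge of the
descriptive 10 +/- 3.5 range, a consequence of keeping the daytime interval
mean at 60 min.

Event amplitudes deserve a note. Real traces are means over ~1e5 animal
pixels, so frame noise is orders of magnitude below event depth; the
defaults (flashes 14x, bouts 30x frame noise) are conservative relative to
that reality but deliberately place the trace in the event-dominated
variance regime that fixed z thresholds presuppose. With
variance-comparable white noise, a 2 z threshold sits on the Gaussian
noise floor and *any* detector parameterized this way floods with false
positives -- a structural property worth knowing when transferring the
published thresholds to noisier pipelines. Flashes are generated in every
daytime QS stretch (including before the first and after the last bout):
a zero-event stretch has no event-dominated variance and would be
mis-scored by any z-based detector.

The generator does not model: waking locomotion or posture changes (night
"wake" is spectrally identical to QS baseline), lighting drift, animal
growth across days, or the skewness of real bout-duration distributions.
Passing tests therefore demonstrate correct recovery of the configured
statistical structure, not robustness to every artifact of real video.

`gen_lfp()` synthesizes band-limited noise per channel whose low
(0.1--10 Hz) and high (20--150 Hz) band SDs switch with behavioural state
(AS > wake > QS by default), spindle-like Hann-windowed sinusoids
(12--18 Hz, 0.3--1 s, 200--700 uV) on a designated channel subset during
QS only with log-normal inter-event intervals (meanlog log 8, sdlog 0.8 --
mean ~11 s, chosen to yield tens of events per 10-min QS stretch), plus a
common-mode artifact added identically to every channel. It does not model
1/f spectral shape within bands, spikes, or probe drift.

`gen_pattern_trajectories()` builds a library of 70 macroscopic patterns
whitened to an exactly isotropic rank-60 latent covariance (the library
must exceed the rank for the dimensionality to be a well-posed recovery
target), embedded in 512 dimensions by a random orthonormal basis. Each
bout visits 20 random library patterns (dwell ~Poisson(100) frames,
25-frame linear transits, ~83 s per bout at 30 fps -- inside the real
75 +/- 28 s range), with AR(1) jitter (rho 0.5, innovation 0.22/dim)
around the itinerary, a small per-animal offset (SD 0.1, so animals
overlap), and exact white-pattern endpoints. Visiting 20 of 70 patterns
gives bout pairs enough shared patterns that the nearest-point distance
distribution overlaps the intra-step distribution (coefficient ~0.24),
while the zero-lag inter distance stays ~5x the intra distance --
qualitatively matching the reported real-data geometry (~6x). It does not
model pattern-specific dwell preferences or sequential correlations
between visited patterns.

`gen_pattern_image_pair()` renders a mottled mantle texture (dark
elliptical Gaussians plus band-limited noise on a bright background) and
a warped copy generated by the package's own MLS warp from a 4 x 4
control grid with ~12 px displacements (random direction, magnitude
0.8--1.2x, so every seed's warp is substantial); fold-over (non-positive
Jacobian) raises an error rather than producing a silently invalid pair.

# Problem sizes and tolerances

The test suite and the acceptance script use these sizes: 20 seeds of
24-h behavioural traces; 20 seeds of 600-s spindle injections at 2.5 kHz;
2000 replicates per Rayleigh condition; 100 exhaustive DTW instances
(T <= 6); pattern-space checks on the full default generator (24 bouts,
~60k frames) for dimensionality and silhouette, and 2-animal x 2-bout
datasets with 4-frame striding of the pairwise distance computations for
the per-seed ordering checks (striding affects only the nearest/inter
estimates, conservatively); 20 image pairs. Monte-Carlo assertions use
2--3 SEM bands computed from the data; exact properties (common-mode
cancellation, DTW vs enumeration, identity warps) are asserted at
machine precision.

# Known limitations

* Bouts longer than the 110-s duration window are reported as truncated
  lower bounds (see above).
* The low-band Hilbert envelope underestimates sub-7 Hz amplitudes by
  design of the 151-tap transformer.
* The flash-duration crossing rule is noise-sensitive for events whose
  windowed z height sits near 2; the estimator flags clamped windows but
  cannot flag mid-window noise crossings.
* `align_start()`'s 0.1 threshold applies to PC1 scores in feature units;
  featurizers with very different output scales need a rescaled threshold.
* HDF5 containers are not read or written; traces, schedules and event
  tables move through CSV/JSON, and in-memory matrices stand in for image
  and LFP payloads.
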