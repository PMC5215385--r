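---
title: "holotrace: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{holotrace: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holotrace)
```

holotrace implements the computational core of scanless two-photon
imaging: instead of raster-scanning a single focus, a spatial light
modulator (SLM) splits the excitation beam into many stationary
diffraction-limited spots, one per neuron, and a camera records all of
them simultaneously at up to kilohertz frame rates. The per-target dwell
time is then the inverse of the acquisition frequency, independent of
how many targets are illuminated (`dwell_time()`), which is what buys
the order-of-magnitude gain in signal-to-noise over scanning at matched
frame rates. The package covers four computational blocks — hologram
synthesis, fluorescence trace processing and event detection,
population correlation statistics, and optical-contamination modeling —
plus a synthetic-data generator that stands in for the microscope and
the juxtasomal electrode, so that every stage is testable end to end
without hardware.

## Hologram synthesis

The SLM is modeled as an `n x n` phase-only array under a unit-disc
aperture; the focal field is its discrete Fourier transform, so focal
coordinates are integer DFT bins with the undiffracted zero order at
bin (0, 0) (`slm_grid()`, `propagate()`). The propagation oracle is
normalized so that total focal energy equals total aperture energy
(Parseval), which the tests enforce to a relative 1e-10.

Multi-spot masks are synthesized with a weighted Gerchberg–Saxton
iterative Fourier-transform algorithm (`wgs()`): propagate, read the
complex amplitude at each target, update the per-site weight by the
ratio of the mean site amplitude to that site's amplitude (each
measured relative to its target), impose the weighted target amplitudes
at the sites with the current phases, inverse-transform and keep the
phase over the aperture. Two numerical choices matter:

* **Damping.** The textbook weight update has gain close to 2 when few
  sites share the energy: correcting a site pushes energy out of the
  others, so a pair of sites with unequal targets oscillates
  indefinitely. The update is therefore applied with an exponent of 0.5
  (`damping`), which makes every case contractive; for ten or more
  uniform targets the damped and undamped variants converge to the same
  >= 0.90 min/max intensity uniformity within 30 iterations.
* **Zero order.** The undiffracted component is not modeled optically;
  bin (0, 0) is simply reserved and rejected as a target, matching the
  experimental practice of steering the zero order onto a
  non-fluorescent structure or defocusing it.

Per-site intensity compensation corrects fluorescence losses at
specific sites (vasculature above a cell, diffraction-efficiency
fall-off toward the edge of the field of view, where efficiency drops
to ~40%). From measured site intensities `I_m` with average `Ibar`, the
factor is `xi_m = clip((Ibar/I_m)^rho, 0.5, 4)` with `rho` in
[0.5, 2] (`compute_xi()`), applied as a fixed multiplicative prefactor
on the target amplitude across all WGS iterations. The closed loop
(`feedback_compensation()`) alternates synthesis with simulated
measurement (propagation attenuated by a radial efficiency model) and
accumulates xi multiplicatively. Because the measured intensity
responds quadratically to an amplitude prefactor, the loop contracts
fastest at `rho = 0.5` (one round under an ideal quadratic response)
and oscillates at `rho = 1`; the closed-loop default is therefore 0.5,
while `compute_xi()` keeps `rho = 1` as its single-shot default.
Convergence is checked before any update, so a uniform efficiency is an
exact fixed point with xi staying 1. When the required correction
exceeds the [0.5, 4] clip range the best round is returned with a
warning flag rather than an extrapolated mask.

`fit_calibration()` maps scan-image coordinates to SLM focal
coordinates with a least-squares affine transform (>= 3 non-collinear
pairs); synthetic affine maps are recovered to residuals below 1e-9.

## Trace extraction and normalization

For each illumination site the signal is the mean of the 4 pixels
closest to the site and the local background the mean over an outer
ring of 20 pixels (`roi_geometry()`, `extract_traces()`). The ring is
defined as the 20 pixels whose centre distance is closest to 2.5 px,
excluding the signal pixels, with deterministic (angle, index)
tie-breaks; coordinates are 0-based (row, col) with pixel centres at
integers. Intensities are camera digits (dgt).

Two normalizations are provided (`normalize_traces()`):
`dF/F0 = (F - F0)/F0` with a running baseline `F0` computed by a 0.75 s
centred moving average followed by a running minimum over a +/- 1.5 s
window, and `dF/bg = (F - bg)/bg` against the ring background. All
windowed operators (moving average, running minimum, the EWMA low-pass
`y_t = alpha x_t + (1 - alpha) y_{t-1}` with
`alpha = 1 - exp(-1/(fs tau))`) use truncated windows at the edges —
no padding is fabricated — and each is tested sample-for-sample
against a naive brute-force oracle. The running minimum uses the
two-pass prefix/suffix (van Herk) algorithm, so `compute_f0()` is O(T)
rather than O(T·W) at kilohertz rates. The average integral of a
normalized trace is its trapezoidal time integral divided by the
recording duration, so a constant trace integrates to its own value;
the normalization is per recording (the per-event alternative is a
caller-side windowing choice).

## Event detection and transient fitting

`detect_events()` implements a derivative-threshold pipeline: EWMA with
tau = 100 ms, first difference, 100 ms moving average, then a noise
estimate and threshold. The noise sd of the processed signal comes from
a least-squares zero-centred Gaussian fit to its histogram
(Freedman–Diaconis bins), restricted to bins with centre <= 0 so that
the positive-going transients in the upper tail do not inflate the
estimate (`estimate_sigma()`; 1% contamination moves the estimate by
less than 5%). Threshold up-crossings above 4–5 sigma (default 5, the
conservative end of the conventional range) become events, with a
150 ms refractory time: a crossing within 150 ms of the previously
accepted one is merged into it. Three conventions are worth stating:

* The refractory spacing is defined on the threshold-crossing
  (detection) times, reported as `detect_s`. This guarantees both the
  >= 150 ms spacing and that the event count is monotone non-increasing
  in the threshold; anchoring the refractory on peak times instead
  provably breaks threshold monotonicity, because a lower threshold
  lengthens the above-threshold run, delays the peak and can blank a
  later event that a higher threshold keeps.
* Detection is blanked during the filter settling regions (the first
  `3 tau + W/2` seconds and the trailing half moving-average window):
  the truncated edge windows inflate the processed-signal variance and
  would otherwise fabricate edge events.
* For low frame rates (<= 40 Hz) negative values of the processed
  signal can be rectified to zero (`rectify_negative`), which helps
  find events riding on the decay of earlier transients; the noise sd
  is always estimated before rectification, since rectification
  destroys the negative side the zero-centred fit relies on.

Each transient is fitted with the four-parameter function
`A (1 - exp(-(t - t0)/tau_up)) exp(-(t - t0)/tau_down)` (zero before
`t0`), with all parameters positive and `tau_up <= 2 s`,
`tau_down <= 5 s`, by bounded Levenberg–Marquardt least squares over a
window around the peak, multi-started on a small (tau_up, tau_down)
grid (`fit_transient()`). The peak time t1 serves as the initial guess;
the onset is the fitted `t0`, estimated on the trace pre-filtered with
a tau = 5 ms EWMA. A local baseline offset is co-estimated as an
unbounded nuisance parameter — subtracting a pre-peak median instead
mistakes slow rises for baseline. Noiseless self-generated curves are
recovered to relative errors below 1e-4; at 10% noise the onset agrees
with a dense grid-search oracle to within two samples.

Ground-truth comparison uses greedy one-to-one nearest-neighbour
matching within +/- 100 ms (`match_events()`; it agrees with an
exhaustive assignment oracle on the matched count), detection accuracy
being the fraction of electrophysiological events with an associated
calcium transient. Spike trains are segmented into bursts by the
100 ms inter-spike rule (`classify_bursts()`), which bounds the
detectable burst-event rate at 10 Hz.

## Correlation statistics

Traces are low-passed with a tau = 15 ms EWMA before Pearson
correlation over every neuronal pair (`pairwise_correlation()`); the
network correlation is the mean over all pairs, and the instantaneous
network correlation recomputes it in overlapping 1 s windows
(`instantaneous_network_correlation()`) with a default stride of 0.1 s
— ten evaluations per window; the within-window recomputation (rather
than averaging precomputed pair series) is the chosen reading of
"overlapping windows". Stimulus-epoch analysis compares the 1 s window
preceding each light onset with the stimulus window itself
(`epoch_correlation()`). Constant traces have undefined correlation and
are excluded from network means with a warning.

## Crosstalk metrics

`separation_S()` scores the resolvability of two neighbouring intensity
peaks on a raw line profile as `S = 1 - 2 I_h / (I_P1 + I_P2)`: 1 for
fully separated peaks, 0 for no dip. `contamination_C()` is the
scale-invariant ratio `C = I_c / I_a` of the signal measured at a
non-illuminated neighbour to the illuminated cell's own signal. Under
the approximations that the two ROIs have similar baselines and noise
(`F_base2 ~ F_base1`, `sd2 ~ sd1`), the SNR of the contaminated
transient in the neighbour reduces to `SNR2 = C * SNR1`
(`propagate_snr()`): with C <= 0.07 and SNR1 ~ 15 (a four-AP burst)
this stays near 1, safely below the 4-sigma detection threshold, so
scattering crosstalk does not fabricate events.

## Contamination Monte Carlo

The imaged neuron is modeled as a fluorescent spherical shell (outer
diameter 13.2 um, thickness 3 um — cytoplasmic GCaMP with a
non-fluorescent nuclear cavity) in an effectively infinite neuropil of
0.7 times the shell intensity. The excitation volume is a separable
3-D Gaussian with FWHM 0.7 x 0.7 x 2.7 um, `sigma = FWHM/2.355` per
axis. A spot is placed uniformly inside the shell, excluding points
within 0.5 um of the outer limit, and the PSF-weighted fluorescence is
integrated on a fixed 0.1 um Cartesian grid spanning +/- 4 sigma per
axis (truncation plus discretization error at the 1e-3 level; a 0.05 um
grid and a direct Monte Carlo sampler agree within 1%). The
neuropil ratio `R = outside/inside` is averaged over 1000 placements
(`neuropil_ratio()`); the per-placement outside *fraction*
`R/(1 + R)` is reported alongside.

Under these defaults the simulation yields `mean R ~ 0.05` with
placement-to-placement sd ~ 0.07: the Gaussian leaks appreciably only
for spots near the shell boundaries, mostly along the elongated z axis.
This is well inside the literature's "up to 30% neuropil" envelope but
smaller than the ~0.3 mean reported for this class of shell geometry.
The discrepancy is parametric, not algorithmic: a compact Gaussian with
the stated widths is a conservative model of the excitation volume,
because real two-photon excitation in homogeneously labeled tissue has
out-of-focus and scattering tails that a diffraction-limited Gaussian
does not capture. Re-running the identical simulation with the FWHM
values used directly as Gaussian sigmas — an effective volume 2.355x
wider per axis — gives `mean R ~ 0.27 +/- 0.16`, reproducing the
published scale; `psf_model(sigma = ...)` exposes exactly this
sensitivity analysis. The package default remains the standard
conversion, and the acceptance checks report the faithful value.

`neighbor_contamination()` adds a second, identical shell at a given
centre distance (along the optical axis by default — the "cell directly
above or below" geometry; laterally via `axis = "x"`), stretching the
integration grid along that axis so the neighbour is always covered,
and reports worst-case and mean contamination (fluorescence excited in
shell 2 over shell 1) across placements. At 15 um the worst case is
~2%, under the 16% empirical bound, and it falls by many orders of
magnitude by 20 um; shells overlap below 13.2 um, which is flagged but
still computed. `pair_distance_fraction()` gives the fraction of cells
whose nearest neighbour lies below a threshold distance (15 um by
default), the quantity that says how often such contamination can occur
at all.

## Synthetic data

The generator produces ground-truth spike trains of Poisson-placed
single APs and bursts (1–4 APs, inter-spike interval < 100 ms inside a
burst). The hard-core 100 ms separation between events is enforced by
the uniform-order-statistics construction with mandatory gaps, which
preserves the Poisson event counts exactly instead of thinning them.
Fluorescence is the linear superposition of one transient kernel per
spike — the same four-parameter form the fitter assumes, with defaults
emulating a fast GCaMP6 indicator (19% dF/F per AP, 50 ms rise, 600 ms
decay, 5 ms onset latency); no amplitude saturation is modeled, the
simplest choice consistent with SNR growing with the number of APs.
Camera digits are emulated as `F = F0 (1 + dFF) + N(0, sd) + drift`
(`add_noise_and_baseline()`); photon shot noise and camera-specific
quadrant gains are deliberately out of scope.

Populations (`generate_population()`) combine shared network events —
each cell recruited with a participation probability and a per-cell
Gaussian onset jitter, the minimal mechanism for synchronized events
with distinct per-cell initiation times — with independent per-cell
events and additive Gaussian noise. The defaults (0.04 events/s shared
rate, participation 0.8, 10 ms jitter, 0.04 events/s independent,
noise sd 0.05 dF/F) emulate sparse spontaneous cortical activity
(~0.04 Hz event rates); disinhibited, gabazine-like synchrony is
reached by raising the shared rate and participation. Crosstalk is
applied as a linear mixing matrix with unit diagonal
(`apply_crosstalk()`), and square-pulse light artifacts of configurable
amplitude emulate single-photon stimulation epochs
(`inject_light_artifact()`).

What passing tests on this generator do and do not show: the generator
shares its kernel with the fitter and its event statistics are exactly
Poisson, so recovery tests demonstrate the correctness of the analysis
chain, not its robustness to model mismatch (indicator nonlinearity,
movement, slow drifts, non-Gaussian camera noise are all absent). The
monotonicity properties (accuracy and SNR vs APs per burst, count vs
threshold, synchrony vs jitter) are the model-independent claims and
are what the suite asserts.

## Problem sizes and determinism

Every stochastic operation takes an explicit integer seed and is
bit-reproducible under it; the pipeline report embeds the fully
resolved configuration. The test suite runs populations of 5–20 cells
at 250–1000 Hz for 12–60 s, 50-seed detection ensembles, and the
full 1000-placement neuropil Monte Carlo — sizes chosen so the whole
suite completes in a few minutes on one core while keeping every Monte
Carlo band well separated from its decision boundary. File I/O is
plain-text CSV/JSON/YAML (plus 16-bit TIFF for masks and stacks), with
a mandatory `fs_hz` metadata line making trace files self-describing.

## Known limitations

* No optical hardware control, Zernike/aberration correction, temporal
  focusing or 3-D multi-plane holography; the FFT far field is an
  aberration-free model.
* The contamination model is geometric: no wave-optics PSF, no
  scattering Monte Carlo through tissue, no depth-dependent crosstalk
  model — and, as discussed, a compact Gaussian understates the
  neuropil ratio relative to measured excitation volumes.
* Event detection is the thresholding pipeline only; no deconvolution
  or template-matching spike inference.
* No motion correction: sessions with movement are expected to be
  discarded upstream rather than corrected.
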