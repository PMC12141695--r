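---
title: "Methods: single-molecule photostability and chromophore-environment analysis"
author: "photoblink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule photostability and chromophore-environment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoblink)
```

# Scope

photoblink characterises the photostability of fluorescent proteins (FPs) at
two scales: single molecules imaged by TIRF microscopy (blinking and
irreversible photobleaching of individual fluorophores), and the chromophore's
molecular environment sampled by molecular-dynamics trajectories (hydrogen
bonding, residue flexibility, buried-water exchange). A third, smaller group
of functions fits the bulk photophysics observables that enter a spectral
comparison table: one-phase decays, pKa titrations, maturation curves, and the
derived scalars brightness ($\varepsilon \cdot QY$) and Stokes shift
($\lambda_{EM} - \lambda_{max}$).

Everything downstream of raw data is testable against known ground truth
because the package carries its own synthetic-data generators: a two-state
blinking/bleaching trace simulator, a camera image-stack renderer, and a
scripted-trajectory builder whose geometry makes H-bond and residency criteria
evaluate exactly as prescribed.

# The single-molecule model

A fluorophore is modelled as a continuous-time telegraph process superimposed
on an irreversible bleaching clock:

* **Bleaching.** Each molecule draws a bleach time $T \sim
  \mathrm{Exponential}(\tau_{bleach})$, independent of its blinking state.
  After $T$ only background is recorded.
* **Blinking.** While unbleached, the molecule alternates between an emitting
  (on) and a dark (off) state with rates $k_{off}$ (leaving on) and $k_{on}$
  (leaving off). Molecules start on at $t=0$: a detected spot is, by
  construction, initially fluorescent. The long-run on fraction is
  $k_{on}/(k_{on}+k_{off})$.
* **Camera discretisation.** Frames last `exposure_s` (default 0.06 s, 1600
  frames, a 96 s acquisition). A frame counts as on when more than half of its
  exposure is spent in the on state — unbiased for dwell segments placed
  symmetrically over frame boundaries.
* **Noise.** Per-frame intensity is $\mu_{bg} + I_{on}\cdot[\mathrm{on}] +
  \mathcal{N}(0, \sigma)$ with $\sigma = \sigma_{on}$ on and $\sigma_{bg}$
  otherwise. There is no EMCCD gain model, no triplet state and no spectral
  diffusion; the generator reproduces the *statistical* structure event
  calling must cope with, not camera physics. Conclusions from passing tests
  therefore transfer to real data only to the extent that real noise is
  near-Gaussian within segments — the threshold-calibration machinery exists
  precisely because real backgrounds are heavier-tailed.

Default simulation conditions (3000 molecules, $\tau_{bleach} = 21.5$ s,
$k_{on} = 0.5\,/s$, $k_{off} = 0.2\,/s$, on-amplitude 10 background SDs) were
chosen once to mirror a realistic single-FP TIRF experiment: a ~20 s lifetime
against a 96 s window gives mild (~1%) censoring, and the 10-SD amplitude
matches the threshold the event caller defaults to. Reproducibility is per
molecule: substream seeds are drawn once from the master seed, so molecule
$m$'s trace does not depend on how many molecules were simulated before it.

# Trace analysis

## Chung–Kennedy filtering

`chung_kennedy()` implements the forward–backward nonlinear filter for
piecewise-constant signals: each point is a weighted mean of a forward
predictor (mean of the preceding window) and a backward predictor (mean of
the following window), weighted by the inverse of each predictor's local mean
squared prediction error raised to $p$ (defaults: window 15 frames, $p = 2$,
chosen to match the event-calling time scale). At a clean step the predictor
that straddles the edge accrues a large error and its weight collapses, so
steps survive unsmoothed; a locally error-free predictor is taken exclusively.
The filter is for visual/diagnostic support — thresholding operates on raw
intensities by default (`use_filtered = TRUE` flips this), because denoising
before thresholding changes the noise statistics that the threshold was
calibrated on.

## Segmentation

`segment_trace()` minimises, by exact optimal-partitioning dynamic
programming, the summed squared deviation from segment means scaled by a
robust noise variance, plus $\beta = 2\log n$ per breakpoint (the BIC-style
price of two extra parameters). The noise scale is
$\hat\sigma = \mathrm{MAD}(\Delta x)/\sqrt{2}$: differencing removes the
piecewise-constant mean, and the MAD resists the step outliers that remain.
The DP is $O(n^2)$ and implemented in C++; a 1600-frame trace segments in
milliseconds, and tests verify exact agreement with exhaustive search on
short traces. Degenerate noiseless traces (where $\hat\sigma = 0$) fall back
to a tiny positive floor so that any real deviation forces a breakpoint —
this reproduces exact staircase recovery.

## Background state and threshold calibration

The photobleached background state of a trace is its lowest-mean segment,
with ties broken toward the longer segment. One refinement proved necessary:
exact segmentation will happily isolate a single low-noise-excursion frame
into its own segment (mean below background, SD zero), and "lowest mean"
would then collapse the threshold onto that singleton. Since the bleached
state is by nature a sustained stretch, segments shorter than `min_len`
(default 15 frames, the event-calling window) are ineligible unless nothing
longer exists.

`calibrate_threshold()` explores candidate multiples $k$ of the background
SD. A trace fails at $k$ when more than 0.1% of its background-segment frames
exceed $\mu_{bg} + k\sigma_{bg}$; the calibration selects the smallest $k$
at which at most 2% of traces fail, and always returns the full $k$-vs-
misdetection table. Both limits are configurable. On strictly Gaussian
backgrounds the selected $k$ is 4 (the Gaussian tail first drops below
$10^{-3}$ there); heavier-tailed backgrounds select larger $k$, which is why
a real TIRF dataset lands near $k = 10$. The default `k_sigma = 10` in
`call_events()` reflects that empirical operating point.

## Event calling

On-frames are raw intensities above $\mu_{bg} + k\sigma_{bg}$. Runs of
on-frames separated by gaps shorter than 15 frames (0.9 s at 0.06 s exposure)
merge into single blinking events — brief dark intervals are treated as part
of one on-event — and events shorter than 15 frames are then discarded, the
window acting as a lower duration limit separating on-state events from noise.
Merging precedes the duration filter so that a genuine event fragmented by
sub-window flicker is not lost. The photobleaching lifetime is the end of the
last surviving event; the cumulative on-time is the summed event duration. An
empty event set is legal (lifetime 0). Frames are 0-based and intervals
half-open, so an event ending at frame $e$ has end time $e \cdot
\mathrm{exposure}$.

A molecule that never photobleaches inside the acquisition has no background
segment, so its per-trace threshold is undefined; such (censored) traces are
the main systematic limitation of the per-trace scheme and are excluded from
oracle comparisons in the tests.

# Ensemble statistics

`survival_fit()` evaluates $S(t) = 1 - \mathrm{ECDF}(t)$ at the observed
lifetimes and fits $S(t) = e^{-t/\tau}$ by least squares, reporting
$t_{1/2} = \tau \ln 2$ (asserted as an exact identity on every summary). The
amplitude is fixed at 1 — a survival curve starts at 1 — with
`free_amplitude = TRUE` available. Least squares on survival values is the
estimator matched to how such curves are usually fitted; it is mildly biased
upward under right-censoring at the acquisition end (about +1.5% at
$\tau = 21.5$ s against a 96 s window in our simulations, rising with
$\tau$/window ratio). Traces with zero events are excluded by default
(`include_empty` includes them); for a shifted exponential this exclusion is
distribution-neutral.

`on_time_distribution()` bins cumulative on-times at 1.2 s and fits a
log-normal by maximum likelihood on the unbinned values, reporting both the
mode $e^{\mu-\sigma^2}$ (the peak of the fitted density, the natural reading
of an "on-time peak") and the mean $e^{\mu+\sigma^2/2}$, since summaries of
skewed dwell-time distributions are ambiguous without both. For pipeline
validation the package compares the *empirical mean* cumulative on-time
against the closed-form telegraph expectation
$$E[\mathrm{on}] = \frac{p}{\lambda}\left(1-e^{-\lambda S}\right) +
\frac{1-p}{\lambda+r}\left(1-e^{-(\lambda+r)S}\right),\qquad
p = \frac{k_{on}}{k_{on}+k_{off}},\; r = k_{on}+k_{off},\;
\lambda = 1/\tau,$$
conditioned on at least one called event; the log-normal mode is not a
meaningful comparator when the underlying on-time distribution is
near-exponential. Gap-merging converts sub-window dark intervals into
on-time, inflating the empirical mean by a few percent — visible and
quantified in the acceptance run.

# Imaging

`normalize_stack()` works in log-intensity space, where laser drift and the
illumination profile are additive. The per-frame drift factor is the
frame-mean log intensity (static spots add the same offset to every frame and
cancel from relative drift); the illumination field is the frame-averaged log
image projected onto a polynomial surface (degree 2 by default — the log of a
Gaussian illumination profile is exactly quadratic, and the surface is too
smooth to follow individual spots). Both estimates are linear projections, so
renormalising an already-normalised stack is an exact no-op up to floating
point — a property the earlier, median-filter-based design could not deliver,
because robust nonlinear estimators re-scramble under their own correction.
The stack mean is preserved.

`detect_spots()` uses a difference of Gaussians with $\sigma_{small} =
d/(2\sqrt2)$ and $\sigma_{large} = 1.6\,\sigma_{small}$ for a nominal spot
diameter $d$ (default 4 px; the 1.6 ratio and the $d/(2\sqrt2)$ mapping are
the standard blob-detector conventions). Local maxima above a quality
threshold are refined to sub-pixel positions by per-axis quadratic
interpolation, with non-maximum suppression at separation $d$. The default
threshold (8 robust SDs of the DoG response) was calibrated on simulated
noise so that pure-noise frames yield fewer than one false spot per ten
frames. Detection runs once on a reference frame (mean of the first five):
the intended specimens are non-diffusing molecules, so static ROIs suffice
and no tracking is attempted. `extract_traces()` averages an inclusive square
ROI (half-width 2 px) per spot per frame; ROIs crossing the border skip the
spot with a message. Pixel coordinates are 0-based (row, col) with pixel
centres at integers.

# Photophysics fits

`one_phase_decay_fit()` fits $F(t) = F_{min} + (F_0 - F_{min})e^{-kt}$, with
$F_0$ the signal at time zero and $F_{min}$ the plateau — the standard
one-phase decay parametrisation. The optimiser is Levenberg–Marquardt driven
directly on the residuals: the conventional `nls` object builder rejects
perfectly converged noiseless fits (plateau exactly on the data) as
"singular", which these synthetic-recovery workflows hit routinely. Reported
scalars are $\tau = 1/k$ and $t_{1/2} = \ln 2 / k$. The in-cell decay keeps
the plateau term as the model's $F_{min}$; no separate plateau flag exists.

`pka_fit()` fits $A(pH) = A_{min} + (A_{max}-A_{min})/(1+10^{\,n(pK_a-pH)})$
with a free Hill coefficient initialised at $\pm 1$ according to the sign of
the pH–absorbance correlation; without the sign-aware start the fit can
converge to the observationally equivalent solution with swapped plateaus and
flipped slope, making $n$ uninterpretable. A `fix_hill` mode fits the
classical $n = 1$ curve for comparability.

`maturation_fit()` fits $F(t) = F_{max}(1 - e^{-kt})$ with $F_{max}$ measured
independently (the dark-matured end point), and standardises the half-time by
anchoring a jointly measured sfGFP reference to its literature value of
13.6 min — absolute maturation half-times are protocol-dependent, ratios much
less so. Quantum-yield determination itself is out of scope; QY is an input.

Brightness and resistance ratios are reported at 1 decimal place, matching
the conventions of FP comparison tables; full precision is available via
`digits = NULL`.

# Trajectory observables

Trajectories are stored in nm and ps (PDB input in Å is converted on read;
multi-model PDB parsing is delegated to bio3d, and a plain whitespace
XYZ-per-frame reader is provided). Frames are 0-based. The geometric H-bond
criterion is donor–acceptor distance $\le 0.35$ nm *and*
hydrogen–donor–acceptor angle $\le 30^\circ$, the widely used
trajectory-analysis defaults; both comparisons are inclusive, with a
$10^{-9}$-scale guard so exactly-on-threshold geometry is not lost to
round-off. Occupancy statistics report any-bond, two-bond and no-bond
percentages plus each triad's share of bonded frames.

`superpose()` is a Kabsch SVD superposition with the determinant correction
enforcing a proper rotation; tests verify agreement with an independent
quaternion (Horn) oracle to $10^{-10}$ on random structures. `rmsf()` aligns
frames to the time-average structure in two passes (align to frame 1,
average, re-align to the average) before computing per-atom fluctuations; a
difference-profile helper follows the reference-minus-variant convention
(positive = reference more flexible). `residue_rmsd_series()` fits globally
on C$\alpha$ atoms by default (a local-fit alternative is exposed through
`fit_selection`), then reports the residue's heavy-atom RMSD against frame 0.

`water_residency()` defines residency as the time from frame 0 until the
water oxygen first leaves the cutoff (0.35 nm) *continuously for longer than*
a grace window (10 ps): single-frame excursions are flicker, not exchange.
The grace window is a declared stand-in — published residency times rarely
state their exit criterion — and is exposed in the interface; a water that
never leaves is flagged `retained` with residency equal to the span.
Trajectories are assumed whole and centred (no periodic-boundary imaging).
`unsolvated_fraction()` counts frames in which no water donates an H-bond to
the acceptor.

The scripted-trajectory generator places atoms so these criteria evaluate
exactly as scripted (bonded: $d = 0.30$ nm, $\theta = 10^\circ$; violated:
$d = 0.50$ nm), with optional sub-tolerance jitter; it is the oracle for all
occupancy and residency values, since reproducing published trajectory
statistics would require the original trajectories.

# Problem sizes and numerical choices

The validation suite exercises: the full pipeline at 3000 molecules × 1600
frames (survival-fit recovery within 5% of the generating $\tau$); threshold
calibration on 40 Gaussian background traces of 2000 frames; exhaustive
segmentation cross-checks on traces up to 30 frames and 3 breakpoints; 100
random structures for the superposition oracle; and 1000-frame scripted
trajectories for occupancy (60% / 5.5% / 55% share), residency (8.5 ns) and
solvation (5.7%) scenarios. Ties in background selection favour longer
segments; all interval logic is half-open 0-based; and every randomised test
fixes its seed.

# Known limitations

* Per-trace thresholding is undefined for molecules that never photobleach
  within the acquisition; population-level calibration mitigates but does not
  remove this.
* The survival estimator ignores right-censoring; use the free-amplitude
  variant and a generous acquisition window, or treat fits with
  $\tau \gtrsim \mathrm{span}/3$ with caution.
* Gap-merging biases cumulative on-times upward by design; interpret on-time
  comparisons between conditions, not absolute values.
* No multi-level (partial-quench) state model, no hidden-Markov inference,
  and no mobile-particle tracking.
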