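# photoblink

Single-molecule photobleaching, blinking and chromophore-environment analysis
for fluorescent proteins.

## What it is for

Engineering brighter, more photostable fluorescent proteins (FPs) requires
quantifying photostability at three levels, and this package implements the
analysis chain for all three:

1. **Single-molecule TIRF traces.** Individual fluorophores blink (reversible
   on/off switching) and finally photobleach (irreversible). From per-molecule
   intensity time series, photoblink denoises (Chung–Kennedy filter), finds
   the photobleached background state by exact change-point segmentation,
   calibrates an intensity threshold as a multiple *k* of the background SD,
   and calls on-events using a 15-frame (0.9 s) temporal window: runs above
   threshold separated by shorter gaps merge into single blinking events,
   shorter events are discarded. The photobleaching lifetime is the end of
   the last event; the cumulative on-time is the summed event duration.
2. **Population statistics.** The survival curve S(t) = 1 − ECDF of
   lifetimes is fitted with a single-component exponential
   S(t) = exp(−t/τ), giving the photobleaching half-life t½ = τ·ln 2;
   cumulative on-times are binned at 1.2 s and fitted with a log-normal
   (mode and mean both reported); tail fractions (e.g. molecules fluorescing
   beyond 25 s) complete the comparison.
3. **Trajectory observables.** From molecular-dynamics trajectories (as
   multi-model PDB or plain XYZ text): hydrogen-bond occupancy under the
   standard geometric criterion (donor–acceptor ≤ 0.35 nm, H–donor–acceptor
   angle ≤ 30°), pair-distance distributions, Kabsch superposition with
   RMSF/RMSD profiles, buried-water residency times, and the fraction of
   time a chromophore oxygen has no water H-bond.

Bulk photophysics fits round out a spectral comparison table: one-phase
decays F(t) = Fmin + (F0 − Fmin)e^(−kt), pKa titrations with a free Hill
coefficient, maturation curves, brightness = ε·QY and Stokes shift =
λ_EM − λ_max.

Because the raw experimental data such analyses are usually developed on are
not redistributable, the package ships first-class synthetic-data
generators: a telegraph-process blinking/bleaching trace simulator with exact
ground truth, a camera image-stack renderer (PSF spots, laser drift,
illumination profile, shot/read noise) feeding the difference-of-Gaussians
spot detector, and scripted atom trajectories whose geometry makes H-bond
and residency criteria evaluate exactly as prescribed.

## Worked example

Simulate a population under realistic single-FP TIRF conditions (0.06 s
exposure, 1600 frames, mean bleach time 21.5 s, blinking at k_on = 0.5/s,
k_off = 0.2/s), run the per-trace pipeline, and summarise:

```r
library(photoblink)

params <- trace_sim_params(500, n_frames = 1600, tau_bleach_s = 21.5,
                           k_on_per_s = 0.5, k_off_per_s = 0.2, seed = 42)
sim <- simulate_traces(params)
sim
#> Synthetic single-molecule traces: 500 molecules x 1600 frames (0.06 s exposure)
#>   tau_bleach = 21.5 s, k_on = 0.5 /s, k_off = 0.2 /s, censored: 6

events <- call_events_all(sim)   # segment, estimate background, call at 10 SD
events[[1]]
#> Event set: 3 on-event(s), bleach lifetime 18.54 s, cumulative on-time 9.96 s
#>      start end
#> [1,]     0  81
#> [2,]   111 127
#> [3,]   240 309

summ <- ensemble_summary(events, thresholds_s = 25)
summ
#> Ensemble summary over 500 traces
#> Exponential survival fit (n = 472): tau = 22.3 s, half-life = 15.5 s (R^2 = 0.9987)
#> Log-normal on-time fit (n = 472): mu = 2.365, sigma = 1.052; mode = 3.52 s, mean = 18.5 s
#> Tail fractions: >25s 0.337
```

The fitted τ = 22.3 s recovers the generating 21.5 s to within the
survival-estimator's censoring bias (~3%); molecule 1's three blinking
events span frames [0,81), [111,127) and [240,309), so its lifetime is
309 × 0.06 s = 18.54 s and it spent 9.96 s on. The spectral scalars work the
same way for measured values:

```r
photophys_record(492, 511, 61.4, 0.92, pKa = 6.2)
#> Photophysics: lambda_max 492 nm, lambda_em 511 nm, eps 61.4, QY 0.92 -> brightness 56.5, Stokes 19 nm
relative_resistance(15.0, 8.3)
#> [1] 1.8
```

## Package layout

| Area | Functions |
|---|---|
| Trace simulation | `trace_sim_params`, `simulate_traces`, `write_traces`/`read_traces` |
| Image stacks | `simulate_image_stack`, `normalize_stack`, `detect_spots`, `extract_traces`, TIFF I/O |
| Per-trace analysis | `chung_kennedy`, `segment_trace`, `background_stats`, `calibrate_threshold`, `call_events`, `call_events_all` |
| Ensemble | `survival_fit`, `on_time_distribution`, `fraction_longer_than`, `ensemble_summary` |
| Photophysics | `brightness`, `stokes_shift`, `one_phase_decay_fit`, `pka_fit`, `maturation_fit`, `relative_resistance`, `photophys_record` |
| Trajectories | `md_trajectory`, PDB/XYZ readers, `hbond_series`, `occupancy_stats`, `pair_distance`, `superpose`, `rmsf`, `residue_rmsd_series`, `water_residency`, `unsolvated_fraction`, `simulate_hbond_trajectory` |

The methods vignette (`vignettes/photoblink-methods.Rmd`) documents the
models, the default parameters and why, the numerical choices, and known
limitations.
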