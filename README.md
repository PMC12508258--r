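# tsaquant

Single-particle quantification for tyramide-amplified immunofluorescence
imaging of extracellular vesicles (EVs) and circulating tumour cells
(CTCs).

## The problem

Most EVs are smaller than the diffraction limit and carry only tens of
copies of any surface marker, so conventional immunofluorescence — a
fluorophore-conjugated primary antibody (direct staining, DS) or a
labelled secondary (primary + secondary staining, PSS) — produces weak,
rapidly bleaching spots that are hard to separate from substrate
background. Tyramide signal amplification (TSA) routes detection through
an HRP-conjugated secondary antibody that enzymatically deposits many
fluorescent tyramide molecules around the epitope, which amplifies the
per-particle signal several-fold, broadens its dynamic range and
stabilises it under continuous excitation. The price of TSA is chemistry:
in sequential two-colour staining, residual active HRP from the first
cycle reacts with the second tyramide probe unless a peroxide quench is
inserted, creating spurious second-channel particles.

tsaquant implements the analysis side of this assay for people building or
validating such protocols:

* a **generative simulator** of the whole imaging chain — per-particle
  protein copies, the DS/PSS/TSA staining stoichiometry
  (expected per-copy signal ratios 1 : 1.5 : 6.4), method-dependent
  photobleaching, Gaussian-PSF optics, a Poisson photon + read-noise
  camera, non-specific background (NSB) particles, and two-plex
  residual-HRP cross-reactivity with quenching — so every downstream stage
  can be validated by parameter recovery on known ground truth;
* **control-calibrated detection**: the intensity threshold (or
  Find-Maxima noise tolerance) is set so EV-free control substrates yield
  fewer than 10 detections, then particles are segmented (fill holes,
  watershed separation, 8-connectivity, minimum 10 px) and measured by
  dilated-mask aperture photometry;
* **quantification**: integrated and normalised intensities
  (`integrated / area / acquisition time`), dynamic ranges (max − min),
  fold changes, counts per field of view, and photobleaching stability
  profiles measured on the t = 0 masks;
* **two-plex colocalization**: mutual-nearest-neighbour matching within
  2× the PSF sigma, single/double-positive percentages, normalized EV
  counts (% of the complete-protocol mean) for cross-reactivity
  estimation, and log-intensity Pearson correlation of double positives;
* a **limit-of-detection estimator**: minimum detectable protein copies
  per EV = round(first peak of the EV intensity distribution / the
  single-antibody calibration peak), with floor 1;
* **cohort statistics**: CTCs/mL, cohort detection rate against a
  healthy-control threshold, and healthy-baseline-subtracted tumour-EV
  percentages clipped at zero.

Results are tidy tibbles designed for piping, with broom-style `tidy()` /
`glance()` methods and `autoplot()` / `plot_*()` ggplot2 graphics.

## A worked example

Simulate a TSA-stained EV substrate together with EV-free controls,
calibrate the detection threshold on the controls, and quantify:

```r
library(tsaquant)

report <- run_pipeline(list(
  seed = 1, methods = c("DS", "TSA"), n_fov = 2, n_controls = 3,
  field = field_config(fov_px = c(512, 512), ev_per_fov = 150)
))
report
#> <ev_report> calibrated threshold 128 ADU
#> # A tibble: 2 x 5
#>   method     n mean_integrated median_integrated counts_per_fov
#>   <chr>  <int>           <dbl>             <dbl>          <dbl>
#> 1 DS       269           2825.              2551           134.
#> 2 TSA      268          18327.             15375           134
```

The calibrated threshold (128 ADU) is the smallest candidate keeping the
pooled control detections under 10. Per-particle integrated intensities
are background-subtracted sums over the dilated detection mask; the
TSA/DS population fold here is `fold_change(18327, 2825)` = 6.5, close to
the generative amplification of 6.4. The same machinery exposes each stage
directly (`sample_field()`, `simulate_staining()`, `render_image()`,
`calibrate_threshold()`, `detect_particles()`, `match_particles()`,
`min_detectable_copies()`, `cohort_table()`, ...) and higher-level
`run_*_experiment()` drivers encode complete simulated experiments.

```r
lod <- run_lod_experiment(seed = 1, copies = 2)
lod
#> <ev_lod> single-antibody peak 263.2 ADU, EV first peak 511.6 ADU
#> -> minimum detectable copies: 2
```

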