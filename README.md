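# mitopore

Amplification-free mitochondrial DNA (mtDNA) copy-number analysis for
solid-state nanopore recordings.

## The problem

mtDNA copy number is a disease biomarker, but the standard qPCR readout
depends on amplification and inherits its biases. Solid-state nanopores count
molecules one at a time: each translocation transiently blocks the ionic
current through the pore, and the blockade waveform carries enough
information to tell *which* molecule passed. Native mtDNA — still complexed
with packaging proteins — produces blockades with strongly elevated in-event
current fluctuations, while clean linear dsDNA of the same length produces
quiet, well-defined blockades. That difference turns a nanopore recording of
an enzymatically prepared total-DNA sample (gDNA selectively fragmented,
mtDNA linearized) into a digital counting assay for mtDNA.

`mitopore` implements the full analysis path for this assay, plus a
statistically calibrated simulator so every stage is testable without raw
recordings:

1. **Event detection** (`estimate_baseline`, `detect_events`,
   `extract_features`): robust open-pore baseline (median-of-medians, MAD
   noise), threshold/hysteresis event calling, and the six per-event
   parameters — open-pore current `i_o`, blocked current `i_b`, dwell time
   `t_D`, blockage amplitude `ΔI = i_o − i_b`, fractional blockage
   `I_B = i_b/i_o`, and in-event RMS `i_rms` (the SD of the blocked current).
2. **Classification** (`build_features`, `train_svm`, `cross_validate`):
   one-vs-one SVM with a fine Gaussian kernel
   (`K(x,y) = exp(−‖x−y‖²/s²)`, kernel scale `s = 2`) on standardized
   `(I_B, log10 t_D, i_rms)` features, with class balancing, stratified
   5-fold cross-validation, confusion matrices, TPR/FNR and one-vs-rest AUC.
3. **Quantification** (`compute_ratio`, `fit_spikein`): the digital count
   ratio `R_NP = n_mt / (n_mt + n_frag)` with a Wilson 95% interval, and a
   spike-in calibration fit of

   `R_NP(m) = (N_mt + c·m) / (N_mt + c·m + N_gDNA)`,

   where `m` is the spiked mtDNA mass, `c = copies_per_ng(16,569 bp)`, and
   the free parameters are the endogenous mtDNA copies `N_mt` and the
   adjusted gDNA fragment count `N_gDNA` (weighted by binomial counting
   variance).
4. **Electro-optical synchrony** (`detect_bursts`, `correlate_events`):
   photon-burst calling in 1 kHz camera frame series and the fraction of
   electrical events with a synchronous optical burst, against a
   circular-shift null.
5. **Simulation** (`synth_trace`, `sample_event_features`,
   `synth_spikein_series`, `synth_photon_trace`): traces with square
   blockades, exponential-tail dwell times, truncated-normal `I_B`,
   log-normal per-event RMS populations and a telegraph in-event
   fluctuation process for mtDNA, with exact ground truth.

## Worked example

```r
library(mitopore)

# simulate a recording of an enzymatically prepared sample:
# ~10:1 gDNA fragments : mtDNA, 2 s at 500 kHz
spec <- trace_spec(duration_s = 2, event_rate_hz = 150,
                   class_mixture = c(fragment = 10/11, mtDNA = 1/11),
                   seed = 5)
sim <- synth_trace(spec, list(class_defaults("fragment"),
                              class_defaults("mtDNA")))

# detect events and extract features
bl <- estimate_baseline(sim$trace)
ev <- extract_features(sim$trace, detect_events(sim$trace, bl), bl)

# train on pure-class samples, classify, count
train <- rbind(sample_event_features(class_defaults("fragment"), 500, seed = 6),
               sample_event_features(class_defaults("mtDNA"), 500, seed = 7))
art <- train_svm(balance_classes(build_features(train), seed = 8))
compute_ratio(predict(art, ev)$label)
#> <count_summary> R_NP = 0.0946 (95% CI 0.0663-0.1333), 28 mtDNA / 268 other events
```

The recovered ratio's confidence interval covers the scheduled mixture
fraction (1/11 ≈ 0.091): 296 detected events, 28 classified as mtDNA.

The same workflow runs from the shell:

```sh
Rscript inst/cli/mitopore pipeline --config config.yaml --out run1/
```

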