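# Shared fixture builders. Everything is generated in code at test time.

# Single-class trace through the full simulate path.
sim_class_trace <- function(label, duration_s, event_rate_hz, seed,
                            noise_sd = 0.03) {
  spec <- trace_spec(duration_s = duration_s, event_rate_hz = event_rate_hz,
                     class_mixture = stats::setNames(1, label),
                     baseline_noise_sd_nA = noise_sd, seed = seed)
  synth_trace(spec, list(class_defaults(label)))
}

# Detect + featurize with package defaults.
detect_and_extract <- function(trace, ...) {
  bl <- estimate_baseline(trace)
  bounds <- detect_events(trace, bl, ...)
  list(baseline = bl, bounds = bounds,
       features = extract_features(trace, bounds, bl))
}

# Hand-built trace: flat baseline with square pulses at given (start, len)
# sample positions (1-based), depth in nA.
pulse_trace <- function(n, i_o = 10, noise_sd = 0, pulses = list(),
                        sampling_rate_hz = 5e5, seed = 1) {
  x <- withr::with_seed(seed, i_o + stats::rnorm(n, 0, noise_sd))
  for (p in pulses) x[p$start:(p$start + p$len - 1L)] <- i_o - p$depth
  ion_trace(x, sampling_rate_hz)
}

# Event feature table with two well-separated synthetic classes, for
# classifier contract tests that need separable data.
separable_features <- function(n_per_class = 100, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    a <- data.frame(I_B = stats::rnorm(n_per_class, 0.9, 0.01),
                    t_D_us = stats::rlnorm(n_per_class, log(100), 0.1),
                    i_rms_nA = stats::rnorm(n_per_class, 0.1, 0.01),
                    class_label = "a")
    b <- a
    b$I_B <- b$I_B - gap * 0.01
    b$i_rms_nA <- b$i_rms_nA + gap * 0.01
    b$class_label <- "b"
    rbind(a, b)
  })
}

# Ground-truth-style event table at Poisson times, without simulating an ion
# trace; for photon-trace and synchrony tests.
fake_truth <- function(n_events, duration_s, dwell_us = 800,
                       sampling_rate_hz = 5e5, seed = 1) {
  withr::with_seed(seed, {
    starts <- sort(stats::runif(n_events, 0.01, duration_s - 0.01))
    start_idx <- as.integer(round(starts * sampling_rate_hz))
    len <- as.integer(round(dwell_us * 1e-6 * sampling_rate_hz))
    data.frame(class_label = "mtDNA", start_idx = start_idx,
               end_idx = start_idx + len,
               i_b_nA = 7, dwell_us = dwell_us,
               i_rms_target_nA = 1)
  })
}
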