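# Generator: event feature sampling, trace synthesis, spike-in series,
# photon traces.

test_that("sampled dwell times carry the configured exponential tail", {
  p <- class_defaults("mtDNA")
  feats <- sample_event_features(p, 10000, seed = 11)
  # independent oracle: exponential MLE on exceedances over the median
  thr <- median(feats$t_D_us)
  tau_hat <- mean(feats$t_D_us[feats$t_D_us > thr] - thr)
  tau_cfg <- p$dwell_tail_us - p$dwell_min_us
  expect_lt(abs(tau_hat - tau_cfg) / tau_cfg, 0.05)
  # the packaged tail fit agrees with the oracle
  expect_equal(fit_dwell_tail(feats$t_D_us)$tau_us, tau_hat, tolerance = 1e-12)
  expect_true(all(feats$t_D_us > p$dwell_min_us))
})

test_that("sampled i_rms matches the configured population moments", {
  p <- class_defaults("mtDNA")
  feats <- sample_event_features(p, 10000, seed = 12)
  se <- p$irms_pop_sd_nA / sqrt(nrow(feats))
  expect_lt(abs(mean(feats$i_rms_nA) - p$irms_pop_mean_nA), 3 * se)
  # degenerate SD gives a point mass
  p0 <- event_class_params("x", 100, 20, 0.8, 0.01, 0.5, 0)
  f0 <- sample_event_features(p0, 50, seed = 1)
  expect_true(all(f0$i_rms_nA == 0.5))
})

test_that("feature sampling validates inputs and is seed-deterministic", {
  p <- class_defaults("syDNA")
  expect_error(sample_event_features(p, 0), "positive count")
  expect_identical(sample_event_features(p, 100, seed = 5),
                   sample_event_features(p, 100, seed = 5))
  # unusable I_B parameters are rejected after bounded retries
  bad <- event_class_params("x", 100, 20, ib_frac_mean = 1e-4,
                            ib_frac_sd = 10, irms_pop_mean_nA = 0.1,
                            irms_pop_sd_nA = 0)
  expect_error(sample_event_features(bad, 1000, seed = 1), "retries")
  expect_error(event_class_params("x", 100, 20, 1.2, 0.1, 0.1, 0),
               "\\(0, 1\\)")
  expect_error(event_class_params("x", 10, 20, 0.5, 0.1, 0.1, 0),
               "dwell")
})

test_that("class defaults respect the published dwell and i_rms orderings", {
  frag <- class_defaults("fragment")
  sy <- class_defaults("syDNA")
  mt <- class_defaults("mtDNA")
  expect_lt(frag$dwell_tail_us, sy$dwell_tail_us)
  expect_lt(sy$dwell_tail_us, mt$dwell_tail_us)
  expect_gte(mt$irms_pop_mean_nA / sy$irms_pop_mean_nA, 6)
  expect_lt(mt$ib_frac_mean, sy$ib_frac_mean) # deeper blockades
  expect_lt(sy$ib_frac_mean, frag$ib_frac_mean)
})

test_that("an eventless trace is pure baseline noise", {
  spec <- trace_spec(duration_s = 0.2, event_rate_hz = 0,
                     class_mixture = c(mtDNA = 1), seed = 3)
  sim <- synth_trace(spec, list(class_defaults("mtDNA")))
  expect_identical(nrow(sim$truth), 0L)
  expect_lt(abs(sd(sim$trace$samples) - spec$baseline_noise_sd_nA),
            0.1 * spec$baseline_noise_sd_nA)
  expect_lt(abs(mean(sim$trace$samples) - 10), 0.01)
})

test_that("a noiseless scheduled pulse has exact depth and duration", {
  # one syDNA-like event, no noise, no fluctuation, I_B fixed at 0.8
  p <- event_class_params("x", dwell_tail_us = 500.0001, dwell_min_us = 500,
                          ib_frac_mean = 0.8, ib_frac_sd = 0,
                          irms_pop_mean_nA = 0, irms_pop_sd_nA = 0,
                          fluctuation = list(model = "none"))
  spec <- trace_spec(duration_s = 0.05, event_rate_hz = 40,
                     class_mixture = c(x = 1), baseline_noise_sd_nA = 0,
                     seed = 8)
  sim <- synth_trace(spec, list(p))
  expect_gte(nrow(sim$truth), 1)
  ev <- sim$truth[1, ]
  idx <- (ev$start_idx + 1):ev$end_idx
  expect_true(all(sim$trace$samples[idx] == 8))
  n_samp <- ev$end_idx - ev$start_idx
  expect_equal(n_samp / spec$sampling_rate_hz * 1e6, 500, tolerance = 1e-2)
  out <- setdiff(seq_along(sim$trace$samples), do.call(c, lapply(
    seq_len(nrow(sim$truth)),
    function(i) (sim$truth$start_idx[i] + 1):sim$truth$end_idx[i])))
  expect_true(all(sim$trace$samples[out] == 10))
})

test_that("scheduled events never overlap and stay in bounds", {
  sim <- sim_class_trace("fragment", duration_s = 0.5, event_rate_hz = 400,
                         seed = 9)
  tr <- sim$truth
  expect_gt(nrow(tr), 50)
  expect_true(all(tr$end_idx > tr$start_idx))
  expect_true(all(tr$start_idx >= 0))
  expect_true(all(tr$end_idx <= length(sim$trace$samples)))
  expect_true(all(diff(tr$start_idx) > 0))
  expect_true(all(tr$start_idx[-1] >= tr$end_idx[-nrow(tr)])) # disjoint
})

test_that("trace synthesis is bit-identical under a fixed seed", {
  s1 <- sim_class_trace("mtDNA", 0.3, 100, seed = 21)
  s2 <- sim_class_trace("mtDNA", 0.3, 100, seed = 21)
  expect_identical(s1$trace$samples, s2$trace$samples)
  expect_identical(s1$truth, s2$truth)
})

test_that("infeasible schedules and bad mixtures are rejected", {
  expect_error(trace_spec(1, 10, c(0.5, 0.5)), "named")
  expect_error(trace_spec(1, 10, c(a = 0.6, b = 0.5)), "sum to 1")
  expect_error(trace_spec(1, 10, c(a = 1.5, b = -0.5)), "nonnegative")
  spec <- trace_spec(1, 1000, c(mtDNA = 1))
  expect_error(synth_trace(spec, list(class_defaults("mtDNA"))),
               "occupancy")
  expect_error(synth_trace(trace_spec(1, 10, c(syDNA = 1)),
                           list(class_defaults("mtDNA"))),
               "cover")
})

test_that("symmetric telegraph sample SD approaches half the peak-to-peak depth", {
  # closed form: states at +/- d/2 with equal occupancy give SD d/2
  d <- 2
  w <- withr::with_seed(4, mitopore:::telegraph_wave(2e5, 5e4, 5e5)) * d / 2
  expect_lt(abs(sd(w) - d / 2) / (d / 2), 0.02)
  expect_setequal(unique(w), c(-1, 1))
})

test_that("spike-in series reproduces the model ratio and is deterministic", {
  # zero-spike limit: observed ratio -> endogenous fraction at large n
  s0 <- synth_spikein_series(2e9, 8e9, masses_ng = 0, events_per_run = 2e5,
                             seed = 6)
  expect_lt(abs(s0$observed_R - 0.2), 3 * sqrt(0.2 * 0.8 / 2e5))
  s1 <- synth_spikein_series(2.53e9, 9.24e9, c(35, 100, 300), 2000, seed = 7)
  s2 <- synth_spikein_series(2.53e9, 9.24e9, c(35, 100, 300), 2000, seed = 7)
  expect_identical(s1, s2)
  expect_error(synth_spikein_series(-1, 1e9, 10, 2000), "nonnegative")
  expect_true(all(s1$n_mt <= s1$n_events))
})

test_that("photon frame bookkeeping and labeling limits behave", {
  truth <- fake_truth(50, duration_s = 1.5, seed = 13)
  pt <- synth_photon_trace(truth, 5e5, 1.5, labeled_fraction = 0,
                           background_mean = 100, background_sd = 30,
                           seed = 14)
  expect_length(pt$frame_counts, ceiling(1.5 * 1000))
  # negative control: nothing resembling a burst
  expect_true(all(pt$frame_counts <= 100 + 10 * 30))
  pt1 <- synth_photon_trace(truth, 5e5, 1.5, labeled_fraction = 1,
                            burst_mean_counts = 400, background_mean = 100,
                            background_sd = 30, seed = 15)
  thr <- 100 + 10 * 30
  hot <- which(pt1$frame_counts > thr)
  # every labeled event overlaps at least one above-threshold frame
  for (i in seq_len(nrow(truth))) {
    f0 <- floor(truth$start_idx[i] / 5e5 * 1000) - 2
    f1 <- floor(truth$end_idx[i] / 5e5 * 1000) + 1
    expect_true(any(hot - 1 >= f0 & hot - 1 <= f1))
  }
  expect_error(synth_photon_trace(truth, 5e5, 1.5, labeled_fraction = 2),
               "labeled_fraction")
})
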