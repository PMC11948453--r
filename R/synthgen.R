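# Synthetic-data generator: ion-current traces, event-level feature samples,
# spike-in series, and photon-count frame series with the statistical
# structure the downstream analysis assumes.

#' Translocation event class parameters
#'
#' Describes one molecular class of translocation events: the exponential
#' dwell-time tail, the fractional-blockage distribution, the target
#' population of per-event blocked-level RMS values, and the in-event
#' fluctuation process used when full traces are simulated.
#'
#' Dwell times are drawn as `dwell_min_us + Exponential(dwell_tail_us -
#' dwell_min_us)`, so an exponential fit to the dwell distribution tail
#' recovers `dwell_tail_us - dwell_min_us`. Fractional blockage `I_B` is
#' normal truncated to (0, 1). Per-event RMS targets are log-normal with the
#' stated arithmetic mean and SD.
#'
#' @param class_label Class name, e.g. `"fragment"`, `"mtDNA"`, `"syDNA"`.
#' @param dwell_tail_us Characteristic exponential-tail dwell time, microseconds.
#' @param dwell_min_us Truncation floor for dwell times, microseconds.
#' @param ib_frac_mean,ib_frac_sd Mean and SD of fractional blockage `I_B`.
#' @param irms_pop_mean_nA,irms_pop_sd_nA Target population mean and SD of the
#'   per-event blocked-level RMS, nA.
#' @param fluctuation In-event fluctuation process: a list with `model` one of
#'   `"none"`, `"gaussian"` (white in-event noise scaled to the per-event RMS
#'   target) or `"telegraph"` (symmetric two-state switching at `rate_hz`,
#'   rescaled per event to the RMS target).
#' @return An object of class `"event_class_params"`.
#' @seealso [class_defaults()] for presets calibrated to published populations.
#' @export
event_class_params <- function(class_label,
                               dwell_tail_us,
                               dwell_min_us = 20,
                               ib_frac_mean,
                               ib_frac_sd,
                               irms_pop_mean_nA,
                               irms_pop_sd_nA,
                               fluctuation = list(model = "gaussian",
                                                  rate_hz = 5000)) {
  stopifnot(is.character(class_label), length(class_label) == 1L)
  if (!(ib_frac_mean > 0 && ib_frac_mean < 1))
    stop("ib_frac_mean must lie in (0, 1)", call. = FALSE)
  if (ib_frac_sd < 0) stop("ib_frac_sd must be >= 0", call. = FALSE)
  if (!(dwell_tail_us > dwell_min_us && dwell_min_us > 0))
    stop("need dwell_tail_us > dwell_min_us > 0", call. = FALSE)
  if (irms_pop_mean_nA < 0 || irms_pop_sd_nA < 0)
    stop("i_rms population parameters must be >= 0", call. = FALSE)
  fluctuation$model <- match.arg(fluctuation$model,
                                 c("none", "gaussian", "telegraph"))
  if (fluctuation$model == "telegraph") {
    fluctuation$rate_hz <- fluctuation$rate_hz %||% 5000
    stopifnot(fluctuation$rate_hz > 0)
  }
  structure(list(class_label = class_label,
                 dwell_tail_us = dwell_tail_us,
                 dwell_min_us = dwell_min_us,
                 ib_frac_mean = ib_frac_mean,
                 ib_frac_sd = ib_frac_sd,
                 irms_pop_mean_nA = irms_pop_mean_nA,
                 irms_pop_sd_nA = irms_pop_sd_nA,
                 fluctuation = fluctuation),
            class = "event_class_params")
}

#' Default class parameterizations
#'
#' Presets for the four event classes used throughout the package, calibrated
#' to the published population statistics: dwell tails of 57 us (gDNA
#' fragments), 680 us (17 kbp linear dsDNA, "syDNA"), 1,280 us (linearized
#' native mtDNA) and 546 us (linearized pcDNA3.1); per-event RMS populations
#' 0.16 +/- 0.04 nA (syDNA), 1.1 +/- 0.8 nA (mtDNA), 0.2 +/- 0.07 nA (pcDNA);
#' fractional blockages 0.81 +/- 0.03 (pcDNA, printed) and assumed values
#' respecting the reported ordering (fragments shallowest, mtDNA deepest) for
#' the remaining classes. Native mtDNA carries a telegraph in-event
#' fluctuation process; the clean linear molecules carry white in-event noise.
#'
#' @param label One of `"fragment"`, `"mtDNA"`, `"syDNA"`, `"pcDNA"`.
#' @return An [event_class_params()] object.
#' @export
class_defaults <- function(label = c("fragment", "mtDNA", "syDNA", "pcDNA")) {
  label <- match.arg(label)
  switch(label,
    fragment = event_class_params("fragment", dwell_tail_us = 57,
      dwell_min_us = 20, ib_frac_mean = 0.92, ib_frac_sd = 0.03,
      irms_pop_mean_nA = 0.12, irms_pop_sd_nA = 0.04,
      fluctuation = list(model = "gaussian")),
    mtDNA = event_class_params("mtDNA", dwell_tail_us = 1280,
      dwell_min_us = 20, ib_frac_mean = 0.70, ib_frac_sd = 0.05,
      irms_pop_mean_nA = 1.1, irms_pop_sd_nA = 0.8,
      fluctuation = list(model = "telegraph", rate_hz = 5000)),
    syDNA = event_class_params("syDNA", dwell_tail_us = 680,
      dwell_min_us = 20, ib_frac_mean = 0.85, ib_frac_sd = 0.03,
      irms_pop_mean_nA = 0.16, irms_pop_sd_nA = 0.04,
      fluctuation = list(model = "gaussian")),
    pcDNA = event_class_params("pcDNA", dwell_tail_us = 546,
      dwell_min_us = 20, ib_frac_mean = 0.81, ib_frac_sd = 0.03,
      irms_pop_mean_nA = 0.2, irms_pop_sd_nA = 0.07,
      fluctuation = list(model = "gaussian")))
}

#' Trace simulation specification
#'
#' @param duration_s Trace length, seconds.
#' @param event_rate_hz Mean translocation rate (Poisson), events per second.
#' @param class_mixture Named numeric vector of class fractions (sums to 1).
#' @param open_pore_current_nA Open-pore current, nA.
#' @param baseline_noise_sd_nA Baseline Gaussian noise SD, nA.
#' @param sampling_rate_hz Sampling rate, Hz. The default 500 kHz is at least
#'   twice the emulated 100 kHz low-pass bandwidth.
#' @param voltage_mV Applied bias, metadata only.
#' @param seed Integer seed controlling all randomness of [synth_trace()].
#' @return An object of class `"trace_spec"`.
#' @export
trace_spec <- function(duration_s,
                       event_rate_hz,
                       class_mixture,
                       open_pore_current_nA = 10,
                       baseline_noise_sd_nA = 0.03,
                       sampling_rate_hz = 5e5,
                       voltage_mV = 150,
                       seed = NULL) {
  stopifnot(duration_s > 0, event_rate_hz >= 0, open_pore_current_nA > 0,
            baseline_noise_sd_nA >= 0, sampling_rate_hz > 0)
  if (is.null(names(class_mixture)) || any(!nzchar(names(class_mixture))))
    stop("class_mixture must be a named vector", call. = FALSE)
  if (any(class_mixture < 0))
    stop("mixture fractions must be nonnegative", call. = FALSE)
  if (abs(sum(class_mixture) - 1) > 1e-9)
    stop("mixture fractions must sum to 1", call. = FALSE)
  structure(list(duration_s = duration_s,
                 event_rate_hz = event_rate_hz,
                 class_mixture = class_mixture,
                 open_pore_current_nA = open_pore_current_nA,
                 baseline_noise_sd_nA = baseline_noise_sd_nA,
                 sampling_rate_hz = sampling_rate_hz,
                 voltage_mV = voltage_mV,
                 seed = seed),
            class = "trace_spec")
}

#' Ion-current trace container
#'
#' @param samples Numeric vector of current samples, nA.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param voltage_mV Applied bias, metadata.
#' @param meta Free-form metadata list.
#' @return Object of class `"ion_trace"`.
#' @export
ion_trace <- function(samples, sampling_rate_hz, voltage_mV = NA_real_,
                      meta = list()) {
  stopifnot(sampling_rate_hz > 0)
  if (any(!is.finite(samples)))
    stop("trace samples must all be finite", call. = FALSE)
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz,
                 voltage_mV = voltage_mV,
                 meta = meta),
            class = "ion_trace")
}

#' @export
print.ion_trace <- function(x, ...) {
  cat(sprintf("<ion_trace> %d samples @ %.3g kHz (%.3f s), %.3g mV\n",
              length(x$samples), x$sampling_rate_hz / 1e3,
              length(x$samples) / x$sampling_rate_hz, x$voltage_mV))
  invisible(x)
}

#' Sample per-event features from a class population
#'
#' Draws `(I_B, t_D, i_rms)` triplets directly from the class distributions,
#' bypassing trace synthesis. Dwell times are floor-shifted exponentials,
#' `I_B` is truncated normal and `i_rms` log-normal with the configured
#' arithmetic mean/SD.
#'
#' @param params An [event_class_params()] object.
#' @param n Number of events (>= 1).
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `I_B`, `t_D_us`, `i_rms_nA`,
#'   `class_label`.
#' @export
sample_event_features <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "event_class_params"))
  if (!(is.numeric(n) && length(n) == 1L && n >= 1))
    stop("n must be a positive count", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    t_d <- params$dwell_min_us +
      stats::rexp(n, rate = 1 / (params$dwell_tail_us - params$dwell_min_us))
    i_b <- rnorm_trunc01(n, params$ib_frac_mean, params$ib_frac_sd)
    irms <- rlnorm_meansd(n, params$irms_pop_mean_nA, params$irms_pop_sd_nA)
    data.frame(I_B = i_b, t_D_us = t_d, i_rms_nA = irms,
               class_label = params$class_label,
               stringsAsFactors = FALSE)
  })
}

# Symmetric two-state telegraph waveform of length n at `rate_hz` switching
# rate, values in {-1, +1}, random initial state.
telegraph_wave <- function(n, rate_hz, sampling_rate_hz) {
  state <- sample(c(-1, 1), 1L)
  w <- numeric(n)
  pos <- 1L
  while (pos <= n) {
    run <- max(1L, ceiling(stats::rexp(1, rate_hz) * sampling_rate_hz))
    end <- min(n, pos + run - 1L)
    w[pos:end] <- state
    state <- -state
    pos <- end + 1L
  }
  w
}

# In-event fluctuation waveform (0 mean) for one pulse. The amplitude is set
# so the pulse samples, together with the baseline noise that persists inside
# the event, realize the per-event RMS target: sd_f = sqrt(target^2 -
# noise^2). Because per-event RMS is measured on the blockade interior
# (entry/exit transients trimmed), telegraph pulses are rescaled so the SD
# over the central (1 - 2 * edge_frac) of the pulse equals sd_f; pulses whose
# interior contains no state switch fall back to white noise at the same SD,
# so short events still carry the class's elevated RMS.
event_fluctuation <- function(params, n, sd_target, sampling_rate_hz,
                              baseline_noise_sd = 0, edge_frac = 0.1) {
  if (params$fluctuation$model == "none") return(numeric(n))
  sd_f <- sqrt(max(sd_target^2 - baseline_noise_sd^2, 0))
  if (sd_f <= 0) return(numeric(n))
  if (params$fluctuation$model == "telegraph" && n > 1L) {
    w <- telegraph_wave(n, params$fluctuation$rate_hz, sampling_rate_hz)
    tr <- floor(edge_frac * n)
    if (n - 2L * tr < 2L) tr <- 0L
    core <- (tr + 1L):(n - tr)
    s <- stats::sd(w[core])
    if (is.finite(s) && s > 0) return((w - mean(w[core])) / s * sd_f)
  }
  stats::rnorm(n, 0, sd_f)
}

#' Simulate a full ion-current trace with ground truth
#'
#' Builds an open-pore baseline with Gaussian noise and superimposes square
#' translocation pulses scheduled by a Poisson process thinned to forbid
#' overlap. Each pulse drops to `i_b = I_B * i_o` with the class fluctuation
#' process inside the pulse; the per-event fluctuation amplitude is rescaled
#' so the realized in-pulse SD matches the value drawn from the class i_rms
#' population. Telegraph events whose upper state would approach the open-pore
#' level are shifted toward deeper blockage so each event remains one
#' contiguous blockade.
#'
#' @param spec A [trace_spec()].
#' @param classes List of [event_class_params()] covering every mixture label.
#' @return List with elements `trace` (an [ion_trace()]) and `truth`
#'   (`data.frame` of scheduled events: `class_label`, 0-based half-open
#'   `start_idx`/`end_idx`, true `i_b_nA`, `dwell_us`).
#' @export
synth_trace <- function(spec, classes) {
  stopifnot(inherits(spec, "trace_spec"))
  labels <- vapply(classes, function(p) p$class_label, "")
  mix <- spec$class_mixture
  if (!all(names(mix) %in% labels))
    stop("classes must cover every label in class_mixture", call. = FALSE)
  mean_dwell_s <- sum(mix * vapply(names(mix), function(l) {
    p <- classes[[match(l, labels)]]
    (p$dwell_min_us + (p$dwell_tail_us - p$dwell_min_us)) * 1e-6
  }, 0))
  if (spec$event_rate_hz * mean_dwell_s > 0.5)
    stop("requested occupancy (rate x mean dwell) exceeds 0.5; infeasible schedule",
         call. = FALSE)

  fs <- spec$sampling_rate_hz
  n <- as.integer(round(spec$duration_s * fs))
  with_seed(spec$seed, {
    x <- spec$open_pore_current_nA +
      stats::rnorm(n, 0, spec$baseline_noise_sd_nA)

    tl_class <- character(0)
    tl_start <- integer(0)
    tl_end <- integer(0)
    tl_ib <- numeric(0)
    tl_dwell <- numeric(0)
    tl_irms <- numeric(0)
    if (spec$event_rate_hz > 0) {
      gap_min <- max(2L, as.integer(round(100e-6 * fs))) # 100 us recovery gap
      t_now <- 0
      prev_end <- gap_min
      repeat {
        t_now <- t_now + stats::rexp(1, spec$event_rate_hz)
        if (t_now >= spec$duration_s) break
        lab <- sample(names(mix), 1L, prob = mix)
        p <- classes[[match(lab, labels)]]
        t_d <- p$dwell_min_us +
          stats::rexp(1, 1 / (p$dwell_tail_us - p$dwell_min_us))
        i_b_frac <- rnorm_trunc01(1L, p$ib_frac_mean, p$ib_frac_sd)
        irms <- rlnorm_meansd(1L, p$irms_pop_mean_nA, p$irms_pop_sd_nA)
        n_ev <- max(1L, as.integer(round(t_d * 1e-6 * fs)))
        start <- as.integer(round(t_now * fs)) + 1L
        if (start < prev_end + gap_min) next # thinned: would overlap
        end <- start + n_ev - 1L
        if (end > n - gap_min) next
        i_b <- i_b_frac * spec$open_pore_current_nA
        # keep the blockade below the detector's working band: shift deeper
        # (never shallower) if fluctuation peaks approach the open-pore
        # level; redraw waveforms too wide to fit above zero current, so
        # clipping does not erode the calibrated per-event SD
        ceiling_nA <- spec$open_pore_current_nA -
          9 * spec$baseline_noise_sd_nA - 1e-9
        for (try in 1:5) {
          fl <- event_fluctuation(p, n_ev, irms, fs,
                                  spec$baseline_noise_sd_nA)
          excess <- (i_b + max(fl)) - ceiling_nA
          i_b_eff <- if (excess > 0) i_b - excess else i_b
          if (i_b_eff + min(fl) >= 0) break
        }
        pulse <- pmax(i_b_eff + fl, 0)
        idx <- start:end
        x[idx] <- x[idx] - spec$open_pore_current_nA + pulse
        tl_class <- c(tl_class, lab)
        tl_start <- c(tl_start, start - 1L)
        tl_end <- c(tl_end, end) # 0-based half-open
        tl_ib <- c(tl_ib, mean(pulse))
        tl_dwell <- c(tl_dwell, n_ev / fs * 1e6)
        tl_irms <- c(tl_irms, irms)
        prev_end <- end
      }
    }
    truth <- data.frame(class_label = tl_class, start_idx = tl_start,
                        end_idx = tl_end, i_b_nA = tl_ib,
                        dwell_us = tl_dwell, i_rms_target_nA = tl_irms,
                        stringsAsFactors = FALSE)
    list(trace = ion_trace(x, fs, spec$voltage_mV,
                           meta = list(seed = spec$seed,
                                       open_pore_current_nA =
                                         spec$open_pore_current_nA)),
         truth = truth)
  })
}

#' Simulate a spike-in dilution series
#'
#' For each spiked mass the true mtDNA event fraction follows
#' [spikein_model()]; the observed count of mtDNA-classified events is
#' binomial, reflecting the digital counting statistics of the assay.
#'
#' @param n_endo Endogenous mtDNA copies in the sample.
#' @param n_gdna Adjusted gDNA fragment copies (counting background).
#' @param masses_ng Spiked mtDNA masses, ng.
#' @param events_per_run Classified events collected per run (>= 100).
#' @param mt_length_bp mtDNA length, bp.
#' @param seed Optional integer seed.
#' @return Object of class `"spikein_series"`: a `data.frame` with columns
#'   `mass_ng`, `n_events`, `n_mt`, `observed_R`; attribute `mt_length_bp`.
#' @export
synth_spikein_series <- function(n_endo, n_gdna, masses_ng,
                                 events_per_run = 2000,
                                 mt_length_bp = 16569, seed = NULL) {
  if (n_endo < 0 || n_gdna < 0)
    stop("copy numbers must be nonnegative", call. = FALSE)
  stopifnot(all(masses_ng >= 0), all(events_per_run >= 100))
  n_run <- rep_len(as.integer(events_per_run), length(masses_ng))
  with_seed(seed, {
    r_true <- spikein_model(masses_ng, n_endo, n_gdna, mt_length_bp)
    n_mt <- stats::rbinom(length(masses_ng), n_run, r_true)
    out <- data.frame(mass_ng = masses_ng, n_events = n_run, n_mt = n_mt,
                      observed_R = n_mt / n_run)
    attr(out, "mt_length_bp") <- mt_length_bp
    class(out) <- c("spikein_series", "data.frame")
    out
  })
}

#' Photon-count trace container
#' @param frame_counts Photon counts per frame.
#' @param frame_rate_hz Frame rate, Hz (camera frames per second).
#' @param background_mean,background_rms Background statistics, counts/frame
#'   (optional metadata; estimated robustly downstream when absent).
#' @return Object of class `"photon_trace"`.
#' @export
photon_trace <- function(frame_counts, frame_rate_hz = 1000,
                         background_mean = NA_real_,
                         background_rms = NA_real_) {
  stopifnot(frame_rate_hz > 0)
  if (any(frame_counts < 0)) stop("photon counts must be >= 0", call. = FALSE)
  structure(list(frame_counts = as.numeric(frame_counts),
                 frame_rate_hz = frame_rate_hz,
                 background_mean = background_mean,
                 background_rms = background_rms),
            class = "photon_trace")
}

#' Simulate a synchronous photon-count frame series
#'
#' Emulates camera frames acquired at 1 kHz alongside the ion-current
#' recording: Gaussian background (floored at zero) plus Poisson photon
#' bursts over the frames spanning each labeled translocation. Burst onsets
#' lead the electrical start by a random jitter, mirroring molecules dwelling
#' near the pore before threading.
#'
#' @param truth Ground-truth event table from [synth_trace()].
#' @param sampling_rate_hz Sampling rate of the parent ion trace, Hz.
#' @param duration_s Duration of the recording, seconds.
#' @param labeled_fraction Fraction of events carrying fluorophores, in
#'   `[0, 1]`.
#' @param burst_mean_counts Mean added counts/frame during a burst.
#' @param background_mean,background_sd Background level and SD, counts/frame.
#' @param frame_rate_hz Frame rate, Hz.
#' @param max_lead_ms Maximum burst lead before the electrical start, ms.
#' @param seed Optional integer seed.
#' @return A [photon_trace()] with `ceiling(duration_s * frame_rate_hz)`
#'   frames.
#' @export
synth_photon_trace <- function(truth, sampling_rate_hz, duration_s,
                               labeled_fraction,
                               burst_mean_counts = 400,
                               background_mean = 100, background_sd = 30,
                               frame_rate_hz = 1000, max_lead_ms = 2,
                               seed = NULL) {
  stopifnot(frame_rate_hz > 0, duration_s > 0)
  if (labeled_fraction < 0 || labeled_fraction > 1)
    stop("labeled_fraction must lie in [0, 1]", call. = FALSE)
  n_f <- as.integer(ceiling(duration_s * frame_rate_hz))
  with_seed(seed, {
    counts <- pmax(0, stats::rnorm(n_f, background_mean, background_sd))
    if (nrow(truth) > 0 && labeled_fraction > 0) {
      labeled <- stats::runif(nrow(truth)) < labeled_fraction
      for (i in which(labeled)) {
        lead <- stats::runif(1, 0, max_lead_ms / 1000)
        t0 <- max(0, truth$start_idx[i] / sampling_rate_hz - lead)
        t1 <- truth$end_idx[i] / sampling_rate_hz
        f0 <- max(1L, as.integer(floor(t0 * frame_rate_hz)) + 1L)
        f1 <- min(n_f, as.integer(floor(t1 * frame_rate_hz)) + 1L)
        if (f1 >= f0) {
          idx <- f0:f1
          counts[idx] <- counts[idx] +
            stats::rpois(length(idx), burst_mean_counts)
        }
      }
    }
    photon_trace(counts, frame_rate_hz, background_mean, background_sd)
  })
}
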