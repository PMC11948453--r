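# Event detection: open-pore baseline estimation, threshold/hysteresis event
# calling, and per-event feature extraction.

#' Estimate the open-pore baseline of an ion trace
#'
#' The open-pore current is the median of per-window medians, which is robust
#' to event occupancies up to 50%. The baseline noise SD is a scaled MAD of
#' the samples above an event-exclusion level, so blockades do not inflate
#' the noise estimate.
#'
#' @param trace An [ion_trace()].
#' @param window_s Window length for the running median, seconds.
#' @return Object of class `"baseline_model"` with fields `i_o` (nA),
#'   `noise_sd` (nA) and `window_samples`.
#' @export
estimate_baseline <- function(trace, window_s = 0.1) {
  stopifnot(inherits(trace, "ion_trace"))
  x <- trace$samples
  if (length(x) == 0L) stop("empty trace", call. = FALSE)
  if (all(x == 0)) stop("trace is identically zero: no pore current",
                        call. = FALSE)
  w <- max(1L, min(length(x), as.integer(round(window_s * trace$sampling_rate_hz))))
  if (length(x) < w) stop("trace shorter than baseline window", call. = FALSE)
  nw <- length(x) %/% w
  meds <- vapply(seq_len(nw),
                 function(k) stats::median(x[((k - 1L) * w + 1L):(k * w)]),
                 numeric(1))
  i_o <- stats::median(meds)
  s0 <- stats::mad(x, center = i_o)
  if (s0 == 0) {
    noise_sd <- 0
  } else {
    keep <- x > i_o - 3 * s0 # exclude blockade samples
    noise_sd <- stats::mad(x[keep], center = i_o)
  }
  structure(list(i_o = i_o, noise_sd = noise_sd, window_samples = w),
            class = "baseline_model")
}

#' Detect translocation events by threshold crossing with hysteresis
#'
#' An event opens when the current drops below `i_o - k_sigma * noise_sd` and
#' closes when it first returns to at least `i_o - k_close * noise_sd`.
#' Events shorter than `min_dur_us` are discarded; events longer than
#' `max_dur_us` are treated as pore clogs and excluded, as are events touching
#' either trace end. Returned bounds are disjoint, sorted, 0-based half-open.
#'
#' @param trace An [ion_trace()].
#' @param baseline A [estimate_baseline()] result.
#' @param k_sigma Opening threshold in baseline noise SDs (default 6).
#' @param k_close Closing threshold in noise SDs (default 1, hysteresis).
#' @param min_dur_us Minimum event duration, microseconds.
#' @param max_dur_us Clog cutoff, microseconds.
#' @return `data.frame` with columns `start_idx`, `end_idx` (0-based,
#'   half-open).
#' @export
detect_events <- function(trace, baseline, k_sigma = 6, k_close = 1,
                          min_dur_us = 20, max_dur_us = 1e5) {
  stopifnot(inherits(trace, "ion_trace"), inherits(baseline, "baseline_model"))
  if (k_sigma <= 0) stop("k_sigma must be > 0", call. = FALSE)
  if (!(min_dur_us < max_dur_us))
    stop("need min_dur_us < max_dur_us", call. = FALSE)
  x <- trace$samples
  if (length(x) == 0L) stop("empty trace", call. = FALSE)
  open_thr <- baseline$i_o - k_sigma * baseline$noise_sd
  close_thr <- baseline$i_o - k_close * baseline$noise_sd

  open_idx <- which(x < open_thr)
  empty <- data.frame(start_idx = integer(), end_idx = integer())
  if (length(open_idx) == 0L) return(empty)
  above_idx <- which(x >= close_thr)

  starts <- integer()
  ends <- integer()
  oi <- 1L
  n_open <- length(open_idx)
  while (oi <= n_open) {
    s <- open_idx[oi]
    p <- findInterval(s, above_idx) + 1L # first recovery strictly after s
    if (p > length(above_idx)) break     # never recovers: touches trace end
    e <- above_idx[p]
    if (s > 1L) { # drop events already in progress at the trace start
      starts <- c(starts, s)
      ends <- c(ends, e)
    }
    nxt <- findInterval(e - 1L, open_idx) + 1L # first opening at or after e
    oi <- max(nxt, oi + 1L)
  }
  if (length(starts) == 0L) return(empty)
  dur_us <- (ends - starts) / trace$sampling_rate_hz * 1e6
  keep <- dur_us >= min_dur_us & dur_us <= max_dur_us
  data.frame(start_idx = starts[keep] - 1L, end_idx = ends[keep] - 1L)
}

#' Extract per-event blockade features
#'
#' Computes the six per-event parameters from detected bounds: dwell time
#' `t_D` over the full bounds, mean blocked current `i_b` and in-event RMS
#' `i_rms` over the event interior (a fraction `edge_frac` is trimmed from
#' each side to exclude the entry/exit transients), blockage amplitude
#' `delta_I = i_o - i_b` and fractional blockage `I_B = i_b / i_o` clipped to
#' `[0, 1]`. `i_rms` is the standard deviation of the raw in-event current;
#' baseline noise is not subtracted.
#'
#' @param trace An [ion_trace()].
#' @param bounds `data.frame` of 0-based half-open `start_idx`/`end_idx`.
#' @param baseline A [estimate_baseline()] result.
#' @param edge_frac Fraction trimmed from each event edge, in `[0, 0.5)`.
#' @return `data.frame` with columns `start_idx`, `end_idx`, `t_D_us`,
#'   `i_o_nA`, `i_b_nA`, `delta_I_nA`, `I_B`, `i_rms_nA`, `n_interior`.
#' @export
extract_features <- function(trace, bounds, baseline, edge_frac = 0.1) {
  stopifnot(inherits(trace, "ion_trace"), inherits(baseline, "baseline_model"))
  if (edge_frac < 0 || edge_frac >= 0.5)
    stop("edge_frac must lie in [0, 0.5)", call. = FALSE)
  x <- trace$samples
  fs <- trace$sampling_rate_hz
  n_ev <- nrow(bounds)
  i_b <- numeric(n_ev)
  i_rms <- numeric(n_ev)
  n_int <- integer(n_ev)
  for (i in seq_len(n_ev)) {
    s0 <- bounds$start_idx[i]
    e0 <- bounds$end_idx[i]
    if (!(e0 > s0) || s0 < 0 || e0 > length(x))
      stop("invalid event bounds at row ", i, call. = FALSE)
    len <- e0 - s0
    tr <- floor(edge_frac * len)
    if (len - 2L * tr < 1L) tr <- (len - 1L) %/% 2L
    interior <- x[(s0 + tr + 1L):(e0 - tr)]
    if (length(interior) < 1L)
      stop("event at row ", i, " too short after edge trimming", call. = FALSE)
    i_b[i] <- mean(interior)
    i_rms[i] <- if (length(interior) > 1L) stats::sd(interior) else 0
    n_int[i] <- length(interior)
  }
  len_all <- bounds$end_idx - bounds$start_idx
  data.frame(start_idx = bounds$start_idx, end_idx = bounds$end_idx,
             t_D_us = len_all / fs * 1e6,
             i_o_nA = rep(baseline$i_o, n_ev),
             i_b_nA = i_b,
             delta_I_nA = baseline$i_o - i_b,
             I_B = pmin(1, pmax(0, i_b / baseline$i_o)),
             i_rms_nA = i_rms,
             n_interior = n_int)
}

#' Exponential tail fit of a dwell-time distribution
#'
#' Maximum-likelihood exponential fit to the dwell times above a quantile
#' threshold (default the median). For a floor-shifted exponential dwell law
#' this recovers the characteristic tail time by memorylessness.
#'
#' @param t_D_us Dwell times, microseconds.
#' @param prob Quantile defining the fitted tail (default 0.5).
#' @return List with `tau_us` (characteristic time), `threshold_us`, `n_tail`.
#' @export
fit_dwell_tail <- function(t_D_us, prob = 0.5) {
  stopifnot(length(t_D_us) >= 10, all(t_D_us > 0), prob >= 0, prob < 1)
  thr <- as.numeric(stats::quantile(t_D_us, prob))
  tail_vals <- t_D_us[t_D_us > thr]
  if (length(tail_vals) < 5) stop("too few dwell times above the threshold",
                                  call. = FALSE)
  list(tau_us = mean(tail_vals - thr), threshold_us = thr,
       n_tail = length(tail_vals))
}
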