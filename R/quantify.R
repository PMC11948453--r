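# Quantification: digital count ratios, spike-in calibration model and fit,
# and conversions to qPCR-scale and mass/mass ratios.

#' Digital count ratio with Wilson confidence interval
#'
#' Counts mtDNA-classified events against all others and reports the nanopore
#' ratio `R_NP = n_mt / (n_mt + n_frag)` with a 95% Wilson score interval,
#' reflecting the binomial statistics of single-molecule digital counting.
#'
#' @param labels Classified event labels (factor or character).
#' @param positive Label counted as mtDNA (default `"mtDNA"`).
#' @return Object of class `"count_summary"`: `n_mt_events`, `n_frag_events`,
#'   `R_NP`, `ci_low`, `ci_high`.
#' @export
compute_ratio <- function(labels, positive = "mtDNA") {
  n <- length(labels)
  if (n < 1) stop("at least one classified event required", call. = FALSE)
  n_mt <- sum(labels == positive)
  ci <- if (n > 0)
    suppressWarnings(stats::prop.test(n_mt, n, correct = FALSE)$conf.int)
  structure(list(n_mt_events = n_mt, n_frag_events = n - n_mt,
                 R_NP = n_mt / n, ci_low = ci[1], ci_high = ci[2]),
            class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf("<count_summary> R_NP = %.4f (95%% CI %.4f-%.4f), %d mtDNA / %d other events\n",
              x$R_NP, x$ci_low, x$ci_high, x$n_mt_events, x$n_frag_events))
  invisible(x)
}

#' Copies per nanogram of a dsDNA molecule of given length
#'
#' Molar conversion from mass: `1 ng / (length_bp * 650 g mol^-1 bp^-1 / N_A)`
#' with the average dsDNA base-pair mass of 650 g/mol.
#'
#' @param length_bp Molecule length, bp (>= 1).
#' @return Copies per nanogram.
#' @export
copies_per_ng <- function(length_bp) {
  if (any(length_bp < 1)) stop("length_bp must be >= 1", call. = FALSE)
  avogadro <- 6.02214076e23
  1e-9 * avogadro / (length_bp * 650)
}

#' Spike-in calibration model for the nanopore ratio
#'
#' Saturating two-population model: spiking mass `m` of mtDNA into a fixed
#' counting background of `N_gdna_adj` fragments gives
#' `R = (N_mt_endo + c m) / (N_mt_endo + c m + N_gdna_adj)` with
#' `c = copies_per_ng(mt_length_bp)`, i.e. the total mtDNA is the sum of the
#' endogenous and spiked copies. `R` is strictly increasing in mass, equals
#' the endogenous fraction at zero spike and saturates toward 1.
#'
#' @param mass_ng Spiked mtDNA mass (vectorized), ng.
#' @param N_mt_endo Endogenous mtDNA copies.
#' @param N_gdna_adj Adjusted gDNA fragment copies.
#' @param mt_length_bp mtDNA length, bp.
#' @return Predicted nanopore ratio in `[0, 1)`.
#' @export
spikein_model <- function(mass_ng, N_mt_endo, N_gdna_adj,
                          mt_length_bp = 16569) {
  if (any(mass_ng < 0) || N_mt_endo < 0 || N_gdna_adj < 0)
    stop("masses and copy numbers must be nonnegative", call. = FALSE)
  mt <- N_mt_endo + copies_per_ng(mt_length_bp) * mass_ng
  denom <- mt + N_gdna_adj
  if (any(denom == 0))
    stop("total copy number is zero: model undefined", call. = FALSE)
  mt / denom
}

#' Fit the spike-in calibration model
#'
#' Weighted nonlinear least squares of the observed nanopore ratios against
#' [spikein_model()], with weights from the binomial counting variance
#' (`n / (R (1 - R))`) and nonnegativity bounds on both copy numbers. The
#' background `N_gdna_adj` is initialized from the smallest-mass point and
#' `N_mt_endo` from a linear extrapolation of the ratio to zero mass;
#' jittered restarts recover from a failed initial fit.
#'
#' @param series A [synth_spikein_series()] object or `data.frame` with
#'   columns `mass_ng`, `n_events`, `observed_R` (>= 3 distinct masses).
#' @param mt_length_bp mtDNA length, bp; defaults to the series attribute.
#' @param max_restarts Jittered restarts after a failed fit.
#' @return Object of class `"spikein_fit"`: `N_mt_endo`, `N_gdna_adj`,
#'   `se` (named standard errors from the local curvature), `fitted`,
#'   `residuals`, `converged`.
#' @export
fit_spikein <- function(series, mt_length_bp = NULL, max_restarts = 5) {
  df <- as.data.frame(series)
  need <- c("mass_ng", "n_events", "observed_R")
  if (!all(need %in% names(df)))
    stop("series needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (length(unique(df$mass_ng)) < 3)
    stop("spike-in fit requires >= 3 distinct masses", call. = FALSE)
  mt_length_bp <- mt_length_bp %||% attr(series, "mt_length_bp") %||% 16569
  c_ng <- copies_per_ng(mt_length_bp)

  p <- pmin(pmax(df$observed_R, 1 / (4 * df$n_events)),
            1 - 1 / (4 * df$n_events))
  w <- df$n_events / (p * (1 - p))

  # initialization: extrapolate R to zero mass, solve the smallest-mass point
  r0 <- as.numeric(stats::predict(stats::lm(observed_R ~ mass_ng, df),
                                  data.frame(mass_ng = 0)))
  r0 <- min(max(r0, 1e-4), 1 - 1e-4)
  i1 <- which.min(df$mass_ng)
  r1 <- min(max(df$observed_R[i1], 1e-4), 1 - 1e-4)
  m1 <- df$mass_ng[i1]
  den <- r1 - r0 * (1 - r1) / (1 - r0)
  ng0 <- if (is.finite(den) && den > 0) c_ng * m1 * (1 - r1) / den else NA
  if (!is.finite(ng0) || ng0 <= 0)
    ng0 <- c_ng * stats::median(df$mass_ng) * (1 - mean(p)) / max(mean(p), 1e-4)
  ne0 <- max(r0 / (1 - r0) * ng0, 1)

  do_fit <- function(w, start) {
    for (try in seq_len(max_restarts + 1)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          observed_R ~ (ne + c_ng * mass_ng) / (ne + c_ng * mass_ng + ng),
          data = df, start = start, weights = w, lower = c(0, 0),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) return(fit)
      start <- list(ne = start$ne * stats::runif(1, 0.2, 5),
                    ng = start$ng * stats::runif(1, 0.2, 5))
    }
    stop("spike-in fit failed to converge after restarts", call. = FALSE)
  }
  fit <- do_fit(w, list(ne = ne0, ng = ng0))
  # one reweighting pass: weights from the model-implied binomial variance
  p_fit <- pmin(pmax(as.numeric(stats::fitted(fit)), 1 / (4 * df$n_events)),
                1 - 1 / (4 * df$n_events))
  w2 <- df$n_events / (p_fit * (1 - p_fit))
  est0 <- as.list(stats::coef(fit))
  fit <- do_fit(w2, list(ne = max(est0$ne, 1), ng = max(est0$ng, 1)))
  est <- stats::coef(fit)

  # standard errors from the local curvature with the known counting
  # variances (no residual-dispersion scaling: df would be tiny)
  num <- est["ne"] + c_ng * df$mass_ng
  den <- num + est["ng"]
  J <- cbind(ne = est["ng"] / den^2, ng = -num / den^2)
  cov <- tryCatch(solve(t(J) %*% (w2 * J)), error = function(e)
    matrix(NA_real_, 2, 2, dimnames = list(c("ne", "ng"), c("ne", "ng"))))
  se <- sqrt(pmax(diag(cov), 0))
  structure(list(N_mt_endo = unname(est["ne"]),
                 N_gdna_adj = unname(est["ng"]),
                 se = c(N_mt_endo = unname(se[1]),
                        N_gdna_adj = unname(se[2])),
                 fitted = as.numeric(stats::fitted(fit)),
                 residuals = df$observed_R - as.numeric(stats::fitted(fit)),
                 mt_length_bp = mt_length_bp,
                 converged = TRUE),
            class = "spikein_fit")
}

#' @export
print.spikein_fit <- function(x, ...) {
  cat(sprintf("<spikein_fit> N_mt_endo = %.3g +/- %.2g, N_gdna_adj = %.3g +/- %.2g copies\n",
              x$N_mt_endo, x$se["N_mt_endo"], x$N_gdna_adj,
              x$se["N_gdna_adj"]))
  invisible(x)
}

#' Convert a nanopore ratio to the qPCR-scale mtDNA:gDNA ratio
#'
#' Single-parameter linkage between the two measurement scales:
#' `ratio = kappa * R_NP / (1 - R_NP)`, the count odds scaled by `kappa`.
#'
#' @param R_NP Nanopore ratio in `[0, 1)`.
#' @param kappa Positive scale factor linking the two assays.
#' @return mtDNA:gDNA ratio on the qPCR scale.
#' @export
nanopore_to_qpcr <- function(R_NP, kappa) {
  stopifnot(kappa > 0)
  if (any(R_NP < 0) || any(R_NP >= 1))
    stop("R_NP must lie in [0, 1)", call. = FALSE)
  kappa * R_NP / (1 - R_NP)
}

#' Inverse of [nanopore_to_qpcr()]
#' @param ratio qPCR-scale mtDNA:gDNA ratio (>= 0).
#' @param kappa Positive scale factor.
#' @return Nanopore ratio in `[0, 1)`.
#' @export
qpcr_to_nanopore <- function(ratio, kappa) {
  stopifnot(kappa > 0)
  if (any(ratio < 0)) stop("ratio must be >= 0", call. = FALSE)
  r <- ratio / kappa
  r / (1 + r)
}

#' Expected mass/mass percentage of mtDNA to gDNA
#'
#' Converts the copy-number ratio implied by the nanopore measurement into a
#' mass percentage using the molecule lengths:
#' `100 * nanopore_to_qpcr(R_NP, kappa) * mt_length_bp / genome_size_bp`.
#'
#' @inheritParams nanopore_to_qpcr
#' @param mt_length_bp mtDNA length, bp.
#' @param genome_size_bp Diploid nuclear genome size, bp (default 6e9).
#' @return Mass/mass ratio, percent.
#' @export
mass_ratio_percent <- function(R_NP, kappa, mt_length_bp = 16569,
                               genome_size_bp = 6e9) {
  stopifnot(mt_length_bp > 0, genome_size_bp > 0)
  100 * nanopore_to_qpcr(R_NP, kappa) * mt_length_bp / genome_size_bp
}
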