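# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# A NULL seed leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(list = ".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# Normal draw truncated to the open interval (0, 1) by rejection.
# Signals an error if values remain out of range after `max_retry` passes,
# which indicates unusable (mean, sd) parameters.
rnorm_trunc01 <- function(n, mean, sd, max_retry = 100L) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0 | x >= 1)
  tries <- 0L
  while (length(bad) > 0L && tries < max_retry) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0 | x >= 1)
    tries <- tries + 1L
  }
  if (length(bad) > 0L)
    stop("fractional blockage parameters incompatible with (0, 1) after ",
         max_retry, " truncation retries", call. = FALSE)
  x
}

# Log-normal draw parameterized by its arithmetic mean and SD.
rlnorm_meansd <- function(n, mean, sd) {
  stopifnot(mean >= 0, sd >= 0)
  if (sd == 0) return(rep(mean, n))
  if (mean == 0) stop("log-normal with zero mean but positive sd is undefined",
                      call. = FALSE)
  sigma2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# Mann-Whitney rank statistic AUC of `score` for the logical `positive` class.
auc_rank <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires both positive and negative examples", call. = FALSE)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
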