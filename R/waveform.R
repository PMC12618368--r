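#' Fourier-series representation of a pulsatile inlet velocity
#'
#' An 11-term (by default) truncated Fourier series
#' \deqn{V(t) = \alpha_0 + \sum_{n=1}^{N} \alpha_n \cos(2\pi n t/T)
#'   + \beta_n \sin(2\pi n t/T)}
#' describing the cycle-periodic inlet velocity of a coronary artery.
#'
#' @param alpha0 mean velocity (m/s).
#' @param alpha,beta cosine/sine coefficients (m/s), length N each.
#' @param T_cycle cardiac period (s); 1.4 s corresponds to 43 bpm.
#' @return An object of class `fourier_waveform`.
#' @export
fourier_waveform <- function(alpha0, alpha, beta, T_cycle = 1.4) {
  if (length(alpha) != length(beta))
    stop("fourier_waveform: alpha and beta must have the same length", call. = FALSE)
  if (length(alpha) < 1) stop("fourier_waveform: need at least one harmonic", call. = FALSE)
  if (T_cycle <= 0) stop("fourier_waveform: period T must be > 0", call. = FALSE)
  structure(list(alpha0 = alpha0, alpha = as.numeric(alpha),
                 beta = as.numeric(beta), T_cycle = T_cycle,
                 n_terms = length(alpha)),
            class = "fourier_waveform")
}

#' @export
print.fourier_waveform <- function(x, ...) {
  cat(sprintf("Fourier inlet waveform: %d harmonics, T = %g s\n",
              x$n_terms, x$T_cycle))
  cat(sprintf("  mean velocity alpha0 = %.6g m/s\n", x$alpha0))
  rng <- waveform_range(x)
  cat(sprintf("  range [%.6g, %.6g] m/s, pulsatility (max-min)/mean = %.4g\n",
              rng[1], rng[2], diff(rng) / x$alpha0))
  invisible(x)
}

#' Evaluate a Fourier waveform
#'
#' @param w a [fourier_waveform()].
#' @param t time(s) in seconds (vectorised); evaluation is T-periodic.
#' @return Velocity (m/s).
#' @export
evaluate_waveform <- function(w, t) {
  stopifnot(inherits(w, "fourier_waveform"))
  om <- 2 * pi / w$T_cycle
  v <- rep(w$alpha0, length(t))
  for (n in seq_len(w$n_terms))
    v <- v + w$alpha[n] * cos(om * n * t) + w$beta[n] * sin(om * n * t)
  v
}

# min/max of the series over one period (fine grid + local refinement)
waveform_range <- function(w, n_grid = 4096) {
  tg <- seq(0, w$T_cycle, length.out = n_grid + 1)
  v <- evaluate_waveform(w, tg)
  lo <- stats::optimize(function(t) evaluate_waveform(w, t),
                        lower = max(0, tg[which.min(v)] - w$T_cycle / n_grid),
                        upper = min(w$T_cycle, tg[which.min(v)] + w$T_cycle / n_grid))
  hi <- stats::optimize(function(t) -evaluate_waveform(w, t),
                        lower = max(0, tg[which.max(v)] - w$T_cycle / n_grid),
                        upper = min(w$T_cycle, tg[which.max(v)] + w$T_cycle / n_grid))
  c(min(v, lo$objective), max(v, -hi$objective))
}

#' Fit a Fourier series to sampled velocity data
#'
#' Least-squares fit of the truncated Fourier series to (time, velocity)
#' samples covering one period.  The fit uses an orthogonal (QR) decomposition
#' of the trigonometric design matrix, so non-uniformly spaced samples (e.g.
#' digitised from a published waveform) are handled.
#'
#' @param samples a data.frame or matrix with columns time (s) and velocity
#'   (m/s), times within [0, T).
#' @param T_cycle period (s).
#' @param n_terms number of harmonics (default 11).
#' @return A [fourier_waveform()] with attribute `"rms_residual"` giving the
#'   root-mean-square fit residual (m/s).
#' @export
fit_fourier <- function(samples, T_cycle = 1.4, n_terms = 11) {
  samples <- as.matrix(samples)
  t <- samples[, 1]
  v <- samples[, 2]
  if (length(t) < 2 * n_terms + 1)
    stop("fit_fourier: need at least 2*n_terms + 1 samples (",
         2 * n_terms + 1, "), got ", length(t), call. = FALSE)
  om <- 2 * pi / T_cycle
  X <- matrix(1, length(t), 1 + 2 * n_terms)
  for (n in seq_len(n_terms)) {
    X[, 2 * n] <- cos(om * n * t)
    X[, 2 * n + 1] <- sin(om * n * t)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("fit_fourier: rank-deficient design (duplicated or too few ",
         "distinct sample times)", call. = FALSE)
  coefs <- qr.coef(qrX, v)
  res <- v - X %*% coefs
  w <- fourier_waveform(coefs[1], coefs[2 * seq_len(n_terms)],
                        coefs[2 * seq_len(n_terms) + 1], T_cycle)
  attr(w, "rms_residual") <- sqrt(mean(res^2))
  w
}

#' Synthesise a coronary-like inlet waveform
#'
#' Deterministic (for a given seed) generator of a cycle-periodic velocity
#' waveform with coronary character: a brief systolic dip followed by a
#' dominant diastolic hump, as seen in left coronary inflow.  The shape is
#' built from a small set of harmonics with seed-jittered phases, fitted with
#' the standard 11-term series, then rescaled so that the mean velocity and
#' the pulsatility index (max - min)/mean match the request exactly.
#'
#' This generator is a synthetic stand-in for digitised patient waveforms; it
#' makes no claim about any specific subject.
#'
#' @param mean_velocity cycle-mean velocity (m/s), > 0.
#' @param T_cycle period (s).
#' @param pulsatility_index requested (max - min)/mean, >= 0.
#' @param seed integer seed controlling phase jitter.
#' @param n_terms harmonics in the returned series.
#' @return A strictly positive [fourier_waveform()].
#' @export
synthesize_coronary_waveform <- function(mean_velocity = 0.15, T_cycle = 1.4,
                                         pulsatility_index = 1.2, seed = 1,
                                         n_terms = 11) {
  if (mean_velocity <= 0) stop("synthesize_coronary_waveform: mean_velocity must be > 0", call. = FALSE)
  if (T_cycle <= 0) stop("synthesize_coronary_waveform: T must be > 0", call. = FALSE)
  if (pulsatility_index < 0) stop("synthesize_coronary_waveform: pulsatility must be >= 0", call. = FALSE)
  if (pulsatility_index == 0)
    return(fourier_waveform(mean_velocity, rep(0, n_terms), rep(0, n_terms),
                            T_cycle))
  jit <- withr_seed_runif(seed, 3, -0.05, 0.05)
  # base shape on [0,1): systolic dip near t/T ~ 0.15, diastolic hump ~ 0.65
  shape <- function(s) {
    s <- s %% 1
    1 - 0.75 * exp(-((s - 0.15 - jit[1]) / 0.09)^2) +
      1.15 * exp(-((s - 0.62 - jit[2]) / (0.16 + jit[3]))^2)
  }
  tg <- seq(0, T_cycle, length.out = 257)[-257]
  w <- fit_fourier(cbind(tg, shape(tg / T_cycle)), T_cycle, n_terms)
  # rescale harmonics so PI is exact, then pin the mean
  rng <- waveform_range(w)
  sc <- pulsatility_index * mean_velocity / (rng[2] - rng[1])
  w$alpha <- w$alpha * sc
  w$beta <- w$beta * sc
  w$alpha0 <- mean_velocity
  if (waveform_range(w)[1] <= 0)
    stop("synthesize_coronary_waveform: requested pulsatility forces ",
         "non-positive velocity; reduce pulsatility_index", call. = FALSE)
  w
}

# deterministic uniform draws that do not disturb the caller's RNG state
withr_seed_runif <- function(seed, n, lo, hi) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n, lo, hi)
}

#' Read / write waveform CSV
#'
#' Two-column CSV with header `time_s, velocity_m_per_s`.
#'
#' @param path file path.
#' @return `read_waveform_csv`: a data.frame with the two columns.
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "velocity_m_per_s")
  if (!all(need %in% names(df)))
    stop("read_waveform_csv: expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df[need]
}

#' @rdname read_waveform_csv
#' @param w a [fourier_waveform()] to sample and write.
#' @param n_samples samples over one period.
#' @export
write_waveform_csv <- function(w, path, n_samples = 128) {
  t <- seq(0, w$T_cycle, length.out = n_samples + 1)[-(n_samples + 1)]
  utils::write.csv(data.frame(time_s = t,
                              velocity_m_per_s = evaluate_waveform(w, t)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
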