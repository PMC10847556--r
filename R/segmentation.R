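#' @useDynLib pcgscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

.lowpass <- function(x, fs, fc, order = 1) {
  bf <- signal::butter(order, min(0.99, fc / (fs / 2)), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Daubechies-4 (two-vanishing-moment) decomposition filters
.db2_lo <- c(0.4829629131445341, 0.8365163037378079,
             0.2241438680420134, -0.1294095225512604)
.db2_hi <- c(-0.1294095225512604, -0.2241438680420134,
             0.8365163037378079, -0.4829629131445341)

.swt_detail <- function(x, level = 3) {
  a <- x
  d <- x
  for (l in seq_len(level)) {
    dil <- 2^(l - 1)
    lo <- rep(0, (length(.db2_lo) - 1) * dil + 1)
    hi <- lo
    lo[seq(1, length(lo), by = dil)] <- .db2_lo
    hi[seq(1, length(hi), by = dil)] <- .db2_hi
    d <- as.numeric(stats::filter(a, hi, method = "convolution", sides = 2))
    a <- as.numeric(stats::filter(a, lo, method = "convolution", sides = 2))
    a[is.na(a)] <- 0; d[is.na(d)] <- 0
  }
  d
}

#' Envelope features for cardiac-cycle segmentation
#'
#' Computes four envelopes at the envelope rate (default 50 Hz): the
#' homomorphic envelope (low-pass filtered log-magnitude of the analytic
#' signal), the analytic-signal magnitude envelope, 40-60 Hz band power, and a
#' level-3 wavelet-detail envelope. Each envelope is standardized to zero mean
#' and unit variance over the recording.
#'
#' @param samples Preprocessed audio.
#' @param sample_rate_hz Audio rate (working rate, 2205 Hz).
#' @param env_fs Envelope rate in Hz.
#' @return Matrix with one row per envelope frame and four columns.
#' @export
pcg_envelopes <- function(samples, sample_rate_hz, env_fs = 50) {
  x <- samples
  fs <- sample_rate_hz
  analytic <- .hilbert_analytic(x)
  mag <- Mod(analytic)
  homo <- exp(.lowpass(log(mag + 1e-8), fs, 8))
  bf <- signal::butter(2, c(40, 60) / (fs / 2), type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, x))
  band <- .lowpass(abs(bp), fs, 8)
  wd <- .lowpass(abs(.swt_detail(x, 3)), fs, 8)

  n_frames <- floor(length(x) / fs * env_fs)
  ft <- (seq_len(n_frames) - 0.5) / env_fs
  tt <- (seq_along(x) - 1) / fs
  res <- function(e) stats::approx(tt, e, xout = ft, rule = 2)$y
  E <- cbind(homomorphic = res(homo), hilbert = res(mag),
             band40_60 = res(band), wavelet = res(wd))
  apply(E, 2, function(col) {
    s <- stats::sd(col)
    if (s == 0) col * 0 else (col - mean(col)) / s
  })
}

#' Estimate heart rate from an envelope autocorrelation
#'
#' The mean-removed normalized autocorrelation of the (homomorphic) envelope
#' is searched for its maximum at lags between 0.5 and 2 s; the heart rate is
#' 60 divided by that lag. The systolic interval is the autocorrelation argmax
#' between 0.2 s and half the cycle lag.
#'
#' @param envelope Envelope samples at `env_fs` Hz, at least 3 s.
#' @param env_fs Envelope rate in Hz.
#' @return List with `heart_rate_bpm` (in \[30, 120\]), `systolic_interval_ms`,
#'   `autocorrelation` (normalized, for fusion), and `low_confidence`.
#' @export
estimate_heart_rate <- function(envelope, env_fs = 50) {
  max_lag <- round(2.0 * env_fs)
  if (length(envelope) < max_lag + env_fs)
    stop("envelope too short for heart-rate lag search (need > 3 s)")
  x <- envelope - mean(envelope)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  # ac[1] is lag 0; normalize
  ac <- ac / ac[1]
  .pick_hr_peaks(ac, env_fs)
}

.pick_hr_peaks <- function(ac, env_fs) {
  lags <- seq_along(ac) - 1L
  lo <- round(0.5 * env_fs); hi <- round(2.0 * env_fs)
  win <- which(lags >= lo & lags <= hi)
  i_star <- win[which.max(ac[win])]
  lag_star <- lags[i_star]
  hr <- 60 / (lag_star / env_fs)
  s_lo <- round(0.2 * env_fs); s_hi <- max(s_lo + 1, floor(lag_star / 2))
  swin <- which(lags >= s_lo & lags <= s_hi)
  si_lag <- lags[swin[which.max(ac[swin])]]
  list(heart_rate_bpm = hr,
       systolic_interval_ms = 1000 * si_lag / env_fs,
       autocorrelation = ac,
       low_confidence = ac[i_star] < 0.15)
}

#' Fuse heart-rate evidence across auscultation positions
#'
#' Averages the normalized envelope autocorrelations of all non-noisy
#' recordings pointwise and applies the same peak picking as
#' [estimate_heart_rate()]. With a single usable recording this reduces
#' exactly to the single-recording estimate.
#'
#' @param autocorrelations List of normalized autocorrelation vectors.
#' @param noise_flags Logical vector; `TRUE` entries are excluded.
#' @param env_fs Envelope rate in Hz.
#' @return As [estimate_heart_rate()].
#' @export
fuse_heart_rate <- function(autocorrelations, noise_flags = NULL, env_fs = 50) {
  if (is.null(noise_flags)) noise_flags <- rep(FALSE, length(autocorrelations))
  keep <- which(!noise_flags)
  if (length(keep) == 0)
    stop("all recordings flagged noisy; participant must be excluded")
  acs <- autocorrelations[keep]
  len <- min(vapply(acs, length, 1L))
  avg <- Reduce(`+`, lapply(acs, function(a) a[seq_len(len)])) / length(acs)
  .pick_hr_peaks(avg, env_fs)
}

#' Fit the per-state Gaussian emission model on labelled synthetic frames
#'
#' Synthesizes `n_train` labelled recordings, computes envelope features, and
#' fits a diagonal Gaussian per cardiac state (S1, systole, S2, diastole).
#'
#' @param n_train Number of training recordings.
#' @param seed Seed for the synthetic training set.
#' @param sample_rate_hz Audio rate.
#' @param env_fs Envelope rate.
#' @return List of class `hsmm_emissions` with `mean` and `var` (4 states x
#'   4 features).
#' @export
fit_emission_model <- function(n_train = 24, seed = 7L, sample_rate_hz = 2205,
                               env_fs = 50) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  hrs <- stats::runif(n_train, 50, 95)
  g_sys <- sample(c(0, 0, 1, 2, 3), n_train, replace = TRUE)
  g_dia <- sample(c(0, 0, 0, 1), n_train, replace = TRUE)
  feats <- NULL; labs <- NULL
  for (i in seq_len(n_train)) {
    r <- synthesize_pcg(hrs[i], g_sys[i], g_dia[i], sample_rate_hz, 10,
                        seed = .derive_seed(seed, i))
    E <- pcg_envelopes(r$waveform, sample_rate_hz, env_fs)
    m <- min(nrow(E), length(r$frame_states))
    feats <- rbind(feats, E[seq_len(m), ])
    labs <- c(labs, r$frame_states[seq_len(m)])
  }
  mu <- t(vapply(1:4, function(s) colMeans(feats[labs == s, , drop = FALSE]),
                 numeric(4)))
  va <- t(vapply(1:4, function(s) {
    v <- apply(feats[labs == s, , drop = FALSE], 2, stats::var)
    pmax(v, 1e-4)
  }, numeric(4)))
  structure(list(mean = mu, var = va), class = "hsmm_emissions")
}

.emission_loglik <- function(E, emissions) {
  T_ <- nrow(E)
  L <- matrix(0, T_, 4)
  for (s in 1:4) {
    mu <- emissions$mean[s, ]; va <- emissions$var[s, ]
    L[, s] <- -0.5 * colSums((t(E) - mu)^2 / va) -
      0.5 * sum(log(2 * pi * va))
  }
  L
}

.duration_priors <- function(heart_rate_bpm, systolic_interval_ms, env_fs = 50) {
  cycle_ms <- 60000 / heart_rate_bpm
  m_s1 <- 122; m_s2 <- 92
  m_sys <- max(40, systolic_interval_ms - m_s1)
  m_dia <- max(60, cycle_ms - (m_s1 + m_sys + m_s2))
  means <- c(m_s1, m_sys, m_s2, m_dia)
  sds <- c(22, max(30, 0.25 * m_sys), 22, max(30, 0.25 * m_dia))
  lapply(1:4, function(s) {
    mu <- means[s] / 1000 * env_fs; sd <- sds[s] / 1000 * env_fs
    dmax <- max(2L, ceiling(mu + 3.5 * sd))
    d <- seq_len(dmax)
    lp <- stats::dnorm(d, mu, sd, log = TRUE)
    lp - log(sum(exp(lp - max(lp))) ) - max(lp)  # normalize over support
  })
}

#' Segment a recording into cardiac states with a duration-dependent HSMM
#'
#' Decodes the cyclic state sequence S1 -> systole -> S2 -> diastole at the
#' envelope rate with duration-dependent Viterbi: Gaussian duration priors
#' whose means derive from the fused heart rate and systolic interval
#' (S1 122 ms, S2 92 ms, systole = systolic interval - S1, diastole = cycle
#' remainder), and per-state Gaussian emission likelihoods over the four
#' envelope features.
#'
#' @param samples Preprocessed audio.
#' @param sample_rate_hz Audio rate.
#' @param heart_rate_bpm,systolic_interval_ms Fused cycle parameters.
#' @param emissions An `hsmm_emissions` model from [fit_emission_model()].
#' @param env_fs Envelope rate.
#' @return List of class `segmentation_result`: `frame_states` (integer, 50 Hz,
#'   1 = S1, 2 = systole, 3 = S2, 4 = diastole), `cycle_starts` (S1 onset
#'   sample indices at audio rate), `heart_rate_bpm`, `systolic_interval_ms`,
#'   `log_prob`.
#' @export
segment_hsmm <- function(samples, sample_rate_hz, heart_rate_bpm,
                         systolic_interval_ms, emissions, env_fs = 50,
                         envelopes = NULL) {
  E <- if (is.null(envelopes)) pcg_envelopes(samples, sample_rate_hz, env_fs)
       else envelopes
  L <- .emission_loglik(E, emissions)
  dur <- .duration_priors(heart_rate_bpm, systolic_interval_ms, env_fs)
  v <- hsmm_viterbi_cpp(L, dur)
  states <- v$states
  onset_frames <- which(states == 1L & c(4L, states[-length(states)]) != 1L)
  cycle_starts <- as.integer(round((onset_frames - 1) / env_fs * sample_rate_hz) + 1L)
  structure(list(frame_states = states, cycle_starts = cycle_starts,
                 heart_rate_bpm = heart_rate_bpm,
                 systolic_interval_ms = systolic_interval_ms,
                 log_prob = v$log_prob),
            class = "segmentation_result")
}

#' Cut a segmented recording into overlapping four-cycle blocks
#'
#' Blocks of `n_per_block` consecutive cardiac cycles with 50 percent overlap
#' (stride of two cycles), at most `max_blocks` blocks (the first ones if more
#' are available). A recording with fewer than `n_per_block` complete cycles
#' yields a single block covering all complete cycles; one with no complete
#' cycle yields an empty set.
#'
#' @param cycle_starts Sorted S1 onset sample indices; consecutive onsets
#'   bound the complete cycles, so `length(cycle_starts) - 1` cycles exist.
#' @param n_per_block Cycles per block.
#' @param overlap Fractional overlap between consecutive blocks.
#' @param max_blocks Cap on the number of blocks.
#' @return Data frame with `block_index` (0-based), `start_sample`,
#'   `end_sample`, `start_cycle`, `n_cycles`.
#' @export
extract_blocks <- function(cycle_starts, n_per_block = 4, overlap = 0.5,
                           max_blocks = 6) {
  onsets <- sort(cycle_starts)
  n_cycles <- length(onsets) - 1L
  empty <- data.frame(block_index = integer(0), start_sample = integer(0),
                      end_sample = integer(0), start_cycle = integer(0),
                      n_cycles = integer(0))
  if (n_cycles < 1) return(empty)
  stride <- max(1L, round(n_per_block * (1 - overlap)))
  if (n_cycles < n_per_block) {
    return(data.frame(block_index = 0L, start_sample = onsets[1],
                      end_sample = onsets[n_cycles + 1L] - 1L,
                      start_cycle = 0L, n_cycles = n_cycles))
  }
  starts <- seq(1L, n_cycles - n_per_block + 1L, by = stride)
  starts <- starts[seq_len(min(length(starts), max_blocks))]
  data.frame(block_index = seq_along(starts) - 1L,
             start_sample = onsets[starts],
             end_sample = onsets[starts + n_per_block] - 1L,
             start_cycle = starts - 1L,
             n_cycles = n_per_block)
}
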