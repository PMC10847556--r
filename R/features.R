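.hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
.mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

.mel_filterbank <- function(n_filters, nfft, fs) {
  edges <- .mel_to_hz(seq(.hz_to_mel(0), .hz_to_mel(fs / 2),
                          length.out = n_filters + 2))
  bin_freqs <- (0:(nfft / 2)) * fs / nfft
  fb <- matrix(0, n_filters, nfft / 2 + 1)
  for (i in seq_len(n_filters)) {
    lo <- edges[i]; ce <- edges[i + 1]; hi <- edges[i + 2]
    up <- (bin_freqs - lo) / (ce - lo)
    dn <- (hi - bin_freqs) / (hi - ce)
    fb[i, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

.dct2_matrix <- function(n_coef, n_in) {
  # orthonormal type-II DCT
  C <- matrix(0, n_coef, n_in)
  for (k in 0:(n_coef - 1)) {
    C[k + 1, ] <- cos(pi * k * ((1:n_in) - 0.5) / n_in) * sqrt(2 / n_in)
  }
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

#' Mel-frequency cepstral coefficients of a phonocardiogram block
#'
#' Spectrogram with Hann windows of 35 ms (a 25 ms step plus 10 ms overlap),
#' a 26-filter triangular Mel filterbank spanning 0 to Nyquist (HTK Mel
#' scale), log filterbank energies (floor 1e-10), and an orthonormal type-II
#' DCT keeping the first `n_coef` coefficients (c0 included by default).
#'
#' @param samples Block audio at the working rate.
#' @param sample_rate_hz Audio rate (2205 Hz default).
#' @param window_ms,hop_ms Analysis window and hop in milliseconds.
#' @param n_filters Number of Mel filters.
#' @param n_coef Number of cepstral coefficients kept.
#' @param keep_c0 Drop the energy coefficient if `FALSE` (then `n_coef`
#'   coefficients c1.. are returned).
#' @param log_floor Floor applied to filterbank energies before the log.
#' @return Matrix of `n_coef` rows by one column per analysis frame.
#' @export
pcg_mfcc <- function(samples, sample_rate_hz = 2205, window_ms = 35,
                     hop_ms = 25, n_filters = 26, n_coef = 13,
                     keep_c0 = TRUE, log_floor = 1e-10) {
  n <- length(samples)
  win <- round(window_ms / 1000 * sample_rate_hz)
  hop <- round(hop_ms / 1000 * sample_rate_hz)
  if (n < win)
    stop("block too short for one analysis window (", n, " < ", win, " samples)")
  n_frames <- floor((n - win) / hop) + 1L
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  nfft <- 2^ceiling(log2(win))
  starts <- (seq_len(n_frames) - 1L) * hop + 1L
  frames <- vapply(starts, function(s) samples[s:(s + win - 1L)] * w,
                   numeric(win))
  frames <- rbind(frames, matrix(0, nfft - win, n_frames))
  spec <- Mod(stats::mvfft(frames))^2
  spec <- spec[1:(nfft / 2 + 1), , drop = FALSE]
  fb <- .mel_filterbank(n_filters, nfft, sample_rate_hz)
  fbe <- log(pmax(fb %*% spec, log_floor))
  n_keep <- if (keep_c0) n_coef else n_coef + 1L
  cc <- .dct2_matrix(n_keep, n_filters) %*% fbe
  if (!keep_c0) cc <- cc[-1, , drop = FALSE]
  cc
}

#' Resize an MFCC matrix to 13 x 200 and standardize it
#'
#' Cubic-spline interpolation along the time axis only, to exactly
#' `n_columns` columns, followed by subtraction of the scalar matrix mean and
#' division by the scalar matrix standard deviation.
#'
#' @param m Coefficient matrix (rows are coefficients, columns time frames,
#'   at least 2 columns).
#' @param n_columns Target number of time columns.
#' @return Standardized matrix with the same number of rows and `n_columns`
#'   columns; mean 0 and SD 1 within 1e-6.
#' @export
resize_and_standardize <- function(m, n_columns = 200) {
  if (!is.matrix(m) || ncol(m) < 2) stop("matrix with >= 2 time columns required")
  T_ <- ncol(m)
  xout <- seq(1, T_, length.out = n_columns)
  out <- t(apply(m, 1, function(row) {
    stats::spline(seq_len(T_), row, xout = xout, method = "fmm")$y
  }))
  s <- stats::sd(as.vector(out))
  if (!is.finite(s) || s == 0) stop("degenerate (zero-variance) feature block")
  (out - mean(out)) / s
}

#' Feature blocks for one segmented recording
#'
#' Applies [extract_blocks()], [pcg_mfcc()] and [resize_and_standardize()] to
#' every four-cycle block of a recording.
#'
#' @param samples Preprocessed audio at the working rate.
#' @param sample_rate_hz Audio rate.
#' @param cycle_starts S1 onset sample indices.
#' @param ... Passed to [extract_blocks()].
#' @return List of standardized 13 x 200 matrices (possibly empty).
#' @export
recording_feature_blocks <- function(samples, sample_rate_hz, cycle_starts, ...) {
  blocks <- extract_blocks(cycle_starts, ...)
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    seg <- samples[blocks$start_sample[i]:min(blocks$end_sample[i], length(samples))]
    mat <- tryCatch(
      resize_and_standardize(pcg_mfcc(seg, sample_rate_hz)),
      error = function(e) NULL)
    if (!is.null(mat)) out[[length(out) + 1L]] <- mat
  }
  out
}
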