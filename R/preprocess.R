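#' Remove high-amplitude spike artifacts from a phonocardiogram
#'
#' Iterative maximum-absolute-amplitude (MAA) spike removal. The signal is
#' partitioned into non-overlapping 500 ms windows (last partial window kept).
#' While the largest window MAA exceeds three times the median window MAA, the
#' maximum-amplitude sample in the offending window is located, the span around
#' it is expanded to the nearest zero crossings on both sides (or the window
#' edges), that span is zeroed, and the MAAs are recomputed.
#'
#' @param samples Numeric signal.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param window_s MAA window length in seconds.
#' @return Signal of identical length with spike spans zeroed.
#' @export
remove_spikes <- function(samples, sample_rate_hz, window_s = 0.5) {
  n <- length(samples)
  if (n == 0 || !all(is.finite(samples))) stop("non-empty finite signal required")
  wlen <- max(1L, round(window_s * sample_rate_hz))
  starts <- seq(1L, n, by = wlen)
  ends <- pmin(starts + wlen - 1L, n)
  nw <- length(starts)
  x <- samples
  maa <- vapply(seq_len(nw), function(w) max(abs(x[starts[w]:ends[w]])), 0)
  iter_cap <- nw * 10L
  it <- 0L
  while (max(maa) > 3 * stats::median(maa) && it < iter_cap) {
    it <- it + 1L
    w <- which.max(maa)
    a <- starts[w]; b <- ends[w]
    seg <- x[a:b]
    k <- a + which.max(abs(seg)) - 1L
    # expand to nearest zero crossings (sign change or exact zero) within window
    lo <- k
    while (lo > a && !(x[lo - 1L] == 0 || sign(x[lo - 1L]) != sign(x[lo]))) lo <- lo - 1L
    hi <- k
    while (hi < b && !(x[hi + 1L] == 0 || sign(x[hi + 1L]) != sign(x[hi]))) hi <- hi + 1L
    x[lo:hi] <- 0
    maa[w] <- max(abs(x[a:b]))
  }
  x
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Downsample audio to the pipeline working rate
#'
#' Polyphase-style anti-aliased rational rate conversion: zero-stuffing by the
#' upsampling factor, a Hamming-windowed sinc low-pass FIR applied by FFT
#' convolution, and decimation, with the filter group delay compensated so the
#' output is time-aligned with the input.
#'
#' @param samples Numeric signal at `from_hz`.
#' @param from_hz Input rate; must be at least `to_hz` (no upsampling path).
#' @param to_hz Target rate (default 2205 Hz).
#' @return Signal at `to_hz`, length `round(length(samples) * to_hz/from_hz)`
#'   give or take one sample.
#' @export
downsample <- function(samples, from_hz, to_hz = 2205) {
  if (from_hz <= 0) stop("from_hz must be positive")
  if (from_hz < to_hz) stop("upsampling not supported (from_hz < to_hz)")
  if (from_hz == to_hz) return(samples)
  g <- .gcd(round(from_hz), round(to_hz))
  p <- round(to_hz) / g    # up factor
  q <- round(from_hz) / g  # down factor
  n <- length(samples)
  up <- numeric(n * p)
  up[seq(1, length(up), by = p)] <- samples
  # low-pass at the target Nyquist in the upsampled domain
  m <- max(p, q)
  taps <- 2L * 10L * m + 1L
  mid <- (taps - 1L) / 2L
  k <- seq_len(taps) - 1L - mid
  fc <- 0.46 / m                      # normalized cutoff (cycles/sample), slight margin
  h <- 2 * fc * sinc_(2 * fc * k)
  h <- h * (0.54 + 0.46 * cos(2 * pi * k / (taps - 1)))   # Hamming
  h <- p * h / sum(h)
  y <- signal::fftfilt(h, c(up, numeric(mid)))
  y <- y[(mid + 1L):(mid + length(up))]
  y[seq(1, length(y), by = q)]
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Preprocess one recording: spike removal then downsampling
#'
#' @param samples Raw audio in \[-1,1\].
#' @param sample_rate_hz Input rate.
#' @param target_hz Working rate (default 2205 Hz).
#' @return List with `samples` at `target_hz` and `sample_rate_hz = target_hz`.
#' @export
preprocess_pcg <- function(samples, sample_rate_hz, target_hz = 2205) {
  x <- remove_spikes(samples, sample_rate_hz)
  if (sample_rate_hz != target_hz) x <- downsample(x, sample_rate_hz, target_hz)
  list(samples = x, sample_rate_hz = target_hz)
}
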