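# Acoustic measurement oracle: verify rendered audio against the intended
# synthesis parameters.

# 5-term flat-top window; near-flat main lobe makes amplitude-weighted
# spectral measurements insensitive to bin misalignment.
flattop_window <- function(n) {
  a <- c(0.21557895, 0.41663158, 0.277263158, 0.083578947, 0.006947368)
  k <- seq(0, n - 1) / (n - 1)
  a[1] - a[2] * cos(2 * pi * k) + a[3] * cos(4 * pi * k) -
    a[4] * cos(6 * pi * k) + a[5] * cos(8 * pi * k)
}

# Steady-state (sustain) segment: central half of the signal, skipping
# attack and decay transients. Returns the windowed magnitude spectrum on
# a zero-padded FFT grid of at least nfft points.
sustain_spectrum <- function(audio, nfft_min = 2^15) {
  x <- audio$samples
  n <- length(x)
  seg <- x[max(1, floor(n / 4)):floor(3 * n / 4)]
  seg <- seg * flattop_window(length(seg))
  nfft <- max(nfft_min, 2^ceiling(log2(length(seg))))
  spec <- Mod(stats::fft(c(seg, numeric(nfft - length(seg)))))
  half <- floor(nfft / 2)
  list(freq = (seq_len(half) - 1) * audio$sample_rate_hz / nfft,
       mag = spec[seq_len(half)],
       bin_hz = audio$sample_rate_hz / nfft)
}

check_nonsilent <- function(audio) {
  if (max(abs(audio$samples)) == 0) {
    stop("measurement undefined for silent audio", call. = FALSE)
  }
}

#' Measured spectral centroid of rendered audio
#'
#' Amplitude-weighted mean frequency of the magnitude spectrum over the
#' steady-state (central) segment, using a flat-top window.
#'
#' @param audio `tpt_audio`.
#' @return Centroid in Hz.
#' @export
#' @examples
#' a <- synthesize_tone(stimulus_spec("C4"))
#' measured_spectral_centroid(a)
measured_spectral_centroid <- function(audio) {
  check_nonsilent(audio)
  sp <- sustain_spectrum(audio)
  sum(sp$freq * sp$mag) / sum(sp$mag)
}

# FFT-based analytic signal; Mod() of it is the amplitude envelope.
analytic_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Measured attack time of rendered audio
#'
#' Time from the amplitude envelope first exceeding 1% of its peak to
#' first reaching 99% of it. The envelope is the magnitude of the
#' analytic signal, moving-average smoothed (default 5 ms) to remove
#' harmonic-rate ripple. Detuned partials superimpose beating on the
#' envelope at rates comparable to the attack times themselves, which no
#' envelope follower can separate from the ramp; verify the envelope
#' dimension on in-phase stimuli (`flux_slider = 0`).
#'
#' @param audio `tpt_audio`.
#' @param smooth_ms Moving-average smoothing width (default 5 ms).
#' @return Attack time in milliseconds.
#' @export
measured_attack_time <- function(audio, smooth_ms = 5) {
  check_nonsilent(audio)
  env <- smoothed(analytic_envelope(audio$samples),
                  smooth_ms, audio$sample_rate_hz)
  pk <- max(env)
  i0 <- which(env > 0.01 * pk)[1]
  i1 <- which(env >= 0.99 * pk)[1]
  (i1 - i0) / audio$sample_rate_hz * 1000
}

# Centered moving average with truncated windows at the edges.
smoothed <- function(x, window_ms, fs) {
  n <- length(x)
  h <- round(window_ms / 1000 * fs / 2)
  if (h < 1) return(x)
  cs <- cumsum(x)
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
}

#' Mean harmonic ratio deviation (beta)
#'
#' Arithmetic mean absolute deviation of the four detuned partial ratios
#' from their whole-number bases (3, 4, 5, 6); the scalar summary of the
#' spectral-flux manipulation.
#'
#' @param ratios Numeric vector of four partial ratios, e.g. from
#'   [flux_link()].
#' @return Non-negative scalar beta.
#' @export
#' @examples
#' harmonic_deviation_beta(flux_link(100))  # 0.25
harmonic_deviation_beta <- function(ratios) {
  stopifnot(length(ratios) == 4)
  mean(abs(ratios - c(3, 4, 5, 6)))
}

#' Count spectral peaks
#'
#' Number of local maxima in the sustain-segment magnitude spectrum whose
#' height exceeds `threshold` times the global maximum. Maxima closer
#' than `min_separation_hz` are merged, so each partial counts once.
#'
#' @param audio `tpt_audio` (unfiltered steady-state tone for partial
#'   counting).
#' @param threshold Relative magnitude threshold (default 0.05).
#' @param min_separation_hz Minimum spacing between distinct peaks.
#' @return Integer peak count.
#' @export
count_spectral_peaks <- function(audio, threshold = 0.05,
                                 min_separation_hz = 20) {
  sp <- sustain_spectrum(audio)
  m <- sp$mag
  n <- length(m)
  is_max <- c(FALSE, m[2:(n - 1)] > m[1:(n - 2)] & m[2:(n - 1)] >= m[3:n], FALSE)
  cand <- which(is_max & m > threshold * max(m))
  if (length(cand) == 0) return(0L)
  f <- sp$freq[cand]
  keep <- order(m[cand], decreasing = TRUE)
  sel <- numeric(0)
  for (i in keep) {
    if (all(abs(f[i] - sel) > min_separation_hz)) sel <- c(sel, f[i])
  }
  length(sel)
}

#' Frequencies of the strongest spectral peaks
#'
#' Locates up to `k` merged spectral peaks (as in
#' [count_spectral_peaks()]) and returns their frequencies in ascending
#' order, refined by parabolic interpolation around each bin.
#'
#' @inheritParams count_spectral_peaks
#' @param k Maximum number of peaks to return.
#' @return Numeric vector of peak frequencies in Hz.
#' @export
spectral_peak_frequencies <- function(audio, k = 8, threshold = 0.05,
                                      min_separation_hz = 20) {
  sp <- sustain_spectrum(audio)
  m <- sp$mag
  n <- length(m)
  is_max <- c(FALSE, m[2:(n - 1)] > m[1:(n - 2)] & m[2:(n - 1)] >= m[3:n], FALSE)
  cand <- which(is_max & m > threshold * max(m))
  ord <- cand[order(m[cand], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= k) break
    if (all(abs(sp$freq[i] - sp$freq[sel]) > min_separation_hz)) sel <- c(sel, i)
  }
  refine <- vapply(sel, function(i) {
    if (i <= 1 || i >= n) return(sp$freq[i])
    d <- (m[i - 1] - m[i + 1]) / (m[i - 1] - 2 * m[i] + m[i + 1]) / 2
    sp$freq[i] + d * sp$bin_hz
  }, numeric(1))
  sort(refine)
}

#' Amplitude-fluctuation proxy for beating strength
#'
#' Band-limited coefficient of variation of the steady-state amplitude
#' envelope: the RMS of envelope-spectrum components between `lo_hz` and
#' `hi_frac` times the fundamental, relative to the mean envelope. The
#' band keeps the beating that detuned partials produce (spacings drop
#' below the fundamental as detuning grows) while excluding the
#' harmonic-rate ripple every complex tone has, so the value rises with
#' the spectral-flux slider.
#'
#' @param audio `tpt_audio`.
#' @param f0_hz Fundamental frequency of the tone; sets the upper band
#'   edge. When `NULL` the band extends to `hi_hz`.
#' @param hi_frac Upper band edge as a fraction of `f0_hz`
#'   (default 0.75).
#' @param lo_hz Lower band edge (default 3 Hz, above the per-tone drift).
#' @param hi_hz Upper band edge when `f0_hz` is not given.
#' @return Non-negative band-limited envelope CV.
#' @export
envelope_fluctuation <- function(audio, f0_hz = NULL, hi_frac = 0.75,
                                 lo_hz = 3, hi_hz = 200) {
  check_nonsilent(audio)
  env <- analytic_envelope(audio$samples)
  n <- length(env)
  seg <- env[max(1, floor(n / 4)):floor(3 * n / 4)]
  mu <- mean(seg)
  w <- flattop_window(length(seg))
  sp <- Mod(stats::fft((seg - mu) * w))
  f <- (seq_along(sp) - 1) * audio$sample_rate_hz / length(sp)
  hi <- if (!is.null(f0_hz)) hi_frac * f0_hz else hi_hz
  band <- f > lo_hz & f < hi
  # Parseval with window power compensation: RMS of the band relative
  # to the mean level
  sqrt(2 * sum(sp[band]^2) / (sum(w^2) * length(seg))) / mu
}

#' Verify a rendered stimulus against intended parameters
#'
#' Convenience wrapper bundling the measurement oracle: measured spectral
#' centroid, measured attack time, peak count and envelope fluctuation.
#'
#' @param audio `tpt_audio`.
#' @return List of class `tpt_measurement`.
#' @export
measure_audio <- function(audio) {
  structure(list(
    measured_centroid_hz = measured_spectral_centroid(audio),
    measured_attack_ms = measured_attack_time(audio),
    n_peaks = count_spectral_peaks(audio),
    envelope_fluctuation = envelope_fluctuation(audio)
  ), class = "tpt_measurement")
}

#' @export
print.tpt_measurement <- function(x, ...) {
  cat(sprintf(paste0("Measured: centroid %.1f Hz, attack %.1f ms, ",
                     "%d spectral peaks, envelope CV %.3f\n"),
              x$measured_centroid_hz, x$measured_attack_ms,
              x$n_peaks, x$envelope_fluctuation))
  invisible(x)
}
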