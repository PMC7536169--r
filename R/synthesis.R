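# Slider-to-parameter link functions ------------------------------------

#' Named pitch set used by default
#'
#' The test spans G3 to A#4; the three interior pitches default to C4, E4
#' and G4. Frequencies are 12-TET with A4 = 440 Hz.
#'
#' @return Named numeric vector of fundamental frequencies in Hz.
#' @export
#' @examples
#' tpt_pitch_set()
tpt_pitch_set <- function() {
  c(G3 = 196.00, C4 = 261.63, E4 = 329.63, G4 = 392.00, "A#4" = 466.16)
}

check_slider <- function(s) {
  if (!is.numeric(s) || anyNA(s) || any(s < 0) || any(s > 100)) {
    stop("slider value must lie in [0, 100]", call. = FALSE)
  }
  invisible(s)
}

#' Envelope link: slider to attack and decay times
#'
#' Maps a slider position to the attack/decay pair of the amplitude
#' envelope. Both follow an exponential curve with base 1.03, affinely
#' calibrated so that the endpoints are attack 5 -> 291 ms and decay
#' 50 -> 5 ms: attack(s) = A * 1.03^s + B with A = 286 / (1.03^100 - 1),
#' B = 5 - A, and the analogous calibration for decay. Attack is strictly
#' increasing and decay strictly decreasing in the slider.
#'
#' @param s Slider position in [0, 100].
#' @return List with `attack_ms` and `decay_ms` (milliseconds).
#' @export
#' @examples
#' envelope_link(0)    # attack 5 ms, decay 50 ms
#' envelope_link(100)  # attack 291 ms, decay 5 ms
envelope_link <- function(s) {
  check_slider(s)
  g <- (1.03^s - 1) / (1.03^100 - 1)  # 0 at s=0, 1 at s=100
  list(attack_ms = 5 + 286 * g, decay_ms = 50 - 45 * g)
}

#' Spectral-flux link: slider to partial frequency ratios
#'
#' The four partials at base multiples 3, 4, 5 and 6 of the fundamental
#' are detuned linearly with the slider: ratios run from (3.0, 4.0, 5.0,
#' 6.0) at slider 0 to (3.3, 3.7, 5.2, 5.8) at slider 100. Multiples 3 and
#' 5 are raised, 4 and 6 lowered, so neighbouring partials converge and
#' beat against each other.
#'
#' @param s Slider position in [0, 100].
#' @return Numeric vector of four frequency ratios (multiples of f0).
#' @export
#' @examples
#' flux_link(0)
#' flux_link(100)
flux_link <- function(s) {
  check_slider(s)
  x <- s / 100
  c(3 + 0.3 * x, 4 - 0.3 * x, 5 + 0.2 * x, 6 - 0.2 * x)
}

#' Spectral-centroid link: slider to filter centre frequency
#'
#' The bandpass filter centre frequency follows a quadratic link,
#' centre = 600 + 400 * (s/100)^2 Hz, which places 700 Hz at slider 50.
#' The quality factor Q (centre / bandwidth) is fixed at 1.8.
#'
#' @param s Slider position in [0, 100].
#' @return List with `centre_hz` and `q_factor`.
#' @export
#' @examples
#' centroid_link(50)  # 700 Hz
centroid_link <- function(s) {
  check_slider(s)
  list(centre_hz = 600 + 400 * (s / 100)^2, q_factor = 1.8)
}

# Stimulus specification ------------------------------------------------

#' Construct a stimulus specification
#'
#' A stimulus is a complex tone of eight partials at a given fundamental,
#' with all three timbre dimensions fixed by slider values. Trials repeat
#' the tone three times with 800 ms silent gaps by default.
#'
#' @param f0_hz Fundamental frequency in Hz, or a note name from
#'   [tpt_pitch_set()].
#' @param envelope_slider,flux_slider,centroid_slider Slider positions in
#'   [0, 100] for the three dimensions.
#' @param tone_duration_ms Tone duration in milliseconds (default 700).
#' @param n_repetitions Number of tone repetitions in a trial (default 3).
#' @param repetition_interval_ms Silent gap between tone offset and next
#'   onset, in milliseconds (default 800).
#' @param sample_rate_hz Sample rate (default 44100).
#' @return Object of class `tpt_stimulus_spec`.
#' @export
#' @examples
#' stimulus_spec("G3", envelope_slider = 20, flux_slider = 50,
#'               centroid_slider = 80)
stimulus_spec <- function(f0_hz, envelope_slider = 50, flux_slider = 50,
                          centroid_slider = 50, tone_duration_ms = 700,
                          n_repetitions = 3, repetition_interval_ms = 800,
                          sample_rate_hz = 44100) {
  if (is.character(f0_hz)) {
    ps <- tpt_pitch_set()
    if (!f0_hz %in% names(ps)) {
      stop("unknown note name '", f0_hz, "'", call. = FALSE)
    }
    f0_hz <- unname(ps[f0_hz])
  }
  if (!is.numeric(f0_hz) || f0_hz <= 0) stop("f0 must be positive", call. = FALSE)
  if (tone_duration_ms <= 0) stop("tone duration must be positive", call. = FALSE)
  check_slider(c(envelope_slider, flux_slider, centroid_slider))
  structure(list(
    f0_hz = f0_hz,
    envelope_slider = envelope_slider,
    flux_slider = flux_slider,
    centroid_slider = centroid_slider,
    tone_duration_ms = tone_duration_ms,
    n_repetitions = n_repetitions,
    repetition_interval_ms = repetition_interval_ms,
    sample_rate_hz = sample_rate_hz
  ), class = "tpt_stimulus_spec")
}

#' @export
print.tpt_stimulus_spec <- function(x, ...) {
  cat("Stimulus: f0", x$f0_hz, "Hz; sliders (env/flux/cent)",
      x$envelope_slider, x$flux_slider, x$centroid_slider,
      "\n  tone", x$tone_duration_ms, "ms,", x$n_repetitions,
      "repetition(s),", x$repetition_interval_ms, "ms gap,",
      x$sample_rate_hz, "Hz\n")
  invisible(x)
}

tpt_audio <- function(samples, sample_rate_hz) {
  structure(list(
    samples = samples,
    sample_rate_hz = sample_rate_hz,
    duration_ms = 1000 * length(samples) / sample_rate_hz
  ), class = "tpt_audio")
}

#' @export
print.tpt_audio <- function(x, ...) {
  cat(sprintf("Audio: %d samples @ %d Hz (%.1f ms), peak %.3f\n",
              length(x$samples), x$sample_rate_hz, x$duration_ms,
              max(abs(x$samples))))
  invisible(x)
}

# Bandpass resonator coefficients: constant-peak-gain biquad with
# alpha = sin(w0) / (2 Q), so the -3 dB bandwidth is centre/Q up to
# bilinear warping (negligible at fs = 44.1 kHz for centres <= 1 kHz).
resonator_coefficients <- function(centre_hz, q_factor, sample_rate_hz) {
  w0 <- 2 * pi * centre_hz / sample_rate_hz
  alpha <- sin(w0) / (2 * q_factor)
  a0 <- 1 + alpha
  list(b = c(alpha, 0, -alpha) / a0,
       a = c(1, -2 * cos(w0) / a0, (1 - alpha) / a0))
}

#' Impulse response of the centroid bandpass filter
#'
#' Exposed so the filter's frequency response can be verified directly
#' (e.g. locating the -3 dB points and checking centre/bandwidth = Q).
#'
#' @param centroid_slider Slider position in [0, 100].
#' @param n Length of the impulse response in samples.
#' @param sample_rate_hz Sample rate.
#' @return `tpt_audio` containing the impulse response.
#' @export
filter_impulse_response <- function(centroid_slider, n = 2^16,
                                    sample_rate_hz = 44100) {
  cp <- centroid_link(centroid_slider)
  co <- resonator_coefficients(cp$centre_hz, cp$q_factor, sample_rate_hz)
  x <- c(1, numeric(n - 1))
  y <- as.numeric(signal::filter(co$b, co$a, x))
  tpt_audio(y, sample_rate_hz)
}

#' Synthesize one complex-tone stimulus
#'
#' Renders the sum of eight equal-amplitude sinusoidal partials at
#' f0 x {1..8}, with the partials at base multiples 3-6 replaced by the
#' detuned ratios from [flux_link()]. A bandpass resonator at the
#' [centroid_link()] centre frequency (Q = 1.8) is applied, then a linear
#' attack/sustain/decay amplitude envelope from [envelope_link()]. The
#' output is peak-normalized to 1 and fully deterministic.
#'
#' @param spec A [stimulus_spec()].
#' @param apply_filter Apply the centroid bandpass stage (default TRUE;
#'   disable to inspect the raw harmonic spectrum).
#' @param apply_envelope Apply the amplitude envelope (default TRUE).
#' @return `tpt_audio` of duration `spec$tone_duration_ms`.
#' @export
#' @examples
#' a <- synthesize_tone(stimulus_spec("C4"))
synthesize_tone <- function(spec, apply_filter = TRUE, apply_envelope = TRUE) {
  stopifnot(inherits(spec, "tpt_stimulus_spec"))
  fs <- spec$sample_rate_hz
  n <- round(spec$tone_duration_ms / 1000 * fs)
  t <- seq_len(n) / fs
  ratios <- c(1, 2, flux_link(spec$flux_slider), 7, 8)
  x <- numeric(n)
  for (r in ratios) x <- x + sin(2 * pi * spec$f0_hz * r * t)
  if (apply_filter) {
    cp <- centroid_link(spec$centroid_slider)
    co <- resonator_coefficients(cp$centre_hz, cp$q_factor, fs)
    x <- as.numeric(signal::filter(co$b, co$a, x))
  }
  if (apply_envelope) {
    ep <- envelope_link(spec$envelope_slider)
    if (ep$attack_ms + ep$decay_ms > spec$tone_duration_ms) {
      stop("attack + decay exceed tone duration", call. = FALSE)
    }
    na <- max(1, round(ep$attack_ms / 1000 * fs))
    nd <- max(1, round(ep$decay_ms / 1000 * fs))
    env <- rep(1, n)
    # open-ended ramps (no exactly-zero samples, so tone onsets/offsets
    # stay detectable and silent gaps keep their nominal length)
    env[seq_len(na)] <- seq_len(na) / na
    env[(n - nd + 1):n] <- seq(1, 0, length.out = nd + 1)[seq_len(nd)]
    x <- x * env
  }
  x <- x / max(abs(x))
  tpt_audio(x, fs)
}

#' Render a full trial (repeated tone)
#'
#' Concatenates `n_repetitions` copies of the synthesized tone separated
#' by silent gaps of `repetition_interval_ms` (offset-to-onset), mirroring
#' the three-fold presentation of each stimulus.
#'
#' @inheritParams synthesize_tone
#' @return `tpt_audio` of total duration
#'   `n_rep * tone + (n_rep - 1) * interval` ms.
#' @export
render_trial <- function(spec, apply_filter = TRUE, apply_envelope = TRUE) {
  tone <- synthesize_tone(spec, apply_filter, apply_envelope)
  k <- spec$n_repetitions
  if (k == 1) return(tone)
  gap <- numeric(round(spec$repetition_interval_ms / 1000 * spec$sample_rate_hz))
  out <- tone$samples
  for (i in seq_len(k - 1)) out <- c(out, gap, tone$samples)
  tpt_audio(out, spec$sample_rate_hz)
}

# WAV I/O ---------------------------------------------------------------
# Minimal RIFF/WAVE PCM writer and reader (mono or interleaved, 16-bit).

#' Write audio to a 16-bit PCM WAV file
#'
#' @param audio `tpt_audio` object (samples in [-1, 1]).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_wav <- function(audio, path) {
  stopifnot(inherits(audio, "tpt_audio"))
  x <- pmax(-1, pmin(1, audio$samples))
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(audio$sample_rate_hz)
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")            # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")        # byte rate
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return `tpt_audio` with samples rescaled to [-1, 1].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file", call. = FALSE)
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found", call. = FALSE)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 2, size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", sz - 16)
      if (fmt[1] != 1L || fmt[2] != 1L) {
        stop("only mono 16-bit PCM supported", call. = FALSE)
      }
    } else if (id == "data") {
      pcm <- readBin(con, "integer", sz / 2, size = 2, endian = "little")
      return(tpt_audio(pcm / 32767, fs))
    } else {
      readBin(con, "raw", sz)
    }
  }
}
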