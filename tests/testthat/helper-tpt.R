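# Shared fixtures, built in code.

# Raw audio object from a sample vector (bypasses synthesis).
audio_from_samples <- function(x, fs = 44100) {
  structure(list(samples = x, sample_rate_hz = fs,
                 duration_ms = 1000 * length(x) / fs),
            class = "tpt_audio")
}

sine_audio <- function(freq, dur_s = 1, fs = 44100, amp = 1) {
  t <- seq_len(round(dur_s * fs)) / fs
  audio_from_samples(amp * sin(2 * pi * freq * t), fs)
}

# Response table with given per-item unmoved fractions, n respondents.
responses_with_unmoved <- function(session, unmoved_frac, n = 100,
                                   seed = 42) {
  set.seed(seed)
  items <- scored_items(session)
  rows <- lapply(seq_len(n), function(r) {
    moved <- vapply(items$item_id, function(id) {
      f <- unmoved_frac[[id]]
      if (is.null(f)) f <- 0
      # deterministic fraction: first round(f*n) respondents stick
      r > round(f * n)
    }, logical(1))
    data.frame(respondent_id = sprintf("R%03d", r),
               item_id = items$item_id,
               final_slider = ifelse(moved,
                                     pmin(100, pmax(0, items$target_slider +
                                                      rnorm(nrow(items), 0, 12))),
                                     50),
               moved = moved,
               n_stimulus_playbacks = 1L,
               n_reproduction_playbacks = 1L,
               stringsAsFactors = FALSE)
  })
  tpt_responses(do.call(rbind, rows))
}

# Multivariate normal with exact sample covariance (small local version
# of the empirical=TRUE construction: standardize principal components).
exact_mvn <- function(n, Sigma, seed = 1) {
  set.seed(seed)
  p <- ncol(Sigma)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- X %*% solve(chol(var(X)))
  X %*% chol(Sigma)
}
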