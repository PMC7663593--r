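# Shared fixtures and independent oracles, built in code at test time.

# A shortened protocol for fast I/O and unit tests (still has all five
# blocks and >= 60 s resting states); 100 Hz keeps the gamma band
# representable while cutting sample counts.
short_protocol <- function(rate = 100) {
  protocol_spec(durations = c(RS1 = 60, MIST_TRAIN = 20, MIST_TASK = 40,
                              RELAX = 40, RS2 = 60),
                sampling_rate = rate)
}

# Blocks long enough for the stress arc (task plateau vs relax decay) to be
# separable, but still much shorter than the standard 18-minute session.
medium_protocol <- function(rate = 250) {
  protocol_spec(durations = c(RS1 = 60, MIST_TRAIN = 30, MIST_TASK = 120,
                              RELAX = 120, RS2 = 60),
                sampling_rate = rate)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

test_subject <- function(id = "S01", group = "control", polarity = "direct",
                         seed = 101L, ...) {
  subject_spec(id, group, polarity, seed = seed, ...)
}

# Full single-subject chain on a session, message-free.
run_chain <- function(session, cfg = validate_config()) {
  quiet(process_session(session, cfg))
}

# Independent oracle: brute-force exact two-sided signed-rank p-value by
# enumerating all 2^n sign assignments over the midranked |differences|.
enum_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Independent band-variance oracle: the signal's variance restricted to
# [low, high), read directly off the full-length periodogram (both spectral
# halves), with no filtering involved.
band_variance_oracle <- function(x, low, high, rate) {
  n <- length(x)
  P <- Mod(stats::fft(x - mean(x)))^2 / n^2
  f <- (seq_len(n) - 1) * rate / n
  sel <- (f >= low & f < high) | (f > rate - high & f <= rate - low)
  sum(P[sel])
}
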