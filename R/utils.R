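# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive k reproducible sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rg <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Single-pass ARMA (IIR) filter y = filter(b, a, x), direct form II
# transposed (compiled); used for both noise synthesis and the zero-phase
# preprocessing filters.
arma_filter <- function(b, a, x) {
  if (a[1] != 1) {
    b <- b / a[1]
    a <- a / a[1]
  }
  arma_filter_cpp(as.numeric(b), as.numeric(a), as.numeric(x))
}

# Zero-phase (forward-backward) filtering with odd-symmetric edge padding of
# three times the filter order, so transients decay outside the signal.
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  p <- min(3L * (max(length(a), length(b)) - 1L), n - 1L)
  if (p > 0L) {
    head_ext <- 2 * x[1] - x[(p + 1L):2L]
    tail_ext <- 2 * x[n] - x[(n - 1L):(n - p)]
    ext <- c(head_ext, x, tail_ext)
  } else {
    ext <- x
  }
  y <- arma_filter(b, a, ext)
  y <- rev(arma_filter(b, a, rev(y)))
  y[(p + 1L):(p + n)]
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

# Variance gain of a digital filter for unit white-noise input: mean of
# |H(e^iw)|^2 over the frequency circle (dense grid). With `low`/`high`/`fs`
# given, only the contribution inside [low, high) Hz (both spectral halves)
# is counted, i.e. the in-band output variance per unit input variance.
filter_variance_gain <- function(b, a, n_grid = 4096L,
                                 low = NULL, high = NULL, fs = NULL,
                                 power = 2) {
  w <- 2 * pi * (seq_len(n_grid) - 1L) / n_grid
  z <- exp(-1i * w)
  H <- outer(z, seq_along(b) - 1L, `^`) %*% b /
    (outer(z, seq_along(a) - 1L, `^`) %*% a)
  h2 <- Mod(H)^power
  if (!is.null(low)) {
    f <- w / (2 * pi) * fs
    sel <- (f >= low & f < high) | (f > fs - high & f <= fs - low)
    h2 <- h2 * sel
  }
  mean(h2)
}
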