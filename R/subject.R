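#' Synthetic subject specification
#'
#' Ground-truth parameters for one simulated participant: group assignment,
#' responder polarity (whether relative gamma rises or falls with stress),
#' per-band amplitude baselines, the depth of the stress modulation, and
#' nuisance levels (amplitude artifacts, 50 Hz line coupling).
#'
#' @param subject_id Subject identifier (e.g. "S01").
#' @param group `"control"` or `"test"`.
#' @param responder_polarity `"direct"` (relative gamma rises with stress)
#'   or `"inverse"`.
#' @param band_amplitudes Named amplitude spectral densities in uV/sqrt(Hz)
#'   for the five classical bands; a band's baseline variance is
#'   amplitude^2 times its width in Hz.
#' @param modulation_depth Fractional amplitude change at full stress:
#'   gamma is scaled by `(1 + depth * s(t))` and alpha/theta by
#'   `(1 - depth * s(t))` for direct responders (signs swapped for inverse
#'   responders). Must lie in `[0, 1)`.
#' @param artifact_rate Expected number of high-amplitude transient
#'   artifacts per minute (Poisson).
#' @param line_noise_uv Amplitude of the 50 Hz line-coupling sinusoid (uV).
#' @param seed Integer seed making this subject's recording reproducible.
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id,
                         group = c("control", "test"),
                         responder_polarity = c("direct", "inverse"),
                         band_amplitudes = c(delta = 2.0, theta = 1.5,
                                             alpha = 2.0, beta = 0.8,
                                             gamma = 0.3),
                         modulation_depth = 0.5,
                         artifact_rate = 2,
                         line_noise_uv = 2,
                         seed = 1L) {
  group <- match.arg(group)
  responder_polarity <- match.arg(responder_polarity)
  if (any(band_amplitudes < 0)) stop_rg("band amplitudes must be >= 0")
  if (modulation_depth < 0 || modulation_depth >= 1)
    stop_rg("modulation_depth must lie in [0, 1)")
  if (artifact_rate < 0) stop_rg("artifact_rate must be >= 0")
  if (line_noise_uv < 0) stop_rg("line_noise_uv must be >= 0")
  structure(list(subject_id = subject_id, group = group,
                 responder_polarity = responder_polarity,
                 band_amplitudes = band_amplitudes,
                 modulation_depth = modulation_depth,
                 artifact_rate = artifact_rate,
                 line_noise_uv = line_noise_uv,
                 seed = as.integer(seed)),
            class = "subject_spec")
}

#' Build a synthetic cohort
#'
#' Creates `n` subjects split evenly into control and test groups
#' (alternating assignment, mirroring a pseudo-random allocation), with
#' responder polarity drawn as direct with probability `p_direct`
#' (default 7/17, echoing the observed split of direct vs inverse
#' responders) and per-subject seeds derived from `seed`.
#'
#' @param n Number of subjects (even; default 20).
#' @param seed Master seed for polarity draws and per-subject seeds.
#' @param p_direct Probability that a subject is a direct responder.
#' @param ... Further arguments passed to [subject_spec()] (e.g.
#'   `modulation_depth`, `artifact_rate`).
#' @return A list of `subject_spec` objects.
#' @export
make_cohort <- function(n = 20, seed = 1L, p_direct = 7 / 17, ...) {
  if (!is_count(n) || n < 2 || n %% 2 != 0)
    stop_rg("n must be an even integer >= 2 (equal-sized groups)")
  seeds <- derive_seeds(seed, n)
  polarity <- with_seed(seed + 1L, ifelse(stats::runif(n) < p_direct,
                                          "direct", "inverse"))
  lapply(seq_len(n), function(i) {
    subject_spec(subject_id = sprintf("S%02d", i),
                 group = if (i %% 2 == 1) "control" else "test",
                 responder_polarity = polarity[i],
                 seed = seeds[i], ...)
  })
}
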