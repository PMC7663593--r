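test_that("stress trajectory follows the protocol arc", {
  pr <- protocol_spec()
  prof <- stress_profile(pr)
  on <- cumsum(c(0, pr$durations))

  expect_identical(stress_profile_eval(prof, 60), 0)     # mid-RS1: rest is zero
  expect_equal(stress_profile_eval(prof, on[4]), 1)      # end of MIST task

  # closed-form relax ramp: (1+q) exp(-dt/tau) - q, clipped at zero
  q <- prof$relax_undershoot
  expected_2min <- (1 + q) * exp(-120 / prof$tau_relax) - q
  got <- stress_profile_eval(prof, on[4] + 120)
  expect_equal(got, expected_2min, tolerance = 1e-12)
  expect_lt(got, 0.1)

  tt <- seq(0, sum(pr$durations), by = 0.5)
  s <- stress_profile_eval(prof, tt)
  expect_true(all(s >= 0 & s <= 1))
  task <- tt >= on[3] & tt <= on[4]
  expect_true(all(diff(s[task]) >= -1e-12))              # non-decreasing in task
  relax2 <- tt >= on[4] & tt <= on[4] + 120
  expect_true(all(diff(s[relax2]) <= 1e-12))             # non-increasing, first 2 min

  expect_error(stress_profile_eval(prof, -1), "outside")
  expect_error(stress_profile_eval(prof, sum(pr$durations) + 1), "outside")
})

test_that("session generation is deterministic and respects the seed", {
  pr <- short_protocol()
  subj <- test_subject(seed = 7L)
  s1 <- generate_session(pr, subj)
  s2 <- generate_session(pr, subj)
  expect_identical(s1, s2)
  s3 <- generate_session(pr, test_subject(seed = 8L))
  expect_false(identical(s1$blocks$RS1, s3$blocks$RS1))
})

test_that("clean generation stays under the artifact threshold", {
  pr <- short_protocol()
  subj <- test_subject(seed = 11L, modulation_depth = 0,
                       artifact_rate = 0, line_noise_uv = 0)
  sess <- generate_session(pr, subj)
  peak <- max(vapply(sess$blocks, function(b) max(abs(b)), numeric(1)))
  expect_lt(peak, 100)
})

test_that("gamma unrepresentable at low sampling rates", {
  pr <- protocol_spec(sampling_rate = 80)
  expect_error(generate_session(pr, test_subject()), "gamma")
})

test_that("stress modulation raises gamma variance during the task (direct responder)", {
  pr <- short_protocol(rate = 250)
  subj <- test_subject(seed = 21L, modulation_depth = 0.5,
                       artifact_rate = 0, line_noise_uv = 0)
  sess <- generate_session(pr, subj)
  v_task <- band_variance_oracle(sess$blocks$MIST_TASK[1, ], 25, 45, 250)
  v_rs1 <- band_variance_oracle(sess$blocks$RS1[1, ], 25, 45, 250)
  expect_gt(v_task, v_rs1)
})

test_that("per-band variance matches the configured amplitudes within 10%", {
  # 240 s of rest, averaged over the 8 independent channels, keeps the
  # band-variance estimator's own noise well below the 10% tolerance
  pr <- protocol_spec(durations = c(RS1 = 240, MIST_TRAIN = 20, MIST_TASK = 40,
                                    RELAX = 40, RS2 = 60),
                      sampling_rate = 250)
  subj <- test_subject(seed = 31L, modulation_depth = 0,
                       artifact_rate = 0, line_noise_uv = 0)
  sess <- generate_session(pr, subj)
  rest <- sess$blocks$RS1
  bands <- default_bands()
  for (i in seq_len(nrow(bands))) {
    target <- subj$band_amplitudes[[bands$name[i]]]^2 * (bands$high[i] - bands$low[i])
    got <- mean(apply(rest, 1, band_variance_oracle,
                      bands$low[i], bands$high[i], 250))
    expect_lt(abs(got - target) / target, 0.10,
              label = sprintf("band %s relative error", bands$name[i]))
  }
})

test_that("responder polarity is encoded in the raw variance ratio", {
  pr <- medium_protocol()
  ratio_contrast <- function(polarity, seed) {
    subj <- test_subject(polarity = polarity, seed = seed,
                         artifact_rate = 0, line_noise_uv = 0)
    sess <- generate_session(pr, subj)
    rat <- function(block) {
      g <- mean(apply(block, 1, band_variance_oracle, 25, 45, 250))
      at <- mean(apply(block, 1, band_variance_oracle, 8, 13, 250)) +
        mean(apply(block, 1, band_variance_oracle, 4, 8, 250))
      g / at
    }
    rat(sess$blocks$MIST_TASK) - rat(sess$blocks$RELAX)
  }
  expect_gt(ratio_contrast("direct", 41L), 0)
  expect_lt(ratio_contrast("inverse", 42L), 0)
})

test_that("survey generation respects means, clipping and determinism", {
  cohort <- make_cohort(n = 10, seed = 5L)
  exact <- generate_spsl(cohort, means = c(2, 4, 2, 2), sd = 0, seed = 1L)
  expect_true(all(exact$T1 == 2 & exact$T2 == 4 & exact$T3 == 2 & exact$T4 == 2))

  clipped <- generate_spsl(cohort, means = c(1, 5, 1.5, 1), sd = 2, seed = 2L)
  vals <- as.matrix(clipped[, c("T1", "T2", "T3", "T4")])
  expect_true(all(vals >= 1 & vals <= 5))

  expect_identical(generate_spsl(cohort, seed = 3L), generate_spsl(cohort, seed = 3L))
  expect_error(generate_spsl(cohort, sd = -1), "sd")
  expect_error(generate_spsl(cohort, means = c(4, 2, 2, 2)), "T2 > T1")
})

test_that("simulated stress arc is detectable in nearly every survey draw", {
  cohort <- make_cohort(n = 10, seed = 6L)
  hits <- vapply(seq_len(200), function(s) {
    sv <- generate_spsl(cohort, means = c(2, 4, 2, 2), sd = 0.5, seed = s)
    wilcoxon_signed_rank(sv$T1, sv$T2)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fixture sets round-trip through EDF within 16-bit quantization", {
  pr <- short_protocol()
  cohort <- list(test_subject("S01", seed = 51L), test_subject("S02", "test", seed = 52L))
  dir <- withr::local_tempdir()
  manifest <- write_fixture_set(cohort, dir, protocol = pr)
  expect_length(manifest, 4)  # 2 signal files + surveys.csv + truth.json
  expect_setequal(basename(manifest), c("S01.edf", "S02.edf", "surveys.csv", "truth.json"))

  sess <- generate_session(pr, cohort[[1]])
  back <- load_session(manifest[1])
  expect_identical(names(back$blocks), names(sess$blocks))
  qstep <- 800 / 65535
  expect_lt(max(abs(back$blocks$RS1 - sess$blocks$RS1)), qstep)
  expect_identical(back$subject_id, "S01")
  expect_identical(back$group, "control")

  truth <- jsonlite::read_json(manifest[4])
  expect_identical(truth$S02$responder_polarity, cohort[[2]]$responder_polarity)

  expect_identical(write_fixture_set(list(), dir), character(0))
})
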