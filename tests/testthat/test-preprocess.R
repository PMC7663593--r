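test_that("EDF sessions load with all blocks, channels and metadata", {
  pr <- short_protocol()
  subj <- test_subject(seed = 61L)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "S01.edf")
  write_session_edf(generate_session(pr, subj), p)
  sess <- load_session(p)
  expect_identical(names(sess$blocks), c("RS1", "MIST_TRAIN", "MIST_TASK",
                                         "RELAX", "RS2"))
  expect_identical(nrow(sess$blocks$RS1), 8L)
  expect_identical(sess$sampling_rate, 100)
})

test_that("CSV and EDF renderings of a session agree downstream", {
  pr <- short_protocol()
  subj <- test_subject(seed = 62L, artifact_rate = 0)
  sess <- generate_session(pr, subj)
  dir <- withr::local_tempdir()
  pe <- file.path(dir, "s.edf"); pc <- file.path(dir, "s.csv")
  write_session_edf(sess, pe)
  write_session_csv(sess, pc)
  sig_e <- concatenate_blocks(load_session(pe))
  sig_c <- concatenate_blocks(load_session(pc))
  expect_identical(dim(sig_e$data), dim(sig_c$data))
  qstep <- 800 / 65535
  expect_lt(max(abs(sig_e$data - sig_c$data)), qstep)
  expect_identical(sig_e$boundaries, sig_c$boundaries)
})

test_that("a session missing a block is a format error naming it", {
  pr <- short_protocol()
  sess <- generate_session(pr, test_subject(seed = 63L))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "s.csv")
  write_session_csv(sess, p)
  dt <- data.table::fread(p)
  data.table::fwrite(dt[dt$block != "RELAX", ], p)
  expect_error(load_session(p), "RELAX")
  sess$blocks$MIST_TASK <- NULL
  expect_error(concatenate_blocks(sess), "MIST_TASK")
})

test_that("central minute selection follows midpoint arithmetic", {
  rate <- 250
  m <- matrix(seq_len(120 * rate), nrow = 1)      # values = 1-based sample index
  cut <- select_central_minute(m, rate)
  expect_identical(ncol(cut), 15000L)
  expect_identical(cut[1, 1], 7501L)               # 0-based sample 7500
  expect_identical(cut[1, 15000], 22500L)          # half-open end at 22500

  m60 <- matrix(rnorm(60 * rate), nrow = 1)
  expect_identical(select_central_minute(m60, rate), m60)

  m61 <- matrix(seq_len(61 * rate), nrow = 1)
  cut61 <- select_central_minute(m61, rate)
  expect_identical(ncol(cut61), 15000L)
  expect_identical(cut61[1, 1], 126L)              # starts at 0-based sample 125

  expect_error(select_central_minute(matrix(0, 1, 59 * rate), rate), "60 s")
})

test_that("concatenation yields the 16-minute analysis window with exact boundaries", {
  pr <- protocol_spec()
  subj <- test_subject(seed = 64L, artifact_rate = 0, line_noise_uv = 0)
  sess <- generate_session(pr, subj)
  sig <- concatenate_blocks(sess)
  expect_identical(ncol(sig$data), 240000L)       # 16 min at 250 Hz
  expect_identical(sig$boundaries$RELAX[1], (1L + 9L) * 60L * 250L)
  expect_identical(sig$boundaries$RS2, c(15L * 60L * 250L, 16L * 60L * 250L))

  # energy preservation: concatenation only selects samples
  included <- cbind(select_central_minute(sess$blocks$RS1, 250),
                    sess$blocks$MIST_TRAIN, sess$blocks$MIST_TASK,
                    sess$blocks$RELAX,
                    select_central_minute(sess$blocks$RS2, 250))
  expect_identical(sum(sig$data^2), sum(included^2))
})

test_that("band-pass filtering is zero-phase and length-preserving", {
  rate <- 250
  t <- seq(0, 12, by = 1 / rate)
  x <- sin(2 * pi * 10 * t)
  y <- bandpass_filter(x, rate = rate)
  expect_length(y, length(x))
  # peak cross-correlation at zero lag
  lags <- -20:20
  cc <- vapply(lags, function(l) {
    i <- seq(500, length(x) - 500)
    stats::cor(x[i], y[i + l])
  }, numeric(1))
  expect_identical(lags[which.max(cc)], 0L)
  # passband amplitude essentially preserved
  mid <- seq(500, length(x) - 500)
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.02)
})

test_that("slow drift is strongly attenuated by the 1-50 Hz band-pass", {
  rate <- 250
  t <- seq(0, 40, by = 1 / rate)
  drift <- sin(2 * pi * 0.2 * t)
  y <- bandpass_filter(drift, rate = rate)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  atten_db <- 20 * log10(max(abs(y[mid])))
  expect_lt(atten_db, -20)
  expect_identical(bandpass_filter(numeric(1000), rate = rate), numeric(1000))
  expect_error(bandpass_filter(drift, high = 130, rate = rate), "Nyquist")
})

test_that("notch removes 50 Hz but leaves 10 Hz intact", {
  rate <- 250
  t <- seq(0, 20, by = 1 / rate)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  rms <- function(v) sqrt(mean(v^2))
  line <- sin(2 * pi * 50 * t)
  y50 <- notch_filter(line, rate = rate)
  expect_lt(rms(y50[mid]) / rms(line[mid]), 0.10)  # >= 20 dB attenuation
  alphaw <- sin(2 * pi * 10 * t)
  y10 <- notch_filter(alphaw, rate = rate)
  expect_lt(abs(rms(y10[mid]) / rms(alphaw[mid]) - 1), 0.05)
  atten_10_db <- -20 * log10(rms(y10[mid]) / rms(alphaw[mid]))
  expect_lt(abs(atten_10_db), 1)
  expect_identical(notch_filter(numeric(500), rate = rate), numeric(500))
  expect_error(notch_filter(line, freq = 125, rate = rate), "Nyquist")
})

test_that("filtering is channel-independent", {
  rate <- 250
  set.seed(71)
  m <- matrix(rnorm(3 * 5000), nrow = 3)
  joint <- notch_filter(bandpass_filter(m, rate = rate), rate = rate)
  for (i in 1:3) {
    single <- notch_filter(bandpass_filter(m[i, ], rate = rate), rate = rate)
    expect_equal(joint[i, ], single, tolerance = 1e-12)
  }
})
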