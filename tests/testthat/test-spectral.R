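make_epochs <- function(m, rate) quiet(epoch_signal(m, rate = rate))

test_that("epoching follows the two-second non-overlap rule", {
  pr <- protocol_spec()
  sess <- generate_session(pr, test_subject(seed = 81L, artifact_rate = 0))
  ep <- epoch_signal(concatenate_blocks(sess))
  expect_identical(dim(ep$data), c(480L, 8L, 500L))

  m <- matrix(rnorm(5 * 250), nrow = 1)            # 5 s at 250 Hz
  expect_warning(ep2 <- epoch_signal(m, rate = 250), "1 s")
  expect_identical(dim(ep2$data)[1], 2L)

  m2 <- matrix(rnorm(500), nrow = 1)               # exactly one epoch
  ep1 <- epoch_signal(m2, rate = 250)
  expect_identical(as.vector(ep1$data[1, 1, ]), m2[1, ])

  expect_error(epoch_signal(matrix(0, 1, 300), rate = 250), "shorter")
})

test_that("epoch boundaries and block map are consistent (Eq.-style accounting)", {
  pr <- protocol_spec()
  sess <- generate_session(pr, test_subject(seed = 82L, artifact_rate = 0))
  ep <- epoch_signal(concatenate_blocks(sess))
  b <- ep$boundaries_epochs
  expect_identical(b$RS1, c(0L, 30L))
  expect_identical(b$MIST_TASK, c(120L, 300L))
  expect_identical(b$RELAX, c(300L, 450L))
  expect_identical(b$RS2, c(450L, 480L))
  # epoch count x epoch length = analysis window duration exactly
  expect_identical(dim(ep$data)[1] * 2L, 960L)
})

test_that("amplitude-based rejection masks exactly the offending epoch-channels", {
  set.seed(83)
  m <- matrix(rnorm(8 * 20 * 500, sd = 5), nrow = 8)   # 20 epochs at 250 Hz
  # inject a 150 uV transient on channel 3, epoch 7 (0-based: epoch index 8)
  m[3, 7 * 500 + 250] <- 150
  ep <- reject_artifacts(make_epochs(m, 250))
  expect_true(ep$mask[8, 3])
  expect_identical(sum(ep$mask), 1L)
  expect_true(all(ep$data[8, 3, ] == 0))
  expect_identical(ep$rejected_fraction, 0)

  clean <- reject_artifacts(make_epochs(matrix(rnorm(4 * 2000, sd = 5), 4), 250))
  expect_false(any(clean$mask))
  expect_identical(clean$rejected_fraction, 0)

  allbad <- matrix(rnorm(2 * 1000, sd = 5), nrow = 2)
  allbad[, 501:1000] <- 200
  ep2 <- reject_artifacts(make_epochs(allbad, 250))
  expect_identical(ep2$rejected, c(FALSE, TRUE))
})

test_that("detrend + z-score removes trend and fixes scale", {
  rate <- 250
  set.seed(85)
  ramp <- matrix(5 * seq(0, 1, length.out = 500) + rnorm(500), nrow = 1)
  ep <- detrend_zscore(make_epochs(ramp, rate))
  x <- as.vector(ep$data[1, 1, ])
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(stats::var(x), 1, tolerance = 1e-9)
  expect_lt(abs(stats::cor(x, seq_len(500))), 1e-6)

  # an exact ramp has zero residual variance: degenerate, left at zeros
  pure <- matrix(seq(0, 1, length.out = 500), nrow = 1)
  expect_message(epp <- detrend_zscore(make_epochs(pure, rate)), "zero-variance")
  expect_true(all(epp$data == 0))

  set.seed(84)
  wn <- matrix(rnorm(500), nrow = 1)
  epw <- detrend_zscore(make_epochs(wn, rate))
  xw <- as.vector(epw$data[1, 1, ])
  expect_equal(mean(xw), 0, tolerance = 1e-12)
  expect_equal(stats::var(xw), 1, tolerance = 1e-9)

  # masked channel stays exactly zero
  m <- matrix(rnorm(2 * 500, sd = 5), nrow = 2)
  m[2, 100] <- 500
  epm <- detrend_zscore(reject_artifacts(make_epochs(m, rate)))
  expect_true(all(epm$data[1, 2, ] == 0))
})

test_that("band power localizes a pure alpha tone and respects identities", {
  rate <- 250
  t <- seq_len(500) / rate
  tone <- matrix(sin(2 * pi * 10 * t), nrow = 1)
  bp <- band_power(make_epochs(tone, rate))
  total_1_45 <- sum(bp$power[1, ])
  expect_gte(bp$power[1, "alpha"] / total_1_45, 0.95)

  zero <- band_power(make_epochs(matrix(0, 1, 500), rate))
  expect_true(all(zero$power[1, ] == 0))

  two <- matrix(rep(sin(2 * pi * 7 * t), 2), nrow = 2, byrow = TRUE)
  bp2 <- band_power(make_epochs(two, rate))
  bp1 <- band_power(make_epochs(two[1, , drop = FALSE], rate))
  expect_equal(bp2$power, bp1$power, tolerance = 1e-12)

  expect_error(band_power(make_epochs(tone, rate),
                          data.frame(name = "x", low = 10, high = 130)),
               "50")
})

test_that("periodogram band powers are Parseval-consistent", {
  rate <- 250
  t <- seq_len(500) / rate
  # band-limited content on exact bins: 5.5, 17 and 33 Hz
  x <- matrix(0.8 * sin(2 * pi * 5.5 * t) + 0.5 * sin(2 * pi * 17 * t) +
                0.3 * cos(2 * pi * 33 * t), nrow = 1)
  ep <- detrend_zscore(make_epochs(x, rate))
  bp <- band_power(ep)
  xd <- as.vector(ep$data[1, 1, ])
  expect_lt(abs(sum(bp$power[1, ]) - stats::var(xd)) / stats::var(xd), 0.01)
})

test_that("relative gamma is the gamma over alpha-plus-theta power ratio", {
  fake_bp <- structure(list(
    power = cbind(delta = c(1, 1), theta = c(0.5, 0.6), alpha = c(0.5, 0.4),
                  beta = c(1, 1), gamma = c(2, 1)),
    rejected = c(FALSE, FALSE), boundaries_epochs = NULL,
    subject_id = NULL, group = NULL), class = "band_power_series")
  rg <- relative_gamma(fake_bp)
  expect_equal(rg$values, c(2, 1))
})

test_that("relative gamma is invariant to common channel rescaling", {
  rate <- 250
  set.seed(86)
  m <- matrix(rnorm(4 * 10 * 500), nrow = 4)
  rg1 <- relative_gamma(band_power(make_epochs(m, rate)))
  rg2 <- relative_gamma(band_power(make_epochs(m * 7.3, rate)))
  expect_equal(rg1$values, rg2$values, tolerance = 1e-12)
})

test_that("direct responders show higher relative gamma in the task than in relax", {
  pr <- medium_protocol()
  sess <- generate_session(pr, test_subject(seed = 87L, modulation_depth = 0.5))
  res <- run_chain(sess)
  b <- res$rg$boundaries_epochs
  task_mean <- mean(res$rg$values[(b$MIST_TASK[1] + 1):b$MIST_TASK[2]])
  relax_mean <- mean(res$rg$values[(b$RELAX[1] + 1):b$RELAX[2]])
  expect_gt(task_mean, relax_mean)
})

test_that("rejected-epoch bookkeeping stays below the expected ceiling", {
  pr <- medium_protocol()
  fractions <- vapply(1:4, function(i) {
    sess <- generate_session(pr, test_subject(seed = 90L + i))
    ep <- reject_artifacts(quiet(epoch_signal(notch_filter(bandpass_filter(
      concatenate_blocks(sess))))))
    ep$masked_fraction
  }, numeric(1))
  expect_true(all(fractions < 0.09))
})
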