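test_that("heart rate is recovered from an exactly periodic envelope", {
  # impulse train with 800 ms period at the 50 Hz envelope rate
  env <- rep(0, 500)
  env[seq(1, 500, by = 40)] <- 1
  est <- estimate_heart_rate(env)
  expect_lt(abs(est$heart_rate_bpm - 75), 1)
  expect_false(est$low_confidence)
})

test_that("heart-rate estimates always land in the 30-120 bpm search band", {
  for (seed in 1:5) {
    set.seed(seed)
    est <- estimate_heart_rate(rnorm(400))
    expect_gte(est$heart_rate_bpm, 30)
    expect_lte(est$heart_rate_bpm, 120)
    expect_true(est$low_confidence)
  }
  expect_error(estimate_heart_rate(rnorm(100)), "too short")
})

test_that("fusion reduces to the single-recording estimate with one usable input", {
  r <- synthesize_pcg(72, 1, 0, 2205, 10, seed = 5)
  env <- pcg_envelopes(r$waveform, 2205)
  single <- estimate_heart_rate(env[, 1])
  fused <- fuse_heart_rate(list(single$autocorrelation), FALSE)
  expect_identical(fused$heart_rate_bpm, single$heart_rate_bpm)
  expect_identical(fused$systolic_interval_ms, single$systolic_interval_ms)
})

test_that("fusing three clean positions with one noisy one stays near truth", {
  acs <- lapply(1:3, function(i) {
    r <- synthesize_pcg(75, i - 1, 0, 2205, 10, seed = 30 + i)
    estimate_heart_rate(pcg_envelopes(r$waveform, 2205)[, 1])$autocorrelation
  })
  set.seed(99)
  noise_ac <- estimate_heart_rate(rnorm(500))$autocorrelation
  fused <- fuse_heart_rate(c(acs, list(noise_ac)),
                           c(FALSE, FALSE, FALSE, TRUE))
  expect_lt(abs(fused$heart_rate_bpm - 75), 2)
  expect_error(fuse_heart_rate(list(noise_ac), TRUE), "noisy")
})

test_that("fused estimate stays inside the hull of clean per-recording rates", {
  hrs <- c(74, 75, 75, 76)
  acs <- lapply(seq_along(hrs), function(i) {
    r <- synthesize_pcg(hrs[i], 1, 0, 2205, 10, seed = 40 + i)
    estimate_heart_rate(pcg_envelopes(r$waveform, 2205)[, 1])$autocorrelation
  })
  fused <- fuse_heart_rate(acs, rep(FALSE, 4))
  expect_gte(fused$heart_rate_bpm, 74 - 1e-9)
  expect_lte(fused$heart_rate_bpm, 76 + 1e-9)
})

test_that("fusion is no worse than the corrupted single recording", {
  set.seed(61)
  errs <- replicate(30, {
    hr <- runif(1, 55, 90)
    acs <- lapply(1:3, function(i) {
      r <- synthesize_pcg(hr, sample(0:2, 1), 0, 2205, 10,
                          seed = sample.int(1e6, 1))
      estimate_heart_rate(pcg_envelopes(r$waveform, 2205)[, 1])$autocorrelation
    })
    bad <- estimate_heart_rate(rnorm(500))
    fused_naive <- fuse_heart_rate(c(acs, list(bad$autocorrelation)),
                                   rep(FALSE, 4))
    c(fused = abs(fused_naive$heart_rate_bpm - hr),
      single = abs(bad$heart_rate_bpm - hr))
  })
  expect_lte(median(errs["fused", ]), median(errs["single", ]))
})

test_that("the decoder agrees with an exhaustive dynamic-programming reference", {
  set.seed(17)
  for (rep in 1:6) {
    T_ <- sample(c(30, 60, 120, 200), 1)
    L <- matrix(rnorm(T_ * 4), T_, 4)
    dur <- lapply(1:4, function(s) {
      dmax <- sample(3:10, 1)
      lp <- log(runif(dmax) + 0.05)
      lp - max(lp)
    })
    got <- pcgscreen:::hsmm_viterbi_cpp(L, dur)
    ref <- viterbi_reference(L, dur)
    expect_equal(got$log_prob, ref, tolerance = 1e-9)
  }
})

test_that("decoded paths only move through the cyclic state order", {
  em <- shared_emissions()
  r <- synthesize_pcg(65, 2, 0, 2205, 10, seed = 13)
  seg <- segment_hsmm(r$waveform, 2205, 65, 0.15 * 1000 + 0.2 * 60000 / 65,
                      em)
  s <- seg$frame_states
  steps <- cbind(s[-length(s)], s[-1])
  ok <- steps[, 1] == steps[, 2] | (steps[, 1] %% 4) + 1 == steps[, 2]
  expect_true(all(ok))
  # S1 duration plausible on a clean decode
  runs <- rle(s)
  s1_ms <- runs$lengths[runs$values == 1] / 50 * 1000
  expect_gte(mean(s1_ms), 60)
  expect_lte(mean(s1_ms), 200)
})

test_that("block extraction follows the four-cycle, 50%-overlap, six-block rule", {
  onsets <- function(C) as.integer(seq(1, by = 1000, length.out = C + 1))
  b14 <- extract_blocks(onsets(14))
  expect_equal(nrow(b14), 6)
  expect_equal(b14$start_cycle, c(0, 2, 4, 6, 8, 10))
  expect_equal(nrow(extract_blocks(onsets(10))), 4)
  b4 <- extract_blocks(onsets(4))
  expect_equal(nrow(b4), 1)
  expect_equal(b4$n_cycles, 4)
  b2 <- extract_blocks(onsets(2))
  expect_equal(b2$n_cycles, 2)
  expect_equal(nrow(extract_blocks(1L)), 0)
  # spans never exceed the recording and consecutive blocks share two cycles
  expect_true(all(b14$end_sample <= max(onsets(14))))
  expect_true(all(diff(b14$start_cycle) == 2))
})
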