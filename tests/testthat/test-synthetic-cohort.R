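test_that("stenosis grade follows the 15/20/40 mm Hg gradient cutoffs", {
  expect_equal(as_grade_from_avpg(c(5, 14.9, 15, 19.9, 20, 22, 39.9, 40, 80)),
               c(0, 0, 1, 1, 2, 2, 2, 3, 3))
})

test_that("identical configuration and seed give bit-identical cohorts", {
  cfg <- cohort_config(n_participants = 6, seed = 31)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$recordings, b$recordings)
  expect_identical(a$audio[[1]]$waveform, b$audio[[1]]$waveform)
  expect_identical(a$audio[[20]]$frame_states, b$audio[[20]]$frame_states)
})

test_that("noise-flag prevalence matches the configured position rates", {
  coh <- generate_cohort(cohort_config(n_participants = 2000, seed = 5,
                                       render_audio = FALSE))
  p1 <- mean(coh$recordings$annotator1_noise[coh$recordings$position == 1])
  expect_lt(abs(p1 - 0.061), 0.015)
})

test_that("stored stenosis grades are consistent with the emitted gradients", {
  coh <- generate_cohort(cohort_config(n_participants = 800, seed = 9,
                                       render_audio = FALSE))
  expect_identical(as_grade_from_avpg(coh$participants$avpg_mean),
                   coh$participants$as_grade)
})

test_that("annotator disagreement grows with the annotation noise level", {
  mad_at <- function(sd) {
    coh <- generate_cohort(cohort_config(n_participants = 400, seed = 12,
                                         annotator_noise_sd = sd,
                                         render_audio = FALSE))
    ok <- !(coh$recordings$annotator1_noise | coh$recordings$annotator2_noise)
    mean(abs(coh$recordings$annotator1_grade[ok] -
               coh$recordings$annotator2_grade[ok]))
  }
  m <- c(mad_at(0.2), mad_at(0.6), mad_at(1.2))
  expect_true(all(diff(m) > 0))
})

test_that("gradient and aortic murmur grade are positively linked in stenosis", {
  coh <- generate_cohort(cohort_config(n_participants = 400, seed = 4,
                                       prevalence = list(as = 0.4),
                                       render_audio = FALSE))
  part <- coh$participants
  aortic <- coh$recordings[coh$recordings$position == 1, ]
  sel <- part$as_grade >= 1
  expect_gt(sum(sel), 50)
  rho <- cor(part$avpg_mean[sel], aortic$true_grade[sel], method = "spearman")
  expect_gt(rho, 0.5)
  # the stenosis loudness component itself is non-decreasing in the gradient
  ord <- order(part$avpg_mean[sel])
  comp <- coh$truth$as_component_aortic[sel][ord]
  expect_true(all(diff(comp) >= 0))
})

test_that("synthesized recordings respect amplitude, cycle and loudness contracts", {
  r <- synthesize_pcg(75, 0, 0, 2205, 10, seed = 2)
  expect_true(all(r$waveform >= -1 & r$waveform <= 1))
  expect_true(length(r$s1_onsets) >= 11 && length(r$s1_onsets) <= 13)

  band_energy <- function(wave) {
    bf <- signal::butter(3, c(100, 440) / (2205 / 2), type = "pass")
    sum(as.numeric(signal::filter(bf, wave))^2)
  }
  r1 <- synthesize_pcg(75, 1, 0, 2205, 10, seed = 2)
  r4 <- synthesize_pcg(75, 4, 0, 2205, 10, seed = 2)
  expect_gt(band_energy(r4$waveform), band_energy(r1$waveform))

  # no-murmur recording: systolic-window RMS stays below the grade-1 ratio
  si <- r$systolic_interval_ms / 1000
  s1_len <- round(0.122 * 2205)
  sys_idx <- unlist(lapply(r$s1_onsets, function(o)
    (o + s1_len):(o + round(si * 2205) - 1)))
  s1_idx <- unlist(lapply(r$s1_onsets, function(o) o:(o + s1_len - 1)))
  ratio <- sqrt(mean(r$waveform[sys_idx]^2)) / sqrt(mean(r$waveform[s1_idx]^2))
  expect_lt(ratio, 0.12)

  expect_identical(synthesize_pcg(60, 2, 1, 2205, 10, seed = 9)$waveform,
                   synthesize_pcg(60, 2, 1, 2205, 10, seed = 9)$waveform)

  short <- synthesize_pcg(40, 0, 0, 2205, 0.8, seed = 1)
  expect_length(short$s1_onsets, 0)
})

test_that("degenerate cohort configurations behave as specified", {
  empty <- generate_cohort(cohort_config(n_participants = 0, seed = 1,
                                         render_audio = FALSE))
  expect_equal(nrow(empty$participants), 0)
  expect_error(cohort_config(n_participants = 10,
                             noise_flag_probs = c(-0.1, 0, 0, 0)))
  expect_error(cohort_config(n_participants = 10,
                             prevalence = list(as = 1.4)),
               "probabilities")
})

test_that("written cohorts round-trip through the CSV/WAV loader", {
  coh <- generate_cohort(cohort_config(n_participants = 4, seed = 77))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- load_cohort(dir)
  expect_setequal(back$participants$participant_id,
                  coh$participants$participant_id)
  expect_equal(nrow(back$recordings), 16)
  expect_equal(back$recordings$murmur_grade,
               coh$recordings$murmur_grade)
  w0 <- coh$audio[[1]]$waveform
  w1 <- back$audio[[paste0(coh$recordings$participant_id[1], "_1")]]$waveform
  expect_lt(max(abs(w0 - w1)), 1 / 32768 + 1e-12)
})
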