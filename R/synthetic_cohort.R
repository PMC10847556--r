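#' Configuration for the synthetic auscultation cohort
#'
#' Defaults emulate the statistical structure the screening analysis assumes:
#' four-position phonocardiograms with S1/S2/murmur structure, murmur loudness
#' tied to valve-disease severity, aortic-stenosis grading by mean pressure
#' gradient cutoffs (15/20/40 mm Hg), position-specific noise-flag prevalences
#' (6.1, 5.3, 2.8, 7.1 percent), two noisy annotators, and clinical covariates
#' with disease-linked shifts (age +7 y, heart rate -3 bpm for the disease
#' subgroup) and realistic missingness rates.
#'
#' @param n_participants Number of participants.
#' @param sample_rate_hz Audio sampling rate; 2205 (the pipeline working rate)
#'   by default, 44100 available to exercise the downsampler.
#' @param duration_s Recording length in seconds.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical cohorts.
#' @param prevalence Named list of disease prevalences: `as` is P(AS grade >= 1),
#'   `ms` P(MS >= 1), `ar3`/`ar4` P(AR = 3)/P(AR = 4), `mr3`/`mr4` likewise,
#'   `innocent` the rate of innocent (non-pathological) murmurs.
#' @param noise_flag_probs Probability that a recording from each of the four
#'   positions (aortic, pulmonic, tricuspid, mitral) is flagged noisy.
#' @param annotator_noise_sd SD (in grade units) of the Gaussian error added to
#'   the true murmur grade before rounding to each annotator's integer grade.
#' @param murmur_rms_per_grade Murmur-to-S1 RMS ratio per grade unit; grade g
#'   is rendered at RMS ratio `murmur_rms_per_grade * g`.
#' @param missingness Named list of missingness rates for clinical variables.
#' @param render_audio If `FALSE`, only labels/covariates are generated
#'   (fast path for label-level simulations).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 100,
                          sample_rate_hz = 2205,
                          duration_s = 10,
                          seed = 1L,
                          prevalence = list(),
                          noise_flag_probs = c(0.061, 0.053, 0.028, 0.071),
                          annotator_noise_sd = 0.5,
                          murmur_rms_per_grade = 0.12,
                          missingness = list(),
                          render_audio = TRUE) {
  prev <- utils::modifyList(list(
    as = 0.021, ms = 0.006,
    ar1 = 0.15, ar2 = 0.08, ar3 = 0.053, ar4 = 0.018,
    mr1 = 0.20, mr2 = 0.10, mr3 = 0.100, mr4 = 0.037,
    innocent = 0.12), prevalence)
  miss <- utils::modifyList(list(
    breathless = 0.0424, mmrc = 0.0603, heart_rate = 0.0612,
    chest_pain = 0.017, high_bp = 0.0245, smoking = 0.014,
    diabetes = 0.028), missingness)
  stopifnot(n_participants >= 0, sample_rate_hz > 400, duration_s > 0,
            length(noise_flag_probs) == 4,
            all(noise_flag_probs >= 0 & noise_flag_probs <= 1),
            annotator_noise_sd >= 0, murmur_rms_per_grade >= 0)
  p <- unlist(prev)
  if (any(p < 0 | p > 1)) stop("prevalences must be probabilities in [0,1]")
  if (any(unlist(miss) < 0)) stop("negative missingness rates rejected")
  structure(list(
    n_participants = as.integer(n_participants),
    sample_rate_hz = sample_rate_hz, duration_s = duration_s,
    seed = as.integer(seed), prevalence = prev,
    noise_flag_probs = noise_flag_probs,
    annotator_noise_sd = annotator_noise_sd,
    murmur_rms_per_grade = murmur_rms_per_grade,
    missingness = miss, render_audio = isTRUE(render_audio)),
    class = "cohort_config")
}

#' Aortic-stenosis grade from the mean aortic valve pressure gradient
#'
#' Cutoffs: 15 mm Hg (mild), 20 mm Hg (moderate), 40 mm Hg (severe).
#'
#' @param avpg_mean Mean pressure gradient in mm Hg.
#' @return Integer grade 0-3.
#' @export
as_grade_from_avpg <- function(avpg_mean) {
  findInterval(avpg_mean, c(15, 20, 40))
}

# position labels used throughout
pcg_positions <- c("aortic", "pulmonic", "tricuspid", "mitral")

#' Synthesize one phonocardiogram recording
#'
#' Renders S1 and S2 as Hann-windowed band-limited bursts (about 120 ms and
#' 90 ms, 40-200 Hz), a systolic interval set as a linear function of cycle
#' length, and systolic/diastolic murmurs as band-passed noise (about
#' 100-440 Hz) whose RMS relative to S1 is proportional to the murmur grade.
#' Ambient white noise is always added; `noisy = TRUE` adds strong broadband
#' interference so flagged-noisy fixtures are physically noisy.
#'
#' @param heart_rate_bpm Heart rate, 30-150 bpm.
#' @param murmur_grade_systolic,murmur_grade_diastolic Continuous grades >= 0.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param duration_s Duration in seconds.
#' @param seed Integer seed.
#' @param noisy Render low-SNR broadband interference.
#' @param n_spikes Number of high-amplitude spike artifacts to inject.
#' @param rms_per_grade Murmur/S1 RMS ratio per grade unit.
#' @return List with `waveform` (in \[-1,1\]), `s1_onsets` (sample indices,
#'   1-based, of cycles that fit completely), `frame_states` (integer labels at
#'   50 Hz: 1 = S1, 2 = systole, 3 = S2, 4 = diastole), `heart_rate_bpm`,
#'   `systolic_interval_ms`.
#' @export
synthesize_pcg <- function(heart_rate_bpm, murmur_grade_systolic = 0,
                           murmur_grade_diastolic = 0,
                           sample_rate_hz = 2205, duration_s = 10,
                           seed = 1L, noisy = FALSE, n_spikes = 0L,
                           rms_per_grade = 0.12) {
  stopifnot(heart_rate_bpm >= 30, heart_rate_bpm <= 150,
            murmur_grade_systolic >= 0, murmur_grade_diastolic >= 0)
  fs <- sample_rate_hz
  n <- round(duration_s * fs)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  cycle <- 60 / heart_rate_bpm
  si <- 0.15 + 0.2 * cycle            # S1 onset to S2 onset, seconds
  dur_s1 <- 0.122; dur_s2 <- 0.092
  t0 <- 0.05
  onsets_t <- seq(t0, duration_s, by = cycle)
  onsets_t <- onsets_t + c(0, stats::rnorm(length(onsets_t) - 1, 0, 0.004))
  x <- numeric(n)
  tt <- (seq_len(n) - 1) / fs

  burst <- function(center_freqs, dur) {
    m <- round(dur * fs)
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1) / (m - 1))
    tb <- (seq_len(m) - 1) / fs
    s <- numeric(m)
    for (f in center_freqs) s <- s + sin(2 * pi * f * tb + stats::runif(1, 0, 2 * pi))
    s * w
  }
  add_at <- function(x, seg, start_sample) {
    i0 <- start_sample; i1 <- min(n, i0 + length(seg) - 1L)
    if (i0 > n || i1 < 1) return(x)
    idx <- i0:i1
    x[idx] <- x[idx] + seg[seq_along(idx)]
    x
  }
  for (ot in onsets_t) {
    i0 <- round(ot * fs) + 1L
    x <- add_at(x, burst(c(45, 90, 150), dur_s1), i0)
    x <- add_at(x, 0.8 * burst(c(55, 110, 180), dur_s2), round((ot + si) * fs) + 1L)
  }
  s1_rms <- {
    idx <- unlist(lapply(onsets_t, function(ot) {
      i0 <- round(ot * fs) + 1L
      seq(i0, min(n, i0 + round(dur_s1 * fs) - 1L))
    }))
    idx <- idx[idx >= 1 & idx <= n]
    if (length(idx)) sqrt(mean(x[idx]^2)) else 1
  }

  band_noise <- function() {
    lo <- 100 / (fs / 2); hi <- min(0.95, 440 / (fs / 2))
    bf <- signal::butter(3, c(lo, hi), type = "pass")
    as.numeric(signal::filter(bf, stats::rnorm(n)))
  }
  diamond <- function(m) {
    k <- seq_len(m)
    1 - abs(2 * (k - 1) / (m - 1) - 1)
  }
  add_murmur <- function(x, grade, from_t, to_t) {
    if (grade <= 0) return(x)
    nz <- band_noise()
    env <- numeric(n)
    for (ot in onsets_t) {
      a <- round((ot + from_t) * fs) + 1L; b <- round((ot + to_t) * fs)
      if (a >= n || b <= a) next
      b <- min(b, n)
      env[a:b] <- diamond(b - a + 1L)
    }
    sup <- env > 0
    if (!any(sup)) return(x)
    cur_rms <- sqrt(mean((nz[sup] * env[sup])^2))
    if (cur_rms <= 0) return(x)
    x + nz * env * (rms_per_grade * grade * s1_rms / cur_rms)
  }
  # systole: S1 end to S2 onset; diastole: S2 end to next S1
  x <- add_murmur(x, murmur_grade_systolic, dur_s1, si)
  x <- add_murmur(x, murmur_grade_diastolic, si + dur_s2, cycle)

  x <- x + stats::rnorm(n, 0, 0.01 * s1_rms)
  if (isTRUE(noisy)) x <- x + stats::rnorm(n, 0, 0.8 * s1_rms)
  if (n_spikes > 0) {
    pos <- sample.int(n - 10L, n_spikes)
    x[pos] <- x[pos] + sample(c(-1, 1), n_spikes, replace = TRUE) * 10 * max(abs(x), 0.1)
  }
  peak <- max(abs(x))
  if (peak > 0) x <- 0.9 * x / peak

  complete <- onsets_t[onsets_t + cycle <= duration_s + 1e-9]
  s1_onsets <- round(complete * fs) + 1L
  if (length(onsets_t) == 0 || (onsets_t[1] + cycle) > duration_s) s1_onsets <- integer(0)

  n_frames <- floor(duration_s * 50)
  ft <- (seq_len(n_frames) - 0.5) / 50
  states <- rep(4L, n_frames)
  for (ot in onsets_t) {
    ph <- ft - ot
    states[ph >= 0 & ph < dur_s1] <- 1L
    states[ph >= dur_s1 & ph < si] <- 2L
    states[ph >= si & ph < si + dur_s2] <- 3L
    states[ph >= si + dur_s2 & ph < cycle] <- 4L
  }
  list(waveform = x, s1_onsets = s1_onsets, frame_states = states,
       heart_rate_bpm = heart_rate_bpm, systolic_interval_ms = si * 1000)
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# deterministic per-recording seed derived from the cohort seed
.derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(idx) * 104729) %% 2147483629)
}

#' Generate a seeded synthetic screening cohort
#'
#' Draws valve-disease status with configured prevalences, a mean aortic
#' pressure gradient consistent with the stenosis grade (low-gradient mass near
#' 3-8 mm Hg for non-stenotic participants, heavier tail for stenosis), true
#' murmur grades mapped from disease severity (aortic stenosis drives
#' aortic/pulmonic-dominant systolic murmurs, mitral regurgitation
#' mitral-dominant ones, mitral stenosis adds a diastolic component), two
#' integer annotator grades (true grade plus Gaussian noise, rounded and
#' clipped to 0-6), per-position noise flags, and clinical covariates with
#' disease-linked shifts and injected missingness.
#'
#' @param config A [cohort_config()].
#' @return A list of class `pcg_cohort` with elements `participants` (one row
#'   per participant: echo labels, clinical covariates), `recordings` (one row
#'   per recording: annotator grades, noise flags, derived murmur grade),
#'   `truth` (true continuous murmur grades per position and latent variables),
#'   `audio` (named list of [synthesize_pcg()] outputs, if rendered), and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  n <- config$n_participants
  prev <- config$prevalence

  draw_reg <- function(p1, p2, p3, p4) {
    p0 <- 1 - (p1 + p2 + p3 + p4)
    sample(0:4, n, replace = TRUE, prob = c(p0, p1, p2, p3, p4))
  }
  as_pos <- stats::runif(n) < prev$as
  avpg <- ifelse(as_pos, 0, pmin(14.5, 3 + stats::rgamma(n, shape = 2, scale = 1.3)))
  sev <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  avpg[as_pos] <- c(stats::runif(sum(as_pos)) *
                      c(5, 20, 40)[sev[as_pos]] + c(15, 20, 40)[sev[as_pos]])
  as_g <- as_grade_from_avpg(avpg)
  ms_g <- ifelse(stats::runif(n) < prev$ms,
                 sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2)), 0L)
  ar_g <- draw_reg(prev$ar1, prev$ar2, prev$ar3, prev$ar4)
  mr_g <- draw_reg(prev$mr1, prev$mr2, prev$mr3, prev$mr4)
  any_vhd <- as_g >= 1 | ms_g >= 1 | ar_g >= 3 | mr_g >= 3
  expression_lat <- stats::runif(n)   # latent loudness/symptom expression

  # true continuous murmur grades per position
  sys_g <- matrix(0, n, 4, dimnames = list(NULL, pcg_positions))
  dia_g <- matrix(0, n, 4, dimnames = list(NULL, pcg_positions))
  as_component <- ifelse(as_g >= 1, pmin(6, 1 + 4.3 * (avpg - 15) / 65), 0)
  sys_g[, "aortic"]    <- as_component
  sys_g[, "pulmonic"]  <- 0.85 * as_component
  sys_g[, "tricuspid"] <- 0.50 * as_component
  sys_g[, "mitral"]    <- 0.40 * as_component
  mr_loud <- 0.75 * mr_g * (0.4 + 1.2 * expression_lat)
  sys_g[, "mitral"]    <- sys_g[, "mitral"] + mr_loud
  sys_g[, "tricuspid"] <- sys_g[, "tricuspid"] + 0.4 * mr_loud
  innocent <- stats::runif(n) < prev$innocent
  inn_g <- ifelse(innocent, stats::runif(n, 0.5, 1.8), 0)
  sys_g[, "aortic"]   <- sys_g[, "aortic"] + inn_g
  sys_g[, "pulmonic"] <- sys_g[, "pulmonic"] + 0.7 * inn_g
  dia_g[, "mitral"] <- 0.8 * ms_g
  dia_g[, "aortic"] <- ifelse(ar_g >= 3, pmax(0, 0.2 * (ar_g - 2)) * (0.4 + 1.6 * expression_lat), 0)
  sys_g <- pmin(sys_g, 6); dia_g <- pmin(dia_g, 6)
  true_total <- pmax(sys_g, dia_g)

  heart_rate <- pmin(95, pmax(50, stats::rnorm(n, 64.5, 9) - 3 * any_vhd))
  age <- pmin(95, pmax(40, stats::rnorm(n, 62.6, 9.5) + 7 * any_vhd))
  female <- stats::runif(n) < (0.554 - 0.078 * any_vhd)
  p_sym <- stats::plogis(-3.4 + 2.2 * expression_lat + 1.6 * any_vhd)
  breathless_rest  <- stats::runif(n) < 0.5 * p_sym
  breathless_level <- stats::runif(n) < p_sym
  breathless_uphill <- stats::runif(n) < pmin(1, 0.22 + 1.2 * p_sym)
  mmrc <- pmin(4L, stats::rpois(n, 0.35 + 1.5 * p_sym))
  bmi <- stats::rnorm(n, 27.2, 4.3)
  chest_pain <- stats::runif(n) < (0.082 + 0.05 * any_vhd)
  high_bp <- stats::runif(n) < (0.357 + 0.07 * any_vhd)
  smoking <- stats::runif(n) < 0.14
  diabetes <- stats::runif(n) < 0.068

  inject_na <- function(x, rate) { x[stats::runif(n) < rate] <- NA; x }
  miss <- config$missingness
  participants <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    as_grade = as_g, ms_grade = ms_g, ar_grade = ar_g, mr_grade = mr_g,
    avpg_mean = avpg,
    age = age, female = female,
    heart_rate = inject_na(heart_rate, miss$heart_rate),
    breathless_rest = inject_na(breathless_rest, miss$breathless),
    breathless_level = inject_na(breathless_level, miss$breathless),
    breathless_uphill = inject_na(breathless_uphill, miss$breathless),
    mmrc = inject_na(mmrc, miss$mmrc),
    bmi = bmi,
    chest_pain = inject_na(chest_pain, miss$chest_pain),
    high_bp = inject_na(high_bp, miss$high_bp),
    smoking = inject_na(smoking, miss$smoking),
    diabetes = inject_na(diabetes, miss$diabetes),
    stringsAsFactors = FALSE)

  # recordings: noise flags, annotator grades
  rec <- expand.grid(position = 1:4, row = seq_len(n))[, 2:1]
  nr <- nrow(rec)
  latent_noisy <- stats::runif(nr) < config$noise_flag_probs[rec$position]
  g_true <- true_total[cbind(rec$row, rec$position)]
  ann_grade <- function() {
    g <- round(g_true + stats::rnorm(nr, 0, config$annotator_noise_sd))
    pmin(6L, pmax(0L, as.integer(g)))
  }
  a1 <- ann_grade(); a2 <- ann_grade()
  a1[latent_noisy] <- 0L; a2[latent_noisy] <- 0L
  recordings <- data.frame(
    participant_id = participants$participant_id[rec$row],
    position = rec$position,
    position_name = pcg_positions[rec$position],
    annotator1_grade = a1, annotator2_grade = a2,
    annotator1_noise = latent_noisy, annotator2_noise = latent_noisy,
    murmur_grade = (a1 + a2) / 2,
    true_grade = g_true,
    true_grade_systolic = sys_g[cbind(rec$row, rec$position)],
    true_grade_diastolic = dia_g[cbind(rec$row, rec$position)],
    stringsAsFactors = FALSE)

  truth <- data.frame(
    participant_id = participants$participant_id,
    heart_rate_bpm = heart_rate,
    expression = expression_lat,
    as_component_aortic = as_component,
    true_max_grade = apply(true_total, 1, max))

  audio <- NULL
  if (config$render_audio && n > 0) {
    audio <- vector("list", nr)
    names(audio) <- paste0(recordings$participant_id, "_", recordings$position)
    for (k in seq_len(nr)) {
      i <- rec$row[k]; p <- rec$position[k]
      audio[[k]] <- synthesize_pcg(
        heart_rate_bpm = heart_rate[i],
        murmur_grade_systolic = sys_g[i, p],
        murmur_grade_diastolic = dia_g[i, p],
        sample_rate_hz = config$sample_rate_hz,
        duration_s = config$duration_s,
        seed = .derive_seed(config$seed, k),
        noisy = latent_noisy[k],
        rms_per_grade = config$murmur_rms_per_grade)
    }
  }
  structure(list(participants = participants, recordings = recordings,
                 truth = truth, audio = audio, config = config),
            class = "pcg_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits one PCM16 mono WAV per recording (`{participant}_{position}.wav`),
#' a manifest CSV, an echo CSV, a clinical CSV, and a ground-truth JSON with
#' S1 onsets and framewise state labels.
#'
#' @param cohort A `pcg_cohort` with rendered audio.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pcg_cohort"))
  if (is.null(cohort$audio)) stop("cohort has no rendered audio")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wav_dir <- file.path(dir, "wav")
  dir.create(wav_dir, showWarnings = FALSE)
  man <- cohort$recordings[, c("participant_id", "position",
                               "annotator1_grade", "annotator2_grade",
                               "annotator1_noise", "annotator2_noise")]
  man$wav_path <- file.path("wav", paste0(man$participant_id, "_", man$position, ".wav"))
  fs <- cohort$config$sample_rate_hz
  for (k in seq_len(nrow(man))) {
    write_wav(cohort$audio[[k]]$waveform, fs, file.path(dir, man$wav_path[k]))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  echo_cols <- c("participant_id", "as_grade", "ms_grade", "ar_grade",
                 "mr_grade", "avpg_mean")
  utils::write.csv(cohort$participants[, echo_cols],
                   file.path(dir, "echo.csv"), row.names = FALSE)
  clin <- cohort$participants[, setdiff(names(cohort$participants),
                                        setdiff(echo_cols, "participant_id"))]
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  gt <- lapply(seq_along(cohort$audio), function(k) {
    a <- cohort$audio[[k]]
    list(s1_onsets = a$s1_onsets, frame_states = a$frame_states,
         heart_rate_bpm = a$heart_rate_bpm)
  })
  names(gt) <- names(cohort$audio)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"), auto_unbox = FALSE)
  invisible(dir)
}
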