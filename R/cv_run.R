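#' Run the full audio feature pipeline over a cohort
#'
#' For every participant: condition each recording (spike removal,
#' downsampling to the working rate), estimate the heart rate per recording,
#' fuse the envelope autocorrelations of the non-noisy positions, decode the
#' cardiac state path with the duration-dependent HSMM, cut four-cycle blocks
#' and compute standardized 13 x 200 MFCC feature blocks. Noisy recordings
#' (either annotator flag) are not decoded: downstream they contribute grade
#' 0 by convention. Participants with all four recordings noisy, or with no
#' usable recording, are excluded with a reason.
#'
#' @param cohort A `pcg_cohort` with rendered audio.
#' @param emissions An `hsmm_emissions` model.
#' @param target_hz Working rate.
#' @return List with `X` (13 x 200 x N feature array), `index` (data frame:
#'   one row per block with `participant_id`, `position`, `block_index`,
#'   `label` = annotator-mean murmur grade of the recording), `recordings`
#'   (per-recording decode summary) and `exclusions`.
#' @export
prepare_features <- function(cohort, emissions, target_hz = 2205) {
  stopifnot(inherits(cohort, "pcg_cohort"))
  if (is.null(cohort$audio)) stop("cohort has no audio")
  rec <- cohort$recordings
  noisy <- rec$annotator1_noise | rec$annotator2_noise
  ids <- unique(rec$participant_id)
  blocks <- list(); idx_rows <- list(); rec_rows <- list(); excl <- list()

  for (id in ids) {
    rows <- which(rec$participant_id == id)
    if (all(noisy[rows])) {
      excl[[length(excl) + 1L]] <- data.frame(
        participant_id = id, reason = "all recordings noisy")
      next
    }
    pre <- list(); acfs <- list(); ok <- logical(length(rows))
    for (j in seq_along(rows)) {
      k <- rows[j]
      key <- paste0(rec$participant_id[k], "_", rec$position[k])
      a <- cohort$audio[[key]]
      if (is.null(a)) next
      fs_in <- if (!is.null(a$sample_rate_hz)) a$sample_rate_hz
               else cohort$config$sample_rate_hz
      p <- preprocess_pcg(a$waveform, fs_in, target_hz)
      env <- pcg_envelopes(p$samples, target_hz)
      hr <- tryCatch(estimate_heart_rate(env[, 1]), error = function(e) NULL)
      pre[[j]] <- list(samples = p$samples, env = env)
      if (!is.null(hr)) { acfs[[j]] <- hr$autocorrelation; ok[j] <- TRUE }
    }
    usable <- ok & !noisy[rows]
    if (!any(usable)) {
      excl[[length(excl) + 1L]] <- data.frame(
        participant_id = id, reason = "no usable recording")
      next
    }
    fused <- fuse_heart_rate(acfs[usable], rep(FALSE, sum(usable)))
    for (j in seq_along(rows)) {
      k <- rows[j]
      if (noisy[k] || !ok[j]) next
      seg <- segment_hsmm(pre[[j]]$samples, target_hz, fused$heart_rate_bpm,
                          fused$systolic_interval_ms, emissions,
                          envelopes = pre[[j]]$env)
      fb <- recording_feature_blocks(pre[[j]]$samples, target_hz,
                                     seg$cycle_starts)
      rec_rows[[length(rec_rows) + 1L]] <- data.frame(
        participant_id = id, position = rec$position[k],
        n_blocks = length(fb), n_cycles = length(seg$cycle_starts) - 1L,
        heart_rate_bpm = fused$heart_rate_bpm)
      for (b in seq_along(fb)) {
        blocks[[length(blocks) + 1L]] <- fb[[b]]
        idx_rows[[length(idx_rows) + 1L]] <- data.frame(
          participant_id = id, position = rec$position[k],
          block_index = b - 1L, label = rec$murmur_grade[k])
      }
    }
  }
  if (length(blocks) == 0) stop("no feature blocks produced")
  X <- array(0, dim = c(nrow(blocks[[1]]), ncol(blocks[[1]]), length(blocks)))
  for (i in seq_along(blocks)) X[, , i] <- blocks[[i]]
  list(X = X, index = do.call(rbind, idx_rows),
       recordings = do.call(rbind, rec_rows),
       exclusions = if (length(excl)) do.call(rbind, excl)
                    else data.frame(participant_id = character(0),
                                    reason = character(0)))
}

# fit a given term structure, dropping terms whose design column is constant
# in this split (unidentifiable), and return the fit plus kept terms
.fit_avpg_structure <- function(terms, data) {
  mg <- as.matrix(data[, c("MG_A", "MG_P", "MG_T", "MG_M")])
  noise <- as.matrix(data[, c("noise_A", "noise_P", "noise_T", "noise_M")])
  cols <- .term_columns(terms, mg * (noise == 0), noise)
  keep <- apply(cols, 2, function(v) stats::sd(v) > 0)
  if (!any(keep)) stop("no identifiable terms in this split")
  fit_avpg_ols(terms[keep], data)
}

.participant_predictors <- function(index, preds, rec) {
  # recording-level grades (median over blocks), then per-participant 4-vectors
  key <- paste(index$participant_id, index$position)
  med <- tapply(preds, key, stats::median)
  ids <- unique(rec$participant_id)
  mg <- matrix(0, length(ids), 4,
               dimnames = list(ids, c("MG_A", "MG_P", "MG_T", "MG_M")))
  nz <- matrix(0L, length(ids), 4,
               dimnames = list(ids, c("noise_A", "noise_P", "noise_T", "noise_M")))
  for (r in seq_len(nrow(rec))) {
    id <- rec$participant_id[r]; p <- rec$position[r]
    if (rec$annotator1_noise[r] || rec$annotator2_noise[r]) {
      nz[id, p] <- 1L
    } else {
      v <- med[paste(id, p)]
      if (!is.na(v)) mg[id, p] <- v
    }
  }
  list(ids = ids, mg = mg, noise = nz,
       max_grade = apply(mg * (nz == 0), 1, max))
}

#' Cross-validated screening run on a cohort
#'
#' The end-to-end harness: feature pipeline, participant-level eightfold
#' cross-validation with a holdout set (stratified by aortic-stenosis
#' status), per-fold training of the murmur-grade network, per-fold refit of
#' the multiposition pressure-gradient model coefficients, decision
#' thresholds selected on each training split (maximum sensitivity +
#' specificity with sensitivity above 50 percent), joint screening under the
#' three disease definitions, clinical-fusion logistic models fit on
#' out-of-fold predictions, the symptomatic-subgroup comparison, and a
#' holdout evaluation with the network retrained on the full development
#' set.
#'
#' @param cohort A `pcg_cohort` with audio and echo/clinical tables.
#' @param net_cfg A [net_config()]; the per-fold network seed is offset by
#'   the fold number.
#' @param emissions Optional `hsmm_emissions`; fitted from labelled synthetic
#'   recordings when `NULL`.
#' @param n_folds,holdout_frac,seed Cross-validation plan parameters.
#' @param features Optional precomputed [prepare_features()] output.
#' @return List of class `pcg_cv_report`; see the methods vignette.
#' @export
cv_run <- function(cohort, net_cfg = net_config(epochs = 4), emissions = NULL,
                   n_folds = 8, holdout_frac = 0.10, seed = 1L,
                   features = NULL) {
  stopifnot(inherits(cohort, "pcg_cohort"))
  if (is.null(emissions)) emissions <- fit_emission_model(seed = seed)
  if (is.null(features)) features <- prepare_features(cohort, emissions)
  part <- cohort$participants
  excl_ids <- unique(features$exclusions$participant_id)
  analyzed <- part[!part$participant_id %in% excl_ids, ]
  idx <- features$index
  rec <- cohort$recordings[cohort$recordings$participant_id %in%
                             analyzed$participant_id, ]

  plan <- make_folds(analyzed$participant_id, analyzed$as_grade >= 1,
                     n_folds, holdout_frac, seed)
  dev_ids <- plan$participant_id[!plan$holdout]
  hold_ids <- plan$participant_id[plan$holdout]
  fold_of <- stats::setNames(plan$fold, plan$participant_id)

  preset_terms <- avpg_preset_model()$terms
  dev_rows <- list()
  for (f in seq_len(n_folds)) {
    train_ids <- dev_ids[fold_of[dev_ids] != f]
    val_ids <- dev_ids[fold_of[dev_ids] == f]
    tr_blocks <- which(idx$participant_id %in% train_ids)
    bal <- balance_training_set(idx$label[tr_blocks],
                                seed = .derive_seed(seed, f),
                                target_ratio = net_cfg$balance_target_ratio)
    cfg_f <- net_cfg; cfg_f$seed <- net_cfg$seed + f
    model <- train_murmur_net(features$X[, , tr_blocks[bal], drop = FALSE],
                              idx$label[tr_blocks[bal]], cfg_f)
    dev_blocks <- which(idx$participant_id %in% dev_ids)
    preds <- predict_murmur_net(model, features$X[, , dev_blocks, drop = FALSE])
    pp <- .participant_predictors(idx[dev_blocks, ], preds,
                                  rec[rec$participant_id %in% dev_ids, ])
    tr <- pp$ids %in% train_ids; va <- pp$ids %in% val_ids
    avpg_data <- data.frame(pp$mg, pp$noise,
                            avpg_mean = part$avpg_mean[
                              match(pp$ids, part$participant_id)])
    avpg_fit <- .fit_avpg_structure(preset_terms, avpg_data[tr, ])
    avpg_pred <- evaluate_avpg(avpg_fit$spec, pp$mg, pp$noise)
    echo_tr <- analyzed[match(pp$ids[tr], analyzed$participant_id), ]
    def1_tr <- joint_screen(echo_tr, pp$max_grade[tr], 1)
    thr_def1 <- select_threshold(def1_tr$predictor, def1_tr$positive_class)
    as_tr <- echo_tr$as_grade >= 1
    thr_as <- tryCatch(select_threshold(avpg_pred[tr], as_tr),
                       error = function(e) list(threshold = NA_real_))
    dev_rows[[f]] <- data.frame(
      participant_id = pp$ids[va], fold = f,
      max_grade = pp$max_grade[va],
      mitral_grade = pp$mg[va, "MG_M"] * (pp$noise[va, "noise_M"] == 0),
      avpg_pred = avpg_pred[va],
      thr_def1 = thr_def1$threshold, thr_as = thr_as$threshold)
  }
  dev_pred <- do.call(rbind, dev_rows)
  dev_echo <- analyzed[match(dev_pred$participant_id, analyzed$participant_id), ]

  # pooled out-of-fold metrics
  as_pos <- dev_echo$as_grade >= 1
  as_auc <- tryCatch(roc_auc(dev_pred$avpg_pred, as_pos), error = function(e) NA)
  joint <- lapply(1:3, function(d) {
    js <- joint_screen(dev_echo, dev_pred$max_grade, d)
    list(definition = d,
         auc = tryCatch(roc_auc(js$predictor, js$positive_class),
                        error = function(e) NA_real_),
         n_pos = sum(js$positive_class))
  })
  screen_pos <- dev_pred$max_grade >= dev_pred$thr_def1
  sten <- dev_echo$as_grade >= 1 | dev_echo$ms_grade >= 1
  sten_detect <- list(detected = sum(screen_pos & sten), total = sum(sten),
                      rate = if (sum(sten)) mean(screen_pos[sten]) else NA_real_)
  def1 <- joint_screen(dev_echo, dev_pred$max_grade, 1)
  sens <- sum(screen_pos & def1$positive_class) / sum(def1$positive_class)
  spec <- sum(!screen_pos & !def1$positive_class) / sum(!def1$positive_class)
  sens_ci <- exact_binomial_ci(sum(screen_pos & def1$positive_class),
                               sum(def1$positive_class))
  spec_ci <- exact_binomial_ci(sum(!screen_pos & !def1$positive_class),
                               sum(!def1$positive_class))

  # symptomatic-subgroup comparison among significant regurgitation cases
  reg <- dev_echo$ar_grade >= 3 | dev_echo$mr_grade >= 3
  symp <- symptomatic_status(dev_echo)
  symptom_test <- if (any(reg & screen_pos) && any(reg & !screen_pos))
    symptom_subgroup_test(symp[reg & screen_pos], symp[reg & !screen_pos])
  else list(prevalence_tp = NA, prevalence_fn = NA, p_value = NA, flagged = TRUE)

  # clinical-fusion models on out-of-fold audio predictions
  murmur_for <- list(AR = dev_pred$max_grade, MR = dev_pred$mitral_grade,
                     AS = dev_pred$avpg_pred, MS = dev_pred$max_grade)
  clinical <- lapply(names(murmur_for), function(tg) {
    fit <- tryCatch(fit_clinical_model(tg, dev_echo, murmur_for[[tg]]),
                    error = function(e) NULL)
    if (is.null(fit)) return(list(target = tg, auc = NA_real_, fit = NULL))
    pr <- stats::predict(fit$fit, type = "response")
    lab <- fit$fit$y
    list(target = tg, fit = fit,
         auc = tryCatch(roc_auc(pr, lab), error = function(e) NA_real_))
  })
  names(clinical) <- names(murmur_for)

  # holdout: retrain on the full development set
  holdout <- NULL
  if (length(hold_ids) > 0) {
    tr_blocks <- which(idx$participant_id %in% dev_ids)
    bal <- balance_training_set(idx$label[tr_blocks],
                                seed = .derive_seed(seed, 99L),
                                target_ratio = net_cfg$balance_target_ratio)
    model <- train_murmur_net(features$X[, , tr_blocks[bal], drop = FALSE],
                              idx$label[tr_blocks[bal]], net_cfg)
    all_blocks <- which(idx$participant_id %in% c(dev_ids, hold_ids))
    preds <- predict_murmur_net(model, features$X[, , all_blocks, drop = FALSE])
    pp <- .participant_predictors(idx[all_blocks, ], preds, rec)
    is_dev <- pp$ids %in% dev_ids; is_hold <- pp$ids %in% hold_ids
    echo_dev <- analyzed[match(pp$ids[is_dev], analyzed$participant_id), ]
    d1 <- joint_screen(echo_dev, pp$max_grade[is_dev], 1)
    thr <- select_threshold(d1$predictor, d1$positive_class)
    echo_h <- analyzed[match(pp$ids[is_hold], analyzed$participant_id), ]
    d1h <- joint_screen(echo_h, pp$max_grade[is_hold], 1)
    sten_h <- echo_h$as_grade >= 1 | echo_h$ms_grade >= 1
    pos_h <- pp$max_grade[is_hold] >= thr$threshold
    holdout <- list(
      n = length(hold_ids), threshold = thr$threshold,
      auc_def1 = tryCatch(roc_auc(d1h$predictor, d1h$positive_class),
                          error = function(e) NA_real_),
      stenosis_detected = sum(pos_h & sten_h), stenosis_total = sum(sten_h))
  }

  counts <- list(input = nrow(part), analyzed = nrow(analyzed),
                 excluded = length(excl_ids))
  structure(list(
    fold_plan = plan, dev_predictions = dev_pred,
    as_auc = as_auc, joint = joint,
    def1_sensitivity = sens, def1_specificity = spec,
    def1_sens_ci = sens_ci, def1_spec_ci = spec_ci,
    stenosis_detection = sten_detect, symptom_test = symptom_test,
    clinical = clinical, holdout = holdout,
    exclusions = features$exclusions, counts = counts),
    class = "pcg_cv_report")
}

#' @export
print.pcg_cv_report <- function(x, ...) {
  cat("Cross-validated screening report\n")
  cat(sprintf("  participants: %d analyzed, %d excluded (of %d)\n",
              x$counts$analyzed, x$counts$excluded, x$counts$input))
  cat(sprintf("  AS (>=1) AUC from multiposition gradient model: %.3f\n",
              x$as_auc))
  for (j in x$joint)
    cat(sprintf("  joint screening definition %d: AUC %.3f (%d positives)\n",
                j$definition, j$auc, j$n_pos))
  cat(sprintf("  definition-1 sensitivity %.3f spec %.3f\n",
              x$def1_sensitivity, x$def1_specificity))
  cat(sprintf("  stenosis cases detected: %d of %d (%.1f%%)\n",
              x$stenosis_detection$detected, x$stenosis_detection$total,
              100 * x$stenosis_detection$rate))
  invisible(x)
}
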