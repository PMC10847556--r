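#' Configuration of the murmur-grade recurrent regressor
#'
#' Two recurrent (LSTM) layers of 50 units, a 30-unit rectified fully
#' connected layer and a linear scalar output; squared-error loss; initial
#' learning rate 0.002 halved every five epochs.
#'
#' @param lstm_units Units per recurrent layer.
#' @param fc_units Units in the fully connected layer.
#' @param initial_lr Initial learning rate.
#' @param lr_halving_period_epochs Epochs between halvings of the rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed Seed controlling initialization and shuffling.
#' @param balance_target_ratio Target ratio of murmur to non-murmur samples
#'   after resampling.
#' @return List of class `net_config`.
#' @export
net_config <- function(lstm_units = 50, fc_units = 30, initial_lr = 0.002,
                       lr_halving_period_epochs = 5, epochs = 30,
                       batch_size = 64, seed = 1L,
                       balance_target_ratio = 1.0) {
  stopifnot(lstm_units > 0, fc_units > 0, initial_lr > 0, epochs > 0,
            batch_size > 0, lr_halving_period_epochs > 0)
  structure(list(lstm_layers = 2L, lstm_units = as.integer(lstm_units),
                 fc_units = as.integer(fc_units), initial_lr = initial_lr,
                 lr_halving_period_epochs = as.integer(lr_halving_period_epochs),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 balance_target_ratio = balance_target_ratio),
            class = "net_config")
}

#' Learning rate at a given epoch
#'
#' `lr(epoch) = initial_lr * 0.5^floor(epoch / halving_period)`, epochs
#' counted from 0.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param config A [net_config()].
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, config = net_config()) {
  config$initial_lr * 0.5^(epoch %/% config$lr_halving_period_epochs)
}

#' Balance murmur and non-murmur training blocks
#'
#' Resamples (with replacement) from the class with murmur grade >= 1 and
#' appends until the ratio of grade >= 1 to grade < 1 samples is
#' approximately the target (within \[0.95, 1.05\] of it). All original
#' samples are retained and labels are unchanged.
#'
#' @param labels Numeric block labels (murmur grades).
#' @param seed Seed for the resampling draws.
#' @param target_ratio Target murmur : non-murmur ratio.
#' @return Integer indices into the input (originals first, then resampled
#'   additions).
#' @export
balance_training_set <- function(labels, seed = 1L, target_ratio = 1.0) {
  pos <- which(labels >= 1)
  neg <- which(labels < 1)
  if (length(pos) == 0 || length(neg) == 0)
    stop("degenerate training set: a murmur class is empty")
  idx <- seq_along(labels)
  ratio <- length(pos) / length(neg)
  if (ratio >= 0.95 * target_ratio) return(idx)
  n_add <- round(target_ratio * length(neg)) - length(pos)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  c(idx, sample(pos, n_add, replace = TRUE))
}

#' Train the murmur-grade regressor
#'
#' @param X Feature array of dimension 13 x 200 x N (one standardized MFCC
#'   block per slice).
#' @param labels Numeric vector of N murmur-grade labels in \[0, 6\].
#' @param config A [net_config()].
#' @return List of class `murmur_net` with `params`, `loss_history`, `config`.
#' @export
train_murmur_net <- function(X, labels, config = net_config()) {
  stopifnot(length(dim(X)) == 3, dim(X)[3] == length(labels),
            all(labels >= 0 & labels <= 6))
  p0 <- lstm_init_cpp(dim(X)[1], config$lstm_units, config$fc_units,
                      config$seed)
  fit <- lstm_train_cpp(X, labels, p0, config$lstm_units, config$epochs,
                        config$batch_size, config$initial_lr,
                        config$lr_halving_period_epochs, config$seed + 1L)
  structure(list(params = fit$params, loss_history = fit$loss_history,
                 config = config), class = "murmur_net")
}

#' Predict block-level murmur grades
#'
#' @param model A trained `murmur_net`.
#' @param X Feature array 13 x 200 x N.
#' @return Numeric vector of N raw (unclipped) grade predictions.
#' @export
predict_murmur_net <- function(model, X) {
  stopifnot(inherits(model, "murmur_net"), length(dim(X)) == 3)
  as.numeric(lstm_predict_cpp(X, model$params, model$config$lstm_units))
}

#' Aggregate block predictions into a recording-level grade
#'
#' The recording grade is the median of the block grades (mean of the middle
#' two for an even count).
#'
#' @param block_grades Numeric vector of block predictions (non-empty).
#' @param recording_id Optional identifier carried through.
#' @param position Optional auscultation position.
#' @return List of class `murmur_prediction` with `block_grades` and
#'   `recording_grade`.
#' @export
predict_recording <- function(block_grades, recording_id = NA, position = NA) {
  if (length(block_grades) == 0) stop("recording unusable: zero blocks")
  structure(list(recording_id = recording_id, position = position,
                 block_grades = block_grades,
                 recording_grade = stats::median(block_grades)),
            class = "murmur_prediction")
}

#' Aggregate recording grades to participant-level predictors
#'
#' Noisy positions contribute grade 0. Mode `"max"` returns the maximum
#' predicted grade; mode `"per-position"` returns the 4-vector of grades
#' (noisy entries zeroed) together with the noise indicator bits, the input
#' expected by the multiposition pressure-gradient model. Participants with
#' all four recordings noisy must be excluded upstream; such input raises a
#' condition of class `pcg_all_noisy`.
#'
#' @param grades Numeric 4-vector of recording grades (aortic, pulmonic,
#'   tricuspid, mitral).
#' @param noise_flags Logical 4-vector.
#' @param mode `"max"` or `"per-position"`.
#' @return For `"max"` a scalar; for `"per-position"` a list with `grades`
#'   and `noise`.
#' @export
aggregate_participant <- function(grades, noise_flags = rep(FALSE, 4),
                                  mode = c("max", "per-position")) {
  mode <- match.arg(mode)
  stopifnot(length(grades) == 4, length(noise_flags) == 4)
  if (all(noise_flags))
    stop(structure(class = c("pcg_all_noisy", "error", "condition"),
                   list(message = "all four recordings noisy: participant excluded",
                        call = sys.call())))
  g <- ifelse(noise_flags, 0, grades)
  if (mode == "max") max(g)
  else list(grades = g, noise = as.integer(noise_flags))
}
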