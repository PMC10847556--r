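#' Specify a multiposition linear model for the mean aortic pressure gradient
#'
#' A model is an intercept plus a sum of coefficient-weighted product terms.
#' Each term is a character vector of factors drawn from `MG_A`, `MG_P`,
#' `MG_T`, `MG_M` (predicted murmur grades at the aortic, pulmonic, tricuspid
#' and mitral positions; a factor repeated twice denotes the square) and
#' `noise_A` ... `noise_M` (0/1 noise indicators).
#'
#' @param terms List of character vectors (one per term).
#' @param coefficients Numeric vector, one per term.
#' @param intercept Intercept in mm Hg.
#' @return List of class `linear_model_spec`.
#' @export
linear_model_spec <- function(terms, coefficients, intercept) {
  stopifnot(length(terms) == length(coefficients))
  ids <- vapply(terms, function(t) paste(sort(t), collapse = ":"), "")
  if (anyDuplicated(ids)) stop("duplicate terms in model specification")
  for (t in terms) {
    mg <- grepl("^MG_", t)
    if (any(table(t[mg]) > 2)) stop("murmur-grade degree above 2 in term")
  }
  structure(list(terms = terms, coefficients = coefficients,
                 intercept = intercept), class = "linear_model_spec")
}

#' The published multiposition pressure-gradient model
#'
#' The fitted model printed in the source analysis:
#' `AVPGmean = 3.5 + 0.6 MG_A^2 + 1.1 MG_P^2 + 0.5 MG_T
#'  + 0.9 MG_A^2 noise_P + 8.9 MG_M noise_A noise_P noise_T`
#' (the publication elides further terms; the preset implements exactly the
#' printed ones).
#'
#' @return A `linear_model_spec`.
#' @export
avpg_preset_model <- function() {
  linear_model_spec(
    terms = list(c("MG_A", "MG_A"),
                 c("MG_P", "MG_P"),
                 "MG_T",
                 c("MG_A", "MG_A", "noise_P"),
                 c("MG_M", "noise_A", "noise_P", "noise_T")),
    coefficients = c(0.6, 1.1, 0.5, 0.9, 8.9),
    intercept = 3.5)
}

.term_columns <- function(terms, mg, noise) {
  # mg, noise: matrices n x 4 with columns A, P, T, M
  vals <- cbind(MG_A = mg[, 1], MG_P = mg[, 2], MG_T = mg[, 3], MG_M = mg[, 4],
                noise_A = noise[, 1], noise_P = noise[, 2],
                noise_T = noise[, 3], noise_M = noise[, 4])
  out <- vapply(terms, function(t) {
    v <- rep(1, nrow(vals))
    for (f in t) v <- v * vals[, f]
    v
  }, numeric(nrow(vals)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(vals))
  out
}

#' Evaluate a multiposition model
#'
#' Murmur grades at noisy positions are forced to 0 before evaluation (the
#' convention for noisy recordings). Participants with all four positions
#' noisy are excluded; such rows raise a `pcg_all_noisy` condition.
#'
#' @param spec A `linear_model_spec`.
#' @param mg Numeric 4-vector (or n x 4 matrix) of predicted murmur grades
#'   in the order aortic, pulmonic, tricuspid, mitral.
#' @param noise 0/1 4-vector (or n x 4 matrix) of noise indicators.
#' @return Predicted mean gradient(s) in mm Hg.
#' @export
evaluate_avpg <- function(spec, mg, noise = c(0, 0, 0, 0)) {
  stopifnot(inherits(spec, "linear_model_spec"))
  if (is.null(dim(mg))) mg <- matrix(mg, nrow = 1)
  if (is.null(dim(noise))) noise <- matrix(noise, nrow = 1, ncol = 4)
  if (any(rowSums(noise != 0) == 4))
    stop(structure(class = c("pcg_all_noisy", "error", "condition"),
                   list(message = "all four positions noisy: excluded from gradient model",
                        call = sys.call())))
  mg <- mg * (noise == 0)
  X <- .term_columns(spec$terms, mg, noise)
  drop(spec$intercept + X %*% spec$coefficients)
}

#' Ordinary least squares fit of a term set
#'
#' @param terms List of term factor vectors.
#' @param data Data frame (or list) with columns `MG_A` ... `MG_M`,
#'   `noise_A` ... `noise_M` and the response `avpg_mean`.
#' @return List with `spec` (fitted `linear_model_spec`), `se`, `p_values`
#'   (per term, intercept first), `rss`, `bic` (computed as
#'   `n log(RSS/n) + k log(n)` with k = terms + intercept + variance), `n`.
#' @export
fit_avpg_ols <- function(terms, data) {
  mg <- as.matrix(data.frame(data)[, c("MG_A", "MG_P", "MG_T", "MG_M")])
  noise <- as.matrix(data.frame(data)[, c("noise_A", "noise_P", "noise_T", "noise_M")])
  mg <- mg * (noise == 0)
  y <- data.frame(data)$avpg_mean
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, .term_columns(terms, mg, noise))
  k_cols <- ncol(X)
  if (n <= k_cols) stop("need more observations than terms")
  qrX <- qr(X)
  if (qrX$rank < k_cols) {
    bad <- setdiff(seq_len(k_cols), qrX$pivot[seq_len(qrX$rank)])
    nm <- c("(Intercept)", vapply(terms, paste, "", collapse = ":"))
    stop("rank-deficient design; collinear terms: ", paste(nm[bad], collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / (n - k_cols)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = n - k_cols, lower.tail = FALSE)
  k <- length(terms) + 2   # intercept + residual variance
  bic <- n * log(rss / n) + k * log(n)
  list(spec = linear_model_spec(terms, beta[-1], beta[1]),
       se = se, p_values = p, rss = rss, bic = bic, n = n,
       residuals = as.numeric(res), design = X)
}

.term_id <- function(t) paste(sort(t), collapse = ":")

.stepwise_phase <- function(current, pool, data, alpha) {
  fit <- fit_avpg_ols(current, data)
  repeat {
    cur_ids <- vapply(current, .term_id, "")
    cand_add <- pool[!vapply(pool, .term_id, "") %in% cur_ids]
    best_bic <- fit$bic; best_fit <- NULL; best_terms <- NULL
    # additions: the new term must be significant in the candidate fit
    for (tm in cand_add) {
      f2 <- tryCatch(fit_avpg_ols(c(current, list(tm)), data),
                     error = function(e) NULL)
      if (is.null(f2)) next
      p_new <- f2$p_values[length(f2$p_values)]
      if (is.finite(p_new) && p_new < alpha && f2$bic < best_bic - 1e-10) {
        best_bic <- f2$bic; best_fit <- f2; best_terms <- c(current, list(tm))
      }
    }
    # removals: candidates are current terms with p > alpha
    if (length(current) > 0) {
      p_terms <- fit$p_values[-1]
      for (j in seq_along(current)) {
        if (is.finite(p_terms[j]) && p_terms[j] <= alpha) next
        trial <- current[-j]
        f2 <- tryCatch(fit_avpg_ols(trial, data), error = function(e) NULL)
        if (!is.null(f2) && f2$bic < best_bic - 1e-10) {
          best_bic <- f2$bic; best_fit <- f2; best_terms <- trial
        }
      }
    }
    if (is.null(best_fit)) return(list(terms = current, fit = fit))
    current <- best_terms; fit <- best_fit
  }
}

#' Stepwise BIC selection of the multiposition model
#'
#' Phase 1 starts from the base model with one linear term per murmur-grade
#' prediction and repeatedly applies the single-term addition (requiring
#' p < `alpha` for the new term) or removal (candidates are terms with
#' p > `alpha`) that most lowers the BIC, stopping when no move lowers it.
#' Phase 2 repeats the procedure over noise-indicator terms (main effects and
#' interactions of each selected term with each noise indicator); phase-1
#' terms stay in the pool and remain removable. Deterministic; ties are broken
#' toward the earlier candidate.
#'
#' @param data As in [fit_avpg_ols()].
#' @param alpha Significance gate for additions/removals.
#' @return List with `spec` (the selected fitted model), `fit` (full fit
#'   object), `terms`.
#' @export
stepwise_select <- function(data, alpha = 0.05) {
  base <- list("MG_A", "MG_P", "MG_T", "MG_M")
  squares <- list(c("MG_A", "MG_A"), c("MG_P", "MG_P"),
                  c("MG_T", "MG_T"), c("MG_M", "MG_M"))
  ph1 <- .stepwise_phase(base, c(base, squares), data, alpha)
  noise_main <- list("noise_A", "noise_P", "noise_T", "noise_M")
  inter <- list()
  for (tm in ph1$terms)
    for (nz in c("noise_A", "noise_P", "noise_T", "noise_M"))
      if (!nz %in% tm) inter[[length(inter) + 1L]] <- c(tm, nz)
  ph2 <- .stepwise_phase(ph1$terms, c(ph1$terms, noise_main, inter), data, alpha)
  list(spec = ph2$fit$spec, fit = ph2$fit, terms = ph2$terms)
}

#' AUC for gradient-threshold exceedance across a threshold sweep
#'
#' For each threshold u, computes the AUC for predicting `avpg_mean > u` from
#' the model predictions, with a seeded percentile bootstrap confidence
#' interval (resampling participants).
#'
#' @param predictions Predicted gradients.
#' @param avpg_values Observed gradients.
#' @param thresholds Thresholds u in mm Hg.
#' @param n_boot Bootstrap replicates.
#' @param level Confidence level.
#' @param seed Seed for resampling.
#' @return Data frame with `threshold`, `auc`, `ci_low`, `ci_high`, `n_pos`;
#'   thresholds with a degenerate class are skipped with a warning.
#' @export
threshold_sweep_auc <- function(predictions, avpg_values, thresholds = 7:30,
                                n_boot = 1000, level = 0.95, seed = 1L) {
  stopifnot(length(predictions) == length(avpg_values))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- length(predictions)
  rows <- list()
  skipped <- c()
  boot_idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  for (u in thresholds) {
    lab <- avpg_values > u
    if (!any(lab) || all(lab)) { skipped <- c(skipped, u); next }
    point <- roc_auc(predictions, lab)
    bs <- vapply(seq_len(n_boot), function(b) {
      i <- boot_idx[, b]
      l <- lab[i]
      if (!any(l) || all(l)) return(NA_real_)
      roc_auc(predictions[i], l)
    }, 0)
    qs <- stats::quantile(bs, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      threshold = u, auc = point, ci_low = qs[1], ci_high = qs[2],
      n_pos = sum(lab))
  }
  if (length(skipped))
    warning("thresholds skipped (degenerate class): ",
            paste(skipped, collapse = ", "))
  if (length(rows) == 0) stop("degenerate class at all thresholds")
  do.call(rbind, rows)
}
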