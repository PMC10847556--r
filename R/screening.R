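#' Participant-level cross-validation folds with a holdout set
#'
#' Draws the holdout participants first (about `holdout_frac` of the cohort),
#' then stratifies the remainder by aortic-stenosis status (AS grade >= 1)
#' into `n_folds` folds so positive counts per fold differ by at most one.
#' All splits are keyed by participant identifier.
#'
#' @param participant_ids Character vector of unique identifiers.
#' @param as_positive Logical vector (AS grade >= 1), aligned with ids.
#' @param n_folds Number of folds.
#' @param holdout_frac Fraction set aside as the holdout.
#' @param seed Seed; the plan is deterministic given it.
#' @return Data frame of class `fold_plan` with `participant_id`, `holdout`
#'   (logical) and `fold` (integer, NA for holdout participants).
#' @export
make_folds <- function(participant_ids, as_positive, n_folds = 8,
                       holdout_frac = 0.10, seed = 1L) {
  n <- length(participant_ids)
  stopifnot(length(as_positive) == n, !anyDuplicated(participant_ids))
  if (n < n_folds) stop("fewer participants than folds")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n_hold <- round(holdout_frac * n)
  hold <- if (n_hold > 0) sample.int(n, n_hold) else integer(0)
  dev <- setdiff(seq_len(n), hold)
  if (sum(as_positive[dev]) < n_folds)
    warning("fewer positive stenosis cases than folds; stratification is thin")
  fold <- rep(NA_integer_, n)
  for (cls in c(TRUE, FALSE)) {
    members <- dev[as_positive[dev] == cls]
    members <- members[sample.int(length(members))]
    if (length(members))
      fold[members] <- rep_len(seq_len(n_folds), length(members))
  }
  structure(data.frame(participant_id = participant_ids,
                       holdout = seq_len(n) %in% hold,
                       fold = fold, stringsAsFactors = FALSE),
            class = c("fold_plan", "data.frame"))
}

#' Select a decision threshold under the sensitivity constraint
#'
#' Among candidate thresholds (midpoints of consecutive sorted unique scores,
#' a decision rule `score >= threshold`), returns the one maximizing
#' sensitivity + specificity subject to sensitivity exceeding 50 percent.
#' Ties are broken toward higher specificity, then lower threshold. If no
#' candidate satisfies the constraint, the minimum score is returned with a
#' warning (sensitivity 1).
#'
#' @param scores Numeric predictor.
#' @param labels Logical class labels; both classes must occur.
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
select_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) stop("both classes required")
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  stats_at <- function(thr) {
    pos <- scores >= thr
    c(sens = sum(pos & labels) / sum(labels),
      spec = sum(!pos & !labels) / sum(!labels))
  }
  S <- vapply(cand, stats_at, c(sens = 0, spec = 0))
  ok <- S["sens", ] > 0.5
  if (!any(ok)) {
    warning("no threshold attains sensitivity > 50%; returning minimum score")
    thr <- min(scores)
    st <- stats_at(thr)
    return(list(threshold = thr, sensitivity = st[["sens"]],
                specificity = st[["spec"]]))
  }
  cand <- cand[ok]; S <- S[, ok, drop = FALSE]
  # round away float noise so the specificity tie-break is exact
  j <- order(-round(S["sens", ] + S["spec", ], 9),
             -round(S["spec", ], 9), cand)[1]
  list(threshold = cand[j], sensitivity = unname(S["sens", j]),
       specificity = unname(S["spec", j]))
}

#' Symptomatic status under the study definition
#'
#' Breathlessness at rest or while walking calmly on level ground, or an
#' mMRC dyspnea score of at least 2.
#'
#' @param tbl Data frame with `breathless_rest`, `breathless_level`, `mmrc`.
#' @return Logical vector (NA components treated as absent).
#' @export
symptomatic_status <- function(tbl) {
  r <- tbl$breathless_rest; l <- tbl$breathless_level; m <- tbl$mmrc
  r[is.na(r)] <- FALSE; l[is.na(l)] <- FALSE; m[is.na(m)] <- 0
  r | l | m >= 2
}

#' Joint screening class membership
#'
#' Three definitions of significant valve disease: (1) grade >= 3
#' regurgitation or grade >= 1 stenosis, (2) grade >= 4 regurgitation or
#' grade >= 1 stenosis, (3) symptomatic grade >= 3 regurgitation or grade
#' >= 1 stenosis (the stenosis clause carries no symptom filter).
#'
#' @param echo Data frame with `as_grade`, `ms_grade`, `ar_grade`, `mr_grade`
#'   and, for definition 3, the symptom columns of [symptomatic_status()].
#' @param predictor Participant-level predictor (maximum predicted murmur
#'   grade across the four positions), aligned with `echo` rows.
#' @param definition 1, 2 or 3.
#' @return Data frame with `positive_class` (logical) and `predictor`.
#' @export
joint_screen <- function(echo, predictor, definition = 1) {
  stopifnot(definition %in% 1:3, length(predictor) == nrow(echo))
  if (anyNA(echo[, c("as_grade", "ms_grade", "ar_grade", "mr_grade")]))
    stop("missing echo grades; exclude those participants before screening")
  sten <- echo$as_grade >= 1 | echo$ms_grade >= 1
  reg3 <- echo$ar_grade >= 3 | echo$mr_grade >= 3
  reg4 <- echo$ar_grade >= 4 | echo$mr_grade >= 4
  pos <- switch(definition,
                reg3 | sten,
                reg4 | sten,
                (reg3 & symptomatic_status(echo)) | sten)
  data.frame(positive_class = pos, predictor = predictor)
}

#' Impute missing categorical answers by the most frequent value
#'
#' @param x Vector with possible NAs.
#' @return Vector with NAs replaced by the modal non-missing value.
#' @export
impute_mode <- function(x) {
  if (!anyNA(x)) return(x)
  tab <- table(x[!is.na(x)])
  if (length(tab) == 0) stop("cannot impute: all values missing")
  mode_val <- names(tab)[which.max(tab)]
  filled <- if (is.logical(x)) as.logical(mode_val)
            else if (is.numeric(x)) as.numeric(mode_val) else mode_val
  x[is.na(x)] <- filled
  x
}

# covariate formula per screening target
.clinical_formulas <- list(
  AR = positive ~ murmur + age + female + breathless_uphill + heart_rate,
  MR = positive ~ murmur + age + heart_rate,
  AS = positive ~ murmur + female + female:murmur,
  MS = positive ~ murmur + age + heart_rate)

#' Fit a clinical-fusion logistic model for one disease target
#'
#' Targets and covariates: AR (grade >= 3): murmur + age + gender +
#' breathlessness walking uphill + heart rate; MR (grade >= 3): murmur + age
#' + heart rate; AS (grade >= 1): murmur + gender + gender x murmur
#' interaction; MS (grade >= 1): murmur + age + heart rate. The audio
#' predictor entering as `murmur` is, per target: AR and MS the maximum
#' predicted grade, MR the mitral-position grade, AS the multiposition
#' pressure-gradient prediction. Missing categorical answers are imputed with
#' the most frequent answer (numeric covariates with the median) before
#' fitting.
#'
#' @param target One of `"AR"`, `"MR"`, `"AS"`, `"MS"`.
#' @param tbl Participant table with echo grades and clinical covariates.
#' @param murmur Audio predictor vector aligned with `tbl`.
#' @return List of class `logistic_model_spec` with `target`, `formula`,
#'   `coefficients`, `se`, `fit` (the `glm` object), `n`.
#' @export
fit_clinical_model <- function(target = c("AR", "MR", "AS", "MS"), tbl, murmur) {
  target <- match.arg(target)
  stopifnot(length(murmur) == nrow(tbl))
  positive <- switch(target,
                     AR = tbl$ar_grade >= 3, MR = tbl$mr_grade >= 3,
                     AS = tbl$as_grade >= 1, MS = tbl$ms_grade >= 1)
  df <- data.frame(positive = positive, murmur = murmur,
                   age = tbl$age, female = tbl$female,
                   heart_rate = tbl$heart_rate,
                   breathless_uphill = tbl$breathless_uphill)
  for (col in c("female", "breathless_uphill"))
    df[[col]] <- impute_mode(df[[col]])
  for (col in c("age", "heart_rate"))
    if (anyNA(df[[col]])) df[[col]][is.na(df[[col]])] <-
        stats::median(df[[col]], na.rm = TRUE)
  fit <- stats::glm(.clinical_formulas[[target]], data = df,
                    family = stats::binomial())
  if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE))
    stop("separation or non-convergence detected in ", target,
         " model; coefficients: ",
         paste(signif(stats::coef(fit), 3), collapse = ", "))
  sm <- summary(fit)
  structure(list(target = target, formula = .clinical_formulas[[target]],
                 coefficients = stats::coef(fit),
                 se = sm$coefficients[, "Std. Error"],
                 fit = fit, n = nrow(df)),
            class = "logistic_model_spec")
}

#' Compare symptom prevalence between detected and missed cases
#'
#' Two-sided Fisher exact test on the 2x2 table of detected/missed by
#' symptomatic/asymptomatic.
#'
#' @param tp_symptomatic Logical vector: symptom status of the true positives
#'   (cases the screen detected).
#' @param fn_symptomatic Logical vector: symptom status of the false
#'   negatives (cases it missed).
#' @return List with `prevalence_tp`, `prevalence_fn`, `p_value` (NA with
#'   `flagged = TRUE` when a subset is empty).
#' @export
symptom_subgroup_test <- function(tp_symptomatic, fn_symptomatic) {
  ptp <- mean(tp_symptomatic); pfn <- mean(fn_symptomatic)
  if (length(tp_symptomatic) == 0 || length(fn_symptomatic) == 0) {
    return(list(prevalence_tp = ptp, prevalence_fn = pfn,
                p_value = NA_real_, flagged = TRUE))
  }
  tab <- matrix(c(sum(tp_symptomatic), sum(!tp_symptomatic),
                  sum(fn_symptomatic), sum(!fn_symptomatic)),
                nrow = 2, byrow = TRUE)
  list(prevalence_tp = ptp, prevalence_fn = pfn,
       p_value = stats::fisher.test(tab)$p.value, flagged = FALSE)
}
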