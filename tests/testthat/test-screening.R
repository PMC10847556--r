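test_that("fold plans partition participants with even stenosis stratification", {
  ids <- sprintf("P%04d", 1:2124)
  as_pos <- rep(FALSE, 2124); as_pos[sample(2124, 45)] <- TRUE
  plan <- make_folds(ids, as_pos, n_folds = 8, holdout_frac = 0.10, seed = 3)
  expect_equal(sum(plan$holdout), 212)
  expect_true(all(is.na(plan$fold[plan$holdout])))
  expect_true(all(!is.na(plan$fold[!plan$holdout])))
  expect_setequal(plan$participant_id, ids)
  counts <- table(plan$fold[as_pos & !plan$holdout])
  expect_lte(diff(range(counts)), 1)
  expect_identical(plan, make_folds(ids, as_pos, 8, 0.10, seed = 3))

  # divisible case: 40 positives over 8 folds, no holdout -> exactly 5 each
  ids2 <- sprintf("Q%03d", 1:400)
  pos2 <- rep(c(TRUE, FALSE), c(40, 360))
  plan2 <- make_folds(ids2, pos2, 8, holdout_frac = 0, seed = 1)
  expect_true(all(table(plan2$fold[pos2]) == 5))

  expect_error(make_folds(ids[1:5], as_pos[1:5], 8), "fewer participants")
})

test_that("threshold selection matches exhaustive search on random instances", {
  set.seed(23)
  checked <- 0
  for (rep in 1:200) {
    n <- 30
    scores <- round(rnorm(n), 2)
    labels <- runif(n) < plogis(scores)
    if (!any(labels) || all(labels)) next
    ref <- threshold_bruteforce(scores, labels)
    if (is.null(ref)) next
    got <- select_threshold(scores, labels)
    expect_equal(got$threshold, ref$thr, tolerance = 1e-12)
    expect_equal(got$sensitivity, ref$sens, tolerance = 1e-12)
    expect_equal(got$specificity, ref$spec, tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gt(checked, 100)
})

test_that("the sensitivity constraint overrides the unconstrained optimum", {
  # unconstrained optimum is a cut above 5 (sens 0.4, spec 1); the returned
  # threshold must differ and satisfy the sensitivity constraint
  scores <- c(1, 2, 3, 4, 5, 10, 11, 0.1, 0.2, 0.3)
  labels <- c(F, F, F, F, F, T, T, T, T, T)
  got <- select_threshold(scores, labels)
  expect_gt(got$sensitivity, 0.5)
  expect_lt(got$threshold, 1)
  # and on a perfectly separated instance both rates are 1
  sep <- select_threshold(c(1, 2, 3, 7, 8, 9), c(F, F, F, T, T, T))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
})

test_that("joint screening definitions classify the worked cases", {
  echo <- data.frame(as_grade = c(0, 0, 1), ms_grade = 0,
                     ar_grade = 0, mr_grade = c(3, 0, 0),
                     breathless_rest = FALSE, breathless_level = FALSE,
                     mmrc = 0)
  for (d in 1:3) {
    js <- joint_screen(echo, c(2, 2, 2), d)
    expect_equal(js$positive_class[2], FALSE)           # all grades 0
    expect_equal(js$positive_class[3], TRUE)            # stenosis, any def
  }
  expect_true(joint_screen(echo, c(2, 2, 2), 1)$positive_class[1])
  expect_false(joint_screen(echo, c(2, 2, 2), 2)$positive_class[1])
  expect_false(joint_screen(echo, c(2, 2, 2), 3)$positive_class[1])
})

test_that("the symptomatic definition covers rest, level ground and mMRC", {
  tbl <- data.frame(breathless_rest = c(TRUE, FALSE, FALSE, FALSE, NA),
                    breathless_level = c(FALSE, TRUE, FALSE, FALSE, FALSE),
                    mmrc = c(0, 0, 2, 1, NA))
  expect_equal(symptomatic_status(tbl), c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("Fisher p-values match hypergeometric enumeration", {
  tab <- matrix(c(10, 5, 2, 30), 2, byrow = TRUE)
  got <- symptom_subgroup_test(rep(c(TRUE, FALSE), c(10, 5)),
                               rep(c(TRUE, FALSE), c(2, 30)))
  expect_equal(got$p_value, fisher_enumeration(tab), tolerance = 1e-12)
  expect_equal(got$prevalence_tp, 10 / 15)
  expect_equal(got$prevalence_fn, 2 / 32)

  even <- symptom_subgroup_test(rep(c(TRUE, FALSE), 5), rep(c(TRUE, FALSE), 5))
  expect_equal(even$p_value, 1)

  set.seed(31)
  for (rep in 1:20) {
    a <- runif(15) < 0.4; b <- runif(20) < 0.4
    p <- symptom_subgroup_test(a, b)$p_value
    expect_gte(p, 0); expect_lte(p, 1)
  }
  expect_true(symptom_subgroup_test(logical(0), c(TRUE))$flagged)
})

test_that("mode imputation fills categorical gaps with the most frequent answer", {
  x <- c(TRUE, TRUE, FALSE, NA, TRUE, NA)
  expect_identical(impute_mode(x), c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(impute_mode(c(2, 2, 3, NA)), c(2, 2, 3, 2))
  expect_error(impute_mode(c(NA, NA)), "all values missing")
})

make_clinical_cohort <- function(n, seed, beta) {
  set.seed(seed)
  tbl <- data.frame(
    age = rnorm(n, 65, 9), female = runif(n) < 0.5,
    heart_rate = rnorm(n, 65, 9),
    breathless_uphill = runif(n) < 0.3,
    breathless_rest = FALSE, breathless_level = FALSE, mmrc = 0,
    ms_grade = 0, as_grade = 0, mr_grade = 0)
  murmur <- pmax(0, rnorm(n, 1, 1))
  eta <- beta[1] + beta[2] * murmur + beta[3] * (tbl$age - 65) / 10 +
    beta[4] * tbl$female + beta[5] * tbl$breathless_uphill +
    beta[6] * (tbl$heart_rate - 65) / 10
  tbl$ar_grade <- ifelse(runif(n) < plogis(eta), 3, 0)
  list(tbl = tbl, murmur = murmur)
}

test_that("logistic recovery: known coefficients within two standard errors", {
  beta <- c(-2.5, 0.8, 0.5, -0.4, 0.7, -0.3)
  cc <- make_clinical_cohort(2000, 41, beta)
  fit <- fit_clinical_model("AR", cc$tbl, cc$murmur)
  est <- fit$coefficients
  se <- fit$se
  truth <- c(`(Intercept)` = beta[1] - beta[3] * 6.5 - beta[6] * 6.5,
             murmur = beta[2], age = beta[3] / 10,
             femaleTRUE = beta[4], breathless_uphillTRUE = beta[5],
             heart_rate = beta[6] / 10)
  for (nm in names(truth))
    expect_lt(abs(est[[nm]] - truth[[nm]]), 2 * se[[nm]])
})

test_that("clinical model covariate lists follow the per-target formulas", {
  cc <- make_clinical_cohort(600, 43, c(-2, 1, 0.4, 0, 0.5, -0.2))
  tbl <- cc$tbl
  tbl$mr_grade <- tbl$ar_grade
  tbl$ms_grade <- ifelse(runif(600) < plogis(-3 + cc$murmur), 1, 0)
  tbl$as_grade <- tbl$ms_grade
  mr <- fit_clinical_model("MR", tbl, cc$murmur)
  expect_setequal(names(mr$coefficients),
                  c("(Intercept)", "murmur", "age", "heart_rate"))
  as_fit <- fit_clinical_model("AS", tbl, cc$murmur)
  expect_true("murmur:femaleTRUE" %in% names(as_fit$coefficients))
  ms <- fit_clinical_model("MS", tbl, cc$murmur)
  expect_setequal(names(ms$coefficients),
                  c("(Intercept)", "murmur", "age", "heart_rate"))
})

test_that("missing answers are imputed so the fitted n equals the cohort n", {
  cc <- make_clinical_cohort(500, 47, c(-2, 1, 0.4, 0, 0.5, -0.2))
  tbl <- cc$tbl
  tbl$breathless_uphill[sample(500, 20)] <- NA
  tbl$heart_rate[sample(500, 20)] <- NA
  fit <- fit_clinical_model("AR", tbl, cc$murmur)
  expect_equal(fit$n, 500)
  expect_equal(nobs(fit$fit), 500)
})

test_that("informative clinical covariates raise CV AUC over weak audio alone", {
  # AR-like scenario: weak murmur signal, informative age and breathlessness
  beta <- c(-2.8, 0.25, 0.9, 0, 1.2, 0)
  cc <- make_clinical_cohort(2000, 53, beta)
  folds <- rep_len(1:4, 2000)[sample(2000)]
  auc_audio <- auc_fused <- numeric(4)
  for (f in 1:4) {
    tr <- folds != f
    fit <- fit_clinical_model("AR", cc$tbl[tr, ], cc$murmur[tr])
    pr <- predict(fit$fit, newdata = data.frame(
      murmur = cc$murmur[!tr], age = cc$tbl$age[!tr],
      female = cc$tbl$female[!tr],
      breathless_uphill = cc$tbl$breathless_uphill[!tr],
      heart_rate = cc$tbl$heart_rate[!tr]), type = "response")
    lab <- cc$tbl$ar_grade[!tr] >= 3
    auc_fused[f] <- roc_auc(pr, lab)
    auc_audio[f] <- roc_auc(cc$murmur[!tr], lab)
  }
  expect_gt(mean(auc_fused), mean(auc_audio))
})
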