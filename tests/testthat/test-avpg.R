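test_that("the printed multiposition model evaluates as published", {
  m <- avpg_preset_model()
  expect_identical(evaluate_avpg(m, c(0, 0, 0, 0)), 3.5)
  expect_equal(evaluate_avpg(m, c(2, 1, 1, 0)), 3.5 + 0.6 * 4 + 1.1 + 0.5)
  # three noisy positions: only the triple-noise mitral term survives
  expect_equal(evaluate_avpg(m, c(2, 0, 0, 1.5), c(1, 1, 1, 0)),
               3.5 + 8.9 * 1.5)
  expect_error(evaluate_avpg(m, c(1, 1, 1, 1), c(1, 1, 1, 1)),
               class = "pcg_all_noisy")
})

test_that("evaluation is linear in the coefficients", {
  t_set <- list(c("MG_A", "MG_A"), "MG_T", c("MG_M", "noise_A"))
  c1 <- c(0.3, 1.2, -0.5); c2 <- c(1.1, 0.2, 2.0)
  mg <- c(1.5, 0.7, 2.2, 0.4); nz <- c(1, 0, 0, 0)
  v1 <- evaluate_avpg(linear_model_spec(t_set, c1, 1), mg, nz)
  v2 <- evaluate_avpg(linear_model_spec(t_set, c2, 2), mg, nz)
  v12 <- evaluate_avpg(linear_model_spec(t_set, c1 + c2, 3), mg, nz)
  expect_equal(v12, v1 + v2, tolerance = 1e-12)
})

make_avpg_data <- function(n, seed, gen = function(d) rnorm(n)) {
  set.seed(seed)
  d <- data.frame(MG_A = runif(n, 0, 4), MG_P = runif(n, 0, 4),
                  MG_T = runif(n, 0, 4), MG_M = runif(n, 0, 4),
                  noise_A = 0, noise_P = 0, noise_T = 0, noise_M = 0)
  d$avpg_mean <- gen(d)
  d
}

test_that("least squares recovers an exact linear signal and its BIC closed form", {
  d <- make_avpg_data(200, 1, function(d) 2 + 1.0 * d$MG_A^2)
  f <- fit_avpg_ols(list(c("MG_A", "MG_A")), d)
  expect_equal(unname(f$spec$coefficients), 1, tolerance = 1e-9)
  expect_equal(unname(f$spec$intercept), 2, tolerance = 1e-9)
  expect_lt(f$rss, 1e-16)

  d2 <- make_avpg_data(500, 2, function(d) 2 + d$MG_A^2 + rnorm(500))
  f2 <- fit_avpg_ols(list(c("MG_A", "MG_A"), "MG_T"), d2)
  k <- 2 + 2
  expect_equal(f2$bic, 500 * log(f2$rss / 500) + k * log(500),
               tolerance = 1e-9)
  # residual orthogonality to the design
  expect_lt(max(abs(crossprod(f2$design, f2$residuals))), 1e-8)
})

test_that("simulated quadratic coefficients are recovered within two standard errors", {
  hit <- 0
  for (s in 1:20) {
    d <- make_avpg_data(1000, 100 + s,
                        function(d) 2 + 1.0 * d$MG_A^2 + rnorm(1000))
    f <- fit_avpg_ols(list(c("MG_A", "MG_A")), d)
    if (abs(f$spec$coefficients[1] - 1) <= 2 * f$se[2]) hit <- hit + 1
  }
  expect_gte(hit, 19)
})

test_that("rank-deficient designs are rejected with the offending terms named", {
  d <- make_avpg_data(100, 3)
  expect_error(fit_avpg_ols(list("MG_A", "MG_A"), d), "collinear")
  d$MG_P <- d$MG_A
  expect_error(fit_avpg_ols(list("MG_A", "MG_P"), d), "collinear")
})

test_that("stepwise selection recovers the generating terms and is deterministic", {
  hits <- 0
  for (s in 1:10) {
    d <- make_avpg_data(1000, 200 + s,
                        function(d) 2 + d$MG_A^2 + 0.5 * d$MG_T + rnorm(1000))
    sel <- stepwise_select(d)
    ids <- vapply(sel$terms, function(t) paste(sort(t), collapse = ":"), "")
    if (all(c("MG_A:MG_A", "MG_T") %in% ids)) hits <- hits + 1
  }
  expect_gte(hits, 8)

  d <- make_avpg_data(1000, 250,
                      function(d) 2 + d$MG_A^2 + 0.5 * d$MG_T + rnorm(1000))
  a <- stepwise_select(d); b <- stepwise_select(d)
  expect_identical(a$terms, b$terms)
})

test_that("a pure-noise response yields an intercept-dominant model", {
  lean <- 0
  for (s in 1:10) {
    d <- make_avpg_data(1000, 300 + s, function(d) rnorm(1000))
    sel <- stepwise_select(d)
    if (length(sel$terms) <= 1) lean <- lean + 1
  }
  expect_gte(lean, 8)
})

test_that("the selected model is locally optimal in BIC", {
  d <- make_avpg_data(800, 400,
                      function(d) 2 + d$MG_A^2 + 0.5 * d$MG_T + rnorm(800))
  sel <- stepwise_select(d)
  bic0 <- sel$fit$bic
  expect_true(is.finite(bic0))
  expect_gte(length(sel$terms), 1)
  ids <- vapply(sel$terms, function(t) paste(sort(t), collapse = ":"), "")
  pool <- c(list("MG_A", "MG_P", "MG_T", "MG_M"),
            list(c("MG_A", "MG_A"), c("MG_P", "MG_P"),
                 c("MG_T", "MG_T"), c("MG_M", "MG_M")))
  # no admissible single move (significant addition or p>alpha removal)
  # may lower the BIC below the selected model's
  neighbour_bics <- c()
  for (tm in pool) {
    if (paste(sort(tm), collapse = ":") %in% ids) next
    f <- tryCatch(fit_avpg_ols(c(sel$terms, list(tm)), d),
                  error = function(e) NULL)
    p_new <- if (is.null(f)) NA else f$p_values[length(f$p_values)]
    if (!is.null(f) && is.finite(p_new) && p_new < 0.05)
      neighbour_bics <- c(neighbour_bics, f$bic)
  }
  for (j in seq_along(sel$terms)) {
    if (sel$fit$p_values[-1][j] <= 0.05) next
    f <- tryCatch(fit_avpg_ols(sel$terms[-j], d), error = function(e) NULL)
    if (!is.null(f)) neighbour_bics <- c(neighbour_bics, f$bic)
  }
  expect_true(all(neighbour_bics >= bic0 - 1e-9))
})

test_that("the threshold sweep behaves at the extremes and under permutation", {
  set.seed(11)
  avpg <- c(runif(450, 3, 12), runif(50, 15, 60))
  sw <- threshold_sweep_auc(avpg, avpg, thresholds = 7:30, n_boot = 200)
  expect_true(all(sw$auc == 1))
  expect_true(all(sw$ci_low <= sw$auc & sw$auc <= sw$ci_high))

  perm <- sample(avpg)
  sw2 <- threshold_sweep_auc(perm, avpg, thresholds = 10, n_boot = 200)
  expect_gt(sw2$auc, 0.4)
  expect_lt(sw2$auc, 0.6)

  expect_warning(
    threshold_sweep_auc(avpg[1:450], avpg[1:450], thresholds = c(10, 29)),
    "skipped")
})
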