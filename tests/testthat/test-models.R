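# eating-quality regression: fitting, subset selection, published models

test_that("fit_ols recovers a noiseless linear signal exactly", {
  set.seed(41)
  df <- data.frame(viscosity = rnorm(50), appearance = rnorm(50),
                   taste = rnorm(50))
  df$IVOE <- 0.20 * df$viscosity + 0.35 * df$appearance + 0.59 * df$taste + 0.13
  m <- fit_ols(df, "IVOE", c("viscosity", "appearance", "taste"))
  expect_equal(unname(m$coefficients), c(0.20, 0.35, 0.59), tolerance = 1e-10)
  expect_equal(m$intercept, 0.13, tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-12)
})

test_that("independent noise gives near-zero R2 at large n", {
  set.seed(42)
  df <- data.frame(x1 = rnorm(1000), x2 = rnorm(1000), y = rnorm(1000))
  m <- fit_ols(df, "y", c("x1", "x2"))
  expect_lt(m$r2, 0.02)
})

test_that("residuals are orthogonal to every predictor (normal equations)", {
  set.seed(43)
  df <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  df$y <- df$a - 2 * df$b + rnorm(40)
  m <- fit_ols(df, "y", c("a", "b", "c"))
  res <- stats::residuals(m$fit)
  for (v in c("a", "b", "c")) {
    expect_lt(abs(sum(res * df[[v]])), 1e-8)
  }
})

test_that("degenerate designs are rejected with the offending columns named", {
  set.seed(44)
  df <- data.frame(a = rnorm(20), b = 1, y = rnorm(20))
  expect_error(fit_ols(df, "y", c("a", "b")), "constant.*b",
               class = "riceval_input_error")
  df2 <- data.frame(a = rnorm(20), y = rnorm(20))
  df2$a2 <- 2 * df2$a
  expect_error(fit_ols(df2, "y", c("a", "a2")), "collinear",
               class = "riceval_input_error")
  expect_error(fit_ols(df2[1:3, ], "y", c("a", "a2")), "n > p",
               class = "riceval_input_error")
})

test_that("tidy and glance expose broom-style summaries", {
  set.seed(45)
  df <- data.frame(x = rnorm(30))
  df$y <- 2 * df$x + rnorm(30)
  m <- fit_ols(df, "y", "x")
  td <- tidy(m)
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$nobs, 30)
  # published constants tidy without fit statistics
  td4 <- tidy(ivoe_model(4))
  expect_equal(td4$estimate, c(-0.34, 0.37, -0.71, 0.89))
})

test_that("best_subset enumerates exhaustively and finds planted predictors", {
  set.seed(46)
  n <- 80
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("x", 1:6)))
  y <- 1.5 * X[, 3] + rnorm(n, 0, 0.3)   # x3 is the one real predictor
  df <- data.frame(X, y = y)
  sel <- best_subset(df, "y", paste0("x", 1:6))
  expect_equal(sel$predictors[[1]], "x3")   # size-1 winner
  # with the R2 criterion the overall winner is always the full model
  expect_true(sel$best[sel$size == 6])
  # 3 predictors -> exactly 7 non-empty subsets
  sel3 <- best_subset(df, "y", paste0("x", 1:3))
  expect_equal(sum(choose(3, 1:3)), 7)
  expect_equal(nrow(sel3), 3)
  expect_error(best_subset(data.frame(matrix(rnorm(30 * 21), 30, 21), y = rnorm(30)),
                           "y"), "20", class = "riceval_config_error")
})

test_that("best_subset per-size winners match the brute-force QR oracle", {
  set.seed(47)
  for (i in 1:5) {
    n <- 60
    p <- 8
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    beta <- rnorm(p) * rbinom(p, 1, 0.5)
    y <- X %*% beta + rnorm(n)
    df <- data.frame(X, y = as.vector(y))
    sel <- best_subset(df, "y", paste0("x", 1:p))
    for (k in c(1, 3, 5, 8)) {
      orc <- oracle_best_subset_r2(X, y, k)
      expect_equal(sel$r2[sel$size == k], orc$r2, tolerance = 1e-10)
      expect_setequal(sel$predictors[[k]], paste0("x", orc$set))
    }
  }
})

test_that("adjusted criteria can prefer smaller subsets than raw R2", {
  set.seed(48)
  n <- 60
  df <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                   n3 = rnorm(n), n4 = rnorm(n))
  df$y <- df$signal + rnorm(n, 0, 0.2)
  sel_bic <- best_subset(df, "y", criterion = "bic")
  expect_equal(sel_bic$predictors[[which(sel_bic$best)]], "signal")
})

test_that("published model constants give the printed intercepts at zero features", {
  zero4 <- data.frame(adhesiveness = 0, yellow_area = 0, taste = 0)
  expect_identical(predict_ivoe(zero4, ivoe_model("model4"))$.pred, -0.34)
  zero1 <- data.frame(viscosity = 0, appearance = 0, taste = 0)
  expect_identical(predict_ivoe(zero1, ivoe_model("model1"))$.pred, 0.13)
  # hand arithmetic on the Model 4 coefficients
  feat <- data.frame(adhesiveness = 1, yellow_area = 0.1, taste = 0.5)
  expect_equal(predict_ivoe(feat, ivoe_model(4))$.pred,
               0.37 - 0.071 + 0.445 - 0.34, tolerance = 1e-12)
})

test_that("predict_ivoe is linear and errors on missing predictors/units", {
  m <- ivoe_model(4)
  a <- data.frame(adhesiveness = 2, yellow_area = 10, taste = 1)
  b <- data.frame(adhesiveness = 5, yellow_area = 3, taste = -1)
  pa <- predict_ivoe(a, m)$.pred
  pb <- predict_ivoe(b, m)$.pred
  psum <- predict_ivoe(a + b, m)$.pred
  expect_equal(psum, pa + pb - m$intercept, tolerance = 1e-12)

  expect_error(predict_ivoe(a[-1], m), "adhesiveness",
               class = "riceval_input_error")
  expect_error(
    predict_ivoe(a, m, units = c(yellow_area = "fraction of pixels")),
    "unit mismatch", class = "riceval_config_error"
  )
  expect_silent(predict_ivoe(a, m, units = m$units))
})

test_that("round-trip fit on noiseless Model-4 data recovers the constants", {
  set.seed(49)
  df <- data.frame(adhesiveness = runif(60, 0, 5),
                   yellow_area = runif(60, 5, 62), taste = runif(60, -3, 1))
  df$IVOE <- predict_ivoe(df, ivoe_model(4))$.pred
  m <- fit_ols(df, "IVOE", c("adhesiveness", "yellow_area", "taste"))
  expect_equal(unname(m$coefficients), c(0.37, -0.71, 0.89), tolerance = 1e-7)
  expect_equal(m$intercept, -0.34, tolerance = 1e-7)
})

test_that("evaluate_predictions reports correlation-based agreement", {
  set.seed(50)
  obs <- rnorm(40)
  same <- data.frame(obs = obs, .pred = obs)
  expect_equal(evaluate_predictions(same, "obs")$r2, 1, tolerance = 1e-12)
  # affine invariance of the correlation-based R2
  aff <- data.frame(obs = obs, .pred = 3 * obs - 2)
  ev <- evaluate_predictions(aff, "obs")
  expect_equal(ev$r2, 1, tolerance = 1e-12)
  expect_equal(ev$slope, 1 / 3, tolerance = 1e-10)
  expect_warning(evaluate_predictions(data.frame(obs = obs, .pred = 1),
                                      "obs"), "zero variance")
})

test_that("synthetic panels reproduce the generating fit quality", {
  sim <- simulate_panel(n_varieties = 322, n_reps = 1, seed = 51)
  wide <- panel_to_wide(sim$data)
  m <- fit_ols(wide, "IVOE", c("viscosity", "appearance", "taste"))
  # per-variety averaging reduces the IVOE noise, so fit R2 should be at
  # least the generating signal fraction
  expect_gt(m$r2, 0.75)
  expect_equal(unname(m$coefficients), c(0.20, 0.35, 0.59), tolerance = 0.15)
  pred <- predict_ivoe(wide, m)
  ev <- evaluate_predictions(pred, "IVOE")
  expect_equal(ev$r2, m$r2, tolerance = 1e-10)
})
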