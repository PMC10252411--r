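test_that("an exact single-predictor relation is recovered perfectly", {
  x <- matrix(seq(-2, 2, length.out = 10), ncol = 1,
              dimnames = list(NULL, "x"))
  fit <- fit_pls1(x, 3 * x[, 1], n_factors = 1)
  expect_equal(fit$r2, 1)
  expect_equal(unname(fit$b_raw), 3)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
})

test_that("full-rank PLS predictions match an OLS normal-equations oracle", {
  for (seed in 1:12) {
    prob <- random_regression(seed)
    fit <- fit_pls1(prob$X, prob$y, n_factors = prob$p)
    # independent oracle: centered normal equations solved directly
    Xc <- scale(prob$X, scale = FALSE)
    yc <- prob$y - mean(prob$y)
    beta <- solve(crossprod(Xc), crossprod(Xc, yc))
    pred_ols <- drop(Xc %*% beta) + mean(prob$y)
    expect_equal(predict(fit, prob$X), pred_ols, tolerance = 1e-8,
                 info = paste("seed", seed))
    expect_equal(unname(fit$b_raw), unname(drop(beta)), tolerance = 1e-8)
  }
})

test_that("coefficient prediction equals the factor expansion", {
  prob <- random_regression(42)
  fit <- fit_pls1(prob$X, prob$y, n_factors = 2)
  via_factors <- fit$y_mean + drop(fit$t_scores %*% fit$q_loadings)
  expect_equal(fit$fitted, via_factors, tolerance = 1e-10)
})

test_that("score columns are mutually orthogonal", {
  for (seed in c(2, 17, 33)) {
    prob <- random_regression(seed)
    fit <- fit_pls1(prob$X, prob$y, n_factors = prob$p)
    G <- crossprod(fit$t_scores)
    off <- max(abs(G[upper.tri(G)])) / max(diag(G))
    expect_lt(off, 1e-8)
  }
})

test_that("degenerate predictor blocks are rejected, not silently truncated", {
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(10)
  xz <- x; xz[, 2] <- 5
  expect_error(fit_pls1(xz, y, 2), "zero-variance column.*b")
  expect_error(fit_pls1(x, y, 4), "n_factors")
  xdup <- cbind(x, d = x[, 1])  # rank 3, 4 columns
  expect_error(fit_pls1(xdup, y, 4), "exhausted")
  expect_silent(fit_pls1(xdup, y, 3))
  expect_error(fit_pls1(x[1:2, ], y[1:2], 1), "at least 3")
  xna <- x; xna[1, 1] <- NA
  expect_error(fit_pls1(xna, y, 2), "missing values")
})

test_that("explained variance behaves at the rank-1 and null limits", {
  # rank-1 X: one factor captures all X variance
  v <- rnorm(4); t1 <- rnorm(15)
  x1 <- tcrossprod(t1, v) + 0  # noiseless rank-1
  colnames(x1) <- paste0("v", 1:4)
  fit1 <- fit_pls1(x1, t1 + rnorm(15, sd = 0.1), n_factors = 1,
                   autoscale = FALSE)
  expect_equal(fit1$explained_variance_x[1], 100, tolerance = 1e-6)

  # response orthogonal to the X column space: ~no y variance explained
  set.seed(8)
  xo <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  yo <- residuals(lm(rnorm(20) ~ xo))
  fito <- fit_pls1(xo, yo, n_factors = 2)
  expect_lt(sum(fito$explained_variance_y), 1e-6)

  # cumulative y variance is non-decreasing and bounded by 100
  for (seed in c(3, 9)) {
    prob <- random_regression(seed)
    fit <- fit_pls1(prob$X, prob$y, n_factors = prob$p)
    ev <- explained_variance(fit)
    expect_true(all(diff(ev$y_cumulative) >= -1e-10))
    expect_lte(max(ev$x_cumulative, ev$y_cumulative), 100 + 1e-8)
    expect_true(all(ev$x_variance >= 0 & ev$y_variance >= 0))
  }
})

test_that("factor selection stops at the RMSECV plateau", {
  expect_equal(select_n_factors(c(1, 1, 1)), 1)
  expect_equal(select_n_factors(c(1.0, 0.5, 0.499, 0.498)), 2)
  expect_equal(select_n_factors(c(3, 2, 1)), 3)
  expect_equal(select_n_factors(0.7), 1)
})

test_that("cross-validation is seeded, exhaustive and exact in the noiseless limit", {
  set.seed(21)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, -2, 0.5))
  cv1 <- cross_validate(X, y, n_factors = 3, n_segments = 5, seed = 99)
  cv2 <- cross_validate(X, y, n_factors = 3, n_segments = 5, seed = 99)
  expect_identical(cv1$segments, cv2$segments)
  expect_equal(cv1$metrics, cv2$metrics)
  expect_lt(cv1$metrics$rmsecv, 1e-6)   # noiseless linear data

  # leave-one-out: every segment has exactly one sample
  loo <- cross_validate(X, y, n_factors = 2, n_segments = 20, seed = 1)
  expect_equal(sort(unique(loo$segments)), 1:20)
  expect_equal(max(table(loo$segments)), 1)
  expect_error(cross_validate(X, y, 2, n_segments = 21), "n_segments")
  expect_error(cross_validate(X, y, 2, n_segments = 1), "n_segments")

  # with centered residuals sec carries exactly the n/(n-1) df correction,
  # so it sits just above rmsec
  yn <- y + rnorm(20, sd = 0.3)
  cvn <- cross_validate(X, yn, n_factors = 3, n_segments = 5, seed = 2)
  m <- cvn$metrics
  expect_gt(m$sec, m$rmsec)
  expect_equal(m$sec, m$rmsec * sqrt(20 / 19), tolerance = 1e-6)
})

test_that("jackknife limits collapse to the point when submodels agree", {
  prob <- random_regression(5)
  fit <- fit_pls1(prob$X, prob$y, n_factors = 2)
  ja <- jackknife_uncertainty(fit, list(fit, fit, fit))
  expect_equal(ja$se, rep(0, prob$p))
  expect_true(all(ja$significant[abs(ja$coefficient) > 0]))
  expect_true(all(ja$lower <= ja$coefficient & ja$coefficient <= ja$upper))
  expect_error(jackknife_uncertainty(fit, list(fit)), "at least 2")
})

test_that("jackknife screening separates informative from noise variables", {
  eqt <- balanced_equation(effect = 1)
  vars <- names(eqt$coefficients)
  hits <- 0; rejections <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    cfg <- synthetic_config(n_samples = 60, seed = 2000 + r,
                            true_equation = eqt, panel_noise_sd = 0.5)
    chem <- generate_chemistry(cfg)
    y <- generate_panel_scores(chem, cfg)
    X <- as.matrix(chem[, vars])
    set.seed(3000 + r)
    X <- cbind(X, noise1 = rnorm(60), noise2 = rnorm(60))
    cv <- cross_validate(X, y, n_factors = 5, n_segments = 20,
                         seed = 4000 + r)
    ja <- jackknife_uncertainty(cv$full, cv$submodels, alpha = 0.05)
    hits <- hits + sum(ja$significant[seq_along(vars)])
    rejections <- rejections + sum(!ja$significant[length(vars) + 1:2])
  }
  expect_gte(hits / (n_rep * length(vars)), 0.9)
  expect_gte(rejections / (n_rep * 2), 0.9)
})

test_that("a constructed 10-SD outlier is flagged by the T2 screen", {
  cfg <- synthetic_config(n_samples = 40, seed = 7)
  chem <- inject_outliers(generate_chemistry(cfg), 1, displacement = 10,
                          seed = 9)
  y <- generate_panel_scores(chem, cfg)
  vars <- dryness_model_variables("model3")
  fit <- fit_pls1(chem[, vars], y, n_factors = 2)
  screen <- hotelling_t2(fit, alpha = 0.05, ids = chem$sample_id)
  injected <- attr(chem, "outlier_ids")
  expect_true(injected %in% screen$flagged)
  expect_equal(names(which.max(screen$t2)), injected)
  expect_true(all(screen$t2 >= 0))
  expect_setequal(screen$flagged,
                  screen$ids[screen$t2 > screen$critical])

  # flagging is invariant to sample order
  set.seed(31)
  perm <- sample(40)
  fitp <- fit_pls1(chem[perm, vars], y[perm], n_factors = 2)
  screenp <- hotelling_t2(fitp, alpha = 0.05, ids = chem$sample_id[perm])
  expect_setequal(screenp$flagged, screen$flagged)
})
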