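test_that("linear least squares recovers exact and noisy coefficients", {
  set.seed(110)
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  beta <- c(2, -1, 0.5, 3)
  y <- 1.5 + X %*% beta
  m <- fit_linear(X, y, intercept = TRUE)
  expect_equal(unname(m$coef), c(1.5, beta), tolerance = 1e-10)
  expect_lt(max(abs(predict(m, X) - y)), 1e-9)

  ## normal-equation oracle on noisy data
  y2 <- y + rnorm(50)
  m2 <- fit_linear(X, y2, intercept = TRUE)
  Xa <- cbind(1, X)
  expect_equal(unname(m2$coef), as.numeric(solve(crossprod(Xa), crossprod(Xa, y2))),
               tolerance = 1e-10)

  ## rank-deficient design warns and returns the minimum-norm solution
  Xr <- cbind(X, x5 = X[, 1] + X[, 2])
  expect_warning(fit_linear(Xr, y2), "rank-deficient")

  expect_error(fit_linear(X[1:4, ], y2[1:4]), "N > K")
})

test_that("SCS mode recovers unit coefficients when the label is the component sum", {
  ## independent random systems give a well-conditioned component design
  X <- t(sapply(1:25, function(s) {
    sd <- random_sysdata(500 + s)
    blocks <- integral_blocks_from_df(sd$df)
    t1 <- first_order_amplitudes(sd$system, blocks$g_oovv)
    mp3_components(t1, blocks)
  }))
  y <- rowSums(X)
  m <- fit_linear(X, y, intercept = FALSE)
  expect_equal(unname(m$coef), rep(1, 10), tolerance = 1e-8)
})

test_that("KRR solves the dual system and interpolates at zero ridge", {
  set.seed(112)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- rnorm(30)
  m <- fit_krr(X, y, alpha = 1e-3, gamma = 0.5)
  ## closed-form dense solve oracle
  K <- exp(-0.5 * as.matrix(dist(X))^2)
  w_or <- solve(K + 1e-3 * diag(30), y)
  expect_equal(m$dual_weights, as.numeric(w_or), tolerance = 1e-10)

  ## alpha = 0 with distinct, well-separated points reproduces the labels
  Xi <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(NULL, paste0("V", 1:3)))
  yi <- rnorm(15)
  m0 <- fit_krr(Xi, yi, alpha = 0, gamma = 1)
  m0$feature_names <- paste0("V", 1:3)
  expect_equal(predict(m0, Xi), yi, tolerance = 1e-8)
  colnames(X) <- paste0("V", 1:3)

  ## infinite-ridge limit predicts the training-label mean in original units
  sx <- fit_scaler(X); sy <- fit_scaler(matrix(y))
  mi <- fit_krr(apply_scaler(X, sx), as.numeric(apply_scaler(matrix(y), sy)),
                alpha = 1e9, gamma = 0.5)
  mi$scaler_x <- sx; mi$scaler_y <- sy; mi$feature_names <- paste0("V", 1:3)
  expect_equal(predict(mi, X), rep(mean(y), 30), tolerance = 1e-6)
})

test_that("error metrics match their definitions and the MAPE exclusion rule", {
  expect_equal(unlist(error_metrics(c(1, 2), c(1, 2)))[1:3],
               c(rmse = 0, mae = 0, mape = 0))
  m <- error_metrics(c(1, 2), c(2, 4))
  expect_equal(m$rmse, sqrt(2.5), tolerance = 1e-12)
  expect_equal(m$mae, 1.5)
  expect_equal(m$mape, 100)
  ## loop oracle on random vectors
  set.seed(113)
  y <- rnorm(40); yh <- rnorm(40)
  mm <- error_metrics(y, yh)
  rmse_or <- 0; mae_or <- 0; mape_or <- 0
  for (i in 1:40) {
    rmse_or <- rmse_or + (y[i] - yh[i])^2 / 40
    mae_or <- mae_or + abs(y[i] - yh[i]) / 40
    mape_or <- mape_or + 100 * abs((y[i] - yh[i]) / y[i]) / 40
  }
  expect_equal(mm$rmse, sqrt(rmse_or), tolerance = 1e-13)
  expect_equal(mm$mae, mae_or, tolerance = 1e-13)
  expect_equal(mm$mape, mape_or, tolerance = 1e-12)
  ## zeros are excluded from MAPE with a logged count
  mz <- error_metrics(c(0, 1), c(0.5, 2))
  expect_equal(mz$n_mape_excluded, 1)
  expect_equal(mz$mape, 100)
})

test_that("percent improvement follows its definition and reporting convention", {
  expect_equal(pct_improvement(0.1337, 0.0517), 61.3313, tolerance = 1e-4)
  expect_equal(round_pct(pct_improvement(0.1337, 0.0517)), 61)
  expect_equal(round_pct(pct_improvement(0.1337, 0.0292)), 78)
  expect_equal(pct_improvement(0.5, 0.5), 0)
  expect_error(pct_improvement(0, 0.1), "> 0")
  expect_equal(round_pct(c(-0.5, 0.5, 1.49)), c(-1, 1, 1))  # half away from zero
})

test_that("hyperparameter tuning degrades nothing and honors a single-point grid", {
  cfg <- generator_config(seed = 114, c_true = rep(0, 3), bump_amplitude = 2,
                          bump_bandwidth = 1, noise_sd = 0.05)
  d <- generate_planted_regression(cfg, 50, 3)
  single <- tune_hyperparameters(d$X, d$y, grid_alpha = 1e-2, grid_gamma = 1e-1,
                                 k = 5, seed = 1)
  expect_equal(c(single$alpha, single$gamma), c(1e-2, 1e-1))
  tn <- tune_hyperparameters(d$X, d$y, grid_alpha = 10^seq(-6, 0, 2),
                             grid_gamma = 10^seq(-3, 1, 2), k = 5, seed = 1)
  expect_lte(tn$loss, min(tn$trace$loss))   # refinement never degrades
  expect_error(tune_hyperparameters(d$X, d$y, numeric(0), 1), "empty grid")
})

test_that("cross-validation is deterministic and its bookkeeping is self-consistent", {
  cfg <- generator_config(seed = 115)
  suites <- lapply(generate_corpus(cfg, 40), thc_energy_suite, delta = 1)
  feats <- build_feature_table(suites)
  labels <- build_molecule_labels(suites, "delta_molecule")
  cv1 <- suppressWarnings(cross_validate(feats, labels, model_spec("mlr"),
                                         k = 5, seed = 9))
  cv2 <- suppressWarnings(cross_validate(feats, labels, model_spec("mlr"),
                                         k = 5, seed = 9))
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$predictions, cv2$predictions)

  ## mean RMSE equals recomputation from the stored per-fold predictions
  pr <- cv1$predictions
  rmse_manual <- mean(sapply(1:5, function(f) {
    sel <- pr$fold == f
    sqrt(mean((pr$y[sel] - pr$y_pred[sel])^2))
  }))
  expect_equal(unname(cv1$means["rmse"]), rmse_manual, tolerance = 1e-12)
  ## %IMP is consistent with its two inputs
  expect_equal(unname(cv1$pct_imp["rmse"]),
               pct_improvement(cv1$means[["base_rmse"]], cv1$means[["rmse"]]),
               tolerance = 1e-12)
})

test_that("KRR in the linear regime approaches MLR on planted linear data", {
  cfg <- generator_config(seed = 116, c_true = c(1.5, -2, 0.7), bump_amplitude = 0,
                          noise_sd = 0.1)
  d <- generate_planted_regression(cfg, 80, 3)
  ft <- data.frame(species_id = sprintf("p%03d", 1:80), d$X)
  lb <- data.frame(id = ft$species_id, y = d$y, y_base = 0)
  cvm <- suppressWarnings(cross_validate(ft, lb, model_spec("mlr"), k = 5, seed = 2))
  cvk <- suppressWarnings(cross_validate(ft, lb,
           model_spec("krr", alpha = 1e-6, gamma = 1e-4), k = 5, seed = 2))
  expect_lt(cvk$means["rmse"], cvm$means["rmse"] * 1.1)
})

test_that("models round-trip through JSON with bit-reproducible predictions", {
  set.seed(117)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rnorm(20)
  sx <- fit_scaler(X); sy <- fit_scaler(matrix(y))
  m <- fit_krr(apply_scaler(X, sx), as.numeric(apply_scaler(matrix(y), sy)),
               alpha = 1e-2, gamma = 0.3)
  m$scaler_x <- sx; m$scaler_y <- sy; m$feature_names <- colnames(X)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  Xnew <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, colnames(X)))
  expect_identical(predict(m, Xnew), predict(m2, Xnew))
  ## linear model too
  ml <- fit_linear(X, y)
  save_model(ml, path)
  expect_identical(predict(ml, Xnew), predict(load_model(path), Xnew))
  unlink(path)
})
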