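## SCS-style component scaling, multiple linear regression, RBF-kernel ridge
## regression, hyperparameter tuning, cross-validated evaluation, metrics.

#' Fit a linear model by least squares
#'
#' Minimizes the mean squared residual; with a rank-deficient design the
#' minimum-norm solution is returned with a warning. The SCS-style model is
#' this fit restricted to the ten MP3b diagram components, without intercept
#' and without feature scaling.
#'
#' @param X numeric design matrix (rows = observations).
#' @param y numeric response.
#' @param intercept include a fitted intercept.
#' @param rcond relative singular-value cutoff: directions of the design
#'   below `rcond * max(singular value)` are treated as numerically
#'   rank-deficient and excluded, giving the minimum-norm solution (with a
#'   warning). Keeps coefficient noise amplification bounded by `1/rcond`.
#' @return an object of class `thc_model` with `kind = "mlr"`.
#' @export
fit_linear <- function(X, y, intercept = TRUE, rcond = 1e-6) {
  X <- as.matrix(X)
  N <- nrow(X)
  Xa <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  if (N <= ncol(Xa))
    stop("fit_linear: need more observations than parameters (N > K)")
  sv <- svd(Xa)
  keep <- sv$d > max(sv$d) * rcond
  if (!all(keep))
    warning("fit_linear: numerically rank-deficient design; returning the minimum-norm solution")
  coef <- as.numeric(sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep]))
  names(coef) <- colnames(Xa)
  structure(list(kind = "mlr", coef = coef, intercept = intercept,
                 feature_names = colnames(X),
                 scaler_x = NULL, scaler_y = NULL),
            class = "thc_model")
}

## Squared-Euclidean cross-distance matrix.
sq_dist <- function(X1, X2) {
  d <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  pmax(d, 0)
}

rbf_kernel <- function(X1, X2, gamma) exp(-gamma * sq_dist(X1, X2))

#' Fit kernel ridge regression with an RBF kernel
#'
#' Solves `(K + alpha I) w = y` with `K[i,k] = exp(-gamma ||x_i - x_k||^2)`;
#' every training row is a support row. Inputs are expected already scaled
#' (see [fit_scaler()]); attach the scaler states afterwards for original-unit
#' prediction, as [cross_validate()] does.
#'
#' @param X_scaled scaled feature matrix.
#' @param y_scaled scaled response.
#' @param alpha ridge strength (on the scaled objective).
#' @param gamma RBF inverse squared length scale.
#' @return an object of class `thc_model` with `kind = "krr"`.
#' @export
fit_krr <- function(X_scaled, y_scaled, alpha, gamma) {
  X_scaled <- as.matrix(X_scaled)
  K <- rbf_kernel(X_scaled, X_scaled, gamma)
  A <- K + diag(alpha, nrow(K))
  w <- tryCatch(
    backsolve(chol(A), forwardsolve(t(chol(A)), y_scaled)),
    error = function(e) {
      warning("fit_krr: kernel system not positive definite; least-squares fallback")
      qr.solve(A, y_scaled)
    }
  )
  structure(list(kind = "krr", dual_weights = as.numeric(w),
                 support = X_scaled, alpha = alpha, gamma = gamma,
                 feature_names = colnames(X_scaled),
                 scaler_x = NULL, scaler_y = NULL),
            class = "thc_model")
}

#' Predict from a fitted model
#'
#' Applies the model's stored feature scaler (if any) to the new rows,
#' evaluates the model, and inverse-scales predictions to original units.
#'
#' @param object a `thc_model`.
#' @param newdata numeric matrix or data frame of raw feature rows with the
#'   model's feature columns.
#' @param ... unused.
#' @return numeric predictions in original label units.
#' @export
predict.thc_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  if (!is.null(object$scaler_x)) X <- apply_scaler(X, object$scaler_x)
  yhat <- if (object$kind == "krr") {
    as.numeric(rbf_kernel(X, object$support, object$gamma) %*% object$dual_weights)
  } else {
    cf <- object$coef
    if (object$intercept)
      as.numeric(cf[1] + X %*% cf[-1])
    else
      as.numeric(X %*% cf)
  }
  if (!is.null(object$scaler_y))
    yhat <- as.numeric(invert_scaler(matrix(yhat), object$scaler_y))
  yhat
}

#' @export
print.thc_model <- function(x, ...) {
  cat(sprintf("<thc_model> kind = %s, %d feature(s)", x$kind,
              length(x$feature_names)))
  if (x$kind == "krr")
    cat(sprintf(", alpha = %g, gamma = %g, %d support rows",
                x$alpha, x$gamma, nrow(x$support)))
  cat("\n")
  invisible(x)
}

#' Error metrics
#'
#' Root mean squared error, mean absolute error and mean absolute percent
#' error. Rows with `|y| <= tol_mape` are excluded from MAPE (which is
#' undefined at `y = 0`); the excluded count is reported.
#'
#' @param y reference values.
#' @param yhat predictions.
#' @param tol_mape exclusion threshold for MAPE, in label units.
#' @return named list `rmse`, `mae`, `mape` (percent), `n_mape_excluded`.
#' @export
error_metrics <- function(y, yhat, tol_mape = 1e-12) {
  if (length(y) != length(yhat)) stop("error_metrics: length mismatch")
  err <- y - yhat
  ok <- abs(y) > tol_mape
  list(rmse = sqrt(mean(err^2)),
       mae = mean(abs(err)),
       mape = if (any(ok)) 100 * mean(abs(err[ok] / y[ok])) else NA_real_,
       n_mape_excluded = sum(!ok))
}

#' Fractional improvement over a baseline error statistic
#'
#' `%IMP = (x_base - x_pred) / x_base * 100` for a baseline error statistic
#' `x_base > 0`. [round_pct()] applies the integer reporting convention
#' (round half away from zero).
#'
#' @param x_base baseline statistic (uncorrected THC error), must be > 0.
#' @param x_pred statistic after correction.
#' @return improvement in percent (unrounded).
#' @export
pct_improvement <- function(x_base, x_pred) {
  if (any(x_base <= 0)) stop("pct_improvement: baseline statistic must be > 0")
  (x_base - x_pred) / x_base * 100
}

#' @rdname pct_improvement
#' @param x percentage to round.
#' @export
round_pct <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Tune KRR hyperparameters by grid search plus Nelder-Mead refinement
#'
#' Evaluates the k-fold cross-validated RMSE (original units, per-fold
#' scaling) on the full `alpha x gamma` grid, then refines the grid optimum
#' with Nelder-Mead in `(log10 alpha, log10 gamma)` space (standard
#' reflection/expansion/contraction coefficients, 200 iteration cap, 1e-4
#' relative tolerance). The refined point never has a worse CV loss than the
#' grid optimum.
#'
#' @param X raw feature matrix.
#' @param y raw labels.
#' @param grid_alpha,grid_gamma candidate values (decade-spaced by default).
#' @param k folds.
#' @param seed fold seed.
#' @return list `alpha`, `gamma`, `loss`, `trace` (data frame of all grid
#'   evaluations), `grid_best`.
#' @export
tune_hyperparameters <- function(X, y,
                                 grid_alpha = 10^seq(-9, 3, by = 1),
                                 grid_gamma = 10^seq(-7, 1, by = 1),
                                 k = 10, seed = 42) {
  if (!length(grid_alpha) || !length(grid_gamma))
    stop("tune_hyperparameters: empty grid")
  X <- as.matrix(X)
  N <- nrow(X)
  fold <- make_folds(N, k, seed)
  cv_loss <- function(alpha, gamma) {
    errs <- lapply(seq_len(k), function(f) {
      tr <- fold != f
      sx <- fit_scaler(X[tr, , drop = FALSE])
      sy <- fit_scaler(matrix(y[tr]))
      m <- fit_krr(apply_scaler(X[tr, , drop = FALSE], sx),
                   as.numeric(apply_scaler(matrix(y[tr]), sy)),
                   alpha, gamma)
      m$scaler_x <- sx; m$scaler_y <- sy
      m$feature_names <- colnames(X)
      predict(m, X[!tr, , drop = FALSE]) - y[!tr]
    })
    sqrt(mean(unlist(errs)^2))
  }
  grid <- expand.grid(alpha = grid_alpha, gamma = grid_gamma)
  grid$loss <- mapply(cv_loss, grid$alpha, grid$gamma)
  best <- grid[which.min(grid$loss), ]
  if (nrow(grid) == 1L)
    return(list(alpha = best$alpha, gamma = best$gamma, loss = best$loss,
                trace = grid, grid_best = best))
  opt <- tryCatch(
    stats::optim(log10(c(best$alpha, best$gamma)),
                 function(p) cv_loss(10^p[1], 10^p[2]),
                 method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-4)),
    error = function(e) {
      warning("tune_hyperparameters: simplex refinement failed; keeping grid optimum")
      list(par = log10(c(best$alpha, best$gamma)), value = best$loss)
    }
  )
  if (opt$value <= best$loss)
    list(alpha = 10^opt$par[1], gamma = 10^opt$par[2], loss = opt$value,
         trace = grid, grid_best = best)
  else
    list(alpha = best$alpha, gamma = best$gamma, loss = best$loss,
         trace = grid, grid_best = best)
}

#' Model specification helper
#'
#' @param kind `"scs"`, `"mlr"` or `"krr"`.
#' @param alpha,gamma KRR hyperparameters; `NULL` means tune by
#'   [tune_hyperparameters()].
#' @param grid_alpha,grid_gamma tuning grids (KRR only).
#' @return a `model_spec` list.
#' @export
model_spec <- function(kind = c("scs", "mlr", "krr"), alpha = NULL, gamma = NULL,
                       grid_alpha = 10^seq(-9, 3, by = 1),
                       grid_gamma = 10^seq(-7, 1, by = 1)) {
  kind <- match.arg(kind)
  structure(list(kind = kind, alpha = alpha, gamma = gamma,
                 grid_alpha = grid_alpha, grid_gamma = grid_gamma),
            class = "model_spec")
}

## Feature columns used by a model kind: SCS sees only the ten MP3b diagram
## components; MLR/KRR use every feature column present.
spec_feature_cols <- function(spec, feature_table) {
  all_cols <- setdiff(names(feature_table), "species_id")
  if (spec$kind == "scs") paste0("E", 1:10, "_b") else all_cols
}

## Train one model on given raw rows, handling per-kind scaling.
train_model <- function(spec, X, y) {
  if (spec$kind == "scs") {
    m <- fit_linear(X, y, intercept = FALSE)
    m$kind <- "scs"
    m
  } else if (spec$kind == "mlr") {
    sx <- fit_scaler(X); sy <- fit_scaler(matrix(y))
    m <- fit_linear(apply_scaler(X, sx), as.numeric(apply_scaler(matrix(y), sy)),
                    intercept = TRUE)
    m$scaler_x <- sx; m$scaler_y <- sy
    m$feature_names <- colnames(X)
    m
  } else {
    sx <- fit_scaler(X); sy <- fit_scaler(matrix(y))
    m <- fit_krr(apply_scaler(X, sx), as.numeric(apply_scaler(matrix(y), sy)),
                 spec$alpha, spec$gamma)
    m$scaler_x <- sx; m$scaler_y <- sy
    m$feature_names <- colnames(X)
    m
  }
}

#' Cross-validated evaluation of a correction model
#'
#' k-fold protocol: folds are a seeded partition of the label rows; for each
#' fold the scaler and model are fitted on the training rows only and the
#' held-out rows are predicted in original units. Baseline metrics come from
#' the uncorrected THC predictions (`y_base`) on the same folds. KRR
#' hyperparameters, when not given, are tuned by grid search + simplex with
#' the same fold seed. Deterministic for a fixed seed.
#'
#' @param feature_table data frame from [build_feature_table()].
#' @param labels data frame from [build_molecule_labels()] (or any
#'   `id, y, y_base` table keyed like the feature rows).
#' @param spec a [model_spec()].
#' @param k folds.
#' @param seed fold seed.
#' @return an object of class `cv_report`: per-fold metrics, means and
#'   standard deviations, baseline metrics, percent improvements, the
#'   out-of-fold predictions, and the hyperparameters used.
#' @export
cross_validate <- function(feature_table, labels, spec, k = 10, seed = 42) {
  stopifnot(inherits(spec, "model_spec"))
  merged <- merge(labels, feature_table, by.x = "id", by.y = "species_id",
                  sort = FALSE)
  if (nrow(merged) != nrow(labels))
    stop("cross_validate: some label rows have no feature row")
  cols <- spec_feature_cols(spec, feature_table)
  X <- as.matrix(merged[, cols, drop = FALSE])
  y <- merged$y
  y_base <- merged$y_base
  N <- length(y)
  if (spec$kind == "krr" && (is.null(spec$alpha) || is.null(spec$gamma))) {
    tuned <- tune_hyperparameters(X, y, spec$grid_alpha, spec$grid_gamma,
                                  k = k, seed = seed)
    spec$alpha <- tuned$alpha; spec$gamma <- tuned$gamma
    tune_trace <- tuned$trace
  } else tune_trace <- NULL

  fold <- make_folds(N, k, seed)
  y_pred <- rep(NA_real_, N)
  fold_rows <- lapply(seq_len(k), function(f) {
    te <- fold == f
    if (sum(te) < 1L || sum(!te) < 2L)
      stop("cross_validate: fold ", f, " is too small")
    m <- train_model(spec, X[!te, , drop = FALSE], y[!te])
    pr <- predict(m, X[te, , drop = FALSE])
    y_pred[te] <<- pr
    mm <- error_metrics(y[te], pr)
    mb <- error_metrics(y[te], y_base[te])
    data.frame(fold = f, rmse = mm$rmse, mae = mm$mae, mape = mm$mape,
               base_rmse = mb$rmse, base_mae = mb$mae, base_mape = mb$mape)
  })
  folds <- do.call(rbind, fold_rows)
  mean_of <- function(col) mean(folds[[col]], na.rm = TRUE)
  sd_of <- function(col) stats::sd(folds[[col]], na.rm = TRUE)
  means <- c(rmse = mean_of("rmse"), mae = mean_of("mae"), mape = mean_of("mape"),
             base_rmse = mean_of("base_rmse"), base_mae = mean_of("base_mae"),
             base_mape = mean_of("base_mape"))
  sds <- c(rmse = sd_of("rmse"), mae = sd_of("mae"), mape = sd_of("mape"))
  imp <- c(
    rmse = if (means["base_rmse"] > 0) pct_improvement(means[["base_rmse"]], means[["rmse"]]) else NA_real_,
    mae = if (means["base_mae"] > 0) pct_improvement(means[["base_mae"]], means[["mae"]]) else NA_real_,
    mape = if (isTRUE(means[["base_mape"]] > 0)) pct_improvement(means[["base_mape"]], means[["mape"]]) else NA_real_
  )
  final <- train_model(spec, X, y)
  structure(
    list(kind = spec$kind, k = k, seed = seed,
         alpha = spec$alpha, gamma = spec$gamma,
         folds = folds, means = means, sds = sds, pct_imp = imp,
         predictions = data.frame(id = merged$id, fold = fold, y = y,
                                  y_base = y_base, y_pred = y_pred,
                                  stringsAsFactors = FALSE),
         model = final, tune_trace = tune_trace),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d-fold (seed %d)\n", x$kind, x$k, x$seed))
  cat(sprintf("  RMSE %.5g (baseline %.5g, %%IMP %s), MAE %.5g\n",
              x$means["rmse"], x$means["base_rmse"],
              ifelse(is.na(x$pct_imp["rmse"]), "-",
                     sprintf("%d%%", round_pct(x$pct_imp["rmse"]))),
              x$means["mae"]))
  invisible(x)
}

#' Save / load a fitted model as JSON
#'
#' The file stores the model kind, coefficients or dual weights with the
#' support rows, hyperparameters, scaler states, feature names and a format
#' version. Numeric payloads are written as 17-significant-digit strings so
#' doubles round-trip bit-exactly and reloaded predictions are
#' bit-reproducible.
#'
#' @param model a `thc_model`.
#' @param path JSON file path.
#' @return `path` / the reloaded `thc_model`.
#' @export
save_model <- function(model, path) {
  num <- function(x) {
    if (is.matrix(x)) matrix(sprintf("%.17g", x), nrow(x)) else sprintf("%.17g", x)
  }
  ser <- list(format = "thc-correct-model/1", kind = model$kind,
              feature_names = model$feature_names)
  if (model$kind == "krr") {
    ser$dual_weights <- num(model$dual_weights)
    ser$support <- num(model$support)
    ser$alpha <- num(model$alpha)
    ser$gamma <- num(model$gamma)
  } else {
    ser$coef <- num(model$coef)
    ser$coef_names <- names(model$coef)
    ser$intercept <- model$intercept
  }
  for (s in c("scaler_x", "scaler_y")) {
    st <- model[[s]]
    if (!is.null(st))
      ser[[s]] <- list(mean = num(unname(st$mean)), sd = num(unname(st$sd)))
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ser$format, "thc-correct-model/1"))
    stop("load_model: unsupported format")
  num <- function(x) {
    if (is.matrix(x)) matrix(as.numeric(x), nrow(x)) else as.numeric(x)
  }
  mk_scaler <- function(st) {
    if (is.null(st)) return(NULL)
    sdv <- num(st$sd)
    structure(list(mean = num(st$mean), sd = sdv, constant = sdv == 0),
              class = "scaler_state")
  }
  if (ser$kind == "krr") {
    m <- structure(list(kind = "krr", dual_weights = num(ser$dual_weights),
                        support = num(as.matrix(ser$support)),
                        alpha = num(ser$alpha), gamma = num(ser$gamma),
                        feature_names = ser$feature_names,
                        scaler_x = mk_scaler(ser$scaler_x),
                        scaler_y = mk_scaler(ser$scaler_y)),
                   class = "thc_model")
  } else {
    m <- structure(list(kind = ser$kind,
                        coef = stats::setNames(num(ser$coef), ser$coef_names),
                        intercept = isTRUE(ser$intercept),
                        feature_names = ser$feature_names,
                        scaler_x = mk_scaler(ser$scaler_x),
                        scaler_y = mk_scaler(ser$scaler_y)),
                   class = "thc_model")
  }
  m
}
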