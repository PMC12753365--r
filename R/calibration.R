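#' Cross-validation plan
#'
#' Balanced fold assignment (sizes differ by at most one) with a seeded
#' shuffle, shared across model and selection tuning so that every
#' candidate sees the same folds.
#'
#' @param n Number of calibration samples.
#' @param n_folds Number of folds (default 5).
#' @param seed Shuffle seed.
#' @return A `cv_plan` with the per-sample `fold` assignment.
#' @export
cv_plan <- function(n, n_folds = 5, seed = 1L) {
  stopifnot(n >= n_folds, n_folds >= 2)
  folds <- local_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  structure(list(n = n, n_folds = n_folds, seed = as.integer(seed),
                 fold = folds),
            class = "cv_plan")
}

#' Fit a PLS1 regression model by NIPALS
#'
#' Extracts latent components in the directions of maximum covariance
#' between the (mean-centered) spectral matrix and the response, deflating
#' X after each component. Absorbance channels share units, so X is
#' centered but not variance-scaled. The regression vector is folded back
#' into channel space, `b = W (P'W)^{-1} q`, so predictions are a single
#' affine map of the input spectrum.
#'
#' @param X Calibration matrix, samples x channels.
#' @param y Calibration response vector.
#' @param n_components Number of latent components; must not exceed
#'   `min(n_samples - 1, n_channels)`.
#' @param tol Deflation stopping tolerance on residual X-y covariance.
#' @return A `plsr_model` with centering stats, NIPALS structures
#'   (`weights`, `loadings`, `scores`, `q`), the channel-space coefficient
#'   vector `b` and `intercept`, and `n_components` actually extracted.
#' @export
fit_plsr <- function(X, y, n_components, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  bound <- min(n - 1, p)
  if (n_components > bound) {
    stop("n_components (", n_components, ") exceeds min(n_samples - 1, n_channels) = ", bound)
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  a_used <- 0L
  for (a in seq_len(n_components)) {
    cov_xy <- crossprod(E, f)          # direction of max covariance
    nrm <- sqrt(sum(cov_xy^2))
    if (nrm < tol) break               # no covariance left to model
    w <- cov_xy / nrm
    t_score <- E %*% w
    tt <- sum(t_score^2)
    if (tt < tol) break
    p_load <- crossprod(E, t_score) / tt
    q_a <- sum(f * t_score) / tt
    E <- E - t_score %*% t(p_load)
    f <- f - q_a * t_score
    W[, a] <- w; P[, a] <- p_load; Tm[, a] <- t_score; q[a] <- q_a
    a_used <- a
  }
  if (a_used == 0L) stop("no latent component could be extracted (zero X-y covariance)")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  b <- W %*% solve(crossprod(P, W), q)
  structure(list(n_components = a_used, x_mean = x_mean, y_mean = y_mean,
                 weights = W, loadings = P, scores = Tm, q = q,
                 b = as.numeric(b),
                 intercept = y_mean - sum(x_mean * b)),
            class = "plsr_model")
}

#' Predict from a PLSR model
#'
#' `yhat = (X - x_mean) b + y_mean`.
#'
#' @param model A `plsr_model`.
#' @param X Matrix (or single spectrum vector) with matching channel count.
#' @return Numeric vector of predictions.
#' @export
predict_plsr <- function(model, X) {
  stopifnot(inherits(model, "plsr_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_mean)) {
    stop("channel count mismatch: model has ", length(model$x_mean),
         ", input has ", ncol(X))
  }
  as.numeric(sweep(X, 2, model$x_mean) %*% model$b + model$y_mean)
}

#' @export
predict.plsr_model <- function(object, newdata, ...) predict_plsr(object, newdata)

# Coefficient path: channel-space b and intercept for every component count
# 1..A from a single A-component NIPALS fit (the first a columns of W, P, q
# are exactly the a-component fit, so no refitting is needed).
plsr_coef_path <- function(model) {
  A <- model$n_components
  lapply(seq_len(A), function(a) {
    W <- model$weights[, seq_len(a), drop = FALSE]
    P <- model$loadings[, seq_len(a), drop = FALSE]
    b <- W %*% solve(crossprod(P, W), model$q[seq_len(a)])
    list(b = as.numeric(b), intercept = model$y_mean - sum(model$x_mean * b))
  })
}

#' Choose the PLSR component count by cross-validation
#'
#' Computes RMSECV for every candidate component count under one shared
#' fold plan and returns the count minimizing it (ties go to the smaller,
#' more parsimonious count). The zero-component predict-the-mean baseline is
#' reported alongside but is never selected.
#'
#' @param X,y Calibration data.
#' @param grid Candidate component counts (default 1..20, truncated to the
#'   feasible rank bound of the smallest training fold).
#' @param cv A `cv_plan` for `nrow(X)` samples.
#' @return List with `best`, `rmsecv` (named by component count) and
#'   `rmsecv0` (mean-prediction baseline).
#' @export
select_n_components <- function(X, y, grid = 1:20, cv = cv_plan(nrow(X))) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(inherits(cv, "cv_plan"), cv$n == nrow(X))
  bound <- min(nrow(X) - max(tabulate(cv$fold, cv$n_folds)) - 1, ncol(X))
  grid <- grid[grid <= bound]
  if (!length(grid)) stop("no feasible component count under the rank bound ", bound)
  A <- max(grid)
  press <- numeric(A)
  press0 <- 0
  for (k in seq_len(cv$n_folds)) {
    hold <- cv$fold == k
    fit <- fit_plsr(X[!hold, , drop = FALSE], y[!hold], A)
    path <- plsr_coef_path(fit)
    Xh <- X[hold, , drop = FALSE]
    press0 <- press0 + sum((y[hold] - mean(y[!hold]))^2)
    for (a in seq_len(fit$n_components)) {
      pred <- as.numeric(Xh %*% path[[a]]$b + path[[a]]$intercept)
      press[a] <- press[a] + sum((y[hold] - pred)^2)
    }
    if (fit$n_components < A) {      # rank collapsed early; reuse last model
      for (a in (fit$n_components + 1):A) {
        pred <- as.numeric(Xh %*% path[[fit$n_components]]$b +
                             path[[fit$n_components]]$intercept)
        press[a] <- press[a] + sum((y[hold] - pred)^2)
      }
    }
  }
  rmsecv <- sqrt(press / length(y))[grid]
  names(rmsecv) <- grid
  best <- grid[which.min(rmsecv)]
  list(best = best, rmsecv = rmsecv, rmsecv0 = sqrt(press0 / length(y)))
}

#' Hyperparameter grids for support vector regression
#'
#' The canonical search grids: cost `C` in {0.01, 0.1, 1, 10, 100}, RBF
#' width `gamma` in {1e-4, 1e-3, 0.01, 0.1, 1, 10} (RBF kernel only), and
#' `epsilon` in {0.01, 0.05, 0.1, 0.2} — 20 combinations for the linear
#' kernel, 120 for RBF. `extended_c = TRUE` appends C = 1000, flagged
#' non-canonical.
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param extended_c Include C = 1000.
#' @return A data.frame of configurations (columns `C`, `gamma`, `epsilon`).
#' @export
svr_grid <- function(kernel = c("linear", "rbf"), extended_c = FALSE) {
  kernel <- match.arg(kernel)
  Cs <- c(0.01, 0.1, 1, 10, 100)
  if (extended_c) Cs <- c(Cs, 1000)
  eps <- c(0.01, 0.05, 0.1, 0.2)
  if (kernel == "linear") {
    expand.grid(C = Cs, gamma = NA_real_, epsilon = eps)
  } else {
    expand.grid(C = Cs, gamma = c(1e-4, 1e-3, 0.01, 0.1, 1, 10), epsilon = eps)
  }
}

#' Grid-searched epsilon-insensitive SVR
#'
#' Standardizes channels with calibration statistics (SVMs are
#' scale-sensitive), then exhaustively cross-validates the configuration
#' grid and refits the winner on the full calibration set. The
#' epsilon-insensitive loss machinery is delegated to \pkg{e1071}; the
#' grids, fold protocol, standardization and reporting are owned here.
#'
#' @param X,y Calibration data.
#' @param kernel `"linear"` or `"rbf"`.
#' @param cv A `cv_plan`.
#' @param extended_c Include the non-canonical C = 1000 grid point.
#' @return An `svr_model` with the winning config, RMSECV table and fitted
#'   e1071 model, or a constant predictor (with a warning) for constant y.
#' @export
fit_svr_grid <- function(X, y, kernel = c("linear", "rbf"),
                         cv = cv_plan(nrow(X)), extended_c = FALSE) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(inherits(cv, "cv_plan"), cv$n == nrow(X))
  if (stats::sd(y) < 1e-12) {
    warning("constant response; returning constant predictor")
    return(structure(list(kernel = kernel, constant = mean(y)),
                     class = "svr_model"))
  }
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  grid <- svr_grid(kernel, extended_c)
  grid$rmsecv <- NA_real_
  for (g in seq_len(nrow(grid))) {
    press <- 0
    for (k in seq_len(cv$n_folds)) {
      hold <- cv$fold == k
      fit <- svm_call(Z[!hold, , drop = FALSE], y[!hold], kernel, grid[g, ])
      pred <- as.numeric(stats::predict(fit, Z[hold, , drop = FALSE]))
      press <- press + sum((y[hold] - pred)^2)
    }
    grid$rmsecv[g] <- sqrt(press / length(y))
  }
  best <- which.min(grid$rmsecv)
  model <- svm_call(Z, y, kernel, grid[best, ])
  structure(list(kernel = kernel, config = grid[best, c("C", "gamma", "epsilon")],
                 rmsecv = grid, x_mean = mu, x_sd = sg, fit = model),
            class = "svr_model")
}

svm_call <- function(Z, y, kernel, cfg) {
  args <- list(x = Z, y = y, type = "eps-regression", scale = FALSE,
               kernel = if (kernel == "rbf") "radial" else "linear",
               cost = cfg$C, epsilon = cfg$epsilon)
  if (kernel == "rbf") args$gamma <- cfg$gamma
  do.call(e1071::svm, args)
}

#' Predict from a fitted SVR model
#'
#' @param model An `svr_model` from [fit_svr_grid()].
#' @param X Matrix with matching channel count.
#' @return Numeric vector of predictions.
#' @export
predict_svr <- function(model, X) {
  stopifnot(inherits(model, "svr_model"))
  X <- as.matrix(X)
  if (!is.null(model$constant)) return(rep(model$constant, nrow(X)))
  Z <- sweep(sweep(X, 2, model$x_mean), 2, model$x_sd, "/")
  as.numeric(stats::predict(model$fit, Z))
}

#' @export
predict.svr_model <- function(object, newdata, ...) predict_svr(object, newdata)
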