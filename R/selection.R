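#' Selection result container
#'
#' @param method One of `"PLSRC"`, `"CARS"`, `"SPA"`, `"UVE"`.
#' @param selected Ordered unique channel indices.
#' @param importance Full-length per-channel importance scores (every
#'   channel keeps its computed score, selected or not).
#' @param diagnostics Method-specific diagnostics (RMSECV traces, cutoffs).
#' @return A `selection_result`.
#' @export
selection_result <- function(method, selected, importance, diagnostics = list()) {
  selected <- as.integer(selected)
  stopifnot(length(selected) >= 1, !anyDuplicated(selected),
            all(selected >= 1), all(selected <= length(importance)),
            all(is.finite(importance) | is.infinite(importance)))
  structure(list(method = method, selected = selected,
                 importance = as.numeric(importance),
                 diagnostics = diagnostics),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", x$method, ": ", length(x$selected), " of ",
      length(x$importance), " channels\n", sep = "")
  invisible(x)
}

#' Wavelength selection by PLSR regression-coefficient magnitude
#'
#' Channels are ranked by the absolute regression coefficient `|b|` of the
#' CV-optimal full-spectrum PLSR model — a larger |b| marks a channel the
#' model leans on more. The retained count k is chosen by refitting PLSR on
#' each top-k candidate set over a k-grid and minimizing RMSECV (ties to
#' the smaller k).
#'
#' @param X,y Calibration data (already preprocessed).
#' @param cv A `cv_plan`.
#' @param k_grid Candidate top-k sizes; default `seq(5, min(60, p), 5)`.
#' @param max_components Cap on PLSR components during tuning.
#' @return A `selection_result` with importance `|b|`.
#' @export
plsrc_select <- function(X, y, cv = cv_plan(nrow(X)),
                         k_grid = NULL, max_components = 20) {
  X <- as.matrix(X); y <- as.numeric(y)
  p <- ncol(X)
  if (is.null(k_grid)) k_grid <- seq(5, min(60, p), by = 5)
  k_grid <- sort(unique(pmin(k_grid, p)))
  sel0 <- select_n_components(X, y, 1:max_components, cv)
  full <- fit_plsr(X, y, sel0$best)
  importance <- abs(full$b)
  rank_order <- order(importance, decreasing = TRUE)
  rmsecv_k <- vapply(k_grid, function(k) {
    idx <- rank_order[seq_len(k)]
    min(select_n_components(X[, idx, drop = FALSE], y, 1:max_components, cv)$rmsecv)
  }, numeric(1))
  best_k <- k_grid[which.min(rmsecv_k)]
  selected <- sort(rank_order[seq_len(best_k)])
  selection_result("PLSRC", selected, importance,
                   list(k_grid = k_grid, rmsecv = rmsecv_k, best_k = best_k,
                        n_components_full = sel0$best))
}

#' Exponentially decreasing retention schedule for CARS
#'
#' The fraction of channels retained at run i follows `r_i = a * exp(-k *
#' i)` with the endpoints pinned so that all p channels survive run 1 and
#' exactly 2 survive the final run: `k = log(p/2) / (n_runs - 1)`,
#' `a = exp(k)`.
#'
#' @param p Total channel count.
#' @param n_runs Number of sampling runs.
#' @return Numeric vector `r_1..r_n` of retention fractions.
#' @export
cars_edf <- function(p, n_runs) {
  stopifnot(p >= 2, n_runs >= 2)
  k <- log(p / 2) / (n_runs - 1)
  r <- exp(-k * (seq_len(n_runs) - 1))   # a * exp(-k i) with a = exp(k)
  r[n_runs] <- 2 / p                     # pin the endpoint exactly
  r
}

#' Competitive adaptive reweighted sampling
#'
#' Monte-Carlo wavelength selection: each run fits PLSR on a random
#' calibration subset, ranks the surviving channels by normalized `|b|`,
#' enforces the exponentially decreasing retention schedule ([cars_edf()]),
#' and then resamples within the kept set with probability proportional to
#' `|b|` (adaptive reweighted sampling). The run whose retained set gives
#' the lowest RMSECV wins.
#'
#' @param X,y Calibration data.
#' @param n_runs Number of runs (default 50).
#' @param subset_frac Fraction of calibration samples drawn per run.
#' @param cv A `cv_plan` used for the per-run RMSECV.
#' @param seed RNG seed; identical seeds give identical selections.
#' @param max_components Cap on PLSR components.
#' @return A `selection_result`; importance is each channel's selection
#'   frequency over runs, diagnostics carry the retained-count and RMSECV
#'   traces.
#' @export
cars_select <- function(X, y, n_runs = 50, subset_frac = 0.8,
                        cv = cv_plan(nrow(X)), seed = 1L, max_components = 10) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n_runs >= 2)
  r_sched <- cars_edf(p, n_runs)
  local_seed(seed, {
    current <- seq_len(p)
    kept_sets <- vector("list", n_runs)
    rmsecv_trace <- rep(NA_real_, n_runs)
    counts <- integer(n_runs)
    freq <- numeric(p)
    for (i in seq_len(n_runs)) {
      if (length(current) < 2) {
        n_runs <- i - 1L
        kept_sets <- kept_sets[seq_len(n_runs)]
        rmsecv_trace <- rmsecv_trace[seq_len(n_runs)]
        counts <- counts[seq_len(n_runs)]
        break
      }
      rows <- sample(n, max(2, round(subset_frac * n)))
      ncomp <- min(max_components, length(rows) - 1, length(current))
      fit <- fit_plsr(X[rows, current, drop = FALSE], y[rows], ncomp)
      w <- abs(fit$b)
      keep_count <- max(2L, min(ceiling(r_sched[i] * p), length(current)))
      forced <- current[order(w, decreasing = TRUE)[seq_len(keep_count)]]
      w_forced <- w[match(forced, current)]
      if (sum(w_forced) <= 0) w_forced <- rep(1, length(forced))
      drawn <- sample(forced, keep_count, replace = TRUE,
                      prob = w_forced / sum(w_forced))
      current <- sort(unique(drawn))
      if (length(current) < 2) current <- sort(forced[1:2])  # keep >= 2 channels
      kept_sets[[i]] <- current
      counts[i] <- length(current)
      freq[current] <- freq[current] + 1
      ncv <- min(max_components, length(current))
      sel <- select_n_components(X[, current, drop = FALSE], y, 1:ncv, cv)
      rmsecv_trace[i] <- min(sel$rmsecv)
    }
    best_run <- which.min(rmsecv_trace)
    selection_result("CARS", kept_sets[[best_run]], freq / n_runs,
                     list(retained_counts = counts, rmsecv = rmsecv_trace,
                          best_run = best_run, edf = r_sched))
  })
}

# Deterministic SPA chain from one start: successively pick the column with
# the largest residual norm after projecting out the span of the chosen
# columns. Truncates on rank collapse (residual norms all ~ 0).
spa_chain <- function(X, start, m_max, tol = 1e-12) {
  p <- ncol(X)
  R <- X
  chain <- integer(0)
  current <- start
  for (m in seq_len(m_max)) {
    chain <- c(chain, current)
    q <- R[, current]
    nq <- sqrt(sum(q^2))
    if (nq < tol) break
    q <- q / nq
    R <- R - q %*% crossprod(q, R)
    R[, chain] <- 0
    norms <- sqrt(colSums(R^2))
    if (m == m_max || max(norms) <= tol) break
    current <- which.max(norms)
  }
  chain
}

rmsecv_mlr <- function(X, y, cv) {
  press <- 0
  for (k in seq_len(cv$n_folds)) {
    hold <- cv$fold == k
    A <- cbind(1, X[!hold, , drop = FALSE])
    fit <- stats::.lm.fit(A, y[!hold])
    coef <- fit$coefficients
    coef[is.na(coef)] <- 0
    pred <- as.numeric(cbind(1, X[hold, , drop = FALSE]) %*% coef)
    press <- press + sum((y[hold] - pred)^2)
  }
  sqrt(press / length(y))
}

#' Successive projections algorithm
#'
#' Builds minimally collinear wavelength chains: from every possible
#' starting channel, the next channel is always the one with the largest
#' residual norm after orthogonal projection onto the complement of the
#' span of those already chosen. Every (start, chain length) candidate is
#' scored by the RMSECV of a multiple linear regression on those channels,
#' and the global minimizer is returned (ties go to fewer channels, then
#' the lower start index). The final reported model is conventionally a
#' PLSR refit on the selected channels ([refit_with_selection()]).
#'
#' @param X,y Calibration data.
#' @param m_max Maximum chain length; capped at
#'   `min(smallest training fold size - 2, n_channels)`.
#' @param cv A `cv_plan` for the internal MLR scoring.
#' @return A `selection_result`; importance scores channels by how early
#'   and how often they enter the p chains (sum of inverse entry
#'   positions).
#' @export
spa_select <- function(X, y, m_max = 25, cv = cv_plan(nrow(X))) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  min_train <- n - max(tabulate(cv$fold, cv$n_folds))
  m_max <- min(m_max, min_train - 2, p)
  stopifnot(m_max >= 1)
  best <- list(rmsecv = Inf, chain = NULL, start = NA_integer_, len = NA_integer_)
  importance <- numeric(p)
  trace <- matrix(NA_real_, p, m_max)
  for (s in seq_len(p)) {
    chain <- spa_chain(X, s, m_max)
    importance[chain] <- importance[chain] + 1 / seq_along(chain)
    for (m in seq_along(chain)) {
      r <- rmsecv_mlr(X[, chain[seq_len(m)], drop = FALSE], y, cv)
      trace[s, m] <- r
      if (r < best$rmsecv - 1e-15 ||
          (abs(r - best$rmsecv) <= 1e-15 &&
           (m < best$len || (m == best$len && s < best$start)))) {
        best <- list(rmsecv = r, chain = chain[seq_len(m)], start = s, len = m)
      }
    }
  }
  selection_result("SPA", sort(best$chain), importance,
                   list(best_start = best$start, best_length = best$len,
                        best_rmsecv = best$rmsecv, rmsecv_trace = trace))
}

#' Uninformative variable elimination
#'
#' Appends as many artificial noise channels as there are real ones
#' (uniform draws scaled by `noise_scale`), refits PLSR once per
#' leave-one-out resample, and scores every channel by the stability of its
#' regression coefficient, `c_j = mean(b_j) / sd(b_j)`. The cutoff is the
#' largest |c| attained by any noise channel — a real channel survives only
#' if its coefficient is more stable than everything the noise achieves, so
#' noise channels are excluded by construction.
#'
#' @param X,y Calibration data (`nrow(X) >= 3`).
#' @param noise_scale Amplitude of the artificial noise channels.
#' @param seed RNG seed for the noise draws.
#' @param max_components Cap on PLSR components (tuned once by CV on the
#'   real channels).
#' @param cv A `cv_plan` for that tuning.
#' @return A `selection_result`; importance is |c| over the real channels,
#'   diagnostics carry the cutoff and the noise-channel scores.
#' @export
uve_select <- function(X, y, noise_scale = 1e-10, seed = 1L,
                       max_components = 15, cv = cv_plan(nrow(X))) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 3)
  ncomp <- select_n_components(X, y, 1:max_components, cv)$best
  noise <- local_seed(seed, matrix(stats::runif(n * p), n, p)) * noise_scale
  aug <- cbind(X, noise)
  B <- matrix(NA_real_, n, 2 * p)
  for (i in seq_len(n)) {
    fit <- fit_plsr(aug[-i, , drop = FALSE], y[-i], min(ncomp, n - 2))
    B[i, ] <- fit$b
  }
  mu <- colMeans(B)
  sg <- apply(B, 2, stats::sd)
  cstab <- rep(Inf, 2 * p)
  ok <- sg > 0
  cstab[ok] <- mu[ok] / sg[ok]
  if (any(!ok)) warning("zero coefficient SD; treating |c| as infinite for ",
                        sum(!ok), " channel(s)")
  cutoff <- max(abs(cstab[(p + 1):(2 * p)]))
  selected <- which(abs(cstab[seq_len(p)]) > cutoff)
  if (!length(selected)) {
    warning("no channel exceeded the noise cutoff; keeping the most stable one")
    selected <- which.max(abs(cstab[seq_len(p)]))
  }
  selection_result("UVE", selected, abs(cstab[seq_len(p)]),
                   list(cutoff = cutoff, noise_stability = cstab[(p + 1):(2 * p)],
                        n_components = ncomp))
}

#' Refit PLSR on a selected channel set and evaluate it
#'
#' Re-selects the component count by cross-validation on the reduced
#' matrix, fits, and reports calibration/validation metrics plus wall time
#' (median of `time_repeats` fit+predict repeats).
#'
#' @param sel A `selection_result` (or integer channel indices).
#' @param Xc,yc Calibration data. @param Xv,yv Validation data.
#' @param cv A `cv_plan`. @param max_components Component cap.
#' @param time_repeats Timing repeats (default 3).
#' @return An `evaluation_report` (see [evaluate_predictions()]) with the
#'   fitted model and selection attached.
#' @export
refit_with_selection <- function(sel, Xc, yc, Xv, yv,
                                 cv = cv_plan(nrow(Xc)), max_components = 20,
                                 time_repeats = 3) {
  idx <- if (inherits(sel, "selection_result")) sel$selected else as.integer(sel)
  stopifnot(length(idx) >= 1)
  Xc <- as.matrix(Xc); Xv <- as.matrix(Xv)
  Xcs <- Xc[, idx, drop = FALSE]
  Xvs <- Xv[, idx, drop = FALSE]
  ncv <- min(max_components, nrow(Xcs) - max(tabulate(cv$fold, cv$n_folds)) - 1,
             length(idx))
  tuned <- select_n_components(Xcs, yc, 1:ncv, cv)
  times <- vapply(seq_len(time_repeats), function(r) {
    t0 <- proc.time()[["elapsed"]]
    m <- fit_plsr(Xcs, yc, tuned$best)
    invisible(predict_plsr(m, Xvs))
    proc.time()[["elapsed"]] - t0
  }, numeric(1))
  model <- fit_plsr(Xcs, yc, tuned$best)
  report <- evaluate_predictions(yc, predict_plsr(model, Xcs),
                                 yv, predict_plsr(model, Xvs),
                                 fit_seconds = stats::median(times))
  report$n_components <- tuned$best
  report$n_selected <- length(idx)
  report$model <- model
  report$selection <- if (inherits(sel, "selection_result")) sel else NULL
  report
}
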