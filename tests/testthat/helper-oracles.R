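# Independent reference implementations used as oracles. These deliberately
# take different computational routes from the package code.

# Random spectra set on a small grid.
random_spectra <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    spectra_set(seq(940, by = 5, length.out = p),
                matrix(rnorm(n * p), n, p))
  })
}

# Textbook iterative NIPALS for a single response, predicting through the
# factor form (score-by-score deflation of the query matrix) rather than a
# channel-space coefficient vector.
nipals_reference <- function(X, y, A, Xnew) {
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  Enew <- sweep(as.matrix(Xnew), 2, xm)
  yhat <- rep(ym, nrow(Enew))
  for (a in seq_len(A)) {
    w <- drop(t(E) %*% f)
    w <- w / sqrt(sum(w^2))
    t_ <- drop(E %*% w)
    p_ <- drop(t(E) %*% t_) / sum(t_^2)
    q_ <- sum(f * t_) / sum(t_^2)
    tn <- drop(Enew %*% w)
    yhat <- yhat + q_ * tn
    E <- E - outer(t_, p_)
    f <- f - q_ * t_
    Enew <- Enew - outer(tn, p_)
  }
  yhat
}

# Exhaustive greedy SPXY re-implementation: plain double loops, no
# vectorized distance bookkeeping.
spxy_oracle <- function(X, y, ids, n_cal) {
  ord <- order(ids, method = "radix")
  X <- X[ord, , drop = FALSE]; y <- y[ord]; ids <- ids[ord]
  n <- nrow(X)
  dx <- matrix(0, n, n); dy <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    dx[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    dy[i, j] <- abs(y[i] - y[j])
  }
  D <- dx / max(dx) + dy / max(dy)
  best <- c(1, 2); bestd <- -1
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bestd + 1e-15) { best <- c(i, j); bestd <- D[i, j] }
  }
  sel <- best
  while (length(sel) < n_cal) {
    cand <- setdiff(1:n, sel)
    score <- sapply(cand, function(i) min(D[i, sel]))
    sel <- c(sel, cand[which(score > max(score) - 1e-15)][1])
  }
  ids[sel]
}

# SPA chain by brute force: residual norms via QR at every step.
spa_chain_oracle <- function(X, start, m_max) {
  chain <- start
  while (length(chain) < m_max) {
    qrx <- qr(X[, chain, drop = FALSE])
    norms <- apply(X, 2, function(col) sqrt(sum(qr.resid(qrx, col)^2)))
    norms[chain] <- -1
    if (max(norms) <= 1e-12) break
    chain <- c(chain, which.max(norms))
  }
  chain
}

# Per-row affine fit of each spectrum on a reference via explicit normal
# equations.
affine_fit_oracle <- function(X, ref) {
  t(apply(X, 1, function(r) {
    A <- cbind(1, ref)
    coef <- solve(t(A) %*% A, t(A) %*% r)
    c(bias = coef[1], gain = coef[2])
  }))
}

# A default synthetic dataset split and preprocessed with the named plan.
prepared_dataset <- function(seed, plan = "d1+msc", cfg = synthetic_config(seed = seed)) {
  d <- generate_dataset(cfg)
  sp <- spxy_split(d$spectra, d$protein)
  cal <- subset_spectra(d$spectra, sp$calibration_ids)
  val <- subset_spectra(d$spectra, sp$validation_ids)
  pr <- apply_plan(plan, cal, val)
  list(Xc = pr$calibration$absorbance, Xv = pr$validation$absorbance,
       yc = as.numeric(d$protein[sp$calibration_ids]),
       yv = as.numeric(d$protein[sp$validation_ids]),
       truth = d$truth, split = sp, data = d,
       cv = cv_plan(length(sp$calibration_ids), seed = seed))
}
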