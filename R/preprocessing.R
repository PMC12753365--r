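#' Fit a multiplicative scatter correction model
#'
#' The MSC reference is the channel-wise mean spectrum of the calibration
#' set. Fitting only on calibration spectra keeps the held-out set from
#' leaking into the correction.
#'
#' @param calibration A `spectra_set` with at least 2 spectra.
#' @return An `msc_model` holding the reference spectrum.
#' @export
msc_fit <- function(calibration) {
  stopifnot(inherits(calibration, "spectra_set"))
  if (nrow(calibration$absorbance) < 2) stop("MSC needs at least 2 calibration spectra")
  reference <- colMeans(calibration$absorbance)
  if (stats::sd(reference) < 1e-12) stop("degenerate MSC reference: zero variance")
  structure(list(reference = reference, wavelengths = calibration$wavelengths),
            class = "msc_model")
}

#' Apply multiplicative scatter correction
#'
#' Each spectrum is regressed on the reference, `R_i = Gain_i * Rbar +
#' Bias_i` (univariate least squares), and corrected as `(R_i - Bias_i) /
#' Gain_i`. An exact affine image of the reference is therefore mapped back
#' onto the reference itself.
#'
#' @param model An `msc_model` from [msc_fit()].
#' @param spectra A `spectra_set` on the same grid.
#' @return A list with the corrected `spectra_set` (element `spectra`) and
#'   the per-spectrum `gain` and `bias` vectors.
#' @export
msc_apply <- function(model, spectra) {
  stopifnot(inherits(model, "msc_model"), inherits(spectra, "spectra_set"))
  if (length(model$reference) != length(spectra$wavelengths)) {
    stop("channel grid mismatch between MSC model and spectra")
  }
  ref <- model$reference
  refc <- ref - mean(ref)
  denom <- sum(refc^2)
  X <- spectra$absorbance
  gain <- as.numeric(X %*% refc) / denom   # slope of R_i on Rbar
  bias <- rowMeans(X) - gain * mean(ref)
  small <- which(abs(gain) < 1e-12)
  if (length(small)) {
    stop("MSC gain numerically zero for sample(s): ",
         paste(spectra$sample_ids[small], collapse = ", "))
  }
  corrected <- sweep(sweep(X, 1, bias, "-"), 1, gain, "/")
  list(spectra = spectra_set(spectra$wavelengths, corrected, spectra$sample_ids),
       gain = stats::setNames(gain, spectra$sample_ids),
       bias = stats::setNames(bias, spectra$sample_ids))
}

#' Standard normal variate transform
#'
#' Standardizes each spectrum to mean 0 and unit standard deviation (sample
#' SD, divisor n-1), removing per-spectrum additive offsets and
#' multiplicative scaling.
#'
#' @param spectra A `spectra_set`; every row must have positive SD.
#' @return The transformed `spectra_set`.
#' @export
snv <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  X <- spectra$absorbance
  mu <- rowMeans(X)
  sd_row <- apply(X, 1, stats::sd)
  zero <- which(sd_row < 1e-300)
  if (length(zero)) {
    stop("SNV undefined for constant spectrum of sample(s): ",
         paste(spectra$sample_ids[zero], collapse = ", "))
  }
  Z <- sweep(sweep(X, 1, mu, "-"), 1, sd_row, "/")
  spectra_set(spectra$wavelengths, Z, spectra$sample_ids)
}

#' First derivative with respect to wavelength
#'
#' Central differences in the interior, one-sided differences at the two
#' ends, so the output keeps the full channel grid and channel indices stay
#' comparable across preprocessing schemes. Requires a uniform grid.
#'
#' @param spectra A `spectra_set` with at least 3 channels.
#' @return A `spectra_set` of d(absorbance)/d(wavelength) values (AU/nm).
#' @export
first_derivative <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  wl <- spectra$wavelengths
  p <- length(wl)
  if (p < 3) stop("first derivative needs at least 3 channels")
  h <- diff(wl)
  if (max(abs(h - h[1])) > 1e-6 * h[1]) stop("non-uniform wavelength grid")
  h <- h[1]
  X <- spectra$absorbance
  D <- X
  D[, 2:(p - 1)] <- (X[, 3:p] - X[, 1:(p - 2)]) / (2 * h)
  D[, 1] <- (X[, 2] - X[, 1]) / h
  D[, p] <- (X[, p] - X[, p - 1]) / h
  spectra_set(wl, D, spectra$sample_ids)
}

# Value-reproducing smoothing weights for every output position: centered
# window in the interior, shrinking one-sided windows at the two edges
# (same polynomial order throughout). Returns a p x p matrix S with
# smoothed = X %*% t(S).
savgol_weights <- function(p, window, order) {
  half <- (window - 1L) %/% 2L
  S <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- max(1L, j - half):min(p, j + half)
    ord <- min(order, length(idx) - 1L)   # shrunk edge windows cap the order
    V <- outer(idx - j, 0:ord, "^")
    # evaluate the LS polynomial at offset 0 via QR (Vandermonde normal
    # equations are too ill-conditioned at order close to the window)
    qrv <- qr(V)
    Rinv_row1 <- backsolve(qr.R(qrv), diag(ord + 1L))[1L, ]
    S[j, idx] <- drop(Rinv_row1 %*% t(qr.Q(qrv)))
  }
  S
}

#' Savitzky-Golay smoothing
#'
#' Replaces each channel by the value of a least-squares polynomial fitted
#' in a moving window. The defaults (window 7, order 2) suit pixel-level
#' noise on short-wave NIR arrays. At the edges the window shrinks to the
#' available one-sided channels while keeping the polynomial order, so
#' polynomials up to `order` are reproduced exactly everywhere.
#'
#' @param spectra A `spectra_set`.
#' @param window Odd window length, `order < window <= n_channels`.
#' @param order Polynomial order.
#' @return The smoothed `spectra_set`.
#' @export
savgol_smooth <- function(spectra, window = 7L, order = 2L) {
  stopifnot(inherits(spectra, "spectra_set"))
  p <- length(spectra$wavelengths)
  if (window %% 2L == 0L) stop("Savitzky-Golay window must be odd")
  if (window > p) stop("window (", window, ") exceeds channel count (", p, ")")
  if (order >= window) stop("polynomial order must be less than the window")
  S <- savgol_weights(p, as.integer(window), as.integer(order))
  spectra_set(spectra$wavelengths, spectra$absorbance %*% t(S), spectra$sample_ids)
}

#' Define a preprocessing plan
#'
#' An ordered sequence of step names from `MSC`, `SNV`, `D1` (first
#' derivative) and `SG` (Savitzky-Golay smoothing). The eight named schemes
#' used throughout the package are `msc`, `snv`, `d1`, `sg`, `d1+snv`,
#' `d1+msc`, `sg+snv` and `sg+msc` — in the composite schemes the derivative
#' or smoothing runs first and the scatter correction second.
#'
#' @param steps Character vector of step names (case-insensitive), or a
#'   single string like `"d1+msc"`.
#' @param sg_window,sg_order Savitzky-Golay parameters used by `SG` steps.
#' @return A `preprocess_plan`.
#' @export
preprocess_plan <- function(steps, sg_window = 7L, sg_order = 2L) {
  if (length(steps) == 1 && grepl("\\+", steps)) {
    steps <- strsplit(steps, "+", fixed = TRUE)[[1]]
  }
  steps <- toupper(trimws(steps))
  valid <- c("MSC", "SNV", "D1", "SG")
  bad <- setdiff(steps, valid)
  if (length(bad)) stop("unknown preprocessing step(s): ", paste(bad, collapse = ", "))
  if (sg_window %% 2L == 0L || sg_order >= sg_window) {
    stop("SG window must be odd and greater than the polynomial order")
  }
  structure(list(steps = steps, sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order)),
            class = "preprocess_plan")
}

#' The eight standard preprocessing scheme names
#' @return Character vector of plan names accepted by [preprocess_plan()].
#' @export
standard_plans <- function() {
  c("msc", "snv", "d1", "sg", "d1+snv", "d1+msc", "sg+snv", "sg+msc")
}

#' Apply a preprocessing plan to calibration and validation sets
#'
#' Steps run left to right. Any MSC step fits its reference on the (already
#' partially processed) calibration spectra only and applies the same model
#' to both sets, so no validation information enters the correction.
#'
#' @param plan A `preprocess_plan` (or a string accepted by
#'   [preprocess_plan()]).
#' @param calibration,validation `spectra_set`s on a shared grid.
#'   `validation` may be `NULL`.
#' @return A list with processed `calibration` and `validation` sets.
#' @export
apply_plan <- function(plan, calibration, validation = NULL) {
  if (is.character(plan)) plan <- preprocess_plan(plan)
  stopifnot(inherits(plan, "preprocess_plan"))
  cal <- calibration
  val <- validation
  for (step in plan$steps) {
    if (step == "MSC") {
      model <- msc_fit(cal)
      cal <- msc_apply(model, cal)$spectra
      if (!is.null(val)) val <- msc_apply(model, val)$spectra
    } else if (step == "SNV") {
      cal <- snv(cal)
      if (!is.null(val)) val <- snv(val)
    } else if (step == "D1") {
      cal <- first_derivative(cal)
      if (!is.null(val)) val <- first_derivative(val)
    } else if (step == "SG") {
      cal <- savgol_smooth(cal, plan$sg_window, plan$sg_order)
      if (!is.null(val)) val <- savgol_smooth(val, plan$sg_window, plan$sg_order)
    }
  }
  list(calibration = cal, validation = val)
}
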