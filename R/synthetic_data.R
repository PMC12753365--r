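#' Gaussian absorption band specification
#'
#' A single constituent absorption band: a Gaussian profile of the given
#' center and width whose peak absorbance is proportional to the constituent
#' concentration.
#'
#' @param center_nm Band center (nm).
#' @param width_nm Gaussian sigma (nm), > 0.
#' @param intensity_per_pct Peak absorbance contributed per percentage point
#'   of the constituent.
#' @return A `band_spec` list.
#' @export
band_spec <- function(center_nm, width_nm, intensity_per_pct) {
  stopifnot(width_nm > 0, is.finite(center_nm), is.finite(intensity_per_pct))
  structure(list(center_nm = center_nm, width_nm = width_nm,
                 intensity_per_pct = intensity_per_pct),
            class = "band_spec")
}

#' Configuration for the synthetic maize-powder NIR generator
#'
#' Defaults emulate a 90-sample maize powder study: three replicate spectra
#' per sample on a 940-1660 nm grid, protein uniform on 8.43-11.25% (so the
#' population mean sits at 9.84%), protein-linked N-H overtone bands near
#' 1000, 1515 and 1582 nm, and background starch (C-H, ~1206 nm) and
#' moisture (O-H, ~1460 nm) bands whose concentrations vary independently
#' across samples. Replicates differ by multiplicative scatter gain, additive
#' offset, linear baseline drift and white channel noise.
#'
#' @param n_samples Number of samples (default 90).
#' @param replicate_count Replicate spectra per sample (default 3).
#' @param protein_range_pct Protein content range, % dry basis.
#' @param protein_bands List of `band_spec` tied to protein concentration.
#' @param background_bands List of `band_spec` for non-protein constituents.
#' @param background_conc_ranges List of concentration ranges (one per
#'   background band) giving the independent uniform part of each
#'   background constituent's concentration.
#' @param closure_coefficients Numeric vector, one per background band:
#'   each background concentration is the uniform draw plus
#'   `coefficient * (protein - range midpoint)`. The default `c(-1, 0)`
#'   encodes mass closure — every percentage point of protein displaces
#'   one point of starch, while moisture varies independently. Without
#'   this coupling the total constituent load would drift freely with
#'   protein, and scatter-normalizing preprocessing (MSC/SNV), which can
#'   only preserve composition ratios, would destroy the protein signal —
#'   the opposite of how these corrections behave on real powder spectra.
#' @param wavelengths Wavelength grid (nm); default [default_grid()].
#' @param scatter_gain_sd SD of the per-replicate multiplicative gain about 1.
#' @param scatter_offset_sd SD of the per-replicate additive offset (AU).
#' @param baseline_slope_sd SD of the per-replicate linear drift amplitude
#'   across the grid (AU).
#' @param noise_sd SD of per-channel white noise (AU).
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 90,
                             replicate_count = 3,
                             protein_range_pct = c(8.43, 11.25),
                             protein_bands = list(
                               band_spec(1000, 25, 0.012),
                               band_spec(1515, 30, 0.009),
                               band_spec(1582, 25, 0.007)),
                             background_bands = list(
                               band_spec(1206, 40, 0.008),
                               band_spec(1460, 50, 0.020)),
                             background_conc_ranges = list(c(61, 67), c(9, 13)),
                             closure_coefficients = c(-1, 0),
                             wavelengths = default_grid(),
                             scatter_gain_sd = 0.12,
                             scatter_offset_sd = 0.05,
                             baseline_slope_sd = 0.10,
                             noise_sd = 0.002,
                             seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              replicate_count = as.integer(replicate_count),
              protein_range_pct = as.numeric(protein_range_pct),
              protein_bands = protein_bands,
              background_bands = background_bands,
              background_conc_ranges = background_conc_ranges,
              closure_coefficients = as.numeric(closure_coefficients),
              wavelengths = as.numeric(wavelengths),
              scatter_gain_sd = scatter_gain_sd,
              scatter_offset_sd = scatter_offset_sd,
              baseline_slope_sd = baseline_slope_sd,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  if (cfg$n_samples < 1) stop("n_samples must be positive")
  if (cfg$replicate_count < 1) stop("replicate_count must be at least 1")
  if (length(cfg$protein_range_pct) != 2 ||
      cfg$protein_range_pct[1] > cfg$protein_range_pct[2]) {
    stop("protein_range_pct must be an ordered interval")
  }
  if (any(cfg$protein_range_pct <= 0) || any(cfg$protein_range_pct >= 100)) {
    stop("protein_range_pct must lie inside (0, 100)")
  }
  sds <- c(cfg$scatter_gain_sd, cfg$scatter_offset_sd,
           cfg$baseline_slope_sd, cfg$noise_sd)
  if (any(sds < 0)) stop("all noise/scatter SDs must be non-negative")
  if (length(cfg$background_bands) != length(cfg$background_conc_ranges)) {
    stop("one concentration range is required per background band")
  }
  if (length(cfg$closure_coefficients) != length(cfg$background_bands)) {
    stop("one closure coefficient is required per background band")
  }
  span <- range(cfg$wavelengths)
  for (b in c(cfg$protein_bands, cfg$background_bands)) {
    if (!inherits(b, "band_spec")) stop("bands must be band_spec objects")
    if (b$center_nm < span[1] || b$center_nm > span[2]) {
      stop("band center ", b$center_nm, " nm outside the wavelength grid")
    }
  }
  structure(cfg, class = "synthetic_config")
}

# Evaluate RNG-consuming code under a seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

gaussian_profile <- function(wavelengths, band) {
  exp(-((wavelengths - band$center_nm)^2) / (2 * band$width_nm^2))
}

#' Draw protein reference values
#'
#' Protein contents are sampled uniformly on the configured range, so the
#' expected mean is the range midpoint. A degenerate range (lo = hi) yields a
#' constant vector with a warning.
#'
#' @param cfg A `synthetic_config`.
#' @return A `protein_reference` of length `cfg$n_samples`.
#' @export
protein_sampler <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  rng <- cfg$protein_range_pct
  vals <- if (rng[1] == rng[2]) {
    warning("degenerate protein range; returning constant vector")
    rep(rng[1], cfg$n_samples)
  } else {
    local_seed(cfg$seed, stats::runif(cfg$n_samples, rng[1], rng[2]))
  }
  protein_reference(vals, paste0("S", seq_len(cfg$n_samples)))
}

#' Generate a synthetic maize-powder NIR dataset
#'
#' Each sample's clean spectrum is a Beer-Lambert sum of Gaussian bands,
#' `sum_b intensity_b * concentration * exp(-(lambda - center_b)^2 / (2
#' width_b^2))`, over the protein bands (scaled by that sample's protein %)
#' and the background bands (scaled by per-sample constituent draws). Each
#' replicate k then observes
#' `gain * clean + offset + slope * (lambda - min) / (max - min) + noise`,
#' with `gain ~ 1 + N(0, scatter_gain_sd)` and offset/slope/noise Gaussian,
#' all drawn independently per replicate. Deterministic given `cfg$seed`.
#'
#' @param cfg A `synthetic_config`.
#' @return A list with elements `replicates` (a `replicate_set`), `spectra`
#'   (the replicate-averaged `spectra_set`), `protein` (a
#'   `protein_reference`), and `truth` (ground-truth bookkeeping: clean
#'   spectra, per-replicate gain/offset/slope matrices, background
#'   concentrations, and `informative_channels`, the channel indices within
#'   one band width of any protein band center).
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  wl <- cfg$wavelengths
  p <- length(wl)
  n <- cfg$n_samples
  k <- cfg$replicate_count
  ramp <- (wl - min(wl)) / (max(wl) - min(wl))
  local_seed(cfg$seed, {
    rng <- cfg$protein_range_pct
    protein <- if (rng[1] == rng[2]) rep(rng[1], n) else stats::runif(n, rng[1], rng[2])
    mid <- mean(rng)
    bg_conc <- vapply(seq_along(cfg$background_conc_ranges), function(j) {
      r <- cfg$background_conc_ranges[[j]]
      stats::runif(n, r[1], r[2]) + cfg$closure_coefficients[j] * (protein - mid)
    }, numeric(n))
    bg_conc <- matrix(bg_conc, nrow = n)

    clean <- matrix(0, n, p)
    for (b in cfg$protein_bands) {
      clean <- clean + outer(protein * b$intensity_per_pct, gaussian_profile(wl, b))
    }
    for (j in seq_along(cfg$background_bands)) {
      b <- cfg$background_bands[[j]]
      clean <- clean + outer(bg_conc[, j] * b$intensity_per_pct,
                             gaussian_profile(wl, b))
    }

    gains <- matrix(1 + stats::rnorm(n * k, 0, cfg$scatter_gain_sd), n, k)
    offsets <- matrix(stats::rnorm(n * k, 0, cfg$scatter_offset_sd), n, k)
    slopes <- matrix(stats::rnorm(n * k, 0, cfg$baseline_slope_sd), n, k)
    reps <- vector("list", n)
    for (i in seq_len(n)) {
      m <- matrix(0, k, p)
      for (r in seq_len(k)) {
        m[r, ] <- gains[i, r] * clean[i, ] + offsets[i, r] +
          slopes[i, r] * ramp +
          stats::rnorm(p, 0, cfg$noise_sd)
      }
      reps[[i]] <- m
    }
    ids <- paste0("S", seq_len(n))
    informative <- sort(unique(unlist(lapply(cfg$protein_bands, function(b) {
      which(abs(wl - b$center_nm) <= b$width_nm)
    }))))
    repset <- replicate_set(wl, reps, ids)
    list(replicates = repset,
         spectra = average_replicates(repset),
         protein = protein_reference(protein, ids),
         truth = list(clean = clean, gains = gains, offsets = offsets,
                      slopes = slopes, background_conc = bg_conc,
                      informative_channels = informative))
  })
}
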