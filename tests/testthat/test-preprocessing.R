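grid3 <- function(p) seq(940, by = 10, length.out = p)

test_that("msc_fit takes the channel-wise calibration mean as reference", {
  s <- spectra_set(grid3(3), rbind(c(0, 1, 2), c(2, 3, 4)))
  expect_equal(as.numeric(msc_fit(s)$reference), c(1, 2, 3))

  r <- random_spectra(5, 10, seed = 11)
  oracle <- sapply(1:10, function(j) mean(r$absorbance[, j]))
  expect_equal(as.numeric(msc_fit(r)$reference), oracle, tolerance = 1e-14)

  flat <- spectra_set(grid3(3), rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_error(msc_fit(flat), "degenerate MSC reference")
  expect_error(msc_fit(subset_spectra(r, 1)), "at least 2")
})

test_that("msc_apply inverts per-spectrum affine corruption", {
  r <- random_spectra(4, 8, seed = 5)
  model <- msc_fit(r)
  ref <- model$reference
  probe <- spectra_set(r$wavelengths, rbind(ref, 2 * ref + 1), c("id", "aff"))
  out <- msc_apply(model, probe)
  expect_equal(as.numeric(out$gain), c(1, 2), tolerance = 1e-10)
  expect_equal(as.numeric(out$bias), c(0, 1), tolerance = 1e-10)
  expect_lt(max(abs(out$spectra$absorbance[1, ] - ref)), 1e-10)
  expect_lt(max(abs(out$spectra$absorbance[2, ] - ref)), 1e-10)
})

test_that("msc_apply per-spectrum fits match the normal-equations oracle", {
  r <- random_spectra(3, 6, seed = 21)
  model <- msc_fit(r)
  out <- msc_apply(model, r)
  oracle <- affine_fit_oracle(r$absorbance, model$reference)
  expect_equal(as.numeric(out$gain), as.numeric(oracle[, "gain"]), tolerance = 1e-10)
  expect_equal(as.numeric(out$bias), as.numeric(oracle[, "bias"]), tolerance = 1e-10)
})

test_that("snv standardizes every spectrum to mean 0 and sample SD 1", {
  s <- spectra_set(grid3(3), matrix(c(1, 2, 3), 1))
  expect_equal(as.numeric(snv(s)$absorbance), c(-1, 0, 1))
  expect_error(snv(spectra_set(grid3(3), matrix(2, 1, 3))), "constant spectrum")

  r <- random_spectra(1, 40, seed = 2)
  z <- snv(r)$absorbance
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)

  # invariance to per-spectrum affine corruption
  corrupted <- spectra_set(r$wavelengths, 3.7 * r$absorbance + 0.9)
  expect_equal(snv(corrupted)$absorbance, z, tolerance = 1e-10)
})

test_that("first derivative kills constants, recovers linear slopes, tracks analytics", {
  wl <- default_grid()
  const <- spectra_set(wl, matrix(5, 1, length(wl)))
  expect_true(all(first_derivative(const)$absorbance == 0))

  lin <- spectra_set(wl, matrix(3 + 0.25 * wl, 1))
  expect_equal(as.numeric(first_derivative(lin)$absorbance),
               rep(0.25, length(wl)), tolerance = 1e-10)

  f <- sin(2 * pi * wl / 300)
  got <- as.numeric(first_derivative(spectra_set(wl, matrix(f, 1)))$absorbance)
  want <- (2 * pi / 300) * cos(2 * pi * wl / 300)
  h <- diff(wl)[1]
  w <- 2 * pi / 300
  bound <- w^2 * h / 2 + w^3 * h^2 / 6   # one-sided edge + central truncation
  expect_lt(max(abs(got - want)), bound * 1.01)

  # translation invariance
  expect_equal(first_derivative(spectra_set(wl, matrix(f + 11, 1)))$absorbance,
               first_derivative(spectra_set(wl, matrix(f, 1)))$absorbance)

  expect_error(first_derivative(spectra_set(c(940, 950, 970),
                                            matrix(0, 1, 3))), "non-uniform")
})

test_that("Savitzky-Golay (7,2) reproduces quadratics and matches the local LS kernel", {
  wl <- grid3(31)
  x <- seq_along(wl)
  quad <- spectra_set(wl, matrix(2 - 0.3 * x + 0.05 * x^2, 1))
  expect_equal(savgol_smooth(quad, 7, 2)$absorbance, quad$absorbance,
               tolerance = 1e-10)

  # interior impulse response vs an independent least-squares fit per window
  impulse <- matrix(0, 1, 31); impulse[16] <- 1
  sm <- savgol_smooth(spectra_set(wl, impulse), 7, 2)$absorbance
  oracle <- sapply(13:19, function(j) {
    off <- (j - 3):(j + 3) - j
    yy <- impulse[1, (j - 3):(j + 3)]
    fit <- stats::lm(yy ~ off + I(off^2))
    unname(stats::predict(fit, data.frame(off = 0)))
  })
  expect_equal(as.numeric(sm[1, 13:19]), oracle, tolerance = 1e-10)

  expect_error(savgol_smooth(quad, 6, 2), "odd")
  expect_error(savgol_smooth(quad, 7, 7), "less than the window")
  expect_error(savgol_smooth(spectra_set(grid3(5), matrix(0, 1, 5)), 7, 2),
               "exceeds channel count")
})

test_that("Savitzky-Golay smoothing shrinks white-noise variance", {
  wl <- grid3(64)
  vars <- withr::with_seed(31, t(replicate(100, {
    x <- rnorm(64)
    c(raw = stats::var(x),
      sm = stats::var(as.numeric(savgol_smooth(spectra_set(wl, matrix(x, 1)))$absorbance)))
  })))
  expect_true(all(vars[, "sm"] < vars[, "raw"]))
})

test_that("savgol with order >= window - 1 is the identity", {
  r <- random_spectra(2, 20, seed = 6)
  expect_equal(savgol_smooth(r, 5, 4)$absorbance, r$absorbance, tolerance = 1e-9)
})

test_that("apply_plan composes steps and never leaks validation into MSC", {
  d <- generate_dataset(synthetic_config(n_samples = 12, seed = 4))
  cal <- subset_spectra(d$spectra, 1:8)
  val <- subset_spectra(d$spectra, 9:12)

  got <- apply_plan("sg+snv", cal, val)
  manual <- snv(savgol_smooth(cal, 7, 2))
  expect_equal(got$calibration$absorbance, manual$absorbance)

  # empty plan = identity
  idp <- apply_plan(preprocess_plan(character(0)), cal, val)
  expect_equal(idp$calibration$absorbance, cal$absorbance)

  # dropping a validation sample must not change the others
  full <- apply_plan("d1+msc", cal, val)$validation$absorbance
  dropped <- apply_plan("d1+msc", cal, subset_spectra(val, 1:3))$validation$absorbance
  expect_equal(full[1:3, ], dropped)

  # the eight named schemes all run and are pairwise distinct
  outs <- lapply(standard_plans(), function(pl) apply_plan(pl, cal, val)$calibration$absorbance)
  for (i in 1:7) for (j in (i + 1):8) {
    expect_gt(max(abs(outs[[i]] - outs[[j]])), 0)
  }
})

test_that("plan parsing accepts the composite names and rejects junk", {
  expect_equal(preprocess_plan("d1+msc")$steps, c("D1", "MSC"))
  expect_error(preprocess_plan("osc"), "unknown preprocessing step")
  expect_error(preprocess_plan("sg", sg_window = 6), "odd")
})
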