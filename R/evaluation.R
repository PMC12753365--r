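#' Pearson correlation coefficient
#'
#' `R = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) * sum((y -
#' ybar)^2))`; the standard goodness-of-fit statistic between measured and
#' predicted values.
#'
#' @param measured,predicted Numeric vectors of equal length >= 2, neither
#'   constant.
#' @return The correlation in [-1, 1].
#' @export
pearson_r <- function(measured, predicted) {
  measured <- as.numeric(measured); predicted <- as.numeric(predicted)
  stopifnot(length(measured) == length(predicted), length(measured) >= 2)
  if (stats::sd(measured) == 0 || stats::sd(predicted) == 0) {
    stop("undefined correlation: constant vector")
  }
  stats::cor(measured, predicted)
}

#' Root mean square error
#'
#' `RMSE = sqrt(mean((measured - predicted)^2))`, divisor m (the number of
#' pairs), residuals taken against the predictions.
#'
#' @param measured,predicted Numeric vectors of equal length >= 1.
#' @return Non-negative RMSE in the units of `measured`.
#' @export
rmse <- function(measured, predicted) {
  measured <- as.numeric(measured); predicted <- as.numeric(predicted)
  if (length(measured) != length(predicted)) {
    stop("length mismatch: ", length(measured), " vs ", length(predicted))
  }
  stopifnot(length(measured) >= 1)
  sqrt(mean((measured - predicted)^2))
}

#' Residual predictive deviation
#'
#' `RPD = SD / RMSEP`, where SD is the sample standard deviation (divisor
#' n-1) of the validation-set reference values. An RPD above 2 is the
#' conventional threshold for a usable quantitative NIR model.
#'
#' @param reference_sd Sample SD of the validation reference values.
#' @param rmsep Validation RMSE, > 0.
#' @return The RPD.
#' @export
rpd <- function(reference_sd, rmsep) {
  stopifnot(reference_sd >= 0)
  if (rmsep <= 0) stop("RPD undefined for RMSEP <= 0")
  reference_sd / rmsep
}

#' Assemble an evaluation report from measured/predicted pairs
#'
#' @param yc,yc_hat Calibration reference values and predictions.
#' @param yv,yv_hat Validation reference values and predictions.
#' @param fit_seconds,predict_seconds Optional wall times.
#' @param model_id,plan_id Optional identifiers for reporting.
#' @return An `evaluation_report` with `r_c`, `rmse_c`, `r_p`, `rmse_p`,
#'   `sd_validation`, `rpd` and the timing/identity fields.
#' @export
evaluate_predictions <- function(yc, yc_hat, yv, yv_hat,
                                 fit_seconds = NA_real_,
                                 predict_seconds = NA_real_,
                                 model_id = NA_character_,
                                 plan_id = NA_character_) {
  sd_v <- stats::sd(yv)
  rmse_p <- rmse(yv, yv_hat)
  structure(list(r_c = pearson_r(yc, yc_hat), rmse_c = rmse(yc, yc_hat),
                 r_p = pearson_r(yv, yv_hat), rmse_p = rmse_p,
                 sd_validation = sd_v, rpd = rpd(sd_v, rmse_p),
                 fit_seconds = fit_seconds, predict_seconds = predict_seconds,
                 model_id = model_id, plan_id = plan_id),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> R_c %.3f RMSE_c %.3f | R_p %.3f RMSE_p %.3f RPD %.3f\n",
              x$r_c, x$rmse_c, x$r_p, x$rmse_p, x$rpd))
  invisible(x)
}

#' Histogram of prediction errors
#'
#' Bins the residuals `predicted - measured` into bins of the given width,
#' with bin edges anchored at zero (`[0, w)`, `[w, 2w)`, `[-w, 0)`, ...).
#' The counts always sum to the number of pairs, whatever the width.
#'
#' @param measured,predicted Numeric vectors of equal length.
#' @param bin_width Positive bin width.
#' @return A data.frame with `lower`, `upper` and `count` per occupied bin.
#' @export
error_histogram <- function(measured, predicted, bin_width) {
  if (bin_width <= 0) stop("bin_width must be positive")
  resid <- as.numeric(predicted) - as.numeric(measured)
  stopifnot(length(resid) >= 1)
  bin <- floor(resid / bin_width)
  tab <- table(bin)
  lower <- as.numeric(names(tab)) * bin_width
  data.frame(lower = lower, upper = lower + bin_width,
             count = as.integer(tab))
}

#' Define a factorial experiment grid
#'
#' @param plans Preprocessing plan names (default the eight of
#'   [standard_plans()]).
#' @param models Model names among `"plsr"`, `"svr-linear"`, `"svr-rbf"`.
#' @param selections Optional selection method names among `"plsrc"`,
#'   `"cars"`, `"spa"`, `"uve"`, run with PLSR on `selection_plan`.
#' @param selection_plan Preprocessing plan used for the selection rows.
#' @param seed Master seed; every randomized stage draws a sub-seed from it.
#' @param cv_folds Cross-validation folds.
#' @return An `experiment_grid`.
#' @export
experiment_grid <- function(plans = standard_plans(),
                            models = "plsr",
                            selections = character(0),
                            selection_plan = "d1+msc",
                            seed = 1L, cv_folds = 5) {
  stopifnot(length(plans) >= 1, length(models) >= 1)
  bad <- setdiff(models, c("plsr", "svr-linear", "svr-rbf"))
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(selections, c("plsrc", "cars", "spa", "uve"))
  if (length(bad)) stop("unknown selection method(s): ", paste(bad, collapse = ", "))
  for (pl in unique(c(plans, if (length(selections)) selection_plan))) preprocess_plan(pl)
  structure(list(plans = plans, models = models, selections = selections,
                 selection_plan = selection_plan, seed = as.integer(seed),
                 cv_folds = cv_folds),
            class = "experiment_grid")
}

#' Run the full preprocessing x model (x selection) experiment
#'
#' Splits the samples once with SPXY (shared by every cell), then for each
#' plan/model cell preprocesses, tunes, fits and evaluates, and finally
#' runs any requested selection methods with a PLSR refit on the selection
#' plan. A failing cell is recorded in the `error` column without aborting
#' the grid. Metric columns are deterministic given the grid seed.
#'
#' @param grid An `experiment_grid`.
#' @param spectra A `spectra_set` of replicate-averaged sample spectra.
#' @param protein A `protein_reference` aligned with the spectra.
#' @param ratio SPXY calibration:validation ratio (default 2).
#' @return A data.frame with one row per grid cell: `plan`, `model`,
#'   `selection`, `n_selected`, `n_components`, hyperparameters, `r_c`,
#'   `rmse_c`, `r_p`, `rmse_p`, `rpd`, `fit_seconds`, `error`. The SPXY
#'   split is attached as attribute `"split"`.
#' @export
run_experiment <- function(grid, spectra, protein, ratio = 2) {
  stopifnot(inherits(grid, "experiment_grid"), inherits(spectra, "spectra_set"))
  split <- spxy_split(spectra, protein, ratio)
  cal <- subset_spectra(spectra, split$calibration_ids)
  val <- subset_spectra(spectra, split$validation_ids)
  yc <- as.numeric(protein[split$calibration_ids])
  yv <- as.numeric(protein[split$validation_ids])
  cv <- cv_plan(length(yc), grid$cv_folds, seed = grid$seed)

  rows <- list()
  cell <- function(plan, model, selection, fn) {
    out <- tryCatch(fn(), error = function(e) conditionMessage(e))
    row <- data.frame(plan = plan, model = model, selection = selection,
                      n_selected = NA_integer_, n_components = NA_integer_,
                      C = NA_real_, gamma = NA_real_, epsilon = NA_real_,
                      r_c = NA_real_, rmse_c = NA_real_, r_p = NA_real_,
                      rmse_p = NA_real_, rpd = NA_real_,
                      fit_seconds = NA_real_, error = NA_character_)
    if (is.character(out)) {
      row$error <- out
    } else {
      scalar_fields <- c("n_selected", "n_components", "C", "gamma", "epsilon",
                         "r_c", "rmse_c", "r_p", "rmse_p", "rpd", "fit_seconds")
      for (f in intersect(names(out), scalar_fields)) row[[f]] <- out[[f]]
    }
    rows[[length(rows) + 1L]] <<- row
  }

  for (plan in grid$plans) {
    prep <- apply_plan(plan, cal, val)
    Xc <- prep$calibration$absorbance
    Xv <- prep$validation$absorbance
    for (model in grid$models) {
      cell(plan, model, "none", function() {
        t0 <- proc.time()[["elapsed"]]
        if (model == "plsr") {
          tuned <- select_n_components(Xc, yc, 1:20, cv)
          fit <- fit_plsr(Xc, yc, tuned$best)
          rep_ <- evaluate_predictions(yc, predict_plsr(fit, Xc),
                                       yv, predict_plsr(fit, Xv))
          rep_$n_components <- tuned$best
        } else {
          kern <- sub("svr-", "", model)
          fit <- fit_svr_grid(Xc, yc, kern, cv)
          rep_ <- evaluate_predictions(yc, predict_svr(fit, Xc),
                                       yv, predict_svr(fit, Xv))
          rep_$C <- fit$config$C
          rep_$gamma <- fit$config$gamma
          rep_$epsilon <- fit$config$epsilon
        }
        rep_$fit_seconds <- proc.time()[["elapsed"]] - t0
        rep_
      })
    }
  }

  if (length(grid$selections)) {
    prep <- apply_plan(grid$selection_plan, cal, val)
    Xc <- prep$calibration$absorbance
    Xv <- prep$validation$absorbance
    for (method in grid$selections) {
      cell(grid$selection_plan, "plsr", method, function() {
        sel <- switch(method,
          plsrc = plsrc_select(Xc, yc, cv),
          cars = cars_select(Xc, yc, cv = cv, seed = grid$seed + 1L),
          spa = spa_select(Xc, yc, cv = cv),
          uve = uve_select(Xc, yc, seed = grid$seed + 2L, cv = cv))
        refit_with_selection(sel, Xc, yc, Xv, yv, cv)
      })
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "split") <- split
  out
}
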