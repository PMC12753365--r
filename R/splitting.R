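#' Joint spectral-response distance matrix
#'
#' The SPXY distance between samples i and j is the sum of a spectral term
#' and a response term, each normalized by its maximum over all pairs:
#' `d(i,j) = dx(i,j)/max(dx) + dy(i,j)/max(dy)`, with `dx` Euclidean on
#' spectra and `dy = |y_i - y_j|`. If either term is degenerate (all
#' spectra, or all responses, identical) it is dropped with a warning.
#'
#' @param X Numeric sample-by-channel matrix.
#' @param y Numeric response vector (protein %), length `nrow(X)`.
#' @return Symmetric `n x n` distance matrix with zero diagonal.
#' @export
joint_distance_matrix <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2, all(is.finite(X)), all(is.finite(y)))
  dx <- unname(as.matrix(stats::dist(X)))
  dy <- abs(outer(y, y, "-"))
  mx <- max(dx)
  my <- max(dy)
  d <- matrix(0, nrow(X), nrow(X))
  if (mx > 0) d <- d + dx / mx else warning("all spectra identical; spectral term dropped")
  if (my > 0) d <- d + dy / my else warning("all responses identical; response term dropped")
  d
}

#' SPXY calibration/validation split
#'
#' Deterministic sample-set partitioning that jointly covers spectral and
#' response space. The calibration set is seeded with the pair at maximal
#' joint distance, then grown greedily: at each step the sample whose
#' minimum joint distance to the current calibration set is largest joins
#' the set, until `floor(n * ratio / (ratio + 1))` samples are reached. The
#' remainder forms the validation set. Ties are broken toward the lowest
#' index after a lexicographic sort of sample ids, so the split is invariant
#' to row order.
#'
#' @param spectra A `spectra_set` (raw, as-loaded spectra are conventional).
#' @param y A `protein_reference` or numeric vector aligned with the samples.
#' @param ratio Calibration:validation ratio (default 2, i.e. 2:1, giving
#'   60/30 from 90 samples).
#' @return An object of class `split_result` with `calibration_ids`,
#'   `validation_ids` (both ordered), the index vectors `calibration_idx` /
#'   `validation_idx` into the original sample order, and `ratio`.
#' @export
spxy_split <- function(spectra, y, ratio = 2) {
  stopifnot(inherits(spectra, "spectra_set"))
  y <- as.numeric(y)
  n <- nrow(spectra$absorbance)
  stopifnot(length(y) == n)
  if (n < 3) stop("SPXY needs at least 3 samples")
  n_cal <- floor(n * ratio / (ratio + 1))
  if (n_cal < 2) stop("calibration size ", n_cal, " is below the minimum of 2")

  ord <- order(spectra$sample_ids, method = "radix")
  ids <- spectra$sample_ids[ord]
  D <- joint_distance_matrix(spectra$absorbance[ord, , drop = FALSE], y[ord])

  # seed with the globally farthest pair (lowest indices on ties)
  flat <- which(D == max(D), arr.ind = TRUE)
  flat <- flat[flat[, 1] < flat[, 2], , drop = FALSE]
  flat <- flat[order(flat[, 1], flat[, 2]), , drop = FALSE]
  sel <- as.integer(flat[1, ])
  remaining <- setdiff(seq_len(n), sel)

  dmin <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < n_cal) {
    cand <- remaining[which(dmin[remaining] == max(dmin[remaining]))]
    nxt <- min(cand)
    sel <- c(sel, nxt)
    remaining <- setdiff(remaining, nxt)
    dmin <- pmin(dmin, D[, nxt])
  }
  cal_ids <- ids[sel]
  val_ids <- ids[sort(remaining)]
  structure(list(calibration_ids = cal_ids,
                 validation_ids = val_ids,
                 calibration_idx = match(cal_ids, spectra$sample_ids),
                 validation_idx = match(val_ids, spectra$sample_ids),
                 ratio = ratio),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result> ", length(x$calibration_ids), " calibration / ",
      length(x$validation_ids), " validation (ratio ", x$ratio, ":1)\n", sep = "")
  invisible(x)
}

#' Per-set reference statistics for a split
#'
#' Summarizes each side of a split the way calibration-transfer tables are
#' usually reported: count, range, mean and sample SD of the reference
#' values.
#'
#' @param split A `split_result`.
#' @param y A `protein_reference` named by sample id.
#' @return A data.frame with one row per set.
#' @export
split_summary <- function(split, y) {
  stopifnot(inherits(split, "split_result"))
  one <- function(ids, label) {
    v <- as.numeric(y[ids])
    data.frame(set = label, n = length(v), min = min(v), max = max(v),
               mean = mean(v), sd = stats::sd(v))
  }
  rbind(one(split$calibration_ids, "calibration"),
        one(split$validation_ids, "validation"))
}
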