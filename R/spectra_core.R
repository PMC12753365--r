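#' Construct a spectra set
#'
#' A `spectra_set` bundles an absorbance matrix with its wavelength grid and
#' sample identifiers. Rows are samples, columns are spectral channels.
#'
#' @param wavelengths Numeric vector of channel wavelengths in nm, strictly
#'   increasing.
#' @param absorbance Numeric matrix, `n_samples x n_channels`, finite values.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row. Defaults to `S1, S2, ...`.
#' @return An object of class `spectra_set` with fields `wavelengths`,
#'   `absorbance` (row names set to the sample ids) and `sample_ids`.
#' @export
spectra_set <- function(wavelengths, absorbance, sample_ids = NULL) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- if (nrow(absorbance) > 0) paste0("S", seq_len(nrow(absorbance))) else character(0)
  }
  sample_ids <- as.character(sample_ids)
  if (length(wavelengths) != ncol(absorbance)) {
    stop("channel count mismatch: ", length(wavelengths), " wavelengths vs ",
         ncol(absorbance), " absorbance columns")
  }
  if (length(wavelengths) >= 2 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths not increasing")
  }
  if (any(!is.finite(absorbance))) {
    bad <- which(!is.finite(absorbance), arr.ind = TRUE)[1, ]
    stop("non-finite absorbance at row ", bad[1], ", column ", bad[2])
  }
  if (nrow(absorbance) != length(sample_ids)) {
    stop("row count (", nrow(absorbance), ") does not match number of sample ids (",
         length(sample_ids), ")")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- format(wavelengths, trim = TRUE, digits = 15)
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 sample_ids = sample_ids),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " samples x ",
      length(x$wavelengths), " channels", sep = "")
  if (length(x$wavelengths)) {
    cat(" (", min(x$wavelengths), "-", max(x$wavelengths), " nm)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Default wavelength grid
#'
#' 128 evenly spaced channels over the 940-1660 nm short-wave NIR window, the
#' region that carries the N-H, C-H and O-H overtone bands used for protein
#' work in cereal powders.
#'
#' @param n_channels Number of channels (default 128).
#' @param from,to Wavelength span in nm.
#' @return Numeric vector of wavelengths in nm.
#' @export
default_grid <- function(n_channels = 128, from = 940, to = 1660) {
  seq(from, to, length.out = n_channels)
}

#' Subset a spectra set by sample and/or channel
#'
#' @param spectra A `spectra_set`.
#' @param samples Sample ids or row indices (optional).
#' @param channels Channel indices (optional).
#' @return A `spectra_set` restricted to the requested rows/columns.
#' @export
subset_spectra <- function(spectra, samples = NULL, channels = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  rows <- if (is.null(samples)) seq_len(nrow(spectra$absorbance)) else samples
  if (is.character(rows)) rows <- match(rows, spectra$sample_ids)
  cols <- if (is.null(channels)) seq_along(spectra$wavelengths) else sort(unique(channels))
  spectra_set(spectra$wavelengths[cols],
              spectra$absorbance[rows, cols, drop = FALSE],
              spectra$sample_ids[rows])
}

#' Construct a replicate set
#'
#' Replicate measurements of each sample on a shared wavelength grid, prior
#' to averaging. Each element of `replicates` is an `n_replicates x
#' n_channels` matrix for one sample.
#'
#' @param wavelengths Shared wavelength grid (nm).
#' @param replicates List of numeric matrices, one per sample.
#' @param sample_ids Unique sample identifiers.
#' @return An object of class `replicate_set`.
#' @export
replicate_set <- function(wavelengths, replicates, sample_ids = NULL) {
  wavelengths <- as.numeric(wavelengths)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_along(replicates))
  stopifnot(length(replicates) == length(sample_ids))
  replicates <- lapply(replicates, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != length(wavelengths)) {
      stop("replicate grid mismatch: ", ncol(m), " channels vs ",
           length(wavelengths), " wavelengths")
    }
    if (nrow(m) < 1) stop("each sample needs at least one replicate")
    m
  })
  structure(list(wavelengths = wavelengths, replicates = replicates,
                 sample_ids = as.character(sample_ids)),
            class = "replicate_set")
}

#' Average replicate spectra into one spectrum per sample
#'
#' Each sample's final spectrum is the channel-wise arithmetic mean of its
#' replicate measurements, the usual way repeated probe placements on a
#' powder cell are consolidated.
#'
#' @param reps A `replicate_set`.
#' @return A `spectra_set` with one averaged row per sample.
#' @export
average_replicates <- function(reps) {
  stopifnot(inherits(reps, "replicate_set"))
  avg <- t(vapply(reps$replicates, colMeans, numeric(length(reps$wavelengths))))
  if (length(reps$replicates) == 1) avg <- matrix(avg, nrow = 1)
  spectra_set(reps$wavelengths, avg, reps$sample_ids)
}

#' Construct a protein reference vector
#'
#' @param values Numeric vector of protein contents (% dry basis).
#' @param sample_ids Sample identifiers aligned with `values`.
#' @param range Plausible range check, default 0-100%.
#' @return Named numeric vector of class `protein_reference`.
#' @export
protein_reference <- function(values, sample_ids = names(values),
                              range = c(0, 100)) {
  force(sample_ids)
  values <- as.numeric(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_along(values))
  stopifnot(length(values) == length(sample_ids))
  if (any(!is.finite(values))) stop("non-finite protein values")
  if (any(values < range[1] | values > range[2])) {
    stop("protein values outside plausible range [", range[1], ", ", range[2], "]")
  }
  names(values) <- as.character(sample_ids)
  class(values) <- c("protein_reference", "numeric")
  values
}

#' Read a spectra CSV (and optional protein reference CSV)
#'
#' The spectral CSV has a first column `sample_id` and remaining column
#' headers giving wavelengths in nm; one row per sample. The reference CSV
#' has columns `sample_id` and `protein_pct`.
#'
#' @param path Path to the spectral CSV.
#' @param reference_path Optional path to the protein reference CSV.
#' @return A `spectra_set`, or if `reference_path` is given a list with
#'   elements `spectra` and `protein` (reference reordered to match the
#'   spectra's sample order).
#' @export
read_spectra <- function(path, reference_path = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 1 || names(raw)[1] != "sample_id") {
    stop("first column must be 'sample_id' in ", path)
  }
  ids <- raw[[1]]
  wl <- suppressWarnings(as.numeric(names(raw)[-1]))
  if (length(wl) && any(is.na(wl))) {
    stop("non-numeric wavelength header at column ",
         which(is.na(wl))[1] + 1, " of ", path)
  }
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(wl))
  for (j in seq_along(wl)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    if (any(is.na(v) & !is.na(raw[[j + 1]]))) {
      stop("non-numeric cell at row ", which(is.na(v))[1], ", column ", j + 1,
           " of ", path)
    }
    mat[, j] <- v
  }
  spectra <- spectra_set(wl, mat, ids)
  if (is.null(reference_path)) return(spectra)
  ref <- utils::read.csv(reference_path, check.names = FALSE)
  if (!all(c("sample_id", "protein_pct") %in% names(ref))) {
    stop("reference CSV needs columns sample_id and protein_pct")
  }
  idx <- match(spectra$sample_ids, as.character(ref$sample_id))
  if (any(is.na(idx))) {
    stop("reference is missing samples: ",
         paste(spectra$sample_ids[is.na(idx)], collapse = ", "))
  }
  prot <- protein_reference(ref$protein_pct[idx], spectra$sample_ids)
  list(spectra = spectra, protein = prot)
}

#' Write a spectra set to CSV
#'
#' Full double precision is preserved (17 significant digits) so that
#' `read_spectra(write_spectra(x))` round-trips exactly.
#'
#' @param spectra A `spectra_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_set"))
  header <- c("sample_id", format(spectra$wavelengths, trim = TRUE, digits = 15))
  lines <- paste(header, collapse = ",")
  if (nrow(spectra$absorbance) > 0) {
    body <- vapply(seq_len(nrow(spectra$absorbance)), function(i) {
      paste(c(spectra$sample_ids[i],
              formatC(spectra$absorbance[i, ], format = "g", digits = 17)),
            collapse = ",")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a protein reference to CSV
#'
#' @param protein A `protein_reference`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein <- function(protein, path) {
  df <- data.frame(sample_id = names(protein),
                   protein_pct = formatC(as.numeric(protein), format = "g", digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
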