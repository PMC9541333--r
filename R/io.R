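#' Write spectra to a wide CSV with a JSON sidecar
#'
#' Serializes a long spectra tibble as a wide CSV (first column
#' `wavelength_nm`, then one column per spectrum named
#' `<label>.<spectrum>`), plus a JSON sidecar `<path>.json` recording the
#' labels and the per-spectrum nuisance draws when present.
#'
#' @param data A long spectra tibble (see [simulate_spectra()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_spectra()]
#' @export
write_spectra <- function(data, path) {
  mats <- spectra_matrices(data)
  wide <- data.frame(wavelength_nm = mats$grid)
  for (lbl in names(mats$sets)) {
    m <- mats$sets[[lbl]]
    cols <- as.data.frame(t(m))
    names(cols) <- paste0(lbl, ".", seq_len(nrow(m)))
    wide <- cbind(wide, cols)
  }
  write.csv(wide, path, row.names = FALSE)
  sidecar <- list(
    labels = names(mats$sets),
    n_spectra = vapply(mats$sets, nrow, integer(1)),
    nuisance = nuisance_summary(data)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", null = "null")
  invisible(path)
}

#' Read spectra written by [write_spectra()]
#'
#' @param path CSV path produced by [write_spectra()].
#' @return A long spectra tibble with columns `label`, `spectrum`,
#'   `wavelength`, `reflectance`.
#' @export
read_spectra <- function(path) {
  wide <- read.csv(path, check.names = FALSE)
  if (names(wide)[1] != "wavelength_nm") {
    abort("Expected first column 'wavelength_nm'.")
  }
  grid <- wide[[1]]
  ids <- names(wide)[-1]
  parts <- regmatches(ids, regexpr("\\.[0-9]+$", ids))
  if (length(parts) != length(ids)) {
    abort("Spectrum columns must be named '<label>.<index>'.")
  }
  labels <- substr(ids, 1, nchar(ids) - nchar(parts))
  bind_rows(lapply(seq_along(ids), function(j) {
    tibble(label = labels[j],
           spectrum = as.integer(sub("^\\.", "", parts[j])),
           wavelength = grid,
           reflectance = wide[[j + 1]])
  }))
}

#' Ingest an external labeled-spectra table
#'
#' Entry point for real (e.g. clinical) data: a CSV with one row per
#' measured spectrum, a label column naming the tissue type, and one
#' numeric column per wavelength whose name is (or ends in) the wavelength
#' in nm (`"500"`, `"wl_500"`, `"X500"`, ...). At least two distinct labels
#' are required, since the overlap analysis compares tissue types.
#'
#' @param path CSV file path.
#' @param label_column Name of the label column (default `"label"`).
#' @return A long spectra tibble suitable for [preprocess_spectra()] and
#'   [pairwise_overlap()].
#' @export
ingest_spectra <- function(path, label_column = "label") {
  df <- read.csv(path, check.names = FALSE)
  if (!label_column %in% names(df)) {
    abort(paste0("Label column '", label_column, "' not found in ", path, "."))
  }
  labels <- as.character(df[[label_column]])
  spec_cols <- setdiff(names(df), label_column)
  wl <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", spec_cols)))
  if (anyNA(wl)) {
    abort(paste0("Column(s) ", paste(spec_cols[is.na(wl)], collapse = ", "),
                 " do not encode a wavelength."))
  }
  if (any(diff(wl) <= 0)) {
    abort("Wavelength columns must be in strictly increasing order.")
  }
  X <- as.matrix(df[spec_cols])
  if (!is.numeric(X) || anyNA(X)) {
    bad <- which(apply(df[spec_cols], 2, function(c) anyNA(suppressWarnings(as.numeric(c)))))
    abort(paste0("Non-numeric reflectance values in column(s) ",
                 paste(spec_cols[bad], collapse = ", "), "."))
  }
  if (length(unique(labels)) < 2) {
    abort("Need at least two distinct labels to compare tissue types.")
  }
  idx <- stats::ave(seq_along(labels), labels, FUN = seq_along)
  bind_rows(lapply(seq_len(nrow(X)), function(i) {
    tibble(label = labels[i], spectrum = idx[i], wavelength = wl,
           reflectance = X[i, ])
  }))
}
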