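#' Preprocessing algorithm names
#'
#' The eight benchmark algorithms plus the identity baseline, grouped by
#' what they correct: scale and offset (`snv`, `msc`, `min_max`), scale only
#' (`auc`, `single_wavelength`), offset only (`mean_center`), and derivative
#' shape descriptors (`first_derivative`, `second_derivative`).
#'
#' @return Character vector of algorithm names accepted by
#'   [preprocess_spectra()].
#' @export
preprocessing_algorithms <- function() {
  c("none", "snv", "msc", "min_max", "mean_center", "auc",
    "single_wavelength", "first_derivative", "second_derivative")
}

# family annotation used in summaries and plots
algorithm_family <- function(algorithm) {
  fam <- c(none = "baseline", snv = "scale+offset", msc = "scale+offset",
           min_max = "scale+offset", auc = "scale", single_wavelength = "scale",
           mean_center = "offset", first_derivative = "derivative",
           second_derivative = "derivative")
  unname(fam[algorithm])
}

#' Standard normal variate
#'
#' Centers each spectrum to zero mean and scales it to unit standard
#' deviation (sample, n-1 denominator). Removes per-spectrum offset and
#' scale without reference to any other spectrum.
#'
#' @param x Numeric vector (one spectrum).
#' @return Standardized vector with mean 0 and sd 1.
#' @examples
#' snv(c(1, 2, 3))
#' @export
snv <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("SNV undefined for a constant spectrum (standard deviation is 0).")
  }
  (x - mean(x)) / s
}

#' Min-max normalization
#'
#' Maps each spectrum affinely onto `[0, 1]` using its own minimum and
#' maximum.
#'
#' @param x Numeric vector (one spectrum).
#' @return Vector with `min = 0` and `max = 1`.
#' @export
min_max_scale <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    abort("Min-max normalization undefined for a constant spectrum.")
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Mean centering
#'
#' Subtracts each spectrum's own mean; scale is deliberately retained.
#'
#' @param x Numeric vector (one spectrum).
#' @return Vector with mean 0.
#' @export
mean_center <- function(x) x - mean(x)

#' Area-under-the-curve (L1) normalization
#'
#' Divides each spectrum by the sum of its values, so non-negative spectra
#' integrate to 1. Removes per-spectrum scale; offsets are retained.
#'
#' @param x Numeric vector (one spectrum).
#' @return Vector summing to 1.
#' @export
auc_normalize <- function(x) {
  s <- sum(x)
  if (s == 0) abort("AUC normalization undefined: spectrum sums to zero.")
  x / s
}

#' Single-wavelength normalization
#'
#' Divides each spectrum by its value at a reference wavelength, chosen in a
#' low-absorption window (default 730 nm, where blood, water and fat all
#' absorb weakly). No interpolation: the reference must be a grid point.
#'
#' @param x Numeric vector (one spectrum).
#' @param grid Wavelength grid of `x` in nm.
#' @param lambda0 Reference wavelength in nm (default 730).
#' @return Vector equal to 1 at the reference wavelength.
#' @export
sw_normalize <- function(x, grid, lambda0 = 730) {
  j <- match(TRUE, abs(grid - lambda0) < 1e-9)
  if (is.na(j)) {
    abort(paste0("Reference wavelength ", lambda0,
                 " nm is not on the grid (no interpolation is performed)."))
  }
  if (x[j] == 0) {
    abort(paste0("Spectrum is zero at the reference wavelength ",
                 lambda0, " nm."))
  }
  x / x[j]
}

# Savitzky-Golay projection applied along the rows of X (spectra).
# Interior points use the central least-squares coefficients; within half a
# window of either end, the one-sided rows of the projection matrix are
# used (a full polynomial fit over the first/last window), as in the usual
# sgolayfilt transient handling.
sg_filter_matrix <- function(X, window, polyorder, deriv = 0) {
  nw <- ncol(X)
  if (window %% 2 != 1) abort("`window` must be odd (in samples).")
  if (polyorder >= window) abort("`polyorder` must be smaller than `window`.")
  if (deriv > polyorder) abort("Derivative order must not exceed `polyorder`.")
  if (window > nw) {
    abort(paste0("Savitzky-Golay window (", window,
                 " samples) exceeds the segment length (", nw, ")."))
  }
  FF <- signal::sgolay(p = polyorder, n = window, m = deriv, ts = 1)
  FF <- unclass(FF)
  h <- (window - 1) / 2
  center <- FF[h + 1, ]
  # interior via FIR convolution (columns of t(X) are spectra)
  Yt <- stats::filter(t(X), rev(center), method = "convolution", sides = 2)
  Y <- t(Yt)
  # transients from the one-sided projection rows
  Y[, seq_len(h)] <- X[, seq_len(window), drop = FALSE] %*% t(FF[seq_len(h), , drop = FALSE])
  Y[, (nw - h + 1):nw] <- X[, (nw - window + 1):nw, drop = FALSE] %*%
    t(FF[(h + 2):window, , drop = FALSE])
  unname(Y)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with an odd window. Polynomials
#' of degree `polyorder` or less pass through unchanged.
#'
#' @param x Numeric vector (one spectrum) on a uniform grid.
#' @param window Window length in samples (odd; default 199, i.e. 199 nm on
#'   a 1-nm grid).
#' @param polyorder Polynomial order (default 2).
#' @return Smoothed vector, same length.
#' @export
sg_smooth <- function(x, window = 199, polyorder = 2) {
  as.vector(sg_filter_matrix(matrix(x, nrow = 1), window, polyorder, deriv = 0))
}

#' Savitzky-Golay spectral derivative
#'
#' First or second derivative of a spectrum with respect to wavelength,
#' computed in a single pass with Savitzky-Golay derivative coefficients
#' (equivalent to smoothing with the same window and differentiating the
#' local polynomial fit). Units are per sample spacing: per nm for the
#' default 1-nm grid (first derivative), per nm^2 (second).
#'
#' @inheritParams sg_smooth
#' @param order Derivative order, 1 or 2.
#' @param spacing Grid spacing in nm (default 1).
#' @return Derivative vector, same length as `x`.
#' @examples
#' grid <- 1:300
#' max(abs(sg_derivative(3 * grid + 2, order = 1) - 3))  # exact for lines
#' @export
sg_derivative <- function(x, order = 1, window = 199, polyorder = 2,
                          spacing = 1) {
  if (!order %in% c(1, 2)) abort("`order` must be 1 or 2.")
  y <- sg_filter_matrix(matrix(x, nrow = 1), window, polyorder, deriv = order)
  as.vector(y) / spacing^order
}

#' Fit a multiplicative scatter correction model
#'
#' The reference spectrum is the column-wise mean of all spectra in the
#' dataset. Each spectrum is then modeled as `offset + scale * reference`
#' by ordinary least squares, and corrected as `(spectrum - offset) / scale`.
#' Because the reference is a dataset mean, adding or removing spectra
#' changes the correction of every spectrum (unlike SNV).
#'
#' @param data A long spectra tibble (see [simulate_spectra()]) or a numeric
#'   matrix with spectra in rows. All spectra passed in one call share one
#'   reference.
#' @return An object of class `msc_model` with elements `reference`
#'   (numeric vector), `grid` (if known) and `n_spectra`.
#' @seealso [msc_apply()]
#' @export
msc_fit <- function(data) {
  if (is.data.frame(data)) {
    mats <- spectra_matrices(data)
    X <- do.call(rbind, mats$sets)
    grid <- mats$grid
  } else {
    X <- as.matrix(data)
    grid <- NULL
  }
  if (nrow(X) < 2) abort("MSC needs at least two spectra to form a reference.")
  reference <- colMeans(X)
  if (var(reference) == 0) {
    abort("MSC reference spectrum is constant; the regression is degenerate.")
  }
  structure(
    list(reference = reference, grid = grid, n_spectra = nrow(X)),
    class = "msc_model"
  )
}

#' Apply a multiplicative scatter correction model
#'
#' @param model An [msc_fit()] model.
#' @param x A numeric vector (one spectrum) or matrix with spectra in rows,
#'   on the model's grid.
#' @param tol Smallest admissible magnitude of the fitted scale (spectra
#'   essentially uncorrelated with the reference cannot be corrected).
#' @return Corrected spectrum (vector) or matrix of corrected spectra.
#' @export
msc_apply <- function(model, x, tol = 1e-12) {
  stopifnot(inherits(model, "msc_model"))
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != length(model$reference)) {
    abort("Spectrum length does not match the MSC reference.")
  }
  cf <- msc_coefficients(model, X)
  if (any(abs(cf$scale) < tol)) {
    abort(paste0("MSC scale coefficient ~0 for spectrum row(s) ",
                 paste(head(which(abs(cf$scale) < tol), 5), collapse = ", "),
                 "; correction undefined."))
  }
  Y <- (X - cf$offset) / cf$scale
  if (vec) as.vector(Y) else Y
}

# per-row OLS of X on the model reference
msc_coefficients <- function(model, X) {
  r <- model$reference
  mr <- mean(r)
  vr <- mean(r^2) - mr^2
  rowm <- rowMeans(X)
  cross <- as.vector(X %*% r) / length(r) - rowm * mr
  scale <- cross / vr
  offset <- rowm - scale * mr
  list(offset = offset, scale = scale)
}

#' @export
print.msc_model <- function(x, ...) {
  cat("<msc_model> reference over", x$n_spectra, "spectra,",
      length(x$reference), "wavelengths\n")
  invisible(x)
}

#' @rdname msc_fit
#' @param x An `msc_model`.
#' @param ... Unused.
#' @method glance msc_model
#' @export
glance.msc_model <- function(x, ...) {
  tibble(n_spectra = x$n_spectra, n_wavelengths = length(x$reference))
}

#' @rdname msc_fit
#' @param newdata Optional spectra (long tibble or matrix) whose fitted
#'   offset and scale coefficients are returned; defaults to nothing, in
#'   which case only the reference spectrum is tidied.
#' @method tidy msc_model
#' @export
tidy.msc_model <- function(x, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(tibble(
      wavelength = x$grid %||% seq_along(x$reference),
      reference = x$reference
    ))
  }
  X <- if (is.data.frame(newdata)) {
    do.call(rbind, spectra_matrices(newdata)$sets)
  } else {
    as.matrix(newdata)
  }
  cf <- msc_coefficients(x, X)
  tibble(spectrum = seq_len(nrow(X)), offset = cf$offset, scale = cf$scale)
}

# ---- dataset-level engine -------------------------------------------------

# Apply one algorithm to a pooled matrix of spectra (rows). `grid` is the
# wavelength axis of the columns. Returns a matrix of the same shape.
process_matrix <- function(X, grid, algorithm, reference_wavelength = 730,
                           sg_window = 199, sg_polyorder = 2,
                           row_ids = NULL) {
  n <- nrow(X)
  fail_row <- function(i, cond) {
    where <- if (is.null(row_ids)) paste0("row ", i) else row_ids[i]
    abort(paste0(conditionMessage(cond), " [", where, "]"))
  }
  per_row <- function(f) {
    for (i in seq_len(n)) {
      X[i, ] <- tryCatch(f(X[i, ]), error = function(e) fail_row(i, e))
    }
    X
  }
  switch(
    algorithm,
    none = X,
    snv = {
      rm <- rowMeans(X)
      rs <- sqrt(rowSums((X - rm)^2) / (ncol(X) - 1))
      if (any(rs == 0)) {
        per_row(snv)  # re-run element-wise for an identified error
      } else {
        (X - rm) / rs
      }
    },
    min_max = per_row(min_max_scale),
    mean_center = X - rowMeans(X),
    auc = {
      s <- rowSums(X)
      if (any(s == 0)) per_row(auc_normalize) else X / s
    },
    single_wavelength = {
      j <- match(TRUE, abs(grid - reference_wavelength) < 1e-9)
      if (is.na(j)) {
        abort(paste0("Reference wavelength ", reference_wavelength,
                     " nm is not on the processed grid segment."))
      }
      if (any(X[, j] == 0)) {
        per_row(function(x) sw_normalize(x, grid, reference_wavelength))
      } else {
        X / X[, j]
      }
    },
    msc = {
      model <- msc_fit(X)
      msc_apply(model, X)
    },
    first_derivative = {
      check_uniform_grid(grid)
      sg_filter_matrix(X, sg_window, sg_polyorder, deriv = 1) / mean(diff(grid))
    },
    second_derivative = {
      check_uniform_grid(grid)
      sg_filter_matrix(X, sg_window, sg_polyorder, deriv = 2) / mean(diff(grid))^2
    },
    abort(paste0("Unknown algorithm '", algorithm, "'. Choose one of: ",
                 paste(preprocessing_algorithms(), collapse = ", "), "."))
  )
}

#' Preprocess sets of spectra
#'
#' Applies one of the benchmark preprocessing algorithms to every spectrum
#' in a long spectra tibble. Per-spectrum algorithms (SNV, min-max, mean
#' centering, AUC, single-wavelength, derivatives) are applied row-wise;
#' MSC fits its reference spectrum on *all* spectra passed in the call,
#' pooled across tissue labels, so that all sets are corrected against a
#' common reference.
#'
#' If `segments` is given (a list of `c(lo, hi)` wavelength intervals, in
#' nm, disjoint and jointly covering the grid), each interval is processed
#' independently and re-concatenated - the situation of instruments that
#' split the spectral range over separate cameras. For derivative
#' algorithms each segment must be a uniform grid at least one window long;
#' for single-wavelength normalization, `reference_wavelength` may be a
#' vector with one reference per segment.
#'
#' @param data A long spectra tibble (columns `label`, `spectrum`,
#'   `wavelength`, `reflectance`).
#' @param algorithm One of [preprocessing_algorithms()].
#' @param reference_wavelength Reference wavelength in nm for
#'   `single_wavelength` (default 730); one value per segment if segmented.
#' @param sg_window Savitzky-Golay window for the derivatives, in samples
#'   (odd; default 199 = 199 nm on the 1-nm grid).
#' @param sg_polyorder Savitzky-Golay polynomial order (default 2).
#' @param segments Optional list of wavelength intervals, see above.
#' @return A tibble of the same layout with `reflectance` replaced by the
#'   processed values.
#' @examples
#' tissues <- scenario_table1("bvf")[1:2, ]
#' cfg <- acquisition_config(grid = seq(500, 900, by = 10), n_spectra = 5)
#' simulate_spectra(tissues, cfg, seed = 1) |>
#'   preprocess_spectra("snv")
#' @export
preprocess_spectra <- function(data, algorithm = "snv",
                               reference_wavelength = 730,
                               sg_window = 199, sg_polyorder = 2,
                               segments = NULL) {
  algorithm <- match.arg(algorithm, preprocessing_algorithms())
  mats <- spectra_matrices(data)
  grid <- mats$grid
  X <- do.call(rbind, mats$sets)
  counts <- vapply(mats$sets, nrow, integer(1))
  row_ids <- unlist(lapply(names(mats$sets), function(lbl) {
    paste0("set '", lbl, "' spectrum ", seq_len(nrow(mats$sets[[lbl]])))
  }), use.names = FALSE)

  seg_idx <- segment_indices(grid, segments)
  ref <- rep_len(reference_wavelength, length(seg_idx))
  pieces <- lapply(seq_along(seg_idx), function(s) {
    idx <- seg_idx[[s]]
    process_matrix(X[, idx, drop = FALSE], grid[idx], algorithm,
                   reference_wavelength = ref[s],
                   sg_window = sg_window, sg_polyorder = sg_polyorder,
                   row_ids = row_ids)
  })
  Y <- do.call(cbind, pieces)

  ends <- cumsum(counts)
  starts <- c(1, head(ends, -1) + 1)
  out_sets <- lapply(seq_along(counts), function(i) {
    Y[starts[i]:ends[i], , drop = FALSE]
  })
  names(out_sets) <- names(mats$sets)
  matrices_to_long(out_sets, grid, template = data)
}

check_uniform_grid <- function(grid) {
  d <- diff(grid)
  if (diff(range(d)) > 1e-8 * mean(d)) {
    abort("Derivative preprocessing requires a uniform wavelength grid within each segment.")
  }
  invisible(grid)
}

# Split the grid into column index blocks; validate disjoint cover.
segment_indices <- function(grid, segments) {
  if (is.null(segments)) return(list(seq_along(grid)))
  if (!is.list(segments)) segments <- list(segments)
  idx <- lapply(segments, function(s) {
    stopifnot(length(s) == 2, s[1] <= s[2])
    which(grid >= s[1] & grid <= s[2])
  })
  all_idx <- sort(unlist(idx))
  if (anyDuplicated(all_idx)) abort("`segments` must be disjoint.")
  if (!identical(all_idx, seq_along(grid))) {
    abort("`segments` must jointly cover every grid wavelength.")
  }
  idx
}
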