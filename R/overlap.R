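#' Overlap coefficient of two samples at one wavelength
#'
#' Szymkiewicz-Simpson overlap of two sets of reflectance values. A shared
#' histogram with `n_bins` equal-width bins is built over the pooled range
#' of both samples (right-most bin closed); the intersection is
#' \eqn{\sum_{bins} \min(c_1, c_2)} over the per-sample counts, and the
#' coefficient is the intersection divided by the size of the smaller
#' sample. 0 means perfectly separable at this wavelength; 1 means
#' indistinguishable. If all pooled values are identical the samples are
#' maximally similar and 1 is returned.
#'
#' @param x,y Numeric vectors of reflectance values (one wavelength, two
#'   tissue sets).
#' @param n_bins Number of shared histogram bins (default 25).
#' @return A scalar in `[0, 1]`.
#' @examples
#' overlap_coefficient(c(1, 1, 3, 3), c(3, 3, 7, 9), n_bins = 5)  # 0.5
#' @export
overlap_coefficient <- function(x, y, n_bins = 25) {
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be non-empty.")
  if (n_bins < 1) abort("`n_bins` must be >= 1.")
  lo <- min(x, y)
  hi <- max(x, y)
  if (lo == hi) return(1)
  width <- (hi - lo) / n_bins
  bx <- pmin(floor((x - lo) / width) + 1, n_bins)
  by <- pmin(floor((y - lo) / width) + 1, n_bins)
  cx <- tabulate(bx, nbins = n_bins)
  cy <- tabulate(by, nbins = n_bins)
  sum(pmin(cx, cy)) / min(length(x), length(y))
}

# Column-wise overlap for two matrices (spectra in rows, wavelengths in
# columns). Vectorized version of overlap_coefficient over the grid.
overlap_columns <- function(m1, m2, n_bins = 25) {
  stopifnot(ncol(m1) == ncol(m2))
  n1 <- nrow(m1)
  n2 <- nrow(m2)
  denom <- min(n1, n2)
  lo <- pmin(colmin(m1), colmin(m2))
  hi <- pmax(colmax(m1), colmax(m2))
  out <- numeric(ncol(m1))
  width <- (hi - lo) / n_bins
  for (j in seq_len(ncol(m1))) {
    if (width[j] == 0) {
      out[j] <- 1
      next
    }
    b1 <- pmin(floor((m1[, j] - lo[j]) / width[j]) + 1, n_bins)
    b2 <- pmin(floor((m2[, j] - lo[j]) / width[j]) + 1, n_bins)
    out[j] <- sum(pmin(tabulate(b1, n_bins), tabulate(b2, n_bins))) / denom
  }
  out
}

colmin <- function(m) do.call(pmin, c(asplit(m, 1), list(na.rm = FALSE)))
colmax <- function(m) do.call(pmax, c(asplit(m, 1), list(na.rm = FALSE)))

#' Per-wavelength and mean overlap between two labeled sets
#'
#' Computes the overlap coefficient at every wavelength between the spectra
#' of two tissue labels, and its mean over wavelengths (the figure of merit
#' used throughout the benchmarks: lower = more separable).
#'
#' @param data A long spectra tibble containing (at least) the two labels.
#' @param labels Character vector of length 2; defaults to the only two
#'   labels present.
#' @param n_bins Number of shared histogram bins (default 25).
#' @return An object of class `overlap_result`: a list with
#'   `per_wavelength` (tibble `wavelength`, `overlap`), `mean_overlap`,
#'   `n_bins` and `labels`. Supports [tidy()] (per-wavelength curve) and
#'   [glance()] (one-row summary).
#' @examples
#' tissues <- scenario_table1("bvf")[c(1, 5), ]
#' cfg <- acquisition_config(grid = seq(500, 900, by = 10), n_spectra = 20)
#' spectra <- simulate_spectra(tissues, cfg, seed = 1)
#' glance(mean_overlap(spectra))
#' @export
mean_overlap <- function(data, labels = NULL, n_bins = 25) {
  mats <- spectra_matrices(data)
  if (is.null(labels)) {
    if (length(mats$sets) != 2) {
      abort("`labels` must be given when the data contain more than two sets.")
    }
    labels <- names(mats$sets)
  }
  if (length(labels) != 2 || !all(labels %in% names(mats$sets))) {
    abort("`labels` must name two sets present in the data.")
  }
  ov <- overlap_columns(mats$sets[[labels[1]]], mats$sets[[labels[2]]], n_bins)
  structure(
    list(
      per_wavelength = tibble(wavelength = mats$grid, overlap = ov),
      mean_overlap = mean(ov),
      n_bins = n_bins,
      labels = labels
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result> ", x$labels[1], " vs ", x$labels[2],
      ": mean overlap ", signif(x$mean_overlap, 3),
      " (", x$n_bins, " bins, ", nrow(x$per_wavelength),
      " wavelengths)\n", sep = "")
  invisible(x)
}

#' @rdname mean_overlap
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @method tidy overlap_result
#' @export
tidy.overlap_result <- function(x, ...) x$per_wavelength

#' @rdname mean_overlap
#' @method glance overlap_result
#' @export
glance.overlap_result <- function(x, ...) {
  tibble(label_1 = x$labels[1], label_2 = x$labels[2],
         mean_overlap = x$mean_overlap, n_bins = x$n_bins,
         n_wavelengths = nrow(x$per_wavelength))
}

#' Pairwise mean-overlap matrix of all labeled sets
#'
#' Evaluates [mean_overlap()] for every unordered pair of labels and
#' returns the symmetric matrix in tidy form (unique pairs only; a set
#' against itself is identically 1 and is excluded from averages).
#'
#' @param data A long spectra tibble with two or more labels.
#' @param n_bins Number of shared histogram bins (default 25).
#' @return A tibble of class `overlap_pairs` with columns `label_1`,
#'   `label_2`, `mean_overlap`, one row per unique pair, and attributes
#'   `labels` and `n_bins`. Use [overlap_matrix()] for the full symmetric
#'   matrix and [autoplot()] for a heatmap.
#' @examples
#' tissues <- scenario_table1("bvf")[1:3, ]
#' cfg <- acquisition_config(grid = seq(500, 900, by = 10), n_spectra = 20)
#' simulate_spectra(tissues, cfg, seed = 1) |> pairwise_overlap()
#' @export
pairwise_overlap <- function(data, n_bins = 25) {
  mats <- spectra_matrices(data)
  labs <- names(mats$sets)
  if (length(labs) < 2) abort("Need at least two labeled sets.")
  pairs <- combn(labs, 2)
  vals <- apply(pairs, 2, function(p) {
    mean(overlap_columns(mats$sets[[p[1]]], mats$sets[[p[2]]], n_bins))
  })
  out <- tibble(label_1 = pairs[1, ], label_2 = pairs[2, ], mean_overlap = vals)
  attr(out, "labels") <- labs
  attr(out, "n_bins") <- n_bins
  class(out) <- c("overlap_pairs", class(out))
  out
}

#' Symmetric overlap matrix from tidy pairs
#'
#' @param pairs An `overlap_pairs` tibble from [pairwise_overlap()].
#' @return A symmetric numeric matrix with unit diagonal and the set labels
#'   as dimnames.
#' @export
overlap_matrix <- function(pairs) {
  labs <- attr(pairs, "labels") %||% unique(c(pairs$label_1, pairs$label_2))
  m <- matrix(1, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_len(nrow(pairs))) {
    m[pairs$label_1[i], pairs$label_2[i]] <- pairs$mean_overlap[i]
    m[pairs$label_2[i], pairs$label_1[i]] <- pairs$mean_overlap[i]
  }
  m
}

#' Relative improvement of the overlap coefficient
#'
#' Percentage reduction of the mean overlap relative to the unprocessed
#' baseline: `(unprocessed - processed) / unprocessed * 100`. Negative
#' values mean the preprocessing made the sets *less* separable.
#'
#' @param unprocessed,processed Mean overlap coefficients (vectors recycle).
#' @return Improvement in percent.
#' @examples
#' overlap_improvement(0.8, 0.2)   #  75
#' overlap_improvement(0.5, 0.6)   # -20
#' @export
overlap_improvement <- function(unprocessed, processed) {
  if (any(unprocessed == 0)) {
    abort("Improvement undefined when the unprocessed overlap is 0.")
  }
  (unprocessed - processed) / unprocessed * 100
}

#' Heatmap of an overlap-pairs result
#'
#' Mirrors the standard presentation of pairwise overlap matrices: one tile
#' per pair of sets, annotated with the mean overlap (2 decimals), lighter
#' tiles indicating lower overlap (better separability).
#'
#' @param object An `overlap_pairs` tibble from [pairwise_overlap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot overlap_pairs
#' @export
autoplot.overlap_pairs <- function(object, ...) {
  labs_order <- attr(object, "labels")
  m <- overlap_matrix(object)
  df <- as_tibble(as.table(m), .name_repair = ~ c("label_1", "label_2", "overlap"))
  df$label_1 <- factor(df$label_1, levels = labs_order)
  df$label_2 <- factor(df$label_2, levels = rev(labs_order))
  ggplot(df, aes(x = .data$label_1, y = .data$label_2, fill = .data$overlap)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$overlap)), size = 3) +
    scale_fill_gradient(low = "white", high = "#b2182b", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "overlap") +
    theme_minimal()
}
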