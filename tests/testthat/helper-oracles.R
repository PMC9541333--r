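# Independent brute-force overlap oracle: explicit per-bin membership count
# over shared equal-width edges spanning the pooled range (last bin closed).
naive_overlap <- function(x, y, n_bins) {
  lo <- min(c(x, y))
  hi <- max(c(x, y))
  if (lo == hi) return(1)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  count_in <- function(v, k) {
    if (k < n_bins) {
      sum(v >= edges[k] & v < edges[k + 1])
    } else {
      sum(v >= edges[k] & v <= edges[k + 1])
    }
  }
  inter <- 0
  for (k in seq_len(n_bins)) {
    inter <- inter + min(count_in(x, k), count_in(y, k))
  }
  inter / min(length(x), length(y))
}

# Small acquisition setup used by most unit tests: coarse grid, few spectra.
tiny_config <- function(...) {
  acquisition_config(grid = seq(500, 900, by = 10), n_spectra = 8, ...)
}

# Build a long spectra tibble directly from a named list of matrices
# (spectra in rows) on a shared grid.
spectra_from_matrices <- function(mats, grid) {
  dplyr::bind_rows(lapply(names(mats), function(lbl) {
    m <- mats[[lbl]]
    tibble::tibble(
      label = lbl,
      spectrum = rep(seq_len(nrow(m)), each = length(grid)),
      wavelength = rep(grid, times = nrow(m)),
      reflectance = as.vector(t(m))
    )
  }))
}

# Matrix view of one label of a long spectra tibble.
set_matrix <- function(data, lbl) {
  d <- dplyr::filter(data, .data$label == lbl)
  d <- dplyr::arrange(d, .data$spectrum, .data$wavelength)
  nw <- dplyr::n_distinct(d$wavelength)
  matrix(d$reflectance, ncol = nw, byrow = TRUE)
}
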