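#' Reduced scattering coefficient
#'
#' Power-law wavelength dependence \eqn{\mu_s'(\lambda) = a (\lambda /
#' \lambda_0)^{-b}} with scatter amplitude `a` (cm^-1 at the reference
#' wavelength) and scatter slope `b`.
#'
#' @param grid Wavelengths in nm.
#' @param a Scatter amplitude in cm^-1, `> 0`.
#' @param b Scatter slope, dimensionless, `>= 0`.
#' @param lambda0 Reference wavelength in nm (default 500).
#' @return Numeric vector of \eqn{\mu_s'} in cm^-1.
#' @examples
#' reduced_scattering(c(500, 1000), a = 15.35, b = 1.25)
#' @export
reduced_scattering <- function(grid, a, b, lambda0 = 500) {
  if (a <= 0) abort("Scatter amplitude `a` must be > 0.")
  if (b < 0) abort("Scatter slope `b` must be >= 0.")
  a * (grid / lambda0)^(-b)
}

#' Transport albedo
#'
#' \eqn{\alpha'(\lambda) = \mu_s' / (\mu_s' + \mu_a)}: the fraction of total
#' attenuation due to scattering.
#'
#' @param mus_prime,mua Non-negative vectors (cm^-1) on a common grid.
#' @return Vector of albedos in `[0, 1]`.
#' @export
transport_albedo <- function(mus_prime, mua) {
  stopifnot(length(mus_prime) == length(mua))
  if (any(mus_prime < 0) || any(mua < 0)) {
    abort("`mus_prime` and `mua` must be non-negative.")
  }
  tot <- mus_prime + mua
  bad <- which(tot == 0)
  if (length(bad) > 0) {
    abort(paste0(
      "Transport albedo undefined where mus_prime + mua = 0 (element(s) ",
      paste(head(bad, 5), collapse = ", "), ")."
    ))
  }
  mus_prime / tot
}

#' Diffuse reflectance under the diffusion approximation
#'
#' For a homogeneous semi-infinite medium under wide-beam illumination,
#' \deqn{R_{diffuse} = \frac{\alpha'}{1 + 2k(1-\alpha') +
#'   (1 + 2k/3)\sqrt{3(1-\alpha')}},}
#' where `k` is the internal reflection coefficient at the tissue-air
#' boundary. The approximation assumes \eqn{\mu_a \ll \mu_s'}; it is still
#' evaluated (as in practice) inside strong absorption bands where the
#' assumption is locally violated.
#'
#' @param alpha_prime Transport albedo in `[0, 1]`.
#' @param k Internal reflection coefficient, `> 0`; see
#'   [internal_reflection_k()].
#' @return Reflectance in `[0, 1]`.
#' @examples
#' diffuse_reflectance(c(0, 0.9, 1), k = internal_reflection_k())
#' @export
diffuse_reflectance <- function(alpha_prime, k) {
  if (any(alpha_prime < 0 | alpha_prime > 1)) {
    abort("`alpha_prime` must lie in [0, 1].")
  }
  if (k <= 0) abort("`k` must be > 0.")
  alpha_prime /
    (1 + 2 * k * (1 - alpha_prime) + (1 + 2 * k / 3) * sqrt(3 * (1 - alpha_prime)))
}

#' Internal reflection coefficient from the tissue refractive index
#'
#' Groenhuis' empirical relation for the internally reflected fraction
#' \eqn{r_d = -1.44 n^{-2} + 0.710 n^{-1} + 0.668 + 0.0636 n}, from which
#' \eqn{k = (1 + r_d) / (1 - r_d)}. At the default tissue index `n = 1.4`
#' this gives `k` of about 3.25.
#'
#' @param n_tissue Tissue refractive index (default 1.4).
#' @return The internal reflection coefficient `k`.
#' @export
internal_reflection_k <- function(n_tissue = 1.4) {
  rd <- -1.44 / n_tissue^2 + 0.710 / n_tissue + 0.668 + 0.0636 * n_tissue
  (1 + rd) / (1 - rd)
}

#' Fresnel specular reflection at normal incidence
#'
#' \eqn{R_s = |(n_1 - n_2)/(n_1 + n_2)|^2}. Used as the upper bound of the
#' glare added to each simulated spectrum; the default indices are air and
#' water (tissue surface), whose mismatch varies by less than 2% over
#' 400-1600 nm, so a wavelength-independent value is used.
#'
#' @param n1 Refractive index of the incident medium (default 1.0, air).
#' @param n2 Refractive index of the reflecting medium (default 1.33, water).
#' @return Specular reflectance, dimensionless.
#' @examples
#' fresnel_specular()        # air-water, about 0.020
#' fresnel_specular(1, 1.5)  # air-glass, 0.04
#' @export
fresnel_specular <- function(n1 = 1.0, n2 = 1.33) {
  if (any(n1 <= 0) || any(n2 <= 0)) abort("Refractive indices must be > 0.")
  abs((n1 - n2) / (n1 + n2))^2
}

#' Distance scaling factors for diffuse light and glare
#'
#' Sample-height variation moves the tissue surface relative to source and
#' detector by a relative distance `d >= 1`. Glare travels source-to-surface
#' and surface-to-detector as a specular ray, giving
#' \eqn{\beta_{glare} = 1/(4d^2)}; diffusely reflected light re-emerges with
#' isotropic radiance, giving \eqn{\beta_{diffuse} = 1/d^4}.
#'
#' @param d Relative distance(s), `>= 1` (1 is the calibration position).
#' @return A tibble with columns `d`, `beta_diffuse`, `beta_glare`.
#' @examples
#' distance_factors(c(1, 1.2))
#' @export
distance_factors <- function(d) {
  if (any(d < 1)) abort("`d` must be >= 1 (relative to the calibration distance).")
  tibble(d = d, beta_diffuse = 1 / d^4, beta_glare = 1 / (4 * d^2))
}

#' Wavelength-dependent noise envelope
#'
#' Empirical envelope of measurement noise in benchtop hyperspectral systems:
#' largest at the spectral extremes, smallest mid-range,
#' \deqn{I_\gamma(\lambda) = 1.0497\times10^{-15}\,|\lambda - \bar\lambda|^5
#'   + 9.5469\times10^{-4},}
#' with \eqn{\bar\lambda} the mean grid wavelength (1000 nm for the default
#' 400-1600 nm grid). Additive noise is drawn per wavelength as
#' \eqn{\gamma(\lambda) = I_\gamma(\lambda)\,U(-0.5, 0.5)}.
#'
#' @param grid Wavelengths in nm.
#' @param lambda_bar Center wavelength; defaults to `mean(grid)`.
#' @return Vector of noise envelope intensities.
#' @export
noise_intensity <- function(grid, lambda_bar = mean(grid)) {
  1.0497e-15 * abs(grid - lambda_bar)^5 + 9.5469e-4
}

#' Acquisition and nuisance configuration for simulated spectra
#'
#' Bundles the wavelength grid, diffusion-model constant, Fresnel indices,
#' distance range and nuisance toggles used by [simulate_spectra()] and the
#' scenario generators.
#'
#' @param grid Wavelength grid in nm, strictly increasing (default
#'   `seq(400, 1600, by = 1)`).
#' @param k Internal reflection coefficient; default
#'   [internal_reflection_k()] at tissue index 1.4 (about 3.25).
#' @param n_incident,n_surface Refractive indices for the Fresnel specular
#'   term (defaults: air 1.0 and water 1.33).
#' @param d_max Maximum relative distance (default 1.2, i.e. up to 20%
#'   height variation); per-spectrum `d ~ U(1, d_max)`.
#' @param glare,distance,noise Logical toggles for the three nuisance
#'   factors.
#' @param n_spectra Spectra per tissue set (default 100).
#' @return An object of class `acquisition_config` (a list).
#' @examples
#' acquisition_config(n_spectra = 10, grid = seq(500, 600, by = 5))
#' @export
acquisition_config <- function(grid = seq(400, 1600, by = 1),
                               k = internal_reflection_k(),
                               n_incident = 1.0, n_surface = 1.33,
                               d_max = 1.2,
                               glare = TRUE, distance = TRUE, noise = TRUE,
                               n_spectra = 100) {
  if (any(diff(grid) <= 0)) abort("`grid` must be strictly increasing.")
  if (d_max < 1) abort("`d_max` must be >= 1.")
  if (n_spectra < 1) abort("`n_spectra` must be >= 1.")
  if (k <= 0) abort("`k` must be > 0.")
  structure(
    list(grid = as.numeric(grid), k = k,
         n_incident = n_incident, n_surface = n_surface,
         d_max = d_max, glare = isTRUE(glare), distance = isTRUE(distance),
         noise = isTRUE(noise), n_spectra = as.integer(n_spectra)),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat("<acquisition_config>\n",
      " grid: ", min(x$grid), "-", max(x$grid), " nm (", length(x$grid),
      " points)\n",
      " k = ", signif(x$k, 4), ", Fresnel n1 = ", x$n_incident,
      ", n2 = ", x$n_surface, "\n",
      " d_max = ", x$d_max, ", n_spectra = ", x$n_spectra, "\n",
      " nuisance: glare=", x$glare, " distance=", x$distance,
      " noise=", x$noise, "\n", sep = "")
  invisible(x)
}

# Deterministic per-set substream: adding a set never perturbs earlier sets.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483647)
}

#' Noise-free diffuse reflectance of one tissue
#'
#' Computes \eqn{R_{diffuse}(\lambda)} from a tissue composition and
#' scattering parameters on the configured grid, without any nuisance terms.
#'
#' @param tissue One row of a tissue table: columns `bvf`, `so2`, `wvf`,
#'   `fvf`, `bilirubin`, `a`, `b` (see [scenario_table1()]).
#' @param config An [acquisition_config()].
#' @return Numeric vector of diffuse reflectance on `config$grid`.
#' @export
diffuse_reflectance_spectrum <- function(tissue, config = acquisition_config()) {
  stopifnot(is.data.frame(tissue), nrow(tissue) == 1)
  mua <- absorption_coefficient(tissue, config$grid)
  musp <- reduced_scattering(config$grid, a = tissue$a, b = tissue$b)
  diffuse_reflectance(transport_albedo(musp, mua), k = config$k)
}

# Corrupt a matrix of diffuse spectra (rows) with glare, distance and noise.
# Consumes the active RNG stream; returns list(spectra, glare, distance).
apply_nuisance <- function(rdiff, config) {
  n <- nrow(rdiff)
  nw <- ncol(rdiff)
  rs <- fresnel_specular(config$n_incident, config$n_surface)
  g <- if (config$glare) runif(n) else numeric(n)
  d <- if (config$distance) runif(n, 1, config$d_max) else rep(1, n)
  gamma <- if (config$noise) {
    env <- noise_intensity(config$grid)
    matrix(runif(n * nw, -0.5, 0.5), n, nw) * rep(env, each = n)
  } else {
    0
  }
  spectra <- rdiff * (1 / d^4) + (g * rs) * (1 / (4 * d^2)) + gamma
  list(spectra = spectra, glare = g, distance = d)
}

# Assemble a long spectra tibble from a per-set result.
set_to_long <- function(label, sim, grid) {
  n <- nrow(sim$spectra)
  tibble(
    label = label,
    spectrum = rep(seq_len(n), each = length(grid)),
    wavelength = rep(grid, times = n),
    reflectance = as.vector(t(sim$spectra)),
    glare = rep(sim$glare, each = length(grid)),
    distance = rep(sim$distance, each = length(grid))
  )
}

#' Simulate sets of corrupted reflectance spectra
#'
#' For each tissue (row of `tissues`) computes the noise-free diffuse
#' reflectance, then generates `config$n_spectra` corrupted spectra
#' \deqn{R_{tot}(\lambda) = R_{diffuse}(\lambda)/d^4 +
#'   g\,R_s/(4 d^2) + \gamma(\lambda),}
#' with a fresh glare fraction \eqn{g \sim U(0,1)}, relative distance
#' \eqn{d \sim U(1, d_{max})} and per-wavelength noise for every spectrum.
#' Each tissue set uses an independent RNG substream derived from `seed` and
#' the row index, so results per set are stable when sets are added or
#' removed.
#'
#' @param tissues A tissue table: columns `label`, `bvf`, `so2`, `wvf`,
#'   `fvf`, `bilirubin`, `a`, `b`. See [scenario_table1()].
#' @param config An [acquisition_config()].
#' @param seed Integer seed for the nuisance draws.
#' @return A long tibble with columns `label`, `spectrum`, `wavelength`,
#'   `reflectance`, `glare`, `distance` (the latter two record the nuisance
#'   draw for each spectrum).
#' @examples
#' tissues <- scenario_table1("bvf")[1:2, ]
#' cfg <- acquisition_config(grid = seq(500, 900, by = 10), n_spectra = 5)
#' spectra <- simulate_spectra(tissues, cfg, seed = 1)
#' dplyr::count(spectra, label)
#' @export
simulate_spectra <- function(tissues, config = acquisition_config(), seed = 1L) {
  stopifnot(is.data.frame(tissues), nrow(tissues) >= 1)
  if (!"label" %in% names(tissues)) abort("`tissues` must have a `label` column.")
  if (anyDuplicated(tissues$label)) abort("Tissue labels must be unique.")
  out <- vector("list", nrow(tissues))
  for (i in seq_len(nrow(tissues))) {
    tissue <- tissues[i, ]
    rdiff_vec <- diffuse_reflectance_spectrum(tissue, config)
    check_diffusion_validity(rdiff_vec, tissue, config)
    rdiff <- matrix(rdiff_vec, nrow = config$n_spectra,
                    ncol = length(config$grid), byrow = TRUE)
    set.seed(derive_seed(seed, i))
    sim <- apply_nuisance(rdiff, config)
    out[[i]] <- set_to_long(tissue$label, sim, config$grid)
  }
  bind_rows(out)
}

# The diffusion formula assumes mua << mus'; flag (informational, not a
# warning: the standard tissue bands violate it locally by construction).
check_diffusion_validity <- function(rdiff, tissue, config) {
  mua <- absorption_coefficient(tissue, config$grid)
  musp <- reduced_scattering(config$grid, a = tissue$a, b = tissue$b)
  frac <- mean(transport_albedo(musp, mua) < 0.5)
  if (frac > 0) {
    rlang::inform(
      paste0("Set '", tissue$label, "': transport albedo < 0.5 at ",
             round(100 * frac, 1),
             "% of wavelengths (diffusion approximation weak there)."),
      class = "specprep_diffusion_validity"
    )
  }
  invisible(frac)
}

#' Plot simulated spectra
#'
#' Line plot of reflectance versus wavelength, one line per spectrum,
#' colored by tissue label.
#'
#' @param data A long spectra tibble from [simulate_spectra()] or
#'   [preprocess_spectra()].
#' @param alpha Line transparency (default 0.4).
#' @return A ggplot object.
#' @export
plot_spectra <- function(data, alpha = 0.4) {
  check_spectra(data)
  ggplot(data, aes(x = .data$wavelength, y = .data$reflectance,
                   group = interaction(.data$label, .data$spectrum),
                   colour = .data$label)) +
    geom_line(alpha = alpha) +
    labs(x = "wavelength (nm)", y = "reflectance", colour = "tissue") +
    theme_minimal()
}

# Validate the long spectra layout shared by all downstream verbs.
check_spectra <- function(data) {
  needed <- c("label", "spectrum", "wavelength", "reflectance")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("Spectra data must have columns ",
                 paste(needed, collapse = ", "), "; missing: ",
                 paste(missing, collapse = ", "), "."))
  }
  invisible(data)
}

# Long tibble -> named list of [n_spectra x n_wavelengths] matrices + grid.
# Relies on each (label, spectrum) pair covering the identical grid.
spectra_matrices <- function(data) {
  check_spectra(data)
  grid <- sort(unique(data$wavelength))
  lab <- factor(data$label, levels = unique(data$label))
  data <- data[order(lab, data$spectrum, data$wavelength), ]
  lab <- factor(data$label, levels = levels(lab))
  sets <- split(data$reflectance, lab)
  ids <- split(data$spectrum, lab)
  mats <- lapply(names(sets), function(lbl) {
    nspec <- length(unique(ids[[lbl]]))
    if (length(sets[[lbl]]) != nspec * length(grid)) {
      abort(paste0("Set '", lbl, "' is ragged: spectra do not share the grid."))
    }
    matrix(sets[[lbl]], nrow = nspec, ncol = length(grid), byrow = TRUE)
  })
  names(mats) <- names(sets)
  list(grid = grid, sets = mats)
}

# Rebuild a long tibble from matrices, preserving per-spectrum metadata
# columns (glare, distance) of the template where present.
matrices_to_long <- function(mats, grid, template = NULL) {
  out <- bind_rows(lapply(names(mats), function(lbl) {
    m <- mats[[lbl]]
    tibble(
      label = lbl,
      spectrum = rep(seq_len(nrow(m)), each = length(grid)),
      wavelength = rep(grid, times = nrow(m)),
      reflectance = as.vector(t(m))
    )
  }))
  if (!is.null(template) && all(c("glare", "distance") %in% names(template))) {
    meta <- distinct(template, .data$label, .data$spectrum,
                     .data$glare, .data$distance)
    out <- left_join(out, meta, by = c("label", "spectrum"))
  }
  out
}
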