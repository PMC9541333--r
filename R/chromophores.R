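#' Chromophore absorption tables
#'
#' The package bundles absorption spectra for the four chromophores that
#' dominate soft-tissue absorption between 400 and 1600 nm: water, fat,
#' oxy- and deoxyhemoglobin, and bilirubin. Hemoglobin and bilirubin are
#' stored as molar extinction coefficients and converted to absorption
#' coefficients at composition time (whole blood at 150 g/L hemoglobin;
#' bilirubin from its concentration in mg/dL). The bundled tables are
#' synthetic anchor-point reconstructions of the standard public-domain
#' compilations (see `inst/extdata/chromophores/metadata.json`), adequate
#' for simulation studies but not metrology-grade.
#'
#' @param name One of `"water"`, `"fat"`, `"hb_oxy"`, `"hb_deoxy"`,
#'   `"bilirubin"`.
#'
#' @return A tibble with columns `wavelength_nm` (strictly increasing) and
#'   `value`, with attributes `chromophore`, `units`
#'   (`"mua_cm1"` or `"molar_extinction_cm1_M"`) and `support_nm`.
#' @examples
#' water <- load_chromophore("water")
#' range(water$wavelength_nm)
#' @export
load_chromophore <- function(name) {
  meta <- chromophore_metadata()
  if (!is.character(name) || length(name) != 1 || !name %in% names(meta)) {
    abort(paste0(
      "Unknown chromophore ", deparse(name), ". Available: ",
      paste(names(meta), collapse = ", "), "."
    ))
  }
  info <- meta[[name]]
  path <- system.file("extdata", "chromophores", info$file,
                      package = "specprep", mustWork = TRUE)
  tab <- as_tibble(read.csv(path))
  stopifnot(all(diff(tab$wavelength_nm) > 0), all(tab$value >= 0))
  attr(tab, "chromophore") <- name
  attr(tab, "units") <- info$units
  attr(tab, "support_nm") <- range(tab$wavelength_nm)
  tab
}

chromophore_metadata <- function() {
  path <- system.file("extdata", "chromophores", "metadata.json",
                      package = "specprep", mustWork = TRUE)
  jsonlite::read_json(path)$chromophores
}

#' Resample a chromophore table onto a wavelength grid
#'
#' Linear interpolation within the table's support. Outside the support the
#' absorption is taken to be zero (with a warning): the chromophores whose
#' tabulations end early (bilirubin, hemoglobin) have negligible absorption
#' beyond their tabulated range relative to water, and extrapolating a molar
#' extinction tail would invent structure the sources do not contain.
#'
#' @param table A chromophore table from [load_chromophore()], or any data
#'   frame with columns `wavelength_nm` and `value`.
#' @param grid Strictly increasing numeric vector of wavelengths in nm.
#' @return Numeric vector of length `length(grid)`, in the table's units,
#'   zero outside the tabulated support.
#' @export
resample_chromophore <- function(table, grid) {
  stopifnot(is.numeric(grid), length(grid) >= 1)
  if (any(diff(grid) <= 0)) abort("`grid` must be strictly increasing.")
  out <- stats::approx(table$wavelength_nm, table$value, xout = grid,
                       method = "linear", rule = 1)$y
  outside <- is.na(out)
  if (any(outside)) {
    name <- attr(table, "chromophore") %||% "chromophore"
    warn(paste0(
      sum(outside), " grid wavelength(s) outside the tabulated support of ",
      name, " [", min(table$wavelength_nm), ", ", max(table$wavelength_nm),
      "] nm; absorption set to 0 there."
    ))
    out[outside] <- 0
  }
  pmax(out, 0)
}

#' Specify a tissue composition
#'
#' Volume fractions of blood, water and fat, the oxygen saturation of the
#' blood, and a bilirubin concentration. Fractions are volume fractions
#' multiplying the pure-substance absorption; they need not sum to 1 (the
#' simulated tissues deliberately do not), but a sum above 1 draws a warning.
#'
#' @param bvf,wvf,fvf Blood / water / fat volume fractions in `[0, 1]`.
#' @param so2 Oxygen saturation of blood in `[0, 1]` (default 0.75).
#' @param bilirubin Bilirubin concentration in mg/dL, `>= 0`.
#' @return A one-row tibble with columns `bvf`, `so2`, `wvf`, `fvf`,
#'   `bilirubin`.
#' @examples
#' tissue_composition(bvf = 0.02, wvf = 0.35, fvf = 0.35)
#' @export
tissue_composition <- function(bvf = 0, so2 = 0.75, wvf = 0, fvf = 0,
                               bilirubin = 0) {
  vals <- c(bvf = bvf, so2 = so2, wvf = wvf, fvf = fvf)
  if (any(vals < 0 | vals > 1)) {
    abort("`bvf`, `so2`, `wvf` and `fvf` must all lie in [0, 1].")
  }
  if (bilirubin < 0) abort("`bilirubin` must be >= 0 mg/dL.")
  if (bvf + wvf + fvf > 1) {
    warn("Volume fractions bvf + wvf + fvf exceed 1; proceeding anyway.")
  }
  tibble(bvf = bvf, so2 = so2, wvf = wvf, fvf = fvf, bilirubin = bilirubin)
}

# ln(10) * 150 g/L / 64500 g/mol: molar extinction -> whole-blood mua (cm^-1)
.blood_extinction_factor <- log(10) * 150 / 64500
.bilirubin_mw <- 584.66

#' Tissue absorption coefficient
#'
#' Composes the bundled chromophore spectra into the absorption coefficient
#' of a homogeneous tissue,
#' \deqn{\mu_a(\lambda) = \mathrm{BVF}\,[S\,\mu_{a,HbO_2} + (1-S)\,\mu_{a,Hb}]
#'   + \mathrm{WVF}\,\mu_{a,water} + \mathrm{FVF}\,\mu_{a,fat}
#'   + \mu_{a,bili}(C),}
#' where whole-blood hemoglobin absorption assumes 150 g/L hemoglobin and
#' bilirubin is converted from mg/dL via its molecular weight (584.66 g/mol).
#'
#' @param composition A data frame (one row) as from [tissue_composition()].
#' @param grid Wavelength grid in nm, strictly increasing.
#' @param quiet Suppress out-of-support resampling warnings (default `TRUE`;
#'   the hemoglobin and bilirubin tables end below 1600 nm by design).
#' @return Numeric vector `mua` in cm^-1, same length as `grid`, all `>= 0`.
#' @examples
#' grid <- seq(400, 1600, by = 10)
#' mua <- absorption_coefficient(
#'   tissue_composition(bvf = 0.02, wvf = 0.35, fvf = 0.35), grid
#' )
#' @export
absorption_coefficient <- function(composition, grid, quiet = TRUE) {
  stopifnot(is.data.frame(composition), nrow(composition) == 1)
  comp <- as.list(composition)
  resamp <- function(name) {
    tab <- load_chromophore(name)
    if (quiet) {
      suppressWarnings(resample_chromophore(tab, grid))
    } else {
      resample_chromophore(tab, grid)
    }
  }
  mua <- numeric(length(grid))
  if (comp$bvf > 0) {
    eps_blood <- comp$so2 * resamp("hb_oxy") + (1 - comp$so2) * resamp("hb_deoxy")
    mua <- mua + comp$bvf * .blood_extinction_factor * eps_blood
  }
  if (comp$wvf > 0) mua <- mua + comp$wvf * resamp("water")
  if (comp$fvf > 0) mua <- mua + comp$fvf * resamp("fat")
  if (comp$bilirubin > 0) {
    molar <- comp$bilirubin * 0.01 / .bilirubin_mw  # mg/dL -> mol/L
    mua <- mua + log(10) * molar * resamp("bilirubin")
  }
  pmax(mua, 0)
}
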