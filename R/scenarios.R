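#' Tissue parameter sets for the single-contrast scenarios
#'
#' Returns the five tissue parameter sets for one of the four synthetic
#' contrasts used throughout the package benchmarks. In every scenario the
#' blood oxygen saturation is 75% and the scattering reference wavelength is
#' 500 nm; the non-varied parameters are held at BVF 4.0%, FVF 35%, WVF 35%,
#' `a` 15.35 cm^-1, `b` 1.25.
#'
#' * `"bvf"` - blood volume fraction 0.5, 2.0, 3.5, 5.0, 6.5% (FVF = WVF =
#'   35%).
#' * `"absorbers"` - absorber combinations B; B+W; B+W+F; B+W+Bi; B+W+F+Bi
#'   at BVF 4.0%, with WVF 70% when fat is absent, WVF = FVF = 35% when
#'   both present, and bilirubin 13.5 mg/dL where included.
#' * `"amplitude"` - scatter amplitude a = 8, 12, 16, 20, 24 cm^-1.
#' * `"slope"` - scatter slope b = 0.500, 0.875, 1.250, 1.625, 2.000.
#'
#' @param contrast One of `"bvf"`, `"absorbers"`, `"amplitude"`, `"slope"`.
#' @return A five-row tibble with columns `label`, `bvf`, `so2`, `wvf`,
#'   `fvf`, `bilirubin`, `a`, `b`, suitable for [simulate_spectra()].
#' @examples
#' scenario_table1("bvf")
#' @export
scenario_table1 <- function(contrast = c("bvf", "absorbers", "amplitude", "slope")) {
  contrast <- match.arg(contrast)
  base <- list(so2 = 0.75, a = 15.35, b = 1.25)
  switch(
    contrast,
    bvf = {
      bvf <- c(0.5, 2.0, 3.5, 5.0, 6.5) / 100
      tibble(
        label = sprintf("bvf=%.1f%%", 100 * bvf),
        bvf = bvf, so2 = base$so2, wvf = 0.35, fvf = 0.35, bilirubin = 0,
        a = base$a, b = base$b
      )
    },
    absorbers = tibble(
      label = c("B", "B+W", "B+W+F", "B+W+Bi", "B+W+F+Bi"),
      bvf = 0.04, so2 = base$so2,
      wvf = c(0, 0.70, 0.35, 0.70, 0.35),
      fvf = c(0, 0, 0.35, 0, 0.35),
      bilirubin = c(0, 0, 0, 13.5, 13.5),
      a = base$a, b = base$b
    ),
    amplitude = {
      a <- c(8, 12, 16, 20, 24)
      tibble(
        label = sprintf("a=%g", a),
        bvf = 0.04, so2 = base$so2, wvf = 0.35, fvf = 0.35, bilirubin = 0,
        a = a, b = base$b
      )
    },
    slope = {
      b <- c(0.500, 0.875, 1.250, 1.625, 2.000)
      tibble(
        label = sprintf("b=%.3f", b),
        bvf = 0.04, so2 = base$so2, wvf = 0.35, fvf = 0.35, bilirubin = 0,
        a = base$a, b = b
      )
    }
  )
}

#' Optical-property ranges for the mixed healthy-versus-tumor scenario
#'
#' Per-class uniform sampling ranges emulating the within-tissue-type
#' variability measured by diffuse reflectance spectroscopy in breast:
#' healthy tissue is fat-dominated with low water; tumor tissue has the
#' fat-water ratio inverted, lower oxygen saturation and stronger
#' scattering.
#'
#' @return A tibble with one row per class (`healthy`, `tumor`) and `_min` /
#'   `_max` columns for `bvf`, `so2`, `wvf`, `fvf` (fractions), `a` (cm^-1)
#'   and `b`.
#' @export
scenario_table2 <- function() {
  tibble(
    label = c("healthy", "tumor"),
    bvf_min = c(0.00, 0.02), bvf_max = c(0.06, 0.10),
    so2_min = c(0.30, 0.05), so2_max = c(0.80, 0.60),
    wvf_min = c(0.02, 0.35), wvf_max = c(0.04, 0.37),
    fvf_min = c(0.30, 0.33), fvf_max = c(0.68, 0.35),
    a_min = c(10, 12), a_max = c(15, 35),
    b_min = c(0.8, 0.9), b_max = c(1.0, 1.3)
  )
}

#' Simulate the mixed healthy-versus-tumor spectra
#'
#' Unlike the single-contrast scenarios, every spectrum here gets its own
#' tissue: each optical property is drawn uniformly within its class range
#' from [scenario_table2()], the noise-free diffuse reflectance is computed
#' per spectrum, and glare, distance scaling and noise are applied as in
#' [simulate_spectra()]. Defaults produce 1000 spectra per class.
#'
#' @param config An [acquisition_config()]; `config$n_spectra` is the number
#'   of spectra per class (set it to 1000 for the full-size simulation).
#' @param seed Integer seed.
#' @param ranges Class ranges, by default [scenario_table2()].
#' @return A long spectra tibble (see [simulate_spectra()]) with labels
#'   `healthy` and `tumor`.
#' @examples
#' cfg <- acquisition_config(grid = seq(500, 900, by = 20), n_spectra = 5)
#' mixed <- simulate_mixed(cfg, seed = 1)
#' dplyr::count(mixed, label)
#' @export
simulate_mixed <- function(config = acquisition_config(n_spectra = 1000),
                           seed = 1L, ranges = scenario_table2()) {
  grid <- config$grid
  eps_oxy <- suppressWarnings(resample_chromophore(load_chromophore("hb_oxy"), grid))
  eps_deoxy <- suppressWarnings(resample_chromophore(load_chromophore("hb_deoxy"), grid))
  mua_water <- suppressWarnings(resample_chromophore(load_chromophore("water"), grid))
  mua_fat <- suppressWarnings(resample_chromophore(load_chromophore("fat"), grid))

  out <- vector("list", nrow(ranges))
  for (i in seq_len(nrow(ranges))) {
    r <- ranges[i, ]
    n <- config$n_spectra
    set.seed(derive_seed(seed, i))
    bvf <- runif(n, r$bvf_min, r$bvf_max)
    so2 <- runif(n, r$so2_min, r$so2_max)
    wvf <- runif(n, r$wvf_min, r$wvf_max)
    fvf <- runif(n, r$fvf_min, r$fvf_max)
    a <- runif(n, r$a_min, r$a_max)
    b <- runif(n, r$b_min, r$b_max)

    mua <- .blood_extinction_factor *
      ((bvf * so2) %o% eps_oxy + (bvf * (1 - so2)) %o% eps_deoxy) +
      wvf %o% mua_water + fvf %o% mua_fat
    musp <- a * exp(outer(-b, log(grid / 500)))
    alpha <- musp / (musp + mua)
    rdiff <- alpha / (1 + 2 * config$k * (1 - alpha) +
                        (1 + 2 * config$k / 3) * sqrt(3 * (1 - alpha)))
    sim <- apply_nuisance(rdiff, config)
    long <- set_to_long(r$label, sim, grid)
    long$bvf <- rep(bvf, each = length(grid))
    long$so2 <- rep(so2, each = length(grid))
    long$wvf <- rep(wvf, each = length(grid))
    long$fvf <- rep(fvf, each = length(grid))
    long$a <- rep(a, each = length(grid))
    long$b <- rep(b, each = length(grid))
    out[[i]] <- long
  }
  bind_rows(out)
}
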