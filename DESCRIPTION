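Package: specprep
Title: Benchmarking Spectral Preprocessing for Hyperspectral Tissue Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates diffuse-reflectance spectra of soft tissue from
    chromophore volume fractions and power-law scattering, corrupts them with
    glare (a random fraction of the Fresnel specular reflection), sample-height
    distance scaling and wavelength-dependent noise, applies eight common
    spectral preprocessing algorithms (SNV, MSC, min-max, mean centering, AUC
    and single-wavelength normalization, Savitzky-Golay first and second
    derivatives), and quantifies between-tissue-type separability with the
    Szymkiewicz-Simpson overlap coefficient. Provides scenario generators for
    contrasts in blood volume fraction, absorber composition, scatter amplitude
    and scatter slope, plus a mixed healthy-versus-tumor simulation, and tidy
    summaries and heatmaps of the resulting overlap matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
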