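test_that("reduced scattering follows the power law", {
  expect_equal(reduced_scattering(500, a = 15.35, b = 1.25), 15.35)
  expect_equal(reduced_scattering(c(400, 800, 1600), a = 7, b = 0),
               rep(7, 3))
  # frozen from an independent evaluation of 15.35 * 2^(-1.25)
  expect_equal(reduced_scattering(1000, a = 15.35, b = 1.25),
               6.45388, tolerance = 1e-6)
  expect_error(reduced_scattering(500, a = 0, b = 1), "amplitude")
  expect_error(reduced_scattering(500, a = 1, b = -1), "slope")
})

test_that("transport albedo is the scattering fraction of total attenuation", {
  expect_equal(transport_albedo(c(5, 2), c(0, 0)), c(1, 1))
  expect_equal(transport_albedo(3, 3), 0.5)
  expect_equal(transport_albedo(6.455, 0.717222), 0.9, tolerance = 1e-6)
  expect_error(transport_albedo(c(1, 0), c(1, 0)), "element\\(s\\) 2")
  expect_error(transport_albedo(-1, 2), "non-negative")
})

test_that("diffuse reflectance has the diffusion-theory limits and monotonicity", {
  k <- 3.25
  expect_equal(diffuse_reflectance(1, k), 1)
  expect_equal(diffuse_reflectance(0, k), 0)
  # frozen from an independent evaluation: 0.9 / (1 + 2k*0.1 + (1+2k/3)*sqrt(0.3))
  expect_equal(diffuse_reflectance(0.9, k), 0.2659217, tolerance = 1e-6)
  alphas <- seq(0, 1, length.out = 2001)
  r <- diffuse_reflectance(alphas, k)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r <= 1))
  expect_error(diffuse_reflectance(1.2, k), "\\[0, 1\\]")
})

test_that("internal reflection coefficient matches the Groenhuis relation at n = 1.4", {
  expect_equal(internal_reflection_k(1.4), 3.25, tolerance = 0.01)
})

test_that("Fresnel specular reflection at normal incidence", {
  expect_equal(fresnel_specular(1.4, 1.4), 0)
  expect_equal(fresnel_specular(1, 1.5), 0.04)
  expect_equal(fresnel_specular(), ((0.33) / 2.33)^2)
  expect_error(fresnel_specular(0, 1), "> 0")
})

test_that("distance factors: inverse-square for glare, inverse-fourth for diffuse", {
  f1 <- distance_factors(1)
  expect_equal(f1$beta_diffuse, 1)
  expect_equal(f1$beta_glare, 0.25)
  f12 <- distance_factors(1.2)
  expect_equal(f12$beta_diffuse, 1 / 2.0736)
  expect_equal(f12$beta_glare, 1 / 5.76)
  f11 <- distance_factors(1.1)
  expect_equal(f11$beta_diffuse / f11$beta_glare, 4 / 1.1^2)
  # both factors shrink with distance
  fs <- distance_factors(seq(1, 1.2, by = 0.01))
  expect_true(all(diff(fs$beta_diffuse) < 0))
  expect_true(all(diff(fs$beta_glare) < 0))
  expect_error(distance_factors(0.9), ">= 1")
})

test_that("noise envelope: quintic in distance from the center wavelength", {
  grid <- seq(400, 1600, by = 1)
  env <- noise_intensity(grid)
  expect_equal(env[grid == 1000], 9.5469e-4)
  expect_equal(env[grid == 400], 1.0497e-15 * 600^5 + 9.5469e-4)
  # symmetric about the center
  expect_equal(noise_intensity(1000 + c(37, 250), lambda_bar = 1000),
               noise_intensity(1000 - c(37, 250), lambda_bar = 1000))
})

test_that("simulated sets are reproducible and respect the nuisance toggles", {
  tissues <- scenario_table1("bvf")[1:2, ]
  cfg <- tiny_config()
  s1 <- suppressMessages(simulate_spectra(tissues, cfg, seed = 11))
  s2 <- suppressMessages(simulate_spectra(tissues, cfg, seed = 11))
  expect_identical(s1, s2)
  s3 <- suppressMessages(simulate_spectra(tissues, cfg, seed = 12))
  expect_false(identical(s1$reflectance, s3$reflectance))

  # recorded nuisance draws stay in their modeled ranges
  expect_true(all(s1$glare >= 0 & s1$glare <= 1))
  expect_true(all(s1$distance >= 1 & s1$distance <= cfg$d_max))

  # all toggles off: every spectrum equals the noise-free diffuse reflectance
  cfg_off <- tiny_config(glare = FALSE, distance = FALSE, noise = FALSE)
  clean <- suppressMessages(simulate_spectra(tissues[1, ], cfg_off, seed = 1))
  rdiff <- suppressMessages(diffuse_reflectance_spectrum(tissues[1, ], cfg_off))
  m <- set_matrix(clean, tissues$label[1])
  for (i in seq_len(nrow(m))) expect_equal(unname(m[i, ]), rdiff)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("default acquisition yields 100 spectra on the 1201-point 1-nm grid", {
  cfg <- acquisition_config()
  expect_equal(length(cfg$grid), 1201)
  spectra <- suppressMessages(
    simulate_spectra(scenario_table1("bvf")[1, ], cfg, seed = 1)
  )
  expect_equal(nrow(spectra), 100 * 1201)
  expect_equal(dplyr::n_distinct(spectra$spectrum), 100)
})

test_that("glare only adds signal; distance only attenuates (noise off)", {
  tissue <- scenario_table1("bvf")[3, ]
  cfg_g <- tiny_config(glare = TRUE, distance = FALSE, noise = FALSE)
  cfg_0 <- tiny_config(glare = FALSE, distance = FALSE, noise = FALSE)
  with_g <- set_matrix(
    suppressMessages(simulate_spectra(tissue, cfg_g, seed = 5)), tissue$label)
  without <- set_matrix(
    suppressMessages(simulate_spectra(tissue, cfg_0, seed = 5)), tissue$label)
  expect_true(all(with_g >= without))

  cfg_d <- tiny_config(glare = FALSE, distance = TRUE, noise = FALSE)
  with_d <- set_matrix(
    suppressMessages(simulate_spectra(tissue, cfg_d, seed = 5)), tissue$label)
  expect_true(all(with_d <= without + 1e-12))
})

test_that("per-wavelength noise is bounded by half the envelope and centered", {
  tissue <- scenario_table1("bvf")[1, ]
  cfg_n <- acquisition_config(grid = seq(450, 1550, by = 25), n_spectra = 200,
                              glare = FALSE, distance = FALSE, noise = TRUE)
  noisy <- set_matrix(
    suppressMessages(simulate_spectra(tissue, cfg_n, seed = 3)), tissue$label)
  rdiff <- suppressMessages(diffuse_reflectance_spectrum(tissue, cfg_n))
  resid <- sweep(noisy, 2, rdiff)
  env <- noise_intensity(cfg_n$grid)
  expect_true(all(abs(resid) <= rep(env / 2, each = nrow(resid)) + 1e-12))
  # symmetric uniform noise: per-wavelength means shrink toward zero
  expect_true(max(abs(colMeans(resid)) / env) < 0.1)
})

test_that("unprocessed overlap drops as the parameter difference grows", {
  tissues <- scenario_table1("bvf")
  cfg <- acquisition_config(grid = seq(450, 1050, by = 10), n_spectra = 40)
  spectra <- suppressMessages(simulate_spectra(tissues, cfg, seed = 2))
  pr <- pairwise_overlap(spectra, n_bins = 25)
  m <- overlap_matrix(pr)
  # first row: neighbor in BVF overlaps more than the most distant set
  expect_gt(m[1, 2], m[1, 5])
  expect_gt(m[2, 3], m[2, 5])
})
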