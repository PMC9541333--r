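set.seed(42)
ref_spec <- abs(cumsum(rnorm(120))) + 0.5  # a generic smooth-ish spectrum

test_that("per-spectrum normalizations match their definitions on worked cases", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(min_max_scale(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(mean_center(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(auc_normalize(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  sw <- sw_normalize(c(2, 5, 8), grid = c(700, 730, 760))
  expect_equal(sw, c(0.4, 1, 1.6))
  expect_equal(sw[2], 1)
})

test_that("degenerate spectra raise identifying errors", {
  expect_error(snv(rep(5, 4)), "constant")
  expect_error(min_max_scale(rep(1, 3)), "constant")
  expect_error(auc_normalize(c(-1, 1)), "zero")
  expect_error(sw_normalize(c(0, 1), grid = c(730, 740)), "zero at the reference")
  expect_error(sw_normalize(c(1, 1), grid = c(700, 760)), "not on the grid")
})

test_that("normalizations have the right invariances", {
  x <- ref_spec
  # scale+offset removed
  expect_equal(snv(3.2 * x + 0.7), snv(x))
  expect_equal(min_max_scale(3.2 * x + 0.7), min_max_scale(x))
  # scale only
  expect_equal(auc_normalize(4.1 * x), auc_normalize(x))
  grid <- seq_along(x) + 700
  expect_equal(sw_normalize(2.5 * x, grid, 710), sw_normalize(x, grid, 710))
  expect_false(isTRUE(all.equal(auc_normalize(x + 1), auc_normalize(x))))
  # offset only; scale deliberately kept
  expect_equal(mean_center(x + 13), mean_center(x))
  expect_equal(mean_center(5 * x), 5 * mean_center(x))
})

test_that("normalizations are idempotent", {
  x <- ref_spec
  expect_equal(snv(snv(x)), snv(x))
  expect_equal(min_max_scale(min_max_scale(x)), min_max_scale(x))
  expect_equal(auc_normalize(auc_normalize(x)), auc_normalize(x))
})

test_that("Savitzky-Golay filters reproduce polynomials and contract noise", {
  grid <- 1:300
  line <- 3 * grid + 2
  expect_equal(sg_smooth(line, window = 21, polyorder = 2), line)
  expect_equal(sg_smooth(rep(4, 100), window = 21, polyorder = 2), rep(4, 100))
  expect_equal(sg_derivative(line, order = 1, window = 21), rep(3, 300))
  expect_equal(sg_derivative(line, order = 2, window = 21), rep(0, 300))
  expect_equal(sg_derivative(grid^2, order = 2, window = 21), rep(2, 300))
  # offset invariance of the first derivative
  set.seed(1)
  y <- rnorm(300)
  expect_equal(sg_derivative(y + 7, window = 21), sg_derivative(y, window = 21))
  # smoothing contracts white-noise variance
  expect_lt(var(sg_smooth(y, window = 21)), var(y))
  # derivative spacing scales as 1/h and 1/h^2
  expect_equal(sg_derivative(line, order = 1, window = 21, spacing = 2),
               rep(1.5, 300))
  expect_error(sg_derivative(y[1:10], window = 21), "exceeds")
  expect_error(sg_smooth(y, window = 20), "odd")
})

test_that("MSC recovers exact affine members and corrects toward the reference", {
  grid <- seq(500, 619, by = 1)
  base <- ref_spec
  X <- rbind(base, 0.8 * base + 0.05, 1.3 * base - 0.02)
  model <- msc_fit(X)
  expect_equal(model$reference, colMeans(X))

  # a spectrum that is exactly 0.1 + 0.9 * reference comes back as the reference
  y <- 0.1 + 0.9 * model$reference
  cf <- tidy(model, newdata = matrix(y, nrow = 1))
  expect_equal(cf$offset, 0.1)
  expect_equal(cf$scale, 0.9)
  expect_equal(msc_apply(model, y), model$reference)

  # self-correction identity
  expect_equal(msc_apply(model, model$reference), model$reference)

  # two-spectrum dataset {x, 2x}: reference is 1.5x and both corrections
  # land on it (closed-form OLS through the two-point system)
  X2 <- rbind(base, 2 * base)
  m2 <- msc_fit(X2)
  expect_equal(m2$reference, 1.5 * base, ignore_attr = TRUE)
  corrected <- msc_apply(m2, X2)
  expect_equal(corrected[1, ], 1.5 * base, ignore_attr = TRUE)
  expect_equal(corrected[2, ], 1.5 * base, ignore_attr = TRUE)

  # affine invariance of the corrected output
  expect_equal(msc_apply(model, 2.2 * y - 0.4), msc_apply(model, y))

  expect_error(msc_fit(matrix(1, 3, 10)), "constant")
  expect_error(msc_fit(matrix(ref_spec, nrow = 1)), "at least two")
  expect_equal(nrow(glance(model)), 1)
})

test_that("preprocess_spectra applies algorithms row-wise over labeled sets", {
  grid <- seq(500, 659, by = 1)
  set.seed(7)
  mats <- list(
    t1 = matrix(runif(5 * length(grid), 0.2, 0.8), nrow = 5),
    t2 = matrix(runif(4 * length(grid), 0.1, 0.9), nrow = 4)
  )
  data <- spectra_from_matrices(mats, grid)

  expect_equal(preprocess_spectra(data, "none")$reflectance, data$reflectance)

  out <- preprocess_spectra(data, "snv")
  m <- set_matrix(out, "t1")
  expect_equal(unname(rowMeans(m)), rep(0, 5))
  expect_equal(apply(m, 1, sd), rep(1, 5), ignore_attr = TRUE)

  # MSC pools all labels into one reference
  pooled <- rbind(mats$t1, mats$t2)
  model <- msc_fit(pooled)
  manual <- msc_apply(model, pooled)
  out_msc <- preprocess_spectra(data, "msc")
  expect_equal(set_matrix(out_msc, "t1"), unname(manual[1:5, ]))
  expect_equal(set_matrix(out_msc, "t2"), unname(manual[6:9, ]))

  # derivatives honor window and are offset-invariant at the dataset level
  out_fd <- preprocess_spectra(data, "first_derivative", sg_window = 21)
  shifted <- dplyr::mutate(data, reflectance = reflectance + 0.3)
  out_fd2 <- preprocess_spectra(shifted, "first_derivative", sg_window = 21)
  expect_equal(out_fd$reflectance, out_fd2$reflectance)

  # errors carry the set label and spectrum index
  bad <- data
  bad$reflectance[bad$label == "t2" & bad$spectrum == 3] <- 0.5
  expect_error(preprocess_spectra(bad, "snv"), "set 't2' spectrum 3")
})

test_that("segmented preprocessing equals blockwise application", {
  grid <- seq(400, 799, by = 1)
  set.seed(8)
  mats <- list(x = matrix(runif(6 * length(grid)), nrow = 6))
  data <- spectra_from_matrices(mats, grid)
  segs <- list(c(400, 599), c(600, 799))

  seg_out <- preprocess_spectra(data, "snv", segments = segs)
  lowdata <- dplyr::filter(data, wavelength <= 599)
  highdata <- dplyr::filter(data, wavelength >= 600)
  manual <- dplyr::bind_rows(preprocess_spectra(lowdata, "snv"),
                             preprocess_spectra(highdata, "snv"))
  manual <- dplyr::arrange(manual, label, spectrum, wavelength)
  seg_sorted <- dplyr::arrange(seg_out, label, spectrum, wavelength)
  expect_equal(seg_sorted$reflectance, manual$reflectance)

  # per-segment reference wavelengths for single-wavelength normalization
  sw_out <- preprocess_spectra(data, "single_wavelength",
                               reference_wavelength = c(500, 700),
                               segments = segs)
  m <- set_matrix(sw_out, "x")
  expect_equal(unname(m[, grid %in% c(500, 700)]),
               matrix(1, nrow = 6, ncol = 2))

  expect_error(preprocess_spectra(data, "snv", segments = list(c(400, 500))),
               "cover")
  expect_error(
    preprocess_spectra(data, "snv",
                       segments = list(c(400, 600), c(600, 799))),
    "disjoint"
  )
})

test_that("scale/offset algorithms suppress glare and distance corruption", {
  tissue <- scenario_table1("bvf")[3, ]
  cfg <- acquisition_config(grid = seq(450, 1050, by = 5), n_spectra = 12,
                            noise = FALSE)
  spectra <- suppressMessages(simulate_spectra(tissue, cfg, seed = 9))
  raw <- set_matrix(spectra, tissue$label)

  rel_spread <- function(m) {
    center <- colMeans(m)
    mean(sqrt(rowSums(sweep(m, 2, center)^2)) / sqrt(sum(center^2)))
  }
  for (alg in c("snv", "msc", "min_max")) {
    proc <- set_matrix(preprocess_spectra(spectra, alg), tissue$label)
    expect_lt(rel_spread(proc), rel_spread(raw) / 5)
  }

  # pure multiplicative corruption (distance only, no glare): AUC and SW
  # collapse all copies of one tissue onto a single spectrum exactly
  cfg_d <- acquisition_config(grid = seq(450, 1050, by = 5), n_spectra = 6,
                              glare = FALSE, noise = FALSE)
  mult <- suppressMessages(simulate_spectra(tissue, cfg_d, seed = 10))
  for (alg in c("auc", "single_wavelength")) {
    m <- set_matrix(preprocess_spectra(mult, alg,
                                       reference_wavelength = 730), tissue$label)
    expect_equal(max(apply(m, 2, function(col) diff(range(col)))), 0,
                 tolerance = 1e-12)
  }
})
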