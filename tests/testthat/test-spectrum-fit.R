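test_that("a noiseless single-line spectrum is recovered exactly", {
  inst <- test_instrument(background_level = 0, instrument_lines = c(Ar = 0))
  lib <- test_library()
  tmpl <- coccoxrf:::element_templates("Ca", lib, inst)
  y <- as.numeric(tmpl %*% 500)
  f <- fit_pixel(y, "Ca", lib, inst, weights = "none")
  expect_equal(unname(f$amplitude[["Ca"]]), 500, tolerance = 1e-9)
  expect_equal(unname(f$amplitude_sigma[["Ca"]]), 0, tolerance = 1e-6)
})

test_that("NNLS matches a brute-force grid oracle on a two-element overlap", {
  # Ni K-alpha on the Cu K-alpha shoulder, noiseless
  inst <- test_instrument(background_level = 0, instrument_lines = c(Ar = 0))
  lib <- test_library()
  tmpl <- coccoxrf:::element_templates(c("Ni", "Cu"), lib, inst)
  truth <- c(Ni = 300, Cu = 700)
  y <- as.numeric(tmpl %*% truth)

  # independent oracle: exhaustive search on an amplitude grid
  grid <- seq(0, 1200, by = 5)
  sse <- outer(grid, grid, Vectorize(function(a, b) {
    sum((y - tmpl[, 1] * a - tmpl[, 2] * b)^2)
  }))
  best <- which(sse == min(sse), arr.ind = TRUE)[1, ]
  oracle <- c(Ni = grid[best[1]], Cu = grid[best[2]])
  expect_equal(unname(oracle), unname(truth))   # grid resolution contains truth

  f <- fit_pixel(y, c("Ni", "Cu"), lib, inst, weights = "none")
  expect_equal(unname(f$amplitude), unname(oracle), tolerance = 5 / 300)
})

test_that("overlapping amplitudes under Poisson noise land within 3 sigma", {
  inst <- test_instrument(instrument_lines = c(Ar = 0), background_level = 0.5)
  lib <- test_library()
  tmpl <- coccoxrf:::element_templates(c("Ni", "Cu"), lib, inst)
  truth <- c(Ni = 2000, Cu = 5000)   # SNR well above 10
  mu <- as.numeric(tmpl %*% truth) + 0.5
  ok <- sapply(1:10, function(s) {
    y <- coccoxrf:::with_seed(s, rpois(length(mu), mu))
    f <- fit_pixel(y, c("Ni", "Cu"), lib, inst)
    all(abs(f$amplitude - truth) <= 3 * f$amplitude_sigma)
  })
  expect_gte(mean(ok), 0.8)
})

test_that("Pb L-lines are absorbed by the merged As* channel", {
  inst <- test_instrument()
  lib <- test_library()
  spec <- specimen_map(list(Ca = matrix(1.5e5, 1, 1)), pixel_size_nm = 100)
  cube <- render_spectra(spec, inst, lib, poisson = FALSE,
                         extra_ppm = list(Pb = matrix(500, 1, 1)))
  f <- fit_pixel(cube$expected[1, 1, ], c("Ca", "As", "Ar", "Si", "Cu", "Kr"),
                 lib, inst, weights = "none")
  expect_gt(f$amplitude[["As"]], 1)   # As absent in truth, channel responds
})

test_that("collinear candidate templates raise an error naming the pair", {
  lib <- data.frame(element = c("Xa", "Xb"), line = "Ka",
                    energy_keV = 5.0, rel_intensity = 1.0,
                    sensitivity = 0.01)
  inst <- test_instrument()
  y <- rep(1, length(inst$energy_bins) - 1)
  expect_error(fit_pixel(y, c("Xa", "Xb"), lib, inst),
               "collinear.*X[ab].*X[ab]")
})

test_that("the evidence rule keeps and drops elements at z sigma", {
  f <- structure(list(amplitude = c(A = 100, B = 10),
                      amplitude_sigma = c(A = 10, B = 10)),
                 class = "fit_result")
  expect_identical(element_inclusion(f, 3), "A")
})

test_that("an absent element is excluded in nearly all seeded replicates", {
  # rate bound fixed from simulation before freezing the test
  inst <- test_instrument()
  lib <- test_library()
  spec <- specimen_map(list(Ca = matrix(1.5e5, 10, 10),
                            Sr = matrix(1100, 10, 10)), pixel_size_nm = 100)
  hits <- sapply(1:20, function(s) {
    cube <- render_spectra(spec, inst, lib, seed = s, poisson = TRUE)
    f <- fit_pixel(sum_spectrum(cube),
                   c("Ca", "Sr", "V", "Ar", "Si", "Cu", "Kr"), lib, inst)
    "V" %in% element_inclusion(f, 3)
  })
  expect_lte(mean(hits), 0.05)
})

test_that("calibration recovers the true flux-area scale", {
  inst <- test_instrument()
  lib <- test_library()
  std <- simulate_standard(inst = inst, library = lib, poisson = FALSE)
  cal <- calibrate(std, line_sensitivities(lib), inst$dwell_s)
  expect_equal(cal$flux_area_scale, inst$flux_area_scale_true,
               tolerance = 0.01)
})

test_that("an injected discrepancy stays on the discrepant element", {
  lib <- test_library()
  sens <- line_sensitivities(lib)
  cert <- c(Ca = 116, Fe = 184, Cu = 160, Zn = 127, Sr = 0.136)
  amps <- 5 * sens[names(cert)] * 0.2 * cert
  std0 <- structure(list(certified = cert, amplitudes = amps),
                    class = "calibration_standard")
  cal0 <- calibrate(std0, sens, 0.2)
  expect_equal(max(abs(cal0$relative_error)), 0, tolerance = 1e-10)
  amps["Fe"] <- amps["Fe"] * 1.1
  std1 <- structure(list(certified = cert, amplitudes = amps),
                    class = "calibration_standard")
  cal1 <- calibrate(std1, sens, 0.2)
  expect_identical(names(which.max(abs(cal1$relative_error))), "Fe")
  expect_lt(max(abs(cal1$relative_error[names(cert) != "Fe"])), 0.03)
})

test_that("Poisson-noised calibration is unbiased within Monte-Carlo error", {
  inst <- test_instrument()
  lib <- test_library()
  ks <- sapply(1:100, function(s) {
    std <- simulate_standard(inst = inst, library = lib, seed = s,
                             poisson = TRUE)
    calibrate(std, line_sensitivities(lib), inst$dwell_s)$flux_area_scale
  })
  se <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - inst$flux_area_scale_true), 3 * se + 1e-6)
})

test_that("single-element calibration warns; zero amplitudes error", {
  sens <- c(Ca = 0.004)
  std <- structure(list(certified = c(Ca = 100),
                        amplitudes = c(Ca = 0.6)),
                   class = "calibration_standard")
  expect_warning(calibrate(std, sens, 0.2), "single-element")
  std0 <- structure(list(certified = c(Ca = 100, Fe = 10),
                         amplitudes = c(Ca = 0.6, Fe = 0)),
                    class = "calibration_standard")
  expect_error(calibrate(std0, c(Ca = 0.004, Fe = 0.008), 0.2), "zero")
})

test_that("fitted amplitudes are linear in the true concentrations", {
  inst <- test_instrument(instrument_lines = c(Ar = 0), background_level = 0)
  lib <- test_library()
  mk <- function(f) specimen_map(list(Ca = matrix(f * 1e5, 1, 1),
                                      Sr = matrix(f * 800, 1, 1)),
                                 pixel_size_nm = 100)
  f1 <- fit_pixel(render_spectra(mk(1), inst, lib, poisson = FALSE)$expected[1, 1, ],
                  c("Ca", "Sr"), lib, inst, weights = "none")
  f2 <- fit_pixel(render_spectra(mk(2), inst, lib, poisson = FALSE)$expected[1, 1, ],
                  c("Ca", "Sr"), lib, inst, weights = "none")
  expect_equal(unname(f2$amplitude), unname(2 * f1$amplitude),
               tolerance = 1e-8)
})

test_that("quantified ppm is invariant to the sensitivity-table scale", {
  inst <- test_instrument()
  lib <- test_library()
  std <- simulate_standard(inst = inst, library = lib, poisson = FALSE)
  amap <- list(Ca = matrix(c(0, 120), 1, 2))
  sens1 <- line_sensitivities(lib)
  sens2 <- sens1 * 37.5
  q1 <- quantify(amap, calibrate(std, sens1, 0.2), sens1, 0.2)
  std2 <- std
  cal2 <- calibrate(std2, sens2, 0.2)
  q2 <- quantify(amap, cal2, sens2, 0.2)
  expect_equal(q1$elements$Ca, q2$elements$Ca, tolerance = 1e-10)
  expect_equal(q1$elements$Ca[1, 1], 0)   # zero amplitude -> zero ppm
})

test_that("the full loop recovers ground truth on a noiseless specimen", {
  inst <- test_instrument()
  lib <- test_library()
  truth <- tiny_truth()
  cube <- render_spectra(truth, inst, lib, poisson = FALSE)
  fr <- fit_specimen(cube, c("Ca", "Sr", "Fe", "V", "Ar", "Si", "Cu", "Kr"),
                     lib, weights = "none")
  expect_setequal(fr$excluded, "V")
  std <- simulate_standard(inst = inst, library = lib, poisson = FALSE)
  cal <- calibrate(std, line_sensitivities(lib), inst$dwell_s)
  q <- quantify(fr$amplitude_maps, cal, line_sensitivities(lib),
                inst$dwell_s, pixel_size_nm = 100)
  for (el in c("Ca", "Sr", "Fe")) {
    tr <- truth$elements[[el]]
    sel <- tr > 1
    expect_lt(max(abs(q$elements[[el]][sel] - tr[sel]) / tr[sel]), 0.005)
  }
})

test_that("a 10 ppm constant concentration is still recoverable", {
  inst <- test_instrument()
  lib <- test_library()
  film <- specimen_map(list(Ca = matrix(1.5e5, 40, 50),
                            Mn = matrix(10, 40, 50)), pixel_size_nm = 100)
  cube <- render_spectra(film, inst, lib, seed = 11, poisson = TRUE)
  f <- fit_pixel(sum_spectrum(cube), c("Ca", "Mn", "Ar", "Si", "Cu", "Kr"),
                 lib, inst)
  expect_true("Mn" %in% element_inclusion(f, 3))
  sens <- line_sensitivities(lib)
  ppm <- f$amplitude[["Mn"]] /
    (inst$flux_area_scale_true * sens[["Mn"]] * inst$dwell_s) / 2000
  expect_equal(ppm, 10, tolerance = 0.5)
})
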