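test_that("calcite mask applies the Ca threshold directly", {
  ca <- matrix(c(1e4, 5e4, 2e5), 1, 3)
  expect_identical(as.logical(mask_calcite(ca, 2e4)), c(FALSE, TRUE, TRUE))
  expect_identical(mask_calcite(ca, 0), ca >= 0)
  expect_warning(mask_calcite(matrix(0, 2, 2), 1e4), "empty")
})

test_that("raising the mask threshold never adds pixels", {
  ca <- template_specimen("control")$elements$Ca
  prev <- mask_calcite(ca, 0)
  for (thr in c(0.1e5, 0.2e5, 0.5e5, 1e5, 2e5)) {
    cur <- mask_calcite(ca, thr)
    expect_true(all(prev | !cur))   # cur subset of prev
    prev <- cur
  }
})

test_that("ratio maps convert ppm pairs to mmol/mol", {
  mask <- matrix(TRUE, 1, 3)
  # frozen from hand computation: (1170/87.62)/(165000/40.078)*1000
  r <- ratio_map(matrix(1.17e3, 1, 3), matrix(1.65e5, 1, 3), "Sr", mask)
  expect_equal(r[1, 1], 3.2433, tolerance = 1e-4)
  # identical ppm and equal weights give 1000 mmol/mol
  r2 <- ratio_map(matrix(5, 1, 3), matrix(5, 1, 3), mask = mask,
                  a_i = 40.078)
  expect_equal(unique(as.numeric(r2)), 1000)
  r3 <- ratio_map(matrix(0, 1, 3), matrix(1e5, 1, 3), "Sr", mask)
  expect_equal(unique(as.numeric(r3)), 0)
  # scale invariance: common ppm factor cancels
  r4 <- ratio_map(matrix(1.17e3, 1, 3) * 7, matrix(1.65e5, 1, 3) * 7, "Sr",
                  mask)
  expect_equal(as.numeric(r4), as.numeric(r), tolerance = 1e-12)
})

test_that("specimen statistics follow mask count and pixel area", {
  ca <- matrix(0, 200, 200)
  ca[1:80, 1:200] <- 1.5e5          # 16,000 masked pixels at 50 nm
  sr <- ca * (87.62 / 40.078) * 3 / 1000
  spec <- specimen_map(list(Ca = ca, Sr = sr), pixel_size_nm = 50)
  st <- specimen_stats(spec)
  expect_equal(st$n_points, 16000)
  expect_equal(st$area_um2, 40)     # 16,000 x 0.0025 um^2
  expect_equal(st$elements$mean_ratio_mmol_per_mol, 3, tolerance = 1e-12)
  # empty-mask sentinel
  st0 <- suppressWarnings(
    specimen_stats(specimen_map(list(Ca = matrix(0, 3, 3),
                                     Sr = matrix(0, 3, 3)))))
  expect_true(is.na(st0$mean_ca_ppm))
  expect_identical(st0$n_points, 0L)
})

test_that("a transect across the coccolith shows the banded Ca zoning", {
  spec <- template_specimen("control")
  d <- dim(spec$elements$Ca)
  yc <- round((d[1] - 1) / 2)
  tr <- extract_transect(spec, rbind(c(2, yc), c(d[2] - 3, yc)))
  expect_identical(collapse_bands(tr$band),
                   c("background", "low", "high", "low", "background"))
  expect_true(all(tr$ca_ppm[tr$band == "high"] >= 1e5))
  expect_false(any(tr$in_calcite[tr$band == "background"]))
})

test_that("rimward lattice gradients appear in transects at equal Ca", {
  th <- make_geometry(geometry_config(length_um = 6, width_um = 4.8,
                                      pixel_size_nm = 50))
  spec <- make_element_fields(
    th, list(Sr = incorporation_model("lattice", base_ratio_mmol_per_mol = 3,
                                      radial_gradient = 2, noise_cv = 0)),
    ca_noise_cv = 0)
  d <- dim(spec$elements$Ca)
  yc <- round((d[1] - 1) / 2)
  tr <- extract_transect(spec, rbind(c(2, yc), c(d[2] - 3, yc)))
  low <- tr$band == "low"
  high <- tr$band == "high"
  # outer (shield) band carries higher Sr/Ca than the tube
  expect_gt(mean(tr$Sr_ca_mmol_mol[low]), mean(tr$Sr_ca_mmol_mol[high]))
  # equal-Ca pixels: internal vs external shield sample on the same ray
  left_shield <- which(low & tr$x < d[2] / 2)
  inner <- max(left_shield)          # adjacent to the tube
  outer <- min(left_shield)          # near the margin
  expect_equal(tr$ca_ppm[inner], tr$ca_ppm[outer], tolerance = 1e-9)
  expect_gt(tr$Sr_ca_mmol_mol[outer], tr$Sr_ca_mmol_mol[inner])
})

test_that("transects fully in the background are rejected", {
  spec <- template_specimen("control")
  expect_error(extract_transect(spec, rbind(c(0, 0), c(4, 0))),
               "background")
})

test_that("region segmentation partitions the mask with the 30-point floor", {
  spec <- template_specimen("control")
  mask <- mask_calcite(spec)
  p <- segment_regions(spec, mask)
  expect_true(all(p$counts >= 30))
  lab <- p$labels
  in_mask <- lab %in% c("tube", "external_rim", "margin")
  expect_identical(unname(in_mask), as.logical(mask))   # exhaustive, disjoint
  # tiny toy mask cannot satisfy the 30-point rule
  toy <- specimen_map(list(Ca = matrix(1e5, 5, 5)))
  expect_error(segment_regions(toy), "rejected")
})

test_that("rimward gradient shows as monotone region means", {
  th <- make_geometry(geometry_config(length_um = 9, width_um = 7,
                                      pixel_size_nm = 50))
  spec <- make_element_fields(
    th, list(Sr = incorporation_model("lattice", base_ratio_mmol_per_mol = 3,
                                      radial_gradient = 2)))
  p <- segment_regions(spec)
  rm <- region_means(spec, p)
  v <- setNames(rm$mean_ratio_mmol_per_mol, rm$region)
  expect_lt(v[["tube"]], v[["external_rim"]])
  expect_lt(v[["external_rim"]], v[["margin"]])
})

test_that("specimens flagged as tilted are excluded from region analysis", {
  spec <- template_specimen("control")
  spec$excluded_from_regions <- TRUE
  expect_error(segment_regions(spec), "excluded")
})

test_that("masked correlation matches affine expectations and brute force", {
  m <- matrix(TRUE, 2, 5)
  a <- matrix(rnorm(10, 5), 2, 5)
  expect_equal(correlate_maps(a, 2 * a + 5, m), 1)
  expect_equal(correlate_maps(a, -a, m), -1)
  b <- matrix(rnorm(10), 2, 5)
  # textbook formula evaluated directly
  av <- as.numeric(a); bv <- as.numeric(b); n <- 10
  oracle <- (sum(av * bv) - sum(av) * sum(bv) / n) /
    sqrt((sum(av^2) - sum(av)^2 / n) * (sum(bv^2) - sum(bv)^2 / n))
  expect_equal(correlate_maps(a, b, m), oracle, tolerance = 1e-12)
  # degenerate variance is a sentinel, not an exception
  z <- correlate_maps(matrix(1, 2, 5), b, m)
  expect_true(is.na(z))
  expect_match(attr(z, "reason"), "variance")
  expect_error(correlate_maps(a, b, matrix(FALSE, 2, 5)), "3 pixels")
})

test_that("lattice elements approach r = 1 as noise vanishes", {
  rs <- sapply(c(0.2, 0.05, 0), function(cv) {
    th <- make_geometry(tiny_geometry())
    spec <- make_element_fields(
      th, list(Sr = incorporation_model("lattice",
                                        base_ratio_mmol_per_mol = 3,
                                        radial_gradient = 1,
                                        noise_cv = cv)),
      ca_noise_cv = 0)
    correlate_maps(spec$elements$Sr, spec$elements$Ca, mask_calcite(spec))
  })
  expect_true(all(diff(rs) > 0) || rs[3] > 0.999)
  expect_equal(rs[3], 1, tolerance = 1e-9)
})
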