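test_that("noiseless flat lattice element has exactly constant molar ratio", {
  th <- make_geometry(tiny_geometry())
  spec <- make_element_fields(
    th, list(Sr = incorporation_model("lattice", base_ratio_mmol_per_mol = 3,
                                      radial_gradient = 1, noise_cv = 0)),
    ca_noise_cv = 0)
  mask <- unclass(th) > 0
  r <- ratio_map(spec$elements$Sr, spec$elements$Ca, "Sr", mask)
  expect_equal(range(r[mask]), c(3, 3), tolerance = 1e-12)
})

test_that("radial gradient scales margin ratio relative to the tube", {
  th <- make_geometry(geometry_config(length_um = 6, width_um = 4.8,
                                      pixel_size_nm = 50))
  spec <- make_element_fields(
    th, list(Sr = incorporation_model("lattice", base_ratio_mmol_per_mol = 3,
                                      radial_gradient = 2, noise_cv = 0)),
    ca_noise_cv = 0)
  mask <- unclass(th) > 0
  r <- ratio_map(spec$elements$Sr, spec$elements$Ca, "Sr", mask)
  rho <- coccoxrf:::radial_coordinate(th)
  outermost <- mask & rho <= 0.1             # margin edge: ratio -> base x 2
  tube_core <- mask & rho >= 1               # at/inside mean tube depth: base
  expect_equal(mean(r[outermost]) / mean(r[tube_core]), 2, tolerance = 0.10)
  expect_equal(mean(r[tube_core]), 3, tolerance = 1e-9)
})

test_that("surface coat fields stay decorrelated from thickness", {
  # bound fixed from a 30-seed simulation of the default coat parameters
  rs <- sapply(1:8, function(s) {
    spec <- simulate_specimen(specimen_template("control", seed = s),
                              seed = s)$specimen
    th <- attr(spec, "thickness")
    abs(correlate_maps(spec$elements$Cl, th, th > 0))
  })
  expect_true(all(rs < 0.3))
})

test_that("surface elements share the organic coat (Cl-like profiles)", {
  spec <- template_specimen("control")
  mask <- mask_calcite(spec)
  expect_gte(correlate_maps(spec$elements$Fe, spec$elements$Cl, mask), 0.3)
  expect_gte(correlate_maps(spec$elements$Ni, spec$elements$Cl, mask), 0.3)
})

test_that("generation is deterministic and seeds change the fields", {
  tpl <- specimen_template("medium", seed = 5)
  a <- simulate_specimen(tpl, seed = 5)$specimen
  b <- simulate_specimen(tpl, seed = 5)$specimen
  expect_identical(a$elements, b$elements)
  c <- simulate_specimen(tpl, seed = 6)$specimen
  expect_false(identical(a$elements$Ca, c$elements$Ca))
})

test_that("control template sits at the published concentration scale", {
  spec <- template_specimen("control")
  st <- specimen_stats(spec)
  expect_equal(st$mean_ca_ppm, 1.5e5, tolerance = 0.1)
  expect_gt(st$n_points, 16000)
  expect_lt(st$n_points, 35000)
})

test_that("stressed templates are thinner than the control", {
  ctrl <- specimen_stats(template_specimen("control"))
  high <- specimen_stats(template_specimen("high"))
  expect_gt(ctrl$mean_ca_ppm, high$mean_ca_ppm)
  expect_gt(ctrl$ca_per_area_ppm_um2, high$ca_per_area_ppm_um2)
})

test_that("lattice generation with no calcite anywhere is rejected", {
  th <- make_geometry(tiny_geometry())
  th[] <- 0
  expect_error(
    make_element_fields(th, list(Sr = incorporation_model(
      "lattice", base_ratio_mmol_per_mol = 3))),
    "degenerate")
})

test_that("recorded ground truth matches the generated fields", {
  spec <- template_specimen("control")
  truth <- attr(spec, "truth")
  st <- specimen_stats(spec, mask = attr(spec, "thickness") > 0)
  m <- merge(st$elements, truth, by = "element")
  keep <- m$mode != "absent"
  expect_equal(m$mean_ratio_mmol_per_mol[keep],
               m$true_mean_ratio_mmol_per_mol[keep], tolerance = 0.02)
})
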