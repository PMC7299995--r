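# Shared fixtures, built in code and cached per test run.

.fx <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# Full-size specimen from a shipped template (default study conditions).
template_specimen <- function(condition = "control", seed = 3) {
  cached(paste0("tpl_", condition, "_", seed), {
    tpl <- specimen_template(condition, seed = seed)
    simulate_specimen(tpl, seed = seed)$specimen
  })
}

# Reduced geometry for spectral work (coarse pixels, small grid).
tiny_geometry <- function(...) {
  geometry_config(length_um = 2.4, width_um = 1.8, pixel_size_nm = 100, ...)
}

# Coarser energy axis than the default: ~6 bins per FWHM, half the bins.
test_instrument <- function(...) {
  instrument_config(energy_bins = seq(0.8, 17.1, by = 0.02), ...)
}

test_library <- function() cached("lib", read_line_library())

# Tiny noiseless lattice+coat specimen used by several spectral tests.
tiny_truth <- function(seed = 1, noise_cv = 0, ca_noise_cv = 0) {
  th <- make_geometry(tiny_geometry(seed = seed))
  models <- list(
    Sr = incorporation_model("lattice", base_ratio_mmol_per_mol = 3,
                             noise_cv = noise_cv),
    Fe = incorporation_model("surface", coat_field_scale = 400,
                             noise_cv = noise_cv))
  make_element_fields(th, models, seed = seed, ca_noise_cv = ca_noise_cv)
}

# Collapse a transect band sequence to its run-length labels.
collapse_bands <- function(bands) rle(as.character(bands))$values
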