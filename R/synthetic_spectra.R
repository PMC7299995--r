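#' Instrument configuration for spectrum rendering and fitting
#'
#' Describes the excitation/detection chain: incident (pink-beam) energy,
#' per-pixel dwell time, the detector energy axis and resolution model, a
#' flat continuum level, the global flux-area sensitivity scalar, and the
#' instrument contaminant lines (hutch Ar and Kr, detector Si, TEM-grid Cu)
#' that appear uniformly over all pixels including the background.
#'
#' The detector resolution follows
#' \code{FWHM(E) = sqrt(electronic_noise_eV^2 + fano_like_slope * E_eV)},
#' a two-parameter stand-in for a silicon drift detector response; defaults
#' give ~170 eV at Mn K-alpha, which leaves the Ni K-alpha peak sitting on
#' the Cu K-alpha shoulder.
#'
#' @param incident_energy_keV excitation energy (default 17.1); only lines
#'   below it are excitable.
#' @param dwell_s counting time per pixel (default 0.2 s).
#' @param energy_bins strictly increasing bin edges in keV.
#' @param electronic_noise_eV,fano_like_slope detector FWHM model.
#' @param background_level expected continuum counts per bin per pixel.
#' @param flux_area_scale_true ground-truth global sensitivity scalar k*
#'   used when rendering (the quantity \code{\link{calibrate}} recovers).
#' @param instrument_lines named vector of per-pixel expected line-family
#'   counts per second for the instrument channels.
#' @return an \code{instrument_config} list.
#' @export
instrument_config <- function(incident_energy_keV = 17.1,
                              dwell_s = 0.2,
                              energy_bins = seq(0.8, 17.1, by = 0.01),
                              electronic_noise_eV = 120,
                              fano_like_slope = 2.46,
                              background_level = 0.02,
                              flux_area_scale_true = 7.5,
                              instrument_lines = c(Ar = 150, Si = 75,
                                                   Cu = 200, Kr = 40)) {
  if (any(diff(energy_bins) <= 0)) stop("bin edges must be strictly increasing")
  if (dwell_s <= 0) stop("dwell must be positive")
  structure(list(incident_energy_keV = incident_energy_keV,
                 dwell_s = dwell_s,
                 energy_bins = energy_bins,
                 electronic_noise_eV = electronic_noise_eV,
                 fano_like_slope = fano_like_slope,
                 background_level = background_level,
                 flux_area_scale_true = flux_area_scale_true,
                 instrument_lines = instrument_lines),
            class = "instrument_config")
}

# Detector FWHM (keV) at energy E (keV).
detector_fwhm <- function(inst, energy_keV) {
  e_ev <- energy_keV * 1000
  sqrt(inst$electronic_noise_eV^2 + inst$fano_like_slope * e_ev) / 1000
}

# Unit-area line profile integrated over the energy bins: one column per
# requested element, each column the sum of its family lines weighted by
# relative intensity. Total column integral equals the family-wise
# rel_intensity sum (1 for complete families), so a coefficient is the total
# counts in the element's line family.
element_templates <- function(elements, library, inst) {
  edges <- inst$energy_bins
  nb <- length(edges) - 1
  out <- matrix(0, nb, length(elements),
                dimnames = list(NULL, elements))
  for (el in elements) {
    rows <- library[library$element == el &
                    library$energy_keV < inst$incident_energy_keV, ]
    if (nrow(rows) == 0) {
      stop("no excitable line in library for element: ", el)
    }
    col <- numeric(nb)
    for (i in seq_len(nrow(rows))) {
      sdv <- detector_fwhm(inst, rows$energy_keV[i]) / 2.35482
      p <- pnorm(edges, rows$energy_keV[i], sdv)
      col <- col + rows$rel_intensity[i] * diff(p)
    }
    out[, el] <- col
  }
  out
}

#' Render per-pixel XRF spectra from ground-truth concentration maps
#'
#' The expected spectrum of a pixel is a flat continuum plus one Gaussian
#' line family per element, with family amplitude
#' \code{k* x sensitivity x ppm x dwell}, plus the instrument lines (Ar, Kr,
#' Si, Cu) added uniformly over all pixels including the background.
#' Observed counts are drawn Poisson around the expectation; the noiseless
#' expectation is stored alongside for testing.
#'
#' @param truth a \code{\link{specimen_map}} of ground-truth ppm fields
#'   (must include Ca).
#' @param inst an \code{\link{instrument_config}}.
#' @param library a \code{\link{read_line_library}} table; every element of
#'   \code{truth} must have an excitable line in it.
#' @param seed integer seed for the Poisson draw.
#' @param poisson draw Poisson counts (\code{FALSE} copies the expectation).
#' @param extra_ppm optional named list of additional ppm maps rendered into
#'   the spectra but not part of the fitted truth (e.g. Pb L-lines).
#' @return a \code{spectrum_cube}: list with \code{counts} and
#'   \code{expected} arrays (nrow x ncol x nbins), \code{energy_bins},
#'   \code{energy_mid}, \code{inst}, \code{elements}.
#' @export
render_spectra <- function(truth, inst, library = read_line_library(),
                           seed = 1L, poisson = TRUE, extra_ppm = NULL) {
  stopifnot(inherits(truth, "specimen_map"), inherits(inst, "instrument_config"))
  elements <- names(truth$elements)
  all_el <- c(elements, names(extra_ppm))
  sens <- line_sensitivities(library)
  missing_sens <- setdiff(all_el, names(sens))
  if (length(missing_sens)) {
    stop("element(s) missing from line library: ",
         paste(missing_sens, collapse = ", "))
  }
  inst_el <- names(inst$instrument_lines)
  tmpl <- element_templates(unique(c(all_el, inst_el)), library, inst)
  nb <- nrow(tmpl)
  nr <- nrow(truth$elements[[1]]); nc <- ncol(truth$elements[[1]])
  npx <- nr * nc

  # amplitude matrix: one row per rendered channel, one column per pixel
  amp <- matrix(0, ncol(tmpl), npx, dimnames = list(colnames(tmpl), NULL))
  kst <- inst$flux_area_scale_true
  for (el in elements) {
    amp[el, ] <- amp[el, ] +
      kst * sens[[el]] * as.numeric(truth$elements[[el]]) * inst$dwell_s
  }
  for (el in names(extra_ppm)) {
    amp[el, ] <- amp[el, ] +
      kst * sens[[el]] * as.numeric(extra_ppm[[el]]) * inst$dwell_s
  }
  for (el in inst_el) {
    amp[el, ] <- amp[el, ] + inst$instrument_lines[[el]] * inst$dwell_s
  }

  expected <- tmpl %*% amp + inst$background_level    # nbins x npx
  counts <- if (poisson) {
    with_seed(seed, matrix(rpois(length(expected), expected), nb, npx))
  } else expected

  structure(list(counts = array(t(counts), c(nr, nc, nb)),
                 expected = array(t(expected), c(nr, nc, nb)),
                 energy_bins = inst$energy_bins,
                 energy_mid = (head_(inst$energy_bins) +
                               tail_(inst$energy_bins)) / 2,
                 inst = inst,
                 elements = elements),
            class = "spectrum_cube")
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1]

#' @export
print.spectrum_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<spectrum_cube> %d x %d px, %d bins (%.2f-%.2f keV), elements: %s\n",
              d[1], d[2], d[3], min(x$energy_bins), max(x$energy_bins),
              paste(x$elements, collapse = " ")))
  invisible(x)
}

#' Summed (specimen-level) spectrum of a cube
#'
#' @param cube a \code{spectrum_cube}.
#' @param expected sum the noiseless expectation instead of the counts.
#' @return numeric vector of per-bin summed counts.
#' @export
sum_spectrum <- function(cube, expected = FALSE) {
  a <- if (expected) cube$expected else cube$counts
  apply(a, 3, sum)
}

#' Simulate a measurement of a homogeneous calibration standard
#'
#' Renders the spectrum of a thin homogeneous film with the certified
#' composition under the given instrument, sums it over the measured pixels
#' and fits the element line amplitudes, returning a calibration-standard
#' object ready for \code{\link{calibrate}} (amplitudes on the per-pixel
#' scale).
#'
#' @param certified named numeric vector of certified mass fractions (ppm),
#'   or a CSV path / data.frame with columns element, certified_ppm. Default
#'   is the packaged synthetic certificate.
#' @param inst an \code{\link{instrument_config}}.
#' @param library line library.
#' @param n_pixels number of pixels averaged.
#' @param seed integer seed.
#' @param poisson draw Poisson counts.
#' @return list of class \code{calibration_standard}: \code{certified} (ppm)
#'   and \code{amplitudes} (fitted per-pixel line-family counts).
#' @export
simulate_standard <- function(certified = NULL, inst = instrument_config(),
                              library = read_line_library(),
                              n_pixels = 400, seed = 1L, poisson = TRUE) {
  if (is.null(certified)) {
    certified <- system.file("extdata", "synthetic_standard_certified.csv",
                             package = "coccoxrf")
  }
  if (is.character(certified)) {
    certified <- read.csv(certified, comment.char = "#")
  }
  if (is.data.frame(certified)) {
    certified <- setNames(certified$certified_ppm, certified$element)
  }
  sens <- line_sensitivities(library)
  tmpl <- element_templates(names(certified), library, inst)
  amp_true <- inst$flux_area_scale_true * sens[names(certified)] *
    certified * inst$dwell_s
  expected <- as.numeric(tmpl %*% amp_true) * n_pixels +
    inst$background_level * n_pixels
  y <- if (poisson) {
    with_seed(child_seed(seed, "standard"), rpois(length(expected), expected))
  } else expected
  fit <- fit_pixel(y, names(certified), library, inst,
                   weights = if (poisson) "poisson" else "none")
  structure(list(certified = certified,
                 amplitudes = fit$amplitude / n_pixels),
            class = "calibration_standard")
}
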