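#' Fit one XRF spectrum by nonnegative least squares
#'
#' Models the spectrum as a nonnegative combination of per-element Gaussian
#' line-family templates (energies, widths and within-family relative
#' intensities fixed by the library and detector model) plus a low-order
#' continuum parameterized on the degree-2 Bernstein basis (so the whole
#' problem is a single Lawson-Hanson NNLS and the continuum is nonnegative,
#' as photon counts are). Amplitudes are total counts in each element's line
#' family; their uncertainties come from the weighted-normal-equations
#' covariance.
#'
#' @param spectrum numeric vector of per-bin counts matching
#'   \code{inst$energy_bins}.
#' @param candidate_elements element symbols to include in the fit.
#' @param library a \code{\link{read_line_library}} table.
#' @param inst an \code{\link{instrument_config}}.
#' @param weights "poisson" (per-bin variance \code{max(counts, 1)}) or
#'   "none" (unweighted; covariance scaled by the residual variance).
#' @param background_degree degree of the Bernstein continuum (default 2).
#' @return a \code{fit_result}: named \code{amplitude} and
#'   \code{amplitude_sigma} vectors, \code{background} coefficients,
#'   \code{fitted}, \code{residual_norm}, \code{included} flags.
#' @export
fit_pixel <- function(spectrum, candidate_elements, library,
                      inst, weights = c("poisson", "none"),
                      background_degree = 2) {
  weights <- match.arg(weights)
  nb <- length(inst$energy_bins) - 1
  if (length(spectrum) != nb) {
    stop("spectrum length does not match instrument energy bins")
  }
  bad <- vapply(candidate_elements, function(el) {
    !any(library$element == el &
         library$energy_keV < inst$incident_energy_keV)
  }, TRUE)
  if (any(bad)) {
    stop("candidate element(s) with no excitable line: ",
         paste(candidate_elements[bad], collapse = ", "))
  }

  tmpl <- element_templates(candidate_elements, library, inst)

  # near-duplicate templates make the design singular; name the pair
  if (ncol(tmpl) > 1) {
    cc <- suppressWarnings(cor(tmpl))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 0
    if (any(cc > 0.9999)) {
      ij <- which(cc > 0.9999, arr.ind = TRUE)[1, ]
      stop(sprintf("collinear line templates for elements %s and %s",
                   colnames(tmpl)[ij[1]], colnames(tmpl)[ij[2]]))
    }
  }

  x <- seq(0, 1, length.out = nb)
  bern <- sapply(0:background_degree, function(k) {
    choose(background_degree, k) * x^k * (1 - x)^(background_degree - k)
  })
  colnames(bern) <- paste0("bg", 0:background_degree)
  A <- cbind(tmpl, bern)

  # Poisson weighting uses the fitted expectation, not the observed counts:
  # weighting by observed counts upweights downward fluctuations and biases
  # low-count amplitudes; one reweighted pass after an unweighted fit is
  # asymptotically unbiased.
  sol <- pracma::lsqnonneg(A, as.numeric(spectrum))
  coefs <- setNames(sol$x, colnames(A))
  fitted <- as.numeric(A %*% coefs)
  w <- rep(1, nb)
  if (weights == "poisson") {
    w <- 1 / pmax(fitted, 1)
    sw <- sqrt(w)
    sol <- pracma::lsqnonneg(A * sw, as.numeric(spectrum) * sw)
    coefs <- setNames(sol$x, colnames(A))
    fitted <- as.numeric(A %*% coefs)
  }
  sw <- sqrt(w)

  # covariance of the (unconstrained) weighted LS estimate; for Poisson
  # weights the scale is already in w, otherwise estimate it from residuals
  xtx <- crossprod(A * sw)
  covm <- tryCatch(solve(xtx), error = function(e) MASS_ginv(xtx))
  if (weights == "none") {
    dof <- max(nb - ncol(A), 1)
    covm <- covm * sum((spectrum - fitted)^2) / dof
  }
  sig <- sqrt(pmax(diag(covm), 0))

  ne <- length(candidate_elements)
  structure(list(amplitude = coefs[seq_len(ne)],
                 amplitude_sigma = setNames(sig[seq_len(ne)],
                                            candidate_elements),
                 background = coefs[-seq_len(ne)],
                 fitted = fitted,
                 residual_norm = sqrt(sum(w * (spectrum - fitted)^2)),
                 included = setNames(rep(TRUE, ne), candidate_elements)),
            class = "fit_result")
}

# Moore-Penrose fallback for singular normal equations (tiny helper; the
# collinearity guard above catches designed duplicates first).
MASS_ginv <- function(x, tol = sqrt(.Machine$double.eps)) {
  s <- svd(x)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Decide which elements show certain evidence in a fit
#'
#' An element is kept only when its fitted line amplitude in the
#' specimen-summed spectrum exceeds \code{z_threshold} times its fit
#' uncertainty; elements without such evidence are left out so the per-pixel
#' fits are not overfitted. The decision is made once, on the summed
#' spectrum, and applied uniformly to all pixels.
#'
#' @param fit a \code{\link{fit_pixel}} result on the summed spectrum.
#' @param z_threshold evidence threshold in sigma units (default 3).
#' @return character vector of retained element symbols.
#' @export
element_inclusion <- function(fit, z_threshold = 3) {
  stopifnot(inherits(fit, "fit_result"))
  keep <- fit$amplitude > z_threshold * fit$amplitude_sigma
  names(fit$amplitude)[keep]
}

#' Calibrate the global flux-area sensitivity against a certified standard
#'
#' Finds the single scalar k such that predicted concentrations
#' \code{amplitude / (k x sensitivity x dwell)} best match the certified
#' mass fractions, minimizing squared log-ratios so elements spanning orders
#' of magnitude weigh evenly. Per-element relative calibration errors are
#' reported.
#'
#' @param standard a \code{calibration_standard} (certified ppm + measured
#'   per-pixel amplitudes, e.g. from \code{\link{simulate_standard}}).
#' @param sensitivities named per-element sensitivity vector
#'   (\code{\link{line_sensitivities}}).
#' @param dwell_s dwell time of the standard measurement in seconds.
#' @return a \code{calibration_result}: \code{flux_area_scale} k and
#'   \code{relative_error} per element.
#' @export
calibrate <- function(standard, sensitivities, dwell_s) {
  el <- intersect(names(standard$certified), names(standard$amplitudes))
  if (length(el) < 1) stop("no common elements between certificate and fit")
  amp <- standard$amplitudes[el]
  cert <- standard$certified[el]
  if (any(cert <= 0)) stop("certified values must be positive")
  if (any(amp <= 0)) {
    stop("zero fitted amplitude for calibration element(s): ",
         paste(el[amp <= 0], collapse = ", "))
  }
  miss <- setdiff(el, names(sensitivities))
  if (length(miss)) stop("missing sensitivity for: ", paste(miss, collapse = ", "))
  if (length(el) < 2) {
    warning("single-element calibration: k solved exactly, no redundancy")
  }
  logk <- mean(log(amp / (sensitivities[el] * dwell_s * cert)))
  k <- exp(logk)
  pred <- amp / (k * sensitivities[el] * dwell_s)
  structure(list(flux_area_scale = k,
                 relative_error = setNames(pred / cert - 1, el),
                 elements = el),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> flux-area scale k = %.4g (%d elements, max |rel err| %.2g%%)\n",
              x$flux_area_scale, length(x$elements),
              100 * max(abs(x$relative_error))))
  invisible(x)
}

#' Convert fitted amplitude maps to semiquantitative concentration maps
#'
#' Applies the calibrated flux-area scale:
#' \code{ppm = amplitude / (k x sensitivity x dwell)}. Amplitudes are
#' nonnegative by construction of the fit, so ppm maps are too. Instrument
#' channels (Ar, Kr, Si, Cu) are fitted but never quantified and are dropped
#' here.
#'
#' @param amplitude_maps named list of per-element amplitude matrices.
#' @param cal a \code{\link{calibrate}} result.
#' @param sensitivities named sensitivity vector (same table used in
#'   \code{calibrate}; quantified ppm is invariant to its overall scale).
#' @param dwell_s dwell time per pixel in seconds.
#' @param pixel_size_nm pixel size recorded on the result.
#' @param drop_instrument drop the instrument channels (default TRUE).
#' @param ... labels passed to \code{\link{specimen_map}}.
#' @return a \code{\link{specimen_map}} of ppm grids.
#' @export
quantify <- function(amplitude_maps, cal, sensitivities, dwell_s,
                     pixel_size_nm = 50, drop_instrument = TRUE, ...) {
  stopifnot(inherits(cal, "calibration_result"))
  els <- names(amplitude_maps)
  if (drop_instrument) els <- setdiff(els, .cx_instrument_channels)
  miss <- setdiff(els, names(sensitivities))
  if (length(miss)) {
    stop("element(s) missing from sensitivity table: ",
         paste(miss, collapse = ", "))
  }
  k <- cal$flux_area_scale
  ppm <- lapply(setNames(els, els), function(el) {
    amplitude_maps[[el]] / (k * sensitivities[[el]] * dwell_s)
  })
  specimen_map(ppm, pixel_size_nm = pixel_size_nm, ...)
}

#' Fit a whole spectrum cube into amplitude maps
#'
#' Runs the quantification chain of a specimen: fit the summed spectrum with
#' the full candidate set, apply the \code{\link{element_inclusion}} rule,
#' then re-fit every pixel with only the retained elements.
#'
#' @param cube a \code{\link{render_spectra}} cube (or any
#'   \code{spectrum_cube}).
#' @param candidate_elements full candidate set for the summed-spectrum fit.
#' @param library line library.
#' @param z_threshold evidence threshold for inclusion.
#' @param weights passed to \code{\link{fit_pixel}}.
#' @return list: \code{amplitude_maps} (named matrices), \code{included},
#'   \code{excluded}, \code{summary_fit} (the summed-spectrum
#'   \code{fit_result}).
#' @export
fit_specimen <- function(cube, candidate_elements,
                         library = read_line_library(),
                         z_threshold = 3, weights = "poisson") {
  stopifnot(inherits(cube, "spectrum_cube"))
  inst <- cube$inst
  summed <- sum_spectrum(cube)
  sfit <- fit_pixel(summed, candidate_elements, library, inst,
                    weights = weights)
  kept <- element_inclusion(sfit, z_threshold)
  if (length(kept) == 0) stop("no element passes the evidence threshold")

  d <- dim(cube$counts)
  nr <- d[1]; nc <- d[2]; nb <- d[3]
  ymat <- matrix(aperm(cube$counts, c(3, 1, 2)), nb, nr * nc)

  tmpl <- element_templates(kept, library, inst)
  x <- seq(0, 1, length.out = nb)
  bern <- sapply(0:2, function(k) choose(2, k) * x^k * (1 - x)^(2 - k))
  A <- cbind(tmpl, bern)

  amps <- matrix(0, nr * nc, length(kept),
                 dimnames = list(NULL, kept))
  for (p in seq_len(nr * nc)) {
    y <- ymat[, p]
    sol <- pracma::lsqnonneg(A, y)
    if (weights == "poisson") {
      sw <- sqrt(1 / pmax(as.numeric(A %*% sol$x), 1))
      sol <- pracma::lsqnonneg(A * sw, y * sw)
    }
    amps[p, ] <- sol$x[seq_along(kept)]
  }
  maps <- lapply(setNames(kept, kept), function(el) {
    matrix(amps[, el], nr, nc)
  })
  list(amplitude_maps = maps,
       included = kept,
       excluded = setdiff(candidate_elements, kept),
       summary_fit = sfit)
}
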