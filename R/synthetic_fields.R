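#' Incorporation model for one element
#'
#' Declares how a synthetic element is distributed on the specimen:
#' \describe{
#'   \item{lattice}{substituted into the calcite; per-pixel ppm follows the
#'     Ca map through a molar i/Ca ratio that interpolates from
#'     \code{base_ratio_mmol_per_mol} at the tube to
#'     \code{base_ratio_mmol_per_mol * radial_gradient} at the margin.}
#'   \item{surface}{deposited with the organic coating; a smooth random
#'     field independent of calcite thickness, present also off-coccolith
#'     (membrane background).}
#'   \item{hotspot}{a low coat baseline plus a few localized Gaussian
#'     enrichments (particulate contamination).}
#'   \item{absent}{identically zero.}
#' }
#'
#' @param mode one of "lattice", "surface", "hotspot", "absent".
#' @param base_ratio_mmol_per_mol lattice i/Ca molar ratio at the tube.
#' @param radial_gradient multiplicative tube-to-margin ratio factor
#'   (>= 1 reproduces the rimward Sr/Ca increase; 1 = flat).
#' @param coat_field_scale mean coat concentration in ppm (surface mode, and
#'   the baseline of hotspot mode).
#' @param coat_correlation_length_px Gaussian correlation length of the coat
#'   field in pixels.
#' @param coat_shared_weight in [0, 1]; weight of the specimen-wide shared
#'   organic-coat field in this element's coat (surface elements ride the
#'   same coating, so their maps correlate with each other as Cl-like
#'   profiles do).
#' @param n_hotspots,hotspot_radius_px,hotspot_intensity hotspot count,
#'   Gaussian sigma in pixels, and peak amplitude in ppm.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   applied last.
#' @return an \code{incorporation_model} list.
#' @export
incorporation_model <- function(mode = c("lattice", "surface", "hotspot",
                                         "absent"),
                                base_ratio_mmol_per_mol = 0,
                                radial_gradient = 1,
                                coat_field_scale = 0,
                                coat_correlation_length_px = 4,
                                coat_shared_weight = 0.85,
                                n_hotspots = 3,
                                hotspot_radius_px = 2,
                                hotspot_intensity = 2000,
                                noise_cv = 0.05) {
  mode <- match.arg(mode)
  if (base_ratio_mmol_per_mol < 0) stop("base_ratio must be >= 0")
  if (radial_gradient < 0) stop("radial_gradient must be >= 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (coat_shared_weight < 0 || coat_shared_weight > 1) {
    stop("coat_shared_weight must be in [0, 1]")
  }
  structure(list(mode = mode,
                 base_ratio_mmol_per_mol = base_ratio_mmol_per_mol,
                 radial_gradient = radial_gradient,
                 coat_field_scale = coat_field_scale,
                 coat_correlation_length_px = coat_correlation_length_px,
                 coat_shared_weight = coat_shared_weight,
                 n_hotspots = n_hotspots,
                 hotspot_radius_px = hotspot_radius_px,
                 hotspot_intensity = hotspot_intensity,
                 noise_cv = noise_cv),
            class = "incorporation_model")
}

# Normalized radial coordinate of the coccolith interior: Euclidean distance
# to the exterior background (central opening filled before the transform),
# rescaled so rho = 0 at the margin and 1 at the mean tube depth. Used to
# interpolate lattice ratios from tube to margin.
radial_coordinate <- function(thickness) {
  mask <- thickness > 0
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  d <- EBImage::distmap(filled)
  d <- d@.Data
  tube <- thickness == max(thickness)
  d_tube <- mean(d[tube])
  rho <- d / d_tube
  rho[!mask] <- NA_real_
  rho
}

# Smooth nonnegative random coat field with unit mean: Gaussian-filtered
# white noise, z-scored, compressed, clipped at zero.
coat_field <- function(nr, nc, corr_len) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  # brush capped so the filter fits small grids (odd, < min dimension)
  r <- min(2 * ceiling(3 * corr_len) + 1, 2 * ((min(nr, nc) - 1) %/% 2) - 1)
  sm <- EBImage::gblur(EBImage::Image(z), sigma = corr_len, radius = r,
                       boundary = "replicate")@.Data
  (sm - mean(sm)) / sd(sm)
}

coat_to_ppm <- function(z, scale) {
  f <- pmax(1 + 0.5 * z, 0)
  scale * f / mean(f)
}

#' Generate ground-truth element concentration maps
#'
#' Builds the per-element ppm stack implied by a thickness map and a set of
#' incorporation models. Ca is proportional to thickness
#' (\code{ppm = k_ca * thickness}); lattice elements follow Ca through their
#' radial molar-ratio profile; surface elements are smooth coat fields
#' independent of thickness (riding a shared specimen-wide coat); hotspot
#' elements add localized Gaussian enrichments on a faint baseline.
#' Multiplicative Gaussian noise of the stated CV is applied last, per
#' element. Ground-truth summaries (mode, noiseless mean masked molar ratio)
#' are recorded for recovery testing.
#'
#' @param thickness a \code{\link{make_geometry}} output.
#' @param models named list of \code{\link{incorporation_model}}s (element
#'   symbols as names; do not include Ca).
#' @param seed integer seed.
#' @param k_ca Ca ppm per thickness unit (default 9e4 puts the control
#'   template mean Ca at ~1.5e5 ppm).
#' @param ca_noise_cv multiplicative noise CV on the Ca map.
#' @param species,experiment labels stored on the result.
#' @return a \code{\link{specimen_map}} with a \code{truth} attribute
#'   (data.frame: element, mode, true_mean_ratio_mmol_per_mol).
#' @export
make_element_fields <- function(thickness, models, seed = 1L,
                                k_ca = 9e4, ca_noise_cv = 0.02,
                                species = "synthetic",
                                experiment = "C") {
  stopifnot(inherits(thickness, "thickness_map"))
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("models must be a named list keyed by element symbol")
  }
  if ("Ca" %in% names(models)) stop("Ca is generated implicitly; do not model it")
  nr <- nrow(thickness); nc <- ncol(thickness)
  mask_true <- thickness > 0
  if (any(vapply(models, function(m) m$mode == "lattice", TRUE)) &&
      !any(mask_true)) {
    stop("degenerate input: lattice model requested but Ca is zero everywhere")
  }

  ca_true <- k_ca * unclass(thickness)
  rho <- radial_coordinate(thickness)

  fields <- list()
  truth <- data.frame(element = character(0), mode = character(0),
                      true_mean_ratio_mmol_per_mol = numeric(0))

  out <- with_seed(child_seed(seed, "fields"), {
    shared_coat <- coat_field(nr, nc, 4)
    for (el in names(models)) {
      m <- models[[el]]
      if (m$mode == "absent") {
        f_true <- matrix(0, nr, nc)
        mean_ratio <- 0
      } else if (m$mode == "lattice") {
        g <- m$radial_gradient
        # ratio(rho): base at the tube (rho >= 1), base*gradient at margin
        ratio <- m$base_ratio_mmol_per_mol *
          (1 + (g - 1) * pmax(0, pmin(1, 1 - rho)))
        ratio[!mask_true] <- 0
        aw <- atomic_weight(el) / atomic_weight("Ca")
        f_true <- ca_true * aw * ratio / 1000
        mean_ratio <- mean(ratio[mask_true])
      } else {
        w <- m$coat_shared_weight
        own <- coat_field(nr, nc, m$coat_correlation_length_px)
        z <- w * shared_coat + sqrt(1 - w^2) * own
        if (m$mode == "surface") {
          f_true <- coat_to_ppm(z, m$coat_field_scale)
        } else {                       # hotspot
          f_true <- coat_to_ppm(z, m$coat_field_scale)
          idx <- which(mask_true)
          pick <- sample(idx, m$n_hotspots)
          cy <- (pick - 1) %% nr
          cx <- (pick - 1) %/% nr
          xg <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
          yg <- matrix(rep(0:(nr - 1), nc), nr, nc)
          for (i in seq_len(m$n_hotspots)) {
            r2 <- (xg - cx[i])^2 + (yg - cy[i])^2
            f_true <- f_true +
              m$hotspot_intensity * exp(-r2 / (2 * m$hotspot_radius_px^2))
          }
        }
        aw <- atomic_weight(el) / atomic_weight("Ca")
        r <- ifelse(mask_true, (f_true / ca_true) / aw * 1000, NA)
        mean_ratio <- mean(r[mask_true])
      }
      truth <- rbind(truth, data.frame(
        element = el, mode = m$mode,
        true_mean_ratio_mmol_per_mol = mean_ratio))
      if (m$noise_cv > 0 && m$mode != "absent") {
        f_true <- f_true * pmax(0, 1 + m$noise_cv * matrix(rnorm(nr * nc),
                                                           nr, nc))
      }
      fields[[el]] <- f_true
    }
    ca <- ca_true
    if (ca_noise_cv > 0) {
      ca <- ca * pmax(0, 1 + ca_noise_cv * matrix(rnorm(nr * nc), nr, nc))
    }
    list(fields = fields, ca = ca, truth = truth)
  })

  elements <- c(list(Ca = out$ca), out$fields)
  spec <- specimen_map(elements,
                       pixel_size_nm = attr(thickness, "pixel_size_nm"),
                       species = species, experiment = experiment)
  attr(spec, "truth") <- out$truth
  attr(spec, "thickness") <- unclass(thickness)
  spec
}

#' Template configurations for the shipped synthetic benchmark
#'
#' Returns geometry and incorporation models emulating the three culture
#' conditions: \code{"control"} (regular 9 um placolith with central bar,
#' thick, modest rimward Sr/Ca gradient), \code{"medium"} (thinner, mildly
#' irregular, stronger gradient, metal-bearing coat) and \code{"high"}
#' (thin, strongly irregular outline, central bar missing, roughly doubled
#' Sr/Ca with a steep rimward gradient). Element modes are the ground truth
#' the classifier is benchmarked against: lattice Sr and Se, surface Cl, Fe
#' and Ni, one hotspot contaminant (W in control, Zn otherwise) and absent V.
#'
#' @param condition "control", "medium" or "high".
#' @param pixel_size_nm pixel size; coarser grids give faster small tests.
#' @param seed geometry seed.
#' @return list with elements \code{geometry} (a
#'   \code{\link{geometry_config}}) and \code{models} (named list of
#'   \code{\link{incorporation_model}}s).
#' @export
specimen_template <- function(condition = c("control", "medium", "high"),
                              pixel_size_nm = 50, seed = 1L) {
  condition <- match.arg(condition)
  geom <- switch(condition,
    control = geometry_config("placolith_bar", length_um = 9, width_um = 7,
                              tube_thickness = 3, shield_thickness = 1,
                              outline_irregularity = 0.04,
                              pixel_size_nm = pixel_size_nm, seed = seed),
    medium = geometry_config("placolith_bar", length_um = 8, width_um = 6.2,
                             tube_thickness = 2.2, shield_thickness = 0.65,
                             outline_irregularity = 0.12,
                             pixel_size_nm = pixel_size_nm, seed = seed),
    high = geometry_config("placolith_bar", length_um = 7.5, width_um = 5.6,
                           tube_thickness = 1.8, shield_thickness = 0.45,
                           central_structure_present = FALSE,
                           outline_irregularity = 0.25,
                           pixel_size_nm = pixel_size_nm, seed = seed))
  sr <- switch(condition,
    control = incorporation_model("lattice", base_ratio_mmol_per_mol = 3.5,
                                  radial_gradient = 1.15),
    medium = incorporation_model("lattice", base_ratio_mmol_per_mol = 4.0,
                                 radial_gradient = 1.5),
    high = incorporation_model("lattice", base_ratio_mmol_per_mol = 5.5,
                               radial_gradient = 2.2))
  se <- switch(condition,
    control = incorporation_model("lattice", base_ratio_mmol_per_mol = 0.047),
    medium = incorporation_model("lattice", base_ratio_mmol_per_mol = 0.040),
    high = incorporation_model("lattice", base_ratio_mmol_per_mol = 0.26))
  coat_scale <- switch(condition, control = 1.2e4, medium = 1.4e4,
                       high = 1.5e4)
  fe_scale <- switch(condition, control = 400, medium = 600, high = 800)
  ni_scale <- switch(condition, control = 120, medium = 650, high = 700)
  models <- list(
    Sr = sr, Se = se,
    Cl = incorporation_model("surface", coat_field_scale = coat_scale),
    Fe = incorporation_model("surface", coat_field_scale = fe_scale),
    Ni = incorporation_model("surface", coat_field_scale = ni_scale),
    V = incorporation_model("absent"))
  spot <- incorporation_model("hotspot", coat_field_scale = 5,
                              n_hotspots = 3, hotspot_radius_px = 2,
                              hotspot_intensity = 2000)
  if (condition == "control") models$W <- spot else models$Zn <- spot
  list(condition = condition, geometry = geom, models = models)
}

#' Simulate a complete synthetic specimen
#'
#' Convenience wrapper: geometry, ground-truth element fields and
#' (optionally) the raw per-pixel spectrum cube, all from one seed.
#'
#' @param template a \code{\link{specimen_template}} result (or a list with
#'   \code{geometry} and \code{models}).
#' @param seed top-level seed; stages derive child streams by fixed offsets.
#' @param render logical; also render the spectrum cube (costly on full-size
#'   grids; meant for reduced geometries).
#' @param instrument an \code{\link{instrument_config}} when
#'   \code{render = TRUE}.
#' @param library line library for rendering.
#' @param poisson draw Poisson counts (TRUE) or keep noiseless expectations.
#' @param ... passed to \code{\link{make_element_fields}} (e.g. k_ca,
#'   ca_noise_cv).
#' @return list with \code{specimen} (ground-truth \code{specimen_map}) and
#'   \code{cube} (\code{NULL} unless rendered).
#' @export
simulate_specimen <- function(template, seed = 1L, render = FALSE,
                              instrument = NULL, library = NULL,
                              poisson = TRUE, ...) {
  geom <- template$geometry
  geom$seed <- as.integer(seed)
  th <- make_geometry(geom)
  spec <- make_element_fields(th, template$models, seed = seed,
                              experiment = switch(template$condition %||% "C",
                                                  control = "C", medium = "M",
                                                  high = "H", "C"),
                              ...)
  cube <- NULL
  if (render) {
    if (is.null(instrument)) instrument <- instrument_config()
    if (is.null(library)) library <- read_line_library()
    cube <- render_spectra(spec, instrument, library,
                           seed = child_seed(seed, "spectra"),
                           poisson = poisson)
  }
  list(specimen = spec, cube = cube)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
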