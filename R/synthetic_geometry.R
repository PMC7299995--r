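#' Geometry configuration for a synthetic placolith
#'
#' Describes a single placolith-type coccolith as an elliptical annulus:
#' proximal+distal shields of uniform thickness, a thicker tube ring around
#' the central area, and an optional central structure (a bar along the long
#' axis for \emph{C. pelagicus}-like forms, two crossing diagonal struts for
#' the \emph{G. oceanica}-like bridge). The outline can be perturbed by a
#' smooth periodic radial deformation to emulate malformed specimens grown
#' under stress.
#'
#' @param species_template "placolith_bar" (bar spanning the central area
#'   along the major axis) or "placolith_bridge" (crossed diagonal struts).
#' @param length_um,width_um ellipse axes in micrometers; length >= width.
#' @param tube_thickness,shield_thickness thickness in arbitrary units;
#'   the tube must be thicker than the shields.
#' @param central_structure_present logical; render the bar/bridge.
#' @param outline_irregularity amplitude in [0, 1] of the periodic radial
#'   outline deformation (0 = perfect ellipse).
#' @param pixel_size_nm scan pixel size (default 50 nm, the map resolution).
#' @param hole_frac,tube_frac inner radii (as fractions of the outline) of
#'   the central opening and of the outer edge of the tube ring.
#' @param border_frac background border around the outline, as a fraction of
#'   the length (>= 0.1 enforced).
#' @param grid_shape optional c(nrow, ncol) override for the pixel grid; an
#'   error is raised if it cannot contain the outline plus border.
#' @param seed integer seed controlling the outline deformation.
#' @return a \code{geometry_config} list.
#' @export
geometry_config <- function(species_template = c("placolith_bar",
                                                 "placolith_bridge"),
                            length_um = 9, width_um = 7,
                            tube_thickness = 3, shield_thickness = 1,
                            central_structure_present = TRUE,
                            outline_irregularity = 0,
                            pixel_size_nm = 50,
                            hole_frac = 0.30, tube_frac = 0.62,
                            border_frac = 0.15,
                            grid_shape = NULL,
                            seed = 1L) {
  species_template <- match.arg(species_template)
  if (!(length_um >= width_um && width_um > 0)) {
    stop("invalid geometry: need length_um >= width_um > 0")
  }
  if (tube_thickness <= shield_thickness || shield_thickness <= 0) {
    stop("need tube_thickness > shield_thickness > 0")
  }
  if (outline_irregularity < 0 || outline_irregularity > 1) {
    stop("outline_irregularity must be in [0, 1]")
  }
  if (!(hole_frac > 0 && hole_frac < tube_frac && tube_frac < 1)) {
    stop("need 0 < hole_frac < tube_frac < 1")
  }
  if (border_frac < 0.1) stop("background border must be >= 10% of length")
  cfg <- list(species_template = species_template,
              length_um = length_um, width_um = width_um,
              tube_thickness = tube_thickness,
              shield_thickness = shield_thickness,
              central_structure_present = central_structure_present,
              outline_irregularity = outline_irregularity,
              pixel_size_nm = pixel_size_nm,
              hole_frac = hole_frac, tube_frac = tube_frac,
              border_frac = border_frac, grid_shape = grid_shape,
              seed = as.integer(seed))
  class(cfg) <- "geometry_config"
  cfg
}

#' Render a synthetic coccolith thickness map
#'
#' Builds the per-pixel calcite-thickness proxy field implied by a
#' \code{\link{geometry_config}}: 0 on the background and in the central
#' opening, \code{shield_thickness} on the shields, \code{tube_thickness} on
#' the tube ring and on the central bar/bridge. The outline is the ellipse
#' radius modulated by a smooth seeded harmonic deformation of amplitude
#' \code{outline_irregularity}. Deterministic given the config (the seed is
#' part of the config).
#'
#' @param config a \code{\link{geometry_config}}.
#' @return numeric matrix of class \code{thickness_map} with attribute
#'   \code{pixel_size_nm}; rows index y, columns index x, pixel centers at
#'   integer (0-based) coordinates.
#' @export
#' @examples
#' th <- make_geometry(geometry_config(length_um = 3, width_um = 2.4,
#'                                     pixel_size_nm = 100))
#' max(th)  # tube thickness
make_geometry <- function(config) {
  stopifnot(inherits(config, "geometry_config"))
  px <- config$pixel_size_nm * 1e-3            # pixel size in um
  a <- (config$length_um / 2) / px             # semi-axes in pixels
  b <- (config$width_um / 2) / px
  reach <- 1 + config$outline_irregularity     # max outline multiple
  border <- max(ceiling(config$border_frac * config$length_um / px),
                ceiling(0.1 * a * reach * 2))
  ncol_need <- ceiling(2 * a * reach) + 2 * border
  nrow_need <- ceiling(2 * b * reach) + 2 * border
  if (is.null(config$grid_shape)) {
    nr <- nrow_need; nc <- ncol_need
  } else {
    nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
    if (nr < nrow_need || nc < ncol_need) {
      stop(sprintf(
        "grid %dx%d too small for geometry (needs at least %dx%d)",
        nr, nc, nrow_need, ncol_need))
    }
  }

  # Seeded harmonic outline deformation; exactly zero when amplitude is 0,
  # so the ideal shape is mirror-symmetric about both axes.
  if (config$outline_irregularity > 0) {
    harm <- with_seed(child_seed(config$seed, "geometry"), {
      k <- 2:5
      amp <- runif(length(k), 0.3, 1)
      phi <- runif(length(k), 0, 2 * pi)
      list(k = k, amp = amp, phi = phi)
    })
    s_fun <- function(theta) {
      s <- rowSums(sapply(seq_along(harm$k), function(i) {
        harm$amp[i] * cos(harm$k[i] * theta + harm$phi[i])
      }))
      s / sum(harm$amp)                         # |s| <= 1
    }
  } else {
    s_fun <- function(theta) rep(0, length(theta))
  }

  cx <- (nc - 1) / 2                            # 0-based center
  cy <- (nr - 1) / 2
  x <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  y <- matrix(rep(0:(nr - 1), nc), nr, nc)
  dx <- (x - cx) / a
  dy <- (y - cy) / b
  u <- sqrt(dx^2 + dy^2)                        # elliptical radius
  theta <- atan2(dy, dx)
  rmul <- 1 + config$outline_irregularity * matrix(s_fun(as.numeric(theta)),
                                                   nr, nc)
  un <- u / rmul                                # normalized radial coordinate

  th <- matrix(0, nr, nc)
  th[un <= 1] <- config$shield_thickness
  th[un < config$tube_frac] <- config$tube_thickness
  th[un < config$hole_frac] <- 0                # central opening

  if (config$central_structure_present) {
    inside_hole <- un < config$hole_frac
    if (config$species_template == "placolith_bar") {
      w <- 0.10                                 # strut half-width, ellipse units
      strut <- abs(dy) <= w
    } else {
      w <- 0.12
      strut <- (abs(dy - dx) <= w * sqrt(2)) | (abs(dy + dx) <= w * sqrt(2))
    }
    th[inside_hole & strut] <- config$tube_thickness
  }

  structure(th, class = c("thickness_map", class(th)),
            pixel_size_nm = config$pixel_size_nm, config = config)
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %d x %d px @ %g nm, %d coccolith px, max %g\n",
              nrow(x), ncol(x), attr(x, "pixel_size_nm"), sum(x > 0), max(x)))
  invisible(x)
}
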