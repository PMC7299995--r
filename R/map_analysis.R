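#' Multi-element concentration map stack for one specimen
#'
#' @param elements named list of equal-shape numeric matrices (ppm), keyed
#'   by element symbol; must include \code{Ca} for downstream analysis.
#' @param pixel_size_nm pixel size in nanometers.
#' @param species,experiment free-text labels (experiment conventionally
#'   C / M / H for control / medium / high metal enrichment).
#' @param excluded_from_regions flag a specimen (e.g. tilted on the support)
#'   whose tube/rim/margin regions cannot be identified; region segmentation
#'   refuses to run on it.
#' @return a \code{specimen_map}.
#' @export
specimen_map <- function(elements, pixel_size_nm = 50,
                         species = "unknown", experiment = "C",
                         excluded_from_regions = FALSE) {
  if (is.null(names(elements)) || any(names(elements) == "")) {
    stop("elements must be a named list keyed by element symbol")
  }
  dims <- vapply(elements, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all element grids must share the same shape")
  }
  if (any(vapply(elements, function(m) any(m < 0), TRUE))) {
    stop("concentrations must be nonnegative")
  }
  structure(list(elements = elements,
                 pixel_size_nm = pixel_size_nm,
                 species = species, experiment = experiment,
                 excluded_from_regions = excluded_from_regions),
            class = "specimen_map")
}

#' @export
print.specimen_map <- function(x, ...) {
  d <- dim(x$elements[[1]])
  cat(sprintf("<specimen_map> %s / %s: %d x %d px @ %g nm, elements: %s\n",
              x$species, x$experiment, d[1], d[2], x$pixel_size_nm,
              paste(names(x$elements), collapse = " ")))
  invisible(x)
}

#' Calcite mask from the Ca map
#'
#' Transects and all further calculations ignore pixels whose Ca
#' concentration falls below the threshold (membrane background and the very
#' end of the external rim, where ratios are unreliable). Default threshold
#' 0.2e5 ppm.
#'
#' @param ca_map Ca ppm matrix, or a \code{\link{specimen_map}}.
#' @param threshold_ppm mask threshold (default 2e4 ppm).
#' @return logical matrix; TRUE on calcite. Warns if empty.
#' @export
mask_calcite <- function(ca_map, threshold_ppm = 0.2e5) {
  if (inherits(ca_map, "specimen_map")) ca_map <- ca_map$elements$Ca
  if (is.null(ca_map)) stop("no Ca map available")
  if (any(ca_map < 0)) stop("Ca map must be nonnegative")
  m <- ca_map >= threshold_ppm
  if (!any(m)) warning("empty calcite mask: no pixel reaches the Ca threshold")
  m
}

#' Molar element/Ca ratio map
#'
#' Converts two ppm maps to a per-pixel molar ratio in mmol/mol:
#' \code{(ppm_i / A_i) / (ppm_Ca / A_Ca) * 1000}. Defined only on the
#' calcite mask; off-mask pixels are NA.
#'
#' @param i_map element ppm matrix.
#' @param ca_map Ca ppm matrix.
#' @param element element symbol (for atomic weight lookup), or supply
#'   \code{a_i} directly.
#' @param mask logical calcite mask.
#' @param a_i,a_ca atomic weights in g/mol (defaults looked up).
#' @return matrix of class \code{ratio_map} (mmol/mol), NA off mask.
#' @export
ratio_map <- function(i_map, ca_map, element = NULL, mask,
                      a_i = NULL, a_ca = atomic_weight("Ca")) {
  if (is.null(a_i)) {
    if (is.null(element)) stop("give either `element` or `a_i`")
    a_i <- atomic_weight(element)
  }
  stopifnot(all(dim(i_map) == dim(ca_map)), all(dim(mask) == dim(ca_map)))
  if (any(ca_map[mask] <= 0)) {
    stop("Ca must be positive inside the calcite mask")
  }
  r <- matrix(NA_real_, nrow(i_map), ncol(i_map))
  r[mask] <- (i_map[mask] / a_i) / (ca_map[mask] / a_ca) * 1000
  structure(r, class = c("ratio_map", class(r)), element = element)
}

#' Specimen-level summary statistics
#'
#' Per-element mean of per-pixel molar ratios over the calcite mask (the
#' tabulated i/Ca convention: mean of ratios, not ratio of means), mean Ca
#' over the mask, coccolith area and Ca per area.
#'
#' @param spec a \code{\link{specimen_map}}.
#' @param elements elements to summarize (default: all but Ca).
#' @param mask calcite mask (default \code{\link{mask_calcite}} at the
#'   standard threshold).
#' @return a \code{specimen_stats} list: \code{elements} data.frame
#'   (element, mean_ratio_mmol_per_mol, mean_ppm), \code{mean_ca_ppm},
#'   \code{area_um2}, \code{ca_per_area_ppm_um2}, \code{n_points}. With an
#'   empty mask all statistics are NA (empty-statistics sentinel).
#' @export
specimen_stats <- function(spec, elements = NULL, mask = NULL) {
  stopifnot(inherits(spec, "specimen_map"))
  if (is.null(mask)) mask <- mask_calcite(spec)
  if (is.null(elements)) elements <- setdiff(names(spec$elements), "Ca")
  px_um2 <- (spec$pixel_size_nm * 1e-3)^2
  n <- sum(mask)
  if (n == 0) {
    out <- list(elements = data.frame(element = elements,
                                      mean_ratio_mmol_per_mol = NA_real_,
                                      mean_ppm = NA_real_),
                mean_ca_ppm = NA_real_, area_um2 = 0,
                ca_per_area_ppm_um2 = NA_real_, n_points = 0L)
    class(out) <- "specimen_stats"
    return(out)
  }
  ca <- spec$elements$Ca
  rows <- lapply(elements, function(el) {
    r <- ratio_map(spec$elements[[el]], ca, element = el, mask = mask)
    data.frame(element = el,
               mean_ratio_mmol_per_mol = mean(r[mask]),
               mean_ppm = mean(spec$elements[[el]][mask]))
  })
  area <- n * px_um2
  mean_ca <- mean(ca[mask])
  out <- list(elements = do.call(rbind, rows),
              mean_ca_ppm = mean_ca,
              area_um2 = area,
              ca_per_area_ppm_um2 = mean_ca / area,
              n_points = n)
  class(out) <- "specimen_stats"
  out
}

#' @export
print.specimen_stats <- function(x, ...) {
  cat(sprintf("<specimen_stats> n = %d px, area = %.1f um^2, mean Ca = %.3g ppm\n",
              x$n_points, x$area_um2, x$mean_ca_ppm))
  print(x$elements, row.names = FALSE)
  invisible(x)
}

# Ca concentration band of a sample: background below the mask threshold,
# low between the mask threshold and the high threshold, high at or above it.
ca_band <- function(ca, low = 0.2e5, high = 1e5) {
  b <- ifelse(ca < low, "background", ifelse(ca < high, "low", "high"))
  factor(b, levels = c("background", "low", "high"))
}

#' Sample a transect across a specimen
#'
#' Samples every element map at one-pixel steps along a polyline
#' (nearest-pixel, no interpolation, consecutive duplicates collapsed),
#' labels each sample with its Ca concentration band and flags background
#' samples, which are excluded from any statistics derived from the
#' transect.
#'
#' @param spec a \code{\link{specimen_map}}.
#' @param polyline numeric matrix with columns x, y (0-based pixel
#'   coordinates) listing the polyline vertices.
#' @param ratio_elements elements for which an i/Ca ratio profile is also
#'   reported (default Sr if present).
#' @param band_low,band_high Ca band thresholds in ppm.
#' @return a \code{transect} data.frame: sample, x, y, ca_ppm, band,
#'   in_calcite, one ppm column per element and one ratio column per
#'   requested ratio element.
#' @export
extract_transect <- function(spec, polyline,
                             ratio_elements = intersect("Sr",
                                                        names(spec$elements)),
                             band_low = 0.2e5, band_high = 1e5) {
  stopifnot(inherits(spec, "specimen_map"))
  polyline <- as.matrix(polyline)
  d <- dim(spec$elements[[1]])
  if (any(polyline[, 1] < 0) || any(polyline[, 1] > d[2] - 1) ||
      any(polyline[, 2] < 0) || any(polyline[, 2] > d[1] - 1)) {
    stop("polyline outside the pixel grid")
  }
  pts <- NULL
  for (i in seq_len(nrow(polyline) - 1)) {
    p0 <- polyline[i, ]; p1 <- polyline[i + 1, ]
    len <- sqrt(sum((p1 - p0)^2))
    t <- seq(0, 1, length.out = max(2, ceiling(len) + 1))
    seg <- cbind(round(p0[1] + t * (p1[1] - p0[1])),
                 round(p0[2] + t * (p1[2] - p0[2])))
    pts <- rbind(pts, seg)
  }
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]

  idx <- cbind(pts[, 2] + 1, pts[, 1] + 1)      # row = y + 1, col = x + 1
  ca <- spec$elements$Ca[idx]
  band <- ca_band(ca, band_low, band_high)
  if (all(band == "background")) {
    stop("transect lies entirely in the background")
  }
  out <- data.frame(sample = seq_len(nrow(pts)) - 1L,
                    x = pts[, 1], y = pts[, 2],
                    ca_ppm = ca, band = band,
                    in_calcite = band != "background")
  for (el in setdiff(names(spec$elements), "Ca")) {
    out[[paste0(el, "_ppm")]] <- spec$elements[[el]][idx]
  }
  for (el in ratio_elements) {
    v <- (out[[paste0(el, "_ppm")]] / atomic_weight(el)) /
      (ca / atomic_weight("Ca")) * 1000
    v[!out$in_calcite] <- NA_real_
    out[[paste0(el, "_ca_mmol_mol")]] <- v
  }
  class(out) <- c("transect", class(out))
  out
}

#' Segment the calcite mask into tube, external rim and margin
#'
#' The margin is the outermost band of the mask (within \code{d_margin}
#' pixels of the outline by Euclidean distance transform, central opening
#' filled so only the outer outline counts); the tube is the high-Ca core
#' (masked pixels at or above the \code{q_tube} quantile of the masked Ca
#' distribution, quantile ties included in the tube); the external rim is
#' everything in between. A partition in which any region has fewer than
#' \code{min_pixels} data points is rejected.
#'
#' @param spec a \code{\link{specimen_map}}.
#' @param mask calcite mask (default standard threshold).
#' @param d_margin margin band width in pixels.
#' @param q_tube Ca quantile defining the tube.
#' @param min_pixels minimum data points per region (default 30).
#' @return a \code{region_partition}: \code{labels} character matrix with
#'   values background/margin/external_rim/tube, and \code{counts}.
#' @export
segment_regions <- function(spec, mask = NULL, d_margin = 4, q_tube = 0.80,
                            min_pixels = 30) {
  stopifnot(inherits(spec, "specimen_map"))
  if (isTRUE(spec$excluded_from_regions)) {
    stop("specimen flagged as excluded from region analysis (e.g. tilted)")
  }
  if (is.null(mask)) mask <- mask_calcite(spec)
  if (!any(mask)) stop("cannot segment an empty mask")
  ca <- spec$elements$Ca
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  dist <- EBImage::distmap(filled)@.Data
  margin <- mask & dist <= d_margin
  qv <- quantile(ca[mask], q_tube, names = FALSE)
  tube <- mask & !margin & ca >= qv
  rim <- mask & !margin & !tube
  counts <- c(tube = sum(tube), external_rim = sum(rim),
              margin = sum(margin))
  if (any(counts < min_pixels)) {
    stop(sprintf(
      "partition rejected: region(s) below %d data points (%s)",
      min_pixels,
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  }
  lab <- matrix("background", nrow(ca), ncol(ca))
  lab[margin] <- "margin"
  lab[rim] <- "external_rim"
  lab[tube] <- "tube"
  structure(list(labels = lab, counts = counts,
                 d_margin = d_margin, q_tube = q_tube),
            class = "region_partition")
}

#' Mean molar ratios per morphological region
#'
#' @param spec a \code{\link{specimen_map}}.
#' @param partition a \code{\link{segment_regions}} result.
#' @param element element for the ratio (default Sr).
#' @return data.frame: region, n, mean_ratio_mmol_per_mol, mean_ca_ppm.
#' @export
region_means <- function(spec, partition, element = "Sr") {
  stopifnot(inherits(partition, "region_partition"))
  ca <- spec$elements$Ca
  el <- spec$elements[[element]]
  if (is.null(el)) stop("no map for element ", element)
  regions <- c("tube", "external_rim", "margin")
  do.call(rbind, lapply(regions, function(rg) {
    sel <- partition$labels == rg
    r <- (el[sel] / atomic_weight(element)) /
      (ca[sel] / atomic_weight("Ca")) * 1000
    data.frame(region = rg, n = sum(sel),
               mean_ratio_mmol_per_mol = mean(r),
               mean_ca_ppm = mean(ca[sel]))
  }))
}

#' Masked Pearson correlation between two maps
#'
#' @param map_a,map_b numeric matrices of equal shape.
#' @param mask logical mask with at least 3 TRUE pixels.
#' @return Pearson r over the masked pixels; \code{NA} (with attribute
#'   \code{reason}) when either map has zero variance on the mask.
#' @export
correlate_maps <- function(map_a, map_b, mask) {
  stopifnot(all(dim(map_a) == dim(map_b)), all(dim(mask) == dim(map_a)))
  if (sum(mask) < 3) stop("mask must contain at least 3 pixels")
  a <- map_a[mask]; b <- map_b[mask]
  if (sd(a) == 0 || sd(b) == 0) {
    return(structure(NA_real_, reason = "zero variance on mask"))
  }
  cor(a, b)
}
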