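#' Thresholds for element localization classification
#'
#' Numeric boundaries formalizing the map-evidence reading: an element
#' co-distributed with Ca (r at or above \code{lattice}) is read as
#' lattice-incorporated; an element uncorrelated with Ca (r below
#' \code{surface}) but following the Cl-like organic coat (r with Cl at or
#' above \code{coat}) is surface-deposited; an element whose mass
#' concentrates in its top 1\% brightest pixels (fraction at or above
#' \code{spot}) is a localized contaminant; an element with no on- vs
#' off-coccolith enrichment (on/off mean contrast at or below
#' \code{contrast}) did not interact with the coccolith. All boundaries are
#' configuration, not constants: the underlying evidence is continuous and
#' any hard rule is a choice.
#'
#' @param lattice minimum r(element, Ca) for a lattice verdict (default 0.6,
#'   below the ~0.98 seen for Sr but safely above coat correlations; a
#'   Se-like r of ~0.7 classifies as lattice).
#' @param surface maximum r(element, Ca) for a surface verdict (default 0.3).
#' @param coat minimum r(element, Cl) supporting a surface verdict
#'   (default 0.3).
#' @param spot minimum top-1\%-mass fraction for a hotspot verdict
#'   (default 0.25).
#' @param contrast maximum on/off-coccolith mean ratio for an
#'   absent-from-coccolith verdict (default 1.5).
#' @return a validated \code{classify_thresholds} list
#'   (\code{surface < lattice} enforced).
#' @export
classify_thresholds <- function(lattice = 0.6, surface = 0.3, coat = 0.3,
                                spot = 0.25, contrast = 1.5) {
  if (!(surface < lattice)) {
    stop("invalid thresholds: surface must be < lattice")
  }
  if (spot <= 0 || spot > 1) stop("spot threshold must be in (0, 1]")
  structure(list(lattice = lattice, surface = surface, coat = coat,
                 spot = spot, contrast = contrast),
            class = "classify_thresholds")
}

# Share of an element's total mass carried by its top 1% brightest pixels.
hotspot_fraction <- function(map) {
  tot <- sum(map)
  if (tot <= 0) return(0)
  n_top <- max(1L, ceiling(0.01 * length(map)))
  v <- sort(as.numeric(map), decreasing = TRUE)
  sum(v[seq_len(n_top)]) / tot
}

#' Classify one element as lattice, surface, hotspot or absent
#'
#' Applies the decision rule to the map evidence: (1) an undetected element
#' (excluded by the fit, or identically zero on the mask) is absent; (2) a
#' top-1\%-mass fraction at or above the spot threshold is a hotspot; (3) a
#' Ca correlation at or above the lattice threshold is lattice; (4) a low Ca
#' correlation with a Cl-like distribution is surface (when no Cl map is
#' available this test degrades to the low-Ca-correlation evidence alone and
#' is flagged); (5) a flat element with no on/off-coccolith enrichment is
#' absent (no interaction); (6) otherwise the larger of the two correlations
#' decides, flagged low-confidence.
#'
#' @param spec a \code{\link{specimen_map}}.
#' @param element element symbol to classify.
#' @param mask calcite mask (default standard threshold).
#' @param thresholds a \code{\link{classify_thresholds}}.
#' @param detected FALSE when the element failed the spectrum-fit inclusion
#'   rule (forces an absent verdict).
#' @return one-row data.frame: element, verdict, r_with_ca, r_with_cl,
#'   hotspot_fraction, on_off_contrast, flags.
#' @export
classify_element <- function(spec, element, mask = NULL,
                             thresholds = classify_thresholds(),
                             detected = TRUE) {
  stopifnot(inherits(spec, "specimen_map"),
            inherits(thresholds, "classify_thresholds"))
  if (is.null(mask)) mask <- mask_calcite(spec)
  m <- spec$elements[[element]]
  if (is.null(m)) stop("no map for element ", element)
  flags <- character(0)
  if (element == "As") {
    flags <- c(flags, "possible Pb L-line contribution")
  }
  row <- function(verdict, r_ca = NA_real_, r_cl = NA_real_,
                  hf = NA_real_, contrast = NA_real_) {
    data.frame(element = element, verdict = verdict,
               r_with_ca = r_ca, r_with_cl = r_cl,
               hotspot_fraction = hf, on_off_contrast = contrast,
               flags = paste(flags, collapse = "; "),
               stringsAsFactors = FALSE)
  }

  if (!detected) return(row("absent"))
  if (all(m[mask] == 0)) {
    warning("element ", element, " is zero everywhere on the mask")
    return(row("absent"))
  }

  r_ca <- as.numeric(correlate_maps(m, spec$elements$Ca, mask))
  cl <- spec$elements$Cl
  if (is.null(cl) || element == "Cl") {
    r_cl <- NA_real_
    if (is.null(cl)) flags <- c(flags, "no Cl map: surface test degraded")
  } else {
    r_cl <- as.numeric(correlate_maps(m, cl, mask))
  }
  hf <- hotspot_fraction(m)
  off <- !mask
  contrast <- if (any(off) && mean(m[off]) > 0) {
    mean(m[mask]) / mean(m[off])
  } else Inf

  if (hf >= thresholds$spot) {
    return(row("hotspot", r_ca, r_cl, hf, contrast))
  }
  if (!is.na(r_ca) && r_ca >= thresholds$lattice) {
    return(row("lattice", r_ca, r_cl, hf, contrast))
  }
  if (element == "Cl") {
    # Cl is the coat reference itself: a low Ca correlation is surface
    if (!is.na(r_ca) && r_ca < thresholds$surface) {
      return(row("surface", r_ca, r_cl, hf, contrast))
    }
  }
  if (!is.na(r_ca) && r_ca < thresholds$surface &&
      (is.na(r_cl) || r_cl >= thresholds$coat)) {
    if (is.na(r_cl)) flags <- c(flags, "surface verdict without Cl support")
    return(row("surface", r_ca, r_cl, hf, contrast))
  }
  if (is.finite(contrast) && contrast <= thresholds$contrast &&
      !is.na(r_ca) && r_ca < thresholds$lattice) {
    # flat everywhere, no enrichment on the coccolith: no interaction
    return(row("absent", r_ca, r_cl, hf, contrast))
  }
  flags <- c(flags, "low confidence: correlations between thresholds")
  verdict <- if (!is.na(r_cl) && r_cl > r_ca) "surface" else "lattice"
  row(verdict, r_ca, r_cl, hf, contrast)
}

#' Classify every element of a specimen
#'
#' @param spec a \code{\link{specimen_map}}.
#' @param mask calcite mask.
#' @param thresholds a \code{\link{classify_thresholds}}.
#' @param detected named logical vector of fit-inclusion flags (elements
#'   missing from it count as detected).
#' @param elements elements to classify (default all but Ca).
#' @return data.frame of class \code{classification_result}, one row per
#'   element.
#' @export
classify_specimen <- function(spec, mask = NULL,
                              thresholds = classify_thresholds(),
                              detected = NULL, elements = NULL) {
  stopifnot(inherits(spec, "specimen_map"))
  if (is.null(mask)) mask <- mask_calcite(spec)
  if (is.null(elements)) elements <- setdiff(names(spec$elements), "Ca")
  out <- do.call(rbind, lapply(elements, function(el) {
    det <- if (!is.null(detected) && el %in% names(detected)) {
      isTRUE(detected[[el]])
    } else TRUE
    suppressWarnings(classify_element(spec, el, mask, thresholds,
                                      detected = det))
  }))
  class(out) <- c("classification_result", class(out))
  out
}

#' Surface vs lattice contrast: the on/off-coccolith enrichment test
#'
#' Convenience accessor mirroring the "did not interact with the coccolith"
#' reading: TRUE when the element's on-mask mean is no more than
#' \code{contrast} times its off-mask mean.
#'
#' @param spec a \code{\link{specimen_map}}.
#' @param element element symbol.
#' @param mask calcite mask.
#' @param contrast threshold (default 1.5).
#' @return logical.
#' @export
no_interaction <- function(spec, element, mask = NULL, contrast = 1.5) {
  if (is.null(mask)) mask <- mask_calcite(spec)
  m <- spec$elements[[element]]
  off <- !mask
  if (!any(off) || mean(m[off]) == 0) return(FALSE)
  mean(m[mask]) / mean(m[off]) <= contrast
}
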