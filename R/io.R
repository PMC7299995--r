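#' Write a specimen map stack to a multi-page TIFF
#'
#' One 32-bit float page per element (page order = element order), samples
#' stored as mass fractions (ppm / 1e6, always in [0, 1]). Page names,
#' pixel size and specimen labels go to a JSON sidecar next to the TIFF
#' (\code{<stem>.json}); this TIFF flavor carries no custom tags.
#'
#' @param spec a \code{\link{specimen_map}}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_maps <- function(spec, path) {
  stopifnot(inherits(spec, "specimen_map"))
  pages <- lapply(spec$elements, function(m) unclass(m) / 1e6)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(elements = names(spec$elements),
               pixel_size_nm = spec$pixel_size_nm,
               species = spec$species,
               experiment = spec$experiment,
               excluded_from_regions = spec$excluded_from_regions,
               units = "mass fraction (ppm / 1e6)")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Read a specimen map stack from a multi-page TIFF
#'
#' Reads the pages written by \code{\link{write_maps}} (32-bit float mass
#' fractions plus JSON sidecar). Legacy integer TIFFs (8/16-bit) are
#' promoted losslessly to double on read; all flavors are interpreted as
#' mass fractions and converted to ppm. Without a sidecar, page names must
#' be supplied and must include Ca.
#'
#' @param path TIFF path.
#' @param elements page names, overriding (or replacing) the sidecar.
#' @param pixel_size_nm pixel size if no sidecar is present.
#' @return a \code{\link{specimen_map}}.
#' @export
read_maps <- function(path, elements = NULL, pixel_size_nm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(elements)) elements <- meta$elements
  if (is.null(elements)) stop("no element page names (no sidecar, none given)")
  if (length(elements) != length(pages)) {
    stop(sprintf("page count (%d) does not match element names (%d)",
                 length(pages), length(elements)))
  }
  if (!("Ca" %in% elements)) {
    stop("map stack must contain a Ca page (Ca is the reference element)")
  }
  shp <- vapply(pages, dim, integer(2))
  if (any(shp != shp[, 1])) stop("TIFF pages differ in shape")
  maps <- lapply(pages, function(p) {
    p <- p[, , drop = TRUE]
    storage.mode(p) <- "double"
    p * 1e6
  })
  names(maps) <- elements
  specimen_map(maps,
               pixel_size_nm = pixel_size_nm %||% meta$pixel_size_nm %||% 50,
               species = meta$species %||% "unknown",
               experiment = meta$experiment %||% "C",
               excluded_from_regions = isTRUE(meta$excluded_from_regions))
}

#' Write / read a spectrum cube
#'
#' The cube container is R serialization of a plain list with a fixed
#' layout: \code{counts} and \code{expected} (nrow x ncol x nbins arrays),
#' \code{energy_bins} (edges, keV), \code{inst}, \code{elements}.
#'
#' @param cube a \code{spectrum_cube}.
#' @param path output path (conventionally \code{.rds}).
#' @return \code{path} invisibly / the cube.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectrum_cube"))
  saveRDS(unclass(cube), path)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  x <- readRDS(path)
  class(x) <- "spectrum_cube"
  x
}

#' Assemble and validate a pipeline configuration
#'
#' @param x a list, or a path to a JSON document, with any of: \code{seed},
#'   \code{simulate} (condition, pixel_size_nm, render, poisson),
#'   \code{maps} (path to a TIFF stack), \code{spectra} (path to a cube),
#'   \code{candidates} (elements for the fit stage), \code{z_threshold},
#'   \code{mask_threshold_ppm}, \code{band_high_ppm}, \code{d_margin},
#'   \code{q_tube}, \code{min_region_pixels}, \code{thresholds} (classify),
#'   \code{solution} (path or ratio table), \code{transects} (list of
#'   "x1,y1:x2,y2" strings), \code{ratio_element}.
#' @return validated \code{pipeline_config} list with defaults filled in.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = TRUE)
  defaults <- list(seed = 1L, simulate = NULL, maps = NULL, spectra = NULL,
                   candidates = NULL, z_threshold = 3,
                   mask_threshold_ppm = 0.2e5, band_high_ppm = 1e5,
                   d_margin = 4, q_tube = 0.80, min_region_pixels = 30,
                   thresholds = list(), solution = NULL,
                   transects = list(), ratio_element = "Sr")
  cfg <- modifyList(defaults, x)
  if (cfg$mask_threshold_ppm <= 0) stop("mask_threshold_ppm must be > 0")
  cfg$thresholds <- do.call(classify_thresholds, cfg$thresholds)
  for (f in c("maps", "spectra")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop(sprintf("configured %s file does not exist: %s", f, cfg[[f]]))
    }
  }
  if (is.null(cfg$simulate) && is.null(cfg$maps) && is.null(cfg$spectra)) {
    stop("config must provide one of: simulate, maps, spectra")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

# Canonical md5 hash of a config (names sorted recursively, JSON-encoded).
config_hash <- function(cfg) {
  canon <- function(x) {
    if (inherits(x, "classify_thresholds")) x <- unclass(x)
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  j <- jsonlite::toJSON(canon(unclass(cfg)), auto_unbox = TRUE, digits = NA,
                        null = "null")
  tf <- tempfile()
  writeLines(as.character(j), tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  h
}

parse_transect_spec <- function(s) {
  pts <- strsplit(strsplit(s, ":")[[1]], ",")
  m <- do.call(rbind, lapply(pts, function(p) as.numeric(p)))
  colnames(m) <- c("x", "y")
  m
}

write_table <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash=", hash), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order: simulate (optional), fit
#' (optional, when spectra are given), analyze (mask, statistics, regions,
#' transects, correlations), partition, classify. All tabular outputs are
#' CSVs stamped with the config hash; a run log records the hash, seed and
#' stage timings. Deterministic and idempotent for a given config and seed.
#'
#' @param config a \code{\link{pipeline_config}} (or list / JSON path).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the specimen, stats, partition table,
#'   classification and file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_lines <- c(sprintf("config_hash=%s", hash),
                 sprintf("seed=%d", config$seed))
  tick <- function(stage, t0) {
    sprintf("stage=%s elapsed=%.2fs", stage,
            as.numeric(proc.time()[3] - t0))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log_lines <<- c(log_lines, tick(name, t0))
    r
  }

  detected <- NULL
  spec <- NULL
  if (!is.null(config$simulate)) {
    spec <- stage("simulate", {
      sim <- config$simulate
      tpl <- specimen_template(sim$condition %||% "control",
                               pixel_size_nm = sim$pixel_size_nm %||% 50)
      simulate_specimen(tpl, seed = config$seed,
                        render = isTRUE(sim$render),
                        poisson = !isFALSE(sim$poisson))$specimen
    })
  } else if (!is.null(config$spectra)) {
    fitres <- stage("fit", {
      cube <- read_cube(config$spectra)
      cands <- config$candidates %||%
        unique(read_line_library()$element)
      fit_specimen(cube, cands, z_threshold = config$z_threshold)
    })
    spec <- stage("quantify", {
      cube <- read_cube(config$spectra)
      lib <- read_line_library()
      std <- simulate_standard(inst = cube$inst, library = lib,
                               seed = config$seed)
      cal <- calibrate(std, line_sensitivities(lib), cube$inst$dwell_s)
      quantify(fitres$amplitude_maps, cal, line_sensitivities(lib),
               cube$inst$dwell_s)
    })
    detected <- setNames(rep(TRUE, length(fitres$included)), fitres$included)
    for (el in fitres$excluded) detected[el] <- FALSE
    log_lines <- c(log_lines,
                   sprintf("included=%s", paste(fitres$included, collapse = ",")),
                   sprintf("excluded=%s", paste(fitres$excluded, collapse = ",")))
  } else {
    spec <- stage("read_maps", read_maps(config$maps))
  }

  res <- stage("analyze", {
    mask <- mask_calcite(spec, config$mask_threshold_ppm)
    stats <- specimen_stats(spec, mask = mask)
    part <- tryCatch(
      segment_regions(spec, mask, d_margin = config$d_margin,
                      q_tube = config$q_tube,
                      min_pixels = config$min_region_pixels),
      error = function(e) e)
    cors <- sapply(setdiff(names(spec$elements), "Ca"), function(el) {
      as.numeric(correlate_maps(spec$elements[[el]], spec$elements$Ca, mask))
    })
    list(mask = mask, stats = stats, partition = part, correlations = cors)
  })

  sol <- if (is.null(config$solution)) default_solution() else
    solution_composition(config$solution)
  ptab <- stage("partition", partition_table(res$stats, sol))
  cls <- stage("classify", classify_specimen(spec, res$mask,
                                             config$thresholds,
                                             detected = detected))

  paths <- list(stats = file.path(out_dir, "stats.csv"),
                classification = file.path(out_dir, "classification.csv"),
                correlations = file.path(out_dir, "correlations.csv"),
                log = file.path(out_dir, "run_log.txt"))
  stats_df <- cbind(ptab,
                    mean_ca_ppm = res$stats$mean_ca_ppm,
                    area_um2 = res$stats$area_um2,
                    n_points = res$stats$n_points)
  write_table(stats_df, paths$stats, hash)
  write_table(as.data.frame(cls), paths$classification, hash)
  write_table(data.frame(element = names(res$correlations),
                         r_with_ca = as.numeric(res$correlations)),
              paths$correlations, hash)

  if (!inherits(res$partition, "error")) {
    rm_df <- region_means(spec, res$partition,
                          element = config$ratio_element)
    paths$region_means <- file.path(out_dir, "region_means.csv")
    write_table(rm_df, paths$region_means, hash)
  } else {
    log_lines <- c(log_lines,
                   paste0("region_partition_rejected: ",
                          conditionMessage(res$partition)))
  }

  if (length(config$transects)) {
    tr <- do.call(rbind, lapply(seq_along(config$transects), function(i) {
      t <- extract_transect(spec, parse_transect_spec(config$transects[[i]]),
                            band_low = config$mask_threshold_ppm,
                            band_high = config$band_high_ppm)
      cbind(transect = i, as.data.frame(t))
    }))
    paths$transects <- file.path(out_dir, "transects.csv")
    write_table(tr, paths$transects, hash)
  }

  writeLines(log_lines, paths$log)
  invisible(list(specimen = spec, stats = res$stats, partition = ptab,
                 classification = cls, mask = res$mask, paths = paths,
                 config_hash = hash))
}
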