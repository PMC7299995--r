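#' Culture-solution composition
#'
#' Represents the growth medium composition as molar element/Ca ratios
#' (mmol/mol), the form the partition coefficient needs. Accepts either a
#' table of ratios to Ca or a table of absolute molarities (converted using
#' the Ca molarity, which must then be present).
#'
#' @param x data.frame with columns \code{element} and either
#'   \code{ratio_to_ca_mmol_per_mol} or \code{molarity_mol_per_l}; or a CSV
#'   path to such a table; or a named numeric vector of ratios (mmol/mol).
#' @return a \code{solution_composition}: named vector of i/Ca molar ratios
#'   in mmol/mol.
#' @export
solution_composition <- function(x) {
  if (is.character(x)) x <- read.csv(x, comment.char = "#")
  if (is.numeric(x) && !is.null(names(x))) {
    ratios <- x
  } else if (is.data.frame(x)) {
    if ("ratio_to_ca_mmol_per_mol" %in% names(x)) {
      ratios <- setNames(x$ratio_to_ca_mmol_per_mol, x$element)
    } else if ("molarity_mol_per_l" %in% names(x)) {
      m <- setNames(x$molarity_mol_per_l, x$element)
      if (!("Ca" %in% names(m)) || m[["Ca"]] <= 0) {
        stop("molarity table must include Ca > 0")
      }
      if (any(m < 0)) stop("molarities must be nonnegative")
      ratios <- m[setdiff(names(m), "Ca")] / m[["Ca"]] * 1000
    } else {
      stop("solution table needs ratio_to_ca_mmol_per_mol or molarity_mol_per_l")
    }
  } else {
    stop("unsupported solution composition input")
  }
  if (any(ratios < 0)) stop("solution ratios must be nonnegative")
  structure(ratios, class = "solution_composition")
}

#' Default reconstructed culture-solution composition
#'
#' Ships Sr/Ca = 8.81 mmol/mol and Se/Ca = 0.98 mmol/mol, back-computed from
#' published calcite-ratio / partition-coefficient pairs (Sr/Ca 3.7 with
#' D_Sr 0.42; Se/Ca 0.047 with D_Se 0.048). These are reconstructed
#' defaults, not a measured medium; override with your own table via
#' \code{\link{solution_composition}}.
#'
#' @return a \code{solution_composition}.
#' @export
default_solution <- function() {
  solution_composition(system.file("extdata", "solution_default.csv",
                                   package = "coccoxrf"))
}

#' Partition coefficient between coccolith calcite and culture solution
#'
#' \code{D_x = (x/Ca)_calcite / (x/Ca)_solution}, a ratio of molar ratios,
#' dimensionless and invariant to the common unit (mmol/mol or mol/mol) as
#' long as both ratios use the same one.
#'
#' @param calcite_ratio_mmol_per_mol element/Ca molar ratio in the calcite.
#' @param solution a \code{\link{solution_composition}} (i/Ca ratios in
#'   mmol/mol).
#' @param element element symbol.
#' @return D (numeric scalar) with a \code{provenance} attribute recording
#'   the two ratios used.
#' @export
#' @examples
#' partition_coefficient(3.7, default_solution(), "Sr")  # ~0.42
partition_coefficient <- function(calcite_ratio_mmol_per_mol, solution,
                                  element) {
  stopifnot(inherits(solution, "solution_composition"))
  if (!(element %in% names(solution))) {
    stop("element absent from solution table: ", element)
  }
  sol <- unclass(solution)[[element]]
  if (sol <= 0) stop("solution ratio for ", element, " must be positive")
  if (calcite_ratio_mmol_per_mol < 0) stop("calcite ratio must be >= 0")
  d <- calcite_ratio_mmol_per_mol / sol
  attr(d, "provenance") <- c(calcite_ratio_mmol_per_mol =
                               calcite_ratio_mmol_per_mol,
                             solution_ratio_mmol_per_mol = sol)
  d
}

#' Partition coefficients for a whole specimen summary
#'
#' Appends a D column to the per-element statistics of
#' \code{\link{specimen_stats}} for every element present in the solution
#' table (others get NA).
#'
#' @param stats a \code{specimen_stats}.
#' @param solution a \code{\link{solution_composition}}.
#' @return the \code{elements} data.frame with an extra \code{D} column.
#' @export
partition_table <- function(stats, solution = default_solution()) {
  stopifnot(inherits(stats, "specimen_stats"))
  df <- stats$elements
  df$D <- vapply(seq_len(nrow(df)), function(i) {
    el <- df$element[i]
    if (el %in% names(solution) && is.finite(df$mean_ratio_mmol_per_mol[i])) {
      as.numeric(partition_coefficient(df$mean_ratio_mmol_per_mol[i],
                                       solution, el))
    } else NA_real_
  }, numeric(1))
  df
}
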