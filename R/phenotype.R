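#' Score neurite outgrowth of a cell
#'
#' A cell counts as differentiated when it extends a neurite strictly
#' longer than `threshold_ratio` times its soma diameter (the conventional
#' ">1.5 x soma" rule for PC12 differentiation). Vectorised over cells.
#'
#' @param neurite_length Longest neurite length per cell, um (>= 0).
#' @param soma_diameter Soma diameter per cell, um (> 0).
#' @param threshold_ratio Dimensionless threshold; default 1.5. The
#'   comparison is strict (`>`), following the rule's wording.
#' @return Logical vector: `TRUE` where the cell scores as differentiated.
#' @examples
#' score_neurite(c(16, 15, 0), soma_diameter = 10)  # TRUE FALSE FALSE
#' @export
score_neurite <- function(neurite_length, soma_diameter,
                          threshold_ratio = 1.5) {
  stopifnot(is.numeric(neurite_length), is.numeric(soma_diameter),
            is.numeric(threshold_ratio), threshold_ratio > 0)
  if (any(soma_diameter <= 0)) {
    stop("soma diameter must be strictly positive", call. = FALSE)
  }
  if (any(neurite_length < 0)) {
    stop("neurite length must be non-negative", call. = FALSE)
  }
  neurite_length > threshold_ratio * soma_diameter
}

#' Percentage of differentiated cells
#'
#' Applies [score_neurite()] to each GFP-positive (i.e. transfected) cell
#' and reports the percentage scored positive. Untransfected cells are
#' excluded from numerator and denominator alike. Scoring fewer than
#' `min_cells` transfected cells is flagged with a warning since published
#' counts use at least 100 per condition.
#'
#' @param records A data.frame with numeric columns `neurite_length` and
#'   `soma_diameter` (um) and logical column `gfp_positive`.
#' @param threshold_ratio Passed to [score_neurite()].
#' @param min_cells Minimum transfected-cell count before warning.
#'   Default 100.
#' @return Percentage in \[0, 100\].
#' @export
differentiation_percent <- function(records, threshold_ratio = 1.5,
                                    min_cells = 100) {
  req <- c("neurite_length", "soma_diameter", "gfp_positive")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop("`records` needs columns neurite_length, soma_diameter, gfp_positive",
         call. = FALSE)
  }
  gfp <- records[records$gfp_positive, , drop = FALSE]
  if (!nrow(gfp)) {
    stop("no GFP-positive cells: percentage undefined", call. = FALSE)
  }
  if (nrow(gfp) < min_cells) {
    warning(sprintf("only %d GFP-positive cells scored (< %d)",
                    nrow(gfp), min_cells), call. = FALSE)
  }
  100 * mean(score_neurite(gfp$neurite_length, gfp$soma_diameter,
                           threshold_ratio))
}

#' Count spheres above a size threshold
#'
#' Tumorsphere/mammosphere assays count only spheres at or above a minimum
#' size; the conventional cutoff is 50 um and is inclusive ("at least").
#'
#' @param sphere_sizes Numeric vector of sphere sizes (um) in one well.
#' @param min_size Inclusive size threshold in um. Default 50.
#' @return Integer count.
#' @examples
#' count_spheres(c(40, 50, 60))  # 2
#' @export
count_spheres <- function(sphere_sizes, min_size = 50) {
  stopifnot(is.numeric(min_size), length(min_size) == 1L)
  if (!length(sphere_sizes)) return(0L)
  stopifnot(is.numeric(sphere_sizes))
  if (any(sphere_sizes < 0)) {
    stop("sphere sizes must be non-negative", call. = FALSE)
  }
  sum(sphere_sizes >= min_size)
}

#' Normalise a count to a vehicle control
#'
#' Expresses a treated-well count as a percentage of the matched
#' vehicle-treated (or empty-vector / scrambled-siRNA) control count. May
#' exceed 100% when the treatment increases the readout.
#'
#' @param treated_count Count in the treated condition (>= 0).
#' @param control_count Count in the control condition (> 0).
#' @return Percentage (>= 0).
#' @examples
#' normalize_to_control(30, 60)  # 50
#' @export
normalize_to_control <- function(treated_count, control_count) {
  stopifnot(is.numeric(treated_count), is.numeric(control_count))
  if (any(control_count <= 0)) {
    stop("control count must be strictly positive", call. = FALSE)
  }
  if (any(treated_count < 0)) {
    stop("treated count must be non-negative", call. = FALSE)
  }
  100 * treated_count / control_count
}

#' Densitometry ratios for an immunoblot band
#'
#' The two ratio conventions used to report Western-blot quantification:
#' the band intensity normalised to the beta-actin loading control, and the
#' phosphorylated-to-total ratio for phospho-epitopes. Vectorised over
#' bands.
#'
#' @param band_intensity Band intensity, arbitrary units (>= 0).
#' @param loading_intensity Loading-control (beta-actin) intensity (> 0).
#' @param phospho_intensity,total_intensity Optional phospho-blot pair;
#'   both or neither. `total_intensity` must be > 0 when given.
#' @return A data.frame with column `normalized_level` and, when the
#'   phospho pair is supplied, `phospho_ratio`.
#' @examples
#' densitometry_ratios(2.0, 1.0)  # normalized_level 2
#' @export
densitometry_ratios <- function(band_intensity, loading_intensity,
                                phospho_intensity = NULL,
                                total_intensity = NULL) {
  stopifnot(is.numeric(band_intensity), is.numeric(loading_intensity))
  if (any(loading_intensity <= 0)) {
    stop("loading-control intensity must be strictly positive", call. = FALSE)
  }
  if (any(band_intensity < 0)) {
    stop("band intensity must be non-negative", call. = FALSE)
  }
  out <- data.frame(normalized_level = band_intensity / loading_intensity)
  if (xor(is.null(phospho_intensity), is.null(total_intensity))) {
    stop("supply both phospho_intensity and total_intensity, or neither",
         call. = FALSE)
  }
  if (!is.null(phospho_intensity)) {
    stopifnot(is.numeric(phospho_intensity), is.numeric(total_intensity))
    if (any(total_intensity <= 0)) {
      stop("total-protein intensity must be strictly positive", call. = FALSE)
    }
    if (any(phospho_intensity < 0)) {
      stop("phospho intensity must be non-negative", call. = FALSE)
    }
    out$phospho_ratio <- phospho_intensity / total_intensity
  }
  out
}
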