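#' Specification of a synthetic phase-contrast field
#'
#' Describes a textured-cell-on-smooth-background image: cells are discs
#' filled with high-contrast speckle (high local entropy), the background is a
#' constant level plus Gaussian noise (low entropy). Intended as ground-truth
#' input for the confluence pipeline.
#'
#' @param height,width frame size in pixels (>= 64).
#' @param confluence_target percent of frame area covered by cells, in
#'   `[0, 100]`; the generator hits it to within +/- 1 percentage point.
#' @param cell_radius_range numeric length-2, min/max cell disc radius (px).
#' @param texture_contrast peak-to-peak amplitude of the bimodal speckle
#'   inside cells (0-255 intensity units).
#' @param background_level constant background intensity (0-255 units).
#' @param noise_sd sd of additive Gaussian pixel noise (intensity units, >= 0).
#' @param seed integer seed; the same spec always regenerates bit-identically.
#' @return an object of class `phase_field_spec`.
#' @export
phase_field_spec <- function(height = 384, width = 384, confluence_target = 50,
                             cell_radius_range = c(10, 22),
                             texture_contrast = 120, background_level = 40,
                             noise_sd = 2, seed = 1) {
  if (height < 64 || width < 64) stop_input("height and width must be >= 64")
  if (confluence_target < 0 || confluence_target > 100)
    stop_input("`confluence_target` must be in [0, 100]")
  if (length(cell_radius_range) != 2L || any(cell_radius_range < 1) ||
      cell_radius_range[1] > cell_radius_range[2])
    stop_input("`cell_radius_range` must be c(min, max) with 1 <= min <= max")
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 confluence_target = confluence_target,
                 cell_radius_range = cell_radius_range,
                 texture_contrast = texture_contrast,
                 background_level = background_level,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phase_field_spec")
}

#' Specification of a synthetic two-channel fluorescence field
#'
#' Non-overlapping disc nuclei textured in the 405 (nuclear stain) channel; a
#' specified fraction of them carries a supra-threshold mean intensity in the
#' 488 (marker) channel, the rest a sub-threshold one. The positivity cutoff
#' the proliferation pipeline applies is mean 488 intensity strictly greater
#' than 10 on the 0-255 scale, so `positive_488_mean` must exceed 10 and
#' `negative_488_mean` must not.
#'
#' @param height,width frame size in pixels.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_range numeric length-2, min/max nucleus radius (px).
#' @param positive_fraction fraction of nuclei that are marker-positive, in
#'   `[0, 1]`; the positive count is `positive_fraction * n_nuclei` rounded
#'   half away from zero.
#' @param positive_488_mean,negative_488_mean target mean 488 intensity of
#'   positive (> 10) and negative (<= 10) nuclei.
#' @param nucleus_405_mean central 405 intensity of nuclei.
#' @param noise_sd sd of additive Gaussian pixel noise.
#' @param min_separation minimum centre-to-centre distance between nuclei
#'   (px); the default keeps nuclei segmentable as separate components after
#'   entropy filtering. Set to 0 to generate overlapping nuclei for
#'   robustness testing.
#' @param seed integer seed.
#' @return an object of class `fluor_field_spec`.
#' @export
fluor_field_spec <- function(height = 512, width = 512, n_nuclei = 50,
                             nucleus_radius_range = c(6, 9),
                             positive_fraction = 0.5,
                             positive_488_mean = 30, negative_488_mean = 3,
                             nucleus_405_mean = 150, noise_sd = 2,
                             min_separation = 2 * max(nucleus_radius_range) + 14,
                             seed = 1) {
  if (positive_fraction < 0 || positive_fraction > 1)
    stop_input("`positive_fraction` must be in [0, 1]")
  if (!(positive_488_mean > 10) || !(negative_488_mean <= 10))
    stop_input("need positive_488_mean > 10 >= negative_488_mean")
  if (length(nucleus_radius_range) != 2L ||
      nucleus_radius_range[1] > nucleus_radius_range[2])
    stop_input("`nucleus_radius_range` must be c(min, max)")
  if (!is_count(n_nuclei)) stop_input("`n_nuclei` must be a nonnegative integer")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_range = nucleus_radius_range,
                 positive_fraction = positive_fraction,
                 positive_488_mean = positive_488_mean,
                 negative_488_mean = negative_488_mean,
                 nucleus_405_mean = nucleus_405_mean,
                 noise_sd = noise_sd, min_separation = min_separation,
                 seed = as.integer(seed)),
            class = "fluor_field_spec")
}

#' Specification of a synthetic scratch-wound time series
#'
#' A confluent textured cell sheet with a cell-free stripe whose area shrinks
#' along a prescribed recovery trajectory: at timepoint `t` the wound area is
#' `A_0 * (1 - recovery_targets[t] / 100)`, realised to within +/- 1 % of
#' `A_0`. Cells close in symmetrically from both wound edges.
#'
#' @param height,width frame size in pixels.
#' @param timepoints hours, strictly increasing, first must be 0.
#' @param recovery_targets percent recovery per timepoint, nondecreasing in
#'   `[0, 100]`, first must be 0.
#' @param wound_orientation `"vertical"` (stripe spans rows) or
#'   `"horizontal"`.
#' @param initial_wound_fraction wound width as a fraction of the frame
#'   dimension perpendicular to the stripe.
#' @inheritParams phase_field_spec
#' @return an object of class `wound_series_spec`.
#' @export
wound_series_spec <- function(height = 400, width = 800,
                              timepoints = c(0, 12, 24, 36),
                              recovery_targets = c(0, 30, 55, 75),
                              wound_orientation = c("vertical", "horizontal"),
                              initial_wound_fraction = 0.3,
                              texture_contrast = 120, background_level = 40,
                              noise_sd = 2, seed = 1) {
  wound_orientation <- match.arg(wound_orientation)
  if (length(timepoints) != length(recovery_targets))
    stop_input("`timepoints` and `recovery_targets` must have equal length")
  if (any(diff(timepoints) <= 0) || timepoints[1] != 0)
    stop_input("`timepoints` must be strictly increasing and start at 0")
  if (recovery_targets[1] != 0 || any(diff(recovery_targets) < 0) ||
      any(recovery_targets < 0 | recovery_targets > 100))
    stop_input("`recovery_targets` must be nondecreasing in [0, 100], starting at 0")
  if (initial_wound_fraction <= 0 || initial_wound_fraction >= 1)
    stop_input("`initial_wound_fraction` must be in (0, 1)")
  structure(list(height = as.integer(height), width = as.integer(width),
                 timepoints = timepoints, recovery_targets = recovery_targets,
                 wound_orientation = wound_orientation,
                 initial_wound_fraction = initial_wound_fraction,
                 texture_contrast = texture_contrast,
                 background_level = background_level,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "wound_series_spec")
}

#' Specification of a synthetic dye-solubilisation curve
#'
#' Two-segment piecewise-linear absorbance difference versus concentration:
#' below the breakpoint (the true CMC) the unimeric segment, above it a
#' steeper micellar segment, joined continuously, plus additive Gaussian
#' noise.
#'
#' @param concentrations polymer concentrations in wt%, strictly positive;
#'   default 10 log-spaced values spanning 0.001-1.0 wt%.
#' @param breakpoint true CMC in wt%, strictly inside the concentration range.
#' @param unimeric_slope,micellar_slope segment slopes (absorbance per wt%),
#'   `micellar_slope > unimeric_slope >= 0`.
#' @param intercept absorbance difference at zero concentration.
#' @param noise_sd sd of additive Gaussian noise (absorbance units).
#' @param seed integer seed.
#' @return an object of class `solubilisation_spec`.
#' @export
solubilisation_spec <- function(concentrations = 10^seq(-3, 0, length.out = 10),
                                breakpoint = 0.03,
                                unimeric_slope = 0.5, micellar_slope = 10,
                                intercept = 0.05, noise_sd = 0, seed = 1) {
  if (any(concentrations <= 0)) stop_input("concentrations must be > 0")
  concentrations <- sort(concentrations)
  if (breakpoint <= min(concentrations) || breakpoint >= max(concentrations))
    stop_input("`breakpoint` must lie strictly inside the concentration range")
  if (!(micellar_slope > unimeric_slope) || unimeric_slope < 0)
    stop_input("need micellar_slope > unimeric_slope >= 0")
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0")
  structure(list(concentrations = concentrations, breakpoint = breakpoint,
                 unimeric_slope = unimeric_slope, micellar_slope = micellar_slope,
                 intercept = intercept, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "solubilisation_spec")
}

#' Specification of a synthetic qPCR Ct table
#'
#' Generates cycle-threshold values whose noiseless comparative-CT analysis
#' recovers the prescribed log2 fold changes exactly: the reference
#' (housekeeping) gene has constant Ct across conditions, and each target
#' gene's Ct in a condition is its control Ct minus the true log2 fold change.
#'
#' @param genes character vector of target gene identifiers (the reference
#'   gene is added automatically).
#' @param conditions character vector of condition identifiers; the first is
#'   the control.
#' @param true_log2_fold_changes numeric matrix `genes x conditions`; the
#'   control column must be all zero.
#' @param reference_gene housekeeping gene identifier.
#' @param base_ct reference-gene Ct in cycles; target-gene control Ct is
#'   `base_ct + 5`.
#' @param replicates technical replicates per (gene, condition), >= 1.
#' @param ct_noise_sd sd of Gaussian Ct noise per replicate (cycles).
#' @param seed integer seed.
#' @return an object of class `ct_table_spec`.
#' @export
ct_table_spec <- function(genes = c("Nqo1", "Hmox1", "Gclm"),
                          conditions = c("media", "polyCEP"),
                          true_log2_fold_changes =
                            matrix(c(0, 0, 0, 1, 2, -1), length(genes), length(conditions),
                                   dimnames = list(genes, conditions)),
                          reference_gene = "Gapdh", base_ct = 18,
                          replicates = 3, ct_noise_sd = 0, seed = 1) {
  if (!is_count(replicates) || replicates < 1)
    stop_input("`replicates` must be an integer >= 1")
  if (!is.matrix(true_log2_fold_changes) ||
      nrow(true_log2_fold_changes) != length(genes) ||
      ncol(true_log2_fold_changes) != length(conditions))
    stop_input("`true_log2_fold_changes` must be a genes x conditions matrix")
  if (any(true_log2_fold_changes[, 1] != 0))
    stop_input("control condition (first column) must have log2 fold change 0")
  if (reference_gene %in% genes)
    stop_input("`reference_gene` must not appear among target `genes`")
  dimnames(true_log2_fold_changes) <- list(genes, conditions)
  structure(list(genes = genes, conditions = conditions,
                 true_log2_fold_changes = true_log2_fold_changes,
                 reference_gene = reference_gene, base_ct = base_ct,
                 replicates = as.integer(replicates), ct_noise_sd = ct_noise_sd,
                 seed = as.integer(seed)),
            class = "ct_table_spec")
}
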