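#' Wound (cell-free) mask from a phase-contrast frame
#'
#' Frequency filtering plus mathematical morphology: the cellular region is
#' estimated exactly as for confluence (Gaussian low-pass at
#' `config$sigma_phase`, pixel-wise local entropy, thresholding,
#' morphological cleanup with boundary recentring), the cell mask is then
#' closed with a large disc (`wound_close_radius`) to bridge intracellular
#' gaps, and the wound is the complement. By default only the largest
#' connected cell-free component is kept (the scratch is a single contiguous
#' region; smaller gaps are biological holes). A fully confluent frame yields
#' an empty wound mask, not an error.
#'
#' With `config$wound_bandpass = TRUE` the cell texture is instead measured
#' on the magnitude of a difference-of-Gaussians band-pass
#' ([dog_bandpass()], sigmas `dog_sigma_low` / `dog_sigma_high`), which
#' additionally suppresses slow illumination gradients. This is off by
#' default because the wide Gaussian spreads texture energy roughly
#' `dog_sigma_high` pixels into the cell-free region and biases the wound
#' boundary far more than the plain low-pass does; prefer it only for frames
#' with strong uneven illumination.
#'
#' @param frame phase-contrast [image_frame()] or numeric matrix.
#' @param config a [filter_config()].
#' @return a logical `segmentation_mask` of the wound; `sum(mask)` is the
#'   wound area in pixels.
#' @export
wound_mask <- function(frame, config = filter_config()) {
  px <- frame_pixels(frame)
  if (isTRUE(config$wound_bandpass))
    px <- clip255(abs(dog_bandpass(px, config$dog_sigma_low,
                                   config$dog_sigma_high)))
  cells <- withCallingHandlers(
    texture_cell_mask(px, config$sigma_phase, config),
    warning = function(w) {
      if (grepl("degenerate entropy map", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (config$wound_close_radius > 0 && any(cells)) {
    img <- EBImage::closing(EBImage::Image(cells * 1),
                            EBImage::makeBrush(2 * round(config$wound_close_radius) + 1,
                                               "disc"))
    cells <- EBImage::imageData(img) > 0.5
  }
  wound <- !cells
  if (isTRUE(config$largest_wound_only) && any(wound)) {
    lab <- label_components_cpp(wound)
    n <- attr(lab, "n")
    if (n > 1L) {
      areas <- tabulate(lab[lab > 0L], nbins = n)
      wound <- lab == which.max(areas)
    }
  }
  new_segmentation_mask(wound, list(op = "wound_mask",
                                    sigma = config$sigma_phase,
                                    wound_close_radius = config$wound_close_radius))
}

#' Wound recovery from an area trajectory
#'
#' Applies the recovery formula `100 * (A_0 - A_t) / A_0`, with `A_0` the
#' wound area measured immediately after scratching (time zero) and `A_t`
#' the area at each later timepoint. Negative values (a growing wound) are
#' reported and flagged, not clipped.
#'
#' @param areas wound areas in pixels, one per timepoint; the first is `A_0`.
#' @param timepoints hours, same length as `areas`, first must be 0.
#' @param well_id identifier carried into the output.
#' @return a `wound_trajectory` data.frame with `timepoint`, `wound_area`,
#'   `baseline_area`, `recovery`, `negative_recovery`.
#' @export
wound_recovery <- function(areas, timepoints = seq_along(areas) - 1,
                           well_id = "well1") {
  if (length(areas) != length(timepoints))
    stop_input("`areas` and `timepoints` must have equal length")
  if (timepoints[1] != 0)
    stop_input("first timepoint must be 0 (the post-scratch baseline)")
  a0 <- areas[1]
  if (!is.finite(a0) || a0 <= 0)
    stop_input("undefined baseline: wound area at time zero must be > 0")
  rec <- 100 * (a0 - areas) / a0
  out <- data.frame(well_id = well_id, timepoint = timepoints,
                    wound_area = areas, baseline_area = a0,
                    recovery = rec, negative_recovery = rec < 0)
  class(out) <- c("wound_trajectory", "data.frame")
  out
}

#' Per-condition wound-recovery summary
#'
#' Mean and sample standard deviation of recovery per condition at the
#' requested timepoints (the assay's standard readouts are 12, 24 and 36 h
#' post-scratch). A well missing a timepoint is flagged and excluded from
#' that timepoint's mean.
#'
#' @param trajectories data.frame with columns `condition`, `well_id`,
#'   `timepoint`, `recovery` (e.g. stacked [wound_recovery()] outputs with a
#'   condition column added).
#' @param timepoints hours at which to summarise.
#' @return a `recovery_summary` data.frame with `condition`, `timepoint`,
#'   `mean_recovery`, `sd`, `n`; wells missing a timepoint are listed in the
#'   `"gaps"` attribute.
#' @export
recovery_summary <- function(trajectories, timepoints = c(12, 24, 36)) {
  need <- c("condition", "well_id", "timepoint", "recovery")
  if (!all(need %in% names(trajectories)))
    stop_input("`trajectories` needs columns: ", paste(need, collapse = ", "))
  gaps <- character(0)
  rows <- list()
  for (cond in unique(trajectories$condition)) {
    tc <- trajectories[trajectories$condition == cond, ]
    wells <- unique(tc$well_id)
    for (tp in timepoints) {
      v <- tc$recovery[tc$timepoint == tp]
      missing_wells <- wells[!wells %in% tc$well_id[tc$timepoint == tp]]
      if (length(missing_wells))
        gaps <- c(gaps, paste0(cond, "/", missing_wells, "@", tp, "h"))
      if (length(v) == 0) next
      rows[[length(rows) + 1L]] <-
        data.frame(condition = cond, timepoint = tp, mean_recovery = mean(v),
                   sd = if (length(v) > 1) sd(v) else 0, n = length(v))
    }
  }
  if (length(rows) == 0) stop_input("no recovery values at the requested timepoints")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "gaps") <- gaps
  class(out) <- c("recovery_summary", "data.frame")
  out
}
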