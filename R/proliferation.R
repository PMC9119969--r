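#' @noRd
resolve_boundary_erode <- function(config, sigma) {
  be <- config$boundary_erode
  if (identical(be, "auto")) (config$entropy_window - 1) / 2 + round(sigma) else be
}

#' @noRd
texture_cell_mask <- function(px, sigma, config, band = config$otsu_band_phase) {
  den <- gaussian_denoise(px, sigma)
  ent <- local_entropy(den, config$entropy_window)
  morphological_cleanup(threshold_entropy(ent, config, band), config,
                        boundary_erode = resolve_boundary_erode(config, sigma))
}

#' Confluence from a phase-contrast frame
#'
#' Runs the phase-contrast pipeline: Gaussian denoising (sigma
#' `config$sigma_phase`, default 2 px), pixel-wise local entropy in the
#' 9 x 9 neighbourhood, entropy thresholding, morphological cleanup.
#' Confluence is 100 x (mask pixels) / (total pixels).
#'
#' @param frame a phase-channel [image_frame()] (or numeric matrix).
#' @param config a [filter_config()].
#' @return one-row data.frame of class `confluence_record` with `field_id`,
#'   `timepoint`, `confluence`; the segmentation mask is attached as
#'   attribute `"mask"`.
#' @export
confluence_from_phase <- function(frame, config = filter_config()) {
  if (inherits(frame, "image_frame") && frame$channel != "phase")
    stop_input("expected a phase-channel frame, got channel ", frame$channel)
  px <- frame_pixels(frame)
  mask <- texture_cell_mask(px, config$sigma_phase, config)
  rec <- data.frame(
    field_id = if (inherits(frame, "image_frame")) frame$field_id else "field1",
    timepoint = if (inherits(frame, "image_frame")) frame$timepoint else 0,
    confluence = 100 * mean(mask))
  class(rec) <- c("confluence_record", "data.frame")
  attr(rec, "mask") <- mask
  rec
}

#' Growth curve: per-timepoint confluence summaries across replicates
#'
#' @param records data.frame with columns `condition`, `replicate`,
#'   `timepoint`, `confluence` (e.g. stacked [confluence_from_phase()]
#'   outputs with condition/replicate columns added). Every replicate of a
#'   condition must cover the same timepoints.
#' @return a `growth_curve` data.frame with per condition x timepoint
#'   `mean_confluence`, `sd` (sample sd, n - 1 denominator; reported as 0
#'   with `single_replicate = TRUE` when n = 1) and `n`.
#' @export
growth_curve <- function(records) {
  need <- c("condition", "replicate", "timepoint", "confluence")
  if (!all(need %in% names(records)))
    stop_input("`records` needs columns: ", paste(need, collapse = ", "))
  # replicates must share timepoints within each condition
  offenders <- character(0)
  for (cond in unique(records$condition)) {
    rc <- records[records$condition == cond, ]
    tp_sets <- lapply(split(rc$timepoint, rc$replicate), function(x) sort(unique(x)))
    ref <- tp_sets[[1]]
    bad <- names(tp_sets)[!vapply(tp_sets, identical, logical(1), y = ref)]
    if (length(bad))
      offenders <- c(offenders, paste0(cond, ":", bad))
  }
  if (length(offenders))
    stop_input("inconsistent timepoints across replicates for: ",
               paste(offenders, collapse = ", "))
  agg <- do.call(rbind, lapply(split(records, records[c("timepoint", "condition")],
                                     drop = TRUE), function(d) {
    data.frame(condition = d$condition[1], timepoint = d$timepoint[1],
               mean_confluence = mean(d$confluence),
               sd = if (nrow(d) > 1) sd(d$confluence) else 0,
               n = nrow(d), single_replicate = nrow(d) == 1L)
  }))
  agg <- agg[order(agg$condition, agg$timepoint), ]
  rownames(agg) <- NULL
  class(agg) <- c("growth_curve", "data.frame")
  agg
}

#' @noRd
measure_labelled <- function(lab, n, frames) {
  if (n == 0L) {
    out <- data.frame(label = integer(), area = integer(),
                      centroid_row = numeric(), centroid_col = numeric())
    for (nm in names(frames)) out[[paste0("mean_", nm)]] <- numeric()
    class(out) <- c("region_table", "data.frame")
    return(out)
  }
  idx <- which(lab > 0L)
  lv <- lab[idx]
  area <- tabulate(lv, nbins = n)
  keep <- area > 0
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  out <- data.frame(label = seq_len(n)[keep], area = area[keep],
                    centroid_row = (as.numeric(rowsum(rows, lv)) / area[keep]),
                    centroid_col = (as.numeric(rowsum(cols, lv)) / area[keep]))
  for (nm in names(frames))
    out[[paste0("mean_", nm)]] <- as.numeric(rowsum(frames[[nm]][idx], lv)) / area[keep]
  out$label <- seq_len(nrow(out))
  class(out) <- c("region_table", "data.frame")
  out
}

#' Segment nuclei from the 405 channel
#'
#' Fluorescence pipeline: Gaussian denoising (sigma `config$sigma_fluor`,
#' default 1 px) of the 405 frame, local entropy (9 x 9), thresholding,
#' morphological cleanup, then connected-component labelling. Mean 488
#' intensities, when a 488 frame is supplied, are measured on the raw
#' (unsmoothed) 488 frame so the fixed positivity cutoff keeps its meaning.
#' With `config$watershed_nuclei = TRUE`, touching nuclei are split by a
#' distance-transform watershed instead of plain connected components.
#'
#' @param frame405 nuclei-channel [image_frame()] (or matrix).
#' @param frame488 optional marker-channel frame, congruent with `frame405`.
#' @param config a [filter_config()].
#' @return a `region_table` (see [label_regions()]) with a `mean_488` column
#'   when `frame488` is given; the nuclear mask is attached as attribute
#'   `"mask"`.
#' @export
segment_nuclei <- function(frame405, frame488 = NULL, config = filter_config()) {
  px <- frame_pixels(frame405)
  frames <- list()
  if (!is.null(frame488)) {
    f488 <- frame_pixels(frame488)
    if (!all(dim(f488) == dim(px)))
      stop_input("405 and 488 frames are not congruent")
    frames$`488` <- f488
  }
  mask <- texture_cell_mask(px, config$sigma_fluor, config,
                            band = config$otsu_band_fluor)
  if (isTRUE(config$watershed_nuclei)) {
    dm <- EBImage::distmap(EBImage::Image(matrix(as.numeric(mask), nrow(mask))))
    lab <- EBImage::imageData(EBImage::watershed(dm))
    storage.mode(lab) <- "integer"
    regions <- measure_labelled(lab, max(lab), frames)
  } else {
    regions <- label_regions(mask, frames)
  }
  attr(regions, "mask") <- mask
  regions
}

#' Classify Ki67-positive nuclei
#'
#' A nucleus counts as proliferating (Ki67-positive) iff its mean 488-channel
#' intensity is strictly greater than `threshold` (default 10 on the 0-255
#' scale; a mean of exactly 10 is negative). With zero nuclei the percentage
#' is reported as `NA` (missing), never 0.
#'
#' @param regions a `region_table` with a `mean_488` column
#'   (from [segment_nuclei()] with a 488 frame).
#' @param threshold positivity cutoff on mean 488 intensity.
#' @param field_id identifier carried into the output.
#' @return one-row data.frame of class `nuclei_quantification` with
#'   `nuclei_count`, `ki67_positive_count`, `ki67_positive_pct`.
#' @export
classify_ki67 <- function(regions, threshold = 10, field_id = "field1") {
  n <- nrow(regions)
  if (n > 0 && !"mean_488" %in% names(regions))
    stop_input("`regions` lacks a mean_488 column; segment with a 488 frame")
  pos <- if (n > 0) sum(regions$mean_488 > threshold) else 0L
  out <- data.frame(field_id = field_id, nuclei_count = n,
                    ki67_positive_count = pos,
                    ki67_positive_pct = if (n > 0) 100 * pos / n else NA_real_)
  class(out) <- c("nuclei_quantification", "data.frame")
  out
}

#' Nuclear mean fluorescence intensity (MFI) in the 488 channel
#'
#' Area-weighted mean 488 intensity over the union of nuclear pixels (the
#' 405/488 overlay readout used for NRF2 nuclear localisation). Accepts
#' either a segmented `region_table` carrying `area` and `mean_488`, or a
#' nuclear mask plus the raw 488 frame.
#'
#' @param regions a `region_table` with `mean_488`, or a logical nuclear mask.
#' @param frame488 the 488 [image_frame()] (required when `regions` is a mask).
#' @return a single intensity value; `NA` when there are no nuclear pixels.
#' @export
nuclear_mfi <- function(regions, frame488 = NULL) {
  if (is.matrix(regions) && is.logical(unclass(regions)[1])) {
    mask <- matrix(as.logical(regions), nrow(regions), ncol(regions))
    if (is.null(frame488)) stop_input("`frame488` required with a mask input")
    px <- frame_pixels(frame488)
    if (!all(dim(px) == dim(mask))) stop_input("mask and 488 frame not congruent")
    if (!any(mask)) return(NA_real_)
    return(mean(px[mask]))
  }
  if (nrow(regions) == 0) return(NA_real_)
  if (!"mean_488" %in% names(regions))
    stop_input("`regions` lacks a mean_488 column")
  sum(regions$mean_488 * regions$area) / sum(regions$area)
}
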