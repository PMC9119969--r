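#' @noRd
pad_reflect <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  if (r >= h || r >= w)
    stop_input("padding radius ", r, " too large for a ", h, " x ", w, " image")
  rows <- c(r:1, 1:h, h:(h - r + 1))
  cols <- c(r:1, 1:w, w:(w - r + 1))
  m[rows, cols, drop = FALSE]
}

#' @noRd
gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian denoising
#'
#' Separable Gaussian smoothing with reflective border padding. The kernel is
#' the sampled Gaussian truncated at 3 sigma and normalised to unit sum, so
#' the filter is linear with DC gain 1: constant images pass unchanged.
#'
#' @param frame an [image_frame()] or numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return object of the same kind as `frame` with smoothed pixels.
#' @export
gaussian_denoise <- function(frame, sigma = 2) {
  px <- frame_pixels(frame)
  if (any(!is.finite(px))) stop_input("frame contains non-finite pixels")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop_input("`sigma` must be a single positive number")
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  p <- pad_reflect(px, r)
  h <- nrow(px); w <- ncol(px)
  # vertical pass
  v <- matrix(0, h, ncol(p))
  for (o in seq_along(k)) v <- v + k[o] * p[(o - 1L) + seq_len(h), , drop = FALSE]
  # horizontal pass
  out <- matrix(0, h, w)
  for (o in seq_along(k)) out <- out + k[o] * v[, (o - 1L) + seq_len(w), drop = FALSE]
  if (inherits(frame, "image_frame")) { frame$pixels <- out; frame } else out
}

#' Difference-of-Gaussians band-pass filter
#'
#' Subtracts a wide Gaussian blur from a narrow one, suppressing both pixel
#' noise and slow illumination gradients while keeping cell-scale texture.
#' Used as the "frequency filtering" step of the wound pipeline.
#'
#' @inheritParams gaussian_denoise
#' @param sigma_low,sigma_high sigmas of the narrow and wide Gaussians (px),
#'   `sigma_low < sigma_high`.
#' @return numeric matrix (may be negative; it is a band-pass residual).
#' @export
dog_bandpass <- function(frame, sigma_low = 2, sigma_high = 16) {
  if (sigma_low >= sigma_high)
    stop_input("`sigma_low` must be smaller than `sigma_high`")
  px <- frame_pixels(frame)
  gaussian_denoise(px, sigma_low) - gaussian_denoise(px, sigma_high)
}

#' Pixel-wise local Shannon entropy
#'
#' For every pixel, the Shannon entropy (base 2, in bits) of the 256-bin
#' intensity histogram over its `window` x `window` neighbourhood, with
#' reflective border padding. Intensities are quantised to integer bins 0-255
#' (values outside are clamped) before histogramming; the result is therefore
#' invariant to any strictly monotone intensity relabelling that preserves bin
#' assignment. Textured (cellular) regions score high; smooth background
#' scores near zero.
#'
#' @inheritParams gaussian_denoise
#' @param window neighbourhood side in pixels (odd, >= 3; default 9).
#' @return numeric matrix of entropies in `[0, 8]` bits.
#' @export
local_entropy <- function(frame, window = 9) {
  px <- frame_pixels(frame)
  if (!is.numeric(window) || length(window) != 1L || window %% 2 == 0 || window < 3)
    stop_input("`window` must be a single odd integer >= 3")
  if (window > nrow(px) || window > ncol(px))
    stop_input("entropy window does not fit in the frame")
  if (any(!is.finite(px))) stop_input("frame contains non-finite pixels")
  local_entropy_cpp(quantise256(px), as.integer(window))
}

#' @noRd
new_segmentation_mask <- function(mask, provenance) {
  structure(mask, provenance = provenance, class = c("segmentation_mask", class(mask)))
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d x %d, %d foreground px (%.1f%%)\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov$op)) cat("  provenance:", prov$op, "\n")
  invisible(x)
}

#' Threshold an entropy map into a segmentation mask
#'
#' The mask is `entropy > threshold`. By default the threshold is Otsu's value
#' computed on the entropy map (256 levels over `[0, 8]` bits), clamped into
#' `band` (see [filter_config()]'s `otsu_band_phase` for why); a fixed
#' threshold in bits can be given in the config instead. A degenerate map
#' (all values equal) yields an empty mask with a warning rather than an
#' error.
#'
#' @param entropy_map numeric matrix from [local_entropy()].
#' @param config a [filter_config()].
#' @param band length-2 clamp interval for the Otsu threshold; defaults to
#'   the config's phase band (the fluorescence pipeline passes its own).
#' @return a logical `segmentation_mask`.
#' @export
threshold_entropy <- function(entropy_map, config = filter_config(),
                              band = config$otsu_band_phase) {
  if (!is.matrix(entropy_map) || any(!is.finite(entropy_map)))
    stop_input("`entropy_map` must be a finite numeric matrix")
  rng <- range(entropy_map)
  if (diff(rng) == 0) {
    warning("degenerate entropy map (all values equal); returning empty mask")
    return(new_segmentation_mask(matrix(FALSE, nrow(entropy_map), ncol(entropy_map)),
                                 list(op = "threshold_entropy", threshold = NA_real_)))
  }
  thr <- if (identical(config$entropy_threshold, "otsu")) {
    raw <- 8 * EBImage::otsu(EBImage::Image(entropy_map / 8),
                             range = c(0, 1), levels = 256L)
    # Otsu assumes bimodality; a value outside the plausible background /
    # texture separation band marks a single-class frame (see filter_config)
    min(max(raw, band[1]), band[2])
  } else {
    config$entropy_threshold
  }
  new_segmentation_mask(entropy_map > thr,
                        list(op = "threshold_entropy", threshold = thr))
}

#' @noRd
remove_small_components <- function(mask, min_area) {
  if (min_area <= 0 || !any(mask)) return(mask)
  lab <- label_components_cpp(mask)
  n <- attr(lab, "n")
  if (n == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(areas >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Morphological mask cleanup
#'
#' Opening (disc radius `r_open`) to remove speckle, then closing (disc radius
#' `r_close`) to bridge small gaps, optional hole filling, an optional
#' boundary-recentring erosion (see [filter_config()]'s `boundary_erode`:
#' sliding-window texture detection dilates regions by about half the window,
#' and the erosion undoes that), then removal of connected components smaller
#' than `min_object_area` pixels. The opening/closing stage is idempotent on
#' its own output.
#'
#' @param mask a logical matrix or `segmentation_mask`.
#' @param config a [filter_config()].
#' @param boundary_erode erosion radius in px; overrides the config so the
#'   calling pipeline can resolve `"auto"` with its own sigma. 0 disables.
#' @return a cleaned logical `segmentation_mask`.
#' @export
morphological_cleanup <- function(mask, config = filter_config(),
                                  boundary_erode = 0) {
  m <- mask
  if (!is.logical(m) || !is.matrix(unclass(m)))
    stop_input("`mask` must be a logical matrix")
  m <- matrix(as.logical(m), nrow(mask), ncol(mask))
  img <- EBImage::Image(m * 1)
  if (config$r_open > 0)
    img <- EBImage::opening(img, EBImage::makeBrush(2 * config$r_open + 1, "disc"))
  if (config$r_close > 0)
    img <- EBImage::closing(img, EBImage::makeBrush(2 * config$r_close + 1, "disc"))
  if (isTRUE(config$fill_holes)) img <- EBImage::fillHull(img)
  if (boundary_erode > 0) {
    # reflect-pad before eroding: erosion must not strip the frame border
    # (the structuring element would otherwise see artificial background
    # outside the frame)
    be <- min(round(boundary_erode), nrow(mask) - 1L, ncol(mask) - 1L)
    padded <- pad_reflect(EBImage::imageData(img), be)
    er <- EBImage::erode(EBImage::Image(padded),
                         EBImage::makeBrush(2 * be + 1, "disc"))
    img <- EBImage::Image(EBImage::imageData(er)[be + seq_len(nrow(mask)),
                                                 be + seq_len(ncol(mask)),
                                                 drop = FALSE])
  }
  m <- EBImage::imageData(img) > 0.5
  m <- remove_small_components(m, config$min_object_area)
  new_segmentation_mask(m, list(op = "morphological_cleanup",
                                r_open = config$r_open, r_close = config$r_close,
                                min_object_area = config$min_object_area,
                                fill_holes = config$fill_holes,
                                boundary_erode = boundary_erode))
}

#' Label connected regions and measure them
#'
#' 8-connected component labelling with labels 1..n; per region the pixel
#' area, the centroid (row, col; 1-based matrix coordinates) and the mean
#' intensity in each supplied channel frame.
#'
#' @param mask a logical matrix or `segmentation_mask`.
#' @param intensity_frames named list of [image_frame()]s or matrices,
#'   congruent with `mask`; names become `mean_<name>` columns.
#' @return a `region_table` data.frame with columns `label`, `area`,
#'   `centroid_row`, `centroid_col` and one `mean_<channel>` per frame.
#' @export
label_regions <- function(mask, intensity_frames = list()) {
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  frames <- lapply(intensity_frames, frame_pixels)
  for (f in frames)
    if (!all(dim(f) == dim(m)))
      stop_input("intensity frame shape does not match the mask")
  lab <- label_components_cpp(m)
  n <- attr(lab, "n")
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
  rows <- ((idx - 1L) %% nrow(m)) + 1L
  cols <- ((idx - 1L) %/% nrow(m)) + 1L
  out <- data.frame(label = seq_len(n), area = area,
                    centroid_row = as.numeric(rowsum(rows, lv)) / area,
                    centroid_col = as.numeric(rowsum(cols, lv)) / area)
  for (nm in names(frames))
    out[[paste0("mean_", nm)]] <- as.numeric(rowsum(frames[[nm]][idx], lv)) / area
  class(out) <- c("region_table", "data.frame")
  out
}
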