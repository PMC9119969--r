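#' Segmentation filter configuration
#'
#' Parameters shared by the texture-segmentation pipelines. Defaults mirror the
#' published pipeline where it states values (Gaussian sigma 2 px for phase
#' contrast, sigma 1 px for fluorescence, 9 x 9 entropy neighbourhood) and use
#' declared, config-exposed choices where it is silent (Otsu threshold on the
#' entropy map; opening radius 1 px, closing radius 3 px, minimum object area
#' 25 px, hole filling off -- enclosed smooth pockets are genuine cell-free
#' background, not segmentation artefacts, so filling them inflates
#' confluence).
#'
#' @param sigma_phase Gaussian denoising sigma for phase-contrast frames (px).
#' @param sigma_fluor Gaussian denoising sigma for fluorescence frames (px).
#' @param entropy_window side of the square entropy neighbourhood (odd, px).
#' @param entropy_threshold `"otsu"` or a fixed numeric threshold in bits.
#' @param otsu_band_phase,otsu_band_fluor numeric length-2 clamping intervals
#'   (bits) for the Otsu threshold in the phase-contrast and fluorescence
#'   pipelines. Otsu's method assumes a bimodal histogram; on a single-class
#'   frame (fully confluent, or bare background) it happily splits the one
#'   mode in half. Denoised smooth background occupies only a few intensity
#'   bins, capping its windowed entropy, while denoised cell texture spreads
#'   over many bins and keeps a much higher entropy floor; a data-driven
#'   threshold outside the gap between those two levels therefore signals a
#'   single-class frame and is clamped to the nearest gap boundary, turning
#'   the decision into the correct near-all-or-nothing call. The gap location
#'   depends on how hard the noise was smoothed: sigma = 2 (phase) leaves
#'   background below ~1.5 bits with a texture floor near 3, sigma = 1
#'   (fluorescence) leaves background below ~3.3 bits with a texture floor
#'   near 4.2. Ignored for fixed numeric thresholds.
#' @param r_open,r_close radii of the disc structuring elements for
#'   morphological opening and closing (px); 0 disables the step.
#' @param min_object_area components smaller than this (px) are removed.
#' @param fill_holes logical; fill enclosed background holes in the mask.
#' @param boundary_erode `"auto"` or a radius in px. Texture detection through
#'   a sliding window dilates the segmented region by about half the window
#'   plus the denoising sigma (a window centred just outside a cell still
#'   contains cell texture); the cleaned mask is eroded by this radius to
#'   recentre the boundary on the true texture edge. `"auto"` uses
#'   `(entropy_window - 1) / 2 + round(sigma)` for the sigma of the pipeline
#'   at hand; 0 disables the compensation.
#' @param dog_sigma_low,dog_sigma_high sigmas (px) for the optional
#'   difference-of-Gaussians band-pass primitive ([dog_bandpass()]), available
#'   for frames with strong illumination gradients.
#' @param wound_bandpass logical; prefilter wound frames with the
#'   difference-of-Gaussians band-pass before texture masking (see
#'   [wound_mask()] for why this is off by default).
#' @param wound_close_radius closing radius used to bridge intracellular gaps
#'   before taking the wound as the complement (px).
#' @param largest_wound_only logical; keep only the largest cell-free component
#'   as the wound.
#' @param watershed_nuclei logical; split touching nuclei with a distance
#'   transform watershed (off by default: plain connected components, faithful
#'   to the described pipeline).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(sigma_phase = 2, sigma_fluor = 1,
                          entropy_window = 9, entropy_threshold = "otsu",
                          otsu_band_phase = c(1.6, 3.0),
                          otsu_band_fluor = c(3.4, 4.2),
                          r_open = 1, r_close = 3, min_object_area = 25,
                          fill_holes = FALSE, boundary_erode = "auto",
                          dog_sigma_low = 2, dog_sigma_high = 16,
                          wound_bandpass = FALSE,
                          wound_close_radius = 12,
                          largest_wound_only = TRUE,
                          watershed_nuclei = FALSE) {
  if (sigma_phase <= 0 || sigma_fluor <= 0)
    stop_input("Gaussian sigmas must be > 0")
  if (entropy_window < 3 || entropy_window %% 2 == 0)
    stop_input("`entropy_window` must be odd and >= 3")
  if (!identical(entropy_threshold, "otsu") &&
      !(is.numeric(entropy_threshold) && length(entropy_threshold) == 1L))
    stop_input("`entropy_threshold` must be \"otsu\" or a single number (bits)")
  for (band in list(otsu_band_phase, otsu_band_fluor))
    if (!is.numeric(band) || length(band) != 2L || band[1] > band[2])
      stop_input("Otsu bands must be c(lo, hi) with lo <= hi")
  if (min_object_area < 0) stop_input("`min_object_area` must be >= 0")
  structure(list(sigma_phase = sigma_phase, sigma_fluor = sigma_fluor,
                 entropy_window = as.integer(entropy_window),
                 entropy_threshold = entropy_threshold,
                 otsu_band_phase = otsu_band_phase,
                 otsu_band_fluor = otsu_band_fluor,
                 r_open = r_open, r_close = r_close,
                 min_object_area = min_object_area, fill_holes = fill_holes,
                 boundary_erode = boundary_erode,
                 dog_sigma_low = dog_sigma_low, dog_sigma_high = dog_sigma_high,
                 wound_bandpass = wound_bandpass,
                 wound_close_radius = wound_close_radius,
                 largest_wound_only = largest_wound_only,
                 watershed_nuclei = watershed_nuclei),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  thr <- if (identical(x$entropy_threshold, "otsu")) "Otsu"
         else sprintf("%.3f bits", x$entropy_threshold)
  cat(sprintf("  denoise: sigma_phase %g px, sigma_fluor %g px\n",
              x$sigma_phase, x$sigma_fluor))
  cat(sprintf("  entropy: %d x %d window, threshold %s\n",
              x$entropy_window, x$entropy_window, thr))
  cat(sprintf("  morphology: open %g px, close %g px, min area %g px, holes %s\n",
              x$r_open, x$r_close, x$min_object_area,
              if (x$fill_holes) "filled" else "kept"))
  cat(sprintf("  wound: DoG sigma %g/%g px, close %g px, largest only %s\n",
              x$dog_sigma_low, x$dog_sigma_high, x$wound_close_radius,
              x$largest_wound_only))
  invisible(x)
}

#' Load a filter configuration from the `imaging` section of a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to [filter_config()]
#' defaults.
#'
#' @param path YAML file with an `imaging:` mapping.
#' @return a `filter_config`.
#' @export
read_filter_config <- function(path) {
  y <- yaml::read_yaml(path)
  sec <- if (!is.null(y$imaging)) y$imaging else y
  known <- names(formals(filter_config))
  bad <- setdiff(names(sec), known)
  if (length(bad))
    stop_input("unknown imaging config keys: ", paste(bad, collapse = ", "))
  do.call(filter_config, sec)
}
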