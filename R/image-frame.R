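#' Image frame: one channel of one field at one timepoint
#'
#' Light container for a single-channel intensity image on the 0-255 scale.
#' Pixels are stored as a numeric matrix (rows = image rows, origin top-left).
#' All quantification in this package assumes this fixed intensity scale, so
#' that the Ki67 positivity cutoff (mean 488 intensity > 10) keeps its meaning;
#' readers must not renormalise images silently.
#'
#' @param pixels numeric matrix of nonnegative finite intensities (0-255 scale).
#' @param channel one of `"phase"`, `"405"` (nuclei), `"488"` (marker).
#' @param timepoint acquisition time in hours.
#' @param field_id identifier of the imaged field/well.
#' @return an object of class `image_frame`.
#' @export
image_frame <- function(pixels, channel = c("phase", "405", "488"),
                        timepoint = 0, field_id = "field1") {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_input("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop_input("`pixels` contains non-finite values")
  if (any(pixels < 0))
    stop_input("`pixels` must be nonnegative (0-255 scale)")
  if (nrow(pixels) < 9 || ncol(pixels) < 9)
    stop_input("frame must be at least 9 x 9 (entropy window must fit)")
  structure(list(pixels = pixels, channel = channel,
                 timepoint = timepoint, field_id = field_id),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d, channel %s, t = %g h, field %s\n",
              nrow(x$pixels), ncol(x$pixels), x$channel, x$timepoint, x$field_id))
  cat(sprintf("  intensity range [%.2f, %.2f]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
as.matrix.image_frame <- function(x, ...) x$pixels

#' @noRd
frame_pixels <- function(frame) {
  if (inherits(frame, "image_frame")) frame$pixels
  else if (is.matrix(frame) && is.numeric(frame)) frame
  else stop_input("expected an `image_frame` or a numeric matrix")
}

#' Read a single-channel image file into an image frame
#'
#' Reads TIFF or PNG, takes the first channel if several are present, and
#' rescales [0, 1]-coded files to the package's 0-255 working scale.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @inheritParams image_frame
#' @return an `image_frame`.
#' @export
read_image_frame <- function(path, channel = "phase", timepoint = 0,
                             field_id = sub("\\.[^.]*$", "", basename(path))) {
  ext <- tolower(sub(".*\\.", "", path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop_input("reading PNG requires the 'png' package")
      png::readPNG(path)
    },
    stop_input("unsupported image format: .", ext)
  )
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  if (max(px) <= 1) px <- px * 255
  image_frame(px, channel = channel, timepoint = timepoint, field_id = field_id)
}

#' Write an image frame to a single-channel TIFF
#'
#' Intensities are stored as 32-bit floats scaled to [0, 1] (divided by 255)
#' so the round trip through [read_image_frame()] is lossless to float
#' precision.
#'
#' @param frame an `image_frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_frame <- function(frame, path) {
  px <- frame_pixels(frame) / 255
  tiff::writeTIFF(px, path, bits.per.sample = 32L)
  invisible(path)
}
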