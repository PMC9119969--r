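#' @noRd
clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Quantise intensities on the 0-255 scale into 256 integer bins
#' @noRd
quantise256 <- function(x) {
  storage.mode(x) <- "double"
  m <- matrix(as.integer(pmin(pmax(floor(x), 0), 255)), nrow(x), ncol(x))
  m
}

#' @noRd
stop_input <- function(...) stop(..., call. = FALSE)

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

#' Round half away from zero
#' @noRd
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
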