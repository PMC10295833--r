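#' Color-channel expansion for sensor-patch colorimetry
#'
#' An RGB triple read off a sensor patch is expanded into an eight-channel
#' color observation: the raw R, G, B levels (0-255), the HSI intensity
#' I = (R+G+B)/3 (kept on the 0-255 scale), the HSV hue H (degrees) and
#' saturation S and value V (percent), and the HSL lightness L (percent).
#' The percent scaling matches how channel tables are conventionally
#' reported in digital-image colorimetry.
#'
#' RGB levels are real-valued: replicate means of integer pixels are
#' fractional, and the channel math is exact on them. Integer quantization
#' is a property of image capture, not of the conversion.
#'
#' @name colorspace
NULL

CHANNEL_NAMES <- c("R", "G", "B", "I", "H", "S", "V", "L")

validate_rgb <- function(r, g, b) {
  if (!is.numeric(r) || !is.numeric(g) || !is.numeric(b))
    stop("RGB channels must be numeric", call. = FALSE)
  n <- length(r)
  if (length(g) != n || length(b) != n)
    stop("R, G, B must have equal length", call. = FALSE)
  bad <- !is.finite(r) | !is.finite(g) | !is.finite(b) |
    r < 0 | r > 255 | g < 0 | g > 255 | b < 0 | b > 255
  if (any(bad))
    stop("RGB channels must be finite and in [0, 255]; offending index: ",
         which(bad)[1], call. = FALSE)
  invisible(TRUE)
}

#' Hue of an RGB triple
#'
#' Piecewise hue formula on the HSV hexagonal model. When
#' `max(R,G,B) == min(R,G,B)` (an achromatic gray) the hue is undefined and
#' `NA` is returned rather than a fabricated angle; feature-matrix assembly
#' resolves the sentinel explicitly (see [as_feature_matrix()]).
#'
#' @param r,g,b red, green, blue levels in \[0, 255\] (vectorized,
#'   real-valued).
#' @return Hue in degrees, in \[0, 360), or `NA` where `max == min`.
#' @examples
#' rgb_to_hue(208.1, 172.5, 3.1)  # ~49.6 degrees, a saturated yellow
#' rgb_to_hue(100, 100, 100)      # NA: gray has no hue
#' @export
rgb_to_hue <- function(r, g, b) {
  validate_rgb(r, g, b)
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  h <- rep(NA_real_, length(r))
  i <- d > 0 & mx == r
  h[i] <- (60 * (g[i] - b[i]) / d[i]) %% 360
  i <- d > 0 & mx == g & mx != r
  h[i] <- 60 * (b[i] - r[i]) / d[i] + 120
  i <- d > 0 & mx == b & mx != r & mx != g
  h[i] <- 60 * (r[i] - g[i]) / d[i] + 240
  h
}

#' Saturation of an RGB triple
#'
#' `S = (1 - min/max) * 100`, in percent; 0 for black (`max == 0`) and for
#' any achromatic gray.
#'
#' @inheritParams rgb_to_hue
#' @return Saturation in percent, \[0, 100\].
#' @export
rgb_to_saturation <- function(r, g, b) {
  validate_rgb(r, g, b)
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  ifelse(mx == 0, 0, (1 - mn / mx) * 100)
}

#' Value (brightness) of an RGB triple
#'
#' `V = max(R,G,B) / 255 * 100`, in percent.
#'
#' @inheritParams rgb_to_hue
#' @return Value in percent, \[0, 100\].
#' @export
rgb_to_value <- function(r, g, b) {
  validate_rgb(r, g, b)
  pmax(r, g, b) / 255 * 100
}

#' Lightness of an RGB triple
#'
#' `L = (max + min) / 2 / 255 * 100`, the HSL lightness in percent.
#'
#' @inheritParams rgb_to_hue
#' @return Lightness in percent, \[0, 100\].
#' @export
rgb_to_lightness <- function(r, g, b) {
  validate_rgb(r, g, b)
  (pmax(r, g, b) + pmin(r, g, b)) / 2 / 255 * 100
}

#' Intensity of an RGB triple
#'
#' `I = (R + G + B) / 3`, kept on the 0-255 scale. Intensity is linear in
#' the channels, so the intensity of a replicate-mean RGB equals the mean
#' of per-replicate intensities.
#'
#' @inheritParams rgb_to_hue
#' @return Intensity on the 0-255 scale.
#' @export
rgb_to_intensity <- function(r, g, b) {
  validate_rgb(r, g, b)
  (r + g + b) / 3
}

#' Expand RGB into the eight-channel color vector
#'
#' Computes I, H, S, V, L from the same RGB triple(s) and returns the full
#' channel observation used as the PLS feature vector.
#'
#' @param rgb a length-3 numeric vector `c(R, G, B)`, or an n x 3 matrix /
#'   data frame of triples (columns R, G, B).
#' @return A data frame with columns `R, G, B, I, H, S, V, L`, one row per
#'   input triple. `H` is `NA` for achromatic inputs.
#' @examples
#' expand_channels(c(181.0, 125.0, 1.7))
#' @export
expand_channels <- function(rgb) {
  if (is.data.frame(rgb)) rgb <- as.matrix(rgb[, c("R", "G", "B")])
  if (is.null(dim(rgb))) {
    if (length(rgb) != 3)
      stop("rgb must be a length-3 vector or an n x 3 matrix", call. = FALSE)
    rgb <- matrix(rgb, nrow = 1)
  }
  if (ncol(rgb) != 3) stop("rgb must have 3 columns (R, G, B)", call. = FALSE)
  r <- as.numeric(rgb[, 1]); g <- as.numeric(rgb[, 2]); b <- as.numeric(rgb[, 3])
  validate_rgb(r, g, b)
  data.frame(
    R = r, G = g, B = b,
    I = rgb_to_intensity(r, g, b),
    H = rgb_to_hue(r, g, b),
    S = rgb_to_saturation(r, g, b),
    V = rgb_to_value(r, g, b),
    L = rgb_to_lightness(r, g, b)
  )
}
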