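#' Gabor dictionary configuration
#'
#' The analysis decomposes each image over a fixed dictionary of Gabor
#' wavelets: every pixel position, crossed with a set of spatial-frequency
#' (SF) levels and orientation levels. The default configuration is the one
#' used throughout the package: 20 SF levels geometrically spaced between
#' 2.4 and 87 cycles per image (cpi), 12 orientations in 15-degree steps up
#' to 180 degrees, and 2200 retained features per image.
#'
#' Orientation is the direction of the carrier's wavefront normal, measured
#' counter-clockwise from the horizontal image axis: 90 degrees means
#' horizontally oriented structure (horizontal stripes), 180 degrees means
#' vertically oriented structure. Pixel coordinates are 0-based, `x` is the
#' column and `y` the row, origin at the top-left corner.
#'
#' @param image_size Side of the (square) images, in pixels.
#' @param n_sf Number of SF levels.
#' @param sf_min,sf_max Lowest and highest SF level, in cycles per image.
#' @param n_orientations Number of orientation levels.
#' @param orientation_step Orientation spacing in degrees; levels are
#'   `orientation_step, 2*orientation_step, ..., 180`.
#' @param n_features Number of wavelets retained per image.
#' @param size_multiplier Envelope standard deviation expressed in carrier
#'   wavelengths; the default 1 gives roughly half-octave bandwidth,
#'   which keeps selections from chaining across neighbouring channels.
#' @param selection_mode `"rank"` (one-shot ranking of fit scores, the
#'   default) or `"pursuit"` (greedy matching pursuit on the residual).
#' @param min_separation_fraction Minimum distance, in wavelengths, between
#'   the centres of two selected atoms of the same SF/orientation channel.
#'   The quadrature fit magnitude decays only with envelope overlap
#'   (exp(-d^2/(4 sd^2))), so the separation must scale with the envelope:
#'   the default of 2 wavelengths (= 2 envelope sds at the default
#'   `size_multiplier`) keeps same-channel atoms below ~0.4 mutual
#'   correlation.
#'
#' @return An object of class `dfm_config` (a named list).
#' @examples
#' cfg <- dfm_config(image_size = 64, n_features = 200)
#' sf_levels(cfg)
#' @export
dfm_config <- function(image_size = 250,
                       n_sf = 20, sf_min = 2.4, sf_max = 87,
                       n_orientations = 12, orientation_step = 15,
                       n_features = 2200,
                       size_multiplier = 1,
                       selection_mode = c("rank", "pursuit"),
                       min_separation_fraction = 2) {
  selection_mode <- match.arg(selection_mode)
  if (image_size < 2) stop("invalid config: image_size must be >= 2", call. = FALSE)
  if (n_sf < 2) stop("invalid config: n_sf must be >= 2", call. = FALSE)
  if (!(sf_min > 0 && sf_max > sf_min)) {
    stop("invalid config: need 0 < sf_min < sf_max", call. = FALSE)
  }
  if (n_orientations < 1) stop("invalid config: n_orientations must be >= 1", call. = FALSE)
  if (abs(n_orientations * orientation_step - 180) > 1e-9) {
    stop("invalid config: orientation levels must tile (0, 180] exactly", call. = FALSE)
  }
  if (n_features < 1) stop("invalid config: n_features must be >= 1", call. = FALSE)
  if (size_multiplier <= 0) stop("invalid config: size_multiplier must be > 0", call. = FALSE)
  structure(list(
    image_size = as.integer(image_size),
    n_sf = as.integer(n_sf), sf_min = sf_min, sf_max = sf_max,
    n_orientations = as.integer(n_orientations),
    orientation_step = orientation_step,
    n_features = as.integer(n_features),
    size_multiplier = size_multiplier,
    selection_mode = selection_mode,
    min_separation_fraction = min_separation_fraction
  ), class = "dfm_config")
}

#' @export
print.dfm_config <- function(x, ...) {
  cat("<dfm_config> ", x$image_size, "x", x$image_size, " px, ",
      x$n_sf, " SFs [", x$sf_min, "-", x$sf_max, " cpi] x ",
      x$n_orientations, " orientations, ", x$n_features, " features (",
      x$selection_mode, " mode)\n", sep = "")
  invisible(x)
}

#' Spatial-frequency levels of a dictionary
#'
#' Levels are geometrically (log-uniformly) spaced: the ratio between
#' consecutive levels is constant, the first level equals `sf_min` and the
#' last equals `sf_max`.
#'
#' @param config A [dfm_config()].
#' @return Numeric vector of `n_sf` SF values in cycles per image.
#' @export
sf_levels <- function(config) {
  with(config, sf_min * (sf_max / sf_min)^((seq_len(n_sf) - 1) / (n_sf - 1)))
}

#' Orientation levels of a dictionary
#'
#' @param config A [dfm_config()].
#' @return Numeric vector of `n_orientations` orientations in degrees,
#'   `(0, 180]`.
#' @export
orientation_levels <- function(config) {
  config$orientation_step * seq_len(config$n_orientations)
}

#' Envelope standard deviation for an SF level
#'
#' One isotropic Gaussian envelope size per SF:
#' `size_multiplier * wavelength`, wavelength in pixels
#' (`image_size / sf`).
#'
#' @param sf SF in cycles per image.
#' @param config A [dfm_config()].
#' @return Envelope sd in pixels.
#' @export
envelope_sd <- function(sf, config) {
  config$size_multiplier * config$image_size / sf
}

#' Render a single Gabor wavelet
#'
#' Cosine carrier at the given SF and orientation, windowed by an isotropic
#' Gaussian envelope centred at `(x, y)` (0-based pixel coordinates,
#' x = column, y = row), scaled by `amplitude`. Phase is referenced to the
#' centre.
#'
#' @param x,y Centre, 0-based pixels.
#' @param sf Spatial frequency in cycles per image.
#' @param orientation Degrees in `(0, 180]`; see [dfm_config()] for the
#'   convention.
#' @param envelope_sd Gaussian envelope sd, pixels (> 0).
#' @param phase Carrier phase at the centre, radians.
#' @param amplitude Peak carrier amplitude.
#' @param image_size Output image side, pixels.
#' @return `image_size` x `image_size` numeric matrix (rows = y, cols = x).
#' @examples
#' g <- render_gabor(32, 32, sf = 4, orientation = 90, envelope_sd = 8,
#'                   image_size = 64)
#' @export
render_gabor <- function(x, y, sf, orientation, envelope_sd,
                         phase = 0, amplitude = 1, image_size) {
  stopifnot(envelope_sd > 0, x >= 0, y >= 0, x < image_size, y < image_size)
  th <- orientation * pi / 180
  f <- sf / image_size
  xs <- seq_len(image_size) - 1
  dx <- matrix(xs - x, image_size, image_size, byrow = TRUE)
  dy <- matrix(xs - y, image_size, image_size)
  u <- dx * cos(th) + dy * sin(th)
  amplitude * exp(-(dx^2 + dy^2) / (2 * envelope_sd^2)) *
    cos(2 * pi * f * u + phase)
}

# Quadrature kernel pair of one channel, truncated at 4 sd.
# Returns list(even, odd, radius, gram = c(gee, goo, geo)).
channel_kernels <- function(sf, orientation, config) {
  sd <- envelope_sd(sf, config)
  r <- as.integer(ceiling(4 * sd))
  th <- orientation * pi / 180
  f <- sf / config$image_size
  s <- seq(-r, r)
  n <- 2L * r + 1L
  dx <- matrix(s, n, n, byrow = TRUE)
  dy <- matrix(s, n, n)
  env <- exp(-(dx^2 + dy^2) / (2 * sd^2))
  u <- 2 * pi * f * (dx * cos(th) + dy * sin(th))
  e <- env * cos(u)
  o <- env * sin(u)
  list(even = e, odd = o, radius = r,
       gram = c(gee = sum(e * e), goo = sum(o * o), geo = sum(e * o)),
       s2 = sum(env^2))
}
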