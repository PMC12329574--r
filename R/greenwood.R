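#' Greenwood cochlear frequency-position map
#'
#' The Greenwood function relates normalized cochlear place `x` (0 at the
#' apex, 1 at the base) to characteristic frequency `f` via
#' `f = A * (10^(a * x) - k)`. Filter bands spaced equally on the position
#' scale ("cochlear-spaced" bands) approximate equal lengths of basilar
#' membrane per channel, the usual choice for noise-vocoder filterbanks.
#'
#' The default constants (`scale_hz = 165.4`, `exponent = 2.1`,
#' `offset = 1`) are the human-map values used by this package's vocoder.
#' Note the integer offset: the frequently quoted `k = 0.88` variant yields
#' slightly different band edges (about 297 Hz instead of 311 Hz for the
#' second edge of a 4-band 50-5000 Hz filterbank).
#'
#' @param scale_hz Frequency scale constant `A` in Hz.
#' @param exponent Dimensionless exponent coefficient `a`.
#' @param offset Dimensionless subtractive constant `k`.
#' @return An object of class `greenwood_map`.
#' @examples
#' m <- greenwood_map()
#' gw_frequency(m, gw_position(m, 1000))  # round-trips to 1000 Hz
#' @export
greenwood_map <- function(scale_hz = 165.4, exponent = 2.1, offset = 1.0) {
  stopifnot(is.numeric(scale_hz), scale_hz > 0,
            is.numeric(exponent), exponent > 0,
            is.numeric(offset))
  structure(list(scale_hz = scale_hz, exponent = exponent, offset = offset),
            class = "greenwood_map")
}

#' @export
print.greenwood_map <- function(x, ...) {
  cat(sprintf("Greenwood map: f = %.4g * (10^(%.4g * x) - %.4g)\n",
              x$scale_hz, x$exponent, x$offset))
  invisible(x)
}

#' Map frequency to cochlear position
#'
#' Inverse of [gw_frequency()]: `x = log10(f / A + k) / a`.
#'
#' @param map A [greenwood_map()].
#' @param f Frequency in Hz (vectorized). Must satisfy `f / A + k > 0`.
#' @return Normalized cochlear position(s).
#' @export
gw_position <- function(map, f) {
  stopifnot(inherits(map, "greenwood_map"), is.numeric(f))
  arg <- f / map$scale_hz + map$offset
  if (any(arg <= 0)) {
    stop("frequency outside the valid range of the Greenwood map")
  }
  log10(arg) / map$exponent
}

#' Map cochlear position to frequency
#'
#' @param map A [greenwood_map()].
#' @param x Normalized cochlear position (vectorized).
#' @return Frequency in Hz.
#' @export
gw_frequency <- function(map, x) {
  stopifnot(inherits(map, "greenwood_map"), is.numeric(x))
  map$scale_hz * (10^(map$exponent * x) - map$offset)
}

#' Greenwood-spaced filterbank band edges
#'
#' Computes the `n + 1` band-edge frequencies of an `n`-channel filterbank
#' spanning `[f_lo, f_hi]`, with interior edges placed at equally spaced
#' cochlear positions between `gw_position(map, f_lo)` and
#' `gw_position(map, f_hi)`. The outer edges are returned exactly as given.
#'
#' With the human map and the 50-5000 Hz span used for vocoded sentence
#' stimuli, the lower edges round to 50, 311, 889, 2169 Hz (4 bands) and
#' 50, 155, 311, 544, 889, 1404, 2169, 3307 Hz (8 bands).
#'
#' @param map A [greenwood_map()].
#' @param n Number of bands (positive integer).
#' @param f_lo,f_hi Filterbank span in Hz, `0 < f_lo < f_hi`.
#' @return Numeric vector of `n + 1` strictly increasing edge frequencies.
#' @examples
#' round(band_edges(greenwood_map(), 4, 50, 5000))
#' @export
band_edges <- function(map, n, f_lo, f_hi) {
  stopifnot(inherits(map, "greenwood_map"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer")
  }
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || f_lo <= 0 || f_lo >= f_hi) {
    stop("need 0 < f_lo < f_hi")
  }
  x <- seq(gw_position(map, f_lo), gw_position(map, f_hi), length.out = n + 1L)
  edges <- gw_frequency(map, x)
  # pin the outer edges to the requested span exactly
  edges[1L] <- f_lo
  edges[n + 1L] <- f_hi
  edges
}
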