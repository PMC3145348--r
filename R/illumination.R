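#' Estimate a per-channel illumination function
#'
#' Averages all images of a channel and smooths the average with a large
#' square median filter, yielding a smooth estimate of the spatial shading
#' shared by the whole image set. The surface is clipped below at 1e-6 and
#' normalized to mean 1, so dividing an image by it leaves intensities on
#' the original scale on average. Averaging (rather than summing) before
#' smoothing differs from accumulating a raw sum only by a constant factor,
#' which the mean-1 normalization removes, and keeps the accumulator in
#' [0,1].
#'
#' The median filter is EBImage's constant-time median with window side
#' \code{filterSize} (internally 16-bit quantized, an error of order 1/65535
#' that is negligible against the shading amplitudes being corrected);
#' borders are handled by the filter's reflective padding, so the estimate
#' is most trustworthy away from the image border.
#'
#' @param rasters list of intensity rasters, identical dimensions
#' @param filterSize odd integer window side, default 151
#' @param channel channel name recorded in the result
#' @return an \code{\linkS4class{IlluminationFunction}}
#' @export
estimateIllumination <- function(rasters, filterSize = 151L,
                                 channel = "unknown") {
  if (!is.list(rasters) || length(rasters) < 1)
    stop("need at least one raster")
  filterSize <- as.integer(filterSize)
  if (filterSize %% 2L != 1L || filterSize < 3L)
    stop("filterSize must be an odd integer >= 3")
  dims <- dim(rasters[[1]])
  for (r in rasters) {
    checkIntensityRaster(r)
    if (!identical(dim(r), dims))
      stop("all rasters must share the same dimensions")
  }
  if (filterSize > max(dims))
    stop("filterSize exceeds both image dimensions")
  avg <- Reduce(`+`, rasters) / length(rasters)
  # EBImage medianFilter takes a radius; window side = 2*radius + 1
  # the square window is symmetric, so the (row, col) orientation is
  # preserved without transposition
  sm <- as.matrix(EBImage::medianFilter(avg, size = (filterSize - 1L) %/% 2L))
  sm <- pmax(sm, 1e-6)
  sm <- sm / mean(sm)
  new("IlluminationFunction", surface = sm, channel = channel,
      filterSize = filterSize)
}

#' Divide an image by its channel's illumination function
#'
#' Flat-field correction: the raster is divided pixel-wise by the
#' illumination surface and the result clipped back into [0,1]. When more
#' than 1\% of pixels are clipped a message reports the fraction, since
#' heavy clipping means the surface normalization and the image intensities
#' are out of scale.
#'
#' @param raster intensity raster
#' @param fn an \code{\linkS4class{IlluminationFunction}} with matching
#'   dimensions
#' @return corrected intensity raster
#' @export
applyIllumination <- function(raster, fn) {
  stopifnot(is(fn, "IlluminationFunction"))
  checkIntensityRaster(raster)
  if (!identical(dim(raster), dim(fn@surface)))
    stop("raster and illumination surface dimensions differ")
  out <- raster / fn@surface
  nclip <- sum(out > 1)
  if (nclip > 0.01 * length(out))
    message(sprintf("illumination correction clipped %.1f%% of pixels",
                    100 * nclip / length(out)))
  pmin(pmax(out, 0), 1)
}
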