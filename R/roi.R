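#' Region-of-interest geometry
#'
#' Describes one imaged field. The defaults correspond to the standard
#' acquisition used throughout: a 41 x 41 micrometre field rendered on a
#' 256 x 256 pixel grid (pixel size about 160.2 nm), 25,000 camera frames
#' at 10 ms exposure.
#'
#' Coordinates are in nanometres with the origin at the top-left corner of
#' the ROI and y increasing downward (image convention). Pixel indices are
#' 0-based; pixel (i, j) covers the half-open interval
#' `[j*px, (j+1)*px) x [i*px, (i+1)*px)` in nm, where `px` is the pixel
#' size `width_nm / pixels_per_side`.
#'
#' @param width_nm,height_nm field extent in nm (must be positive).
#' @param pixels_per_side number of pixels along each side (>= 2).
#' @param n_frames number of camera frames acquired (>= 1).
#' @param exposure_ms exposure time per frame in milliseconds.
#' @return An object of class `roi_geometry`: a list with the above fields
#'   plus the derived `pixel_size_nm` and `area_um2`.
#' @examples
#' roi <- roi_geometry()
#' roi$pixel_size_nm  # ~160.2 nm
#' @export
roi_geometry <- function(width_nm = 41000, height_nm = 41000,
                         pixels_per_side = 256, n_frames = 25000,
                         exposure_ms = 10) {
  check_number(width_nm, "width_nm", lower = 1e-9)
  check_number(height_nm, "height_nm", lower = 1e-9)
  check_number(pixels_per_side, "pixels_per_side", lower = 2)
  check_number(n_frames, "n_frames", lower = 1)
  check_number(exposure_ms, "exposure_ms", lower = 1e-9)
  structure(list(
    width_nm = width_nm, height_nm = height_nm,
    pixels_per_side = as.integer(pixels_per_side),
    n_frames = as.integer(n_frames), exposure_ms = exposure_ms,
    pixel_size_nm = width_nm / pixels_per_side,
    area_um2 = width_nm * height_nm / 1e6
  ), class = "roi_geometry")
}

#' @export
print.roi_geometry <- function(x, ...) {
  cat(sprintf("ROI %.1f x %.1f um, %d x %d px (%.1f nm/px), %d frames @ %g ms\n",
              x$width_nm / 1000, x$height_nm / 1000, x$pixels_per_side,
              x$pixels_per_side, x$pixel_size_nm, x$n_frames, x$exposure_ms))
  invisible(x)
}

# nm coordinates -> 0-based pixel column/row (half-open pixel convention)
nm_to_pixel <- function(x_nm, y_nm, roi) {
  px <- roi$pixel_size_nm
  list(col = pmin(floor(x_nm / px), roi$pixels_per_side - 1L),
       row = pmin(floor(y_nm / px), roi$pixels_per_side - 1L))
}
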