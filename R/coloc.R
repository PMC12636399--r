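#' Binarize a reference intensity image
#'
#' Applies a single absolute threshold to the (max-normalized) reporter
#' image: mask pixels are those with value at or above the threshold.
#' The calibrated thresholds are 0.3 for tissue-derived samples and 0.4
#' for plasma-derived samples. Set `normalize = FALSE` for images that
#' are already on the normalized `[0, 1]` scale.
#'
#' @param img an [intensity_image()].
#' @param absolute_threshold threshold in (0, 1).
#' @param normalize divide by the image maximum first (default).
#' @return A `binary_mask`: logical matrix with attributes `threshold`,
#'   `pixel_size_nm`, `channel`.
#' @export
binarize_reference <- function(img, absolute_threshold = 0.4,
                               normalize = TRUE) {
  check_number(absolute_threshold, "absolute_threshold",
               lower = 1e-12, upper = 1 - 1e-12)
  mat <- unclass(img)
  attributes(mat) <- list(dim = dim(mat))
  if (normalize && max(mat) > 0) mat <- mat / max(mat)
  mask <- mat >= absolute_threshold
  structure(mask, threshold = absolute_threshold,
            pixel_size_nm = attr(img, "pixel_size_nm"),
            channel = attr(img, "channel"),
            class = c("binary_mask", class(mask)))
}

# 0-based pixel of each particle centroid
particle_pixels <- function(particles, pixel_size_nm, npx) {
  list(col = floor(particles$x_nm / pixel_size_nm),
       row = floor(particles$y_nm / pixel_size_nm))
}

#' Align the reporter mask to the localization channel
#'
#' Coarse two-channel registration by integer-pixel translation: finds
#' the shift `(dx, dy)` maximizing the number of particle centroids that
#' land on true mask pixels when looked up at `centroid_pixel - shift`.
#' Equivalently, `-shift` is the estimated displacement of the mask
#' relative to the localization channel. Ties are broken toward the
#' smallest Euclidean shift, then lexicographically by `(dx, dy)`.
#'
#' @param mask a [binarize_reference()] mask.
#' @param particles a `particle_records` table.
#' @param max_shift_nm half-width of the search window (nm).
#' @param pixel_size_nm pixel pitch; defaults to the mask's.
#' @return Integer vector `c(dx, dy)` in pixels, with attributes `score`
#'   (centroids on the mask at the optimum) and `saturated` (`TRUE` when
#'   the optimum sits on the search-window border, with a warning).
#' @export
align_channels <- function(mask, particles, max_shift_nm = 500,
                           pixel_size_nm = attr(mask, "pixel_size_nm")) {
  if (nrow(particles) == 0L || !any(mask)) {
    warning("empty mask or particle set; returning zero shift")
    return(structure(c(dx = 0L, dy = 0L), score = 0L, saturated = FALSE))
  }
  npx <- ncol(mask)
  pp <- particle_pixels(particles, pixel_size_nm, npx)
  S <- max(0L, as.integer(floor(max_shift_nm / pixel_size_nm)))
  best <- NULL
  for (dy in -S:S) for (dx in -S:S) {
    cc <- pp$col - dx; rr <- pp$row - dy
    ok <- cc >= 0 & cc < npx & rr >= 0 & rr < npx
    score <- sum(mask[cbind(rr[ok] + 1L, cc[ok] + 1L)])
    cand <- list(dx = dx, dy = dy, score = score, norm = dx^2 + dy^2)
    if (is.null(best) || score > best$score ||
        (score == best$score && (cand$norm < best$norm ||
          (cand$norm == best$norm &&
           (dx < best$dx || (dx == best$dx && dy < best$dy))))))
      best <- cand
  }
  saturated <- abs(best$dx) == S || abs(best$dy) == S
  if (saturated && S > 0)
    warning("alignment optimum on the search-window border; ",
            "consider a larger max_shift_nm")
  structure(c(dx = best$dx, dy = best$dy), score = best$score,
            saturated = saturated)
}

#' Flag reporter-positive particles
#'
#' A particle is reporter-positive when its centroid pixel, after
#' applying the alignment shift (lookup at `centroid_pixel - shift`),
#' is true in the binary mask. Centroids falling outside the image after
#' the shift are negative (counted in the `n_outside` attribute).
#'
#' @param particles a `particle_records` table.
#' @param mask a [binarize_reference()] mask.
#' @param shift integer `c(dx, dy)` from [align_channels()].
#' @param pixel_size_nm pixel pitch; defaults to the mask's.
#' @return The particle table with a logical `reporter_positive` column;
#'   attributes `positive_fraction` and `n_outside`.
#' @export
flag_positive_particles <- function(particles, mask, shift = c(0L, 0L),
                                    pixel_size_nm = attr(mask, "pixel_size_nm")) {
  npx <- ncol(mask)
  n <- nrow(particles)
  pos <- logical(n)
  outside <- 0L
  if (n > 0L) {
    pp <- particle_pixels(particles, pixel_size_nm, npx)
    cc <- pp$col - shift[1L]; rr <- pp$row - shift[2L]
    inb <- cc >= 0 & cc < npx & rr >= 0 & rr < npx
    outside <- sum(!inb)
    pos[inb] <- mask[cbind(rr[inb] + 1L, cc[inb] + 1L)]
  }
  particles$reporter_positive <- pos
  attr(particles, "positive_fraction") <- if (n > 0L) mean(pos) else NA_real_
  attr(particles, "n_outside") <- outside
  particles
}
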