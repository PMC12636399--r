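#' Sample a ground-truth particle field
#'
#' Draws a Poisson number of particles per class, places centroids
#' uniformly in the ROI (respecting an edge margin), samples per-particle
#' diameter, axial ratio and orientation from the class model, and
#' scatters cargo molecules uniformly inside each particle's ellipse,
#' thinned by the class labelling efficiency. The stored cargo positions
#' are therefore the *labelled* molecules -- the ones that can emit
#' localizations.
#'
#' @param class_mix named numeric vector or list mapping class name to the
#'   expected particle count per ROI (Poisson rate, >= 0).
#' @param roi an [roi_geometry()].
#' @param classes registry of [particle_class()] models; defaults to
#'   [default_particle_classes()].
#' @param reporter_fraction probability that a particle is positive for
#'   the second-channel reporter (e.g. mNeonGreen).
#' @param edge_margin_nm centroids are kept at least this far from the
#'   ROI border so particles are not truncated by the field edge.
#' @param seed integer seed; the draw is fully reproducible given
#'   `(arguments, seed)`.
#' @return A `particle_truth` data frame with one row per particle:
#'   `particle_id` (0-based, unique within the ROI), `class_name`,
#'   centroid `x_nm`/`y_nm`, `diameter_nm`, `axial_ratio`, `orientation`
#'   (radians), `n_cargo`, `reporter_positive`, and a list column `cargo`
#'   holding an `n x 2` matrix of labelled cargo positions (nm) per
#'   particle.
#' @examples
#' roi <- roi_geometry()
#' truth <- sample_particles(c(EV = 20), roi, seed = 1)
#' nrow(truth)
#' @export
sample_particles <- function(class_mix, roi,
                             classes = default_particle_classes(),
                             reporter_fraction = 0, edge_margin_nm = 500,
                             seed = NULL) {
  stopifnot(inherits(roi, "roi_geometry"))
  class_mix <- unlist(class_mix)
  if (is.null(names(class_mix)) || any(!nzchar(names(class_mix))))
    stopf("'class_mix' must be named by particle class")
  for (nm in names(class_mix)) {
    if (!is.finite(class_mix[[nm]]) || class_mix[[nm]] < 0)
      stopf("expected count for class '%s' must be >= 0", nm)
    if (is.null(classes[[nm]]))
      stopf("class '%s' is not in the class registry", nm)
  }
  check_number(reporter_fraction, "reporter_fraction", 0, 1)
  m <- edge_margin_nm
  if (2 * m >= min(roi$width_nm, roi$height_nm))
    stopf("edge_margin_nm too large for the ROI")

  with_seed(seed, {
    rows <- list()
    for (nm in names(class_mix)) {
      n <- rpois(1L, class_mix[[nm]])
      if (n == 0L) next
      cl <- classes[[nm]]
      diam <- sample_dist(cl$diameter_dist, n)
      ar <- pmax(1, sample_dist(cl$axial_ratio_dist, n))
      ori <- runif(n, 0, pi)
      cx <- runif(n, m, roi$width_nm - m)
      cy <- runif(n, m, roi$height_nm - m)
      ncargo_drawn <- pmax(1L, as.integer(round(sample_dist(cl$cargo_count_dist, n))))
      cargo <- vector("list", n)
      ncargo <- integer(n)
      for (k in seq_len(n)) {
        keep <- runif(ncargo_drawn[k]) <= cl$labeling_efficiency
        nk <- sum(keep)
        cargo[[k]] <- cargo_in_ellipse(nk, cx[k], cy[k], diam[k], ar[k], ori[k])
        ncargo[k] <- nk
      }
      rows[[nm]] <- data.frame(
        class_name = nm, x_nm = cx, y_nm = cy, diameter_nm = diam,
        axial_ratio = ar, orientation = ori, n_cargo = ncargo,
        reporter_positive = runif(n) < reporter_fraction,
        stringsAsFactors = FALSE)
      rows[[nm]]$cargo <- cargo
    }
    out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
           else data.frame(class_name = character(), x_nm = numeric(),
                           y_nm = numeric(), diameter_nm = numeric(),
                           axial_ratio = numeric(), orientation = numeric(),
                           n_cargo = integer(),
                           reporter_positive = logical(),
                           cargo = I(list()))
    out <- cbind(particle_id = seq_len(nrow(out)) - 1L, out)
    attr(out, "roi") <- roi
    class(out) <- c("particle_truth", "data.frame")
    out
  })
}

# uniform points inside an ellipse: diameter = 2*sqrt(a*b) (area-equivalent),
# axial ratio ar = a/b, rotated by `theta`
cargo_in_ellipse <- function(n, cx, cy, diameter, ar, theta) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L,
                             dimnames = list(NULL, c("x_nm", "y_nm"))))
  r_eq <- diameter / 2
  a <- r_eq * sqrt(ar); b <- r_eq / sqrt(ar)
  r <- sqrt(runif(n)); phi <- runif(n, 0, 2 * pi)
  u <- a * r * cos(phi); v <- b * r * sin(phi)
  x <- cx + u * cos(theta) - v * sin(theta)
  y <- cy + u * sin(theta) + v * cos(theta)
  cbind(x_nm = x, y_nm = y)
}

# number of localizations per labelled molecule: support {1, 2, ...},
# mean alpha
draw_blink_counts <- function(n, alpha, dist = c("geometric", "poisson")) {
  dist <- match.arg(dist)
  if (n == 0L) return(integer(0))
  if (dist == "geometric") {
    # geometric number of on-events: failures + 1, mean 1/p = alpha
    rgeom(n, prob = 1 / alpha) + 1L
  } else {
    # zero-truncated Poisson with mean alpha: solve lambda/(1-e^-lambda)=alpha
    lambda <- if (alpha <= 1) 1e-8 else
      uniroot(function(l) l / (1 - exp(-l)) - alpha,
              c(1e-8, alpha + 10))$root
    k <- rpois(n, lambda)
    while (any(k == 0L)) k[k == 0L] <- rpois(sum(k == 0L), lambda)
    k
  }
}

#' Emit a localization table from ground truth
#'
#' Every labelled cargo molecule blinks a random number of times (mean
#' `alpha` of the probe; geometric by default, zero-truncated Poisson as
#' an alternative), and each blink is localized at the molecule position
#' plus isotropic Gaussian error with sd `loc_precision_sigma_nm`.
#' Background localizations are added as a uniform Poisson scatter per
#' the [noise_model()]. Frames are assigned uniformly at random over the
#' acquisition. Localizations that fall outside the ROI are discarded
#' (not clamped); the discard count is recorded.
#'
#' @param truth a `particle_truth` from [sample_particles()] (may have
#'   zero rows).
#' @param fluor a [fluorophore()].
#' @param noise a [noise_model()].
#' @param roi an [roi_geometry()].
#' @param channel channel label stored with every row.
#' @param blink_dist per-molecule localization-count distribution.
#' @param intensity constant intensity (photons) written to the intensity
#'   column; nothing downstream depends on it.
#' @param seed integer seed for reproducibility.
#' @return A `loc_table` (see [loc_table()]) with columns `x_nm`, `y_nm`,
#'   `frame`, `intensity`, `channel` and attributes `n_before_discard`
#'   (rows drawn before ROI-boundary rejection), `n_discarded`, and
#'   `source_particle` (the 0-based particle id per retained row, NA for
#'   background) for recovery diagnostics.
#' @export
emit_localizations <- function(truth, fluor, noise, roi,
                               channel = "ch640",
                               blink_dist = c("geometric", "poisson"),
                               intensity = 1000, seed = NULL) {
  stopifnot(inherits(fluor, "fluorophore"), inherits(noise, "noise_model"),
            inherits(roi, "roi_geometry"))
  blink_dist <- match.arg(blink_dist)

  with_seed(seed, {
    cargo_all <- if (nrow(truth)) do.call(rbind, truth$cargo) else
      matrix(numeric(0), 0L, 2L)
    pid_all <- if (nrow(truth))
      rep(truth$particle_id, vapply(truth$cargo, nrow, 1L)) else integer(0)
    nmol <- nrow(cargo_all)

    counts <- draw_blink_counts(nmol, fluor$alpha, blink_dist)
    idx <- rep.int(seq_len(nmol), counts)
    sig <- sum(counts)
    x <- cargo_all[idx, 1L] + rnorm(sig, 0, fluor$loc_precision_sigma_nm)
    y <- cargo_all[idx, 2L] + rnorm(sig, 0, fluor$loc_precision_sigma_nm)
    src <- pid_all[idx]

    nbg <- rpois(1L, noise$background_loc_rate * roi$area_um2)
    if (nbg > 0L) {
      bx <- runif(nbg, 0, roi$width_nm)
      by <- runif(nbg, 0, roi$height_nm)
      if (noise$false_loc_sigma > 0) {
        bx <- bx + rnorm(nbg, 0, noise$false_loc_sigma)
        by <- by + rnorm(nbg, 0, noise$false_loc_sigma)
      }
      x <- c(x, bx); y <- c(y, by); src <- c(src, rep(NA_integer_, nbg))
    }
    n_total <- sig + nbg

    keep <- x >= 0 & x <= roi$width_nm & y >= 0 & y <= roi$height_nm
    frames <- sample.int(roi$n_frames, n_total, replace = TRUE)

    tab <- loc_table(
      x_nm = x[keep], y_nm = y[keep], frame = frames[keep],
      intensity = rep(intensity, sum(keep)),
      channel = rep(channel, sum(keep)), roi = roi)
    attr(tab, "n_before_discard") <- n_total
    attr(tab, "n_discarded") <- n_total - sum(keep)
    attr(tab, "source_particle") <- src[keep]
    tab
  })
}

#' Render the reporter-channel intensity image
#'
#' Simulates the already-reconstructed second-channel image (e.g. the
#' eSRRF output for an mNeonGreen reporter) as a Gaussian-PSF rendering
#' of the reporter-positive particles, normalized to `[0, 1]`. Optional
#' sparse false spots emulate nonspecific background in the reporter
#' channel; with the default rate 0 the image is exactly zero when no
#' particle is reporter-positive.
#'
#' @param truth a `particle_truth`.
#' @param roi an [roi_geometry()].
#' @param psf_sigma_nm width of the rendered spot (nm).
#' @param false_spot_rate_um2 expected false spots per square micrometre.
#' @param false_spot_amp amplitude range of false spots relative to a
#'   unit particle spot.
#' @param channel channel label.
#' @param seed integer seed (used for the false spots).
#' @return An `intensity_image`: a `pixels_per_side` square numeric
#'   matrix (rows = y) with values in `[0, 1]`, with attributes
#'   `pixel_size_nm` and `channel`.
#' @export
render_reporter_image <- function(truth, roi, psf_sigma_nm = 250,
                                  false_spot_rate_um2 = 0,
                                  false_spot_amp = c(0.1, 0.3),
                                  channel = "ch561", seed = NULL) {
  stopifnot(inherits(roi, "roi_geometry"))
  check_number(psf_sigma_nm, "psf_sigma_nm", lower = 1e-9)
  np <- roi$pixels_per_side
  px <- roi$pixel_size_nm
  img <- matrix(0, np, np)
  centers <- (seq_len(np) - 0.5) * px  # pixel-centre coordinates

  add_spot <- function(img, cx, cy, amp) {
    gx <- exp(-(centers - cx)^2 / (2 * psf_sigma_nm^2))
    gy <- exp(-(centers - cy)^2 / (2 * psf_sigma_nm^2))
    img + amp * outer(gy, gx)
  }

  with_seed(seed, {
    pos <- truth[truth$reporter_positive %in% TRUE, , drop = FALSE]
    for (k in seq_len(nrow(pos)))
      img <- add_spot(img, pos$x_nm[k], pos$y_nm[k], 1)
    nspot <- if (false_spot_rate_um2 > 0)
      rpois(1L, false_spot_rate_um2 * roi$area_um2) else 0L
    if (nspot > 0L) {
      sx <- runif(nspot, 0, roi$width_nm)
      sy <- runif(nspot, 0, roi$height_nm)
      sa <- runif(nspot, false_spot_amp[1L], false_spot_amp[2L])
      for (k in seq_len(nspot)) img <- add_spot(img, sx[k], sy[k], sa[k])
    }
    if (max(img) > 0) img <- img / max(img)
    intensity_image(img, pixel_size_nm = px, channel = channel)
  })
}

#' Buffer-control localization table
#'
#' A particle-free field: only background localizations, the synthetic
#' analogue of imaging a buffer blank. Running the full pipeline on this
#' input must yield a near-zero particle count.
#'
#' @inheritParams emit_localizations
#' @return A `loc_table` with background rows only.
#' @export
make_buffer_control <- function(roi, noise, fluor = fluorophore_registry()[["antibody-AF647"]],
                                channel = "ch640", seed = NULL) {
  empty <- sample_particles(c(EV = 0), roi, seed = 0L)
  emit_localizations(empty, fluor, noise, roi, channel = channel, seed = seed)
}
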