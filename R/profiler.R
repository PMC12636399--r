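#' Cluster admission rules
#'
#' The assay's filter set, with the human-sample defaults: small
#' clusters (20-100 nm equivalent-circle diameter) are admitted when
#' they carry between `small_min_factor x alpha` (2 x alpha) and 2,000
#' localizations; large clusters (diameter above 100 nm) when they carry
#' between 100 and 15,000 localizations. Both bounds are inclusive.
#' Clusters below the small-range lower bound are rejected as fragments.
#' An optional `size_cap_nm` (250 nm, used for SNA capture with SNA
#' detection) rejects large clusters above the cap. `mouse_mode` switches
#' to the mouse-sample rules: small range 30-100 nm with a 2.5 x alpha
#' minimum, large-cluster settings unchanged.
#'
#' @param small_range_nm diameter interval of the small class (nm).
#' @param small_min_factor minimum localizations for small clusters, in
#'   units of alpha.
#' @param small_max_loc maximum localizations for small clusters.
#' @param large_min_loc,large_max_loc localization bounds for large
#'   clusters.
#' @param size_cap_nm optional maximum diameter for large clusters.
#' @param mouse_mode apply the mouse-sample small-cluster rules.
#' @return An object of class `cluster_filter_config`.
#' @export
cluster_filter_config <- function(small_range_nm = c(20, 100),
                                  small_min_factor = 2,
                                  small_max_loc = 2000,
                                  large_min_loc = 100,
                                  large_max_loc = 15000,
                                  size_cap_nm = NULL,
                                  mouse_mode = FALSE) {
  if (isTRUE(mouse_mode)) {
    if (missing(small_range_nm)) small_range_nm <- c(30, 100)
    if (missing(small_min_factor)) small_min_factor <- 2.5
  }
  if (length(small_range_nm) != 2L || small_range_nm[1] >= small_range_nm[2])
    stopf("small_range_nm must be an interval with lower < upper")
  check_number(small_min_factor, "small_min_factor", lower = 1e-9)
  check_number(small_max_loc, "small_max_loc", lower = 1)
  check_number(large_min_loc, "large_min_loc", lower = 1)
  check_number(large_max_loc, "large_max_loc", lower = 1)
  if (large_min_loc > large_max_loc || small_max_loc < 1)
    stopf("filter bounds must satisfy min <= max")
  if (!is.null(size_cap_nm)) {
    check_number(size_cap_nm, "size_cap_nm", lower = small_range_nm[2])
  }
  structure(list(small_range_nm = small_range_nm,
                 small_min_factor = small_min_factor,
                 small_max_loc = small_max_loc,
                 large_min_loc = large_min_loc,
                 large_max_loc = large_max_loc,
                 size_cap_nm = size_cap_nm,
                 mouse_mode = isTRUE(mouse_mode)),
            class = "cluster_filter_config")
}

#' Morphology of a localization cluster
#'
#' The particle footprint is the convex hull of the cluster's
#' localizations. Reported metrics: equivalent-circle diameter
#' `2 * sqrt(hull area / pi)`, circularity `4 * pi * area / perimeter^2`
#' (1 for a perfect circle), eccentricity
#' `sqrt(1 - lambda2 / lambda1)` from the eigenvalues of the unweighted
#' localization covariance (0 for a circle), plus the maximum Feret
#' diameter (largest pairwise distance) as an auxiliary size measure.
#'
#' Clusters with fewer than 3 points, or with a degenerate (zero-area)
#' hull, get `diameter_nm` equal to the maximum pairwise distance and
#' `NA` circularity/eccentricity, flagged `degenerate` -- they are never
#' silently dropped here; the admission filter sees them.
#'
#' @param points a 2-column matrix (or data frame) of nm coordinates.
#' @return A list: `diameter_nm`, `feret_nm`, `circularity`,
#'   `eccentricity`, `hull_area_nm2`, `centroid` (length-2),
#'   `degenerate`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 1000)
#' compute_morphology(cbind(50 * cos(th), 50 * sin(th)))$circularity
#' @export
compute_morphology <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  centroid <- colMeans(pts)
  maxpair <- function(p) {
    if (nrow(p) < 2L) return(0)
    d <- 0
    for (i in seq_len(nrow(p) - 1L)) {
      di <- (p[(i + 1L):nrow(p), 1L] - p[i, 1L])^2 +
            (p[(i + 1L):nrow(p), 2L] - p[i, 2L])^2
      d <- max(d, di)
    }
    sqrt(d)
  }
  degen <- function() {
    list(diameter_nm = maxpair(pts), feret_nm = maxpair(pts),
         circularity = NA_real_, eccentricity = NA_real_,
         hull_area_nm2 = 0, centroid = centroid, degenerate = TRUE)
  }
  if (n < 3L) return(degen())
  h <- chull(pts)
  hull <- pts[h, , drop = FALSE]
  A <- polygon_area(hull[, 1L], hull[, 2L])
  if (A <= 0 || nrow(hull) < 3L) return(degen())
  P <- polygon_perimeter(hull[, 1L], hull[, 2L])
  ev <- eigen(cov(pts), symmetric = TRUE, only.values = TRUE)$values
  ecc <- if (ev[1L] <= 0) NA_real_ else sqrt(max(0, 1 - ev[2L] / ev[1L]))
  list(diameter_nm = 2 * sqrt(A / pi),
       feret_nm = maxpair(hull),
       circularity = 4 * pi * A / P^2,
       eccentricity = ecc,
       hull_area_nm2 = A,
       centroid = centroid,
       degenerate = FALSE)
}

#' Cargo molecules from a localization count
#'
#' Converts localizations to molecules through the probe calibration
#' alpha: `round(n_loc / alpha)` with round-half-up, floored at 1 (a
#' detected particle implies at least one probe).
#'
#' @param n_loc localization count(s), >= 1.
#' @param alpha probe calibration, >= 1.
#' @return Integer molecule estimate(s).
#' @examples
#' estimate_cargo(200, 10)  # 20
#' estimate_cargo(25, 10)   # 3 (round-half-up)
#' @export
estimate_cargo <- function(n_loc, alpha) {
  check_number(alpha, "alpha", lower = 1)
  if (any(n_loc < 1)) stopf("n_loc must be >= 1")
  pmax(1L, as.integer(floor(n_loc / alpha + 0.5)))
}

#' Profile clusters into candidate particle records
#'
#' Computes morphology and centroid for every cluster of an assignment.
#' No admission decision is taken here; see [classify_and_filter()].
#'
#' @param locs a `loc_table`.
#' @param assignment a [segment_clusters()] result.
#' @return Data frame with one row per cluster: `label`, `n_loc`,
#'   `x_nm`, `y_nm`, `diameter_nm`, `feret_nm`, `circularity`,
#'   `eccentricity`, `degenerate`.
#' @export
profile_clusters <- function(locs, assignment) {
  lab <- assignment$labels
  keep <- lab >= 0L
  if (!any(keep))
    return(data.frame(label = integer(0), n_loc = integer(0),
                      x_nm = numeric(0), y_nm = numeric(0),
                      diameter_nm = numeric(0), feret_nm = numeric(0),
                      circularity = numeric(0), eccentricity = numeric(0),
                      degenerate = logical(0)))
  sp <- split(which(keep), lab[keep])
  rows <- lapply(names(sp), function(lb) {
    i <- sp[[lb]]
    m <- compute_morphology(cbind(locs$x_nm[i], locs$y_nm[i]))
    data.frame(label = as.integer(lb), n_loc = length(i),
               x_nm = m$centroid[1L], y_nm = m$centroid[2L],
               diameter_nm = m$diameter_nm, feret_nm = m$feret_nm,
               circularity = m$circularity, eccentricity = m$eccentricity,
               degenerate = m$degenerate)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Apply the admission filters
#'
#' Assigns each candidate cluster a size class by its equivalent-circle
#' diameter -- small when inside `small_range_nm` (both ends inclusive;
#' a diameter of exactly 100 nm is small), large when above the range --
#' and admits it according to the [cluster_filter_config()] rules.
#' Admitted clusters get a cargo estimate via [estimate_cargo()].
#' Every rejection is logged with a reason code.
#'
#' @param clusters candidate table from [profile_clusters()].
#' @param filter a [cluster_filter_config()].
#' @param alpha probe calibration of the detection channel.
#' @param roi_id label copied into the output.
#' @return A `particle_records` data frame of admitted particles
#'   (`particle_id`, `roi_id`, `n_loc`, `cargo_estimate`, `diameter_nm`,
#'   `feret_nm`, `circularity`, `eccentricity`, `x_nm`, `y_nm`,
#'   `size_class`), with attribute `rejections`: a data frame of
#'   `label`, `n_loc`, `diameter_nm`, `reason`.
#' @export
classify_and_filter <- function(clusters, filter, alpha, roi_id = "roi1") {
  stopifnot(inherits(filter, "cluster_filter_config"))
  check_number(alpha, "alpha", lower = 1e-9)
  n <- nrow(clusters)
  lo <- filter$small_range_nm[1L]; hi <- filter$small_range_nm[2L]
  d <- clusters$diameter_nm; nl <- clusters$n_loc
  size_class <- ifelse(d > hi, "large", ifelse(d >= lo, "small", "fragment"))
  small_min <- filter$small_min_factor * alpha

  reason <- rep(NA_character_, n)
  reason[size_class == "fragment"] <- "below_size_range"
  s <- size_class == "small"
  reason[s & nl < small_min] <- "too_few_loc_small"
  reason[s & nl > filter$small_max_loc] <- "too_many_loc_small"
  l <- size_class == "large"
  reason[l & nl < filter$large_min_loc] <- "too_few_loc_large"
  reason[l & nl > filter$large_max_loc] <- "too_many_loc_large"
  if (!is.null(filter$size_cap_nm))
    reason[l & is.na(reason) & d > filter$size_cap_nm] <- "exceeds_size_cap"

  admitted <- is.na(reason)
  out <- clusters[admitted, , drop = FALSE]
  out$size_class <- size_class[admitted]
  out$cargo_estimate <- if (nrow(out))
    estimate_cargo(out$n_loc, alpha) else integer(0)
  out$roi_id <- rep(roi_id, nrow(out))
  out$particle_id <- seq_len(nrow(out)) - 1L
  cols <- c("particle_id", "roi_id", "label", "n_loc", "cargo_estimate",
            "diameter_nm", "feret_nm", "circularity", "eccentricity",
            "x_nm", "y_nm", "size_class")
  out <- out[, intersect(cols, names(out)), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- data.frame(
    label = clusters$label[!admitted], n_loc = nl[!admitted],
    diameter_nm = d[!admitted], reason = reason[!admitted])
  attr(out, "alpha") <- alpha
  class(out) <- c("particle_records", "data.frame")
  out
}

#' Run the detection pipeline on one localization table
#'
#' Convenience wrapper: optional blink merging, Voronoi density field,
#' density segmentation, cluster profiling and admission filtering.
#'
#' @param locs a `loc_table`.
#' @param config a [load_config()] configuration (its `cluster`,
#'   `filter` and probe sections drive the stages).
#' @param roi geometry override (defaults to the table's own, then the
#'   config's).
#' @return A `particle_records` table (see [classify_and_filter()]);
#'   the segmentation is attached as attribute `assignment`.
#' @examples
#' cfg <- load_config()
#' roi <- cfg$roi_geometry
#' truth <- sample_particles(c(EV = 10), roi, seed = 7)
#' locs <- emit_localizations(truth, cfg$fluor, noise_model(), roi, seed = 7)
#' nrow(detect_particles(locs, cfg))
#' @export
detect_particles <- function(locs, config = load_config(),
                             roi = attr(locs, "roi")) {
  if (is.null(roi)) roi <- config$roi_geometry
  if (isTRUE(config$cluster$merge_blinks))
    locs <- merge_blinks(locs, config$fluor, config$cluster$merge_radius_nm)
  dens <- voronoi_densities(locs, roi)
  assign <- segment_clusters(locs, dens,
                             threshold_factor = config$cluster$threshold_factor,
                             smooth = isTRUE(config$cluster$smooth),
                             max_edge_nm = config$cluster$max_edge_nm)
  cand <- profile_clusters(locs, assign)
  rec <- classify_and_filter(cand, config$filter_config, config$fluor$alpha,
                             roi_id = attr(locs, "roi_id") %||% "roi1")
  attr(rec, "assignment") <- assign
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
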