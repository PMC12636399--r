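#' Merge re-blinks of the same fluorophore
#'
#' Optional pre-clustering step: localizations closer than
#' `merge_radius_nm` whose frame gap does not exceed the probe's maximum
#' dark time are attributed to the same fluorophore and merged
#' (transitively) to their centroid. Off by default in the pipeline --
#' the admission filters already express counts in units of alpha, which
#' absorbs re-blinking on average.
#'
#' @param locs a `loc_table`.
#' @param fluor a [fluorophore()] supplying `max_dark_time_frames`.
#' @param merge_radius_nm spatial radius for same-molecule attribution.
#' @return A `loc_table` with merged rows (centroid position, earliest
#'   frame, summed intensity); row count is never larger than the input.
#' @export
merge_blinks <- function(locs, fluor, merge_radius_nm = 50) {
  check_number(merge_radius_nm, "merge_radius_nm", lower = 1e-9)
  n <- nrow(locs)
  if (n <= 1L) return(locs)
  ord <- order(locs$frame)
  x <- locs$x_nm[ord]; y <- locs$y_nm[ord]; fr <- locs$frame[ord]
  inten <- locs$intensity[ord]; ch <- locs$channel[ord]
  gap <- fluor$max_dark_time_frames
  r2 <- merge_radius_nm^2

  from <- integer(0); to <- integer(0)
  j0 <- 1L
  for (i in seq_len(n)) {
    while (fr[i] - fr[j0] > gap) j0 <- j0 + 1L
    if (j0 < i) {
      js <- j0:(i - 1L)
      hit <- js[(x[js] - x[i])^2 + (y[js] - y[i])^2 <= r2]
      if (length(hit)) { from <- c(from, hit); to <- c(to, rep(i, length(hit))) }
    }
  }
  comp <- uf_components(n, from, to)
  groups <- split(seq_len(n), comp)
  gx <- vapply(groups, function(g) mean(x[g]), 1)
  gy <- vapply(groups, function(g) mean(y[g]), 1)
  gf <- vapply(groups, function(g) min(fr[g]), 1)
  gi <- vapply(groups, function(g) sum(inten[g]), 1)
  gc <- vapply(groups, function(g) ch[g[1L]], "")
  out <- loc_table(gx, gy, gf, gi, gc, roi = attr(locs, "roi"),
                   roi_id = attr(locs, "roi_id"),
                   capture = attr(locs, "capture"),
                   detection = attr(locs, "detection"))
  attr(out, "n_merged") <- n - nrow(out)
  out
}

#' First-rank Voronoi density field
#'
#' Computes the Voronoi tessellation of the localizations, clips every
#' cell to the ROI rectangle (so all cells are bounded and their areas
#' tile the ROI exactly), and defines each localization's density as the
#' reciprocal of its clipped cell area. Exactly coincident localizations
#' share their common cell's area equally (k coincident points each get
#' area/k, i.e. k-fold density) and are mutually adjacent.
#'
#' Fewer than 4 localizations, or an all-collinear point set, cannot
#' support a meaningful tessellation: the field is flagged degenerate
#' and everything downstream treats the ROI as noise-only.
#'
#' @param locs a `loc_table` (or anything with `x_nm`/`y_nm` columns).
#' @param roi an [roi_geometry()].
#' @return A `voronoi_density` list: `density` (nm^-2 per localization),
#'   `area` (nm^2), `neighbors` (list of integer vectors, cell adjacency
#'   by shared Voronoi edge), `on_boundary` (cell touches the ROI wall),
#'   `degenerate` (scalar flag), `roi`.
#' @export
voronoi_densities <- function(locs, roi = attr(locs, "roi")) {
  stopifnot(inherits(roi, "roi_geometry"))
  x <- locs$x_nm; y <- locs$y_nm
  n <- length(x)
  degenerate <- function() {
    structure(list(density = rep(NA_real_, n), area = rep(NA_real_, n),
                   neighbors = rep(list(integer(0)), n),
                   on_boundary = rep(TRUE, n), degenerate = TRUE, roi = roi),
              class = "voronoi_density")
  }
  if (n < 4L) return(degenerate())
  # collinearity check on centered coordinates
  xc <- x - mean(x); yc <- y - mean(y)
  cross_max <- max(abs(xc * yc[1L] - yc * xc[1L]))
  if (max(abs(xc)) < 1e-12 || max(abs(yc)) < 1e-12 ||
      qr(cbind(xc, yc))$rank < 2L)
    return(degenerate())

  # collapse exact duplicates before tessellating
  z <- complex(real = x, imaginary = y)
  uz <- unique(z)
  uid <- match(z, uz)
  mult <- tabulate(uid, nbins = length(uz))
  if (length(uz) < 4L) return(degenerate())

  res <- .voronoi_clipped_cpp(Re(uz), Im(uz), 0, roi$width_nm,
                              0, roi$height_nm)
  # symmetrize adjacency of unique cells
  deg <- lengths(res$neighbors)
  from_u <- rep.int(seq_along(uz), deg)
  to_u <- unlist(res$neighbors, use.names = FALSE)
  if (length(from_u)) {
    a <- pmin(from_u, to_u); b <- pmax(from_u, to_u)
    key <- unique((a - 1) * length(uz) + b)
    a <- (key - 1) %/% length(uz) + 1L
    b <- (key - 1) %% length(uz) + 1L
  } else a <- b <- integer(0)

  # symmetric adjacency of unique cells
  nb_u <- rep(list(integer(0)), length(uz))
  if (length(a)) {
    nb_list <- split(c(b, a), c(a, b))
    nb_u[as.integer(names(nb_list))] <- lapply(nb_list, sort)
  }
  if (all(mult == 1L)) {
    neighbors <- nb_u[uid]
  } else {
    # map unique-cell adjacency back to original indices; coincident
    # points are mutually adjacent
    members <- split(seq_len(n), uid)
    neighbors <- vector("list", n)
    for (i in seq_len(n)) {
      u <- uid[i]
      nb <- unlist(members[nb_u[[u]]], use.names = FALSE)
      twins <- setdiff(members[[u]], i)
      neighbors[[i]] <- sort(c(nb, twins))
    }
  }
  area <- res$area[uid] / mult[uid]

  structure(list(density = 1 / area, area = area, neighbors = neighbors,
                 on_boundary = res$on_boundary[uid], degenerate = FALSE,
                 roi = roi),
            class = "voronoi_density")
}

#' Segment localizations into density clusters
#'
#' Thresholds the Voronoi density field at `threshold_factor` times the
#' mean ROI density (`n / ROI area`); localizations at or above the
#' threshold are signal (ties included). Connected components are then
#' formed over the Voronoi adjacency graph -- cells sharing an edge,
#' with generators closer than `max_edge_nm` -- and a component becomes
#' a cluster when it contains at least `min_members` signal
#' localizations. All members of such a component belong to the cluster,
#' including sub-threshold "border" localizations (DBSCAN border
#' semantics): the outermost cells of a dense particle bulge into the
#' surrounding empty space and can fall below any density threshold, yet
#' they are part of the particle. Components without enough signal are
#' noise (label -1); clusters are labelled contiguously from 0.
#'
#' `max_edge_nm = NULL` derives the adjacency cut-off from the density
#' threshold itself, `sqrt(1 / threshold_density)`: the inter-point
#' spacing implied by a region at exactly threshold density. Cells of
#' genuinely dense regions are adjacent at much shorter range, while
#' cells of distinct particles separated by empty space can share a
#' (long) Voronoi edge across the void; the cut-off removes only the
#' latter. `max_edge_nm = Inf` restores pure shared-edge connectivity.
#'
#' With `smooth = TRUE`, each localization's density is replaced by the
#' mean first-rank density over itself and its Voronoi neighbours before
#' thresholding, which stabilises the signal call for cluster rims
#' without promoting isolated background points, whose neighbours are
#' other sparse cells.
#'
#' @param locs a `loc_table`.
#' @param dens a [voronoi_densities()] field for `locs`.
#' @param threshold_factor multiple of the mean ROI density (> 0).
#' @param smooth average densities over Voronoi neighbours before
#'   thresholding.
#' @param max_edge_nm adjacency distance cut-off (see above).
#' @param min_members minimum localizations per cluster (>= 2).
#' @return A `cluster_assignment` list: `labels` (integer per
#'   localization, -1 noise), `n_clusters`, `signal` (logical),
#'   `threshold_density`, `max_edge_nm`.
#' @export
segment_clusters <- function(locs, dens, threshold_factor = 2,
                             smooth = TRUE, max_edge_nm = NULL,
                             min_members = 2L) {
  stopifnot(inherits(dens, "voronoi_density"))
  check_number(threshold_factor, "threshold_factor", lower = 1e-12)
  n <- nrow(locs)
  empty <- function(thr, cut) {
    structure(list(labels = rep(-1L, n), n_clusters = 0L,
                   signal = rep(FALSE, n), threshold_density = thr,
                   max_edge_nm = cut),
              class = "cluster_assignment")
  }
  roi <- dens$roi
  mean_density <- n / (roi$width_nm * roi$height_nm)
  thr <- threshold_factor * mean_density
  cut <- if (is.null(max_edge_nm)) sqrt(1 / thr) else max_edge_nm
  if (dens$degenerate || n == 0L) return(empty(thr, cut))

  d <- dens$density
  if (smooth) {
    d <- vapply(seq_len(n), function(i)
      mean(dens$density[c(i, dens$neighbors[[i]])]), 1)
  }
  signal <- d >= thr
  if (!any(signal)) return(empty(thr, cut))

  # Voronoi adjacency over all localizations, restricted by the distance
  # cut; components carrying enough signal become clusters and keep all
  # their members (border semantics)
  from <- rep.int(seq_len(n), lengths(dens$neighbors))
  to <- unlist(dens$neighbors, use.names = FALSE)
  sel <- from < to
  from <- from[sel]; to <- to[sel]
  if (is.finite(cut) && length(from)) {
    dd <- (locs$x_nm[from] - locs$x_nm[to])^2 +
          (locs$y_nm[from] - locs$y_nm[to])^2
    keep <- dd <= cut^2
    from <- from[keep]; to <- to[keep]
  }
  comp <- uf_components(n, from, to)

  sizes <- table(comp[signal])
  good <- as.integer(names(sizes)[sizes >= min_members])
  labels <- rep(-1L, n)
  if (length(good)) {
    good <- sort(good)  # roots are minimum member index: stable order
    lab_of <- seq_along(good) - 1L
    idx <- match(comp, good)
    labels[!is.na(idx)] <- lab_of[idx[!is.na(idx)]]
  }
  structure(list(labels = labels, n_clusters = length(good),
                 signal = signal, threshold_density = thr,
                 max_edge_nm = cut),
            class = "cluster_assignment")
}

#' Per-cluster summary table
#'
#' @param locs a `loc_table`.
#' @param assignment a [segment_clusters()] result.
#' @return Data frame with one row per cluster: `label`, `n_loc`,
#'   centroid `x_nm`/`y_nm`.
#' @export
cluster_summary <- function(locs, assignment) {
  lab <- assignment$labels
  keep <- lab >= 0L
  if (!any(keep))
    return(data.frame(label = integer(0), n_loc = integer(0),
                      x_nm = numeric(0), y_nm = numeric(0)))
  sp <- split(which(keep), lab[keep])
  data.frame(
    label = as.integer(names(sp)),
    n_loc = lengths(sp),
    x_nm = vapply(sp, function(i) mean(locs$x_nm[i]), 1),
    y_nm = vapply(sp, function(i) mean(locs$y_nm[i]), 1),
    row.names = NULL)
}
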