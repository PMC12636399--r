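test_that("merge_blinks merges within radius and dark time, transitively", {
  roi <- roi_geometry()
  fl <- fluorophore("p", 10, max_dark_time_frames = 10)
  # 5 nm / 1 frame apart -> one molecule
  tab <- loc_table(c(100, 105), c(100, 100), c(5, 6), roi = roi)
  expect_equal(nrow(merge_blinks(tab, fl, 50)), 1L)
  # frame gap above the dark time -> kept apart
  tab2 <- loc_table(c(100, 105), c(100, 100), c(5, 30), roi = roi)
  expect_equal(nrow(merge_blinks(tab2, fl, 50)), 2L)
  # chain A-B-C pairwise adjacent -> single transitive group (union-find)
  tab3 <- loc_table(c(100, 140, 180), c(100, 100, 100), c(1, 9, 17),
                    roi = roi)
  m3 <- merge_blinks(tab3, fl, 50)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$x_nm, 140)
  expect_equal(m3$frame, 1L)
})

test_that("clipped Voronoi matches a brute-force half-plane oracle", {
  set.seed(42)
  W <- 5000
  x <- c(rnorm(15, 1000, 30), rnorm(15, 4000, 30), rnorm(15, 2500, 30),
         runif(8, 0, W))
  y <- c(rnorm(15, 1000, 30), rnorm(15, 1200, 30), rnorm(15, 4000, 30),
         runif(8, 0, W))
  res <- evprofiler:::.voronoi_clipped_cpp(x, y, 0, W, 0, W)
  for (i in seq_along(x)) {
    bf <- bf_voronoi_cell(i, x, y, W, W)
    expect_equal(res$area[i], bf$area, tolerance = 1e-9)
    expect_equal(sort(res$neighbors[[i]]), bf$neighbors)
  }
  expect_equal(sum(res$area), W * W, tolerance = 1e-9)
})

test_that("voronoi_densities: symmetry, conservation, degeneracy, duplicates", {
  roi <- roi_geometry(width_nm = 1000, height_nm = 1000, pixels_per_side = 16)
  # 4 points at corners of a centred square: equal cells by symmetry
  sq <- loc_table(c(400, 600, 400, 600), c(400, 400, 600, 600),
                  rep(1, 4), roi = roi)
  dens <- voronoi_densities(sq, roi)
  expect_false(dens$degenerate)
  expect_equal(max(dens$area) - min(dens$area), 0, tolerance = 1e-9)
  expect_equal(sum(dens$area), 1e6, tolerance = 1)

  # density of a uniform scatter tracks n / area: the harmonic mean is
  # exact (tessellation conservation) and the typical cell is within 10%
  # (the arithmetic mean of 1/area is Jensen-biased upward by ~30% for a
  # Poisson-Voronoi tessellation and is deliberately not asserted)
  set.seed(12)
  n <- 2000
  u <- loc_table(runif(n, 0, 1000), runif(n, 0, 1000), rep(1, n), roi = roi)
  du <- voronoi_densities(u, roi)
  expect_equal(1 / mean(du$area) * 1e6 / n, 1, tolerance = 1e-9)
  expect_lt(abs(median(du$density) * 1e6 / n - 1), 0.1)

  # degenerate inputs: too few or collinear
  expect_true(voronoi_densities(loc_table(1:3, 1:3, rep(1, 3), roi = roi),
                                roi)$degenerate)
  lin <- loc_table(seq(10, 900, length.out = 10), rep(500, 10),
                   rep(1, 10), roi = roi)
  expect_true(voronoi_densities(lin, roi)$degenerate)

  # exact duplicates share the cell area and are mutual neighbours
  dup <- loc_table(c(300, 300, 700, 200, 800), c(300, 300, 700, 800, 200),
                   rep(1, 5), roi = roi)
  dd <- voronoi_densities(dup, roi)
  expect_equal(dd$area[1], dd$area[2])
  expect_true(2L %in% dd$neighbors[[1]] && 1L %in% dd$neighbors[[2]])
  expect_equal(sum(dd$area), 1e6, tolerance = 1)
})

test_that("segmentation matches the distance oracle on separated blobs", {
  roi <- roi_geometry(width_nm = 10000, height_nm = 10000,
                      pixels_per_side = 64)
  set.seed(77)
  blob1 <- cbind(rnorm(120, 3000, 25), rnorm(120, 3000, 25))
  blob2 <- cbind(rnorm(150, 3000 + 1000, 25), rnorm(150, 3000, 25))
  pts <- rbind(blob1, blob2)
  tab <- loc_table(pts[, 1], pts[, 2], rep(1, nrow(pts)), roi = roi)
  dens <- voronoi_densities(tab, roi)
  asg <- segment_clusters(tab, dens)
  expect_equal(asg$n_clusters, 2L)
  expect_identical(partition_of(asg$labels),
                   partition_of(oracle_components(tab$x_nm, tab$y_nm, 100)))

  # effectively infinite threshold: nothing is signal
  asg_inf <- segment_clusters(tab, dens, threshold_factor = 1e12)
  expect_equal(asg_inf$n_clusters, 0L)
  expect_true(all(asg_inf$labels == -1L))

  # single compact blob -> one cluster with every blob point
  tab1 <- loc_table(blob1[, 1], blob1[, 2], rep(1, 120), roi = roi)
  asg1 <- segment_clusters(tab1, voronoi_densities(tab1, roi))
  expect_equal(asg1$n_clusters, 1L)
  expect_true(all(asg1$labels == 0L))
})

test_that("row order does not change cluster memberships", {
  roi <- roi_geometry(width_nm = 10000, height_nm = 10000,
                      pixels_per_side = 64)
  set.seed(5)
  pts <- rbind(cbind(rnorm(80, 2000, 20), rnorm(80, 2000, 20)),
               cbind(rnorm(80, 7000, 20), rnorm(80, 7000, 20)),
               cbind(runif(40, 0, 10000), runif(40, 0, 10000)))
  tab <- loc_table(pts[, 1], pts[, 2], rep(1, nrow(pts)), roi = roi)
  asg <- segment_clusters(tab, voronoi_densities(tab, roi))
  perm <- sample(nrow(tab))
  tabp <- loc_table(tab$x_nm[perm], tab$y_nm[perm], tab$frame[perm],
                    roi = roi)
  asgp <- segment_clusters(tabp, voronoi_densities(tabp, roi))
  # compare partitions mapped back to original indices
  labs_back <- integer(nrow(tab)); labs_back[perm] <- asgp$labels
  noise1 <- asg$labels == -1L
  expect_identical(noise1, labs_back == -1L)
  # labels may permute; the partitions must agree as sets of sets
  expect_true(setequal(partition_of(asg$labels[!noise1]),
                       partition_of(labs_back[!noise1])))
})

test_that("raising threshold_factor never increases the signal count", {
  roi <- roi_geometry(width_nm = 10000, height_nm = 10000,
                      pixels_per_side = 64)
  set.seed(6)
  pts <- rbind(cbind(rnorm(150, 5000, 80), rnorm(150, 5000, 80)),
               cbind(runif(150, 0, 10000), runif(150, 0, 10000)))
  tab <- loc_table(pts[, 1], pts[, 2], rep(1, nrow(pts)), roi = roi)
  dens <- voronoi_densities(tab, roi)
  counts <- vapply(c(0.5, 1, 2, 4, 8, 16),
                   function(f) sum(segment_clusters(tab, dens,
                                                    threshold_factor = f)$signal),
                   1)
  expect_true(all(diff(counts) <= 0))
})
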