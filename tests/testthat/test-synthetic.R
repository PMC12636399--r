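roi_small <- roi_geometry(width_nm = 5000, height_nm = 5000,
                          pixels_per_side = 32, n_frames = 1000)

test_that("sample_particles honours rates, seeds and input contracts", {
  roi <- roi_geometry()
  expect_equal(nrow(sample_particles(c(EV = 0), roi, seed = 1)), 0L)

  a <- sample_particles(c(EV = 100), roi, seed = 42)
  b <- sample_particles(c(EV = 100), roi, seed = 42)
  expect_identical(a, b)

  expect_error(sample_particles(c(EV = -1), roi, seed = 1), "EV")
  expect_error(sample_particles(c(nosuch = 5), roi, seed = 1), "nosuch")

  # Poisson rate check: mean count over replicate seeds within 3 SE
  counts <- vapply(1:400, function(s)
    nrow(sample_particles(c(EV = 100), roi, seed = s)), 1L)
  se <- sqrt(100 / 400)
  expect_lt(abs(mean(counts) - 100), 3 * se)
})

test_that("cargo molecules lie inside the particle ellipse", {
  roi <- roi_geometry()
  cls <- fixed_class(diameter = 80, cargo = 30, axial_ratio = 2)
  truth <- sample_particles(c(EV = 20), roi, classes = cls, seed = 3)
  a_semi <- 40 * sqrt(2)  # semi-major of an area-equivalent 80 nm ellipse
  for (k in seq_len(nrow(truth))) {
    d <- sqrt((truth$cargo[[k]][, 1] - truth$x_nm[k])^2 +
              (truth$cargo[[k]][, 2] - truth$y_nm[k])^2)
    expect_true(all(d <= a_semi + 1e-9))
  }
})

test_that("emit_localizations: emission mean, determinism, degenerate noise", {
  roi <- roi_geometry()
  fl <- fluorophore("p", alpha = 10, loc_precision_sigma_nm = 10)
  cls <- fixed_class(diameter = 100, cargo = 20, labeling = 1)
  # deterministic fixture: walk seeds until the Poisson draw gives exactly 1
  s <- 5L
  truth <- sample_particles(c(EV = 1), roi, classes = cls,
                            edge_margin_nm = 2000, seed = s)
  while (nrow(truth) != 1L) {
    s <- s + 1L
    truth <- sample_particles(c(EV = 1), roi, classes = cls,
                              edge_margin_nm = 2000, seed = s)
  }
  # 20 molecules at alpha = 10 -> expected 200 localizations;
  # sd of one draw = sqrt(20 * (alpha^2 - alpha)) ~ 42.4
  tot <- vapply(1:100, function(s)
    nrow(emit_localizations(truth, fl, noise_model(0), roi, seed = s)), 1L)
  expect_lt(abs(mean(tot) - 200), 3 * sqrt(20 * 90 / 100))

  # zero particles, zero background
  empty <- sample_particles(c(EV = 0), roi, seed = 1)
  expect_equal(nrow(emit_localizations(empty, fl, noise_model(0), roi,
                                       seed = 1)), 0L)

  # degenerate localization noise: all blinks at the molecule position
  fl0 <- fluorophore("p", alpha = 5, loc_precision_sigma_nm = 1e-9)
  one <- empty[0, ]
  one <- rbind(one, data.frame(particle_id = 0L, class_name = "EV",
                               x_nm = 1000, y_nm = 1000, diameter_nm = 1,
                               axial_ratio = 1, orientation = 0,
                               n_cargo = 1L, reporter_positive = FALSE,
                               cargo = I(list(cbind(x_nm = 1000,
                                                    y_nm = 1000)))))
  class(one) <- c("particle_truth", "data.frame"); attr(one, "roi") <- roi
  tab <- emit_localizations(one, fl0, noise_model(0), roi, seed = 9)
  expect_true(all(abs(tab$x_nm - 1000) < 1e-6))
  expect_true(all(abs(tab$y_nm - 1000) < 1e-6))

  # seeded determinism and count bookkeeping
  t1 <- emit_localizations(truth, fl, noise_model(1), roi, seed = 7)
  t2 <- emit_localizations(truth, fl, noise_model(1), roi, seed = 7)
  expect_identical(t1, t2)
  expect_equal(nrow(t1) + attr(t1, "n_discarded"),
               attr(t1, "n_before_discard"))
})

test_that("blink-count distributions have mean alpha on support >= 1", {
  set.seed(11)
  for (d in c("geometric", "poisson")) {
    k <- evprofiler:::draw_blink_counts(20000, 6, d)
    expect_true(all(k >= 1L))
    expect_lt(abs(mean(k) - 6), 3 * sd(k) / sqrt(20000))
  }
})

test_that("doubling class rates doubles mean localization count", {
  fl <- fluorophore("p", alpha = 6, loc_precision_sigma_nm = 5)
  cls <- fixed_class(diameter = 50, cargo = 8, labeling = 1)
  n1 <- vapply(1:120, function(s) {
    tr <- sample_particles(c(EV = 10), roi_small, classes = cls,
                           edge_margin_nm = 300, seed = s)
    nrow(emit_localizations(tr, fl, noise_model(0), roi_small,
                            seed = 10000 + s))
  }, 1L)
  n2 <- vapply(1:120, function(s) {
    tr <- sample_particles(c(EV = 20), roi_small, classes = cls,
                           edge_margin_nm = 300, seed = 20000 + s)
    nrow(emit_localizations(tr, fl, noise_model(0), roi_small,
                            seed = 30000 + s))
  }, 1L)
  se <- sqrt(var(n2) / 120 + 4 * var(n1) / 120)
  expect_lt(abs(mean(n2) - 2 * mean(n1)), 3 * se)
})

test_that("reporter image rendering: zero case, peak location, twin peaks", {
  roi <- roi_geometry()
  cls <- fixed_class()
  none <- sample_particles(c(EV = 10), roi, classes = cls,
                           reporter_fraction = 0, seed = 2)
  img0 <- render_reporter_image(none, roi, seed = 1)
  expect_true(all(img0 == 0))

  one <- separated_truth(roi, n = 2, seed = 4)
  one$reporter_positive <- c(TRUE, FALSE)
  img1 <- render_reporter_image(one, roi, seed = 1)
  expect_equal(max(img1), 1)
  pk <- which(unclass(img1) == 1, arr.ind = TRUE)
  ctr <- c(floor(one$x_nm[1] / roi$pixel_size_nm),
           floor(one$y_nm[1] / roi$pixel_size_nm))
  expect_lte(abs(pk[1, "row"] - 1L - ctr[2]), 1)
  expect_lte(abs(pk[1, "col"] - 1L - ctr[1]), 1)

  two <- separated_truth(roi, n = 2, seed = 4)
  two$reporter_positive <- c(TRUE, TRUE)
  img2 <- unclass(render_reporter_image(two, roi, seed = 1))
  for (k in 1:2) {
    r <- floor(two$y_nm[k] / roi$pixel_size_nm) + 1L
    c <- floor(two$x_nm[k] / roi$pixel_size_nm) + 1L
    expect_gt(img2[r, c], 0.9)  # equal particles -> two near-unit maxima
  }
})

test_that("buffer controls are background-only and reproducible", {
  roi <- roi_geometry()
  expect_equal(nrow(make_buffer_control(roi, noise_model(0), seed = 1)), 0L)
  b1 <- make_buffer_control(roi, noise_model(0.5), seed = 5)
  b2 <- make_buffer_control(roi, noise_model(0.5), seed = 5)
  expect_identical(b1, b2)
  expect_gt(nrow(b1), 0L)
})
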