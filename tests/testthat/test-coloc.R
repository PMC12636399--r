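test_that("binarization applies a single absolute threshold", {
  flat <- intensity_image(matrix(0.5, 16, 16), pixel_size_nm = 100)
  expect_true(all(binarize_reference(flat, 0.4, normalize = FALSE)))
  expect_false(any(binarize_reference(flat, 0.6, normalize = FALSE)))
  # all-zero image -> empty mask, no error
  expect_false(any(binarize_reference(intensity_image(matrix(0, 8, 8), 100),
                                      0.3)))
  # a rendered Gaussian peak yields one blob containing the peak pixel
  roi <- roi_geometry()
  tr <- separated_truth(roi, n = 1, seed = 2)
  tr$reporter_positive <- TRUE
  mask <- binarize_reference(render_reporter_image(tr, roi), 0.3)
  expect_true(any(mask))
  pk <- c(floor(tr$y_nm[1] / roi$pixel_size_nm) + 1L,
          floor(tr$x_nm[1] / roi$pixel_size_nm) + 1L)
  expect_true(unclass(mask)[pk[1], pk[2]])
  tp <- which(unclass(mask), arr.ind = TRUE)
  expect_true(all(sqrt((tp[, 1] - pk[1])^2 + (tp[, 2] - pk[2])^2) < 6))
})

test_that("threshold monotonicity: higher threshold, fewer positives", {
  roi <- roi_geometry()
  cfg <- load_config()
  truth <- sample_particles(c(EV = 60), roi, reporter_fraction = 0.6,
                            seed = 33)
  locs <- emit_localizations(truth, cfg$fluor, noise_model(), roi, seed = 34)
  rec <- detect_particles(locs, cfg)
  img <- render_reporter_image(truth, roi, seed = 35)
  npos <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th) {
    sum(flag_positive_particles(rec, binarize_reference(img, th)
                                )$reporter_positive)
  }, 1)
  expect_true(all(diff(npos) <= 0))
})

test_that("alignment recovers synthetic integer shifts exactly", {
  roi <- roi_geometry()
  cfg <- load_config()
  truth <- sample_particles(c(EV = 100), roi, reporter_fraction = 1,
                            seed = 71)
  locs <- emit_localizations(truth, cfg$fluor, noise_model(), roi, seed = 72)
  rec <- detect_particles(locs, cfg)
  # sharp reference (PSF below one pixel) gives an unambiguous optimum
  img <- render_reporter_image(truth, roi, psf_sigma_nm = 100, seed = 73)
  mask <- binarize_reference(img, 0.4)
  expect_equal(as.integer(align_channels(mask, rec)), c(0L, 0L))
  expect_equal(as.integer(align_channels(shift_mask(mask, dx = 2), rec)),
               c(-2L, 0L))
  expect_equal(as.integer(align_channels(shift_mask(mask, dy = -2), rec)),
               c(0L, 2L))
  # empty mask falls back to zero shift with a warning
  none <- binarize_reference(intensity_image(matrix(0, 256, 256),
                                             roi$pixel_size_nm), 0.4)
  expect_warning(z <- align_channels(none, rec), "empty")
  expect_equal(as.integer(z), c(0L, 0L))
  # all-true mask ties everywhere; tie-break selects the zero shift
  allm <- binarize_reference(intensity_image(matrix(1, 256, 256),
                                             roi$pixel_size_nm), 0.4,
                             normalize = FALSE)
  expect_equal(as.integer(align_channels(allm, rec)), c(0L, 0L))
})

test_that("positivity flagging: extremes, shifts, out-of-image centroids", {
  roi <- roi_geometry()
  parts <- data.frame(particle_id = 0:2, x_nm = c(100, 20000, 40900),
                      y_nm = c(100, 20000, 40900), n_loc = 100,
                      cargo_estimate = 10, diameter_nm = 80,
                      circularity = 0.9, eccentricity = 0.2)
  allm <- binarize_reference(intensity_image(matrix(1, 256, 256),
                                             roi$pixel_size_nm), 0.4,
                             normalize = FALSE)
  expect_equal(attr(flag_positive_particles(parts, allm),
                    "positive_fraction"), 1)
  none <- binarize_reference(intensity_image(matrix(0, 256, 256),
                                             roi$pixel_size_nm), 0.4)
  expect_equal(attr(flag_positive_particles(parts, none),
                    "positive_fraction"), 0)
  # a large shift pushes the corner centroid outside: negative + counted
  shifted <- flag_positive_particles(parts, allm, shift = c(-3L, 0L))
  expect_false(shifted$reporter_positive[3])
  expect_equal(attr(shifted, "n_outside"), 1L)
  # positivity does not depend on particle order
  perm <- c(3, 1, 2)
  p2 <- flag_positive_particles(parts[perm, ], allm, shift = c(-3L, 0L))
  expect_equal(p2$reporter_positive, shifted$reporter_positive[perm])
})
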