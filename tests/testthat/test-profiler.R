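test_that("cargo estimation follows the alpha calibration exactly", {
  expect_equal(estimate_cargo(200, 10), 20L)
  expect_equal(estimate_cargo(6, 6), 1L)
  expect_equal(estimate_cargo(25, 10), 3L)   # round-half-up
  expect_equal(estimate_cargo(24, 10), 2L)
  expect_equal(estimate_cargo(3, 10), 1L)    # floored at one molecule
  expect_equal(estimate_cargo(c(60, 66), 6), c(10L, 11L))
  expect_error(estimate_cargo(0, 10), "n_loc")
})

test_that("morphology converges to closed forms", {
  set.seed(21)
  # uniform disk, r = 50: diameter -> 100, circularity -> 1, ecc -> 0
  pts <- sample_disk(10000, 50)
  m <- compute_morphology(pts)
  expect_lt(abs(m$diameter_nm - 100) / 100, 0.05)
  expect_gte(m$circularity, 0.95)
  expect_lte(m$eccentricity, 0.15)
  expect_lte(m$circularity, 1 + 1e-6)

  # 3:1 axis-aligned ellipse boundary: ecc = sqrt(1 - 1/9)
  th <- seq(0, 2 * pi, length.out = 1201)[-1]
  me <- compute_morphology(cbind(150 * cos(th), 50 * sin(th)))
  expect_equal(me$eccentricity, sqrt(1 - 1 / 9), tolerance = 0.01)

  # circle boundary: circularity 1 within polygonal discretisation
  mc <- compute_morphology(cbind(50 * cos(th), 50 * sin(th)))
  expect_equal(mc$circularity, 1, tolerance = 0.02)
  expect_equal(mc$feret_nm, 100, tolerance = 1)
})

test_that("degenerate clusters are flagged, not dropped", {
  m2 <- compute_morphology(cbind(c(0, 30), c(0, 40)))
  expect_true(m2$degenerate)
  expect_equal(m2$diameter_nm, 50)  # max pairwise distance
  expect_true(is.na(m2$circularity))
  ml <- compute_morphology(cbind(c(0, 10, 20, 30), rep(5, 4)))
  expect_true(ml$degenerate)
})

test_that("admission boundaries are inclusive exactly as specified", {
  alpha <- 10
  filt <- cluster_filter_config()
  cand <- function(d, n) data.frame(label = 0L, n_loc = n, x_nm = 0,
                                    y_nm = 0, diameter_nm = d, feret_nm = d,
                                    circularity = 0.9, eccentricity = 0.3,
                                    degenerate = FALSE)
  admit <- function(d, n, f = filt)
    nrow(classify_and_filter(cand(d, n), f, alpha)) == 1L

  # spec-quoted examples
  expect_false(admit(60, 15))    # below 2 x alpha
  expect_true(admit(60, 2000))   # inclusive upper bound
  sna <- cluster_filter_config(size_cap_nm = 250)
  expect_false(admit(300, 500, sna))

  # small-class localization boundaries at 2*alpha and 2,000
  expect_false(admit(60, 19)); expect_true(admit(60, 20))
  expect_true(admit(60, 2000)); expect_false(admit(60, 2001))
  # large-class boundaries at 100 and 15,000
  expect_false(admit(150, 99)); expect_true(admit(150, 100))
  expect_true(admit(150, 15000)); expect_false(admit(150, 15001))
  # diameter class boundaries: 100 nm is small, above is large
  expect_true(admit(100, 20)); expect_false(admit(101, 20))
  expect_true(admit(101, 100))
  expect_false(admit(19, 50))  # fragments below the small range
  expect_true(admit(20, 50))
  # cap boundary is inclusive
  expect_true(admit(250, 500, sna)); expect_false(admit(251, 500, sna))

  # rejection reasons are logged
  rej <- attr(classify_and_filter(cand(60, 15), filt, alpha), "rejections")
  expect_equal(rej$reason, "too_few_loc_small")
})

test_that("filtering is idempotent", {
  set.seed(9)
  cand <- data.frame(label = 0:49,
                     n_loc = sample(c(15, 50, 500, 2500, 16000), 50, TRUE),
                     x_nm = runif(50, 0, 41000), y_nm = runif(50, 0, 41000),
                     diameter_nm = runif(50, 10, 400),
                     feret_nm = runif(50, 10, 400),
                     circularity = runif(50), eccentricity = runif(50),
                     degenerate = FALSE)
  filt <- cluster_filter_config(size_cap_nm = 250)
  once <- classify_and_filter(cand, filt, 10)
  again <- classify_and_filter(as.data.frame(once), filt, 10)
  expect_equal(nrow(again), nrow(once))
  expect_equal(again$n_loc, once$n_loc)
  expect_equal(nrow(attr(again, "rejections")), 0L)
})

test_that("mouse mode tightens the small-cluster gate", {
  alpha <- 10
  m <- cluster_filter_config(mouse_mode = TRUE)
  cand <- data.frame(label = 0L, n_loc = 24, x_nm = 0, y_nm = 0,
                     diameter_nm = 60, feret_nm = 60, circularity = 0.9,
                     eccentricity = 0.3, degenerate = FALSE)
  # 24 < 2.5 x 10 -> rejected in mouse mode, admitted in human mode
  expect_equal(nrow(classify_and_filter(cand, m, alpha)), 0L)
  expect_equal(nrow(classify_and_filter(cand, cluster_filter_config(),
                                        alpha)), 1L)
  # 25 nm diameter is a fragment for mouse (range starts at 30)
  cand$diameter_nm <- 25; cand$n_loc <- 50
  expect_equal(attr(classify_and_filter(cand, m, alpha),
                    "rejections")$reason, "below_size_range")
})

test_that("recovery_report self-match and empty cases", {
  roi <- roi_geometry()
  truth <- sample_particles(c(EV = 20), roi, seed = 14)
  fake <- data.frame(particle_id = truth$particle_id, roi_id = "r",
                     n_loc = 100, cargo_estimate = truth$n_cargo,
                     diameter_nm = truth$diameter_nm,
                     circularity = 0.9, eccentricity = 0.3,
                     x_nm = truth$x_nm, y_nm = truth$y_nm)
  rr <- recovery_report(fake, truth)
  expect_equal(rr$precision, 1)
  expect_equal(rr$recall, 1)
  expect_equal(rr$by_class$cargo_rmse, 0)
  expect_equal(rr$by_class$diameter_rmse, 0)
  empty <- fake[0, ]
  expect_equal(recovery_report(empty, truth)$recall, 0)
})
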