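test_that("a straight chord has curvedness exactly 1 and zero heights", {
  z <- seq(0, 1, length.out = 100)
  crv <- normalized_curve(x = rep(0, 100), y = rep(0, 100), z = z,
                          scale_mm = 191)
  f <- suppressWarnings(compute_features(crv))
  expect_equal(f$curvedness, 1)
  expect_equal(f$cranial_peak_height, 0)
  expect_equal(f$caudal_peak_height, 0)
  expect_equal(f$segment_length_mm, 191)
  expect_equal(f$curve_length_mm, 191)
})

test_that("a semicircular arc has curvedness pi / 2", {
  th <- seq(pi, 0, length.out = 4001)
  crv <- normalized_curve(x = rep(0, 4001), y = 0.5 * sin(th),
                          z = (cos(th) + 1) / 2, scale_mm = 100)
  f <- compute_features(crv)
  expect_equal(f$curvedness, pi / 2, tolerance = 1e-3)
})

test_that("flat-topped peaks resolve to the median index", {
  y <- c(0, 1, 1, 1, 0.5, 0)
  z <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  crv <- normalized_curve(x = rep(0, 6), y = y, z = z, scale_mm = 100)
  f <- compute_features(crv)
  expect_equal(f$peak_location, 0.4) # middle of the three maxima
})

test_that("a peak on an endpoint warns but still reports", {
  z <- seq(0, 1, length.out = 60)
  crv <- normalized_curve(x = rep(0, 60), y = z * 0.1, z = z, scale_mm = 150)
  expect_warning(f <- compute_features(crv), "degenerate")
  expect_equal(f$peak_location, 1)
})

test_that("features are stable under resampling density", {
  f1 <- compute_features(analytic_centerline(0.3, 0.09, 0.06, 180,
                                             n_points = 200))
  f2 <- compute_features(analytic_centerline(0.3, 0.09, 0.06, 180,
                                             n_points = 2000))
  for (col in c("curvedness", "peak_location", "cranial_peak_height",
                "caudal_peak_height"))
    expect_lt(abs(f1[[col]] - f2[[col]]), 1e-3)
})

test_that("mm features scale with scale_mm, dimensionless ones do not", {
  crv <- analytic_centerline(0.3, 0.09, 0.06, 180)
  crv2 <- crv
  attr(crv2, "scale_mm") <- attr(crv, "scale_mm") * 2
  f1 <- compute_features(crv)
  f2 <- compute_features(crv2)
  expect_equal(f2$segment_length_mm, 2 * f1$segment_length_mm)
  expect_equal(f2$curve_length_mm, 2 * f1$curve_length_mm)
  expect_equal(f2$curvedness, f1$curvedness)
  expect_equal(f2$peak_location, f1$peak_location)
})

test_that("group report reproduces means, extremes and derived columns", {
  curves <- list(analytic_centerline(0.28, 0.09, 0.06, 175),
                 analytic_centerline(0.32, 0.07, 0.05, 185),
                 analytic_centerline(0.30, 0.08, 0.055, 180))
  rep <- features_report(curves)
  pl <- rep[rep$feature == "peak_location", ]
  expect_equal(pl$mean, 0.3, tolerance = 1e-12)
  expect_equal(pl$min, 0.28)
  expect_equal(pl$max, 0.32)
  expect_equal(pl$pct_from_cranial, 70, tolerance = 1e-9)
  ch <- rep[rep$feature == "caudal_peak_height", ]
  expect_equal(ch$mean_mm, mean(c(0.06, 0.05, 0.055)) * 180,
               tolerance = 1e-9)
  # identical curves: sd 0, min = max = mean
  same <- list(curves[[1]], curves[[1]])
  rep2 <- features_report(same)
  expect_true(all(rep2$sd == 0))
  expect_equal(rep2$min, rep2$max)
  expect_error(features_report(curves[1]), "at least 2")
})

test_that("peak location percent matches the reference conversions", {
  # male: mean 0.299 -> 70.1% from the cranial end; female: 0.274 -> 72.6%
  male <- features_report(list(analytic_centerline(0.299, 0.074, 0.056, 191),
                               analytic_centerline(0.299, 0.074, 0.056, 191)))
  expect_equal(male$pct_from_cranial[male$feature == "peak_location"], 70.1,
               tolerance = 1e-9)
  female <- features_report(list(analytic_centerline(0.274, 0.092, 0.061, 179),
                                 analytic_centerline(0.274, 0.092, 0.061, 179)))
  expect_equal(female$pct_from_cranial[female$feature == "peak_location"],
               72.6, tolerance = 1e-9)
})

test_that("curvedness exceeds 1 for any non-straight curve", {
  set.seed(21)
  for (i in 1:10) {
    ft <- random_feature_tuple()
    f <- compute_features(analytic_centerline(ft[1], ft[2], ft[3], ft[4]))
    expect_gt(f$curvedness, 1)
  }
})
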