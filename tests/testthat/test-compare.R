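test_that("equal means give t = 0, p = 1; degenerate SDs follow convention", {
  r <- two_sample_t(5, 1, 10, 5, 2, 12)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r0 <- two_sample_t(3, 0, 5, 3, 0, 5)
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  rd <- two_sample_t(3, 0, 5, 4, 0, 5)
  expect_equal(rd$p, 0)
  expect_true(is.infinite(rd$t))
})

test_that("the pooled t matches its closed form on a worked case", {
  # means 0 vs 1, sds 1, n = 10 each: t = -2.23607, p = 0.03828 (df 18)
  r <- two_sample_t(0, 1, 10, 1, 1, 10)
  expect_equal(r$t, -sqrt(5), tolerance = 1e-9)
  expect_equal(r$df, 18)
  expect_equal(r$p, 2 * pt(-sqrt(5), 18), tolerance = 1e-12)
  # cross-check against stats::t.test on raw data with matching summaries
  a <- c(-1, 0, 1); b <- c(1, 2, 3) # means 0/2, sds 1/1
  ref <- stats::t.test(a, b, var.equal = TRUE)
  r2 <- two_sample_t(0, 1, 3, 2, 1, 3)
  expect_equal(r2$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-12)
  # Welch variant against t.test default
  aw <- c(-2, 0, 2, 4); bw <- c(1, 1.5, 2)
  refw <- stats::t.test(aw, bw)
  rw <- two_sample_t(mean(aw), sd(aw), 4, mean(bw), sd(bw), 3, welch = TRUE)
  expect_equal(rw$t, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(rw$p, refw$p.value, tolerance = 1e-12)
})

test_that("swapping groups negates t and keeps p", {
  r1 <- two_sample_t(1.2, 0.4, 20, 0.9, 0.5, 25)
  r2 <- two_sample_t(0.9, 0.5, 25, 1.2, 0.4, 20)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
})

test_that("self-comparison is null everywhere", {
  pf <- reference_group_params("female")
  g <- sample_population(pf, 10, rng_seed = 2)
  pw <- compare_pointwise(g, g, K = 20)
  expect_true(all(pw$t == 0))
  expect_true(all(pw$p == 1))
  expect_equal(nrow(pw), 2 * 19) # 19 locations per axis, origin dropped
  ft <- compare_features(g, g)
  expect_true(all(ft$p == 1))
})

test_that("locations are ordered most-cranial first", {
  pf <- reference_group_params("female")
  g <- sample_population(pf, 5, rng_seed = 2)
  pw <- compare_pointwise(g, g, K = 20)
  y <- pw[pw$axis == "y", ]
  expect_equal(y$location, 1:19)
  expect_equal(y$z[1], 1) # location 1 is Z = 1 (cranial endpoint A)
  expect_equal(y$z[19], 1 / 19, tolerance = 1e-12)
})

test_that("a ventral offset moves Y differences linearly and leaves X alone", {
  z <- seq(0, 1, length.out = 60)
  base_y <- 0.2 * z * (1 - z) * 4
  mk <- function(delta) normalized_curve(x = 0.01 * sin(pi * z),
                                         y = base_y + delta * z, z = z,
                                         scale_mm = 180)
  ga <- list(mk(0), mk(0))
  delta <- 0.015
  gb <- list(mk(delta), mk(delta))
  pw <- compare_pointwise(ga, gb, K = 20)
  y <- pw[pw$axis == "y", ]
  expect_equal(y$mean_a - y$mean_b, -delta * y$z, tolerance = 1e-9)
  x <- pw[pw$axis == "x", ]
  expect_equal(x$mean_a, x$mean_b, tolerance = 1e-12)
})

test_that("male/female simulation reproduces the cranial-dorsal pattern", {
  ga <- sample_population(reference_group_params("male"), 400, rng_seed = 31)
  gb <- sample_population(reference_group_params("female"), 400, rng_seed = 32)
  pw <- compare_pointwise(ga, gb, K = 20)
  y <- pw[pw$axis == "y", ]
  # females more dorsal at the cranial stations: male - female Y difference
  # is positive and largest cranially
  dcran <- mean((y$mean_a - y$mean_b)[1:5])
  dcaud <- mean((y$mean_a - y$mean_b)[15:19])
  expect_gt(dcran, 0)
  expect_gt(dcran, abs(dcaud))
  x <- pw[pw$axis == "x", ]
  expect_lt(max(abs(x$mean_a - x$mean_b)), 0.01) # no systematic X offset
})

test_that("significance counting follows the reference tables", {
  expect_equal(count_significant(reference_pointwise("y"), 0.05), 7)
  expect_equal(count_significant(reference_pointwise("x"), 0.05), 0)
  fake <- tibble::tibble(p = rep(1, 5))
  expect_equal(count_significant(fake, 0.05), 0)
})

test_that("the Bonferroni flag inflates p-values across 19 locations", {
  pf <- reference_group_params("female")
  pm <- reference_group_params("male")
  ga <- sample_population(pm, 60, rng_seed = 41)
  gb <- sample_population(pf, 60, rng_seed = 42)
  pw <- compare_pointwise(ga, gb, K = 20)
  pwb <- compare_pointwise(ga, gb, K = 20, bonferroni = TRUE)
  expect_equal(pwb$p, pmin(1, pw$p * 19), tolerance = 1e-12)
})

test_that("analytic pooled power matches stats::power.t.test", {
  # equal n, common sd: both closed forms must agree
  ref <- stats::power.t.test(n = 40, delta = 0.5, sd = 1, sig.level = 0.05)
  mine <- power_pooled_t(0, 1, 40, 0.5, 1, 40, alpha = 0.05)
  expect_equal(mine, ref$power, tolerance = 1e-4)
})

test_that("comparison report bundles tables with tidiers and JSON export", {
  ga <- sample_population(reference_group_params("male"), 30, rng_seed = 51)
  gb <- sample_population(reference_group_params("female"), 30, rng_seed = 52)
  rep <- compare_models(ga, gb, K = 20)
  expect_s3_class(rep, "comparison_report")
  expect_equal(rep$labels, c("male", "female"))
  td <- tidy(rep)
  expect_equal(nrow(td), 38)
  tf <- tidy(rep, type = "features")
  expect_equal(nrow(tf), 6)
  gl <- glance(rep)
  expect_true(gl$sig_locations_y >= 0 && gl$sig_locations_y <= 19)
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(j$pointwise_y), 19)
  expect_equal(j$n_a, 30)
  unlink(path)
})

test_that("the dorsal-positive display flag negates Y means only", {
  ga <- sample_population(reference_group_params("male"), 10, rng_seed = 61)
  gb <- sample_population(reference_group_params("female"), 10, rng_seed = 62)
  pw <- compare_pointwise(ga, gb, K = 10)
  pws <- compare_pointwise(ga, gb, K = 10, dorsal_sign = TRUE)
  expect_equal(pws$mean_a[pws$axis == "y"], -pw$mean_a[pw$axis == "y"])
  expect_equal(pws$mean_a[pws$axis == "x"], pw$mean_a[pw$axis == "x"])
  expect_equal(pws$p, pw$p)
})
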