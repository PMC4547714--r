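test_that("a symmetric bow comes out symmetric", {
  h <- 0.08
  crv <- analytic_centerline(0.5, h, h, segment_length = 180,
                             scoliosis_amplitude = 0)
  f <- compute_features(crv)
  expect_equal(f$peak_location, 0.5)
  expect_equal(f$caudal_peak_height, h)
  expect_equal(f$cranial_peak_height, h)
  y <- crv$y
  expect_equal(y[1], 0)
  expect_equal(y[length(y)], 0, tolerance = 1e-12)
})

test_that("reference female descriptors round-trip exactly", {
  crv <- analytic_centerline(0.274, 0.092, 0.061, segment_length = 179)
  f <- compute_features(crv)
  expect_equal(f$peak_location, 0.274, tolerance = 1e-6)
  expect_equal(f$cranial_peak_height, 0.092, tolerance = 1e-6)
  expect_equal(f$caudal_peak_height, 0.061, tolerance = 1e-6)
  expect_equal(f$segment_length_mm, 179, tolerance = 1e-3)
})

test_that("descriptor round-trip holds across random valid tuples", {
  set.seed(7)
  for (i in 1:25) {
    ft <- random_feature_tuple()
    crv <- analytic_centerline(ft[1], ft[2], ft[3], segment_length = ft[4],
                               scoliosis_amplitude = runif(1, -0.02, 0.02))
    f <- compute_features(crv)
    expect_lt(abs(f$peak_location - ft[1]), 1e-6)
    expect_lt(abs(f$cranial_peak_height - ft[2]), 1e-6)
    expect_lt(abs(f$caudal_peak_height - ft[3]), 1e-6)
    expect_lt(abs(f$segment_length_mm - ft[4]), 1e-3)
    expect_gte(f$curvedness, 1)
  }
})

test_that("degenerate peak locations are rejected", {
  expect_error(analytic_centerline(0, 0.1, 0.1), "singular|inside")
  expect_error(analytic_centerline(1, 0.1, 0.1), "singular|inside")
  expect_error(analytic_centerline(0.5, 0.1, 0.1, n_points = 10), ">= 50")
})

test_that("noiseless phantom voxels inside the truth mask are pure canal", {
  ph <- small_phantom(0)
  expect_true(all(ph$volume$data[ph$mask$data] == 10))
})

test_that("phantom generation is seed-deterministic", {
  spec <- phantom_spec(segment_length = 60, dim = c(32, 32, 50),
                       spacing = c(1.5, 1.5, 1.5), noise_sd = 15,
                       canal_radius = 5, ring_thickness_mm = 3,
                       rng_seed = 9)
  a <- synthesize_volume(spec)
  b <- synthesize_volume(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  spec2 <- spec; spec2$rng_seed <- 10
  c <- synthesize_volume(spec2)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("truth mask is exactly the tube around the analytic centerline", {
  ph <- small_phantom(0)
  idx <- which(ph$mask$data)
  # brute-force distance of every mask voxel to the centerline polyline
  ijk <- arrayInd(idx, dim(ph$mask$data))
  w <- sweep(ijk - 1, 2, ph$mask$spacing, "*")
  # brute-force point-to-segment distance for every mask voxel center
  m <- as.matrix(ph$curve[, c("x", "y", "z")])
  seg_a <- m[-nrow(m), , drop = FALSE]
  seg_ab <- m[-1, , drop = FALSE] - seg_a
  len2 <- pmax(rowSums(seg_ab^2), 1e-30)
  dist_to_curve <- function(p) {
    ap <- sweep(seg_a, 2, p, "-")
    tt <- pmin(pmax(-rowSums(ap * seg_ab) / len2, 0), 1)
    q <- seg_a + seg_ab * tt
    min(sqrt(rowSums(sweep(q, 2, p, "-")^2)))
  }
  din <- vapply(seq_len(nrow(w)), function(i) dist_to_curve(w[i, ]),
                numeric(1))
  # every mask voxel lies within the canal radius of the centerline
  expect_lte(max(din), 6 + 1e-9)
  # and a sample of outside voxels all lie beyond it
  set.seed(5)
  out_idx <- sample(which(!ph$mask$data), 500)
  ijk_out <- arrayInd(out_idx, dim(ph$mask$data))
  w_out <- sweep(ijk_out - 1, 2, ph$mask$spacing, "*")
  dout <- vapply(seq_len(nrow(w_out)), function(i) dist_to_curve(w_out[i, ]),
                 numeric(1))
  expect_gt(min(dout), 6)
})

test_that("an oversized tube fails to fit the grid", {
  expect_error(
    synthesize_volume(phantom_spec(segment_length = 300,
                                   dim = c(32, 32, 40),
                                   spacing = c(1.5, 1.5, 1.5),
                                   canal_radius = 12,
                                   ring_thickness_mm = 12)),
    "does not fit")
})

test_that("population sampling is deterministic and degenerate at sd = 0", {
  p0 <- group_params("fixed",
                     peak_location = c(0.3, 0),
                     cranial_peak_height = c(0.08, 0),
                     caudal_peak_height = c(0.06, 0),
                     segment_length = c(180, 0),
                     scoliosis_amplitude = c(0.005, 0))
  s <- sample_population(p0, 4, rng_seed = 1)
  for (k in 2:4) expect_equal(as.matrix(s[[1]]), as.matrix(s[[k]]))
  pm <- reference_group_params("male")
  a <- sample_population(pm, 6, rng_seed = 3)
  b <- sample_population(pm, 6, rng_seed = 3)
  cc <- sample_population(pm, 6, rng_seed = 4)
  expect_equal(lapply(a, as.matrix), lapply(b, as.matrix))
  expect_false(isTRUE(all.equal(lapply(a, as.matrix),
                                lapply(cc, as.matrix))))
})

test_that("empirical descriptor means converge to the group parameters", {
  pm <- reference_group_params("male")
  s <- sample_population(pm, 2000, rng_seed = 11)
  f <- population_features(s)
  # 3 * sd / sqrt(n) tolerance around the generating mean
  expect_lt(abs(mean(f$peak_location) - 0.299), 3 * 0.086 / sqrt(2000))
  expect_lt(abs(mean(f$cranial_peak_height) - 0.074),
            3 * 0.024 / sqrt(2000))
  expect_true(all(f$curvedness >= 1))
})
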