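test_that("the automatic seed lands inside the canal", {
  ph <- small_phantom(0)
  seed <- find_seed(ph$volume)
  expect_true(ph$mask$data[seed[1], seed[2], seed[3]])
})

test_that("a uniform soft-tissue volume has no seed", {
  v <- image_volume(array(40, c(32, 32, 32)), c(1, 1, 1))
  expect_error(find_seed(v), class = "canalcurve_seed_not_found")
})

test_that("with two canal-like tubes the more dorsal one is seeded", {
  dims <- c(60, 60, 24); sp <- c(1, 1, 1.5)
  arr <- array(40, dims)
  put_tube <- function(arr, cx, cy, r = 5, ring = 3) {
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
      d <- sqrt((i - cx)^2 + (j - cy)^2)
      if (d <= r) arr[i, j, ] <- 10
      else if (d <= r + ring) arr[i, j, ] <- 1200
    }
    arr
  }
  arr <- put_tube(arr, 30, 15)  # dorsal (low Y index)
  arr <- put_tube(arr, 30, 45)  # ventral
  v <- image_volume(arr, sp)
  seed <- find_seed(v)
  expect_lt(seed[2], 30) # dorsal tube chosen
})

test_that("region growing recovers the canal on a noiseless phantom", {
  ph <- small_phantom(0)
  seed <- find_seed(ph$volume)
  coarse <- region_grow(ph$volume, seed)
  expect_gte(dice_overlap(coarse, ph$mask), 0.90)
})

test_that("a seed outside the intensity band is rejected", {
  ph <- small_phantom(0)
  params <- segmentation_params(intensity_low = 300, intensity_high = 500)
  seed <- find_seed(ph$volume) # from default band
  expect_error(region_grow(ph$volume, seed, params),
               class = "canalcurve_seed_invalid")
})

test_that("an area cap below the tube cross-section stops growth at the seed slice", {
  ph <- small_phantom(0)
  seed <- find_seed(ph$volume)
  # tube cross-section is pi * 6^2 = 113 mm^2
  params <- segmentation_params(slice_area_min = 10, slice_area_max = 80)
  m <- region_grow(ph$volume, seed, params)
  occ <- which(apply(m$data, 3, any))
  expect_identical(occ, seed[3]) # only the seed slice is occupied
})

test_that("refinement with zero iterations is the identity", {
  ph <- small_phantom(0)
  seed <- find_seed(ph$volume)
  coarse <- region_grow(ph$volume, seed)
  params <- segmentation_params(refine_iterations = 0)
  expect_identical(refine_active_surface(ph$volume, coarse, params)$data,
                   coarse$data)
  expect_error(
    refine_active_surface(ph$volume,
                          binary_mask(array(FALSE, dim(ph$volume$data)),
                                      ph$volume$spacing)),
    "empty")
})

test_that("refinement recovers an eroded truth mask without losing overlap", {
  ph <- small_phantom(0)
  eroded <- binary_mask(erode1(ph$mask$data), ph$mask$spacing)
  d0 <- dice_overlap(eroded, ph$mask)
  refined <- refine_active_surface(ph$volume, eroded)
  d1 <- dice_overlap(refined, ph$mask)
  expect_gte(d1, d0)
  expect_gte(d1, 0.97)
})

test_that("on a noisy phantom the refined boundary stays near the truth surface", {
  ph <- small_phantom(30)
  m <- segment_canal(ph$volume)
  # mean distance from the refined boundary to the truth boundary, via the
  # distance transform of the truth boundary voxel set
  dims <- dim(ph$mask$data)
  truth_boundary <- ph$mask$data & !erode1(ph$mask$data)
  dist_to_tb <- array(canalcurve:::cpp_edt3d(!as.logical(truth_boundary),
                                             dims, ph$mask$spacing), dims)
  boundary <- m$data & !erode1(m$data)
  expect_lte(mean(dist_to_tb[boundary]), max(ph$mask$spacing))
})

test_that("segment_canal composes the stages and honors a manual seed", {
  ph <- small_phantom(20)
  auto <- segment_canal(ph$volume)
  expect_gte(dice_overlap(auto, ph$mask), 0.92)
  seed <- find_seed(ph$volume)
  manual <- segment_canal(ph$volume, seed = seed)
  expect_identical(auto$data, manual$data)
  log <- attr(auto, "segmentation_log")
  expect_true(all(c("seed", "coarse_voxels", "refined_voxels") %in%
                  names(log)))
  # no-canal volume propagates the seed error
  flat <- image_volume(array(40, c(32, 32, 32)), c(1, 1, 1))
  expect_error(segment_canal(flat), class = "canalcurve_seed_not_found")
})

test_that("segmentation output is one connected component and deterministic", {
  ph <- small_phantom(20)
  m1 <- segment_canal(ph$volume)
  m2 <- segment_canal(ph$volume)
  expect_identical(m1$data, m2$data)
  dims <- dim(m1$data)
  idx <- which(m1$data)[1]
  comp <- canalcurve:::cpp_keep_component(as.logical(m1$data), dims,
                                          as.integer(idx), TRUE)
  expect_equal(sum(comp), sum(m1$data))
})
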