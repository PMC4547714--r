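test_that("endpoints are slice centroids on the tube axis, swapping under a Z flip", {
  mask <- straight_tube_mask()
  ep <- endpoints_from_mask(mask)
  expect_lt(max(abs(ep$start[1:2] - c(15, 15))), 0.5) # half in-plane spacing
  expect_lt(max(abs(ep$end[1:2] - c(15, 15))), 0.5)
  expect_lt(ep$start[3], ep$end[3])
  flipped <- binary_mask(mask$data[, , dim(mask$data)[3]:1], mask$spacing)
  ep2 <- endpoints_from_mask(flipped)
  expect_equal(ep2$start[1:2], ep$start[1:2])
  expect_equal(ep2$end[1:2], ep$end[1:2])
  thin <- binary_mask(mask$data[, , 1:3, drop = FALSE], mask$spacing)
  expect_error(endpoints_from_mask(thin), "10 slices")
})

test_that("the speed map peaks on the medial axis and is epsilon outside", {
  mask <- straight_tube_mask()
  sp <- speed_map(mask)
  expect_equal(sp$data[1, 1, 1], 1e-6)
  for (k in c(5, 20, 35)) {
    sl <- sp$data[, , k]
    am <- which(sl == max(sl), arr.ind = TRUE)
    expect_lt(max(abs((am[1, ] - 1) * mask$spacing[1:2] - c(15, 15))), 1.01)
  }
  # max-speed voxels lie at least r - 1 voxel from the boundary
  d <- canalcurve:::cpp_edt3d(as.logical(mask$data), dim(mask$data),
                              mask$spacing)
  expect_gte(max(d), 6 - 1)
})

test_that("the minimal path through a uniform-speed straight tube is straight", {
  mask <- straight_tube_mask()
  sp_arr <- ifelse(mask$data, 1, 1e-6)
  sp <- image_volume(array(sp_arr, dim(mask$data)), mask$spacing)
  p <- minimal_path(sp, c(15, 15, 0), c(15, 15, 58.5))
  m <- as.matrix(p[, c("x", "y")])
  expect_lt(max(abs(m[, 1] - 15)), 1.5) # < 1 voxel spacing (in-plane 1 mm)
  expect_lt(max(abs(m[, 2] - 15)), 1.5)
  expect_error(minimal_path(sp, c(15, 15, 30), c(15, 15, 30)),
               "distinct")
})

test_that("arrival time strictly decreases along the back-trace", {
  ph <- small_phantom(0)
  seed <- find_seed(ph$volume)
  m <- region_grow(ph$volume, seed)
  ep <- endpoints_from_mask(m)
  sp <- speed_map(m)
  p <- minimal_path(sp, ep$start, ep$end)
  tt <- attr(p, "path_times") # ordered start -> end
  expect_true(all(diff(tt) > 0))
})

test_that("a disconnected support yields a no-path error", {
  mask <- straight_tube_mask()
  arr <- mask$data
  arr[, , 18:22] <- FALSE # sever the tube
  sp_arr <- ifelse(arr, 1, 1e-6)
  sp <- image_volume(array(sp_arr, dim(arr)), mask$spacing)
  expect_error(minimal_path(sp, c(15, 15, 0), c(15, 15, 58.5)),
               class = "canalcurve_no_path")
})

test_that("fast-marching cost agrees with a Dijkstra voxel-graph oracle", {
  skip_if_not_installed("igraph")
  dims <- c(20, 20, 20); spg <- c(1, 1, 1)
  arr <- array(FALSE, dims)
  cx <- function(k) 10 + 3 * sin(pi * (k - 1) / 19)
  for (k in 1:20) for (j in 1:20) for (i in 1:20)
    if (sqrt((i - cx(k))^2 + (j - 10)^2) <= 4.2) arr[i, j, k] <- TRUE
  mask <- binary_mask(arr, spg)
  sp <- speed_map(mask)
  start <- c(cx(1) - 1, 9, 0); end <- c(cx(20) - 1, 9, 19)
  p <- minimal_path(sp, start, end)
  t_fm <- attr(p, "arrival_time")
  # independent oracle: Dijkstra on the 26-neighbor voxel graph with edge
  # weight = Euclidean length x mean slowness of its endpoints
  idx <- which(arr)
  ijk <- arrayInd(idx, dims)
  id <- array(0L, dims); id[idx] <- seq_along(idx)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  slow <- 1 / sp$data
  edges <- NULL; wts <- NULL
  for (r in seq_len(nrow(off))) {
    nb <- sweep(ijk, 2, off[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    ok[ok] <- arr[nb[ok, , drop = FALSE]]
    from <- id[ijk[ok, , drop = FALSE]]
    to <- id[nb[ok, , drop = FALSE]]
    len <- sqrt(sum(off[r, ]^2))
    w <- len * 0.5 * (slow[ijk[ok, , drop = FALSE]] +
                      slow[nb[ok, , drop = FALSE]])
    keep <- from < to
    edges <- rbind(edges, cbind(from[keep], to[keep]))
    wts <- c(wts, w[keep])
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- wts
  sv <- id[matrix(round(start / spg) + 1, 1)]
  ev <- id[matrix(round(end / spg) + 1, 1)]
  t_dj <- igraph::distances(g, v = sv, to = ev)[1, 1]
  expect_lt(abs(t_fm / t_dj - 1), 0.05)
})

test_that("resampling spaces points uniformly and smoothing reduces noise", {
  # window 1: pure arc-length resampling
  th <- seq(0, pi, length.out = 200)
  crv <- curve3d(x = cos(th), y = sin(th), z = seq(0, 40, length.out = 200))
  r1 <- resample_smooth(crv, step = 1, window = 1)
  seglen <- sqrt(diff(r1$x)^2 + diff(r1$y)^2 + diff(r1$z)^2)
  expect_lt(diff(range(seglen)), 1e-6)
  # straight line is a fixed point of smoothing
  line <- curve3d(x = rep(0, 50), y = rep(0, 50),
                  z = seq(0, 49, length.out = 50))
  sm <- resample_smooth(line, step = 1, window = 5)
  expect_lt(max(abs(sm$x)), 1e-12)
  expect_lt(max(abs(sm$y)), 1e-12)
  # noisy sinusoid: smoothing reduces the residual to the clean curve
  set.seed(3)
  z <- seq(0, 100, length.out = 300)
  clean <- sin(z / 8)
  noisy <- curve3d(x = clean + rnorm(300, 0, 0.3), y = rep(0, 300), z = z)
  smoothed <- resample_smooth(noisy, step = 0.5, window = 5)
  ref <- function(crv) sqrt(mean((crv$x - sin(crv$z / 8))^2))
  expect_lt(ref(smoothed), ref(noisy))
  # arc length is preserved to within 2%
  arc <- function(crv) sum(sqrt(diff(crv$x)^2 + diff(crv$y)^2 + diff(crv$z)^2))
  expect_lt(abs(arc(resample_smooth(crv, 1, 5)) / arc(crv) - 1), 0.02)
  expect_error(resample_smooth(crv, step = 0), "positive")
  expect_error(resample_smooth(crv, step = 1, window = 4), "odd")
})

test_that("the extracted centerline tracks the phantom truth", {
  for (noise in c(0, 20)) {
    ph <- small_phantom(noise)
    m <- segment_canal(ph$volume)
    ctr <- extract_centerline(m)
    d <- curve_distance(ctr, ph$curve)
    expect_lte(d$mean, max(ph$volume$spacing))
    expect_lte(d$max, 2 * max(ph$volume$spacing))
  }
})
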