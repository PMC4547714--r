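# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# small lumbar phantom (64 x 64 x 80 voxels) at a given noise level
small_phantom <- function(noise_sd = 0) {
  fixture(paste0("phantom_", noise_sd), function() {
    synthesize_volume(phantom_spec(
      segment_length = 80, dim = c(64, 64, 80),
      spacing = c(1.2, 1.2, 1.5), noise_sd = noise_sd,
      canal_radius = 6, ring_thickness_mm = 4, rng_seed = 42
    ))
  })
}

# draw one random valid descriptor tuple (within the reference cohort's
# observed ranges)
random_feature_tuple <- function() {
  c(peak_location = runif(1, 0.12, 0.55),
    cranial_peak_height = runif(1, 0.02, 0.15),
    caudal_peak_height = runif(1, 0.012, 0.13),
    segment_length = runif(1, 140, 250))
}

# straight vertical tube mask (axis at `axis_mm`, unit-ish spacing)
straight_tube_mask <- function(dims = c(31, 31, 40),
                               spacing = c(1, 1, 1.5),
                               axis_mm = c(15, 15), radius = 6) {
  arr <- array(FALSE, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    d <- sqrt(((i - 1) * spacing[1] - axis_mm[1])^2 +
              ((j - 1) * spacing[2] - axis_mm[2])^2)
    if (d <= radius) arr[i, j, ] <- TRUE
  }
  binary_mask(arr, spacing)
}

# binary erosion by one voxel (6-neighborhood), for refinement tests
erode1 <- function(arr) {
  n <- dim(arr)
  pad <- array(FALSE, n + 2)
  pad[2:(n[1] + 1), 2:(n[2] + 1), 2:(n[3] + 1)] <- arr
  arr &
    pad[1:n[1], 2:(n[2] + 1), 2:(n[3] + 1)] &
    pad[3:(n[1] + 2), 2:(n[2] + 1), 2:(n[3] + 1)] &
    pad[2:(n[1] + 1), 1:n[2], 2:(n[3] + 1)] &
    pad[2:(n[1] + 1), 3:(n[2] + 2), 2:(n[3] + 1)] &
    pad[2:(n[1] + 1), 2:(n[2] + 1), 1:n[3]] &
    pad[2:(n[1] + 1), 2:(n[2] + 1), 3:(n[3] + 2)]
}
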