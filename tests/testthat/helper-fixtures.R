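# Shared fixtures: everything is generated in code at test time.

tiny_phantom <- function(seed = 1L, shape = c(24L, 24L, 24L), n_vessels = 2L) {
  generate_phantom(phantom_spec(shape = shape, n_vessels = n_vessels,
                                radius_range = c(2, 4), seed = seed))
}

tiny_config <- function(patch_size = 8L, base_channels = 2L, depth = 2L,
                        dilation_rate = 2L, ...) {
  mismatch_config(base_channels = base_channels, depth = depth,
                  dilation_rate = dilation_rate, patch_size = patch_size, ...)
}

# A ramp volume whose value encodes its (z, y, x) voxel coordinates uniquely.
ramp_volume <- function(shape) {
  array(as.numeric(seq_len(prod(shape))), dim = shape)
}

random_mask <- function(shape, p = 0.2, seed = 1L) {
  s <- rng_stream(seed)
  with_stream(s, array(as.numeric(runif(prod(shape)) < p), dim = shape))
}

expect_same_array <- function(a, b, tol = 0) {
  expect_identical(dim(a), dim(b))
  if (tol == 0) expect_identical(as.numeric(a), as.numeric(b))
  else expect_lt(max(abs(a - b)), tol)
}
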