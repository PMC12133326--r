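test_that("plan_patches enumerates the expected grid", {
  ps <- plan_patches(c(10, 10, 10), 4, 2)
  expect_identical(length(ps), 64L)                 # 4 positions per axis
  expect_identical(sort(unique(ps$origins[, 1])), c(0L, 2L, 4L, 6L))
  # stride 3: last window [6, 10) clamps at the edge
  ps3 <- plan_patches(c(10, 10, 10), 4, 3)
  expect_identical(sort(unique(ps3$origins[, 1])), c(0L, 3L, 6L))
})

test_that("stride equal to size on a divisible shape gives an exact partition", {
  ps <- plan_patches(c(8, 8, 8), 4, 4)
  expect_identical(length(ps), 8L)
  v <- ramp_volume(c(8, 8, 8))
  patches <- extract_patches(v, ps)
  expect_identical(sort(unlist(patches)), as.numeric(sort(v)))  # conservation
})

test_that("plan_patches rejects invalid size and stride", {
  expect_error(plan_patches(c(8, 8, 8), 9, 2), "exceeds")
  expect_error(plan_patches(c(8, 8, 8), 4, 0), "stride")
  expect_error(plan_patches(c(8, 8, 8), 4, 5), "stride")
})

test_that("every voxel is covered by at least one planned patch", {
  s <- rng_stream(42)
  for (i in 1:50) {
    prm <- with_stream(s, {
      shape <- sample(8:20, 3, replace = TRUE)
      size <- sample(2:min(shape), 1)
      list(shape = shape, size = size, stride = sample(size, 1))
    })
    ps <- plan_patches(prm$shape, prm$size, prm$stride)
    cov <- array(0L, dim = prm$shape)
    for (j in seq_len(length(ps))) {
      o <- ps$origins[j, ]
      w <- lapply(1:3, function(a) (o[a] + 1):(o[a] + prm$size))
      cov[w[[1]], w[[2]], w[[3]]] <- cov[w[[1]], w[[2]], w[[3]]] + 1L
    }
    expect_true(all(cov >= 1L),
                label = sprintf("coverage for shape=%s size=%d stride=%d",
                                paste(prm$shape, collapse = "x"),
                                prm$size, prm$stride))
  }
})

test_that("stitch of an unmodified extraction reproduces the volume", {
  s <- rng_stream(7)
  for (i in 1:20) {
    prm <- with_stream(s, {
      shape <- sample(6:16, 3, replace = TRUE)
      size <- sample(2:min(shape), 1)
      stride <- if (i %% 2 == 0) size else sample(size, 1)  # partition and overlap
      list(shape = shape, size = size, stride = stride,
           data = array(rnorm(prod(shape)), dim = shape))
    })
    ps <- plan_patches(prm$shape, prm$size, prm$stride)
    st <- stitch_patches(extract_patches(prm$data, ps), ps)
    expect_lt(max(abs(st$data - prm$data)), 1e-12)
  }
})

test_that("overlapping constant predictions blend to their mean", {
  ps <- structure(list(origins = rbind(c(0L, 0L, 0L), c(2L, 0L, 0L)),
                       size = 4L, stride = 2L, source_shape = c(6L, 4L, 4L)),
                  class = "vssl_patchset")
  st <- stitch_patches(list(array(0, c(4, 4, 4)), array(1, c(4, 4, 4))), ps)
  expect_true(all(st$data[1:2, , ] == 0))       # only patch 1
  expect_true(all(st$data[3:4, , ] == 0.5))     # overlap: mean of 0 and 1
  expect_true(all(st$data[5:6, , ] == 1))       # only patch 2
  # three-way overlap of {0, 0.5, 1} averages to 0.5
  ps3 <- structure(list(origins = rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(0L, 0L, 0L)),
                        size = 2L, stride = 2L, source_shape = c(2L, 2L, 2L)),
                   class = "vssl_patchset")
  st3 <- stitch_patches(list(array(0, c(2, 2, 2)), array(0.5, c(2, 2, 2)),
                             array(1, c(2, 2, 2))), ps3)
  expect_true(all(st3$data == 0.5))
})

test_that("stitching an incomplete patchset reports the uncovered region", {
  ps <- plan_patches(c(8, 8, 8), 4, 4)
  ps$origins <- ps$origins[-1, , drop = FALSE]
  patches <- rep(list(array(1, c(4, 4, 4))), length(ps))
  expect_error(stitch_patches(patches, ps), "uncovered")
})

test_that("label-density filter applies strict thresholds", {
  shape <- c(8, 8, 8)
  labels <- array(0, dim = shape)
  ps <- plan_patches(shape, 4, 4)               # 8 disjoint patches
  # empty mask, strict_positive: everything excluded
  expect_identical(length(filter_by_label_density(ps, labels, "strict_positive")), 0L)
  # one labeled voxel in one patch: that patch kept under strict_positive
  labels[1, 1, 1] <- 1
  kept <- filter_by_label_density(ps, labels, "strict_positive")
  expect_identical(length(kept), 1L)
  expect_identical(kept$origins[1, ], c(0L, 0L, 0L))
})

test_that("a patch at 3.8% density is excluded at the 5% level", {
  # 10,000 labeled voxels in a 64^3 patch = 3.8% < 5%
  shape <- c(64, 64, 64)
  labels <- array(0, dim = shape)
  labels[seq_len(10000)] <- 1
  ps <- plan_patches(shape, 64, 64)
  expect_identical(length(filter_by_label_density(ps, labels, 5)), 0L)
  expect_identical(length(filter_by_label_density(ps, labels, 2.5)), 1L)
})

test_that("raising the density level never adds patches", {
  ph <- tiny_phantom(seed = 9, shape = c(32, 32, 32), n_vessels = 3)
  ps <- plan_patches(c(32, 32, 32), 8, 4)
  levels <- list("strict_positive", 1, 2.5, 5)
  ns <- vapply(levels, function(l)
    length(filter_by_label_density(ps, ph$labels, l)), integer(1))
  expect_true(all(diff(ns) <= 0))
  # strict positivity boundary: any patch with >= 1 labeled voxel is kept
  kept <- filter_by_label_density(ps, ph$labels, "strict_positive")
  counts <- vapply(extract_patches(ph$labels$mask, kept), sum, numeric(1))
  expect_true(all(counts >= 1))
})

test_that("labeled_fraction reproduces the printed dataset accounting", {
  expect_equal(labeled_fraction_counts(56665263, 6188038598), 0.9157)
  expect_equal(labeled_fraction_counts(12491944, 731132380), 1.7086)
  expect_equal(labeled_fraction_counts(3204402, 3146478048), 0.1018)
  expect_equal(labeled_fraction(array(0, c(4, 4, 4))), 0)
})

test_that("labeled_fraction is consistent under patch decomposition", {
  m <- random_mask(c(12, 12, 12), p = 0.1, seed = 5)
  ps <- plan_patches(c(12, 12, 12), 4, 4)       # exact partition
  per_patch <- vapply(extract_patches(m, ps), mean, numeric(1))
  expect_equal(round(100 * mean(per_patch), 4), labeled_fraction(m))
})

test_that("patch manifests round-trip through YAML", {
  ps <- plan_patches(c(10, 9, 8), 4, 3)
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  write_patch_manifest(ps, path)
  rt <- read_patch_manifest(path)
  expect_identical(rt$origins, ps$origins)
  expect_identical(rt$size, ps$size)
  expect_identical(rt$source_shape, ps$source_shape)
})
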