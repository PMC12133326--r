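test_that("batch streams honour the counting contract and determinism", {
  cfg <- train_config("mismatch", batch_size = 2, unlabeled_ratio = 3,
                      crop_size = 8, seed = 11)
  nb <- make_batches(20, 30, cfg)
  for (i in 1:5) {
    b <- nb()
    expect_length(b$labeled, 2)
    expect_length(b$unlabeled, 6)                 # 2 * 3
    expect_true(all(b$labeled %in% 1:20) && all(b$unlabeled %in% 1:30))
  }
  # same seed, same sequence
  seq1 <- replicate(10, unlist(make_batches(20, 30, cfg)()), simplify = FALSE)
  nb2 <- make_batches(20, 30, cfg)
  nb1 <- make_batches(20, 30, cfg)
  s1 <- replicate(10, unlist(nb1()), simplify = FALSE)
  s2 <- replicate(10, unlist(nb2()), simplify = FALSE)
  expect_identical(s1, s2)
  # degenerate ratio: purely labeled batches
  cfg0 <- train_config("supervised", unlabeled_ratio = 0, crop_size = 8)
  expect_length(make_batches(5, 0, cfg0)()$unlabeled, 0)
  cfgm <- train_config("mismatch", unlabeled_ratio = 2, crop_size = 8)
  expect_error(make_batches(5, 0, cfgm), "unlabeled")
})

test_that("identity-parameter augmentation only crops", {
  patch <- ramp_volume(c(12, 12, 12))
  labels <- random_mask(c(12, 12, 12), 0.3, seed = 1)
  out <- augment_patch(patch, labels, scheme = "full", crop_size = 8,
                       params = list(contrast = 1, zoom = 1, perm = 1:3,
                                     origin = c(3L, 2L, 5L)))
  expect_same_array(out$patch, patch[3:10, 2:9, 5:12])
  expect_same_array(out$labels, labels[3:10, 2:9, 5:12])
})

test_that("random crops are contiguous sub-windows of the requested size", {
  patch <- ramp_volume(c(16, 16, 16))
  s <- rng_stream(2)
  for (i in 1:10) {
    out <- augment_patch(patch, scheme = "crop", crop_size = 8, stream = s)
    expect_identical(dim(out$patch), c(8L, 8L, 8L))
    o <- out$params$origin
    expect_same_array(out$patch,
                      patch[o[1]:(o[1] + 7), o[2]:(o[2] + 7), o[3]:(o[3] + 7)])
  }
  expect_error(augment_patch(patch, scheme = "crop", crop_size = 32), "exceeds")
})

test_that("geometric transforms co-move image and labels", {
  patch <- ramp_volume(c(10, 10, 10))
  labels <- random_mask(c(10, 10, 10), 0.3, seed = 3)
  prm <- c(2L, 3L, 1L)
  out <- augment_patch(patch, labels, scheme = "full", crop_size = 10,
                       params = list(contrast = 1, zoom = 1, perm = prm,
                                     origin = c(1L, 1L, 1L)))
  expect_same_array(out$labels, aperm(labels, prm))
  expect_same_array(out$patch, aperm(patch, prm))
  # voxelwise correspondence: the image value at every labeled voxel is
  # unchanged by the joint permutation
  expect_identical(sort(out$patch[out$labels == 1]), sort(patch[labels == 1]))
})

test_that("zoom resamples labels with nearest neighbour, keeping them binary", {
  labels <- random_mask(c(9, 9, 9), 0.4, seed = 4)
  patch <- ramp_volume(c(9, 9, 9))
  out <- augment_patch(patch, labels, scheme = "full", crop_size = 9,
                       params = list(contrast = 1.1, zoom = 1.1, perm = 1:3,
                                     origin = c(1L, 1L, 1L)))
  expect_true(all(out$labels %in% c(0, 1)))
  expect_identical(dim(out$labels), c(9L, 9L, 9L))
})

test_that("contrast scaling never touches the labels", {
  labels <- random_mask(c(8, 8, 8), 0.3, seed = 5)
  patch <- array(0.5, c(8, 8, 8))
  out <- augment_patch(patch, labels, scheme = "full", crop_size = 8,
                       params = list(contrast = 1.4, zoom = 1, perm = 1:3,
                                     origin = c(1L, 1L, 1L)))
  expect_same_array(out$labels, labels)
})

test_that("supervised training improves held-out dice on a separable phantom", {
  ph <- generate_phantom(phantom_spec(shape = c(24, 24, 24), n_vessels = 3,
                                      intensity_sd = 0.06, seed = 31))
  vol <- normalize_volume(ph$volume, "zscore")
  ps <- plan_patches(c(24, 24, 24), 8, 8)
  labeled <- mapply(function(x, y) list(x = x, y = y),
                    extract_patches(vol, ps),
                    extract_patches(ph$labels$mask, ps), SIMPLIFY = FALSE)
  val <- labeled[1:4]
  cfg <- train_config("supervised", batch_size = 2, crop_size = 8,
                      base_channels = 2, learning_rate = 5e-3,
                      iterations = 60, seed = 1, validation_cadence = 59)
  m0 <- vesselssl:::model_from_config(cfg, vesselssl:::derive_seed(1L, 3L))
  d0 <- vesselssl:::validate_dice(m0, val)
  res <- fit_model(cfg, labeled, validation = val)
  d1 <- res$log$val_dice[!is.na(res$log$val_dice)]
  expect_gt(utils::tail(d1, 1), d0)
})

test_that("training runs reproduce bit-for-bit under a fixed seed", {
  ph <- tiny_phantom(seed = 32, shape = c(16, 16, 16))
  ps <- plan_patches(c(16, 16, 16), 8, 8)
  labeled <- mapply(function(x, y) list(x = x, y = y),
                    extract_patches(ph$volume$data, ps),
                    extract_patches(ph$labels$mask, ps), SIMPLIFY = FALSE)
  unl <- extract_patches(ph$volume$data, ps)
  cfg <- train_config("mismatch", alpha = 0.1, batch_size = 1, crop_size = 8,
                      base_channels = 2, iterations = 6, seed = 21)
  r1 <- fit_model(cfg, labeled, unl)
  r2 <- fit_model(cfg, labeled, unl)
  expect_identical(r1$log, r2$log)
  expect_identical(net_state(r1$model)$params, net_state(r2$model)$params)
})

test_that("a resumed run continues identically to an uninterrupted one", {
  ph <- tiny_phantom(seed = 33, shape = c(16, 16, 16))
  ps <- plan_patches(c(16, 16, 16), 8, 8)
  labeled <- mapply(function(x, y) list(x = x, y = y),
                    extract_patches(ph$volume$data, ps),
                    extract_patches(ph$labels$mask, ps), SIMPLIFY = FALSE)
  cfg10 <- train_config("supervised", batch_size = 1, crop_size = 8,
                        base_channels = 2, iterations = 10, seed = 8)
  full <- fit_model(cfg10, labeled)
  cfg5 <- cfg10; cfg5$iterations <- 5L
  part <- fit_model(cfg5, labeled)
  resumed <- fit_model(cfg10, labeled, resume = part$state)
  expect_identical(resumed$log$L_total, full$log$L_total)
  expect_identical(net_state(resumed$model)$params, net_state(full$model)$params)
})

test_that("masked supervised loss ignores unannotated slices", {
  ph <- tiny_phantom(seed = 34, shape = c(16, 16, 16))
  sparse <- sparsify_annotation(ph$labels, annotation_policy(4, FALSE, 1))
  labeled <- list(list(x = ph$volume$data, y = sparse$mask,
                       annotated = sparse$annotated_slices))
  cfg <- train_config("supervised", batch_size = 1, crop_size = 16,
                      base_channels = 2, iterations = 3, seed = 2)
  res <- fit_model(cfg, labeled, masked_loss = TRUE)
  expect_identical(nrow(res$log), 3L)
  expect_true(all(is.finite(res$log$L_total)))
})
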