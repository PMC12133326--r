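test_that("pseudo-labels equal brute-force voxelwise thresholding", {
  s <- rng_stream(31)
  for (i in 1:10) {
    probs <- with_stream(s, array(runif(4^3), c(4, 4, 4)))
    # plant exact ties
    probs[c(1, 17, 33)] <- 0.5
    for (T in c(0.3, 0.5, 0.7)) {
      pl <- pseudo_labels(probs, T)
      oracle <- array(0, dim(probs))
      for (z in 1:4) for (y in 1:4) for (x in 1:4)
        oracle[z, y, x] <- if (probs[z, y, x] >= T) 1 else 0
      expect_same_array(pl, oracle)
    }
  }
})

test_that("the tie at exactly T maps to pseudo-label 1", {
  p <- array(c(0.7, 0.5, 0.3, 0.499999), c(4, 1, 1))
  expect_identical(as.numeric(pseudo_labels(p, 0.5)), c(1, 1, 0, 0))
})

test_that("e_step produces detached binary targets from model probabilities", {
  cfg <- tiny_config(patch_size = 8)
  m <- build_unet(cfg, seed = 3)
  s <- rng_stream(5)
  patches <- lapply(1:3, function(i) with_stream(s, array(rnorm(8^3), c(8, 8, 8))))
  pb <- e_step(m, patches, threshold = 0.5)
  expect_length(pb$pseudo, 3)
  for (i in 1:3) {
    expect_true(all(pb$pseudo[[i]] %in% c(0, 1)))
    expect_same_array(pb$pseudo[[i]], pseudo_labels(pb$probs[[i]], 0.5))
    expect_same_array(pb$probs[[i]], net_forward(m, patches[[i]])$p)
  }
  expect_error(e_step(m, list(), 0.5), "empty")
})

test_that("raising T never increases the pseudo-label positive fraction", {
  probs <- with_stream(rng_stream(41), array(runif(6^3), c(6, 6, 6)))
  fr <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
               function(T) mean(pseudo_labels(probs, T)), numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("EM training with a zero iteration budget is a no-op", {
  cfg <- tiny_config(patch_size = 8)
  m <- build_unet(cfg, seed = 1)
  w_before <- net_state(m)
  ph <- generate_phantom(phantom_spec(shape = c(8, 8, 8), n_vessels = 1,
                                      radius_range = c(2, 3), seed = 2))
  labeled <- list(list(x = ph$volume$data, y = ph$labels$mask))
  res <- segpl_fit(m, labeled, list(ph$volume$data),
                   segpl_config(max_iterations = 0))
  expect_identical(nrow(res$log), 0L)
  expect_identical(net_state(res$model)$params, w_before$params)
})

test_that("EM training logs are reproducible under a fixed seed", {
  cfg <- tiny_config(patch_size = 8)
  ph <- tiny_phantom(seed = 3, shape = c(16, 16, 16), n_vessels = 2)
  ps <- plan_patches(c(16, 16, 16), 8, 8)
  labeled <- mapply(function(x, y) list(x = x, y = y),
                    extract_patches(ph$volume$data, ps),
                    extract_patches(ph$labels$mask, ps), SIMPLIFY = FALSE)
  unl <- extract_patches(ph$volume$data, ps)
  run <- function() {
    m <- build_unet(cfg, seed = 9)
    segpl_fit(m, labeled, unl, segpl_config(alpha = 0.1, max_iterations = 8),
              seed = 4)$log
  }
  expect_identical(run(), run())
})

test_that("pseudo-label positive fraction tracks the labeled fraction on a separable phantom", {
  # unlabeled stream duplicated from the labeled stream: after supervised
  # learning drives probabilities apart, thresholded pseudo-labels should
  # approach the true positive fraction
  ph <- generate_phantom(phantom_spec(shape = c(16, 16, 16), n_vessels = 2,
                                      radius_range = c(3, 5),
                                      intensity_sd = 0.05, seed = 12))
  vol <- normalize_volume(ph$volume, "zscore")$data
  labeled <- list(list(x = vol, y = ph$labels$mask))
  m <- build_unet(tiny_config(patch_size = 16), seed = 2)
  res <- segpl_fit(m, labeled, list(vol),
                   segpl_config(alpha = 0.1, max_iterations = 60),
                   batch_size = 1, unlabeled_ratio = 1, lr = 1e-2, seed = 3)
  true_frac <- mean(ph$labels$mask)
  pos <- res$log$positive_fraction
  # the late-training pseudo-positive fraction is far closer to truth than the
  # early one
  err_late <- abs(mean(utils::tail(pos, 5)) - true_frac)
  err_early <- abs(pos[1] - true_frac)
  expect_lt(err_late, err_early)
  expect_lt(err_late, 0.05)
})

test_that("total loss trends down over the first phase of EM training", {
  ph <- generate_phantom(phantom_spec(shape = c(16, 16, 16), n_vessels = 2,
                                      intensity_sd = 0.05, seed = 21))
  vol <- normalize_volume(ph$volume, "zscore")$data
  m <- build_unet(tiny_config(patch_size = 16), seed = 5)
  res <- segpl_fit(m, list(list(x = vol, y = ph$labels$mask)), list(vol),
                   segpl_config(alpha = 0.1, max_iterations = 50),
                   batch_size = 1, lr = 1e-2, seed = 6)
  lt <- res$log$L_total
  expect_lt(mean(utils::tail(lt, 10)), mean(utils::head(lt, 10)))
})
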