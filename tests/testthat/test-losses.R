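test_that("dice_loss matches hand-computed values", {
  # |P ∩ G| = 2, sum(P) = sum(G) = 4 -> Dice 0.5, loss 0.5
  pred <- array(0, c(2, 2, 2)); pred[1:4] <- 1
  target <- array(0, c(2, 2, 2)); target[3:6] <- 1
  expect_equal(dice_loss(pred, target), 0.5, tolerance = 1e-6)
  # identical binary masks -> loss 0 up to eps
  expect_lt(dice_loss(target, target), 1e-6)
  # disjoint nonzero masks -> loss -> 1 as eps -> 0
  a <- array(c(1, 0), c(2, 1, 1)); b <- array(c(0, 1), c(2, 1, 1))
  expect_gt(dice_loss(a, b), 1 - 1e-5)
  expect_lt(dice_loss(a, b), 1)
})

test_that("dice_loss guards shape mismatch and stays in [0, 1)", {
  expect_error(dice_loss(array(0, c(2, 2, 2)), array(0, c(2, 2, 3))), "shape")
  s <- rng_stream(3)
  for (i in 1:20) {
    pred <- with_stream(s, array(runif(27), c(3, 3, 3)))
    target <- random_mask(c(3, 3, 3), 0.4, seed = i)
    l <- dice_loss(pred, target)
    expect_gte(l, 0); expect_lt(l, 1)
  }
})

test_that("consistency_loss matches hand-computed MSE and is symmetric", {
  a <- array(c(0.2, 0.4), c(2, 1, 1)); b <- array(c(0.4, 0.8), c(2, 1, 1))
  expect_equal(consistency_loss(a, b), 0.1, tolerance = 1e-12)  # (0.2^2 + 0.4^2)/2
  expect_identical(consistency_loss(a, b), consistency_loss(b, a))
  expect_identical(consistency_loss(a, a), 0)
  one <- array(1, c(2, 2, 2)); zero <- array(0, c(2, 2, 2))
  expect_identical(consistency_loss(one, zero), 1)
  expect_error(consistency_loss(a, array(0, c(3, 1, 1))), "shapes differ")
})

test_that("the combined consistency-scheme loss is linear in alpha", {
  s <- rng_stream(11)
  labeled <- lapply(1:2, function(i) with_stream(s, list(
    p_final = array(runif(8), c(2, 2, 2)),
    target = array(as.numeric(runif(8) > 0.5), c(2, 2, 2)))))
  unlabeled <- lapply(1:3, function(i) with_stream(s, list(
    p_plus = array(runif(8), c(2, 2, 2)),
    p_minus = array(runif(8), c(2, 2, 2)))))
  sup <- mean(vapply(labeled, function(b) dice_loss(b$p_final, b$target), numeric(1)))
  con <- mean(vapply(unlabeled, function(b) consistency_loss(b$p_plus, b$p_minus), numeric(1)))
  l1 <- mismatch_total_loss(labeled, unlabeled, 1)
  l2 <- mismatch_total_loss(labeled, unlabeled, 2)
  expect_equal(as.numeric(l2) - as.numeric(l1), con, tolerance = 1e-12)
  # alpha = 0 reduces to the supervised term
  expect_equal(as.numeric(mismatch_total_loss(labeled, unlabeled, 0)), sup,
               tolerance = 1e-12)
  # empty labeled batch isolates the weighted consistency term
  expect_equal(as.numeric(mismatch_total_loss(list(), unlabeled, 2)), 2 * con,
               tolerance = 1e-12)
  expect_error(mismatch_total_loss(list(), list(), 1), "empty")
})

test_that("M-step loss combines the two Dice terms linearly in alpha", {
  s <- rng_stream(13)
  lp <- with_stream(s, array(runif(8), c(2, 2, 2)))
  ly <- random_mask(c(2, 2, 2), 0.5, seed = 2)
  up <- with_stream(s, array(runif(8), c(2, 2, 2)))
  pl <- pseudo_labels(up, 0.5)
  L_L <- dice_loss(lp, ly); L_U <- dice_loss(up, pl)
  m1 <- m_step_loss(lp, ly, up, pl, 1)
  m3 <- m_step_loss(lp, ly, up, pl, 3)
  expect_equal(as.numeric(m3) - as.numeric(m1), 2 * L_U, tolerance = 1e-12)
  expect_equal(as.numeric(m_step_loss(lp, ly, up, pl, 0)), L_L, tolerance = 1e-12)
  expect_equal(attr(m1, "L_L"), L_L)
  expect_equal(attr(m1, "L_U"), L_U)
  # binary predictions equal to their pseudo-labels zero the unsupervised term
  mb <- m_step_loss(lp, ly, pl, pl, 1)
  expect_equal(as.numeric(mb), L_L, tolerance = 1e-5)
  expect_error(m_step_loss(lp, ly, list(up), list(pl, pl), 1), "pseudo")
})

test_that("analytic loss gradients agree with finite differences", {
  s <- rng_stream(17)
  pred <- with_stream(s, array(runif(27, 0.05, 0.95), c(3, 3, 3)))
  target <- random_mask(c(3, 3, 3), 0.4, seed = 4)
  g <- vesselssl:::dice_loss_grad(pred, target)
  eps <- 1e-7
  for (i in c(1, 14, 27)) {
    p1 <- pred; p1[i] <- p1[i] + eps
    p2 <- pred; p2[i] <- p2[i] - eps
    expect_equal(g$grad[i], (dice_loss(p1, target) - dice_loss(p2, target)) / (2 * eps),
                 tolerance = 1e-4)
  }
  a <- with_stream(s, array(runif(27), c(3, 3, 3)))
  b <- with_stream(s, array(runif(27), c(3, 3, 3)))
  gc <- vesselssl:::consistency_loss_grad(a, b)
  for (i in c(2, 20)) {
    a1 <- a; a1[i] <- a1[i] + eps
    a2 <- a; a2[i] <- a2[i] - eps
    expect_equal(gc$g_plus[i],
                 (consistency_loss(a1, b) - consistency_loss(a2, b)) / (2 * eps),
                 tolerance = 1e-4)
  }
})
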