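# Loss definitions against independent scalar-loop oracles, the reliability
# semantics, and the cross-coordination truth table.

test_that("dice loss: limits, hand case, smoothing", {
  oh <- rect_onehot(4, 4, 3)
  perfect <- soft_prediction(logits = oh * 50, probs = oh, validate = FALSE)
  expect_equal(dice_loss(perfect, oh), 0, tolerance = 1e-6)

  # p = (1,1,0,0), y = (1,0,0,0) on 4 voxels, 2 classes (fg + complement bg):
  # fg dice = 2*1/(2+1) = 2/3, bg dice = 2*2/(2+3) = 4/5
  p_fg <- c(1, 1, 0, 0); y_fg <- c(1, 0, 0, 0)
  probs <- array(c(1 - p_fg, p_fg), c(4, 1, 2))
  oh2 <- array(c(1 - y_fg, y_fg), c(4, 1, 2))
  expect_equal(dice_loss(probs, oh2, smooth = 0), 1 - (2 / 3 + 4 / 5) / 2,
               tolerance = 1e-12)

  # class absent from both pred and target: contribution governed by the
  # smoothing constant -> s/s = 1, a perfect score
  lab <- array(0L, c(4, 4))
  oh3 <- one_hot(lab, 3)
  pr <- one_hot(lab, 3)  # all background, class 2 and 3 empty
  expect_equal(dice_loss(pr, oh3, smooth = 1e-5), 0, tolerance = 1e-12)

  expect_error(dice_loss(probs, array(0.5, c(4, 1, 2))), "one-hot")
})

test_that("cross-entropy: limits and closed forms", {
  oh <- rect_onehot(4, 4, 3)
  perfect <- soft_prediction(logits = oh * 50, probs = oh, validate = FALSE)
  expect_lt(cross_entropy_loss(perfect, oh), 1e-5)
  # uniform prediction over M classes: per-voxel value log(M)/M
  M <- 4
  unif <- array(1 / M, c(3, 3, M))
  ohu <- one_hot(array(sample(0:(M - 1), 9, TRUE), c(3, 3)), M)
  expect_equal(cross_entropy_loss(unif, ohu), log(M) / M, tolerance = 1e-12)
})

test_that("dice/CE/MSE/BCE agree with scalar-loop oracles on random inputs", {
  set.seed(314)
  for (i in 1:50) {
    M <- sample(2:4, 1)
    pred <- random_pred(4, 4, M, seed = 1000 + i)
    oh <- one_hot(array(sample(0:(M - 1), 16, TRUE), c(4, 4)), M)
    expect_equal(dice_loss(pred, oh), oracle_dice(pred$probs, oh),
                 tolerance = 1e-6)
    expect_equal(cross_entropy_loss(pred, oh), oracle_ce(pred$probs, oh),
                 tolerance = 1e-6)
    other <- random_pred(4, 4, M, seed = 2000 + i)
    expect_equal(consistency_loss(pred, other),
                 oracle_mse(pred$probs, other$probs), tolerance = 1e-6)
    sc <- array(rnorm(16), c(4, 4, 1, 1))
    expect_equal(adversarial_generator_loss(sc), oracle_bce(sc, 1),
                 tolerance = 1e-6)
    expect_equal(discriminator_loss(sc, -sc),
                 0.5 * (oracle_bce(sc, 1) + oracle_bce(-sc, 0)),
                 tolerance = 1e-6)
  }
})

test_that("supervised loss is the stated composition and is linear", {
  pred <- random_pred(6, 6, 3, seed = 7)
  oh <- rect_onehot(6, 6, 3)
  expect_equal(supervised_loss(pred, oh),
               0.5 * dice_loss(pred, oh) + cross_entropy_loss(pred, oh),
               tolerance = 1e-12)
})

test_that("consistency loss single-delta case", {
  a <- array(0.5, c(4, 4, 2))
  b <- a
  b[2, 3, 1] <- b[2, 3, 1] + 0.125
  n <- length(a)
  expect_equal(consistency_loss(a, b), 0.125^2 / n, tolerance = 1e-12)
  expect_equal(consistency_loss(a, a), 0)
  expect_error(consistency_loss(a, array(0.5, c(4, 5, 2))), "shape")
})

test_that("reliability semantics follow the boolean definition", {
  # all-agreeing, fully confident
  oh <- rect_onehot(4, 4, 3)
  pc <- soft_prediction(logits = oh * 50, probs = oh, validate = FALSE)
  rb <- compute_reliability(pc, pc, xi = 0.5)
  expect_true(all(rb$reliable))
  expect_equal(rb$epsilon, 0)

  # agreeing labels but both max-probs below xi -> unreliable
  lowconf <- array(c(0.6, 0.4), c(1, 1, 2))
  pr <- soft_prediction(logits = log(lowconf), probs = lowconf, validate = FALSE)
  rb2 <- compute_reliability(pr, pr, xi = 0.8)
  expect_false(any(rb2$reliable))

  # disagreeing argmax with high confidence -> unreliable (conjunctive)
  a <- array(c(0.99, 0.01), c(1, 1, 2))
  b <- array(c(0.01, 0.99), c(1, 1, 2))
  rb3 <- compute_reliability(
    soft_prediction(log(a), a, validate = FALSE),
    soft_prediction(log(b), b, validate = FALSE), xi = 0.5)
  expect_false(any(rb3$reliable))

  expect_error(compute_reliability(pc, pc, xi = 1.5), "xi")

  # property: R = (labels agree) & (M_x > xi | M_xbar > xi), voxel-wise
  set.seed(21)
  for (xi in c(0, 0.5, 0.8, 1)) {
    p1 <- random_pred(5, 5, 3, seed = 100 + round(xi * 10))
    p2 <- random_pred(5, 5, 3, seed = 200 + round(xi * 10))
    rb <- compute_reliability(p1, p2, xi)
    m1 <- matrix(p1$probs, ncol = 3); m2 <- matrix(p2$probs, ncol = 3)
    for (v in 1:25) {
      l1 <- which.max(m1[v, ]); l2 <- which.max(m2[v, ])
      want <- (l1 == l2) && (m1[v, l1] > xi || m2[v, l2] > xi)
      expect_identical(unname(as.vector(rb$reliable)[v]), want)
    }
    expect_equal(rb$epsilon, sqrt(sum((p1$probs - p2$probs)^2)),
                 tolerance = 1e-12)
  }
})

test_that("cross-coordination reproduces the 8-row truth table", {
  # build predictions whose MSE is known and bundles with controllable
  # (R, epsilon); quorum 0.5 with all-voxels-reliable or none
  mk_bundle <- function(h, w, M, reliable, eps) {
    structure(list(labels = array(1L, c(h, w)), labels_noisy = array(1L, c(h, w)),
                   maxprob = array(1, c(h, w)), maxprob_noisy = array(1, c(h, w)),
                   reliable = array(reliable, c(h, w)), epsilon = eps),
              class = "reliability_bundle")
  }
  p1 <- random_pred(4, 4, 2, seed = 31)
  p2 <- random_pred(4, 4, 2, seed = 32)
  mse <- mean((p1$probs - p2$probs)^2)

  # truth table rows: (R_i, R_j, eps relation) -> (loss_i, loss_j) in units
  # of mse. When both reliable, the strictly less stable student learns;
  # otherwise student i learns iff R_j = 1.
  cases <- list(
    list(1, 1, "gt", 1, 0), list(1, 1, "lt", 0, 1),
    list(1, 0, "gt", 0, 1), list(1, 0, "lt", 0, 1),
    list(0, 1, "gt", 1, 0), list(0, 1, "lt", 1, 0),
    list(0, 0, "gt", 0, 0), list(0, 0, "lt", 0, 0))
  for (cs in cases) {
    eps <- if (cs[[3]] == "gt") c(2, 1) else c(1, 2)
    cc <- cross_coordination_loss(
      mk_bundle(4, 4, 2, cs[[1]] == 1, eps[1]),
      mk_bundle(4, 4, 2, cs[[2]] == 1, eps[2]),
      p1, p2, quorum = 0.5)
    expect_equal(cc$loss_i, cs[[4]] * mse, tolerance = 1e-12,
                 label = sprintf("loss_i for R=(%d,%d) eps %s", cs[[1]],
                                 cs[[2]], cs[[3]]))
    expect_equal(cc$loss_j, cs[[5]] * mse, tolerance = 1e-12,
                 label = sprintf("loss_j for R=(%d,%d) eps %s", cs[[1]],
                                 cs[[2]], cs[[3]]))
  }
  # identical predictions: both losses 0 whatever the gates
  cc0 <- cross_coordination_loss(mk_bundle(4, 4, 2, TRUE, 2),
                                 mk_bundle(4, 4, 2, TRUE, 1), p1, p1)
  expect_equal(cc0$loss_i, 0)
  expect_equal(cc0$loss_j, 0)
  # epsilon tie with both reliable: neither learns
  cct <- cross_coordination_loss(mk_bundle(4, 4, 2, TRUE, 1),
                                 mk_bundle(4, 4, 2, TRUE, 1), p1, p2)
  expect_equal(cct$loss_i + cct$loss_j, 0)
})

test_that("adversarial/discriminator closed forms", {
  # perfectly fooled: large positive logits -> ~0
  expect_lt(adversarial_generator_loss(array(50, c(2, 2, 1, 1))), 1e-12)
  # probability 0.5 everywhere -> log 2 per element
  expect_equal(adversarial_generator_loss(array(0, c(3, 3, 1, 1))), log(2),
               tolerance = 1e-12)
  expect_equal(discriminator_loss(array(0, c(2, 2, 1, 1)),
                                  array(0, c(2, 2, 1, 1))), log(2),
               tolerance = 1e-12)
  expect_lt(discriminator_loss(array(50, c(2, 2, 1, 1)),
                               array(-50, c(2, 2, 1, 1))), 1e-12)
})

test_that("total student loss arithmetic and weight validation", {
  b <- total_student_loss(1, 1, 1, 1, xi_weight = 0.8, lambda_adv = 0.1)
  expect_equal(b$total, 2.9, tolerance = 1e-12)
  b0 <- total_student_loss(0, 0, 0, 0)
  expect_equal(b0$total, 0)
  # lambda_adv = 0 recovers the non-adversarial total
  b1 <- total_student_loss(0.5, 0.2, 0.1, 7, xi_weight = 1, lambda_adv = 0)
  expect_equal(b1$total, 0.8, tolerance = 1e-12)
  expect_error(total_student_loss(1, 1, 1, 1, xi_weight = -1), "negative")
})

test_that("entropy loss vanishes on one-hot predictions", {
  oh <- rect_onehot(4, 4, 3)
  p <- soft_prediction(logits = oh * 50, probs = oh, validate = FALSE)
  expect_lt(entropy_loss(p), 1e-4)
  unif <- array(1 / 3, c(2, 2, 3))
  expect_equal(entropy_loss(unif), log(3), tolerance = 1e-9)
})

test_that("analytic probability-gradients match finite differences", {
  pred <- random_pred(3, 3, 3, seed = 55)
  oh <- one_hot(array(sample(0:2, 9, TRUE), c(3, 3)), 3)
  eps <- 1e-6
  for (fn in list(c(dice_loss, dsseg:::dice_loss_grad),
                  c(cross_entropy_loss, dsseg:::cross_entropy_grad))) {
    f <- fn[[1]]; g <- fn[[2]]
    an <- g(pred$probs, oh)
    for (i in c(1, 10, 20)) {
      pp <- pred$probs; pp[i] <- pp[i] + eps
      pm <- pred$probs; pm[i] <- pm[i] - eps
      fd <- (f(pp, oh) - f(pm, oh)) / (2 * eps)
      expect_equal(unname(an[i]), fd, tolerance = 1e-4)
    }
  }
})
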