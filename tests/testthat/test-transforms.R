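# Transform sampling, replay, and the exact-lattice-symmetry guarantees the
# consistency machinery depends on.

test_that("sampling is deterministic and respects the config", {
  cfg <- transform_config()
  s1 <- sample_transform(7, cfg)
  s2 <- sample_transform(7, cfg)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_transform(8, cfg)))

  # degenerate ranges force the identity rotation
  id_cfg <- transform_config(rot90 = TRUE, k_range = 0L, flip = FALSE,
                             contrast = FALSE, noise = FALSE)
  sp <- sample_transform(3, id_cfg)
  expect_equal(sp$spatial[[1]]$k, 0L)
  expect_length(sp$intensity, 0)

  expect_error(sample_transform(1, transform_config(rot90 = FALSE, flip = FALSE,
                                                    contrast = FALSE,
                                                    noise = FALSE)),
               "no transforms enabled")
})

test_that("image replay is bit-exact and ops act on the right parts", {
  img <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
  sp <- sample_transform(11, transform_config())
  expect_identical(apply_to_image(img, sp), apply_to_image(img, sp))

  # identity spec leaves the image untouched
  id <- structure(list(spatial = list(), intensity = list()),
                  class = "transform_spec")
  expect_identical(apply_to_image(img, id), img)

  # flips are involutions
  fl <- structure(list(spatial = list(list(op = "flip", axis = 2L)),
                       intensity = list()), class = "transform_spec")
  expect_identical(apply_to_image(apply_to_image(img, fl), fl), img)

  # intensity ops never permute voxels: pure-noise spec keeps argsort of a
  # monotone image under a zero-noise contrast gain
  gain <- structure(list(spatial = list(),
                         intensity = list(list(op = "contrast", gain = 1.7))),
                    class = "transform_spec")
  expect_equal(apply_to_image(img, gain), img * 1.7)

  # labels receive spatial ops only
  lab <- matrix(sample(0:3, 32 * 32, TRUE), 32, 32)
  both <- apply_to_image(img, fl, labels = lab)
  expect_identical(both$labels, lab[, 32:1])
  expect_identical(storage.mode(both$labels), "integer")
})

test_that("rot90 matches the coordinate-tracking oracle", {
  m <- matrix(as.numeric(1:16), 4, 4)
  img <- array(m, c(4, 4, 1))
  sp <- structure(list(spatial = list(list(op = "rot90", k = 1L,
                                           axes = c(1L, 2L))),
                       intensity = list()), class = "transform_spec")
  got <- apply_to_image(img, sp)[, , 1]
  expect_identical(got, oracle_rot90_map(m))
  # four quarter-turns are the identity
  x <- img
  for (i in 1:4) x <- apply_to_image(x, sp)
  expect_identical(x, img)
  # odd k on a non-square plane is an error
  bad <- array(rnorm(4 * 6 * 1), c(4, 6, 1))
  expect_error(apply_to_image(bad, sp), "square")
})

test_that("prediction replay moves probability vectors without altering them", {
  pred <- random_pred(8, 8, 3, seed = 4)
  sp <- sample_transform(5, transform_config())
  pt <- apply_spatial_to_prediction(pred, sp)
  # per-voxel sums conserved exactly
  expect_identical(sort(as.vector(pt$probs)), sort(as.vector(pred$probs)))
  expect_equal(max(abs(rowSums(matrix(pt$probs, ncol = 3)) - 1)), 0,
               tolerance = 1e-12)
  # round trip is bit-exact
  back <- apply_spatial_to_prediction(pt, invert_spatial(sp))
  expect_identical(back$probs, pred$probs)
  expect_identical(back$logits, pred$logits)

  # one-hot prediction: argmax map commutes with the flip
  lab <- matrix(sample(0:2, 64, TRUE), 8, 8)
  oh <- one_hot(lab, 3)
  onehot_pred <- soft_prediction(logits = oh * 10, probs = oh, validate = FALSE)
  fl <- structure(list(spatial = list(list(op = "flip", axis = 1L)),
                       intensity = list()), class = "transform_spec")
  moved <- apply_spatial_to_prediction(onehot_pred, fl)
  am <- function(p) array(max.col(matrix(p, ncol = 3)), c(8, 8))
  expect_identical(am(moved$probs), am(oh)[8:1, ])
})

test_that("round trips are bit-exact for many random specs", {
  set.seed(99)
  for (i in 1:20) {
    pred <- random_pred(6, 6, 4, seed = i)
    sp <- sample_transform(i * 13, transform_config())
    back <- apply_spatial_to_prediction(
      apply_spatial_to_prediction(pred, sp), invert_spatial(sp))
    expect_identical(back$probs, pred$probs)
  }
})

test_that("paired-transform plumbing commutes for an equivariant dummy net", {
  # per-voxel thresholding is exactly equivariant to lattice symmetries, so
  # predict(transform(x)) must equal transform(predict(x)) bit-exactly
  dummy_predict <- function(img) {
    p1 <- (img[, , 1] > 0) * 1
    probs <- array(0, c(dim(img)[1], dim(img)[2], 2))
    probs[, , 1] <- 1 - p1
    probs[, , 2] <- p1
    soft_prediction(logits = log(pmax(probs, 1e-7)), probs = probs,
                    validate = FALSE)
  }
  img <- array(rnorm(16 * 16 * 1), c(16, 16, 1))
  for (i in 1:10) {
    sp <- sample_transform(i, transform_config(contrast = FALSE, noise = FALSE))
    lhs <- dummy_predict(apply_to_image(img, sp))
    rhs <- apply_spatial_to_prediction(dummy_predict(img), sp)
    expect_identical(lhs$probs, rhs$probs)
  }
})
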