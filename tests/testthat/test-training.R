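# Schedules, step mechanics, determinism, mode reductions, and the EMA
# oracle for the mean-teacher arm.

test_that("poly learning rate follows the closed form", {
  expect_equal(poly_lr(0.01, 0, 15000), 0.01)
  expect_equal(poly_lr(0.01, 15000, 15000), 0)
  expect_equal(poly_lr(0.01, 7500, 15000, 0.9), 0.01 * 0.5^0.9,
               tolerance = 1e-12)
  expect_error(poly_lr(0.01, 15001, 15000), "iter")
  expect_error(poly_lr(0.01, -1, 15000), "iter")
})

test_that("adversarial weight schedule steps at the switch", {
  cfg <- tiny_config("proposed", max_iter = 100, lambda_switch_iter = 80)
  expect_equal(lambda_adv_at(0, cfg), 0.1)
  expect_equal(lambda_adv_at(79, cfg), 0.1)
  expect_equal(lambda_adv_at(80, cfg), 1.0)
  expect_equal(lambda_adv_at(100, cfg), 1.0)
  # degenerate switch at 0 is constant at the final value
  cfg0 <- tiny_config("proposed", max_iter = 100, lambda_switch_iter = 0)
  expect_equal(lambda_adv_at(0, cfg0), 1.0)
})

test_that("config validation catches bad inputs", {
  expect_error(tiny_config("proposed", max_iter = 10, lambda_switch_iter = 11),
               "lambda_switch_iter")
  expect_error(train_config(mode = "nope"), "arg")
  expect_error(tiny_config("proposed", n_students = 1), "n_students")
  expect_error(tiny_config("super_source", base_lr = 0), "base_lr")
})

test_that("batches carry both domains and hide target labels", {
  ds <- generate_dataset(tiny_spec(), 5, 5, 2, 2, seed = 3)
  cfg <- tiny_config("proposed")
  b <- make_batch(ds, 0, cfg)
  expect_equal(dim(b$source$images), c(16, 16, 2, 2))
  expect_equal(dim(b$source$onehot), c(16, 16, 4, 2))
  expect_equal(dim(b$target$images), c(16, 16, 2, 2))
  # supervised-source batches have no target half
  bs <- make_batch(ds, 0, tiny_config("super_source"))
  expect_null(bs$target)
  # super_all without explicit unhiding raises
  expect_error(make_batch(ds, 0, tiny_config("super_all")), "hidden")
  bu <- make_batch(unhide_target_labels(ds), 0, tiny_config("super_all"))
  expect_equal(dim(bu$source$images), c(16, 16, 2, 2))
})

test_that("super_source step computes only the supervised term", {
  ds <- generate_dataset(tiny_spec(), 5, 5, 2, 2, seed = 3)
  cfg <- tiny_config("super_source")
  st <- init_train_state(cfg)
  r <- train_step(st, make_batch(ds, 0, cfg), 0)
  b <- r$bundles[[1]]
  expect_gt(b$l_seg, 0)
  expect_equal(b$l_con, 0)
  expect_equal(b$l_cross, 0)
  expect_equal(b$l_adv, 0)
  expect_true(is.na(b$l_disc))
  expect_equal(b$total, b$l_seg)
})

test_that("step matches a manual replay of the recorded source pass", {
  # the loss bundle must equal calling the loss ops on the same forward the
  # step performed internally (same derived seeds, same batch)
  ds <- generate_dataset(tiny_spec(), 5, 5, 2, 2, seed = 4)
  cfg <- tiny_config("super_source", seed = 11)
  st <- init_train_state(cfg)
  batch <- make_batch(ds, 0, cfg)
  net0 <- st$students[[1]]
  r <- train_step(st, batch, 0)
  f <- segmentor_forward(net0, batch$source$images, train = TRUE,
                         seed = derive_seed(11, "fs", 0, 1))
  l <- 0
  for (n in 1:2)
    l <- l + supervised_loss(batch_prediction(f, n),
                             batch$source$onehot[, , , n]) / 2
  expect_equal(r$bundles[[1]]$l_seg, l, tolerance = 1e-12)
})

test_that("training is deterministic given config and seed", {
  ds <- generate_dataset(tiny_spec(), 5, 5, 2, 2, seed = 5)
  cfg <- tiny_config("da_ds", max_iter = 3)
  r1 <- train(cfg, ds)
  r2 <- train(cfg, ds)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$state$students[[1]]$params, r2$state$students[[1]]$params)
})

test_that("dual students never couple their weights", {
  ds <- generate_dataset(tiny_spec(), 5, 5, 2, 2, seed = 6)
  cfg <- tiny_config("da_ds", max_iter = 4, quorum = 0)  # gates open
  r <- train(cfg, ds)
  p1 <- r$state$students[[1]]$params
  p2 <- r$state$students[[2]]$params
  # parameter divergence persists after optimization
  diffs <- vapply(names(p1), function(nm) max(abs(p1[[nm]] - p2[[nm]])),
                  numeric(1))
  expect_gt(max(diffs), 1e-3)
})

test_that("mean-teacher EMA update matches the closed-form oracle", {
  ds <- generate_dataset(tiny_spec(), 5, 5, 2, 2, seed = 7)
  cfg <- tiny_config("da_mt", max_iter = 2, ema_alpha = 0.9)
  st <- init_train_state(cfg)
  teach0 <- st$teacher$params
  r <- train_step(st, make_batch(ds, 0, cfg), 0)
  student1 <- r$state$students[[1]]$params
  for (nm in c("enc1_conv1_W", "final_W")) {
    expect_equal(r$state$teacher$params[[nm]],
                 0.9 * teach0[[nm]] + 0.1 * student1[[nm]],
                 tolerance = 1e-12, label = nm)
  }
})

test_that("entropy arm records the entropy of the clean target pass", {
  ds <- generate_dataset(tiny_spec(), 5, 5, 2, 2, seed = 8)
  cfg <- tiny_config("da_entropy_mini", max_iter = 1)
  st <- init_train_state(cfg)
  r <- train_step(st, make_batch(ds, 0, cfg), 0)
  expect_gt(r$bundles[[1]]$l_con, 0)   # entropy logged in the l_con slot
  expect_lt(r$bundles[[1]]$l_con, log(4) + 1e-9)
})

test_that("da_adv with lambda 0 reproduces super_source trajectories", {
  ds <- generate_dataset(tiny_spec(), 5, 5, 2, 2, seed = 9)
  cfg_adv <- tiny_config("da_adv", max_iter = 4, lambda_adv_initial = 0,
                         lambda_adv_final = 0)
  cfg_ss <- tiny_config("super_source", max_iter = 4)
  ra <- train(cfg_adv, ds)
  rs <- train(cfg_ss, ds)
  expect_equal(ra$history$l_seg, rs$history$l_seg, tolerance = 1e-12)
  expect_identical(ra$state$students[[1]]$params, rs$state$students[[1]]$params)
})

test_that("train returns history, validation record and a best checkpoint", {
  ds <- generate_dataset(tiny_spec(), 5, 5, 2, 2, seed = 10)
  cfg <- tiny_config("super_source", max_iter = 1, eval_every = 1)
  r <- train(cfg, ds)
  expect_equal(nrow(r$history), 1)
  expect_s3_class(r$best$net, "dsseg_net")
  expect_true(is.finite(r$best$score))
  expect_true(all(c("iter", "student", "l_seg", "total") %in%
                    colnames(r$history)))
})

test_that("adversarial training drives discriminator accuracy toward chance", {
  # stochastic antagonism property at the smallest adversarial-capable
  # scale (32x32); lenient by design
  spec <- preset_task("cross_modality")
  ds <- generate_dataset(spec, 8, 8, 4, 4, seed = 2)
  cfg <- desk_train_config("proposed", seed = 2, max_iter = 120)
  st <- init_train_state(cfg)
  accs <- numeric(0)
  for (it in 0:(cfg$max_iter - 1)) {
    r <- train_step(st, make_batch(ds, it, cfg), it)
    st <- r$state
    if ((it + 1) %% 30 == 0)
      accs <- c(accs, discriminator_accuracy(st, ds$source[1:4], ds$val))
  }
  # late accuracy does not exceed the early peak (tolerance for noise)
  expect_lte(accs[length(accs)], max(accs[1:2]) + 0.125)
})
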