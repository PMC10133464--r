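# Training procedure for the dual-student adversarial adaptation framework
# and its baseline arms. Every batch contains labeled source items and
# unlabeled target items; per student the step computes (1) supervised
# dice+CE on source, (2) transform-consistency MSE on target, (3) the
# reliability-gated cross-coordination constraint between the students,
# (4) the adversarial loss through the student's own discriminator, then
# takes one SGD step on the composite objective under a poly learning-rate
# schedule, followed by a separate Adam step on the discriminator loss.

TRAIN_MODES <- c("proposed", "super_all", "super_source", "da_mt",
                 "da_entropy_mini", "da_adv", "da_ds")

#' Training configuration
#'
#' Defaults follow the reference recipe for full-scale runs (15000
#' iterations, batch size 2, poly power 0.9, SGD momentum 0.9, weight decay
#' 1e-4, Adam betas 0.45/0.999, adversarial weight 0.1 stepping to 1.0 late
#' in training); desk-scale experiments override `max_iter` and the network
#' sizes (see [desk_train_config()]).
#'
#' @param mode one of `r paste(TRAIN_MODES, collapse = ", ")`.
#' @param max_iter total iterations.
#' @param batch_size items per domain per step (each step sees `batch_size`
#'   source AND `batch_size` target items).
#' @param base_lr student learning rate (SGD).
#' @param poly_power poly decay exponent.
#' @param sgd_momentum,weight_decay student optimizer settings.
#' @param disc_lr,adam_beta1,adam_beta2 discriminator optimizer settings.
#' @param lambda_adv_initial,lambda_adv_final,lambda_switch_iter step
#'   schedule of the adversarial weight; the switch defaults to
#'   `0.8 * max_iter`.
#' @param xi_threshold confidence threshold of the reliability rule.
#' @param xi_weight weight of the consistency term (kept constant: no
#'   ramp-up).
#' @param quorum voxel quorum turning the reliability map into a per-sample
#'   bit; values > 1 force the bit to 0.
#' @param ema_alpha EMA coefficient (da_mt arm only).
#' @param mt_rampup_iters length of the sigmoid consistency ramp-up used by
#'   the da_mt arm only (standard mean-teacher recipe; a cold EMA teacher
#'   with full-weight consistency collapses target predictions). Defaults to
#'   `0.25 * max_iter`. The dual-student modes use a constant weight.
#' @param entropy_weight weight of the entropy term (da_entropy_mini only).
#' @param share_transforms give both students the same sampled transform per
#'   target item instead of independent draws.
#' @param disc_input feed the discriminator `"probs"` (default) or
#'   `"logits"`.
#' @param n_students 1 or 2; `NULL` picks the mode's convention (2 for
#'   proposed/da_ds, 1 otherwise; supervised arms accept either).
#' @param init_schemes weight-init scheme per student.
#' @param eval_every validation cadence in iterations.
#' @param seed master seed; all stochastic streams derive from it.
#' @param segnet a [segnet_config()].
#' @param disc a [disc_config()].
#' @param transform a [transform_config()].
#' @return A validated `train_config` list.
#' @export
train_config <- function(mode = "proposed", max_iter = 15000L, batch_size = 2L,
                         base_lr = 0.01, poly_power = 0.9,
                         sgd_momentum = 0.9, weight_decay = 1e-4,
                         disc_lr = 1e-4, adam_beta1 = 0.45, adam_beta2 = 0.999,
                         lambda_adv_initial = 0.1, lambda_adv_final = 1.0,
                         lambda_switch_iter = NULL,
                         xi_threshold = 0.8, xi_weight = 1.0, quorum = 0.5,
                         ema_alpha = 0.99, mt_rampup_iters = NULL,
                         entropy_weight = 0.1,
                         share_transforms = FALSE,
                         disc_input = c("probs", "logits"),
                         n_students = NULL,
                         init_schemes = c("xavier", "kaiming"),
                         eval_every = 200L, seed = 1L,
                         segnet = segnet_config(), disc = NULL,
                         transform = transform_config()) {
  mode <- match.arg(mode, TRAIN_MODES)
  disc_input <- match.arg(disc_input)
  stopifnot(max_iter >= 1L, batch_size >= 1L, base_lr > 0, disc_lr > 0,
            poly_power > 0, sgd_momentum >= 0, weight_decay >= 0,
            xi_threshold >= 0, xi_threshold <= 1, xi_weight >= 0,
            lambda_adv_initial >= 0, lambda_adv_final >= 0,
            ema_alpha > 0, ema_alpha < 1, entropy_weight >= 0)
  if (is.null(lambda_switch_iter)) lambda_switch_iter <- floor(0.8 * max_iter)
  if (is.null(mt_rampup_iters)) mt_rampup_iters <- floor(0.25 * max_iter)
  if (lambda_switch_iter > max_iter) stop("lambda_switch_iter > max_iter")
  if (is.null(n_students))
    n_students <- if (mode %in% c("proposed", "da_ds")) 2L else 1L
  if (mode %in% c("proposed", "da_ds") && n_students != 2L)
    stop("dual-student modes need n_students = 2")
  if (is.null(disc)) disc <- disc_config(in_channels = segnet$num_classes)
  structure(list(mode = mode, max_iter = as.integer(max_iter),
                 batch_size = as.integer(batch_size), base_lr = base_lr,
                 poly_power = poly_power, sgd_momentum = sgd_momentum,
                 weight_decay = weight_decay, disc_lr = disc_lr,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 lambda_adv_initial = lambda_adv_initial,
                 lambda_adv_final = lambda_adv_final,
                 lambda_switch_iter = as.integer(lambda_switch_iter),
                 xi_threshold = xi_threshold, xi_weight = xi_weight,
                 quorum = quorum, ema_alpha = ema_alpha,
                 mt_rampup_iters = as.integer(mt_rampup_iters),
                 entropy_weight = entropy_weight,
                 share_transforms = isTRUE(share_transforms),
                 disc_input = disc_input,
                 n_students = as.integer(n_students),
                 init_schemes = init_schemes,
                 eval_every = as.integer(eval_every), seed = as.integer(seed),
                 segnet = segnet, disc = disc, transform = transform),
            class = "train_config")
}

#' Desk-scale training configuration
#'
#' The small fixed geometry used by the in-package experiments: depth-2
#' base-width-8 U-Net on 32x32 two-channel phantoms, 600 iterations,
#' batch size 2, base LR 0.02. Chosen once to fit a single-CPU budget;
#' see the methods vignette.
#'
#' @param mode training arm.
#' @param seed master seed.
#' @param max_iter iterations, default 600.
#' @param ... overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
desk_train_config <- function(mode = "proposed", seed = 1L, max_iter = 600L, ...) {
  args <- list(mode = mode, seed = seed, max_iter = max_iter,
               base_lr = 0.02, eval_every = 100L,
               segnet = segnet_config(in_channels = 2L, num_classes = 4L,
                                      depth = 2L, base_width = 8L,
                                      dropout = 0.1),
               disc = disc_config(in_channels = 4L, base_width = 8L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(train_config, args)
}

## ---- schedules --------------------------------------------------------------

#' Poly learning-rate schedule
#'
#' `base_lr * (1 - iter/max_iter)^power`.
#'
#' @param base_lr base learning rate.
#' @param iter current iteration, `0 <= iter <= max_iter`.
#' @param max_iter total iterations.
#' @param power decay exponent.
#' @return The decayed learning rate.
#' @export
poly_lr <- function(base_lr, iter, max_iter, power = 0.9) {
  if (iter < 0 || iter > max_iter) stop("iter outside [0, max_iter]")
  base_lr * (1 - iter / max_iter)^power
}

#' Adversarial-weight step schedule
#'
#' The adversarial weight is small early (the supervised signal dominates
#' while the students learn to segment) and steps to its final value at
#' `lambda_switch_iter`.
#'
#' @param iter current iteration.
#' @param config a `train_config`.
#' @return `lambda_adv_initial` for `iter < lambda_switch_iter`, else
#'   `lambda_adv_final`.
#' @export
lambda_adv_at <- function(iter, config) {
  if (iter < config$lambda_switch_iter) config$lambda_adv_initial
  else config$lambda_adv_final
}

## ---- state ------------------------------------------------------------------

# sigmoid ramp-up of the mean-teacher consistency weight (da_mt arm only)
mt_ramp <- function(iter, cfg) {
  if (cfg$mode != "da_mt" || cfg$mt_rampup_iters <= 0L) return(1)
  t <- min(iter / cfg$mt_rampup_iters, 1)
  exp(-5 * (1 - t)^2)
}

mode_uses <- function(mode) {
  list(consistency = mode %in% c("proposed", "da_ds", "da_mt"),
       cross = mode %in% c("proposed", "da_ds"),
       adv = mode %in% c("proposed", "da_adv"),
       entropy = mode == "da_entropy_mini",
       ema = mode == "da_mt",
       target = !(mode %in% c("super_all", "super_source")))
}

#' Initialize a training state
#'
#' Builds the student network(s) with their distinct initialization schemes,
#' per-student discriminators when the mode is adversarial, and the EMA
#' teacher for the mean-teacher arm.
#'
#' @param config a [train_config()].
#' @return A `train_state`.
#' @export
init_train_state <- function(config) {
  uses <- mode_uses(config$mode)
  adv_on <- uses$adv &&
    (config$lambda_adv_initial > 0 || config$lambda_adv_final > 0)
  students <- lapply(seq_len(config$n_students), function(s)
    build_segmentor(config$segnet, config$init_schemes[s],
                    derive_seed(config$seed, "init", s)))
  discs <- if (adv_on)
    lapply(seq_len(config$n_students), function(s)
      build_discriminator(config$disc, derive_seed(config$seed, "dinit", s)))
  else NULL
  teacher <- if (uses$ema) students[[1L]] else NULL
  structure(list(students = students, opt = vector("list", config$n_students),
                 discs = discs, dopt = if (adv_on)
                   vector("list", config$n_students) else NULL,
                 teacher = teacher, config = config, iter = 0L),
            class = "train_state")
}

stack_images <- function(samples) {
  d <- dim(samples[[1]]$image)
  out <- array(0, c(d, length(samples)))
  for (b in seq_along(samples)) out[, , , b] <- samples[[b]]$image
  out
}

stack_onehot <- function(samples, M) {
  d <- dim(samples[[1]]$labels)
  out <- array(0, c(d, M, length(samples)))
  for (b in seq_along(samples)) out[, , , b] <- one_hot(samples[[b]]$labels, M)
  out
}

#' Assemble one training batch
#'
#' Draws `batch_size` labeled source items and, in adaptation modes,
#' `batch_size` unlabeled target items. For `super_all` the labeled pool is
#' source plus (explicitly unhidden) target.
#'
#' @param ds a `phantom_dataset`.
#' @param iter iteration (drives the deterministic sampling stream).
#' @param config a `train_config`.
#' @return List with `source` (images, onehot) and optionally `target`
#'   (images).
#' @export
make_batch <- function(ds, iter, config) {
  M <- config$segnet$num_classes
  B <- config$batch_size
  uses <- mode_uses(config$mode)
  pool <- ds$source
  if (config$mode == "super_all") {
    labs <- target_train_labels(ds)  # raises unless explicitly unhidden
    tgt_lab <- mapply(function(s, l) { s$labels <- l; s },
                      ds$target_train, labs, SIMPLIFY = FALSE)
    pool <- c(pool, tgt_lab)
  }
  si <- with_seed(derive_seed(config$seed, "bsrc", iter),
                  sample.int(length(pool), B, replace = length(pool) < B))
  src <- pool[si]
  out <- list(source = list(images = stack_images(src),
                            onehot = stack_onehot(src, M)))
  if (uses$target) {
    ti <- with_seed(derive_seed(config$seed, "btgt", iter),
                    sample.int(length(ds$target_train), B,
                               replace = length(ds$target_train) < B))
    out$target <- list(images = stack_images(ds$target_train[ti]))
  }
  out
}

check_finite <- function(value, component) {
  if (!is.finite(value))
    stop("non-finite loss in component '", component, "'")
  value
}

## ---- one optimization step --------------------------------------------------

#' One training step
#'
#' Executes the full per-iteration procedure of the configured arm and
#' returns the updated state plus one `loss_bundle` per student. Gradients
#' are hand-accumulated: the consistency and cross-coordination targets are
#' detached (pure knowledge transfer), the adversarial gradient flows
#' through the frozen discriminator into the student, and the discriminator
#' is updated separately on detached predictions.
#'
#' @param state a `train_state`.
#' @param batch a batch from [make_batch()].
#' @param iter 0-based iteration index.
#' @return List `state`, `bundles` (per student), `lr`.
#' @export
train_step <- function(state, batch, iter) {
  cfg <- state$config
  uses <- mode_uses(cfg$mode)
  seed <- cfg$seed
  B <- cfg$batch_size
  M <- cfg$segnet$num_classes
  lr <- poly_lr(cfg$base_lr, iter, cfg$max_iter, cfg$poly_power)
  lam <- if (!is.null(state$discs)) lambda_adv_at(iter, cfg) else 0
  xi_w <- cfg$xi_weight * mt_ramp(iter, cfg)
  nS <- cfg$n_students

  fwd_tc <- vector("list", nS)   # clean-target forwards
  fwd_tt <- vector("list", nS)   # transformed-target forwards
  specs <- vector("list", nS)
  bundles_rel <- vector("list", nS)
  grads <- vector("list", nS)
  losses <- lapply(seq_len(nS), function(s)
    list(seg = 0, con = 0, cross = 0, adv = 0, disc = NA_real_))
  gp_tc <- vector("list", nS)    # dL/dprobs on the clean-target pass
  has_tc <- logical(nS)

  ## (1) supervised source pass + (2,4 prep) target forwards, per student
  for (s in seq_len(nS)) {
    net <- state$students[[s]]
    fs <- segmentor_forward(net, batch$source$images, train = TRUE,
                            seed = derive_seed(seed, "fs", iter, s))
    state$students[[s]]$bn <- fs$bn
    gp <- array(0, dim(fs$probs))
    for (n in seq_len(B)) {
      pred <- batch_prediction(fs, n)
      y <- batch$source$onehot[, , , n]
      losses[[s]]$seg <- losses[[s]]$seg + supervised_loss(pred, y) / B
      gp[, , , n] <- supervised_grad(pred, y) / B
    }
    check_finite(losses[[s]]$seg, "l_seg")
    grads[[s]] <- segmentor_backward(net, fs$cache,
                                     softmax_backward(fs$probs, gp))
    fwd_src_probs <- fs$probs  # detached, for the discriminator step
    attr(grads[[s]], "src_probs") <- fwd_src_probs
    attr(grads[[s]], "src_logits") <- fs$logits

    if (uses$target) {
      ftc <- segmentor_forward(state$students[[s]], batch$target$images,
                               train = TRUE,
                               seed = derive_seed(seed, "ftc", iter, s))
      state$students[[s]]$bn <- ftc$bn
      fwd_tc[[s]] <- ftc
      gp_tc[[s]] <- array(0, dim(ftc$probs))
      if (uses$consistency || uses$cross) {
        sp <- lapply(seq_len(B), function(n)
          sample_transform(derive_seed(seed, "tf", iter,
                                       if (cfg$share_transforms) 0L else s, n),
                           cfg$transform))
        specs[[s]] <- sp
        xt <- array(0, dim(batch$target$images))
        for (n in seq_len(B))
          xt[, , , n] <- apply_to_image(batch$target$images[, , , n], sp[[n]])
        ftt <- segmentor_forward(state$students[[s]], xt, train = TRUE,
                                 seed = derive_seed(seed, "ftt", iter, s))
        state$students[[s]]$bn <- ftt$bn
        fwd_tt[[s]] <- ftt
      }
    }
  }

  ## (2) transform-consistency, per student
  if (uses$consistency) {
    teacher_fwd <- if (uses$ema)
      segmentor_forward(state$teacher, batch$target$images, train = TRUE,
                        seed = derive_seed(seed, "ftea", iter))
    else NULL
    for (s in seq_len(nS)) {
      gp_tt <- array(0, dim(fwd_tt[[s]]$probs))
      for (n in seq_len(B)) {
        clean_pred <- if (uses$ema) batch_prediction(teacher_fwd, n)
                      else batch_prediction(fwd_tc[[s]], n)
        tgt <- apply_spatial_to_prediction(clean_pred, specs[[s]][[n]])
        pT <- batch_prediction(fwd_tt[[s]], n)
        losses[[s]]$con <- losses[[s]]$con + consistency_loss(pT, tgt) / B
        gp_tt[, , , n] <- consistency_grad(pT, tgt) / B
        if (!uses$ema && xi_w > 0) {
          # both sides of the MSE come from the same student: the replayed
          # clean prediction also carries gradient, mapped back to the
          # clean frame through the inverse permutation
          gclean <- -consistency_grad(pT, tgt) / B   # d/d(tgt)
          inv <- invert_spatial(specs[[s]][[n]])
          gp_tc[[s]][, , , n] <- gp_tc[[s]][, , , n] +
            xi_w * apply_spatial_ops(gclean, inv$spatial)
          has_tc[s] <- TRUE
        }
      }
      check_finite(losses[[s]]$con, "l_con")
      if (xi_w > 0) {
        g <- segmentor_backward(state$students[[s]], fwd_tt[[s]]$cache,
                                softmax_backward(fwd_tt[[s]]$probs, gp_tt))
        grads[[s]] <- acc_grads(grads[[s]], g, xi_w)
      }
    }
  }

  ## (3) reliability + cross-coordination between the two students
  if (uses$cross) {
    for (s in seq_len(nS)) {
      bundles_rel[[s]] <- lapply(seq_len(B), function(n) {
        noisy_back <- apply_spatial_to_prediction(
          batch_prediction(fwd_tt[[s]], n), invert_spatial(specs[[s]][[n]]))
        compute_reliability(batch_prediction(fwd_tc[[s]], n), noisy_back,
                            cfg$xi_threshold)
      })
    }
    for (n in seq_len(B)) {
      p1 <- batch_prediction(fwd_tc[[1L]], n)
      p2 <- batch_prediction(fwd_tc[[2L]], n)
      cc <- cross_coordination_loss(bundles_rel[[1L]][[n]],
                                    bundles_rel[[2L]][[n]],
                                    p1, p2, cfg$quorum)
      losses[[1L]]$cross <- losses[[1L]]$cross + cc$loss_i / B
      losses[[2L]]$cross <- losses[[2L]]$cross + cc$loss_j / B
      if (cc$gate_i > 0)
        gp_tc[[1L]][, , , n] <- gp_tc[[1L]][, , , n] +
          cc$gate_i * consistency_grad(p1, p2) / B
      if (cc$gate_j > 0)
        gp_tc[[2L]][, , , n] <- gp_tc[[2L]][, , , n] +
          cc$gate_j * consistency_grad(p2, p1) / B
    }
    has_tc[1L] <- has_tc[1L] || any(gp_tc[[1L]] != 0)
    if (nS > 1L) has_tc[2L] <- has_tc[2L] || any(gp_tc[[2L]] != 0)
    check_finite(losses[[1L]]$cross, "l_cross")
  }

  ## (4) adversarial generator loss
  glogits_extra <- vector("list", nS)
  if (uses$adv && !is.null(state$discs)) {
    for (s in seq_len(nS)) {
      din <- if (cfg$disc_input == "probs") fwd_tc[[s]]$probs
             else fwd_tc[[s]]$logits
      df <- disc_forward(state$discs[[s]], din, train = TRUE,
                         seed = derive_seed(seed, "dadv", iter, s))
      losses[[s]]$adv <- check_finite(adversarial_generator_loss(df$score),
                                      "l_adv")
      if (lam > 0) {
        db <- disc_backward(state$discs[[s]], df$cache,
                            bce_with_logits_grad(df$score, 1))
        if (cfg$disc_input == "probs") {
          gp_tc[[s]] <- gp_tc[[s]] + lam * db$gx
          has_tc[s] <- TRUE
        } else {
          glogits_extra[[s]] <- lam * db$gx
        }
      }
    }
  }

  ## entropy-minimization arm
  if (uses$entropy) {
    for (s in seq_len(nS)) {
      ent <- 0
      for (n in seq_len(B)) {
        pred <- batch_prediction(fwd_tc[[s]], n)
        ent <- ent + entropy_loss(pred) / B
        gp_tc[[s]][, , , n] <- gp_tc[[s]][, , , n] +
          cfg$entropy_weight * entropy_grad(pred) / B
      }
      losses[[s]]$con <- check_finite(ent, "l_entropy")
      has_tc[s] <- has_tc[s] || cfg$entropy_weight > 0
    }
  }

  ## backprop the accumulated clean-target gradients
  for (s in seq_len(nS)) {
    if (!uses$target || is.null(fwd_tc[[s]])) next
    if (has_tc[s] || !is.null(glogits_extra[[s]])) {
      gl <- softmax_backward(fwd_tc[[s]]$probs, gp_tc[[s]])
      if (!is.null(glogits_extra[[s]])) gl <- gl + glogits_extra[[s]]
      g <- segmentor_backward(state$students[[s]], fwd_tc[[s]]$cache, gl)
      grads[[s]] <- acc_grads(grads[[s]], g, 1)
    }
  }

  ## (5) student optimizer steps
  for (s in seq_len(nS)) {
    up <- sgd_step(state$students[[s]]$params, grads[[s]], state$opt[[s]],
                   lr, cfg$sgd_momentum, cfg$weight_decay)
    state$students[[s]]$params <- up$params
    state$opt[[s]] <- up$state
  }

  ## (6) discriminator steps on detached predictions
  if (!is.null(state$discs) && uses$target) {
    for (s in seq_len(nS)) {
      src_in <- if (cfg$disc_input == "probs") attr(grads[[s]], "src_probs")
                else attr(grads[[s]], "src_logits")
      tgt_in <- if (cfg$disc_input == "probs") fwd_tc[[s]]$probs
                else fwd_tc[[s]]$logits
      dfs <- disc_forward(state$discs[[s]], src_in, train = TRUE,
                          seed = derive_seed(seed, "dds", iter, s))
      dft <- disc_forward(state$discs[[s]], tgt_in, train = TRUE,
                          seed = derive_seed(seed, "ddt", iter, s))
      ld <- check_finite(discriminator_loss(dfs$score, dft$score), "l_disc")
      losses[[s]]$disc <- ld
      g1 <- disc_backward(state$discs[[s]], dfs$cache,
                          0.5 * bce_with_logits_grad(dfs$score, 1))
      g2 <- disc_backward(state$discs[[s]], dft$cache,
                          0.5 * bce_with_logits_grad(dft$score, 0))
      dg <- acc_grads(g1$grads, g2$grads, 1)
      up <- adam_step(state$discs[[s]]$params, dg, state$dopt[[s]],
                      cfg$disc_lr, cfg$adam_beta1, cfg$adam_beta2)
      state$discs[[s]]$params <- up$params
      state$dopt[[s]] <- up$state
    }
  }

  ## EMA teacher update (mean-teacher arm): the one place weights are
  ## averaged — deliberately absent from the dual-student modes.
  if (uses$ema) {
    a <- cfg$ema_alpha
    st <- state$students[[1L]]
    for (nm in names(st$params))
      state$teacher$params[[nm]] <- a * state$teacher$params[[nm]] +
        (1 - a) * st$params[[nm]]
    for (nm in names(st$bn)) {
      state$teacher$bn[[nm]]$mean <- a * state$teacher$bn[[nm]]$mean +
        (1 - a) * st$bn[[nm]]$mean
      state$teacher$bn[[nm]]$var <- a * state$teacher$bn[[nm]]$var +
        (1 - a) * st$bn[[nm]]$var
    }
  }

  state$iter <- iter + 1L
  bundles <- lapply(seq_len(nS), function(s)
    total_student_loss(losses[[s]]$seg, losses[[s]]$con, losses[[s]]$cross,
                       losses[[s]]$adv, xi_w, lam, losses[[s]]$disc))
  list(state = state, bundles = bundles, lr = lr)
}

## ---- full training loop -----------------------------------------------------

#' Train one arm
#'
#' Runs `max_iter` steps with periodic validation on the held-out target
#' validation split (mean foreground DSC); the best-on-validation snapshot is
#' kept. For the mean-teacher arm the teacher is validated and reported; for
#' dual-student modes the better student at each validation is eligible.
#'
#' @param config a [train_config()].
#' @param ds a `phantom_dataset` (unhide target labels first for
#'   `super_all`).
#' @param verbose log a line to stderr every `eval_every` iterations.
#' @return List with `state`, `history` (per-iteration loss components),
#'   `best` (list: `net`, `student`, `iter`, `score`), `val_history`.
#' @export
train <- function(config, ds, verbose = FALSE) {
  state <- init_train_state(config)
  hist <- vector("list", config$max_iter * config$n_students)
  val_hist <- list()
  best <- list(net = NULL, student = NA_integer_, iter = NA_integer_,
               score = -Inf)
  hi <- 0L
  for (iter in 0:(config$max_iter - 1L)) {
    batch <- make_batch(ds, iter, config)
    step <- train_step(state, batch, iter)
    state <- step$state
    for (s in seq_along(step$bundles)) {
      b <- step$bundles[[s]]
      hi <- hi + 1L
      hist[[hi]] <- data.frame(iter = iter, student = s, lr = step$lr,
                               l_seg = b$l_seg, l_con = b$l_con,
                               l_cross = b$l_cross, l_adv = b$l_adv,
                               l_disc = b$l_disc, total = b$total)
    }
    if ((iter + 1L) %% config$eval_every == 0L || iter == config$max_iter - 1L) {
      cand <- eval_candidates(state)
      for (cn in names(cand)) {
        rep <- evaluate_model(cand[[cn]], ds$val)
        val_hist[[length(val_hist) + 1L]] <-
          data.frame(iter = iter, model = cn, foreground_dsc = rep$foreground_dsc)
        if (rep$foreground_dsc > best$score)
          best <- list(net = cand[[cn]], student = cn, iter = iter,
                       score = rep$foreground_dsc)
      }
      if (verbose)
        message(sprintf("[%s] iter %d lr %.5f seg %.4f val-fg-DSC %.2f",
                        config$mode, iter, step$lr,
                        step$bundles[[1L]]$l_seg, best$score))
    }
  }
  list(state = state, history = do.call(rbind, hist[seq_len(hi)]),
       best = best, val_history = do.call(rbind, val_hist))
}

# which network(s) represent the arm at validation/test time
eval_candidates <- function(state) {
  cfg <- state$config
  if (cfg$mode == "da_mt") return(list(teacher = state$teacher))
  out <- list(student1 = state$students[[1L]])
  if (cfg$n_students > 1L) out$student2 <- state$students[[2L]]
  out
}

#' Discriminator domain-classification accuracy on held-out data
#'
#' Runs student 1's discriminator (evaluation mode) on its predictions for
#' held-out source and target images and scores the sign of the mean domain
#' logit per image against the true domain. An aligned segmenter drives this
#' toward chance (0.5).
#'
#' @param state a trained `train_state` (adversarial mode).
#' @param source_samples,target_samples lists of samples with `$image`.
#' @return Accuracy in `[0, 1]`.
#' @export
discriminator_accuracy <- function(state, source_samples, target_samples) {
  if (is.null(state$discs)) stop("state has no discriminators")
  net <- state$students[[1L]]
  dsc <- state$discs[[1L]]
  score1 <- function(img) {
    x <- array(img, c(dim(img), 1L))
    f <- segmentor_forward(net, x, train = FALSE)
    din <- if (state$config$disc_input == "probs") f$probs else f$logits
    mean(disc_forward(dsc, din, train = FALSE)$score)
  }
  s_src <- vapply(source_samples, function(s) score1(s$image), numeric(1))
  s_tgt <- vapply(target_samples, function(s) score1(s$image), numeric(1))
  mean(c(s_src > 0, s_tgt <= 0))
}
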