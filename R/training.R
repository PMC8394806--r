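#' Loss configuration
#'
#' The base loss is the L1 distance between predicted and ground-truth
#' keypoint coordinates. Two geometry-prior terms regularise the clivus line:
#' a translation term, the mean of the distances Da (predicted Ar to the
#' ground-truth Ar-Ba line) and Db (predicted Ba to the same line), and a
#' rotation term, the acute angle between the predicted and ground-truth
#' Ar-Ba directions. Both vanish exactly when the predicted line coincides
#' with the true one, regardless of displacement along the line. With
#' intermediate supervision the combined loss is applied to every hourglass
#' stack; otherwise only to the last.
#'
#' @param lambda_rotation Weight of the rotation term (default 0.1).
#' @param lambda_translation Weight of the translation term (default 0.1).
#' @param intermediate_supervision Supervise every stack (default TRUE).
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(lambda_rotation = 0.1, lambda_translation = 0.1,
                        intermediate_supervision = TRUE) {
  stopifnot(lambda_rotation >= 0, lambda_translation >= 0)
  structure(list(base = "L1", lambda_rotation = lambda_rotation,
                 lambda_translation = lambda_translation,
                 intermediate_supervision = isTRUE(intermediate_supervision)),
            class = "loss_config")
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: SGD with batch size 10,
#' momentum 0.9, weight decay 2e-5, a linear warm-up reaching the initial
#' learning rate 0.001, and annealing of the rate every 5 epochs.
#'
#' @param batch_size Mini-batch size (default 10).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 weight decay (default 2e-5).
#' @param warmup_lr Learning rate reached at the end of warm-up
#'   (default 0.001).
#' @param warmup_epochs Length of the linear warm-up (default 5).
#' @param anneal_every Epoch interval between annealing steps (default 5).
#' @param anneal_factor Multiplicative annealing factor (default 0.9).
#' @param epochs Number of training epochs (default 200).
#' @param seed Integer seed controlling shuffling (default 1).
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 10, momentum = 0.9,
                         weight_decay = 2e-5, warmup_lr = 0.001,
                         warmup_epochs = 5, anneal_every = 5,
                         anneal_factor = 0.9, epochs = 200, seed = 1L) {
  stopifnot(batch_size >= 1, momentum >= 0, momentum < 1, weight_decay >= 0,
            warmup_lr > 0, warmup_epochs >= 1, anneal_every >= 1,
            anneal_factor > 0, anneal_factor <= 1, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay, warmup_lr = warmup_lr,
                 warmup_epochs = as.integer(warmup_epochs),
                 anneal_every = as.integer(anneal_every),
                 anneal_factor = anneal_factor, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Linear warm-up from a tenth of `warmup_lr` at epoch 0 to `warmup_lr` at
#' epoch `warmup_epochs`, then geometric annealing:
#' `warmup_lr * anneal_factor^floor((epoch - warmup_epochs)/anneal_every)`.
#'
#' @param epoch 0-based epoch index.
#' @param cfg A [train_config()].
#' @return The learning rate (positive; non-increasing after warm-up).
#' @export
learning_rate <- function(epoch, cfg = train_config()) {
  stopifnot(epoch >= 0)
  w <- cfg$warmup_epochs
  if (epoch <= w) {
    cfg$warmup_lr * (0.1 + 0.9 * epoch / w)
  } else {
    cfg$warmup_lr * cfg$anneal_factor^((epoch - w) %/% cfg$anneal_every)
  }
}

as_coord_matrix <- function(x) {
  if (inherits(x, "landmark_set") || is.matrix(x)) {
    return(unclass(x)[, c(1, 2), drop = FALSE])
  }
  rlang::abort("expected a landmark_set or 4x2 coordinate matrix",
               class = "cephan_error_shape")
}

#' L1 coordinate loss
#'
#' Mean absolute difference over all 8 coordinate components of the four
#' keypoints (order Ba, Ar, A', PNS).
#'
#' @param pred,gt [landmark_set()] objects (or 4x2 matrices) in the same
#'   units.
#' @return Non-negative scalar in those units.
#' @export
coordinate_loss <- function(pred, gt) {
  p <- as_coord_matrix(pred); g <- as_coord_matrix(gt)
  if (!all(dim(p) == dim(g))) {
    rlang::abort("prediction and ground truth must have matching keypoints",
                 class = "cephan_error_shape")
  }
  mean(abs(p - g))
}

#' Translation prior loss
#'
#' `(Da + Db)/2` where `Da` is the perpendicular distance of the predicted
#' Ar to the ground-truth Ar-Ba line and `Db` that of the predicted Ba.
#' Zero iff both predicted points lie on the true line (displacement along
#' the line is free).
#'
#' @inheritParams coordinate_loss
#' @return Non-negative scalar.
#' @export
translation_loss <- function(pred, gt) {
  p <- as_coord_matrix(pred); g <- as_coord_matrix(gt)
  da <- point_line_distance(p["Ar", ], g["Ar", ], g["Ba", ])
  db <- point_line_distance(p["Ba", ], g["Ar", ], g["Ba", ])
  unname((da + db) / 2)
}

#' Rotation prior loss
#'
#' Unsigned acute angle (radians, in `[0, pi/2]`) between the predicted and
#' ground-truth Ar-to-Ba directions; zero iff the lines are parallel.
#'
#' @inheritParams coordinate_loss
#' @return Angle in radians.
#' @export
rotation_loss <- function(pred, gt) {
  p <- as_coord_matrix(pred); g <- as_coord_matrix(gt)
  v <- p["Ba", ] - p["Ar", ]
  u <- g["Ba", ] - g["Ar", ]
  if (all(v == 0) || all(u == 0)) {
    rlang::abort("degenerate Ar-Ba direction", class = "cephan_error_invalid_geometry")
  }
  cr <- u[1] * v[2] - u[2] * v[1]
  dt <- sum(u * v)
  unname(atan2(abs(cr), abs(dt)))
}

#' Combined training loss over hourglass stacks
#'
#' Sums `coordinate_loss + lambda_r * rotation_loss + lambda_t *
#' translation_loss` over the supervised stacks (all stacks when
#' intermediate supervision is on, else the last only).
#'
#' @param per_stack_preds List of predictions (one [landmark_set()] or 4x2
#'   matrix per stack).
#' @param gt Ground-truth [landmark_set()].
#' @param cfg A [loss_config()].
#' @return List with `total` and a per-term `breakdown` tibble.
#' @export
total_loss <- function(per_stack_preds, gt, cfg = loss_config()) {
  stopifnot(length(per_stack_preds) >= 1)
  idx <- if (cfg$intermediate_supervision) seq_along(per_stack_preds)
         else length(per_stack_preds)
  rows <- purrr::map_dfr(idx, function(s) {
    cl <- coordinate_loss(per_stack_preds[[s]], gt)
    rl <- rotation_loss(per_stack_preds[[s]], gt)
    tl <- translation_loss(per_stack_preds[[s]], gt)
    tibble::tibble(stack = s, coordinate = cl, rotation = rl,
                   translation = tl,
                   total = cl + cfg$lambda_rotation * rl +
                     cfg$lambda_translation * tl)
  })
  list(total = sum(rows$total), breakdown = rows)
}

# ---- batched loss + gradient (heatmap units), used by the training loop ----
# pred, gt: arrays K x N x 2 with keypoint order Ba, Ar, Aprime, PNS.
# Returns value breakdown and gradient d(loss)/d(pred).
batch_loss_grad <- function(pred, gt, cfg) {
  K <- dim(pred)[1]; N <- dim(pred)[2]
  dif <- pred - gt
  l_coord <- mean(abs(dif))
  g <- sign(dif) / (2 * K * N)
  l_rot <- 0; l_tr <- 0
  if (cfg$lambda_rotation > 0 || cfg$lambda_translation > 0) {
    for (i in seq_len(N)) {
      gBa <- gt[1, i, ]; gAr <- gt[2, i, ]
      pBa <- pred[1, i, ]; pAr <- pred[2, i, ]
      u <- gBa - gAr
      L <- sqrt(sum(u^2))
      if (cfg$lambda_translation > 0) {
        # distances of predicted Ar and Ba to the true line through gAr, gBa
        for (ki in c(2, 1)) {
          p <- pred[ki, i, ]
          cr <- u[1] * (p[2] - gAr[2]) - u[2] * (p[1] - gAr[1])
          l_tr <- l_tr + abs(cr) / L / 2
          gr <- sign(cr) * c(-u[2], u[1]) / L / 2
          g[ki, i, ] <- g[ki, i, ] +
            cfg$lambda_translation * gr / N
        }
      }
      if (cfg$lambda_rotation > 0) {
        v <- pBa - pAr
        if (any(v != 0)) {
          cr <- u[1] * v[2] - u[2] * v[1]
          dt <- sum(u * v)
          l_rot <- l_rot + atan2(abs(cr), abs(dt))
          den <- cr^2 + dt^2
          if (cr != 0 && den > 0) {
            dv <- (abs(dt) * sign(cr) * c(-u[2], u[1]) -
                     abs(cr) * sign(dt) * u) / den
            g[1, i, ] <- g[1, i, ] + cfg$lambda_rotation * dv / N
            g[2, i, ] <- g[2, i, ] - cfg$lambda_rotation * dv / N
          }
        }
      }
    }
    l_rot <- l_rot / N
    l_tr <- l_tr / N
  }
  list(coordinate = l_coord, rotation = l_rot, translation = l_tr,
       total = l_coord + cfg$lambda_rotation * l_rot +
         cfg$lambda_translation * l_tr,
       grad = g)
}

coords_to_landmarks <- function(co) {
  landmark_set(co[1, ], co[2, ], co[3, ], co[4, ])
}

# Ground-truth coordinate array (K x N x 2) for a list of samples, in the
# given units-per-pixel scale (heatmap units when scale = input/heatmap).
gt_coord_array <- function(samples, scale = 1) {
  K <- 4
  N <- length(samples)
  out <- array(0, c(K, N, 2))
  for (i in seq_len(N)) {
    out[, i, ] <- unclass(samples[[i]]$landmarks)[, c(1, 2)] / scale
  }
  out
}

batch_image_array <- function(samples, idx, S) {
  x <- array(0, c(S, S, 1, length(idx)))
  for (j in seq_along(idx)) x[, , 1, j] <- samples[[idx[j]]]$image
  x
}

#' Train the keypoint network
#'
#' SGD with momentum, weight decay, warm-up and annealing. Each epoch records
#' the training loss breakdown and four validation metrics: mean per-keypoint
#' localization error (input pixels), PCK-style average precision and recall,
#' and the A/N ratio mean absolute error. The returned fit carries the
#' weights of the epoch with the lowest validation A/N error.
#'
#' @param model A `headnet` from [build_headnet()].
#' @param train_samples,val_samples Lists of `ceph_sample` objects sized to
#'   the model's input.
#' @param tcfg A [train_config()].
#' @param lcfg A [loss_config()].
#' @param ap_thresholds Pixel thresholds for validation AP/AR.
#' @param verbose Print a line per epoch.
#' @return A list of class `cephan_fit`: `model` (best weights), `history`
#'   (tibble, one row per epoch), `best_epoch`, and the configurations.
#' @export
train_headnet <- function(model, train_samples, val_samples,
                          tcfg = train_config(), lcfg = loss_config(),
                          ap_thresholds = 1:10, verbose = FALSE) {
  if (length(train_samples) == 0) {
    rlang::abort("empty training set", class = "cephan_error_config")
  }
  S <- model$cfg$input_size
  scale <- model$cfg$input_size / model$cfg$heatmap_size
  n <- length(train_samples)
  gt_hm <- gt_coord_array(train_samples, scale)
  val_gt <- lapply(val_samples, function(s) s$landmarks)
  val_ratio <- vapply(val_samples, function(s) s$true_ratio, numeric(1))
  set.seed(tcfg$seed)
  hist_rows <- vector("list", tcfg$epochs)
  best <- list(an = Inf, state = params_state(model$params), epoch = 0L)
  n_sup <- if (lcfg$intermediate_supervision) model$cfg$n_stacks else 1L

  for (epoch in seq_len(tcfg$epochs)) {
    lr <- learning_rate(epoch - 1, tcfg)
    perm <- sample.int(n)
    sums <- c(coordinate = 0, rotation = 0, translation = 0, total = 0)
    nb <- 0
    for (start in seq(1, n, by = tcfg$batch_size)) {
      idx <- perm[start:min(start + tcfg$batch_size - 1, n)]
      x <- batch_image_array(train_samples, idx, S)
      gt <- gt_hm[, idx, , drop = FALSE]
      fw <- headnet_fwd(model, x, train = TRUE)
      dlist <- vector("list", model$cfg$n_stacks)
      bl <- NULL
      for (s in seq_len(model$cfg$n_stacks)) {
        if (!lcfg$intermediate_supervision && s < model$cfg$n_stacks) next
        bs <- batch_loss_grad(fw$coords_hm[[s]], gt, lcfg)
        dlist[[s]] <- bs$grad
        bl <- if (is.null(bl)) bs else {
          bs$grad <- NULL
          purrr::map2(bl[names(bs)], bs, `+`)
        }
      }
      if (!is.finite(bl$total)) {
        rlang::abort(sprintf("non-finite loss at epoch %d (lr %.2g)",
                             epoch, lr),
                     class = "cephan_error_numeric")
      }
      headnet_bwd(model, fw, dlist)
      sgd_step(model$params, lr, tcfg$momentum, tcfg$weight_decay)
      sums <- sums + unlist(bl[c("coordinate", "rotation", "translation",
                                 "total")])
      nb <- nb + 1
    }
    vm <- validate_epoch(model, val_samples, val_gt, val_ratio, ap_thresholds)
    hist_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr,
      train_coordinate = sums[["coordinate"]] / nb,
      train_rotation = sums[["rotation"]] / nb,
      train_translation = sums[["translation"]] / nb,
      train_total = sums[["total"]] / nb,
      val_loc_error = vm$loc, val_ap = vm$ap, val_ar = vm$ar,
      val_an_error = vm$an)
    if (verbose) {
      message(sprintf(
        "epoch %3d lr %.5f loss %.4f | val loc %.3f px ap %.3f an %.4f",
        epoch, lr, sums[["total"]] / nb, vm$loc, vm$ap, vm$an))
    }
    if (is.finite(vm$an) && vm$an < best$an) {
      best <- list(an = vm$an, state = params_state(model$params),
                   epoch = epoch)
    }
  }
  if (best$epoch == 0L) {
    # no usable validation metric (e.g. empty validation set): keep the
    # final-epoch weights
    best <- list(an = NA_real_, state = params_state(model$params),
                 epoch = tcfg$epochs)
  }
  restore_params(model$params, best$state)
  structure(list(model = model, history = dplyr::bind_rows(hist_rows),
                 best_epoch = best$epoch, tcfg = tcfg, lcfg = lcfg),
            class = "cephan_fit")
}

validate_epoch <- function(model, val_samples, val_gt, val_ratio,
                           ap_thresholds, batch_size = 16) {
  if (length(val_samples) == 0) {
    return(list(loc = NA_real_, ap = NA_real_, ar = NA_real_, an = NA_real_))
  }
  n <- length(val_samples)
  S <- model$cfg$input_size
  pred <- array(0, c(4, n, 2))
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x <- batch_image_array(val_samples, idx, S)
    fw <- headnet_fwd(model, x, train = FALSE)
    pred[, idx, ] <- fw$coords
  }
  gt <- gt_coord_array(val_samples, 1)
  err <- sqrt((pred[, , 1] - gt[, , 1])^2 + (pred[, , 2] - gt[, , 2])^2)
  frac <- vapply(ap_thresholds, function(t) mean(err <= t), numeric(1))
  an <- vapply(seq_len(n), function(i) {
    tryCatch(abs(compute_an(coords_to_landmarks(pred[, i, ]))$ratio -
                   val_ratio[i]),
             error = function(e) NA_real_)
  }, numeric(1))
  list(loc = mean(err), ap = mean(frac), ar = mean(frac),
       an = mean(an, na.rm = TRUE))
}

#' @export
print.cephan_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(paste0("cephan_fit: %d epochs, best epoch %d ",
                     "(val A/N error %.4f)\n"),
              nrow(h), x$best_epoch,
              h$val_an_error[x$best_epoch]))
  invisible(x)
}
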