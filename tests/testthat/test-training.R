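gt_lm <- landmark_set(Ba = c(10, 40), Ar = c(10, 10),
                      Aprime = c(25, 22), PNS = c(30, 38))

test_that("L1 coordinate loss averages over the 8 components", {
  expect_equal(coordinate_loss(gt_lm, gt_lm), 0)
  shifted <- transform_lm(gt_lm, shift = c(2, 2))
  expect_equal(coordinate_loss(shifted, gt_lm), 2)
  m <- unclass(gt_lm)
  pred <- landmark_set(m["Ba", ] + c(8, 0), m["Ar", ], m["Aprime", ],
                       m["PNS", ])
  expect_equal(coordinate_loss(pred, gt_lm), 1)
})

test_that("translation loss measures only off-line displacement of Ar and Ba", {
  m <- unclass(gt_lm)
  # slide both points along the ground-truth line: loss is exactly zero
  u <- (m["Ba", ] - m["Ar", ]) / sqrt(sum((m["Ba", ] - m["Ar", ])^2))
  slid <- landmark_set(m["Ba", ] + 7 * u, m["Ar", ] - 3 * u,
                       m["Aprime", ], m["PNS", ])
  expect_equal(translation_loss(slid, gt_lm), 0)
  # perpendicular offsets average: (3 + 0)/2 and (2 + 2)/2
  n_hat <- c(-u[2], u[1])
  off_ar <- landmark_set(m["Ba", ], m["Ar", ] + 3 * n_hat, m["Aprime", ],
                         m["PNS", ])
  expect_equal(translation_loss(off_ar, gt_lm), 1.5, tolerance = 1e-9)
  off_both <- landmark_set(m["Ba", ] + 2 * n_hat, m["Ar", ] + 2 * n_hat,
                           m["Aprime", ], m["PNS", ])
  expect_equal(translation_loss(off_both, gt_lm), 2, tolerance = 1e-9)
})

test_that("rotation loss is the acute angle between the Ar-Ba lines", {
  expect_equal(rotation_loss(gt_lm, gt_lm), 0)
  rotated <- transform_lm(gt_lm, angle = 90)
  expect_equal(rotation_loss(rotated, gt_lm), pi / 2, tolerance = 1e-9)
  rotated45 <- transform_lm(gt_lm, angle = 45)
  expect_equal(rotation_loss(rotated45, gt_lm), pi / 4, tolerance = 1e-9)
  # parallel but displaced: zero
  shifted <- transform_lm(gt_lm, shift = c(5, -3))
  expect_equal(rotation_loss(shifted, gt_lm), 0, tolerance = 1e-12)
})

test_that("total loss sums stacks and reduces to L1 when priors are off", {
  pred <- transform_lm(gt_lm, shift = c(1, 2))
  # perfect predictions at every stack
  expect_equal(total_loss(list(gt_lm, gt_lm), gt_lm)$total, 0)
  # lambda = 0 reduces to summed coordinate loss (plain ablation arm)
  l0 <- loss_config(lambda_rotation = 0, lambda_translation = 0)
  expect_equal(total_loss(list(pred, pred), gt_lm, l0)$total,
               2 * coordinate_loss(pred, gt_lm))
  # additivity over stacks with identical errors
  single <- total_loss(list(pred), gt_lm)$total
  expect_equal(total_loss(list(pred, pred), gt_lm)$total, 2 * single)
  # without intermediate supervision only the last stack counts
  lno <- loss_config(intermediate_supervision = FALSE)
  expect_equal(total_loss(list(transform_lm(gt_lm, shift = c(9, 9)), pred),
                          gt_lm, lno)$total,
               total_loss(list(pred), gt_lm)$total)
})

test_that("batched loss/gradient agrees with the scalar loss functions", {
  set.seed(11)
  lcfg <- loss_config(0.1, 0.1)
  pred_lm <- rand_landmarks(); true_lm <- rand_landmarks()
  pred <- array(0, c(4, 1, 2)); gt <- array(0, c(4, 1, 2))
  pred[, 1, ] <- unclass(pred_lm)[, c(1, 2)]
  gt[, 1, ] <- unclass(true_lm)[, c(1, 2)]
  b <- cephan:::batch_loss_grad(pred, gt, lcfg)
  expect_equal(b$coordinate, coordinate_loss(pred_lm, true_lm))
  expect_equal(b$rotation, rotation_loss(pred_lm, true_lm), tolerance = 1e-12)
  expect_equal(b$translation, translation_loss(pred_lm, true_lm),
               tolerance = 1e-12)
  # gradient check against central differences
  for (trial in 1:6) {
    k <- sample(4, 1); d <- sample(2, 1)
    eps <- 1e-7
    up <- pred; up[k, 1, d] <- up[k, 1, d] + eps
    dn <- pred; dn[k, 1, d] <- dn[k, 1, d] - eps
    num <- (cephan:::batch_loss_grad(up, gt, lcfg)$total -
              cephan:::batch_loss_grad(dn, gt, lcfg)$total) / (2 * eps)
    expect_equal(b$grad[k, 1, d], num, tolerance = 1e-5)
  }
})

test_that("the learning-rate schedule warms up then anneals", {
  cfg <- train_config()
  expect_equal(learning_rate(0, cfg), 0.0001)
  expect_equal(learning_rate(5, cfg), 0.001)
  expect_equal(learning_rate(10, cfg), 0.0009)
  expect_equal(learning_rate(15, cfg), 0.00081)
  for (e in seq(5, 60, by = 5)) {
    expect_lte(learning_rate(e + 5, cfg), learning_rate(e, cfg))
  }
})

test_that("one optimizer step reduces the coordinate loss", {
  set.seed(12)
  model <- tiny_model(size = 32, width = 8, seed = 3)
  s <- tiny_samples(1, size = 32, seed = 41)[[1]]
  x <- array(s$image, c(32, 32, 1, 1))
  gt <- cephan:::gt_coord_array(list(s), scale = 4)
  lcfg <- loss_config()
  loss_of <- function() {
    fw <- cephan:::headnet_fwd(model, x, train = TRUE)
    list(fw = fw,
         bl = cephan:::batch_loss_grad(fw$coords_hm[[1]], gt, lcfg))
  }
  st <- loss_of()
  before <- st$bl$total
  cephan:::headnet_bwd(model, st$fw, list(st$bl$grad))
  cephan:::sgd_step(model$params, 0.05, 0, 0)
  after <- loss_of()$bl$total
  expect_lt(after, before)
})

test_that("training records history, selects the best epoch, and is reproducible", {
  samples <- tiny_samples(24, size = 32, seed = 13)
  run <- function() {
    model <- tiny_model(size = 32, width = 8, seed = 2)
    train_headnet(model, samples[1:16], samples[17:24],
                  train_config(batch_size = 8, warmup_lr = 0.01,
                               warmup_epochs = 2, epochs = 5, seed = 9),
                  loss_config())
  }
  fit <- run()
  h <- fit$history
  expect_equal(nrow(h), 5)
  expect_true(all(c("train_total", "val_loc_error", "val_ap", "val_ar",
                    "val_an_error") %in% names(h)))
  expect_true(all(is.finite(h$val_an_error)))
  expect_equal(fit$best_epoch, which.min(h$val_an_error))
  fit2 <- run()
  expect_equal(fit2$history$train_total, h$train_total, tolerance = 1e-6)
  expect_error(train_headnet(tiny_model(), list(), list()),
               class = "cephan_error_config")
})
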