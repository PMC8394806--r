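test_that("default configuration matches the reference layer table", {
  lp <- layer_params(model_config())
  expect_equal(lp$kernel, c(7, 1, 1, 1, 3, 1, 7))
  expect_equal(lp$stride, c(2, 1, 1, 1, 1, 1, 1))
  expect_equal(lp$out_channels, c(64, 4, 256, 128, 128, 16, 1))

  model <- build_headnet(model_config(), seed = 1)
  expect_equal(model$stem$c1$kh, 7L)
  expect_equal(model$stem$c1$stride, 2L)
  expect_equal(model$stem$c1$cout, 64L)
  for (st in model$stacks) expect_equal(st$head$cout, 4L)

  expect_error(model_config(input_size = 256, heatmap_size = 32),
               class = "cephan_error_config")
})

test_that("a test-scale model builds and runs forward on 64x64 input", {
  model <- build_headnet(model_config(input_size = 64, width = 32,
                                      n_stacks = 1, hourglass_depth = 2,
                                      stem_channels = 8), seed = 2)
  x <- array(stats::runif(64 * 64 * 3), c(64, 64, 1, 3))
  fw <- cephan:::headnet_fwd(model, x)
  expect_equal(dim(fw$coords), c(4, 3, 2))
  expect_true(all(fw$coords >= 0 & fw$coords <= 63))
  expect_length(fw$heatmaps, 1)
  expect_equal(dim(fw$heatmaps[[1]]), c(16, 16, 4, 3))

  # deterministic in inference mode
  fw2 <- cephan:::headnet_fwd(model, x)
  expect_identical(fw$coords, fw2$coords)

  expect_error(cephan:::headnet_fwd(model, array(0, c(32, 32, 1, 1))),
               class = "cephan_error_shape")
})

test_that("residual module with zero weights is the identity map", {
  set.seed(3)
  mod <- cephan:::res_init(8)
  for (ly in cephan:::collect_params(mod)) { ly$W[] <- 0; ly$b[] <- 0 }
  x <- array(stats::rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  expect_equal(cephan:::res_fwd(mod, x)$y, x)
  # zero input with zero weights stays zero
  z <- array(0, c(6, 6, 8, 2))
  expect_equal(cephan:::res_fwd(mod, z)$y, z)
  # shape preserved for any spatial size
  x2 <- array(stats::rnorm(10 * 10 * 8), c(10, 10, 8, 1))
  expect_equal(dim(cephan:::res_fwd(mod, x2)$y), dim(x2))
})

test_that("attention gates saturated at 1 reduce to the plain residual module", {
  set.seed(4)
  plain <- cephan:::res_init(8)
  att <- cephan:::res_init(8, attention = TRUE, ca_bottleneck = 4,
                           sa_kernel = 3)
  for (nm in c("c4", "c5", "c3")) {
    att[[nm]]$W <- plain[[nm]]$W
    att[[nm]]$b <- plain[[nm]]$b
  }
  # force both gates to sigmoid(40) ~ 1
  att$ca2$W[] <- 0; att$ca2$b[] <- 40
  att$c7$W[] <- 0; att$c7$b[] <- 40
  x <- array(stats::rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  expect_equal(cephan:::res_fwd(att, x)$y, cephan:::res_fwd(plain, x)$y,
               tolerance = 1e-12)
})

test_that("attention gating only attenuates the branch (sigmoid bound)", {
  set.seed(5)
  mod <- cephan:::res_init(8, attention = TRUE, ca_bottleneck = 4,
                           sa_kernel = 3)
  x <- array(stats::rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  out <- cephan:::res_fwd(mod, x)
  branch_raw <- out$cache$m          # bottleneck output before gating
  branch_gated <- out$y - x          # what was added to the shortcut
  expect_true(all(abs(branch_gated) <= abs(branch_raw) + 1e-12))
  expect_equal(dim(out$y), dim(x))
})

test_that("integral regression satisfies its closed-form identities", {
  # uniform grid -> exact centre
  expect_equal(integral_coordinates(matrix(3.7, 64, 64)),
               c(x = 31.5, y = 31.5))
  # concentrated peak -> peak location
  h <- matrix(0, 64, 64)
  h[11, 21] <- 1000                      # y = 10, x = 20 (0-based)
  expect_equal(integral_coordinates(h), c(x = 20, y = 10), tolerance = 0.01)
  # two equal atoms -> midpoint
  h2 <- matrix(-Inf, 16, 16)
  h2[1, 1] <- 50; h2[11, 1] <- 50        # (x=0,y=0) and (x=0,y=10)
  expect_equal(integral_coordinates(h2), c(x = 0, y = 5), tolerance = 1e-9)
})

test_that("integral regression equals the brute-force softmax expectation", {
  set.seed(6)
  for (i in 1:20) {
    h <- matrix(stats::rnorm(16 * 16, sd = 2), 16, 16)
    p <- exp(h) / sum(exp(h))
    ex <- c(0, 0)
    for (r in 1:16) for (cc in 1:16) {
      ex <- ex + p[r, cc] * c(cc - 1, r - 1)
    }
    expect_equal(unname(integral_coordinates(h)), ex, tolerance = 1e-5)
  }
  # sharply peaked grid: integral within half a pixel of the argmax
  h <- matrix(stats::rnorm(16 * 16), 16, 16)
  h[5, 9] <- 25
  expect_lt(max(abs(integral_coordinates(h) - c(8, 4))), 0.5)
})

test_that("analytic gradients agree with finite differences end to end", {
  set.seed(42)
  model <- tiny_model(size = 16, width = 8, stacks = 2, depth = 1, seed = 5)
  x <- array(stats::runif(16 * 16 * 2), c(16, 16, 1, 2))
  gt <- array(stats::runif(16, 0, 3), c(4, 2, 2))
  lcfg <- loss_config()
  lossfn <- function() {
    fw <- cephan:::headnet_fwd(model, x, train = TRUE)
    sum(vapply(1:2, function(s)
      cephan:::batch_loss_grad(fw$coords_hm[[s]], gt, lcfg)$total,
      numeric(1)))
  }
  fw <- cephan:::headnet_fwd(model, x, train = TRUE)
  dlist <- lapply(1:2, function(s)
    cephan:::batch_loss_grad(fw$coords_hm[[s]], gt, lcfg)$grad)
  cephan:::zero_grads(model$params)
  cephan:::headnet_bwd(model, fw, dlist)
  set.seed(2)
  for (p in sample(model$params, 8)) {
    i <- sample(length(p$W), 1)
    w0 <- p$W[i]
    p$W[i] <- w0 + 1e-6; up <- lossfn()
    p$W[i] <- w0 - 1e-6; dn <- lossfn()
    p$W[i] <- w0
    num <- (up - dn) / 2e-6
    expect_equal(p$gW[i], num, tolerance = 1e-3)
  }
})

test_that("checkpoints round-trip weights and predictions", {
  dir <- withr::local_tempdir()
  model <- tiny_model(size = 32, width = 8, seed = 7)
  x <- matrix(stats::runif(32 * 32), 32, 32)
  before <- predict_landmarks(model, x)
  p <- file.path(dir, "ck.rds")
  save_checkpoint(model, p)
  after <- predict_landmarks(load_checkpoint(p), x)
  expect_equal(after, before, tolerance = 1e-12)
})
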