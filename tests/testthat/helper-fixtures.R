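# Random valid landmark set: Ba-Ar clivus line plus A' and PNS placed on the
# same side, guaranteeing non-degenerate geometry.
rand_landmarks <- function() {
  repeat {
    ba <- stats::runif(2, 0, 200)
    ar <- ba + stats::runif(2, -80, 80)
    if (sum((ar - ba)^2) < 25) next
    u <- (ar - ba) / sqrt(sum((ar - ba)^2))
    n_hat <- c(-u[2], u[1])
    foot <- ba + stats::runif(1, 0.1, 0.9) * (ar - ba)
    ap <- foot + stats::runif(1, 1, 60) * n_hat
    pns <- foot + stats::runif(1, 20, 90) * n_hat +
      stats::runif(1, -30, 30) * u
    if (sum((pns - foot)^2) < 1) next
    return(landmark_set(Ba = ba, Ar = ar, Aprime = ap, PNS = pns))
  }
}

# Apply a rigid-plus-scale transform to every landmark.
transform_lm <- function(lm, angle = 0, shift = c(0, 0), scale = 1) {
  th <- angle * pi / 180
  R <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  m <- unclass(lm)[, c("x", "y")]
  out <- t(R %*% t(m) + shift)
  landmark_set(out[1, ], out[2, ], out[3, ], out[4, ])
}

# Independent oracle for the adenoid depth A: dense sampling of points on the
# Ba-Ar line, refined with golden-section search.
oracle_A <- function(lm) {
  m <- unclass(lm)
  ba <- m["Ba", ]; ar <- m["Ar", ]; ap <- m["Aprime", ]
  dist_at <- function(t) {
    p <- ba + t * (ar - ba)
    sqrt(sum((ap - p)^2))
  }
  ts <- seq(-10, 10, length.out = 4001)
  d <- vapply(ts, dist_at, numeric(1))
  i <- which.min(d)
  lo <- ts[max(1, i - 1)]; hi <- ts[min(length(ts), i + 1)]
  stats::optimize(dist_at, c(lo, hi), tol = 1e-12)$objective
}

tiny_samples <- function(n, size = 32, seed = 99) {
  cfg <- synth_config(image_size = size, seed = seed, noise_sd = 0.01)
  generate_dataset(cfg, n)$samples
}

tiny_model <- function(size = 32, width = 8, stacks = 1, depth = 1,
                       seed = 1) {
  build_headnet(model_config(input_size = size, width = width,
                             n_stacks = stacks, hourglass_depth = depth,
                             stem_channels = 4,
                             channel_attention_bottleneck = 4,
                             spatial_attention_kernel = 3),
                seed = seed)
}
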