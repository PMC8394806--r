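#' Keypoint network configuration
#'
#' Configures the stacked-hourglass keypoint detector: a convolutional stem
#' (7x7 stride-2 convolution, max-pool, 1x1 expansion to `width` channels)
#' followed by `n_stacks` hourglass modules built from bottleneck residual
#' modules, each hourglass flanked by attention residual modules (channel
#' gate then spatial gate) when `use_attention` is on, and a 1x1 head
#' emitting one heatmap per keypoint. A soft-argmax integral regression layer
#' converts each heatmap into continuous coordinates.
#'
#' The default layer geometry reproduces the reference parameterisation:
#' C1 7x7/stride 2/64 channels (stem), C2 1x1/4 (head), C3 1x1/256
#' (expansion), C4 1x1/128 and C5 3x3/128 (bottleneck), C6 1x1/16 (channel
#' attention) and C7 7x7/1 (spatial attention).
#'
#' @param input_size Input image side in pixels (default 256).
#' @param heatmap_size Heatmap side; must equal `input_size / 4` (stride-2
#'   stem convolution plus one 2x max-pool).
#' @param n_keypoints Number of keypoints (fixed at 4 for the A/N pipeline).
#' @param n_stacks Number of stacked hourglasses (default 2).
#' @param hourglass_depth Number of pooling levels per hourglass (default 4).
#' @param width Working channel count (default 256).
#' @param use_attention Use attention residual modules at hourglass entry and
#'   exit (default TRUE); FALSE gives the plain ablation variant.
#' @param channel_attention_bottleneck Channel-gate bottleneck width
#'   (default 16).
#' @param spatial_attention_kernel Spatial-gate kernel size (default 7).
#' @param stem_channels Output channels of the stem 7x7 convolution
#'   (default 64).
#' @return A list of class `model_config`.
#' @export
model_config <- function(input_size = 256, heatmap_size = input_size %/% 4,
                         n_keypoints = 4, n_stacks = 2, hourglass_depth = 4,
                         width = 256, use_attention = TRUE,
                         channel_attention_bottleneck = 16,
                         spatial_attention_kernel = 7, stem_channels = 64) {
  if (heatmap_size * 4 != input_size) {
    rlang::abort("heatmap_size must equal input_size / 4",
                 class = "cephan_error_config")
  }
  if (heatmap_size %% 2^hourglass_depth != 0) {
    rlang::abort("heatmap_size must be divisible by 2^hourglass_depth",
                 class = "cephan_error_config")
  }
  stopifnot(n_stacks >= 1, width >= 2, n_keypoints >= 1)
  structure(list(input_size = as.integer(input_size),
                 heatmap_size = as.integer(heatmap_size),
                 n_keypoints = as.integer(n_keypoints),
                 n_stacks = as.integer(n_stacks),
                 hourglass_depth = as.integer(hourglass_depth),
                 width = as.integer(width),
                 use_attention = isTRUE(use_attention),
                 channel_attention_bottleneck =
                   as.integer(channel_attention_bottleneck),
                 spatial_attention_kernel =
                   as.integer(spatial_attention_kernel),
                 stem_channels = as.integer(stem_channels)),
            class = "model_config")
}

#' Convolutional layer table of a model configuration
#'
#' @param cfg A [model_config()].
#' @return Tibble with one row per named layer (C1..C7): kernel size, stride
#'   and output channels. At the default configuration this equals the
#'   reference table exactly.
#' @export
layer_params <- function(cfg = model_config()) {
  tibble::tibble(
    name = paste0("C", 1:7),
    kernel = c(7, 1, 1, 1, 3, 1, cfg$spatial_attention_kernel),
    stride = c(2, 1, 1, 1, 1, 1, 1),
    out_channels = c(cfg$stem_channels, cfg$n_keypoints, cfg$width,
                     cfg$width %/% 2, cfg$width %/% 2,
                     cfg$channel_attention_bottleneck, 1),
    role = c("stem", "heatmap head", "expansion / bottleneck exit",
             "bottleneck entry", "bottleneck 3x3", "channel attention",
             "spatial attention")
  )
}

#' Build the keypoint network
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the random (He fan-in) initialisation of all
#'   convolution parameters.
#' @return A list of class `headnet` holding the layer structure, the flat
#'   parameter list and the configuration. `n_parameters` is reported in the
#'   print method.
#' @export
build_headnet <- function(cfg = model_config(), seed = 1L) {
  set.seed(seed)
  w <- cfg$width
  mk_res <- function(name, att = FALSE) {
    res_init(w, attention = att && cfg$use_attention,
             ca_bottleneck = cfg$channel_attention_bottleneck,
             sa_kernel = cfg$spatial_attention_kernel, name = name)
  }
  stacks <- lapply(seq_len(cfg$n_stacks), function(s) {
    st <- list(
      att_in = mk_res(sprintf("s%d.in", s), att = TRUE),
      hg = hg_init(cfg$hourglass_depth, w, sprintf("s%d.hg", s)),
      att_out = mk_res(sprintf("s%d.out", s), att = TRUE),
      head = new_conv(1, 1, w, cfg$n_keypoints, name = sprintf("s%d.head", s))
    )
    if (s < cfg$n_stacks) {
      st$merge_f <- new_conv(1, 1, w, w, name = sprintf("s%d.mf", s))
      st$merge_h <- new_conv(1, 1, cfg$n_keypoints, w,
                             name = sprintf("s%d.mh", s))
    }
    st
  })
  model <- list(
    cfg = cfg,
    seed = as.integer(seed),
    stem = list(
      c1 = new_conv(7, 7, 1, cfg$stem_channels, stride = 2, name = "stem.c1"),
      c3 = new_conv(1, 1, cfg$stem_channels, w, name = "stem.c3")
    ),
    stacks = stacks
  )
  model$params <- collect_params(list(model$stem, model$stacks))
  class(model) <- "headnet"
  model
}

#' @export
print.headnet <- function(x, ...) {
  cat(sprintf(paste0("headnet: %d stack(s), depth %d, width %d, ",
                     "attention %s\n  input %dx%d -> heatmaps %dx%dx%d, ",
                     "%s parameters\n"),
              x$cfg$n_stacks, x$cfg$hourglass_depth, x$cfg$width,
              if (x$cfg$use_attention) "on" else "off",
              x$cfg$input_size, x$cfg$input_size, x$cfg$heatmap_size,
              x$cfg$heatmap_size, x$cfg$n_keypoints,
              format(n_parameters(x$params), big.mark = ",")))
  invisible(x)
}

#' Soft-argmax integral regression over one heatmap
#'
#' Normalises raw scores to a probability grid with a softmax over all pixels
#' and returns the expectation of the pixel-centre coordinates. The result is
#' continuous, strictly inside the grid, and differentiable in the scores.
#'
#' @param h Numeric matrix of raw scores (rows = y, columns = x).
#' @return `c(x, y)` in 0-based pixel units of the grid.
#' @export
integral_coordinates <- function(h) {
  if (all(is.na(h))) {
    rlang::abort("heatmap contains no finite scores",
                 class = "cephan_error_numeric")
  }
  p <- exp(h - max(h))
  p <- p / sum(p)
  xs <- 0:(ncol(h) - 1)
  ys <- 0:(nrow(h) - 1)
  c(x = sum(colSums(p) * xs), y = sum(rowSums(p) * ys))
}

# Batched softargmax: heat (Hh, Wh, K, N) -> list(coords = array(K, N, 2)
# in heatmap units, p = prob matrix (Hh*Wh) x (K*N)) for backprop.
integral_fwd <- function(heat) {
  d <- dim(heat)
  HW <- d[1] * d[2]
  hm <- matrix(heat, HW, d[3] * d[4])
  mx <- apply(hm, 2, max)
  p <- exp(hm - rep(mx, each = HW))
  p <- p / rep(colSums(p), each = HW)
  xv <- rep(0:(d[2] - 1), each = d[1])
  yv <- rep(0:(d[1] - 1), times = d[2])
  cx <- colSums(p * xv)
  cy <- colSums(p * yv)
  list(coords = array(c(cx, cy), c(d[3], d[4], 2)), p = p,
       xv = xv, yv = yv, dim = d)
}

# dcoords: array (K, N, 2) -> gradient w.r.t. raw scores, array (Hh,Wh,K,N)
integral_bwd <- function(cache, dcoords) {
  d <- cache$dim
  HW <- d[1] * d[2]
  KN <- d[3] * d[4]
  cx <- colSums(cache$p * cache$xv)
  cy <- colSums(cache$p * cache$yv)
  dcx <- as.vector(dcoords[, , 1])
  dcy <- as.vector(dcoords[, , 2])
  ds <- cache$p * ((cache$xv - rep(cx, each = HW)) * rep(dcx, each = HW) +
                   (cache$yv - rep(cy, each = HW)) * rep(dcy, each = HW))
  array(ds, d)
}

# Full forward pass. images: array (H, W, 1, N) or a single H x W matrix.
# Returns per-stack heatmaps and coordinates (heatmap units) plus the final
# coordinates in input-pixel units; caches retained when train = TRUE.
headnet_fwd <- function(model, images, train = FALSE) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1, 1))
  d <- dim(images)
  if (d[1] != model$cfg$input_size || d[2] != model$cfg$input_size) {
    rlang::abort(sprintf("expected %dx%d input images, got %dx%d",
                         model$cfg$input_size, model$cfg$input_size,
                         d[1], d[2]),
                 class = "cephan_error_shape")
  }
  f1 <- conv_fwd(model$stem$c1, images); a1 <- relu_fwd(f1$y)
  p1 <- pool_fwd(a1)
  f2 <- conv_fwd(model$stem$c3, p1$out); inter <- relu_fwd(f2$y)
  stem_cache <- list(c1 = f1$cache, a1 = a1, pidx = p1$idx, adim = dim(a1),
                     c3 = f2$cache, a2 = inter)
  S <- model$cfg$n_stacks
  heats <- vector("list", S)
  coords <- vector("list", S)
  icaches <- vector("list", S)
  scaches <- vector("list", S)
  for (s in seq_len(S)) {
    st <- model$stacks[[s]]
    r1 <- res_fwd(st$att_in, inter)
    hgo <- hg_fwd(st$hg, r1$y)
    r2 <- res_fwd(st$att_out, hgo$y)
    hd <- conv_fwd(st$head, r2$y)
    heats[[s]] <- hd$y
    ic <- integral_fwd(hd$y)
    coords[[s]] <- ic$coords
    sc <- list(att_in = r1$cache, hg = hgo$cache, att_out = r2$cache,
               head = hd$cache, inter_in = inter)
    if (s < S) {
      mf <- conv_fwd(st$merge_f, r2$y)
      mh <- conv_fwd(st$merge_h, hd$y)
      sc$mf <- mf$cache; sc$mh <- mh$cache
      inter <- inter + mf$y + mh$y
    }
    icaches[[s]] <- ic
    scaches[[s]] <- sc
  }
  scale <- model$cfg$input_size / model$cfg$heatmap_size
  out <- list(heatmaps = heats, coords_hm = coords,
              coords = coords[[S]] * scale, scale = scale)
  if (train) out$cache <- list(stem = stem_cache, stacks = scaches,
                               integral = icaches, xdim = d)
  out
}

# Backward pass from per-stack coordinate gradients (heatmap units).
# dcoords_list: list over stacks (NULL entries allowed = unsupervised stack).
headnet_bwd <- function(model, fwd, dcoords_list) {
  S <- model$cfg$n_stacks
  cache <- fwd$cache
  dinter <- NULL
  for (s in seq(S, 1)) {
    st <- model$stacks[[s]]
    sc <- cache$stacks[[s]]
    dheat <- NULL
    if (!is.null(dcoords_list[[s]])) {
      dheat <- integral_bwd(cache$integral[[s]], dcoords_list[[s]])
    }
    dr2 <- NULL
    if (s < S && !is.null(dinter)) {
      dr2 <- conv_bwd(st$merge_f, sc$mf, dinter)
      dmh <- conv_bwd(st$merge_h, sc$mh, dinter)
      dheat <- if (is.null(dheat)) dmh else dheat + dmh
    }
    if (!is.null(dheat)) {
      dhd <- conv_bwd(st$head, sc$head, dheat)
      dr2 <- if (is.null(dr2)) dhd else dr2 + dhd
    }
    dhg <- res_bwd(st$att_out, sc$att_out, dr2)
    dr1 <- hg_bwd(st$hg, sc$hg, dhg)
    dx <- res_bwd(st$att_in, sc$att_in, dr1)
    dinter <- if (s < S && !is.null(dinter)) dinter + dx else dx
  }
  # stem backward
  sc <- cache$stem
  dinter <- relu_bwd(sc$a2, dinter)
  dp <- conv_bwd(model$stem$c3, sc$c3, dinter)
  da1 <- pool_bwd(dp, sc$pidx, sc$adim)
  da1 <- relu_bwd(sc$a1, da1)
  invisible(conv_bwd(model$stem$c1, sc$c1, da1))
}

#' Detect landmarks in images with a trained network
#'
#' @param model A `headnet` (or a `cephan_fit`, whose best weights are used).
#' @param images A single image matrix, a list of matrices, or a list of
#'   `ceph_sample` objects.
#' @param batch_size Images per forward pass.
#' @return A tibble with one row per image: `id` (when available), predicted
#'   landmark columns in input-pixel units, and the A/N `ratio` and `label`
#'   computed from the detected landmarks.
#' @export
predict_landmarks <- function(model, images, batch_size = 16) {
  if (inherits(model, "cephan_fit")) model <- model$model
  if (is.matrix(images)) images <- list(images)
  ids <- NULL
  if (length(images) > 0 && inherits(images[[1]], "ceph_sample")) {
    ids <- vapply(images, function(s) s$id, character(1))
    images <- lapply(images, function(s) s$image)
  }
  n <- length(images)
  S <- model$cfg$input_size
  rows <- vector("list", ceiling(n / batch_size))
  bi <- 0
  for (start in seq(1, max(n, 1), by = batch_size)) {
    if (n == 0) break
    end <- min(start + batch_size - 1, n)
    nb <- end - start + 1
    batch <- array(0, c(S, S, 1, nb))
    for (i in seq_len(nb)) {
      img <- images[[start + i - 1]]
      if (nrow(img) != S || ncol(img) != S) {
        warning(sprintf("resizing input image from %dx%d to %dx%d",
                        nrow(img), ncol(img), S, S))
        img <- resize_with_landmarks(
          new_ceph_sample("tmp", img,
                          landmark_set(c(1, 1), c(2, 2), c(1, 2), c(2, 1)),
                          0.5, "normal"), S)$image
      }
      batch[, , 1, i] <- img
    }
    fw <- headnet_fwd(model, batch, train = FALSE)
    co <- fw$coords                              # K x nb x 2
    bi <- bi + 1
    rows[[bi]] <- purrr::map_dfr(seq_len(nb), function(i) {
      tibble::tibble(
        Ba_x = co[1, i, 1], Ba_y = co[1, i, 2],
        Ar_x = co[2, i, 1], Ar_y = co[2, i, 2],
        Aprime_x = co[3, i, 1], Aprime_y = co[3, i, 2],
        PNS_x = co[4, i, 1], PNS_y = co[4, i, 2])
    })
  }
  out <- dplyr::bind_rows(rows)
  if (n == 0) return(out)
  if (!is.null(ids)) out <- dplyr::bind_cols(tibble::tibble(id = ids), out)
  an_ratio(out)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration, the initialisation seed and all
#' layer weights.
#'
#' @param model A `headnet` or `cephan_fit`.
#' @param path Checkpoint file path (RDS).
#' @return `load_checkpoint()` returns a `headnet`;
#'   `save_checkpoint()` returns `path` invisibly.
#' @export
save_checkpoint <- function(model, path) {
  fit <- NULL
  if (inherits(model, "cephan_fit")) { fit <- model; model <- model$model }
  saveRDS(list(cfg = unclass(model$cfg), seed = model$seed,
               state = params_state(model$params),
               history = if (!is.null(fit)) fit$history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_headnet(do.call(model_config,
                                 ck$cfg[setdiff(names(ck$cfg), NULL)]),
                         seed = ck$seed)
  restore_params(model$params, ck$state)
  attr(model, "history") <- ck$history
  model
}
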