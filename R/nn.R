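# Minimal CNN layer toolkit used by the keypoint network.
#
# Tensors are R arrays with dim c(H, W, C, N). Convolutions run as
# im2col (C++) + BLAS GEMM; every layer stores its parameters, gradient
# accumulators and momentum buffers in an environment so SGD can update
# in place. Backward passes are hand-derived.

new_conv <- function(kh, kw, cin, cout, stride = 1L, pad = NULL, name = "conv") {
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  e <- new.env(parent = emptyenv())
  e$kh <- as.integer(kh); e$kw <- as.integer(kw)
  e$cin <- as.integer(cin); e$cout <- as.integer(cout)
  e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  k <- kh * kw * cin
  e$W <- matrix(stats::rnorm(k * cout, 0, sqrt(2 / k)), k, cout)  # He fan-in
  e$b <- numeric(cout)
  e$gW <- matrix(0, k, cout); e$gb <- numeric(cout)
  e$vW <- matrix(0, k, cout); e$vb <- numeric(cout)
  e$name <- name
  e$kind <- "conv"
  e
}

conv_fwd <- function(ly, x) {
  d <- dim(x)
  if (ly$kh == 1L && ly$kw == 1L && ly$stride == 1L) {
    # pointwise convolution: plain GEMM over the channel axis
    xm <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1] * d[2] * d[4], d[3])
    y <- xm %*% ly$W
    y <- sweep_add_rows(y, ly$b)
    ya <- aperm(array(y, c(d[1], d[2], d[4], ly$cout)), c(1L, 2L, 4L, 3L))
    return(list(y = ya, cache = list(xm = xm, xdim = d)))
  }
  cols <- im2col_cpp(x, d[1], d[2], d[3], d[4], ly$kh, ly$kw, ly$stride, ly$pad)
  Ho <- (d[1] + 2L * ly$pad - ly$kh) %/% ly$stride + 1L
  Wo <- (d[2] + 2L * ly$pad - ly$kw) %/% ly$stride + 1L
  y <- crossprod(ly$W, cols) + ly$b
  ya <- aperm(array(t(y), c(Ho, Wo, d[4], ly$cout)), c(1L, 2L, 4L, 3L))
  list(y = ya, cache = list(cols = cols, xdim = d))
}

sweep_add_rows <- function(m, b) {
  if (all(b == 0)) return(m)
  m + rep(b, each = nrow(m))
}

conv_bwd <- function(ly, cache, dy) {
  d <- dim(dy)                               # Ho Wo cout N
  dym <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), d[1] * d[2] * d[4], d[3])
  if (ly$kh == 1L && ly$kw == 1L && ly$stride == 1L) {
    ly$gW <- ly$gW + crossprod(cache$xm, dym)
    ly$gb <- ly$gb + colSums(dym)
    dx <- tcrossprod(dym, ly$W)
    xd <- cache$xdim
    return(aperm(array(dx, c(xd[1], xd[2], xd[4], xd[3])), c(1L, 2L, 4L, 3L)))
  }
  ly$gW <- ly$gW + cache$cols %*% dym
  ly$gb <- ly$gb + colSums(dym)
  dcols <- ly$W %*% t(dym)
  xd <- cache$xdim
  col2im_cpp(dcols, xd[1], xd[2], xd[3], xd[4], ly$kh, ly$kw, ly$stride, ly$pad)
}

new_dense <- function(cin, cout, name = "dense") {
  e <- new.env(parent = emptyenv())
  e$W <- matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout)
  e$b <- numeric(cout)
  e$gW <- matrix(0, cin, cout); e$gb <- numeric(cout)
  e$vW <- matrix(0, cin, cout); e$vb <- numeric(cout)
  e$name <- name
  e$kind <- "dense"
  e
}

dense_fwd <- function(ly, x) {             # x: cin x N -> cout x N
  list(y = crossprod(ly$W, x) + ly$b, cache = x)
}

dense_bwd <- function(ly, cache, dy) {
  ly$gW <- ly$gW + cache %*% t(dy)
  ly$gb <- ly$gb + rowSums(dy)
  ly$W %*% dy
}

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_bwd <- function(y, dy) dy * (y > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

pool_fwd <- function(x) {
  d <- dim(x)
  maxpool2_fwd_cpp(x, d[1], d[2], d[3], d[4])
}

pool_bwd <- function(grad, idx, xdim) {
  maxpool2_bwd_cpp(grad, idx, xdim[1], xdim[2], xdim[3], xdim[4])
}

up_fwd <- function(x) {
  d <- dim(x)
  upsample2_fwd_cpp(x, d[1], d[2], d[3], d[4])
}

up_bwd <- function(grad, xdim) {
  upsample2_bwd_cpp(grad, xdim[1], xdim[2], xdim[3], xdim[4])
}

# ---- residual module (bottleneck C4 -> C5 -> C3 + identity shortcut) ----
# With attention: the bottleneck output is gated by a channel-attention part
# (global average pool -> C6 -> ReLU -> expand -> sigmoid) and then a
# spatial-attention part (channel mean -> C7 -> sigmoid) before the add.

res_init <- function(width, attention = FALSE, ca_bottleneck = 16L,
                     sa_kernel = 7L, name = "res") {
  bott <- max(1L, width %/% 2L)
  mod <- list(
    type = if (attention) "att_res" else "res",
    c4 = new_conv(1, 1, width, bott, name = paste0(name, ".c4")),
    c5 = new_conv(3, 3, bott, bott, name = paste0(name, ".c5")),
    c3 = new_conv(1, 1, bott, width, name = paste0(name, ".c3"))
  )
  if (attention) {
    cb <- min(ca_bottleneck, width)
    mod$ca1 <- new_dense(width, cb, name = paste0(name, ".ca1"))
    mod$ca2 <- new_dense(cb, width, name = paste0(name, ".ca2"))
    mod$c7 <- new_conv(sa_kernel, sa_kernel, 1, 1, name = paste0(name, ".c7"))
  }
  mod
}

res_fwd <- function(mod, x) {
  f4 <- conv_fwd(mod$c4, x); a4 <- relu_fwd(f4$y)
  f5 <- conv_fwd(mod$c5, a4); a5 <- relu_fwd(f5$y)
  f3 <- conv_fwd(mod$c3, a5)
  m <- f3$y
  cache <- list(c4 = f4$cache, c5 = f5$cache, c3 = f3$cache,
                a4 = a4, a5 = a5)
  if (mod$type == "att_res") {
    d <- dim(m); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
    # channel attention
    gap <- matrix(colMeans(matrix(m, H * W, C * N)), C, N)
    h1f <- dense_fwd(mod$ca1, gap); h1 <- relu_fwd(h1f$y)
    zf <- dense_fwd(mod$ca2, h1)
    g <- sigmoid(zf$y)                                   # C x N
    m1 <- m * rep(g, each = H * W)
    # spatial attention (channel mean -> C7 -> sigmoid)
    sm <- array(rowMeans(matrix(aperm(m1, c(1, 2, 4, 3)), H * W * N, C)),
                c(H, W, 1, N))
    sf <- conv_fwd(mod$c7, sm)
    gs <- sigmoid(sf$y)                                  # H W 1 N
    gsb <- aperm(array(rep(gs, times = C), c(H, W, N, C)), c(1, 2, 4, 3))
    m2 <- m1 * gsb
    cache <- c(cache, list(m = m, g = g, h1 = h1, gap_dim = c(H, W, C, N),
                           m1 = m1, sm_cache = sf$cache, gs = gs, gsb = gsb))
    m <- m2
  }
  list(y = x + m, cache = cache)
}

res_bwd <- function(mod, cache, dy) {
  dm <- dy                                   # gradient into the branch output
  if (mod$type == "att_res") {
    d <- cache$gap_dim; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
    # through spatial gate: m2 = m1 * gsb
    dm1 <- dm * cache$gsb
    dgs <- array(rowSums(matrix(aperm(dm * cache$m1, c(1, 2, 4, 3)),
                                H * W * N, C)), c(H, W, 1, N))
    ds <- dgs * cache$gs * (1 - cache$gs)
    dsm <- conv_bwd(mod$c7, cache$sm_cache, ds)
    dm1 <- dm1 + aperm(array(rep(dsm / C, times = C), c(H, W, N, C)),
                       c(1, 2, 4, 3))
    # through channel gate: m1 = m * g
    dmm <- dm1 * rep(cache$g, each = H * W)
    dg <- matrix(colSums(matrix(dm1 * cache$m, H * W, C * N)), C, N)
    dz <- dg * cache$g * (1 - cache$g)
    dh1 <- dense_bwd(mod$ca2, cache$h1, dz)
    dh1 <- relu_bwd(cache$h1, dh1)
    dgap <- dense_bwd(mod$ca1, matrix(colMeans(matrix(cache$m, H * W, C * N)),
                                      C, N), dh1)
    dmm <- dmm + array(rep(dgap / (H * W), each = H * W), c(H, W, C, N))
    dm <- dmm
  }
  da5 <- conv_bwd(mod$c3, cache$c3, dm)
  da5 <- relu_bwd(cache$a5, da5)
  da4 <- conv_bwd(mod$c5, cache$c5, da5)
  da4 <- relu_bwd(cache$a4, da4)
  dx <- conv_bwd(mod$c4, cache$c4, da4)
  dx + dy                                    # identity shortcut
}

# ---- hourglass (recursive encoder-decoder of residual modules) ----

hg_init <- function(depth, width, name = "hg") {
  node <- list(
    type = "hg",
    up1 = res_init(width, name = paste0(name, ".up1")),
    low1 = res_init(width, name = paste0(name, ".low1")),
    low3 = res_init(width, name = paste0(name, ".low3"))
  )
  node$inner <- if (depth > 1) hg_init(depth - 1, width, paste0(name, ".in"))
                else res_init(width, name = paste0(name, ".core"))
  node
}

hg_fwd <- function(node, x) {
  u <- res_fwd(node$up1, x)
  p <- pool_fwd(x)
  l1 <- res_fwd(node$low1, p$out)
  l2 <- if (node$inner$type == "hg") hg_fwd(node$inner, l1$y)
        else res_fwd(node$inner, l1$y)
  l3 <- res_fwd(node$low3, l2$y)
  u2 <- up_fwd(l3$y)
  list(y = u$y + u2,
       cache = list(up1 = u$cache, low1 = l1$cache, inner = l2$cache,
                    low3 = l3$cache, pidx = p$idx, xdim = dim(x),
                    ldim = dim(l3$y)))
}

hg_bwd <- function(node, cache, dy) {
  dx_up <- res_bwd(node$up1, cache$up1, dy)
  dl3 <- up_bwd(dy, cache$ldim)
  dl2 <- res_bwd(node$low3, cache$low3, dl3)
  dl1 <- if (node$inner$type == "hg") hg_bwd(node$inner, cache$inner, dl2)
         else res_bwd(node$inner, cache$inner, dl2)
  dp <- res_bwd(node$low1, cache$low1, dl1)
  dx_up + pool_bwd(dp, cache$pidx, cache$xdim)
}

# ---- parameter traversal ----

collect_params <- function(x) {
  if (is.environment(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

n_parameters <- function(params) {
  sum(vapply(params, function(p) length(p$W) + length(p$b), numeric(1)))
}

zero_grads <- function(params) {
  for (p in params) { p$gW[] <- 0; p$gb[] <- 0 }
  invisible(NULL)
}

sgd_step <- function(params, lr, momentum, weight_decay) {
  for (p in params) {
    p$vW <- momentum * p$vW - lr * (p$gW + weight_decay * p$W)
    p$W <- p$W + p$vW
    p$vb <- momentum * p$vb - lr * p$gb
    p$b <- p$b + p$vb
    p$gW[] <- 0; p$gb[] <- 0
  }
  invisible(NULL)
}

params_state <- function(params) {
  lapply(params, function(p) list(W = p$W, b = p$b))
}

restore_params <- function(params, state) {
  for (i in seq_along(params)) {
    params[[i]]$W <- state[[i]]$W
    params[[i]]$b <- state[[i]]$b
  }
  invisible(NULL)
}
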