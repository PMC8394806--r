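#' Synthetic cephalogram generator configuration
#'
#' The generator emulates the three image features a lateral cephalogram
#' contributes to the Fujioka measurement: a bright clivus ridge whose
#' endpoints are Ba and Ar, a hard-palate wedge terminating posteriorly at
#' PNS, and a soft-tissue adenoid bulge whose point of maximal convexity is
#' A'. The class mix defaults to the 651:197:53 normal/moderate/severe
#' proportions of the clinical cohort the pipeline was designed around, with
#' per-class true-ratio ranges that straddle the 0.6 decision threshold while
#' excluding the ambiguous band (0.58, 0.62) so labels stay unambiguous under
#' landmark noise.
#'
#' @param image_size Side length in pixels of the square image (default 256).
#' @param ratio_range_normal,ratio_range_moderate,ratio_range_severe True
#'   A/N ratio intervals for the three severity strata.
#' @param class_mix Length-3 positive weights for normal/moderate/severe;
#'   normalised internally (default 651:197:53).
#' @param noise_sd Additive Gaussian pixel noise (intensity units in `[0,1]`).
#' @param blur_sigma Gaussian blur in pixels; default scales with image size.
#' @param margin Keep-in border: all landmarks stay at least this many pixels
#'   from every edge (default `image_size / 8`, i.e. 32 px at 256).
#' @param seed Integer seed used by [generate_dataset()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(image_size = 256,
                         ratio_range_normal = c(0.25, 0.58),
                         ratio_range_moderate = c(0.62, 0.75),
                         ratio_range_severe = c(0.75, 0.95),
                         class_mix = c(651, 197, 53),
                         noise_sd = 0.02,
                         blur_sigma = max(0.5, image_size / 256),
                         margin = image_size %/% 8,
                         seed = 1L) {
  stopifnot(image_size >= 32, length(class_mix) == 3, all(class_mix >= 0),
            sum(class_mix) > 0, margin < image_size / 2)
  ranges <- list(normal = ratio_range_normal, moderate = ratio_range_moderate,
                 severe = ratio_range_severe)
  for (r in ranges) stopifnot(length(r) == 2, r[1] < r[2], r[1] > 0, r[2] < 1)
  structure(list(image_size = as.integer(image_size),
                 ratio_ranges = ranges,
                 class_mix = class_mix / sum(class_mix),
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 margin = margin, seed = as.integer(seed)),
            class = "synth_config")
}

new_ceph_sample <- function(id, image, landmarks, true_ratio, true_label) {
  structure(list(id = id, image = image, landmarks = landmarks,
                 true_ratio = true_ratio, true_label = true_label),
            class = "ceph_sample")
}

#' @export
print.ceph_sample <- function(x, ...) {
  cat(sprintf("ceph_sample '%s': %dx%d image, true A/N ratio %.4f (%s)\n",
              x$id, nrow(x$image), ncol(x$image), x$true_ratio, x$true_label))
  invisible(x)
}

# Squared distance of every grid pixel to the segment a-b.
grid_segment_dist <- function(xg, yg, a, b) {
  u <- b - a
  len2 <- sum(u^2)
  t <- ((xg - a[1]) * u[1] + (yg - a[2]) * u[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  px <- a[1] + t * u[1]
  py <- a[2] + t * u[2]
  sqrt((xg - px)^2 + (yg - py)^2)
}

#' Generate one synthetic cephalogram
#'
#' Landmark geometry is drawn first (with jitter), then A' is *constructed*
#' so that the rendered landmarks reproduce `target_ratio` exactly: a foot
#' point F is placed on the Ba-Ar chord, N = |PNS - F|, and
#' A' = F + target_ratio * N * n where n is the unit normal pointing to the
#' nasopharyngeal side. Rendering then draws the ridge, palate wedge and
#' adenoid bulge through those exact points.
#'
#' @param cfg A [synth_config()].
#' @param target_ratio True A/N ratio, strictly inside (0, 1).
#' @param id Sample identifier string.
#' @param seed Optional integer; when given, the RNG is seeded locally so the
#'   sample is reproducible in isolation.
#' @return A `ceph_sample`: image matrix in `[0,1]` (rows = y), exact
#'   ground-truth [landmark_set()], `true_ratio` and `true_label`.
#' @export
generate_case <- function(cfg, target_ratio, id = "case", seed = NULL) {
  if (!is.numeric(target_ratio) || target_ratio <= 0 || target_ratio >= 1) {
    rlang::abort("target_ratio must lie strictly inside (0, 1)",
                 class = "cephan_error_domain")
  }
  if (!is.null(seed)) set.seed(seed)
  S <- cfg$image_size
  s <- S / 256
  lo <- cfg$margin
  hi <- S - 1 - cfg$margin
  ok <- function(p) all(p >= lo & p <= hi)

  for (attempt in seq_len(100)) {
    ar <- c(95, 78) * s + stats::runif(2, -8, 8) * s
    ba <- c(138, 152) * s + stats::runif(2, -8, 8) * s
    pns <- c(175, 168) * s + stats::runif(2, -8, 8) * s
    t_foot <- stats::runif(1, 0.20, 0.45)
    foot <- ba + t_foot * (ar - ba)
    u <- (ar - ba) / sqrt(sum((ar - ba)^2))
    n_hat <- c(-u[2], u[1])
    if (sum((pns - foot) * n_hat) < 0) n_hat <- -n_hat  # point toward PNS side
    N <- sqrt(sum((pns - foot)^2))
    A <- target_ratio * N
    aprime <- foot + A * n_hat
    if (ok(ar) && ok(ba) && ok(pns) && ok(aprime)) {
      lm <- landmark_set(Ba = ba, Ar = ar, Aprime = aprime, PNS = pns)
      img <- render_ceph(cfg, lm, A)
      return(new_ceph_sample(id, img, lm, target_ratio,
                             classify_ah(target_ratio)))
    }
  }
  rlang::abort("could not place landmarks inside the margin after 100 attempts",
               class = "cephan_error_geometry_sampling")
}

render_ceph <- function(cfg, lm, A) {
  S <- cfg$image_size
  s <- S / 256
  xg <- matrix(rep(0:(S - 1), each = S), S, S)   # xg[y+1, x+1] = x
  yg <- matrix(rep(0:(S - 1), times = S), S, S)
  ba <- lm["Ba", ]; ar <- lm["Ar", ]; ap <- lm["Aprime", ]; pns <- lm["PNS", ]

  img <- 0.08 + 0.05 * yg / S  # faint vertical background gradient

  # clivus ridge: bright line whose endpoints are exactly Ba and Ar
  d <- grid_segment_dist(xg, yg, ba, ar)
  img <- img + 0.85 * exp(-d^2 / (2 * (2.5 * s)^2))

  # hard palate: wedge running anteriorly from PNS
  pal_dir <- c(1, 0.12)
  pal_dir <- pal_dir / sqrt(sum(pal_dir^2))
  tip <- pns + 55 * s * pal_dir
  d <- grid_segment_dist(xg, yg, pns, tip)
  img <- img + 0.70 * exp(-d^2 / (2 * (3.0 * s)^2))

  # adenoid bulge: soft half-disc whose boundary extremum along the normal
  # is exactly A'; radius tied to the adenoid depth A
  u <- (ar - ba) / sqrt(sum((ar - ba)^2))
  n_hat <- c(-u[2], u[1])
  if (sum((ap - ba) * n_hat) < 0) n_hat <- -n_hat
  r <- max(0.9 * A, 6 * s)
  centre <- ap - r * n_hat
  d <- sqrt((xg - centre[1])^2 + (yg - centre[2])^2)
  img <- img + 0.40 / (1 + exp((d - r) / (1.5 * s)))          # filled mass
  img <- img + 0.22 * exp(-(d - r)^2 / (2 * (1.5 * s)^2))     # convex rim

  img <- gauss_blur_cpp(img, cfg$blur_sigma)
  if (cfg$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(S * S, 0, cfg$noise_sd), S, S)
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic dataset
#'
#' Draws a severity class for each sample from the configured class mix,
#' draws its true A/N ratio uniformly within the class range, and renders the
#' sample with [generate_case()]. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param n Number of samples (>= 0).
#' @param dir Optional directory; when given, images are written as 8-bit
#'   grayscale PNGs and a `manifest.csv` is written alongside.
#' @param prefix Identifier prefix for sample ids.
#' @return A list of class `ceph_dataset` with elements `samples` (list of
#'   `ceph_sample`) and `manifest` (tibble with one row per sample).
#' @export
generate_dataset <- function(cfg, n, dir = NULL, prefix = "syn") {
  stopifnot(n >= 0)
  set.seed(cfg$seed)
  classes <- character(0)
  samples <- vector("list", n)
  if (n > 0) {
    classes <- sample(names(cfg$ratio_ranges), n, replace = TRUE,
                      prob = cfg$class_mix)
    for (i in seq_len(n)) {
      rng <- cfg$ratio_ranges[[classes[i]]]
      ratio <- stats::runif(1, rng[1], rng[2])
      samples[[i]] <- generate_case(cfg, ratio,
                                    id = sprintf("%s_%05d", prefix, i))
    }
  }
  manifest <- samples_to_manifest(samples)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(samples, function(sm) {
      p <- file.path(dir, paste0(sm$id, ".png"))
      png::writePNG(sm$image, p)
      p
    }, character(1))
    if (n > 0) manifest$path <- paths
    write_manifest(manifest, file.path(dir, "manifest.csv"))
  }
  structure(list(samples = samples, manifest = manifest),
            class = "ceph_dataset")
}

# Samples -> manifest tibble (one row per sample, wide landmark columns).
samples_to_manifest <- function(samples) {
  if (length(samples) == 0) {
    return(tibble::tibble(id = character(0), path = character(0),
                          Ba_x = double(0), Ba_y = double(0),
                          Ar_x = double(0), Ar_y = double(0),
                          Aprime_x = double(0), Aprime_y = double(0),
                          PNS_x = double(0), PNS_y = double(0),
                          true_ratio = double(0), true_label = character(0)))
  }
  purrr::map_dfr(samples, function(sm) {
    lm <- sm$landmarks
    tibble::tibble(id = sm$id, path = NA_character_,
                   Ba_x = lm["Ba", "x"], Ba_y = lm["Ba", "y"],
                   Ar_x = lm["Ar", "x"], Ar_y = lm["Ar", "y"],
                   Aprime_x = lm["Aprime", "x"], Aprime_y = lm["Aprime", "y"],
                   PNS_x = lm["PNS", "x"], PNS_y = lm["PNS", "y"],
                   true_ratio = sm$true_ratio, true_label = sm$true_label)
  })
}

#' @export
print.ceph_dataset <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("ceph_dataset: %d samples", n))
  if (n > 0) {
    cat(sprintf(", %d hypertrophic (%.1f%%)",
                sum(x$manifest$true_label == "hypertrophic"),
                100 * mean(x$manifest$true_label == "hypertrophic")))
  }
  cat("\n")
  invisible(x)
}
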