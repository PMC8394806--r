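#' Augmentation configuration
#'
#' The augmentation scheme mirrors a 17-fold expansion: each image yields the
#' original, eight translated copies (10 px up/down/left/right, 20 px along
#' each diagonal, at the 256 px reference scale) and `n_rotations` copies
#' rotated about the image centre. With the defaults one input image yields
#' 17 variants, so 581 inputs yield 9877 images.
#'
#' Rotation angles are evenly spaced over `[-rotation_limit, rotation_limit]`
#' excluding 0 when `n_rotations` is even (the default 8 gives +/-5, 10, 15,
#' 20 degrees).
#'
#' @param rotation_limit Maximum absolute rotation in degrees (default 20).
#' @param n_rotations Number of rotated variants per image (default 8).
#' @param axial_shift Shift in pixels along each axis direction (default 10).
#' @param diagonal_shift Per-axis shift for the four diagonal moves
#'   (default 20, i.e. displacement (+/-20, +/-20)).
#' @param include_original Keep the untransformed image (default TRUE).
#' @param seed Integer seed (kept for config provenance; the scheme itself is
#'   deterministic).
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(rotation_limit = 20, n_rotations = 8,
                           axial_shift = 10, diagonal_shift = 20,
                           include_original = TRUE, seed = 1L) {
  stopifnot(rotation_limit > 0, n_rotations >= 0, axial_shift >= 0,
            diagonal_shift >= 0)
  structure(list(rotation_limit = rotation_limit,
                 n_rotations = as.integer(n_rotations),
                 axial_shift = axial_shift, diagonal_shift = diagonal_shift,
                 include_original = isTRUE(include_original),
                 seed = as.integer(seed)),
            class = "augment_config")
}

rotation_angles <- function(cfg) {
  k <- cfg$n_rotations
  if (k == 0) return(numeric(0))
  if (k %% 2 == 0) {
    a <- seq(-1, 1, length.out = k + 1)
    a <- a[a != 0]
  } else {
    a <- seq(-1, 1, length.out = k)
  }
  cfg$rotation_limit * a
}

shift_offsets <- function(cfg) {
  a <- cfg$axial_shift
  d <- cfg$diagonal_shift
  list(c(a, 0), c(-a, 0), c(0, a), c(0, -a),
       c(d, d), c(d, -d), c(-d, d), c(-d, -d))
}

check_bounds <- function(lm, size) {
  all(lm >= 0 & lm <= size - 1)
}

transform_landmarks <- function(lm, A, b) {
  # p' = A p + b, applied to each row of the 4x2 matrix
  out <- t(A %*% t(unclass(lm)[, c("x", "y")]) + as.vector(b))
  landmark_set(out[1, ], out[2, ], out[3, ], out[4, ])
}

#' Resize a sample, rescaling its landmarks
#'
#' Bilinear image resampling; each landmark coordinate is multiplied by
#' `target / source`. Uniform scaling leaves the A/N ratio unchanged.
#'
#' @param s A `ceph_sample`.
#' @param target Target side length in pixels (>= 8).
#' @return The resized `ceph_sample`.
#' @export
resize_with_landmarks <- function(s, target) {
  H <- nrow(s$image); W <- ncol(s$image)
  if (H != W) {
    rlang::abort("only square images are supported",
                 class = "cephan_error_unsupported_shape")
  }
  stopifnot(target >= 8)
  if (target == H) return(s)
  sc <- H / target                      # source pixels per target pixel
  off <- 0.5 * sc - 0.5                 # half-pixel alignment
  img <- affine_warp_cpp(s$image, target, target, sc, 0, off, 0, sc, off, 0)
  s$image <- pmin(pmax(img, 0), 1)
  s$landmarks <- transform_landmarks(s$landmarks,
                                     diag(2) * (target / H), c(0, 0))
  s
}

#' Rotate a sample about the image centre
#'
#' The image is rotated with bilinear resampling and zero fill; the landmarks
#' are transformed with the exact continuous rotation matrix about the pixel
#' centre `((W-1)/2, (H-1)/2)`. Rotation is rigid, so the A/N ratio is
#' preserved.
#'
#' @param s A `ceph_sample`.
#' @param angle Rotation in degrees (counter-clockwise in the x-right /
#'   y-down pixel frame).
#' @return The rotated `ceph_sample`.
#' @export
rotate_sample <- function(s, angle) {
  H <- nrow(s$image); W <- ncol(s$image)
  c0 <- c((W - 1) / 2, (H - 1) / 2)
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  lm <- transform_landmarks(s$landmarks, R, c0 - R %*% c0)
  if (!check_bounds(lm, H)) {
    rlang::abort("rotation moved a landmark outside the image",
                 class = "cephan_error_roi_violation")
  }
  # image: inverse map output -> source
  Ri <- t(R)
  bi <- c0 - Ri %*% c0
  s$image <- affine_warp_cpp(s$image, H, W, Ri[1, 1], Ri[1, 2], bi[1],
                             Ri[2, 1], Ri[2, 2], bi[2], 0)
  s$landmarks <- lm
  s
}

#' Translate a sample
#'
#' Shifts image content and landmarks by `(dx, dy)` pixels; vacated pixels
#' are filled with 0. Translation is rigid, so the A/N ratio is preserved.
#'
#' @param s A `ceph_sample`.
#' @param dx,dy Shift in pixels (x rightward, y downward).
#' @return The translated `ceph_sample`.
#' @export
translate_sample <- function(s, dx, dy) {
  H <- nrow(s$image); W <- ncol(s$image)
  lm <- transform_landmarks(s$landmarks, diag(2), c(dx, dy))
  if (!check_bounds(lm, H)) {
    rlang::abort("translation moved a landmark outside the image",
                 class = "cephan_error_roi_violation")
  }
  s$image <- affine_warp_cpp(s$image, H, W, 1, 0, -dx, 0, 1, -dy, 0)
  s$landmarks <- lm
  s
}

# Deterministic magnitude-halving guard: shrink the transform until every
# landmark stays in bounds, so the augmentation count law is exact.
guarded <- function(s, apply_fn, max_halvings = 10) {
  f <- 1
  for (i in seq_len(max_halvings + 1)) {
    out <- tryCatch(apply_fn(s, f), cephan_error_roi_violation = function(e) NULL)
    if (!is.null(out)) return(out)
    f <- f / 2
  }
  rlang::abort("transform still violates the ROI after 10 magnitude halvings",
               class = "cephan_error_roi_violation")
}

#' Augment a list of samples
#'
#' Emits, per input sample: the original (if configured), the eight
#' translated copies and `n_rotations` rotated copies. Any variant that would
#' push a landmark out of the image has its magnitude halved (deterministically,
#' at most 10 times) until valid, so the output size is always
#' `n * (include_original + 8 + n_rotations)`.
#'
#' @param samples List of `ceph_sample` objects (or a `ceph_dataset`).
#' @param cfg An [augment_config()].
#' @return List of augmented `ceph_sample` objects.
#' @export
augment_dataset <- function(samples, cfg = augment_config()) {
  if (inherits(samples, "ceph_dataset")) samples <- samples$samples
  angles <- rotation_angles(cfg)
  shifts <- shift_offsets(cfg)
  out <- vector("list", length(samples) *
                  (cfg$include_original + length(shifts) + length(angles)))
  j <- 0
  for (s in samples) {
    if (cfg$include_original) {
      j <- j + 1
      v <- s; v$id <- paste0(s$id, "_orig")
      out[[j]] <- v
    }
    for (sh in shifts) {
      j <- j + 1
      v <- guarded(s, function(x, f) translate_sample(x, f * sh[1], f * sh[2]))
      v$id <- sprintf("%s_t%+g%+g", s$id, sh[1], sh[2])
      out[[j]] <- v
    }
    for (a in angles) {
      j <- j + 1
      v <- guarded(s, function(x, f) rotate_sample(x, f * a))
      v$id <- sprintf("%s_r%+g", s$id, a)
      out[[j]] <- v
    }
  }
  out
}

manifest_cols <- function() {
  c("id", "path", "Ba_x", "Ba_y", "Ar_x", "Ar_y",
    "Aprime_x", "Aprime_y", "PNS_x", "PNS_y", "true_ratio", "true_label")
}

#' Write / read a dataset manifest
#'
#' The manifest is a CSV with columns
#' `id,path,Ba_x,Ba_y,Ar_x,Ar_y,Aprime_x,Aprime_y,PNS_x,PNS_y,true_ratio,true_label`;
#' coordinates are written with 6 decimal places (0-based pixels).
#'
#' @param manifest A manifest tibble (see [generate_dataset()]).
#' @param path File path.
#' @return `read_manifest()` returns the manifest tibble;
#'   `write_manifest()` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  m <- manifest[, manifest_cols()]
  num <- setdiff(manifest_cols(), c("id", "path", "true_label"))
  m[num] <- lapply(m[num], function(v) round(v, 6))
  readr::write_csv(m, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("manifest not found: ", path),
                 class = "cephan_error_io")
  }
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         id = "c", path = "c", true_label = "c",
                         .default = "d"))
  missing <- setdiff(manifest_cols(), names(m))
  if (length(missing) > 0) {
    rlang::abort(paste0("manifest is missing columns: ",
                        paste(missing, collapse = ", ")),
                 class = "cephan_error_parse")
  }
  num <- setdiff(manifest_cols(), c("id", "path", "true_label"))
  for (col in num) {
    bad <- which(!is.finite(m[[col]]))
    if (length(bad) > 0) {
      rlang::abort(sprintf("manifest line %d: column '%s' is missing or not numeric",
                           bad[1] + 1L, col),
                   class = "cephan_error_parse")
    }
  }
  m
}

#' Load a dataset (images + landmarks) from a manifest
#'
#' @param manifest A manifest tibble or a path to a manifest CSV.
#' @return A `ceph_dataset` with images read from the manifest's `path`
#'   column.
#' @export
load_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  samples <- purrr::pmap(manifest, function(id, path, Ba_x, Ba_y, Ar_x, Ar_y,
                                            Aprime_x, Aprime_y, PNS_x, PNS_y,
                                            true_ratio, true_label, ...) {
    if (is.na(path) || !file.exists(path)) {
      rlang::abort(paste0("image file not found: ", path),
                   class = "cephan_error_io")
    }
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    new_ceph_sample(id, img,
                    landmark_set(c(Ba_x, Ba_y), c(Ar_x, Ar_y),
                                 c(Aprime_x, Aprime_y), c(PNS_x, PNS_y)),
                    true_ratio, true_label)
  })
  structure(list(samples = samples, manifest = manifest),
            class = "ceph_dataset")
}

#' Split samples into train / validation / test sets
#'
#' Uniform random permutation under a fixed seed; sizes default to the
#' 581/160/160 proportions scaled to the input size.
#'
#' @param samples List of `ceph_sample` objects (or a `ceph_dataset`).
#' @param sizes Integer vector `c(train, validation, test)`; must sum to at
#'   most `length(samples)`. Default: proportional to 581/160/160.
#' @param seed Integer seed for the permutation.
#' @return A list of class `dataset_split` with elements `train`,
#'   `validation`, `test`.
#' @export
split_dataset <- function(samples, sizes = NULL, seed = 1L) {
  if (inherits(samples, "ceph_dataset")) samples <- samples$samples
  n <- length(samples)
  if (is.null(sizes)) {
    p <- c(581, 160, 160) / 901
    sizes <- c(floor(p[1] * n), floor(p[2] * n), 0)
    sizes[3] <- n - sizes[1] - sizes[2]
  }
  stopifnot(sum(sizes) <= n, all(sizes >= 0))
  set.seed(seed)
  perm <- sample.int(n)
  idx <- split(perm[seq_len(sum(sizes))],
               rep(c("train", "validation", "test"), times = sizes))
  structure(list(train = samples[idx$train %||% integer(0)],
                 validation = samples[idx$validation %||% integer(0)],
                 test = samples[idx$test %||% integer(0)]),
            class = "dataset_split")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
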