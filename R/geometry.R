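#' Construct a landmark set
#'
#' Bundles the four cephalometric keypoints used for the Fujioka
#' adenoid-nasopharyngeal (A/N) ratio: basion (`Ba`), articulare (`Ar`), the
#' point of maximal convexity of the adenoid shadow (`Aprime`) and the
#' posterior nasal spine (`PNS`). Coordinates are continuous pixels, 0-based,
#' origin at the top-left corner, x rightward and y downward; integer
#' coordinates address pixel centres.
#'
#' @param Ba,Ar,Aprime,PNS Numeric length-2 vectors `c(x, y)`.
#' @return A `landmark_set`: a 4 x 2 numeric matrix with rows
#'   `Ba`, `Ar`, `Aprime`, `PNS` and columns `x`, `y`.
#' @examples
#' lm <- landmark_set(Ba = c(100, 200), Ar = c(100, 100),
#'                    Aprime = c(130, 150), PNS = c(140, 190))
#' compute_an(lm)$ratio
#' @export
landmark_set <- function(Ba, Ar, Aprime, PNS) {
  m <- rbind(Ba = as.numeric(Ba), Ar = as.numeric(Ar),
             Aprime = as.numeric(Aprime), PNS = as.numeric(PNS))
  colnames(m) <- c("x", "y")
  if (!all(is.finite(m))) {
    rlang::abort("landmark coordinates must be finite",
                 class = "cephan_error_invalid_geometry")
  }
  if (all(m["Ba", ] == m["Ar", ])) {
    rlang::abort("Ba and Ar coincide: the clivus line is undefined",
                 class = "cephan_error_invalid_geometry")
  }
  class(m) <- c("landmark_set", class(m))
  m
}

keypoint_names <- function() c("Ba", "Ar", "Aprime", "PNS")

as_landmark_set <- function(m) {
  m <- as.matrix(m)[keypoint_names(), c("x", "y"), drop = FALSE]
  landmark_set(m["Ba", ], m["Ar", ], m["Aprime", ], m["PNS", ])
}

check_line <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b)) || all(a == b)) {
    rlang::abort("degenerate line: the two defining points must be distinct and finite",
                 class = "cephan_error_invalid_geometry")
  }
  invisible(NULL)
}

#' Perpendicular distance from a point to an infinite line
#'
#' @param p Numeric `c(x, y)` point.
#' @param a,b Two distinct points defining the line.
#' @return Non-negative distance in pixels.
#' @export
point_line_distance <- function(p, a, b) {
  check_line(a, b)
  u <- b - a
  v <- p - a
  unname(abs(u[1] * v[2] - u[2] * v[1]) / sqrt(sum(u^2)))
}

#' Perpendicular foot of a point on an infinite line
#'
#' Orthogonal projection of `p` onto the line through `a` and `b`.
#'
#' @inheritParams point_line_distance
#' @return The foot point `c(x, y)`.
#' @export
perpendicular_foot <- function(p, a, b) {
  check_line(a, b)
  u <- b - a
  t <- sum((p - a) * u) / sum(u^2)
  unname(a + t * u)
}

#' Fujioka A/N ratio from four landmarks
#'
#' `A` is the adenoid depth: the perpendicular distance from A' to the
#' clivus chord through Ba and Ar (the chord replaces the tangent to the
#' occipital slope). `N` is the nasopharyngeal span: the distance from PNS to
#' the perpendicular foot of A' on that chord. The ratio A/N is
#' scale-, rotation- and translation-invariant; a ratio strictly greater than
#' `threshold` flags adenoid hypertrophy.
#'
#' @param lm A [landmark_set()].
#' @param threshold Classification threshold on the ratio (default 0.6).
#' @return A list of class `an_measurement` with elements `A`, `N`, `ratio`,
#'   `label` (`"normal"` or `"hypertrophic"`) and `foot` (the projection of
#'   A' on the Ba-Ar line).
#' @export
compute_an <- function(lm, threshold = 0.6) {
  lm <- as_landmark_set(lm)
  ba <- lm["Ba", ]; ar <- lm["Ar", ]; ap <- lm["Aprime", ]; pns <- lm["PNS", ]
  A <- unname(point_line_distance(ap, ba, ar))
  foot <- perpendicular_foot(ap, ba, ar)
  N <- unname(sqrt(sum((pns - foot)^2)))
  if (N == 0) {
    rlang::abort("PNS coincides with the projection of A': N = 0, ratio undefined",
                 class = "cephan_error_undefined_ratio")
  }
  ratio <- A / N
  structure(
    list(A = unname(A), N = unname(N), ratio = unname(ratio),
         label = classify_ah(ratio, threshold), foot = foot),
    class = "an_measurement"
  )
}

#' Classify adenoid hypertrophy from an A/N ratio
#'
#' Strict threshold rule: hypertrophic iff `ratio > threshold`.
#'
#' @param ratio Numeric vector of A/N ratios (each >= 0).
#' @param threshold Decision threshold, default 0.6.
#' @return Character vector, `"normal"` or `"hypertrophic"`.
#' @export
classify_ah <- function(ratio, threshold = 0.6) {
  if (any(!is.finite(ratio)) || any(ratio < 0)) {
    rlang::abort("A/N ratio must be finite and non-negative",
                 class = "cephan_error_domain")
  }
  ifelse(ratio > threshold, "hypertrophic", "normal")
}

#' Add A/N measurements to a landmark table
#'
#' Tidy wrapper over [compute_an()]: takes a data frame with landmark columns
#' `Ba_x, Ba_y, Ar_x, Ar_y, Aprime_x, Aprime_y, PNS_x, PNS_y` (the manifest
#' layout) and appends `A`, `N`, `ratio` and `label` columns.
#'
#' @param df Data frame / tibble with the eight landmark columns.
#' @param threshold Decision threshold, default 0.6.
#' @return The input as a tibble with measurement columns appended.
#' @export
an_ratio <- function(df, threshold = 0.6) {
  df <- tibble::as_tibble(df)
  meas <- purrr::pmap(df, function(Ba_x, Ba_y, Ar_x, Ar_y, Aprime_x, Aprime_y,
                                   PNS_x, PNS_y, ...) {
    m <- compute_an(landmark_set(c(Ba_x, Ba_y), c(Ar_x, Ar_y),
                                 c(Aprime_x, Aprime_y), c(PNS_x, PNS_y)),
                    threshold = threshold)
    tibble::tibble(A = m$A, N = m$N, ratio = m$ratio, label = m$label)
  })
  dplyr::bind_cols(df, dplyr::bind_rows(meas))
}

#' @export
print.an_measurement <- function(x, ...) {
  cat(sprintf("A/N measurement: A = %.3f px, N = %.3f px, ratio = %.4f (%s)\n",
              x$A, x$N, x$ratio, x$label))
  invisible(x)
}

# Matrix of landmark coordinates -> landmark_set, tolerating plain matrices.
lm_from_matrix <- function(m) {
  landmark_set(m[1, ], m[2, ], m[3, ], m[4, ])
}
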