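#' Ellipse constructor
#'
#' @param centre Length-2 centre (ms).
#' @param semi_axes Length-2 positive semi-axes (ms).
#' @param rotation Rotation in degrees, counter-clockwise from +x, in
#'   `[0, 180)`.
#' @return List of class `"ellipse"`.
#' @export
ellipse <- function(centre, semi_axes, rotation = 0) {
  stopifnot(length(centre) == 2, length(semi_axes) == 2,
            all(semi_axes > 0))
  rotation <- rotation %% 180
  structure(list(centre = as.numeric(centre),
                 semi_axes = as.numeric(semi_axes),
                 rotation = rotation), class = "ellipse")
}

#' Test whether points lie inside (or on) an ellipse
#'
#' @param points n x 2 matrix.
#' @param ell An [ellipse()].
#' @param tol Numerical tolerance on the boundary (default 1e-9).
#' @return Logical vector.
#' @export
in_ellipse <- function(points, ell, tol = 1e-9) {
  points <- as.matrix(points)
  th <- -ell$rotation * pi / 180
  dx <- points[, 1] - ell$centre[1]
  dy <- points[, 2] - ell$centre[2]
  u <- dx * cos(th) - dy * sin(th)
  v <- dx * sin(th) + dy * cos(th)
  (u / ell$semi_axes[1])^2 + (v / ell$semi_axes[2])^2 <= 1 + tol
}

# k evenly spaced boundary points of an ellipse.
ellipse_boundary <- function(ell, k = 720) {
  t <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  th <- ell$rotation * pi / 180
  u <- ell$semi_axes[1] * cos(t)
  v <- ell$semi_axes[2] * sin(t)
  cbind(ell$centre[1] + u * cos(th) - v * sin(th),
        ell$centre[2] + u * sin(th) + v * cos(th))
}

# Geometric relation of two ellipses, decided from 720 boundary points of
# each plus centre containment: "disjoint", "crossing" (partial overlap),
# "a_in_b", or "b_in_a".
ellipse_relation <- function(a, b, k = 720) {
  ba <- ellipse_boundary(a, k)
  bb <- ellipse_boundary(b, k)
  a_in <- in_ellipse(ba, b)
  b_in <- in_ellipse(bb, a)
  ca_in <- in_ellipse(matrix(a$centre, 1), b)
  cb_in <- in_ellipse(matrix(b$centre, 1), a)
  if (all(a_in)) return("a_in_b")
  if (all(b_in)) return("b_in_a")
  if (any(a_in) || any(b_in) || ca_in || cb_in) return("crossing")
  "disjoint"
}

# Ellipse from first/second moments: axes along the principal directions,
# semi-axes scale * sqrt(eigenvalues).
ellipse_from_moments <- function(centre, covariance, scale = 4) {
  eg <- eigen(covariance, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  if (vals[1] <= 0) stop("degenerate covariance")
  vals[2] <- max(vals[2], 1e-12)
  v1 <- eg$vectors[, 1]
  rot <- (atan2(v1[2], v1[1]) * 180 / pi) %% 180
  ellipse(centre, scale * sqrt(vals), rot)
}
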