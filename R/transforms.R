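#' Affine and rigid spatial transforms
#'
#' A transform maps points as `y = A x + t` (world mm). Rigid transforms
#' (`A` orthonormal) come out of [rigid_align()]; scaling transforms out of
#' [make_scaling_transform()]. In the registration pipeline a transform maps
#' *fixed-space* points into *moving-space* points, matching the resampling
#' direction `moving_resampled(x) = moving(A x + t)`.
#'
#' @param A 3x3 matrix.
#' @param t length-3 translation (mm).
#' @param kind label, e.g. "rigid" or "affine".
#' @return an object of class `spatial_transform`.
#' @export
spatial_transform <- function(A = diag(3), t = c(0, 0, 0), kind = "affine") {
  A <- matrix(as.numeric(A), 3, 3)
  t <- rep_len(as.numeric(t), 3)
  if (any(!is.finite(A)) || any(!is.finite(t)))
    stop("transform must be finite")
  structure(list(A = A, t = t, kind = kind), class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf("<spatial_transform> (%s)\n", x$kind))
  m <- cbind(x$A, x$t)
  dimnames(m) <- list(c("x", "y", "z"), c("Ax", "Ay", "Az", "t"))
  print(round(m, 6))
  invisible(x)
}

#' Apply a transform to points
#'
#' @param tf a [spatial_transform()].
#' @param points `n x 3` matrix (mm).
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(tf, points) {
  points <- as_points(points)
  sweep(points %*% t(tf$A), 2, tf$t, "+")
}

#' Invert / compose transforms
#'
#' `compose_transforms(f, g)` returns the transform `x -> f(g(x))`.
#'
#' @param tf,f,g [spatial_transform()] objects.
#' @return a [spatial_transform()].
#' @export
invert_transform <- function(tf) {
  Ai <- solve(tf$A)
  spatial_transform(Ai, -Ai %*% tf$t, kind = tf$kind)
}

#' @rdname invert_transform
#' @export
compose_transforms <- function(f, g) {
  spatial_transform(f$A %*% g$A, f$A %*% g$t + f$t,
                    kind = if (identical(f$kind, g$kind)) f$kind else "affine")
}

is_identity_transform <- function(tf, tol = 1e-12) {
  all(abs(tf$A - diag(3)) < tol) && all(abs(tf$t) < tol)
}

#' Anisotropic scaling about a center
#'
#' Builds the global pre-scaling used by the Type II pipeline, e.g. elongating
#' a 160-unit-tall subject image by `178/160` along z before registration
#' against a 178-unit-tall baseline.
#'
#' @param factors length-3 positive scale factors (x, y, z).
#' @param center world point (mm) the scaling leaves fixed.
#' @return a [spatial_transform()] mapping `x -> center + factors * (x - center)`.
#' @export
make_scaling_transform <- function(factors, center = c(0, 0, 0)) {
  factors <- rep_len(as.numeric(factors), 3)
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("scale factors must be positive")
  center <- rep_len(as.numeric(center), 3)
  A <- diag(factors)
  spatial_transform(A, center - A %*% center, kind = "scaling")
}

#' Resample an image through a transform onto a target grid
#'
#' `out(x) = img(tf(x))` at every voxel center `x` of `grid`. Labels use
#' nearest-neighbour interpolation and are never blended.
#'
#' @param img a [label_image()].
#' @param tf a [spatial_transform()] mapping output-grid world points into
#'   input-image world points.
#' @param grid a [label_image()] supplying the target grid (its values are
#'   ignored).
#' @param interpolation `"nearest"` or `"linear"`.
#' @return a [label_image()] on `grid`'s lattice.
#' @export
resample_image <- function(img, tf, grid, interpolation = c("nearest",
                                                            "linear")) {
  interpolation <- match.arg(interpolation)
  d_in <- grid_dims(img)
  d_out <- grid_dims(grid)
  vals <- cpp_resample_affine(as.numeric(img$data), as.integer(d_in),
                              img$spacing, img$origin, tf$A, as.numeric(tf$t),
                              as.integer(d_out), grid$spacing, grid$origin,
                              if (interpolation == "nearest") 0L else 1L, 0)
  out <- array(vals, dim = d_out)
  if (interpolation == "nearest" && is.integer(img$data))
    storage.mode(out) <- "integer"
  label_image(out, spacing = grid$spacing, origin = grid$origin,
              strict = FALSE)
}
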