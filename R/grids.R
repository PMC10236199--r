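#' Three-label voxel image
#'
#' A 3D voxel lattice in world millimetres. `data` is an `(nx, ny, nz)` array;
#' `spacing` the voxel edge lengths (mm per voxel along x, y, z) and `origin`
#' the world coordinate of the *center* of voxel `[1, 1, 1]`. Label images
#' carry values 0 (background), 1 (flesh) and 2 (skeleton); grayscale content
#' is accepted when `strict = FALSE` (the registration does not require
#' labels).
#'
#' @param data numeric or integer 3D array.
#' @param spacing numeric length-3 (or scalar, recycled), mm per voxel, > 0.
#' @param origin numeric length-3, world mm of the first voxel center.
#' @param strict if `TRUE`, require all values to lie in `{0, 1, 2}`.
#' @return an object of class `label_image`.
#' @export
label_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        strict = TRUE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive and finite")
  if (any(!is.finite(origin)))
    stop("`origin` must be finite")
  if (strict) {
    vals <- unique(as.vector(data))
    if (!all(vals %in% c(0, 1, 2)))
      stop("label image values must be 0 (background), 1 (flesh) or 2 (skeleton); ",
           "use strict = FALSE for grayscale content")
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "label_image")
}

#' Dense displacement field
#'
#' Per-voxel 3-vectors (mm, world units) on the voxel-center grid of its fixed
#' image: the field value at fixed-space point `x` is the displacement to the
#' corresponding moving-space point `x + u(x)`. Stored as an
#' `(nx, ny, nz, 3)` array with the same `spacing`/`origin` metadata as a
#' [label_image()].
#'
#' @param data numeric 4D array, last dimension 3.
#' @inheritParams label_image
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(data, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 4L || dim(data)[4] != 3L)
    stop("`data` must be an (nx, ny, nz, 3) array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive and finite")
  if (any(!is.finite(data)))
    stop("displacement field must be finite everywhere")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "displacement_field")
}

grid_dims <- function(x) dim(x$data)[1:3]

#' Do two images/fields share the same voxel grid?
#'
#' @param a,b `label_image` or `displacement_field` objects.
#' @param tol relative tolerance on spacing and origin.
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  ref <- max(abs(c(a$spacing, a$origin, 1)))
  identical(grid_dims(a), grid_dims(b)) &&
    all(abs(a$spacing - b$spacing) <= tol * ref) &&
    all(abs(a$origin - b$origin) <= tol * ref)
}

stop_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch: %s must share dims, spacing and origin", what))
  invisible(TRUE)
}

#' World coordinates of all voxel centers
#'
#' @param img a `label_image` or `displacement_field`.
#' @return an `n x 3` matrix in grid-linear (column-major) order.
#' @export
voxel_centers <- function(img) {
  d <- grid_dims(img)
  i <- (seq_len(d[1]) - 1) * img$spacing[1] + img$origin[1]
  j <- (seq_len(d[2]) - 1) * img$spacing[2] + img$origin[2]
  k <- (seq_len(d[3]) - 1) * img$spacing[3] + img$origin[3]
  cbind(rep(i, times = d[2] * d[3]),
        rep(rep(j, each = d[1]), times = d[3]),
        rep(k, each = d[1] * d[2]))
}

#' Convert world coordinates to (fractional, 1-based) voxel indices
#'
#' @param img a `label_image` or `displacement_field`.
#' @param points `n x 3` matrix of world coordinates (mm).
#' @return `n x 3` matrix of fractional indices.
#' @export
world_to_index <- function(img, points) {
  points <- as_points(points)
  sweep(sweep(points, 2, img$origin, "-"), 2, img$spacing, "/") + 1
}

#' @rdname world_to_index
#' @param index `n x 3` matrix of (fractional) 1-based indices.
#' @export
index_to_world <- function(img, index) {
  index <- as_points(index)
  sweep(sweep(index - 1, 2, img$spacing, "*"), 2, img$origin, "+")
}

as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 3) stop("points must be n x 3")
  p
}

#' @export
print.label_image <- function(x, ...) {
  d <- grid_dims(x)
  cat(sprintf("<label_image> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm\n", x$origin[1], x$origin[2],
              x$origin[3]))
  tb <- table(factor(as.vector(x$data), levels = c(0, 1, 2)))
  cat(sprintf("  labels: background %d, flesh %d, skeleton %d\n",
              tb[["0"]], tb[["1"]], tb[["2"]]))
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- grid_dims(x)
  mags <- sqrt(x$data[, , , 1]^2 + x$data[, , , 2]^2 + x$data[, , , 3]^2)
  cat(sprintf("<displacement_field> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  |u|: mean %.3f mm, max %.3f mm\n", mean(mags), max(mags)))
  invisible(x)
}

field_magnitude <- function(u) {
  sqrt(u$data[, , , 1]^2 + u$data[, , , 2]^2 + u$data[, , , 3]^2)
}
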