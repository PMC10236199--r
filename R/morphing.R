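#' Sample a displacement field at arbitrary world points
#'
#' Trilinear interpolation of each vector component at each point. Points
#' outside the field grid follow `outside_policy`: `"nearest"` clamps to the
#' border value (the default -- fingertips and other extremities that poke
#' out of the grid get the nearest boundary displacement), `"zero"` returns
#' a null vector, `"error"` aborts listing offending points.
#'
#' @param u a [displacement_field()].
#' @param points `n x 3` matrix of world coordinates (mm).
#' @param outside_policy `"nearest"`, `"zero"` or `"error"`.
#' @return `n x 3` matrix of displacement vectors (mm) with attribute
#'   `outside_count`.
#' @export
sample_field <- function(u, points, outside_policy = c("nearest", "zero",
                                                       "error")) {
  outside_policy <- match.arg(outside_policy)
  points <- as_points(points)
  if (any(!is.finite(points))) stop("points must be finite")
  pol <- match(outside_policy, c("nearest", "zero", "error")) - 1L
  cpp_sample_field(as.numeric(u$data), as.integer(grid_dims(u)), u$spacing,
                   u$origin, points, pol)
}

#' Morph a finite-element mesh through a displacement field
#'
#' Moves every node from `X_i` to `x_i = X_i + u(X_i)` with `u` linearly
#' interpolated from the field; element definitions, IDs, part IDs and
#' contact declarations are untouched. When the baseline mesh had to be
#' rigidly carried into the fixed-image space first, pass that motion as
#' `pre_transform`; a `post_transform` (e.g. the inverse of a Type II global
#' scaling composed with the rigid alignment) is applied after the
#' displacement.
#'
#' @param mesh an [fe_mesh()].
#' @param u a [displacement_field()] on the fixed-image grid.
#' @param pre_transform optional [spatial_transform()] applied to nodes
#'   before sampling.
#' @param post_transform optional [spatial_transform()] applied to the
#'   displaced nodes.
#' @param outside_policy passed to [sample_field()]; if more than 1% of the
#'   nodes fall outside the grid a warning is raised.
#' @return the morphed [fe_mesh()] with attribute `outside_count`.
#' @export
morph_mesh <- function(mesh, u, pre_transform = NULL, post_transform = NULL,
                       outside_policy = "nearest") {
  X <- mesh$nodes
  if (!is.null(pre_transform)) X <- apply_transform(pre_transform, X)
  ui <- sample_field(u, X, outside_policy = outside_policy)
  n_out <- attr(ui, "outside_count")
  if (n_out > 0.01 * nrow(X))
    warning(sprintf("%d of %d nodes (%.1f%%) outside the field grid",
                    n_out, nrow(X), 100 * n_out / nrow(X)))
  x <- X + ui
  if (!is.null(post_transform)) x <- apply_transform(post_transform, x)
  if (any(!is.finite(x))) stop("morph produced non-finite node coordinates")
  out <- mesh
  out$nodes <- x
  attr(out, "outside_count") <- n_out
  out
}

#' Shield regions: substitute baseline surfaces into the subject
#'
#' The Type III pipeline prevents selected regions (typically the head) from
#' being morphed by replacing the subject's surfaces for those regions with
#' the baseline's, so the two images are locally identical and the
#' registration produces (near-)zero displacement there. Baseline surfaces
#' must already be rigidly aligned to subject space.
#'
#' @param subject_surfaces,baseline_surfaces named lists of [surface_mesh()]
#'   objects; names (or region tags) identify regions.
#' @param regions character vector of region tags to shield; each must exist
#'   in both sets.
#' @return the subject surface set with the listed regions replaced.
#' @export
shield_regions <- function(subject_surfaces, baseline_surfaces, regions) {
  if (length(regions) == 0) return(subject_surfaces)
  s_tags <- vapply(subject_surfaces, function(s) s$region_tag, character(1))
  b_tags <- vapply(baseline_surfaces, function(s) s$region_tag, character(1))
  for (r in regions) {
    si <- which(s_tags == r)
    bi <- which(b_tags == r)
    if (length(si) != 1 || length(bi) != 1)
      stop("region tag '", r, "' must exist exactly once in both surface sets")
    subject_surfaces[[si]] <- baseline_surfaces[[bi]]
  }
  subject_surfaces
}
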