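#' Build an empty voxel grid covering a set of surfaces
#'
#' The grid covers the union bounding box of all surfaces, expanded by
#' `padding` on every side, with `ceil(extent / voxel_size)` voxels per axis.
#' Voxel centers start half a voxel inside the padded box.
#'
#' @param surfaces a [surface_mesh()] or list of them.
#' @param voxel_size voxel edge length (mm), > 0.
#' @param padding extra margin (mm) added on all sides.
#' @return an all-zero [label_image()].
#' @export
compute_grid <- function(surfaces, voxel_size, padding = 0) {
  if (inherits(surfaces, "surface_mesh")) surfaces <- list(surfaces)
  if (length(surfaces) == 0) stop("at least one surface is required")
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be > 0")
  bbs <- lapply(surfaces, surface_bbox)  # each 2 x 3 (min row, max row)
  lo <- do.call(pmin, lapply(bbs, function(b) b[1, ])) - padding
  hi <- do.call(pmax, lapply(bbs, function(b) b[2, ])) + padding
  extent <- hi - lo
  dims <- pmax(1L, as.integer(ceiling(extent / voxel_size - 1e-9)))
  origin <- lo + voxel_size / 2
  label_image(array(0L, dim = dims), spacing = rep(voxel_size, 3),
              origin = origin)
}

#' Voxelize a closed surface into a binary mask
#'
#' Marks voxels whose *centers* lie strictly inside the surface (no
#' partial-volume weighting): the inside test is parity of ray crossings
#' along x with a deterministic sub-voxel tie-break. For surfaces that fail
#' the watertight edge check the test falls back to the generalized
#' winding-number sign, with a warning.
#'
#' @param surface a [surface_mesh()].
#' @param grid a [label_image()] defining the output lattice (values ignored).
#' @return a [label_image()] of 0/1 on `grid`'s lattice.
#' @export
voxelize_binary <- function(surface, grid) {
  if (nrow(surface$triangles) == 0) stop("surface has no triangles")
  d <- grid_dims(grid)
  bb <- surface_bbox(surface)
  g_lo <- grid$origin - grid$spacing / 2
  g_hi <- grid$origin + (d - 1) * grid$spacing + grid$spacing / 2
  if (any(bb[1, ] < g_lo - 1e-9) || any(bb[2, ] > g_hi + 1e-9))
    stop("grid does not cover the surface (extend the grid or padding)")
  if (isTRUE(surface$watertight)) {
    vals <- cpp_voxelize_parity(surface$vertices, surface$triangles,
                                as.integer(d), grid$spacing, grid$origin)
  } else {
    warning("surface '", surface$region_tag,
            "' is not watertight; using winding-number inside test")
    vals <- cpp_voxelize_winding(surface$vertices, surface$triangles,
                                 as.integer(d), grid$spacing, grid$origin)
  }
  label_image(array(vals, dim = d), spacing = grid$spacing,
              origin = grid$origin)
}

#' Compose flesh and skeleton masks into a three-label image
#'
#' Value 2 where the skeleton mask is set (skeleton wins over flesh), 1 where
#' only flesh, 0 elsewhere. The skin-only pipeline variant passes
#' `skeleton_mask = NULL`.
#'
#' @param flesh_mask binary [label_image()].
#' @param skeleton_mask binary [label_image()] on the same grid, or `NULL`
#'   for a body-shape-only image.
#' @return a [label_image()] with values in `{0, 1, 2}`.
#' @export
compose_labels <- function(flesh_mask, skeleton_mask = NULL) {
  out <- array(as.integer(flesh_mask$data != 0), dim = grid_dims(flesh_mask))
  if (!is.null(skeleton_mask)) {
    stop_grid_mismatch(flesh_mask, skeleton_mask, "flesh and skeleton masks")
    out[skeleton_mask$data != 0] <- 2L
  }
  label_image(out, spacing = flesh_mask$spacing, origin = flesh_mask$origin)
}

# Union of several binary masks on a shared grid.
union_masks <- function(masks) {
  out <- masks[[1]]
  if (length(masks) > 1) {
    for (m in masks[-1]) {
      stop_grid_mismatch(out, m, "masks")
      out$data <- array(as.integer(out$data != 0 | m$data != 0),
                        dim = grid_dims(out))
    }
  }
  out
}

#' Voxelize a set of tagged surfaces into a three-label image
#'
#' Convenience wrapper: voxelizes each surface, unions the flesh-tagged and
#' skeleton-tagged masks and composes them with skeleton precedence.
#'
#' @param surfaces named list of [surface_mesh()] objects.
#' @param grid target [label_image()] lattice (see [compute_grid()]).
#' @param skeleton_tags region tags treated as skeleton (label 2); all other
#'   surfaces are flesh (label 1).
#' @param skin_only drop the skeleton entirely (body shape only).
#' @return a [label_image()].
#' @export
voxelize_surfaces <- function(surfaces, grid,
                              skeleton_tags = c("skeleton", "skull"),
                              skin_only = FALSE) {
  tags <- vapply(surfaces, function(s) s$region_tag, character(1))
  is_skel <- tags %in% skeleton_tags
  flesh <- union_masks(lapply(surfaces[!is_skel], voxelize_binary, grid = grid))
  skel <- if (skin_only || !any(is_skel)) NULL else
    union_masks(lapply(surfaces[is_skel], voxelize_binary, grid = grid))
  compose_labels(flesh, skel)
}
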