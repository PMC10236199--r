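#' Warp an image through a displacement field
#'
#' `out(x) = img(x + u_inv(x))` with nearest-neighbour interpolation by
#' default, so labels are never blended. Warping the baseline image through
#' the *inverse* of the registration field produces the image of the
#' personalized model, which is then compared against the subject image.
#'
#' @param img a [label_image()].
#' @param u_inv a [displacement_field()] on `img`'s grid.
#' @param interpolation `"nearest"` (labels) or `"linear"`.
#' @return a [label_image()] on the same grid.
#' @export
warp_image <- function(img, u_inv, interpolation = c("nearest", "linear")) {
  interpolation <- match.arg(interpolation)
  stop_grid_mismatch(img, u_inv, "image and field")
  d <- grid_dims(img)
  vals <- cpp_warp_scalar(as.numeric(img$data), as.integer(d), img$spacing,
                          as.numeric(u_inv$data),
                          if (interpolation == "nearest") 0L else 1L, 0)
  out <- array(vals, dim = d)
  if (interpolation == "nearest") storage.mode(out) <- "integer"
  label_image(out, spacing = img$spacing, origin = img$origin, strict = FALSE)
}

label_mask <- function(img, labels) {
  if (identical(labels, "flesh")) {
    # flesh = total area minus the skeleton part
    img$data %in% c(1, 2) & !(img$data == 2)
  } else if (identical(labels, "body")) {
    img$data %in% c(1, 2)
  } else if (identical(labels, "skeleton")) {
    img$data == 2
  } else {
    img$data %in% labels
  }
}

#' DICE overlap between two label images
#'
#' `2 |A n B| / (|A| + |B|)` over the voxel sets carrying the chosen labels:
#' 1 is perfect overlap, 0 no overlap. `labels = "flesh"` selects the body
#' minus the skeleton in each image independently, `"body"` labels `{1, 2}`,
#' `"skeleton"` label 2 (reported for completeness but not a personalization
#' accuracy measure when baseline and subject skeletons differ in topology);
#' a numeric vector selects those labels directly.
#'
#' @param a,b [label_image()] objects on the same grid.
#' @param labels `"flesh"`, `"body"`, `"skeleton"` or numeric label values.
#' @return DICE coefficient in `[0, 1]`.
#' @export
dice <- function(a, b, labels = "flesh") {
  stop_grid_mismatch(a, b, "images")
  ma <- label_mask(a, labels)
  mb <- label_mask(b, labels)
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0)
    stop("DICE undefined: both label sets are empty")
  2 * sum(ma & mb) / (na + nb)
}

# 6-connected boundary voxels of a logical 3D mask (voxels of the mask with
# at least one face-neighbour outside it, image border included).
boundary_mask <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    if (ax == 1) {
      if (by == 1) out[2:d[1], , ] <- m[1:(d[1] - 1), , ]
      else out[1:(d[1] - 1), , ] <- m[2:d[1], , ]
    } else if (ax == 2) {
      if (by == 1) out[, 2:d[2], ] <- m[, 1:(d[2] - 1), ]
      else out[, 1:(d[2] - 1), ] <- m[, 2:d[2], ]
    } else {
      if (by == 1) out[, , 2:d[3]] <- m[, , 1:(d[3] - 1)]
      else out[, , 1:(d[3] - 1)] <- m[, , 2:d[3]]
    }
    out
  }
  interior <- mask
  for (ax in 1:3) for (by in c(1, -1)) interior <- interior & shift(mask, ax, by)
  mask & !interior
}

#' Hausdorff and percentile-Hausdorff distance between label images
#'
#' Boundary voxels of each chosen mask form the two point sets `C` and `D`.
#' Directed distances are computed exactly via a Euclidean distance transform
#' in world mm; `HD = max(h(C,D), h(D,C))` with `h` the directed maximum, and
#' the percentile variant takes the maximum of the two directed percentiles
#' over boundary voxels (HD95 by default).
#'
#' @param a,b [label_image()] objects on the same grid, non-empty masks.
#' @param percentile percentile for the robust variant (default 95).
#' @param labels as in [dice()].
#' @return named numeric vector `c(hd = ..., hd95 = ...)` in mm (the second
#'   name follows the requested percentile).
#' @export
hausdorff <- function(a, b, percentile = 95, labels = "flesh") {
  stop_grid_mismatch(a, b, "images")
  ma <- label_mask(a, labels); dim(ma) <- grid_dims(a)
  mb <- label_mask(b, labels); dim(mb) <- grid_dims(b)
  if (!any(ma) || !any(mb))
    stop("Hausdorff undefined: empty foreground")
  ba <- boundary_mask(ma)
  bb <- boundary_mask(mb)
  d <- as.integer(grid_dims(a))
  dt_a <- cpp_edt(as.vector(ba), d, a$spacing)  # distance to C
  dt_b <- cpp_edt(as.vector(bb), d, a$spacing)  # distance to D
  h_cd <- dt_b[as.vector(ba)]  # from each c in C to nearest d in D
  h_dc <- dt_a[as.vector(bb)]
  hd <- max(max(h_cd), max(h_dc))
  hdp <- max(quantile(h_cd, percentile / 100, names = FALSE),
             quantile(h_dc, percentile / 100, names = FALSE))
  out <- c(hd, hdp)
  names(out) <- c("hd", paste0("hd", percentile))
  out
}

#' Per-vertex distance from a test surface to a reference surface
#'
#' For each vertex of `test`, the exact distance to the nearest point on any
#' triangle of `reference` (point-to-triangle, not vertex-to-vertex). Used to
#' visualize where a personalized surface deviates from the subject.
#'
#' @param test,reference [surface_mesh()] objects.
#' @return numeric vector of distances (mm), one per test vertex, with a
#'   `summary` attribute (mean and 95th percentile).
#' @export
surface_distance_map <- function(test, reference) {
  if (nrow(test$vertices) == 0 || nrow(reference$triangles) == 0)
    stop("empty surface")
  dists <- cpp_point_triangle_distances(test$vertices, reference$vertices,
                                        reference$triangles)
  attr(dists, "summary") <- c(mean = mean(dists),
                              p95 = quantile(dists, 0.95, names = FALSE))
  dists
}

# hex corner triples: at corner k the three outgoing edges, right-handed for
# the standard node ordering (bottom quad 1-4 counter-clockwise, top 5-8)
hex_corner_edges <- matrix(c(
  1, 2, 4, 5,
  2, 3, 1, 6,
  3, 4, 2, 7,
  4, 1, 3, 8,
  5, 8, 6, 1,
  6, 5, 7, 2,
  7, 6, 8, 3,
  8, 7, 5, 4), ncol = 4, byrow = TRUE)

hex_edges <- matrix(c(1, 2, 2, 3, 3, 4, 4, 1,
                      5, 6, 6, 7, 7, 8, 8, 5,
                      1, 5, 2, 6, 3, 7, 4, 8), ncol = 2, byrow = TRUE)

row_det3 <- function(a, b, c) {
  a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
}

#' Element quality of a finite-element mesh
#'
#' For 8-node hexahedra the *scaled Jacobian* is the minimum over the eight
#' corners of the triple product of the three outgoing edge vectors divided
#' by the product of their lengths (1 for a rectangular box, <= 0 for an
#' inverted element); for 4-node tetrahedra the volume is normalized by that
#' of the regular tetrahedron with the same RMS edge length. Aspect ratio is
#' the longest over the shortest element edge and the minimum edge length is
#' reported per element because it controls the explicit time step. Shells
#' report edge-based aspect ratio and minimum length. Degenerate elements
#' (zero-length edge) are flagged, excluded from ratios and counted.
#'
#' @param mesh an [fe_mesh()].
#' @return a `quality_report`: data frame `elements` (eid, pid, type, scaled
#'   Jacobian, aspect ratio, min edge length), per-part `summary`, and
#'   `degenerate_count`.
#' @export
element_quality <- function(mesh) {
  if (n_solids(mesh) == 0 && n_shells(mesh) == 0)
    stop("mesh has no elements")
  rows <- list()
  if (n_solids(mesh) > 0) {
    s <- mesh$solids
    nn <- solid_nn(s)
    hx <- which(nn == 8L)
    if (length(hx) > 0) {
      conn <- s[hx, 3:10, drop = FALSE]
      P <- lapply(1:8, function(c) mesh$nodes[node_index(mesh, conn[, c]), ,
                                              drop = FALSE])
      elen <- sapply(seq_len(nrow(hex_edges)), function(e)
        sqrt(rowSums((P[[hex_edges[e, 1]]] - P[[hex_edges[e, 2]]])^2)))
      elen <- matrix(elen, nrow = length(hx))
      minlen <- apply(elen, 1, min)
      maxlen <- apply(elen, 1, max)
      degen <- minlen <= 0
      sj <- rep(Inf, length(hx))
      for (c in 1:8) {
        k <- hex_corner_edges[c, 1]
        e1 <- P[[hex_corner_edges[c, 2]]] - P[[k]]
        e2 <- P[[hex_corner_edges[c, 3]]] - P[[k]]
        e3 <- P[[hex_corner_edges[c, 4]]] - P[[k]]
        l1 <- sqrt(rowSums(e1^2)); l2 <- sqrt(rowSums(e2^2))
        l3 <- sqrt(rowSums(e3^2))
        den <- l1 * l2 * l3
        v <- ifelse(den > 0, row_det3(e1, e2, e3) / den, NA_real_)
        sj <- pmin(sj, v, na.rm = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        eid = s[hx, 1], pid = s[hx, 2], type = "hex",
        scaled_jacobian = ifelse(degen, NA_real_, sj),
        aspect_ratio = ifelse(degen, NA_real_, maxlen / minlen),
        min_edge = minlen, degenerate = degen)
    }
    tt <- which(nn == 4L)
    if (length(tt) > 0) {
      conn <- s[tt, 3:6, drop = FALSE]
      P <- lapply(1:4, function(c) mesh$nodes[node_index(mesh, conn[, c]), ,
                                              drop = FALSE])
      ed <- utils::combn(4, 2)
      elen <- sapply(seq_len(ncol(ed)), function(e)
        sqrt(rowSums((P[[ed[1, e]]] - P[[ed[2, e]]])^2)))
      elen <- matrix(elen, nrow = length(tt))
      minlen <- apply(elen, 1, min)
      maxlen <- apply(elen, 1, max)
      degen <- minlen <= 0
      vol <- row_det3(P[[2]] - P[[1]], P[[3]] - P[[1]], P[[4]] - P[[1]]) / 6
      lrms <- sqrt(rowMeans(elen^2))
      # regular tetrahedron volume with edge L is L^3 / (6 sqrt 2)
      sj <- ifelse(lrms > 0, vol / (lrms^3 / (6 * sqrt(2))), NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        eid = s[tt, 1], pid = s[tt, 2], type = "tet",
        scaled_jacobian = ifelse(degen, NA_real_, sj),
        aspect_ratio = ifelse(degen, NA_real_, maxlen / minlen),
        min_edge = minlen, degenerate = degen)
    }
  }
  if (n_shells(mesh) > 0) {
    sh <- mesh$shells
    tri <- sh[, 6] == sh[, 5]
    for (r in seq_len(nrow(sh))) {
      nv <- if (tri[r]) 3L else 4L
      pts <- mesh$nodes[node_index(mesh, sh[r, 3:(2 + nv)]), , drop = FALSE]
      nxt <- c(2:nv, 1)
      el <- sqrt(rowSums((pts[nxt, , drop = FALSE] - pts)^2))
      rows[[length(rows) + 1]] <- data.frame(
        eid = sh[r, 1], pid = sh[r, 2], type = "shell",
        scaled_jacobian = NA_real_,
        aspect_ratio = if (min(el) > 0) max(el) / min(el) else NA_real_,
        min_edge = min(el), degenerate = min(el) <= 0)
    }
  }
  elements <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(elements, elements$pid), function(g)
    data.frame(pid = g$pid[1], n = nrow(g),
               jacobian_min = suppressWarnings(min(g$scaled_jacobian,
                                                   na.rm = TRUE)),
               jacobian_ge_0.5 = mean(g$scaled_jacobian >= 0.5, na.rm = TRUE),
               aspect_max = suppressWarnings(max(g$aspect_ratio, na.rm = TRUE)),
               aspect_le_3 = mean(g$aspect_ratio <= 3, na.rm = TRUE),
               min_edge = min(g$min_edge))))
  structure(list(elements = elements, summary = summ,
                 degenerate_count = sum(elements$degenerate)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  e <- x$elements
  cat(sprintf("<quality_report> %d elements (%d degenerate)\n", nrow(e),
              x$degenerate_count))
  cat(sprintf("  scaled Jacobian: min %.3f, share >= 0.5: %.1f%%\n",
              suppressWarnings(min(e$scaled_jacobian, na.rm = TRUE)),
              100 * mean(e$scaled_jacobian >= 0.5, na.rm = TRUE)))
  cat(sprintf("  aspect ratio: max %.2f, share <= 3: %.1f%%\n",
              suppressWarnings(max(e$aspect_ratio, na.rm = TRUE)),
              100 * mean(e$aspect_ratio <= 3, na.rm = TRUE)))
  cat(sprintf("  min edge length: %.3f mm\n", min(e$min_edge)))
  invisible(x)
}

#' Histogram of element quality
#'
#' @param x a `quality_report`.
#' @param ... unused.
#' @export
plot.quality_report <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  e <- x$elements
  graphics::hist(e$scaled_jacobian, main = "Scaled Jacobian", xlab = "",
                 col = "grey")
  graphics::hist(e$aspect_ratio, main = "Aspect ratio", xlab = "",
                 col = "grey")
  graphics::hist(e$min_edge, main = "Min edge length (mm)", xlab = "",
                 col = "grey")
  invisible(x)
}

# Boundary faces (as triangles) of one part of a solid mesh: faces used by
# exactly one solid of that part, quads split into two triangles. Returns
# vertices (the mesh node table), triangle rows into it, and the global node
# ids per triangle corner.
part_boundary_triangles <- function(mesh, pid) {
  if (n_solids(mesh) == 0) stop("part ", pid, " has no solid elements")
  s <- mesh$solids[mesh$solids[, 2] == pid, , drop = FALSE]
  if (nrow(s) == 0) stop("part ", pid, " has no solid elements")
  nn <- solid_nn(s)
  hex_faces <- matrix(c(1, 2, 3, 4,  5, 8, 7, 6,  1, 5, 6, 2,
                        2, 6, 7, 3,  3, 7, 8, 4,  4, 8, 5, 1),
                      ncol = 4, byrow = TRUE)
  tet_faces <- matrix(c(1, 3, 2,  1, 2, 4,  2, 3, 4,  1, 4, 3),
                      ncol = 3, byrow = TRUE)
  faces <- list(); owner <- list()
  for (r in seq_len(nrow(s))) {
    if (nn[r] == 8L) {
      conn <- s[r, 3:10]
      for (f in 1:6) {
        faces[[length(faces) + 1]] <- conn[hex_faces[f, ]]
        owner[[length(owner) + 1]] <- s[r, 1]
      }
    } else {
      conn <- s[r, 3:6]
      for (f in 1:4) {
        faces[[length(faces) + 1]] <- c(conn[tet_faces[f, ]], NA)
        owner[[length(owner) + 1]] <- s[r, 1]
      }
    }
  }
  fm <- do.call(rbind, faces)
  key <- apply(fm, 1, function(v) paste(sort(v[!is.na(v)]), collapse = "-"))
  once <- key %in% names(which(table(key) == 1L))
  fm <- fm[once, , drop = FALSE]
  own <- unlist(owner)[once]
  tris <- list(); nid <- list(); eids <- list()
  for (r in seq_len(nrow(fm))) {
    v <- fm[r, ]
    if (is.na(v[4])) {
      tris[[length(tris) + 1]] <- v[1:3]
      nid[[length(nid) + 1]] <- v[1:3]
      eids[[length(eids) + 1]] <- own[r]
    } else {
      tris[[length(tris) + 1]] <- v[c(1, 2, 3)]
      tris[[length(tris) + 1]] <- v[c(1, 3, 4)]
      nid[[length(nid) + 1]] <- v[c(1, 2, 3)]
      nid[[length(nid) + 1]] <- v[c(1, 3, 4)]
      eids[[length(eids) + 1]] <- own[r]
      eids[[length(eids) + 1]] <- own[r]
    }
  }
  conn_ids <- do.call(rbind, nid)
  list(vertices = mesh$nodes,
       triangles = matrix(node_index(mesh, conn_ids), ncol = 3),
       node_ids = conn_ids,
       element_ids = unlist(eids))
}

#' Count contact-surface intersections
#'
#' For each declared contact pair the boundary faces of the two parts are
#' extracted (quads triangulated) and strictly penetrating face pairs are
#' counted; exactly touching or coplanar faces (including conforming
#' interfaces that share nodes) do not count. Element IDs of offending pairs
#' are reported in deterministic order.
#'
#' @param mesh an [fe_mesh()].
#' @param pairs two-column matrix of part IDs; defaults to the mesh's
#'   declared `contact_pairs`.
#' @param eps geometric tolerance (mm) below which overlap counts as touching.
#' @return list with `count` and a data frame `pairs` of intersecting element
#'   IDs per contact pair.
#' @export
count_contact_intersections <- function(mesh, pairs = mesh$contact_pairs,
                                        eps = 1e-6) {
  if (is.null(pairs) || nrow(pairs) == 0)
    return(list(count = 0L, pairs = data.frame(pid_a = integer(0),
                                               pid_b = integer(0),
                                               eid_a = integer(0),
                                               eid_b = integer(0))))
  total <- 0L
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- part_boundary_triangles(mesh, pairs[r, 1])
    b <- part_boundary_triangles(mesh, pairs[r, 2])
    res <- cpp_triangle_intersections(a$vertices, a$triangles, a$node_ids,
                                      b$vertices, b$triangles, b$node_ids,
                                      eps)
    total <- total + res$count
    if (res$count > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        pid_a = pairs[r, 1], pid_b = pairs[r, 2],
        eid_a = a$element_ids[res$i], eid_b = b$element_ids[res$j])
    }
  }
  prs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pid_a = integer(0), pid_b = integer(0), eid_a = integer(0),
               eid_b = integer(0))
  prs <- prs[order(prs$pid_a, prs$pid_b, prs$eid_a, prs$eid_b), ,
             drop = FALSE]
  list(count = total, pairs = prs)
}
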