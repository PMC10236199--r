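# Independent brute-force oracles and small fixture builders. Everything here
# deliberately avoids the package's own fast paths: plain R loops over voxel
# and vertex sets, so that agreement is meaningful.

# --- brute-force overlap / distance oracles ----------------------------------

brute_dice <- function(a, b, labels = 1) {
  ma <- a$data %in% labels
  mb <- b$data %in% labels
  2 * sum(ma & mb) / (sum(ma) + sum(mb))
}

# boundary voxels: in mask with at least one 6-neighbour outside (or on the
# image border); returns world coordinates of their centers
brute_boundary_points <- function(img, labels = 1) {
  d <- dim(img$data)
  pts <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!(img$data[i, j, k] %in% labels)) next
    on_border <- i == 1 || i == d[1] || j == 1 || j == d[2] ||
      k == 1 || k == d[3]
    if (!on_border) {
      nb <- c(img$data[i - 1, j, k] %in% labels,
              img$data[i + 1, j, k] %in% labels,
              img$data[i, j - 1, k] %in% labels,
              img$data[i, j + 1, k] %in% labels,
              img$data[i, j, k - 1] %in% labels,
              img$data[i, j, k + 1] %in% labels)
      if (all(nb)) next
    }
    pts <- rbind(pts, img$origin + (c(i, j, k) - 1) * img$spacing)
  }
  pts
}

brute_hausdorff <- function(a, b, percentile = 95, labels = 1) {
  C <- brute_boundary_points(a, labels)
  D <- brute_boundary_points(b, labels)
  dmat <- outer(seq_len(nrow(C)), seq_len(nrow(D)), Vectorize(function(i, j)
    sqrt(sum((C[i, ] - D[j, ])^2))))
  h_cd <- apply(dmat, 1, min)
  h_dc <- apply(dmat, 2, min)
  c(hd = max(max(h_cd), max(h_dc)),
    hdp = max(quantile(h_cd, percentile / 100, names = FALSE),
              quantile(h_dc, percentile / 100, names = FALSE)))
}

# random three-label image with non-empty label sets: a few random blobs
random_label_image <- function(dims = c(12L, 12L, 12L), spacing = c(1, 1, 1)) {
  arr <- array(0L, dim = dims)
  ctrs <- cbind(runif(3, 3, dims[1] - 2), runif(3, 3, dims[2] - 2),
                runif(3, 3, dims[3] - 2))
  r <- runif(3, 1.5, 4)
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  for (bl in 1:2) {  # two flesh blobs
    d2 <- rowSums(sweep(idx, 2, ctrs[bl, ])^2)
    arr[idx[d2 <= r[bl]^2, , drop = FALSE]] <- 1L
  }
  d2 <- rowSums(sweep(idx, 2, ctrs[3, ])^2)
  arr[idx[d2 <= r[3]^2, , drop = FALSE]] <- 2L
  if (!any(arr == 1L)) arr[2, 2, 2] <- 1L
  if (!any(arr == 2L)) arr[3, 3, 3] <- 2L
  label_image(arr, spacing = spacing)
}

# --- triangle-intersection oracle --------------------------------------------

# strict segment-triangle crossing: endpoints strictly on opposite sides of
# the triangle plane and the crossing point strictly inside the triangle
segment_crosses_triangle <- function(p, q, a, b, c, eps = 1e-9) {
  n <- pracma_cross(b - a, c - a)
  nn <- sqrt(sum(n^2))
  if (nn < eps) return(FALSE)
  n <- n / nn
  dp <- sum(n * (p - a))
  dq <- sum(n * (q - a))
  if (!(dp > eps && dq < -eps) && !(dp < -eps && dq > eps)) return(FALSE)
  t <- dp / (dp - dq)
  x <- p + t * (q - p)
  # barycentric coordinates of x
  v0 <- b - a; v1 <- c - a; v2 <- x - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  v > eps && w > eps && (1 - v - w) > eps
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

brute_tri_penetrates <- function(t1, t2) {
  for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
    if (segment_crosses_triangle(t1[e[1], ], t1[e[2], ],
                                 t2[1, ], t2[2, ], t2[3, ])) return(TRUE)
    if (segment_crosses_triangle(t2[e[1], ], t2[e[2], ],
                                 t1[1, ], t1[2, ], t1[3, ])) return(TRUE)
  }
  FALSE
}

# all-pairs penetration count between two triangle soups (V: n x 3, F: m x 3)
brute_intersection_count <- function(V1, F1, V2, F2) {
  count <- 0L
  for (s in seq_len(nrow(F1))) for (t in seq_len(nrow(F2))) {
    if (brute_tri_penetrates(V1[F1[s, ], , drop = FALSE],
                             V2[F2[t, ], , drop = FALSE]))
      count <- count + 1L
  }
  count
}

# --- small mesh fixtures ------------------------------------------------------

# axis-aligned box surface (12 triangles)
box_surface <- function(lo, hi, region_tag = "box") {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertices: 1 (0,0,0) 2 (1,0,0) 3 (0,1,0) 4 (1,1,0) 5..8 top
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo
    c(5, 6, 7), c(6, 8, 7),   # z = hi
    c(1, 2, 5), c(2, 6, 5),   # y = lo
    c(3, 7, 4), c(4, 7, 8),   # y = hi
    c(1, 5, 3), c(3, 5, 7),   # x = lo
    c(2, 4, 6), c(4, 8, 6))   # x = hi
  surface_mesh(v, f, region_tag = region_tag, clean = FALSE)
}

# single-hex (or grid) structured mesh fixture
single_hex_mesh <- function(corner_pts) {
  fe_mesh(node_ids = 1:8, nodes = corner_pts,
          solids = matrix(c(1L, 1L, 1:8), nrow = 1))
}

unit_hex_points <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))

# solid block of nx x ny x nz cubic hexes sharing a corner-lattice node grid
block_fe_mesh <- function(nx, ny, nz, origin = c(0, 0, 0), size = 1,
                          pid = 1L, id_offset = 0L) {
  corner <- function(i, j, k) i + (nx + 1) * (j + (ny + 1) * k) + 1L
  sol <- list()
  for (k in 0:(nz - 1)) for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    sol[[length(sol) + 1]] <- c(length(sol) + 1L, pid,
                                corner(i, j, k), corner(i + 1, j, k),
                                corner(i + 1, j + 1, k), corner(i, j + 1, k),
                                corner(i, j, k + 1), corner(i + 1, j, k + 1),
                                corner(i + 1, j + 1, k + 1),
                                corner(i, j + 1, k + 1))
  }
  sol <- do.call(rbind, sol)
  ids <- seq_len((nx + 1) * (ny + 1) * (nz + 1)) + id_offset
  g <- as.matrix(expand.grid(i = 0:nx, j = 0:ny, k = 0:nz))
  nodes <- sweep(g * size, 2, origin, "+")
  sol[, 3:10] <- sol[, 3:10] + id_offset
  sol[, 1] <- sol[, 1] + id_offset
  fe_mesh(node_ids = ids, nodes = nodes, solids = sol)
}

# deterministic constant field helper
constant_field <- function(dims, spacing, origin, vec) {
  arr <- array(0, dim = c(dims, 3))
  for (c in 1:3) arr[, , , c] <- vec[c]
  displacement_field(arr, spacing = spacing, origin = origin)
}
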