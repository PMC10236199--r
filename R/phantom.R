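#' Specification of a synthetic body phantom
#'
#' The phantom is a desk-scale stand-in for a voxelized human body: a
#' z-axisymmetric spheroid torso with a spherical head on top (flesh), and a
#' cylindrical spine plus a spherical skull inside (skeleton). Because every
#' primitive is a solid of revolution about the z axis, the union volume of
#' the flesh has a closed form (piecewise polynomial integral of the maximal
#' squared cross-section radius), which the tests use as an analytic oracle.
#'
#' All dimensions scale linearly with `height`, which is the exact total z
#' extent (mm) of the analytic flesh. At the default `height = 120` the torso
#' spheroid has semi-axes (32, 32, 48) mm, the head radius is 16 mm centered
#' 56 mm up (so the flesh spans z in (-48, 72)), the skull radius is 10 mm at
#' the head center, and the spine radius 7 mm spans z in (-34, 32) mm. A
#' seeded radial jitter (mm standard deviation, truncated at 2 sd) roughens
#' the surfaces deterministically so they are not perfectly analytic.
#'
#' @param height total body height (mm), z extent of the flesh.
#' @param jitter radial surface jitter standard deviation (mm).
#' @param seed integer seed; the seed fully determines the phantom.
#' @param mesh_resolution hexahedral element edge length (mm) for the
#'   voxel-block FE mesh.
#' @param surface_segments angular resolution of the tessellations.
#' @param spine_radius,skull_radius skeleton primitive sizes (mm); defaults
#'   scale with height. Oversized skeletons that escape the flesh are
#'   rejected.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 120, jitter = 0.3, seed = 1L,
                         mesh_resolution = 5, surface_segments = 48L,
                         spine_radius = NULL, skull_radius = NULL) {
  if (height <= 0) stop("`height` must be > 0")
  s <- height / 120  # base design is 120 mm tall
  spec <- list(
    height = height, scale = s, jitter = jitter, seed = as.integer(seed),
    mesh_resolution = mesh_resolution,
    surface_segments = as.integer(surface_segments),
    body = list(center = c(0, 0, 0) * s, semiaxes = c(32, 32, 48) * s),
    head = list(center = c(0, 0, 56) * s,
                radius = 16 * s),
    skull = list(center = c(0, 0, 56) * s,
                 radius = if (is.null(skull_radius)) 10 * s else skull_radius),
    spine = list(radius = if (is.null(spine_radius)) 7 * s else spine_radius,
                 z = c(-34, 32) * s))
  # skeleton must sit strictly inside the flesh
  rz <- spec$body$semiaxes[3]
  rxy <- spec$body$semiaxes[1]
  spine_top_clearance <- rxy * sqrt(max(0, 1 - (spec$spine$z[2] / rz)^2))
  if (spec$spine$radius >= spine_top_clearance)
    stop("phantom spec error: spine escapes the body")
  if (spec$skull$radius >= spec$head$radius)
    stop("phantom spec error: skull escapes the head")
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> height %g mm, jitter %g mm, seed %d, mesh %g mm\n",
              x$height, x$jitter, x$seed, x$mesh_resolution))
  invisible(x)
}

# --- tessellated primitives ---------------------------------------------------

# Watertight UV-sphere scaled into an ellipsoid.
ellipsoid_mesh <- function(center, semiaxes, n_theta = 24L, n_phi = 48L,
                           region_tag = "surface") {
  th <- seq(0, pi, length.out = n_theta + 1)[2:n_theta]  # exclude poles
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[seq_len(n_phi)]
  grid <- expand.grid(ph = ph, th = th)
  ring <- cbind(sin(grid$th) * cos(grid$ph), sin(grid$th) * sin(grid$ph),
                cos(grid$th))
  v <- rbind(c(0, 0, 1), ring, c(0, 0, -1))
  v <- sweep(sweep(v, 2, semiaxes, "*"), 2, center, "+")
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  tris <- list()
  for (j in seq_len(n_phi)) {  # top cap
    tris[[length(tris) + 1]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  }
  nr <- n_theta - 1L
  for (i in seq_len(nr - 1L)) {
    for (j in seq_len(n_phi)) {
      a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j)
      dd <- idx(i + 1L, j + 1L)
      tris[[length(tris) + 1]] <- c(a, cc, b)
      tris[[length(tris) + 1]] <- c(b, cc, dd)
    }
  }
  bot <- nrow(v)
  for (j in seq_len(n_phi)) {  # bottom cap
    tris[[length(tris) + 1]] <- c(bot, idx(nr, j + 1L), idx(nr, j))
  }
  surface_mesh(v, do.call(rbind, tris), region_tag = region_tag,
               clean = FALSE)
}

# Watertight capped cylinder along z.
cylinder_mesh <- function(radius, z, center_xy = c(0, 0), n_phi = 48L,
                          n_z = 8L, region_tag = "surface") {
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[seq_len(n_phi)]
  zs <- seq(z[1], z[2], length.out = n_z + 1)
  rings <- lapply(zs, function(zz)
    cbind(center_xy[1] + radius * cos(ph), center_xy[2] + radius * sin(ph),
          zz))
  v <- do.call(rbind, rings)
  top_c <- nrow(v) + 1L
  bot_c <- nrow(v) + 2L
  v <- rbind(v, c(center_xy, z[2]), c(center_xy, z[1]))
  idx <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  tris <- list()
  for (i in seq_len(n_z)) {
    for (j in seq_len(n_phi)) {
      a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j)
      dd <- idx(i + 1L, j + 1L)
      tris[[length(tris) + 1]] <- c(a, b, cc)
      tris[[length(tris) + 1]] <- c(b, dd, cc)
    }
  }
  for (j in seq_len(n_phi)) {
    tris[[length(tris) + 1]] <- c(bot_c, idx(1L, j + 1L), idx(1L, j))
    tris[[length(tris) + 1]] <- c(top_c, idx(n_z + 1L, j), idx(n_z + 1L, j + 1L))
  }
  surface_mesh(v, do.call(rbind, tris), region_tag = region_tag,
               clean = FALSE)
}

# Deterministic radial jitter about a center: vertices move along their
# radial direction by a seeded truncated normal. Keeps shells watertight
# because shared vertices move together.
jitter_surface <- function(mesh, center, amount, seed_offset, spec) {
  if (amount <= 0) return(mesh)
  set.seed(spec$seed + seed_offset)
  v <- mesh$vertices
  dir <- sweep(v, 2, center)
  len <- sqrt(rowSums(dir^2))
  len[len == 0] <- 1
  r <- pmax(pmin(rnorm(nrow(v), 0, amount), 2 * amount), -2 * amount)
  mesh$vertices <- v + dir / len * r
  mesh
}

#' Generate a synthetic phantom
#'
#' Builds the tagged surface set (`skin` torso, `head`, `skeleton` spine,
#' `skull`) and a structured voxel-block hexahedral FE mesh with part 1
#' (flesh), part 2 (skeleton) and the contact pair (1, 2). Because elements
#' are axis-aligned blocks, the baseline scaled Jacobian and aspect ratio are
#' exactly 1, so any later quality change is attributable to the morph alone.
#' Output is fully deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom`: list with `surfaces` (named list of
#'   [surface_mesh()]), `mesh` (an [fe_mesh()]), and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  ns <- spec$surface_segments
  body <- ellipsoid_mesh(spec$body$center, spec$body$semiaxes,
                         n_theta = ns %/% 2L, n_phi = ns, region_tag = "skin")
  head <- ellipsoid_mesh(spec$head$center, rep(spec$head$radius, 3),
                         n_theta = ns %/% 2L, n_phi = ns, region_tag = "head")
  skull <- ellipsoid_mesh(spec$skull$center, rep(spec$skull$radius, 3),
                          n_theta = ns %/% 2L, n_phi = ns,
                          region_tag = "skull")
  spine <- cylinder_mesh(spec$spine$radius, spec$spine$z, n_phi = ns,
                         region_tag = "skeleton")
  body <- jitter_surface(body, spec$body$center, spec$jitter, 1L, spec)
  head <- jitter_surface(head, spec$head$center, spec$jitter, 2L, spec)
  surfaces <- list(skin = body, head = head, skeleton = spine, skull = skull)
  mesh <- phantom_block_mesh(spec)
  structure(list(surfaces = surfaces, mesh = mesh, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> height %g mm; %s surfaces; mesh: %d nodes, %d hexes\n",
              x$spec$height, paste(names(x$surfaces), collapse = "/"),
              length(x$mesh$node_ids), n_solids(x$mesh)))
  invisible(x)
}

# implicit inside tests against the analytic primitives (not the jittered
# tessellation) -- used for meshing and for the analytic volume
inside_flesh <- function(spec, pts) {
  b <- sweep(pts, 2, spec$body$center)
  in_body <- (b[, 1] / spec$body$semiaxes[1])^2 +
    (b[, 2] / spec$body$semiaxes[2])^2 +
    (b[, 3] / spec$body$semiaxes[3])^2 <= 1
  h <- sweep(pts, 2, spec$head$center)
  in_head <- rowSums(h^2) <= spec$head$radius^2
  in_body | in_head
}

inside_skeleton <- function(spec, pts) {
  s <- sweep(pts, 2, spec$skull$center)
  in_skull <- rowSums(s^2) <= spec$skull$radius^2
  in_spine <- pts[, 1]^2 + pts[, 2]^2 <= spec$spine$radius^2 &
    pts[, 3] >= spec$spine$z[1] & pts[, 3] <= spec$spine$z[2]
  in_skull | in_spine
}

#' Closed-form phantom volumes
#'
#' Flesh: both torso and head are solids of revolution about the z axis with
#' quadratic squared-radius profiles, so the union volume is
#' `pi * integral of max(Rb(z)^2, Rh(z)^2) dz`, evaluated piecewise exactly.
#' Skeleton: disjoint cylinder + sphere.
#'
#' @param spec a [phantom_spec()].
#' @return named vector `c(flesh = ..., skeleton = ...)` in mm^3 (flesh is
#'   the full body including the skeleton interior).
#' @export
phantom_analytic_volume <- function(spec) {
  a <- spec$body$semiaxes
  hc <- spec$head$center[3]
  hr <- spec$head$radius
  # squared cross-section radius profiles (0 outside support)
  rb2 <- function(z) ifelse(abs(z) <= a[3], a[1]^2 * (1 - (z / a[3])^2), 0)
  rh2 <- function(z) ifelse(abs(z - hc) <= hr, hr^2 - (z - hc)^2, 0)
  zlo <- min(-a[3], hc - hr)
  zhi <- max(a[3], hc + hr)
  # exact piecewise integration of max of two quadratics: split at support
  # bounds and crossings, then integrate the winner analytically
  int_rb2 <- function(l, u) {
    l <- max(l, -a[3]); u <- min(u, a[3])
    if (u <= l) return(0)
    a[1]^2 * ((u - l) - (u^3 - l^3) / (3 * a[3]^2))
  }
  int_rh2 <- function(l, u) {
    l <- max(l, hc - hr); u <- min(u, hc + hr)
    if (u <= l) return(0)
    hr^2 * (u - l) - ((u - hc)^3 - (l - hc)^3) / 3
  }
  # crossings of rb2 - rh2 (quadratic in z)
  A <- -a[1]^2 / a[3]^2 + 1
  B <- -2 * hc
  C <- a[1]^2 - hr^2 + hc^2
  cr <- numeric(0)
  if (abs(A) > 1e-14) {
    disc <- B^2 - 4 * A * C
    if (disc >= 0) cr <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  } else if (abs(B) > 1e-14) cr <- -C / B
  brk <- sort(unique(c(zlo, zhi, -a[3], a[3], hc - hr, hc + hr,
                       cr[cr > zlo & cr < zhi])))
  vol <- 0
  for (i in seq_len(length(brk) - 1)) {
    l <- brk[i]; u <- brk[i + 1]
    zm <- (l + u) / 2
    vol <- vol + if (rb2(zm) >= rh2(zm)) int_rb2(l, u) else int_rh2(l, u)
  }
  flesh <- pi * vol
  skel <- pi * spec$spine$radius^2 * diff(spec$spine$z) +
    4 / 3 * pi * spec$skull$radius^3
  c(flesh = flesh, skeleton = skel)
}

# Structured voxel-block hex mesh: one hex per occupied voxel at
# mesh_resolution, part 2 where the voxel center is inside the skeleton,
# else part 1; nodes shared on the corner lattice, contact pair (1, 2).
phantom_block_mesh <- function(spec) {
  res <- spec$mesh_resolution
  a <- spec$body$semiaxes
  lo <- c(-a[1], -a[2], -a[3])
  lo <- pmin(lo, spec$head$center - spec$head$radius)
  hi <- c(a[1], a[2], a[3])
  hi <- pmax(hi, spec$head$center + spec$head$radius)
  dims <- as.integer(ceiling((hi - lo) / res))
  centers_1d <- function(ax) lo[ax] + (seq_len(dims[ax]) - 0.5) * res
  cx <- centers_1d(1); cy <- centers_1d(2); cz <- centers_1d(3)
  ctr <- cbind(rep(cx, times = dims[2] * dims[3]),
               rep(rep(cy, each = dims[1]), times = dims[3]),
               rep(cz, each = dims[1] * dims[2]))
  occ <- inside_flesh(spec, ctr)
  skel <- inside_skeleton(spec, ctr)
  keep <- which(occ | skel)
  nxn <- dims[1] + 1L; nyn <- dims[2] + 1L
  corner_id <- function(i, j, k) i + nxn * (j + nyn * k) + 1L  # i,j,k 0-based
  kk <- (keep - 1L) %/% (dims[1] * dims[2])
  jj <- ((keep - 1L) %/% dims[1]) %% dims[2]
  ii <- (keep - 1L) %% dims[1]
  n1 <- corner_id(ii,     jj,     kk)
  n2 <- corner_id(ii + 1L, jj,     kk)
  n3 <- corner_id(ii + 1L, jj + 1L, kk)
  n4 <- corner_id(ii,     jj + 1L, kk)
  n5 <- corner_id(ii,     jj,     kk + 1L)
  n6 <- corner_id(ii + 1L, jj,     kk + 1L)
  n7 <- corner_id(ii + 1L, jj + 1L, kk + 1L)
  n8 <- corner_id(ii,     jj + 1L, kk + 1L)
  used <- sort(unique(c(n1, n2, n3, n4, n5, n6, n7, n8)))
  u0 <- used - 1L
  ci <- u0 %% nxn
  cj <- (u0 %/% nxn) %% nyn
  ck <- u0 %/% (nxn * nyn)
  coords <- cbind(lo[1] + ci * res, lo[2] + cj * res, lo[3] + ck * res)
  pid <- ifelse(skel[keep], 2L, 1L)
  solids <- cbind(seq_along(keep), pid, n1, n2, n3, n4, n5, n6, n7, n8)
  colnames(solids) <- c("eid", "pid", paste0("n", 1:8))
  fe_mesh(node_ids = used, nodes = coords, solids = solids,
          parts = data.frame(pid = c(1L, 2L),
                             title = c("flesh", "skeleton")),
          contact_pairs = matrix(c(1L, 2L), ncol = 2))
}

# --- analytic deformations ----------------------------------------------------

#' Analytic phantom deformations
#'
#' Each deformation is a closed-form point map with an exact or numeric
#' inverse (fixed-point iteration at `1e-9` mm tolerance):
#' `deform_none()`; `deform_uniform_scale(s)` about `center`;
#' `deform_axis_scale(sx, sy, sz)` about `center`;
#' `deform_belly_bulge(amplitude, radius, center)` -- a radial (xy) Gaussian
#' bulge, displacement `amplitude * exp(-|x - center|^2 / (2 radius^2))`
#' along the outward xy direction, maximal at the bulge center;
#' `deform_bend(angle, z_range)` -- rotation about the y axis increasing
#' linearly in z from 0 to `angle` radians over `z_range`.
#'
#' @param s,sx,sy,sz scale factors (> 0).
#' @param center fixed point of the map / bulge center (world mm).
#' @param amplitude peak displacement (mm).
#' @param radius Gaussian radius (mm).
#' @param angle bend angle (radians).
#' @param z_range length-2 z interval (mm) over which the bend ramps up.
#' @return an object of class `phantom_deformation` with elements `name`,
#'   `map(points)` and `inverse(points)`.
#' @name phantom_deformations
NULL

new_deformation <- function(name, map, inverse = NULL) {
  if (is.null(inverse)) inverse <- numeric_inverse(map)
  structure(list(name = name, map = map, inverse = inverse),
            class = "phantom_deformation")
}

# fixed-point inverse x_{k+1} = x_k - (map(x_k) - y)
numeric_inverse <- function(map, tol = 1e-9, max_iter = 200L) {
  function(points) {
    y <- as_points(points)
    x <- y
    for (it in seq_len(max_iter)) {
      r <- map(x) - y
      x <- x - r
      if (max(abs(r)) < tol) break
    }
    x
  }
}

#' @rdname phantom_deformations
#' @export
deform_none <- function() {
  new_deformation("none", function(p) as_points(p),
                  inverse = function(p) as_points(p))
}

#' @rdname phantom_deformations
#' @export
deform_uniform_scale <- function(s, center = c(0, 0, 0)) {
  deform_axis_scale(s, s, s, center)
}

#' @rdname phantom_deformations
#' @export
deform_axis_scale <- function(sx, sy, sz, center = c(0, 0, 0)) {
  f <- c(sx, sy, sz)
  if (any(f <= 0)) stop("scale factors must be positive")
  center <- rep_len(as.numeric(center), 3)
  new_deformation(
    "axis_scale",
    function(p) sweep(sweep(sweep(as_points(p), 2, center), 2, f, "*"),
                      2, center, "+"),
    inverse = function(p) sweep(sweep(sweep(as_points(p), 2, center),
                                      2, f, "/"), 2, center, "+"))
}

#' @rdname phantom_deformations
#' @export
deform_belly_bulge <- function(amplitude, radius, center) {
  center <- rep_len(as.numeric(center), 3)
  map <- function(p) {
    p <- as_points(p)
    d2 <- rowSums(sweep(p, 2, center)^2)
    w <- amplitude * exp(-d2 / (2 * radius^2))
    r <- sqrt(p[, 1]^2 + p[, 2]^2)
    dir <- cbind(ifelse(r > 1e-12, p[, 1] / r, 0),
                 ifelse(r > 1e-12, p[, 2] / r, 0), 0)
    p + dir * w
  }
  new_deformation("belly_bulge", map)
}

#' @rdname phantom_deformations
#' @export
deform_bend <- function(angle, z_range) {
  z_range <- as.numeric(z_range)
  map <- function(p) {
    p <- as_points(p)
    t <- pmin(pmax((p[, 3] - z_range[1]) / diff(z_range), 0), 1)
    th <- angle * t
    cbind(cos(th) * p[, 1] + sin(th) * p[, 3],
          p[, 2],
          -sin(th) * p[, 1] + cos(th) * p[, 3])
  }
  new_deformation("bend", map)
}

#' Deform a phantom by an analytic map
#'
#' Applies the closed-form map to every surface vertex and every mesh node.
#' `apply_to = "flesh_only"` deforms only skin/head surfaces and flesh mesh
#' nodes not shared with the skeleton, emulating soft-tissue change over a
#' fixed skeleton (the skin-only-versus-skeleton comparison case).
#'
#' @param phantom a [make_phantom()] result.
#' @param deformation a `phantom_deformation`.
#' @param apply_to `"all"` or `"flesh_only"`.
#' @return a deformed `phantom` carrying the `deformation` used.
#' @export
deform_phantom <- function(phantom, deformation,
                           apply_to = c("all", "flesh_only")) {
  apply_to <- match.arg(apply_to)
  if (!inherits(deformation, "phantom_deformation"))
    stop("unsupported deformation: pass a phantom_deformation object")
  out <- phantom
  skel_tags <- c("skeleton", "skull")
  for (nm in names(out$surfaces)) {
    if (apply_to == "flesh_only" &&
        out$surfaces[[nm]]$region_tag %in% skel_tags) next
    out$surfaces[[nm]]$vertices <-
      deformation$map(out$surfaces[[nm]]$vertices)
  }
  if (apply_to == "all") {
    out$mesh$nodes <- deformation$map(out$mesh$nodes)
  } else {
    skel_nodes <- unique(as.vector(
      out$mesh$solids[out$mesh$solids[, 2] == 2L, 3:10]))
    move <- !(out$mesh$node_ids %in% skel_nodes)
    out$mesh$nodes[move, ] <- deformation$map(out$mesh$nodes[move, ,
                                                             drop = FALSE])
  }
  out$deformation <- deformation
  out$deform_scope <- apply_to
  out
}

#' Rasterize an analytic deformation as a displacement field
#'
#' Evaluates `map(x) - x` at every voxel center of `grid`: the exact field a
#' perfect registration of (phantom, deformed phantom) would return, with the
#' phantom image fixed.
#'
#' @param deformation a `phantom_deformation`.
#' @param grid a [label_image()] supplying the lattice.
#' @return a [displacement_field()].
#' @export
rasterize_deformation <- function(deformation, grid) {
  ctr <- voxel_centers(grid)
  u <- deformation$map(ctr) - ctr
  d <- grid_dims(grid)
  displacement_field(array(u, dim = c(d, 3)), spacing = grid$spacing,
                     origin = grid$origin)
}
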