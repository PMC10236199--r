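#' Triangulated surface mesh
#'
#' Watertight triangulated surfaces are the voxelizer's input. Vertices are
#' world millimetres; triangles index into the vertex table (1-based). The
#' `region_tag` names the anatomical region the surface represents ("skin",
#' "skeleton", "head", ...), which is how shielding identifies regions.
#'
#' @param vertices `n x 3` numeric matrix (mm).
#' @param triangles `m x 3` integer matrix of 1-based vertex indices.
#' @param region_tag character scalar.
#' @param clean deduplicate vertices (within `1e-6` mm) and drop zero-area
#'   triangles.
#' @return an object of class `surface_mesh` with a `watertight` flag (every
#'   edge borders exactly two triangles).
#' @export
surface_mesh <- function(vertices, triangles, region_tag = "surface",
                         clean = TRUE) {
  vertices <- as_points(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3) stop("triangles must be m x 3")
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  if (clean) {
    cl <- clean_surface(vertices, triangles)
    vertices <- cl$vertices
    triangles <- cl$triangles
  }
  structure(list(vertices = vertices, triangles = triangles,
                 region_tag = as.character(region_tag),
                 watertight = is_watertight(triangles)),
            class = "surface_mesh")
}

# Merge vertices closer than tol (exact after rounding to the tol lattice)
# and remove degenerate (repeated-index or zero-area) triangles.
clean_surface <- function(vertices, triangles, tol = 1e-6) {
  if (nrow(vertices) == 0) return(list(vertices = vertices, triangles = triangles))
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  triangles <- matrix(map[triangles], ncol = 3)
  # drop triangles with repeated vertices or (numerically) zero area
  if (nrow(triangles) > 0) {
    dup <- triangles[, 1] == triangles[, 2] | triangles[, 1] == triangles[, 3] |
      triangles[, 2] == triangles[, 3]
    a <- vertices[triangles[, 1], , drop = FALSE]
    e1 <- vertices[triangles[, 2], , drop = FALSE] - a
    e2 <- vertices[triangles[, 3], , drop = FALSE] - a
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    area2 <- cx^2 + cy^2 + cz^2
    keep <- !dup & area2 > (tol^2)
    triangles <- triangles[keep, , drop = FALSE]
  }
  storage.mode(triangles) <- "integer"
  list(vertices = vertices, triangles = triangles)
}

# Every undirected edge must border exactly two triangles.
is_watertight <- function(triangles) {
  if (nrow(triangles) == 0) return(FALSE)
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> '%s': %d vertices, %d triangles%s\n",
              x$region_tag, nrow(x$vertices), nrow(x$triangles),
              if (isTRUE(x$watertight)) ", watertight" else " (NOT watertight)"))
  invisible(x)
}

surface_bbox <- function(mesh) {
  rbind(apply(mesh$vertices, 2, min), apply(mesh$vertices, 2, max))
}

#' Read a surface from an STL file
#'
#' Accepts binary and ASCII STL. Vertices are deduplicated within `1e-6` mm;
#' triangle winding is preserved. A non-manifold surface is flagged via the
#' `watertight` field (with a warning), not rejected.
#'
#' @param path STL file path.
#' @param region_tag region label to attach.
#' @return a [surface_mesh()].
#' @export
read_surface <- function(path, region_tag = "surface") {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("unreadable or empty STL file: ", path)
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(sz, 512))
  close(con)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    !any(head == as.raw(0)) &&
    grepl("facet", rawToChar(head), fixed = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, sz)
  if (nrow(tri) == 0) stop("STL file contains no triangles: ", path)
  verts <- tri
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  mesh <- surface_mesh(verts, faces, region_tag = region_tag, clean = TRUE)
  if (!mesh$watertight)
    warning("surface '", region_tag, "' from ", basename(path),
            " is not watertight")
  mesh
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ASCII STL: ", path)
  nums <- vapply(strsplit(trimws(vl), "\\s+"), function(f)
    as.numeric(f[2:4]), numeric(3))
  t(nums)
}

read_stl_binary <- function(path, sz) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(nt) || nt < 0 || 84 + nt * 50 > sz + 2)
    stop("malformed binary STL: ", path)
  out <- matrix(0, nrow = 3 * nt, ncol = 3)
  for (t in seq_len(nt)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "raw", n = 2)
    out[(3 * t - 2):(3 * t), ] <- matrix(rec[4:12], ncol = 3, byrow = TRUE)
  }
  out
}

#' Write a surface to an STL file
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param binary write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$triangles
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(formatC("morphforge", width = -80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (t in seq_len(nrow(f))) {
      rec <- c(n[t, ], v[f[t, 1], ], v[f[t, 2], ], v[f[t, 3], ])
      writeBin(rec, con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$region_tag), con)
    for (t in seq_len(nrow(f))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g",
                           n[t, 1], n[t, 2], n[t, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           v[f[t, ], 1], v[f[t, ], 2], v[f[t, ], 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", mesh$region_tag), con)
  }
  invisible(path)
}
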