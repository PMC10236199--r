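test_that("warp_image with zero and constant one-voxel fields", {
  arr <- array(0L, c(6, 6, 6))
  arr[3:4, 3:4, 3:4] <- 1L
  img <- label_image(arr, spacing = c(2, 2, 2))

  z <- constant_field(c(6L, 6L, 6L), c(2, 2, 2), c(0, 0, 0), c(0, 0, 0))
  expect_identical(warp_image(img, z)$data, img$data)

  sh <- constant_field(c(6L, 6L, 6L), c(2, 2, 2), c(0, 0, 0), c(2, 0, 0))
  w <- warp_image(img, sh)  # out(x) = img(x + 1 voxel): shifted down in x
  expect_identical(w$data[2:5, , ], img$data[3:6, , ])
})

test_that("dice matches hand counts, is symmetric, and rejects empty sets", {
  a <- label_image(array(0L, c(20, 20, 20)))
  a$data[1:10, 1:10, 1:10] <- 1L       # 1000 voxels
  b <- label_image(array(0L, c(20, 20, 20)))
  b$data[6:15, 1:10, 1:10] <- 1L       # 1000 voxels, 500 shared
  expect_equal(dice(a, b, labels = 1), 0.5)
  expect_equal(dice(a, b, labels = 1), brute_dice(a, b, 1))
  expect_equal(dice(a, a, labels = 1), 1.0)

  disj <- label_image(array(0L, c(20, 20, 20)))
  disj$data[15:18, 15:18, 15:18] <- 1L
  expect_equal(dice(a, disj, labels = 1), 0.0)

  empty <- label_image(array(0L, c(20, 20, 20)))
  expect_error(dice(empty, empty, labels = 1), "empty")
})

test_that("flesh label set is body minus skeleton in each image", {
  a <- label_image(array(0L, c(8, 8, 8)))
  a$data[2:6, 2:6, 2:6] <- 1L
  a$data[3:4, 3:4, 3:4] <- 2L
  b <- a
  b$data[5, 5, 5] <- 2L  # extra skeleton voxel removes it from b's flesh
  d_flesh <- dice(a, b, labels = "flesh")
  na <- sum(a$data == 1L); nb <- sum(b$data == 1L)
  expect_equal(d_flesh, 2 * nb / (na + nb))  # intersection = b's flesh
  expect_equal(dice(a, b, "flesh"), dice(b, a, "flesh"))
  expect_equal(dice(a, b, "body"), 1.0)
})

test_that("hausdorff: identical masks, single-voxel pairs, spacing scaling", {
  a <- label_image(array(0L, c(10, 10, 10)), spacing = c(2, 2, 2))
  a$data[4:6, 4:6, 4:6] <- 1L
  expect_equal(unname(hausdorff(a, a, labels = 1)), c(0, 0))

  p <- label_image(array(0L, c(10, 10, 10)), spacing = c(2, 2, 2))
  q <- p
  p$data[2, 2, 2] <- 1L
  q$data[5, 2, 2] <- 1L  # 3 voxels apart, 2 mm spacing
  h <- hausdorff(p, q, labels = 1)
  expect_equal(unname(h), c(6, 6))

  # linear scaling with spacing
  p2 <- label_image(p$data, spacing = c(1, 1, 1))
  q2 <- label_image(q$data, spacing = c(1, 1, 1))
  expect_equal(unname(hausdorff(p2, q2, labels = 1)), c(3, 3))
  expect_error(hausdorff(p, label_image(array(0L, c(10, 10, 10)),
                                        spacing = c(2, 2, 2)), labels = 1),
               "empty")
})

test_that("dice and hausdorff equal brute-force oracles on random images", {
  set.seed(7)
  for (rep in 1:8) {
    sp <- sample(c(1, 1.5, 2), 3, replace = TRUE)
    a <- random_label_image(c(10L, 9L, 11L), spacing = sp)
    b <- random_label_image(c(10L, 9L, 11L), spacing = sp)
    for (lab in list(1, 2)) {
      expect_equal(dice(a, b, labels = lab[[1]]),
                   brute_dice(a, b, lab[[1]]))
      h <- hausdorff(a, b, percentile = 95, labels = lab[[1]])
      hb <- brute_hausdorff(a, b, 95, lab[[1]])
      expect_equal(unname(h), unname(hb), tolerance = 1e-12)
      expect_lte(h[2], h[1])  # HD95 <= HD
    }
  }
})

test_that("surface distance maps: identity, concentric spheres, offset plane", {
  s <- morphforge:::ellipsoid_mesh(c(0, 0, 0), c(50, 50, 50), 24, 48)
  expect_true(all(surface_distance_map(s, s) < 1e-9))

  s52 <- morphforge:::ellipsoid_mesh(c(0, 0, 0), c(52, 52, 52), 24, 48)
  dmap <- surface_distance_map(s52, s)
  expect_true(all(abs(dmap - 2) < 0.25))  # 2 mm offset, chord error bounded

  # plane patch translated 3 mm along its normal
  g <- expand.grid(x = 0:5, y = 0:5)
  v <- cbind(g$x * 10, g$y * 10, 0)
  f <- NULL
  for (j in 0:4) for (i in 0:4) {
    a <- j * 6 + i + 1
    f <- rbind(f, c(a, a + 1, a + 6), c(a + 1, a + 7, a + 6))
  }
  plane <- surface_mesh(v, f, clean = FALSE)
  lifted <- plane
  lifted$vertices[, 3] <- 3
  expect_equal(surface_distance_map(lifted, plane),
               rep(3, nrow(v)), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("hex quality: unit cube, rectangular box, sheared determinant oracle", {
  cube <- single_hex_mesh(unit_hex_points)
  q <- element_quality(cube)
  expect_equal(q$elements$scaled_jacobian, 1.0)
  expect_equal(q$elements$aspect_ratio, 1.0)
  expect_equal(q$elements$min_edge, 1.0)

  box <- single_hex_mesh(unit_hex_points %*% diag(c(2, 1, 1)))
  qb <- element_quality(box)
  expect_equal(qb$elements$scaled_jacobian, 1.0)
  expect_equal(qb$elements$aspect_ratio, 2.0)
  expect_equal(qb$elements$min_edge, 1.0)

  # shear the top face by 0.5 in x and check corner determinants directly
  pts <- unit_hex_points
  pts[5:8, 1] <- pts[5:8, 1] + 0.5
  qs <- element_quality(single_hex_mesh(pts))
  corner_edges <- morphforge:::hex_corner_edges
  oracle <- Inf
  for (r in 1:8) {
    k <- corner_edges[r, 1]
    e <- sapply(corner_edges[r, 2:4], function(m) pts[m, ] - pts[k, ])
    oracle <- min(oracle, det(e) / prod(sqrt(colSums(e^2))))
  }
  expect_equal(qs$elements$scaled_jacobian, oracle, tolerance = 1e-12)
  expect_lt(qs$elements$scaled_jacobian, 1)
})

test_that("tet quality is 1 for the regular tetrahedron, volume-scaled otherwise", {
  reg <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  tet <- fe_mesh(node_ids = 1:4, nodes = reg,
                 solids = matrix(c(1L, 1L, 1L, 2L, 3L, 4L, 4L, 4L, 4L, 4L),
                                 nrow = 1))
  q <- element_quality(tet)
  expect_equal(q$elements$type, "tet")
  expect_equal(abs(q$elements$scaled_jacobian), 1, tolerance = 1e-12)

  flat <- reg
  flat[4, ] <- flat[4, ] * 0.2  # squashed
  qf <- element_quality(fe_mesh(node_ids = 1:4, nodes = flat,
                                solids = matrix(c(1L, 1L, 1L, 2L, 3L, 4L,
                                                  4L, 4L, 4L, 4L), nrow = 1)))
  expect_lt(abs(qf$elements$scaled_jacobian), 1)
})

test_that("element quality is invariant under rigid motion", {
  ph <- make_phantom(phantom_spec(mesh_resolution = 10))
  mesh <- ph$mesh
  q0 <- element_quality(mesh)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  phi <- 0.3
  R2 <- rbind(c(1, 0, 0), c(0, cos(phi), -sin(phi)), c(0, sin(phi), cos(phi)))
  moved <- mesh
  moved$nodes <- sweep(mesh$nodes %*% t(R2 %*% R), 2, c(13.2, -7.1, 4.4), "+")
  q1 <- element_quality(moved)
  expect_equal(q1$elements$scaled_jacobian, q0$elements$scaled_jacobian,
               tolerance = 1e-9)
  expect_equal(q1$elements$aspect_ratio, q0$elements$aspect_ratio,
               tolerance = 1e-9)
  expect_equal(q1$elements$min_edge, q0$elements$min_edge, tolerance = 1e-9)
})

test_that("degenerate elements are flagged and counted, not crashed on", {
  pts <- unit_hex_points
  pts[2, ] <- pts[1, ]  # zero edge
  q <- element_quality(single_hex_mesh(pts))
  expect_equal(q$degenerate_count, 1L)
  expect_true(is.na(q$elements$aspect_ratio))
})

test_that("contact intersections: separated, overlapping (oracle), touching", {
  a <- block_fe_mesh(2, 2, 2, origin = c(0, 0, 0), pid = 1L)
  b <- block_fe_mesh(2, 2, 2, origin = c(5, 0, 0), pid = 2L,
                     id_offset = 1000L)
  two <- fe_mesh(node_ids = c(a$node_ids, b$node_ids),
                 nodes = rbind(a$nodes, b$nodes),
                 solids = rbind(a$solids, b$solids),
                 contact_pairs = matrix(c(1L, 2L), ncol = 2))
  expect_equal(count_contact_intersections(two)$count, 0L)

  # overlap by 0.1: count must equal the brute-force all-pairs oracle
  b2 <- block_fe_mesh(2, 2, 2, origin = c(1.9, 0.15, 0.1), pid = 2L,
                      id_offset = 1000L)
  both <- fe_mesh(node_ids = c(a$node_ids, b2$node_ids),
                  nodes = rbind(a$nodes, b2$nodes),
                  solids = rbind(a$solids, b2$solids),
                  contact_pairs = matrix(c(1L, 2L), ncol = 2))
  got <- count_contact_intersections(both)
  sa <- morphforge:::part_boundary_triangles(both, 1L)
  sb <- morphforge:::part_boundary_triangles(both, 2L)
  oracle <- brute_intersection_count(sa$vertices, sa$triangles,
                                     sb$vertices, sb$triangles)
  expect_gt(got$count, 0L)
  expect_equal(got$count, oracle)
  # deterministic, ordered report
  expect_false(is.unsorted(got$pairs$eid_a))

  # exact face-to-face touching is not an intersection
  b3 <- block_fe_mesh(2, 2, 2, origin = c(2, 0, 0), pid = 2L,
                      id_offset = 1000L)
  touch <- fe_mesh(node_ids = c(a$node_ids, b3$node_ids),
                   nodes = rbind(a$nodes, b3$nodes),
                   solids = rbind(a$solids, b3$solids),
                   contact_pairs = matrix(c(1L, 2L), ncol = 2))
  expect_equal(count_contact_intersections(touch)$count, 0L)
})
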