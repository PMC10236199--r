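test_that("compute_grid covers the padded bounding box with ceil(extent/voxel)", {
  cube <- box_surface(c(0, 0, 0), c(1000, 1000, 1000))
  g0 <- compute_grid(cube, 10, padding = 0)
  expect_identical(dim(g0$data), c(100L, 100L, 100L))
  expect_equal(g0$origin, c(5, 5, 5))

  g1 <- compute_grid(cube, 10, padding = 20)
  expect_identical(dim(g1$data), c(104L, 104L, 104L))
  expect_equal(g1$origin, c(-15, -15, -15))

  expect_error(compute_grid(list(), 2), "at least one")
  expect_error(compute_grid(cube, 0), "voxel_size")
})

test_that("compute_grid unions disjoint surfaces (brute-force bbox oracle)", {
  s1 <- morphforge:::ellipsoid_mesh(c(-40, 0, 0), c(10, 10, 10), 12, 24)
  s2 <- morphforge:::ellipsoid_mesh(c(35, 5, -8), c(12, 12, 12), 12, 24)
  pad <- 7
  g <- compute_grid(list(s1, s2), 2, padding = pad)
  allv <- rbind(s1$vertices, s2$vertices)
  lo <- apply(allv, 2, min) - pad
  hi <- apply(allv, 2, max) + pad
  expect_equal(g$origin, lo + 1)             # half-voxel inset
  d <- dim(g$data)
  expect_true(all(g$origin + (d - 1) * 2 + 1 >= hi - 1e-9))
  expect_identical(d, as.integer(ceiling((hi - lo) / 2 - 1e-9)))
})

test_that("voxelized sphere volume matches the analytic volume within 2%", {
  sph <- morphforge:::ellipsoid_mesh(c(0, 0, 0), c(50, 50, 50), 24, 48)
  g <- compute_grid(sph, 2, padding = 4)
  m <- voxelize_binary(sph, g)
  vol <- sum(m$data) * prod(m$spacing)
  expect_lt(abs(vol - 4 / 3 * pi * 50^3) / (4 / 3 * pi * 50^3), 0.02)
})

test_that("voxelized volume error decreases monotonically with resolution", {
  sph <- morphforge:::ellipsoid_mesh(c(0, 0, 0), c(30, 30, 30), 24, 48)
  # exact volume of the tessellated solid (divergence theorem over triangles)
  vol_exact <- sum(sapply(seq_len(nrow(sph$triangles)), function(t)
    det(sph$vertices[sph$triangles[t, ], ]) / 6))
  errs <- sapply(c(5, 2.5, 1.25), function(vox) {
    g <- compute_grid(sph, vox, padding = 2 * vox)
    abs(sum(voxelize_binary(sph, g)$data) * vox^3 - vol_exact)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("inside test is center-based: cube center in, corner exterior out", {
  cube <- box_surface(c(0, 0, 0), c(10, 10, 10))
  g <- compute_grid(cube, 2, padding = 4)
  m <- voxelize_binary(cube, g)
  ctr_idx <- round(world_to_index(m, c(5, 5, 5)))
  expect_equal(m$data[ctr_idx[1], ctr_idx[2], ctr_idx[3]], 1L)
  out_idx <- round(world_to_index(m, c(-3, -3, -3)))
  expect_equal(m$data[out_idx[1], out_idx[2], out_idx[3]], 0L)
  # grid not covering the surface is a coverage error
  small <- label_image(array(0L, c(3, 3, 3)), spacing = 1, origin = c(4, 4, 4))
  expect_error(voxelize_binary(cube, small), "cover")
})

test_that("nested spheres: outer mask contains the inner mask", {
  inner <- morphforge:::ellipsoid_mesh(c(0, 0, 0), c(25, 25, 25), 16, 32)
  outer <- morphforge:::ellipsoid_mesh(c(0, 0, 0), c(50, 50, 50), 16, 32)
  g <- compute_grid(outer, 2, padding = 4)
  mi <- voxelize_binary(inner, g)
  mo <- voxelize_binary(outer, g)
  expect_true(all(mo$data[mi$data == 1L] == 1L))
})

test_that("compose_labels gives skeleton precedence and partitions all voxels", {
  d <- c(4L, 4L, 4L)
  flesh <- label_image(array(1L, d))
  skel <- label_image(array(0L, d))
  skel$data[2, 2, 2] <- 1L
  lab <- compose_labels(flesh, skel)
  expect_equal(lab$data[2, 2, 2], 2L)
  expect_equal(sum(lab$data == 1L), prod(d) - 1L)

  # skeleton outside flesh still wins
  flesh2 <- label_image(array(0L, d))
  lab2 <- compose_labels(flesh2, skel)
  expect_equal(lab2$data[2, 2, 2], 2L)
  expect_equal(sum(lab2$data == 0L), prod(d) - 1L)

  # label partition always holds
  expect_equal(sum(lab$data == 0L) + sum(lab$data == 1L) +
                 sum(lab$data == 2L), prod(d))
  expect_error(compose_labels(flesh,
                              label_image(array(0L, c(5L, 4L, 4L)))),
               "grid mismatch")
})

test_that("phantom label-2 voxels equal the skeleton mask (mask algebra)", {
  ph <- make_phantom(phantom_spec())
  g <- compute_grid(ph$surfaces, 2.5, padding = 5)
  lab <- voxelize_surfaces(ph$surfaces, g)
  skel <- morphforge:::union_masks(list(
    voxelize_binary(ph$surfaces$skeleton, g),
    voxelize_binary(ph$surfaces$skull, g)))
  expect_equal(sum(lab$data == 2L), sum(skel$data == 1L))
})

test_that("voxelization is equivariant under joint rigid translation", {
  sph <- morphforge:::ellipsoid_mesh(c(0, 0, 0), c(21, 17, 25), 16, 32)
  g <- compute_grid(sph, 2, padding = 5)
  m0 <- voxelize_binary(sph, g)
  t <- c(13.7, -4.2, 8.9)
  sph2 <- sph
  sph2$vertices <- sweep(sph2$vertices, 2, t, "+")
  g2 <- label_image(g$data, spacing = g$spacing, origin = g$origin + t)
  m1 <- voxelize_binary(sph2, g2)
  expect_identical(m0$data, m1$data)
})

test_that("non-watertight surfaces fall back to the winding-number test", {
  cube <- box_surface(c(0, 0, 0), c(10, 10, 10))
  holed <- surface_mesh(cube$vertices, cube$triangles[-1, , drop = FALSE],
                        clean = FALSE)
  g <- compute_grid(cube, 2, padding = 2)
  expect_warning(m <- voxelize_binary(holed, g), "winding")
  # one missing facet barely changes the classified volume
  full <- voxelize_binary(cube, g)
  expect_gt(sum(m$data) / sum(full$data), 0.9)
})
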