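test_that("phantoms are deterministic per seed and watertight", {
  a <- make_phantom(phantom_spec(seed = 11))
  b <- make_phantom(phantom_spec(seed = 11))
  expect_identical(a$surfaces, b$surfaces)
  expect_identical(a$mesh, b$mesh)
  c <- make_phantom(phantom_spec(seed = 12))
  expect_false(identical(a$surfaces$skin$vertices, c$surfaces$skin$vertices))
  for (s in a$surfaces) expect_true(s$watertight)
})

test_that("an oversized skeleton is rejected by the spec validator", {
  expect_error(phantom_spec(spine_radius = 40), "spine")
  expect_error(phantom_spec(skull_radius = 30), "skull")
  expect_error(phantom_spec(height = -5), "height")
})

test_that("voxelized phantom volume matches the closed-form volume within 3%", {
  spec <- phantom_spec()
  ph <- make_phantom(spec)
  g <- compute_grid(ph$surfaces, 1.5, padding = 4)
  lab <- voxelize_surfaces(ph$surfaces, g)
  vol <- phantom_analytic_volume(spec)
  got_flesh <- sum(lab$data > 0) * prod(lab$spacing)
  expect_lt(abs(got_flesh - vol["flesh"]) / vol["flesh"], 0.03)
  got_skel <- sum(lab$data == 2L) * prod(lab$spacing)
  expect_lt(abs(got_skel - vol["skeleton"]) / vol["skeleton"], 0.05)
})

test_that("the structured block mesh is an ideal hexahedral mesh", {
  ph <- make_phantom(phantom_spec())
  q <- element_quality(ph$mesh)
  expect_true(all(q$elements$scaled_jacobian == 1))
  expect_true(all(q$elements$aspect_ratio == 1))
  expect_equal(unique(q$elements$min_edge), ph$spec$mesh_resolution)
  expect_setequal(unique(q$elements$pid), c(1L, 2L))
  expect_equal(unname(ph$mesh$contact_pairs[1, ]), c(1L, 2L))
  # conforming interface: baseline mesh has no contact intersections
  expect_equal(count_contact_intersections(ph$mesh)$count, 0L)
})

test_that("analytic deformations behave as designed", {
  ph <- make_phantom(phantom_spec(height = 160))
  # identity
  d0 <- deform_phantom(ph, deform_uniform_scale(1.0))
  expect_equal(d0$mesh$nodes, ph$mesh$nodes, tolerance = 1e-12)

  # axis scale 178/160 on a 160-tall phantom gives a 178-tall one
  dz <- deform_phantom(ph, deform_axis_scale(1, 1, 178 / 160))
  zr <- range(dz$surfaces$skin$vertices[, 3], dz$surfaces$head$vertices[, 3])
  zr0 <- range(ph$surfaces$skin$vertices[, 3], ph$surfaces$head$vertices[, 3])
  expect_equal(diff(zr), diff(zr0) * 178 / 160, tolerance = 1e-9)

  # belly bulge: max radial surface displacement equals the amplitude at the
  # bulge center (which sits on the torso surface)
  spec <- ph$spec
  ctr <- c(0, spec$body$semiaxes[2], 0)
  defo <- deform_belly_bulge(20, 30, ctr)
  db <- deform_phantom(ph, defo)
  disp <- sqrt(rowSums((db$surfaces$skin$vertices -
                          ph$surfaces$skin$vertices)^2))
  expect_lte(max(disp), 20 + 1e-9)
  expect_gt(max(disp), 19)  # a vertex close to the center reaches ~A
  # bend leaves y untouched and is invertible numerically
  bd <- deform_bend(0.3, c(-60, 60))
  expect_equal(bd$map(ph$mesh$nodes)[, 2], ph$mesh$nodes[, 2])
})

test_that("numeric inverses undo every supported deformation to 1e-6 mm", {
  ph <- make_phantom(phantom_spec())
  pts <- ph$surfaces$skin$vertices[seq(1, 1000, by = 17), ]
  defs <- list(deform_none(),
               deform_uniform_scale(1.15, c(1, 2, 3)),
               deform_axis_scale(0.9, 1.1, 1.2),
               deform_belly_bulge(10, 25, c(0, 32, 0)),
               deform_bend(0.25, c(-40, 40)))
  for (d in defs) {
    back <- d$inverse(d$map(pts))
    expect_lt(max(abs(back - pts)), 1e-6)
  }
})

test_that("rasterized ground-truth fields agree with the point map", {
  g <- label_image(array(0L, c(6L, 5L, 4L)), spacing = c(3, 3, 3),
                   origin = c(-10, 0, 5))
  defo <- deform_axis_scale(1.2, 0.9, 1.05, center = c(1, 1, 1))
  u <- rasterize_deformation(defo, g)
  ctr <- voxel_centers(g)
  expect_equal(ctr + cbind(as.vector(u$data[, , , 1]),
                           as.vector(u$data[, , , 2]),
                           as.vector(u$data[, , , 3])),
               defo$map(ctr), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("including the skeleton improves skeleton recovery over skin-only", {
  # soft-tissue-only change: belly bulge with the skeleton held fixed
  base <- make_phantom(phantom_spec())
  spec <- base$spec
  subj <- deform_phantom(base,
                         deform_belly_bulge(10, 25,
                                            c(0, spec$body$semiaxes[2], 0)),
                         apply_to = "flesh_only")
  run <- function(skin_only) {
    run_pipeline(pipeline_config(base$surfaces, base$mesh, subj$surfaces,
                                 type = "I", skin_only = skin_only))
  }
  with_skel <- run(FALSE)
  skin_only <- run(TRUE)
  skel_nodes <- unique(as.vector(
    base$mesh$solids[base$mesh$solids[, 2] == 2L, 3:10]))
  sel <- base$mesh$node_ids %in% skel_nodes
  truth <- subj$mesh$nodes  # skeleton nodes did not move
  err_with <- mean(sqrt(rowSums(
    (with_skel$mesh$nodes[sel, ] - truth[sel, ])^2)))
  err_skin <- mean(sqrt(rowSums(
    (skin_only$mesh$nodes[sel, ] - truth[sel, ])^2)))
  expect_lt(err_with, err_skin)
})
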