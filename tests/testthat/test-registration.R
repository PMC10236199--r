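# One moderately sized phantom registration is shared by several property
# tests; it is computed lazily and cached for the file.
local({
  cache <- new.env(parent = emptyenv())
  phantom_pair <<- function() {
    if (is.null(cache$pair)) {
      ph <- make_phantom(phantom_spec())
      g <- compute_grid(ph$surfaces, 2, padding = 12)
      fixed <- voxelize_surfaces(ph$surfaces, g)
      defo <- deform_axis_scale(1, 1, 1.1)
      ph2 <- deform_phantom(ph, defo, "all")
      moving <- voxelize_surfaces(ph2$surfaces, g)
      cache$pair <- list(fixed = fixed, moving = moving, defo = defo,
                         field = demons_register(fixed, moving))
    }
    cache$pair
  }
})

test_that("rigid_align recovers a pure translation and the identity", {
  ph <- make_phantom(phantom_spec(surface_segments = 24L))
  g <- compute_grid(ph$surfaces, 2, padding = 16)
  fixed <- voxelize_surfaces(ph$surfaces, g)
  ph2 <- ph
  for (nm in names(ph2$surfaces))
    ph2$surfaces[[nm]]$vertices <-
      sweep(ph2$surfaces[[nm]]$vertices, 2, c(10, 0, 0), "+")
  moving <- voxelize_surfaces(ph2$surfaces, g)
  tf <- rigid_align(fixed, moving)
  expect_equal(tf$A, diag(3))
  expect_lt(max(abs(tf$t - c(10, 0, 0))), 0.5 * 2)  # < 0.5 voxel

  tf0 <- rigid_align(fixed, fixed)
  expect_equal(tf0$t, c(0, 0, 0), tolerance = 1e-9)

  empty <- label_image(array(0L, c(4, 4, 4)))
  expect_error(rigid_align(empty, fixed), "empty")
})

test_that("principal-axes mode recovers a 90-degree rotation (moments oracle)", {
  # elongated box: unambiguous principal axes up to sign
  bx <- box_surface(c(-40, -10, -16), c(40, 10, 16))
  g <- compute_grid(bx, 2, padding = 30)
  fixed <- voxelize_binary(bx, g)
  # rotate 90 degrees about z: (x, y) -> (-y, x)
  bx2 <- bx
  bx2$vertices <- cbind(-bx$vertices[, 2], bx$vertices[, 1],
                        bx$vertices[, 3])
  moving <- surface_mesh(bx2$vertices, bx2$triangles, clean = FALSE)
  gm <- compute_grid(moving, 2, padding = 30)
  moving_img <- voxelize_binary(moving, gm)
  tf <- rigid_align(fixed, moving_img, rotation = "axes")
  # the recovered rotation must map the fixed long axis (x) onto the moving
  # long axis (y), up to sign
  expect_equal(abs(tf$A[, 1]), c(0, 1, 0), tolerance = 0.05)
  # and realigning the moving image must recover the fixed image well
  realigned <- resample_image(moving_img, tf, fixed)
  expect_gt(brute_dice(realigned, fixed, 1), 0.97)
})

test_that("registering an image to itself returns a (near-)zero field", {
  p <- phantom_pair()
  u0 <- demons_register(p$fixed, p$fixed)
  mags <- morphforge:::field_magnitude(u0)
  expect_lt(mean(mags) / min(u0$spacing), 0.1)
})

test_that("demons recovers a known pure translation in the body interior", {
  ph <- make_phantom(phantom_spec())
  g <- compute_grid(ph$surfaces, 2, padding = 12)
  fixed <- voxelize_surfaces(ph$surfaces, g)
  ph2 <- ph
  for (nm in names(ph2$surfaces))
    ph2$surfaces[[nm]]$vertices <-
      sweep(ph2$surfaces[[nm]]$vertices, 2, c(6, 0, 0), "+")
  moving <- voxelize_surfaces(ph2$surfaces, g)  # 3 voxels along x
  u <- demons_register(fixed, moving)
  fg <- fixed$data > 0
  interior <- fg & !morphforge:::boundary_mask(fg)
  err <- sqrt((u$data[, , , 1][interior] - 6)^2 +
                u$data[, , , 2][interior]^2 +
                u$data[, , , 3][interior]^2)
  expect_lt(mean(err) / 2, 0.5)  # mean error < 0.5 voxel
})

test_that("sphere-to-sphere field points radially outward and overlaps well", {
  s40 <- morphforge:::ellipsoid_mesh(c(0, 0, 0), c(40, 40, 40), 32, 64)
  s50 <- morphforge:::ellipsoid_mesh(c(0, 0, 0), c(50, 50, 50), 32, 64)
  g <- compute_grid(list(s40, s50), 1, padding = 6)
  fixed <- compose_labels(voxelize_binary(s40, g))
  moving <- compose_labels(voxelize_binary(s50, g))
  u <- demons_register(fixed, moving,
                       registration_config(iterations = c(80L, 40L, 8L)))
  # outward on the fixed sphere's surface band
  bm <- morphforge:::boundary_mask(fixed$data > 0)
  ctr <- voxel_centers(fixed)[as.vector(bm), ]
  uu <- cbind(u$data[, , , 1][bm], u$data[, , , 2][bm], u$data[, , , 3][bm])
  proj <- rowSums(uu * ctr / sqrt(rowSums(ctr^2)))
  expect_true(all(proj > 0))
  # warped moving against fixed
  d <- dim(fixed$data)
  wm <- array(morphforge:::cpp_warp_scalar(
    as.numeric(moving$data), as.integer(d), fixed$spacing,
    as.numeric(u$data), 0L, 0), dim = d)
  dice_fg <- 2 * sum(wm == 1 & fixed$data == 1) /
    (sum(wm == 1) + sum(fixed$data == 1))
  expect_gte(dice_fg, 0.98)
})

test_that("demons errors on mismatched grids", {
  a <- label_image(array(0L, c(6, 6, 6)))
  b <- label_image(array(0L, c(6, 6, 7)))
  expect_error(demons_register(a, b), "grid mismatch")
})

test_that("field inversion: zero, constant translation, sinusoid residual", {
  d <- c(12L, 12L, 12L)
  z <- constant_field(d, c(1, 1, 1), c(0, 0, 0), c(0, 0, 0))
  iz <- invert_field(z)
  expect_equal(max(abs(iz$data)), 0)

  t <- constant_field(d, c(2, 2, 2), c(0, 0, 0), c(3, -1, 2))
  it <- invert_field(t)
  expect_equal(it$data[, , , 1], -t$data[, , , 1], tolerance = 1e-9)
  expect_equal(it$data[, , , 2], -t$data[, , , 2], tolerance = 1e-9)

  # smooth sinusoidal field, amplitude 2 voxels
  dd <- c(24L, 24L, 24L)
  arr <- array(0, dim = c(dd, 3))
  ctr <- voxel_centers(label_image(array(0L, dd)))
  arr[, , , 1] <- array(2 * sin(2 * pi * ctr[, 1] / 24) *
                          sin(2 * pi * ctr[, 2] / 24), dim = dd)
  arr[, , , 3] <- array(2 * cos(2 * pi * ctr[, 3] / 24) *
                          sin(2 * pi * ctr[, 1] / 24), dim = dd)
  u <- displacement_field(arr, spacing = c(1, 1, 1))
  v <- invert_field(u, tol = 1e-4, max_iter = 100L)
  res <- attr(v, "residual")
  expect_lt(res["mean"], 0.1)  # voxels (spacing 1)
})

test_that("scaling transform elongates by 178/160 and round-trips", {
  tf <- make_scaling_transform(c(1, 1, 178 / 160), center = c(0, 0, 0))
  pts <- rbind(c(5, 5, 0), c(5, 5, 160))
  out <- apply_transform(tf, pts)
  expect_equal(out[2, 3] - out[1, 3], 178)
  expect_equal(out[, 1:2], pts[, 1:2], ignore_attr = TRUE)

  id <- make_scaling_transform(c(1, 1, 1))
  expect_equal(apply_transform(id, pts), pts, ignore_attr = TRUE)

  inv <- make_scaling_transform(c(1, 1, 160 / 178), center = c(0, 0, 0))
  back <- apply_transform(inv, apply_transform(tf, pts))
  expect_equal(back, pts, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(make_scaling_transform(c(1, 0, 1)), "positive")
})

test_that("returned fields are diffeomorphic and consistently invertible", {
  p <- phantom_pair()
  jd <- warp_jacobian(p$field)
  d <- dim(jd)
  interior <- jd[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  expect_true(all(interior > 0))

  v <- invert_field(p$field)
  expect_lt(attr(v, "residual")["mean"] / min(p$field$spacing), 0.2)
})

test_that("foreground DICE is non-decreasing across pyramid levels", {
  p <- phantom_pair()
  log <- attr(p$field, "level_log")
  expect_true(all(diff(log$dice_foreground) > -1e-6))
})

test_that("larger smooth factors never increase the max field gradient", {
  p <- phantom_pair()
  maxgrad <- function(u) {
    d <- dim(u$data)[1:3]
    g2 <- array(0, d)
    for (c in 1:3) {
      a <- u$data[, , , c]
      gx <- (a[c(2:d[1], d[1]), , ] - a[c(1, 1:(d[1] - 1)), , ]) /
        (2 * u$spacing[1])
      gy <- (a[, c(2:d[2], d[2]), ] - a[, c(1, 1:(d[2] - 1)), ]) /
        (2 * u$spacing[2])
      gz <- (a[, , c(2:d[3], d[3])] - a[, , c(1, 1:(d[3] - 1))]) /
        (2 * u$spacing[3])
      g2 <- g2 + gx^2 + gy^2 + gz^2
    }
    max(sqrt(g2))
  }
  grads <- sapply(c(1, 2, 4), function(sig)
    maxgrad(demons_register(p$fixed, p$moving,
                            registration_config(smooth_factor = sig))))
  expect_true(all(diff(grads) <= 1e-9))
})

test_that("demons recovers an axis scaling against the analytic field", {
  p <- phantom_pair()
  truth <- rasterize_deformation(p$defo, p$fixed)
  fg <- p$fixed$data > 0
  interior <- fg & !morphforge:::boundary_mask(fg)
  du <- p$field$data - truth$data
  err <- sqrt(du[, , , 1]^2 + du[, , , 2]^2 + du[, , , 3]^2)
  expect_lt(mean(err[interior]) / 2, 0.5)
})
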