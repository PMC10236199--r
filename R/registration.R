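#' Demons registration settings
#'
#' `smooth_factor` is the standard deviation (in voxels) of the Gaussian
#' applied to the accumulated displacement field after every iteration
#' (diffusion-like regularization); 2 is the working default for whole-body
#' label images. `sigma_fluid` smooths each iteration's update before it is
#' exponentiated (fluid-like regularization). The coarse-to-fine pyramid is
#' given as integer shrink factors with a matching iteration budget per
#' level; iteration stops early once the mean update magnitude drops below
#' `tol` voxels. `presmooth` is the Gaussian (voxels) applied to the binary
#' labels so that they carry usable gradients.
#'
#' @param smooth_factor Gaussian sigma (voxels) for the accumulated field.
#' @param pyramid integer shrink factors, coarse to fine.
#' @param iterations iterations per pyramid level (same length as `pyramid`).
#' @param tol convergence tolerance on the mean update magnitude (voxels).
#' @param sigma_fluid Gaussian sigma (voxels) for the per-iteration update.
#' @param max_step per-iteration step cap (voxels).
#' @param presmooth label pre-smoothing sigma (voxels).
#' @return an object of class `registration_config`.
#' @export
registration_config <- function(smooth_factor = 2, pyramid = c(4L, 2L, 1L),
                                iterations = c(100L, 50L, 25L), tol = 0.01,
                                sigma_fluid = 1, max_step = 2,
                                presmooth = 0.5) {
  if (smooth_factor < 0) stop("`smooth_factor` must be >= 0")
  pyramid <- as.integer(pyramid)
  iterations <- as.integer(iterations)
  if (length(pyramid) != length(iterations))
    stop("`pyramid` and `iterations` must have equal length")
  if (any(pyramid < 1L)) stop("pyramid shrink factors must be >= 1")
  if (any(iterations < 1L)) stop("iterations must be > 0")
  structure(list(smooth_factor = smooth_factor, pyramid = pyramid,
                 iterations = iterations, tol = tol,
                 sigma_fluid = sigma_fluid, max_step = max_step,
                 presmooth = presmooth),
            class = "registration_config")
}

#' @export
print.registration_config <- function(x, ...) {
  cat(sprintf(
    "<registration_config> smooth %g vox, pyramid {%s} x {%s} iters, tol %g vox\n",
    x$smooth_factor, paste(x$pyramid, collapse = ","),
    paste(x$iterations, collapse = ","), x$tol))
  invisible(x)
}

foreground_centroid <- function(img) {
  fg <- img$data > 0
  if (!any(fg)) stop("image has an empty foreground")
  w <- which(fg)
  d <- grid_dims(img)
  ijk <- cbind((w - 1) %% d[1],
               ((w - 1) %/% d[1]) %% d[2],
               (w - 1) %/% (d[1] * d[2]))
  colMeans(sweep(sweep(ijk, 2, img$spacing, "*"), 2, img$origin, "+"))
}

foreground_moments <- function(img) {
  fg <- img$data > 0
  w <- which(fg)
  d <- grid_dims(img)
  ijk <- cbind((w - 1) %% d[1],
               ((w - 1) %/% d[1]) %% d[2],
               (w - 1) %/% (d[1] * d[2]))
  pts <- sweep(sweep(ijk, 2, img$spacing, "*"), 2, img$origin, "+")
  ctr <- colMeans(pts)
  list(centroid = ctr, cov = crossprod(sweep(pts, 2, ctr)) / nrow(pts))
}

#' Rigidly align two label images
#'
#' Deterministic moments-based alignment: the returned transform maps the
#' moving foreground centroid onto the fixed one (translation), optionally
#' adding the principal-axes rotation (`rotation = "axes"`; axis signs are
#' disambiguated by making each eigenvector's largest component positive,
#' which leaves a 180-degree ambiguity for strongly symmetric shapes).
#'
#' The transform maps fixed-space points into moving-space points, i.e. it is
#' used directly to resample the moving image onto the fixed grid.
#'
#' @param fixed,moving [label_image()] objects with non-empty foregrounds.
#' @param rotation `"none"` (translation only) or `"axes"`.
#' @return a [spatial_transform()] of kind `"rigid"`.
#' @export
rigid_align <- function(fixed, moving, rotation = c("none", "axes")) {
  rotation <- match.arg(rotation)
  if (rotation == "none") {
    cf <- foreground_centroid(fixed)
    cm <- foreground_centroid(moving)
    return(spatial_transform(diag(3), cm - cf, kind = "rigid"))
  }
  mf <- foreground_moments(fixed)
  mm <- foreground_moments(moving)
  fix_signs <- function(U) {
    for (c in 1:3) {
      i <- which.max(abs(U[, c]))
      if (U[i, c] < 0) U[, c] <- -U[, c]
    }
    if (det(U) < 0) U[, 3] <- -U[, 3]
    U
  }
  Uf <- fix_signs(eigen(mf$cov, symmetric = TRUE)$vectors)
  Um <- fix_signs(eigen(mm$cov, symmetric = TRUE)$vectors)
  R <- Um %*% t(Uf)
  spatial_transform(R, mm$centroid - R %*% mf$centroid, kind = "rigid")
}

#' Diffeomorphic Demons registration of two label images
#'
#' Estimates a dense displacement field `u` on the fixed grid such that the
#' fixed-space point `x` corresponds to the moving-space point `x + u(x)`
#' (`moving(x + u(x)) ~ fixed(x)`). In the personalization pipeline the
#' baseline image is fixed and the subject image moving, so applying `u` to
#' the baseline mesh nodes carries them onto the subject.
#'
#' Per iteration: symmetric demon forces with the classical normalization
#' `diff * J / (|J|^2 + diff^2 / K)` (`J` the mean of fixed and warped-moving
#' gradients, `K` the mean squared spacing), fluid smoothing of the update,
#' exponentiation by scaling-and-squaring (which keeps the accumulated warp
#' diffeomorphic), composition into the field, then diffusion smoothing of
#' the field with `smooth_factor`. Runs over a shrink-factor pyramid and
#' records per-level convergence plus the foreground DICE of warped-moving
#' against fixed in the `level_log` attribute.
#'
#' @param fixed,moving [label_image()] objects on a common grid (rigidly
#'   pre-aligned; see [rigid_align()] and [resample_image()]).
#' @param config a [registration_config()].
#' @param init optional initial [displacement_field()] on the fixed grid.
#' @return a [displacement_field()] with attribute `level_log` (data frame:
#'   level, shrink, iterations, final mean update, foreground DICE).
#' @export
demons_register <- function(fixed, moving, config = registration_config(),
                            init = NULL) {
  stop_grid_mismatch(fixed, moving, "fixed and moving images")
  d_full <- grid_dims(fixed)
  f_full <- as.numeric(fixed$data)
  m_full <- as.numeric(moving$data)
  u <- NULL        # field on the level grid, as (n x 3-comp) numeric vector
  u_grid <- NULL   # its grid metadata
  log_rows <- list()

  nlev <- length(config$pyramid)
  for (lev in seq_len(nlev)) {
    s <- config$pyramid[lev]
    if (s > 1L) {
      fl <- cpp_downsample_mean(f_full, as.integer(d_full), s)
      ml <- cpp_downsample_mean(m_full, as.integer(d_full), s)
      d_lev <- attr(fl, "newdims")
      sp_lev <- fixed$spacing * s
      or_lev <- fixed$origin + (s - 1) / 2 * fixed$spacing
    } else {
      fl <- f_full; ml <- m_full
      d_lev <- as.integer(d_full)
      sp_lev <- fixed$spacing
      or_lev <- fixed$origin
    }
    if (config$presmooth > 0) {
      fl <- cpp_smooth_volume(fl, d_lev, rep(config$presmooth, 3), 1L)
      ml <- cpp_smooth_volume(ml, d_lev, rep(config$presmooth, 3), 1L)
    }
    lev_img <- list(spacing = sp_lev, origin = or_lev)

    u_lev <- if (is.null(u)) {
      if (is.null(init)) {
        numeric(prod(d_lev) * 3)
      } else {
        resample_field_to(init, d_lev, sp_lev, or_lev)
      }
    } else {
      resample_field_to(
        displacement_field(array(u, dim = c(u_grid$dims, 3)),
                           spacing = u_grid$spacing, origin = u_grid$origin),
        d_lev, sp_lev, or_lev)
    }

    res <- cpp_demons_level(fl, ml, d_lev, sp_lev, u_lev,
                            config$iterations[lev], config$smooth_factor,
                            config$sigma_fluid, config$max_step, config$tol)
    u <- res$u
    u_grid <- list(dims = d_lev, spacing = sp_lev, origin = or_lev)

    warped <- cpp_warp_scalar(ml, d_lev, sp_lev, u, 1L, 0)
    wfg <- warped > 0.5; ffg <- fl > 0.5
    dice_fg <- 2 * sum(wfg & ffg) / (sum(wfg) + sum(ffg))
    log_rows[[lev]] <- data.frame(
      level = lev, shrink = s, iterations = res$iterations,
      mean_update = tail(res$mean_updates, 1), dice_foreground = dice_fg)
  }

  out <- displacement_field(array(u, dim = c(u_grid$dims, 3)),
                            spacing = u_grid$spacing, origin = u_grid$origin)
  attr(out, "level_log") <- do.call(rbind, log_rows)
  out
}

# Sample a displacement field onto another grid (vectors are world mm and are
# interpolated componentwise; nearest-border outside).
resample_field_to <- function(field, dims, spacing, origin) {
  i <- (seq_len(dims[1]) - 1) * spacing[1] + origin[1]
  j <- (seq_len(dims[2]) - 1) * spacing[2] + origin[2]
  k <- (seq_len(dims[3]) - 1) * spacing[3] + origin[3]
  pts <- cbind(rep(i, times = dims[2] * dims[3]),
               rep(rep(j, each = dims[1]), times = dims[3]),
               rep(k, each = dims[1] * dims[2]))
  v <- cpp_sample_field(as.numeric(field$data), as.integer(grid_dims(field)),
                        field$spacing, field$origin, pts, 0L)
  as.numeric(v)
}

#' Invert a displacement field
#'
#' Fixed-point iteration `v <- -u(x + v(x))`; the result satisfies
#' `(id + u) o (id + v) ~ id`. The composition residual
#' `|u(x + v(x)) + v(x)|` is reported in the `residual` attribute (mean and
#' max, mm); if the mean residual still exceeds `tol` after `max_iter`
#' sweeps a warning is raised and the field is returned regardless.
#'
#' @param u a [displacement_field()].
#' @param tol residual tolerance (mm).
#' @param max_iter maximum fixed-point sweeps.
#' @return the inverse [displacement_field()] with attribute `residual`.
#' @export
invert_field <- function(u, tol = 0.01, max_iter = 50L) {
  d <- grid_dims(u)
  res <- cpp_invert_field(as.numeric(u$data), as.integer(d), u$spacing,
                          tol, as.integer(max_iter))
  out <- displacement_field(array(res$v, dim = c(d, 3)), spacing = u$spacing,
                            origin = u$origin)
  attr(out, "residual") <- c(mean = res$residual_mean, max = res$residual_max)
  attr(out, "iterations") <- res$iterations
  if (res$residual_mean > tol)
    warning(sprintf(
      "field inversion residual %.4g mm (max %.4g) above tol %g after %d iterations",
      res$residual_mean, res$residual_max, tol, res$iterations))
  out
}

#' Determinant of the warp Jacobian
#'
#' Computes `det(d(x + u(x))/dx)` at every voxel; strictly positive values
#' on the interior certify a locally invertible (fold-free) warp.
#'
#' @param u a [displacement_field()].
#' @return a numeric 3D array of determinants.
#' @export
warp_jacobian <- function(u) {
  d <- grid_dims(u)
  array(cpp_warp_jacobian(as.numeric(u$data), as.integer(d), u$spacing),
        dim = d)
}
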