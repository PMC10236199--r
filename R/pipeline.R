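#' Personalization pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. `type` selects the variant:
#' Type I is the basic pipeline (voxelize, rigid align, Demons, morph,
#' evaluate); Type II adds a global pre-scaling of the subject image (e.g.
#' elongating a 160-unit-tall subject by 178/160 before registering against a
#' 178-unit-tall baseline, the scaling being undone on the morphed nodes);
#' Type III "shields" selected regions by substituting the baseline's
#' surfaces for the subject's so those regions receive (near-)zero
#' displacement.
#'
#' @param baseline_surfaces named list of [surface_mesh()] for the baseline
#'   model (skin + skeleton, optionally regional pieces like "head").
#' @param baseline_mesh the baseline [fe_mesh()].
#' @param subject_surfaces named list of [surface_mesh()] for the subject.
#' @param type `"I"`, `"II"` or `"III"`.
#' @param voxel_size voxel edge (mm); 2 mm is the whole-body default, 1 mm
#'   suits component work.
#' @param padding grid margin (mm).
#' @param skin_only voxelize body shape only, without the skeleton.
#' @param scale_factors Type II: length-3 factors applied to the subject
#'   image about its foreground centroid before registration.
#' @param shield_regions Type III: region tags to shield.
#' @param skeleton_tags region tags voxelized as skeleton (label 2).
#' @param rotation rigid alignment mode, see [rigid_align()].
#' @param registration a [registration_config()].
#' @param out_dir if non-NULL, intermediates are written there
#'   (`img_hbm.mha`, `img_subj.mha`, `img_basewarped2subj.mha`,
#'   `gdemons.mha`, `gdemons_inv.mha`, `personalized.k`).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(baseline_surfaces, baseline_mesh,
                            subject_surfaces, type = c("I", "II", "III"),
                            voxel_size = 2, padding = 10, skin_only = FALSE,
                            scale_factors = NULL, shield_regions = NULL,
                            skeleton_tags = c("skeleton", "skull"),
                            rotation = "none",
                            registration = registration_config(),
                            out_dir = NULL) {
  type <- match.arg(type)
  if (type == "II" && is.null(scale_factors))
    stop("Type II requires `scale_factors`")
  if (type == "III" && (is.null(shield_regions) ||
                        length(shield_regions) == 0))
    stop("Type III requires `shield_regions`")
  structure(list(baseline_surfaces = baseline_surfaces,
                 baseline_mesh = baseline_mesh,
                 subject_surfaces = subject_surfaces, type = type,
                 voxel_size = voxel_size, padding = padding,
                 skin_only = skin_only, scale_factors = scale_factors,
                 shield_regions = shield_regions,
                 skeleton_tags = skeleton_tags, rotation = rotation,
                 registration = registration, out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run a full personalization pipeline
#'
#' Executes voxelization, rigid alignment, the Type II scaling or Type III
#' shielding where requested, Demons registration (baseline image fixed,
#' subject image moving), nodal morphing, field inversion, inverse warping of
#' the baseline image and the accuracy/quality reports.
#'
#' The returned displacement field maps fixed-space (baseline) points into
#' (aligned) subject space, so applying it to the baseline nodes yields the
#' personalized mesh; the final nodes additionally receive the rigid
#' alignment and, for Type II, the inverse global scaling, so the
#' personalized mesh lives in the subject's own space.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `personalization` with the morphed mesh, the
#'   forward and inverse fields, the label images, an evaluation report
#'   (DICE, HD, HD95, surface distances) and baseline/morphed quality
#'   reports.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  vox <- config$voxel_size

  # --- voxelization + rigid alignment --------------------------------------
  subject_surfaces <- config$subject_surfaces
  voxelize_set <- function(surfs, grid = NULL) pipeline_stage("voxelize", {
    if (is.null(grid)) grid <- compute_grid(surfs, vox, config$padding)
    voxelize_surfaces(surfs, grid,
                      skeleton_tags = config$skeleton_tags,
                      skin_only = config$skin_only)
  })
  img_base0 <- voxelize_set(config$baseline_surfaces)
  img_subj <- voxelize_set(subject_surfaces)

  # fixed -> moving map M: subject_in_fixed_space(x) = subject(M(x))
  rigid <- pipeline_stage("rigid_align",
                          rigid_align(img_base0, img_subj,
                                      rotation = config$rotation))
  M <- rigid
  scaling <- NULL
  if (config$type == "II") {
    f <- rep_len(as.numeric(config$scale_factors), 3)
    scaling <- make_scaling_transform(f,
                                      center = foreground_centroid(img_subj))
    # elongated subject image: I'(y) = I_s(scaling^-1 y); in fixed space the
    # subject appears as I'(rigid x) = I_s(scaling^-1 rigid x)
    M <- compose_transforms(invert_transform(scaling), rigid)
  }

  # --- shielding (Type III): replace subject regions by baseline's ---------
  # The baseline surfaces are carried into subject space with the *same*
  # rigid transform used for resampling, so a shielded region of the moving
  # image lands exactly on the corresponding fixed-image region and receives
  # (near-)zero displacement.
  if (config$type == "III") {
    subject_surfaces <- pipeline_stage("shield", {
      aligned_baseline <- lapply(config$baseline_surfaces, function(s) {
        s$vertices <- apply_transform(rigid, s$vertices)
        s
      })
      shield_regions(subject_surfaces, aligned_baseline,
                     config$shield_regions)
    })
    img_subj <- voxelize_set(subject_surfaces)
  }

  # Registration grid: covers the baseline and the aligned subject. The
  # moving image is produced by voxelizing the transformed subject surfaces
  # directly on the fixed grid rather than resampling the subject image,
  # which avoids a second label quantization (an image-only subject would use
  # resample_image() instead).
  moved_surfaces <- pipeline_stage("resample", {
    Minv <- invert_transform(M)
    lapply(subject_surfaces, function(s) {
      s$vertices <- apply_transform(Minv, s$vertices)
      s
    })
  })
  fixed_grid <- compute_grid(c(unname(config$baseline_surfaces),
                               unname(moved_surfaces)), vox, config$padding)
  img_base <- voxelize_set(config$baseline_surfaces, fixed_grid)
  img_moving <- voxelize_set(moved_surfaces, fixed_grid)

  # --- Demons registration --------------------------------------------------
  u <- pipeline_stage("demons",
                      demons_register(img_base, img_moving,
                                      config = config$registration))

  # --- morph ---------------------------------------------------------------
  # fixed-space correspondence x + u(x) lies in (aligned, scaled) subject
  # space; M carries it back into the subject's own space
  morphed <- pipeline_stage("morph",
                            morph_mesh(config$baseline_mesh, u,
                                       post_transform = M))
  morphed_surfaces <- lapply(config$baseline_surfaces, function(s) {
    disp <- sample_field(u, s$vertices)
    s$vertices <- apply_transform(M, s$vertices + disp)
    s
  })

  # --- evaluate -------------------------------------------------------------
  u_inv <- pipeline_stage("invert_field", invert_field(u))
  img_warped <- pipeline_stage("warp", warp_image(img_base, u_inv))
  eval_rep <- pipeline_stage("evaluate", {
    dice_flesh <- dice(img_warped, img_moving, labels = "flesh")
    dice_body <- dice(img_warped, img_moving, labels = "body")
    hd <- hausdorff(img_warped, img_moving, percentile = 95,
                    labels = "flesh")
    sd_list <- list()
    s_tags <- vapply(subject_surfaces, function(s) s$region_tag, character(1))
    for (nm in names(morphed_surfaces)) {
      tag <- morphed_surfaces[[nm]]$region_tag
      si <- which(s_tags == tag)
      if (length(si) == 1) {
        # compare in fixed/aligned space: carry subject surface through M^-1
        ref <- subject_surfaces[[si]]
        test <- morphed_surfaces[[nm]]
        sd_list[[tag]] <- surface_distance_map(test, ref)
      }
    }
    structure(list(dice = c(flesh = dice_flesh, body = dice_body),
                   hd = unname(hd["hd"]), hd95 = unname(hd["hd95"]),
                   surface_distances = sd_list),
              class = "eval_report")
  })
  quality <- pipeline_stage("quality", list(
    baseline = element_quality(config$baseline_mesh),
    morphed = element_quality(morphed)))
  contacts <- pipeline_stage("contacts", list(
    baseline = count_contact_intersections(config$baseline_mesh),
    morphed = count_contact_intersections(morphed)))

  out <- structure(list(
    mesh = morphed, baseline_mesh = config$baseline_mesh,
    morphed_surfaces = morphed_surfaces,
    field = u, field_inverse = u_inv,
    img_baseline = img_base, img_subject = img_subj,
    img_moving = img_moving, img_warped = img_warped,
    rigid = rigid, scaling = scaling,
    evaluation = eval_rep, quality = quality, contacts = contacts,
    level_log = attr(u, "level_log"), config = config),
    class = "personalization")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_image(img_base, p("img_hbm.mha"))
    write_image(img_subj, p("img_subj.mha"))
    write_image(img_moving, p("img_subj_aligned.mha"))
    write_image(img_warped, p("img_basewarped2subj.mha"))
    write_image(u, p("gdemons.mha"))
    write_image(u_inv, p("gdemons_inv.mha"))
    write_fe_mesh(morphed, p("personalized.k"))
  }
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> DICE flesh %.4f (body %.4f), HD %.2f mm, HD95 %.2f mm\n",
              x$dice["flesh"], x$dice["body"], x$hd, x$hd95))
  for (nm in names(x$surface_distances)) {
    s <- attr(x$surface_distances[[nm]], "summary")
    cat(sprintf("  surface '%s': mean %.2f mm, p95 %.2f mm\n", nm,
                s["mean"], s["p95"]))
  }
  invisible(x)
}

#' @export
print.personalization <- function(x, ...) {
  cat(sprintf("<personalization> Type %s, voxel %g mm, grid %s\n",
              x$config$type, x$config$voxel_size,
              paste(grid_dims(x$img_baseline), collapse = "x")))
  print(x$evaluation)
  q <- x$quality$morphed$elements
  cat(sprintf("  quality: %.1f%% scaled Jacobian >= 0.5, %.1f%% aspect <= 3\n",
              100 * mean(q$scaled_jacobian >= 0.5, na.rm = TRUE),
              100 * mean(q$aspect_ratio <= 3, na.rm = TRUE)))
  cat(sprintf("  contact intersections: baseline %d, morphed %d\n",
              x$contacts$baseline$count, x$contacts$morphed$count))
  if (!is.null(attr(x$mesh, "outside_count")))
    cat(sprintf("  nodes outside field grid: %d\n",
                attr(x$mesh, "outside_count")))
  invisible(x)
}

#' @export
summary.personalization <- function(object, ...) {
  q <- object$quality$morphed$elements
  res <- list(
    type = object$config$type,
    dice_flesh = unname(object$evaluation$dice["flesh"]),
    hd_mm = object$evaluation$hd,
    hd95_mm = object$evaluation$hd95,
    jacobian_ge_0.5 = mean(q$scaled_jacobian >= 0.5, na.rm = TRUE),
    aspect_le_3 = mean(q$aspect_ratio <= 3, na.rm = TRUE),
    min_edge_mm = min(q$min_edge),
    new_intersections = object$contacts$morphed$count -
      object$contacts$baseline$count,
    level_log = object$level_log)
  class(res) <- "summary.personalization"
  res
}

#' @export
print.summary.personalization <- function(x, ...) {
  cat(sprintf(
    "Type %s personalization: DICE %.4f, HD95 %.2f mm, Jacobian>=0.5 %.1f%%, new intersections %d\n",
    x$type, x$dice_flesh, x$hd95_mm, 100 * x$jacobian_ge_0.5,
    x$new_intersections))
  print(x$level_log)
  invisible(x)
}

#' Mid-coronal overlay of subject and warped baseline labels
#'
#' @param x a `personalization`.
#' @param slice y index (defaults to the middle).
#' @param ... unused.
#' @export
plot.personalization <- function(x, slice = NULL, ...) {
  d <- grid_dims(x$img_baseline)
  if (is.null(slice)) slice <- ceiling(d[2] / 2)
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  show <- function(img, main) {
    graphics::image(img$data[, slice, ], main = main, axes = FALSE,
                    col = grDevices::gray.colors(3, 0, 1), useRaster = TRUE)
  }
  show(x$img_baseline, "baseline")
  show(x$img_moving, "subject (aligned)")
  show(x$img_warped, "warped baseline")
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML names files rather than in-memory objects:
#' ```yaml
#' type: I
#' voxel_size: 2
#' padding: 10
#' baseline:
#'   mesh: hbm.k
#'   surfaces: {skin: skin.stl, skeleton: skel.stl}
#' subject:
#'   surfaces: {skin: s_skin.stl, skeleton: s_skel.stl}
#' # Type II: scale_factors: [1, 1, 1.1125]
#' # Type III: shield_regions: [head]
#' registration: {smooth_factor: 2, pyramid: [4, 2, 1],
#'                iterations: [100, 50, 25]}
#' out_dir: out/
#' ```
#' Surface keys double as region tags.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(f) if (file.exists(f)) f else file.path(base, f)
  load_surfaces <- function(lst)
    stats::setNames(lapply(names(lst), function(nm)
      read_surface(rel(lst[[nm]]), region_tag = nm)), names(lst))
  reg <- do.call(registration_config, as.list(y$registration %||% list()))
  pipeline_config(
    baseline_surfaces = load_surfaces(y$baseline$surfaces),
    baseline_mesh = read_fe_mesh(rel(y$baseline$mesh)),
    subject_surfaces = load_surfaces(y$subject$surfaces),
    type = y$type %||% "I",
    voxel_size = y$voxel_size %||% 2,
    padding = y$padding %||% 10,
    skin_only = isTRUE(y$skin_only),
    scale_factors = y$scale_factors,
    shield_regions = y$shield_regions,
    skeleton_tags = y$skeleton_tags %||% c("skeleton", "skull"),
    rotation = y$rotation %||% "none",
    registration = reg,
    out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
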