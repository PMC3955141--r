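#' Specification of a digital activity phantom
#'
#' Describes a 3-D activity-concentration phantom with ellipsoidal lesions,
#' a uniform background, an optional axis-aligned bone-marrow box, post-hoc
#' Gaussian smoothing and additive noise. The default geometry mirrors a
#' clinical PET reconstruction: 2.67 x 2.67 x 2.00 mm voxels and a 4-mm
#' smoothing kernel.
#'
#' World coordinates are in mm with the voxel at index (1,1,1) centred at
#' half a voxel from the origin; masks share the image grid exactly.
#'
#' @param grid_shape Three positive integers.
#' @param voxel_size_mm Three positive reals (mm).
#' @param lesions List of lesions, each
#'   `list(center_mm =, semi_axes_mm =, activity_kBq_ml =, type =)` with
#'   `type` `"primary"` or `"node"`.
#' @param background_activity Nonnegative background (kBq/ml).
#' @param bone_box Optional `list(min_mm =, max_mm =, activity_kBq_ml =)`.
#' @param smoothing_fwhm_mm Nonnegative FWHM (mm), default 4.
#' @param noise_sd Nonnegative additive Gaussian noise SD (kBq/ml).
#' @return Object of class `flt_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48),
                         voxel_size_mm = c(2.67, 2.67, 2.00),
                         lesions = list(),
                         background_activity = 0.5,
                         bone_box = NULL,
                         smoothing_fwhm_mm = 4,
                         noise_sd = 0) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive reals")
  if (background_activity < 0 || smoothing_fwhm_mm < 0 || noise_sd < 0)
    stop("activities, smoothing and noise must be nonnegative")
  extent <- grid_shape * voxel_size_mm
  for (les in lesions) {
    stopifnot(length(les$center_mm) == 3L, length(les$semi_axes_mm) == 3L)
    if (les$activity_kBq_ml < 0) stop("lesion activity must be nonnegative")
    if (!les$type %in% c("primary", "node")) stop("lesion type must be primary or node")
    if (any(les$center_mm - les$semi_axes_mm < 0) ||
        any(les$center_mm + les$semi_axes_mm > extent))
      stop("lesion ellipsoid extends outside the grid")
  }
  if (!is.null(bone_box)) {
    stopifnot(length(bone_box$min_mm) == 3L, length(bone_box$max_mm) == 3L)
    if (bone_box$activity_kBq_ml < 0) stop("bone activity must be nonnegative")
    if (any(bone_box$min_mm >= bone_box$max_mm))
      stop("bone box must have positive extent")
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 lesions = lesions, background_activity = background_activity,
                 bone_box = bone_box, smoothing_fwhm_mm = smoothing_fwhm_mm,
                 noise_sd = noise_sd),
            class = "flt_phantom_spec")
}

#' Generate a phantom activity image with ground-truth masks
#'
#' Paints each lesion ellipsoid and the bone box onto a uniform background,
#' applies Gaussian smoothing of the specified FWHM and additive Gaussian
#' noise. The returned lesion masks are the pre-smoothing ground truth
#' (one binary mask per lesion); overlapping lesion ellipsoids are an
#' error because their ground truth would be ambiguous.
#'
#' @param spec An `flt_phantom_spec`.
#' @param seed Integer seed for the noise draw (ignored when
#'   `noise_sd = 0`).
#' @return List: `activity` (3-D array, kBq/ml), `voxel_size_mm`,
#'   `lesion_masks` (list of logical arrays), `lesion_types`, `bone_mask`
#'   (logical array or `NULL`), `spec`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "flt_phantom_spec"))
  d <- spec$grid_shape
  vx <- spec$voxel_size_mm
  cx <- (seq_len(d[1]) - 0.5) * vx[1]
  cy <- (seq_len(d[2]) - 0.5) * vx[2]
  cz <- (seq_len(d[3]) - 0.5) * vx[3]

  act <- array(spec$background_activity, d)
  bone_mask <- NULL
  if (!is.null(spec$bone_box)) {
    bb <- spec$bone_box
    bone_mask <- outer(outer(cx >= bb$min_mm[1] & cx <= bb$max_mm[1],
                             cy >= bb$min_mm[2] & cy <= bb$max_mm[2], "&"),
                       cz >= bb$min_mm[3] & cz <= bb$max_mm[3], "&")
    act[bone_mask] <- bb$activity_kBq_ml
  }

  masks <- vector("list", length(spec$lesions))
  types <- character(length(spec$lesions))
  occupied <- array(FALSE, d)
  for (k in seq_along(spec$lesions)) {
    les <- spec$lesions[[k]]
    qx <- ((cx - les$center_mm[1]) / les$semi_axes_mm[1])^2
    qy <- ((cy - les$center_mm[2]) / les$semi_axes_mm[2])^2
    qz <- ((cz - les$center_mm[3]) / les$semi_axes_mm[3])^2
    m <- outer(outer(qx, qy, "+"), qz, "+") <= 1
    if (any(m & occupied))
      stop("overlapping lesion ellipsoids: ground truth would be ambiguous")
    occupied <- occupied | m
    act[m] <- les$activity_kBq_ml
    masks[[k]] <- m
    types[k] <- les$type
  }

  if (spec$smoothing_fwhm_mm > 0)
    act <- gaussian_smooth_3d(act, spec$smoothing_fwhm_mm, vx)
  if (spec$noise_sd > 0) {
    set.seed(seed)
    act <- act + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
  }

  list(activity = act, voxel_size_mm = vx, lesion_masks = masks,
       lesion_types = types, bone_mask = bone_mask, spec = spec)
}

#' Write a phantom to NIfTI files
#'
#' Writes the activity image plus one mask file per lesion (and the bone
#' mask when present) into a directory.
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(activity = file.path(dir, "activity.nii.gz"))
  write_nifti_image(phantom$activity, phantom$voxel_size_mm, paths["activity"])
  for (k in seq_along(phantom$lesion_masks)) {
    p <- file.path(dir, sprintf("lesion%02d_%s.nii.gz", k,
                                phantom$lesion_types[k]))
    write_nifti_image(phantom$lesion_masks[[k]] * 1, phantom$voxel_size_mm, p)
    paths[sprintf("lesion%02d", k)] <- p
  }
  if (!is.null(phantom$bone_mask)) {
    p <- file.path(dir, "bone.nii.gz")
    write_nifti_image(phantom$bone_mask * 1, phantom$voxel_size_mm, p)
    paths["bone"] <- p
  }
  invisible(paths)
}
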