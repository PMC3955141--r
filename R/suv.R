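#' F-18 physical half-life in minutes
#' @export
F18_HALF_LIFE_MIN <- 109.77

#' Per-scan acquisition metadata
#'
#' Holds the facts needed to normalize an activity image to SUV: injected
#' dose, body weight, and the injection-to-frame delay when the image is
#' not already decay-corrected to injection time.
#'
#' @param patient_id,scan_label Identifiers (`scan_label` one of S1/S2/S3).
#' @param injected_dose_MBq Positive injected activity (MBq).
#' @param body_weight_kg Positive body weight (kg).
#' @param injection_to_frame_min Minutes from injection to the frame
#'   (required when `decay_corrected = FALSE`). The conventional
#'   acquisition window here is 45-60 min post-injection.
#' @param decay_corrected Is the image already decay-corrected to
#'   injection time? Default `TRUE`.
#' @return Object of class `flt_scan_meta`.
#' @export
scan_meta <- function(patient_id, scan_label = c("S1", "S2", "S3"),
                      injected_dose_MBq, body_weight_kg,
                      injection_to_frame_min = NA_real_,
                      decay_corrected = TRUE) {
  scan_label <- match.arg(scan_label)
  if (injected_dose_MBq <= 0) stop("injected dose must be strictly positive")
  if (body_weight_kg <= 0) stop("body weight must be strictly positive")
  if (!decay_corrected && (is.na(injection_to_frame_min) ||
                           injection_to_frame_min < 0))
    stop("injection_to_frame_min required (>= 0) when not decay-corrected")
  structure(list(patient_id = patient_id, scan_label = scan_label,
                 injected_dose_MBq = injected_dose_MBq,
                 body_weight_kg = body_weight_kg,
                 injection_to_frame_min = injection_to_frame_min,
                 decay_corrected = decay_corrected),
            class = "flt_scan_meta")
}

#' SUV parametric map from an activity-concentration image
#'
#' Voxelwise standardized uptake value:
#' `SUV(g/ml) = activity(kBq/ml) * weight(kg) / dose(MBq)`,
#' after decay-correcting the activity to injection time
#' (`A * 2^(t / 109.77)` for F-18) when the input is not already
#' decay-corrected. The kBq/MBq factor of 1e-3 cancels against kg/g under
#' the implicit 1 g/ml tissue density, so 1 kBq/ml at a dose-to-weight
#' ratio of 1 MBq/kg gives SUV 1.0.
#'
#' Small negative voxels (reconstruction noise) are clamped to zero;
#' negative values beyond `neg_tolerance` times the image maximum raise an
#' error.
#'
#' @param activity 3-D numeric array, kBq/ml.
#' @param meta An `flt_scan_meta`.
#' @param voxel_size_mm Length-3 voxel dimensions (mm).
#' @param neg_tolerance Fraction of the image maximum below which negative
#'   voxels are treated as noise (default 0.01).
#' @return Object of class `flt_suv_image`: `values` (g/ml, nonnegative)
#'   and `voxel_size_mm`.
#' @examples
#' m <- scan_meta("P01", "S1", injected_dose_MBq = 350, body_weight_kg = 70)
#' img <- compute_suv_map(array(5, c(2, 2, 2)), m, c(2, 2, 2))
#' img$values[1]  # 1.0
#' @export
compute_suv_map <- function(activity, meta, voxel_size_mm,
                            neg_tolerance = 0.01) {
  stopifnot(inherits(meta, "flt_scan_meta"))
  if (length(dim(activity)) != 3L) stop("activity must be a 3-D array")
  mx <- max(activity)
  if (mx <= 0) stop("activity image has no positive signal")
  if (min(activity) < -neg_tolerance * mx)
    stop("negative activities beyond the noise tolerance")
  a <- pmax(activity, 0)
  if (!meta$decay_corrected)
    a <- a * 2^(meta$injection_to_frame_min / F18_HALF_LIFE_MIN)
  suv <- a * meta$body_weight_kg / meta$injected_dose_MBq
  new_suv_image(suv, voxel_size_mm)
}

new_suv_image <- function(values, voxel_size_mm) {
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive reals")
  structure(list(values = values, voxel_size_mm = voxel_size_mm),
            class = "flt_suv_image")
}

#' @export
print.flt_suv_image <- function(x, ...) {
  cat(sprintf("SUV image %s, voxels %.2f x %.2f x %.2f mm, range [%.3f, %.3f]\n",
              paste(dim(x$values), collapse = " x "),
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Isotropic 3-D Gaussian smoothing
#'
#' Separable Gaussian convolution with `sigma = FWHM / 2.3548` per axis in
#' mm, converted to voxel units from the image geometry. Boundaries are
#' zero-padded; the kernel is truncated at 4 sigma and normalized to unit
#' sum, so total image mass is conserved away from the edges.
#' `fwhm_mm = 0` is the identity.
#'
#' @param img An `flt_suv_image`, or a 3-D array (then `voxel_size_mm` is
#'   required).
#' @param fwhm_mm Nonnegative full width at half maximum (mm).
#' @param voxel_size_mm Voxel dimensions when `img` is a plain array.
#' @return Same type as the input.
#' @export
smooth_image <- function(img, fwhm_mm, voxel_size_mm = NULL) {
  if (fwhm_mm < 0) stop("fwhm_mm must be nonnegative")
  if (inherits(img, "flt_suv_image")) {
    img$values <- gaussian_smooth_3d(img$values, fwhm_mm, img$voxel_size_mm)
    return(img)
  }
  if (is.null(voxel_size_mm))
    stop("voxel_size_mm required for a plain array")
  gaussian_smooth_3d(img, fwhm_mm, voxel_size_mm)
}

gaussian_smooth_3d <- function(arr, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm == 0) return(arr)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_size_mm
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[axis])
    if (length(k) > 1L) arr <- convolve_axis(arr, axis, k)
  }
  arr
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

# Zero-padded 1-D convolution along one axis of a 3-D array, implemented
# as a banded-matrix product over the permuted array.
convolve_axis <- function(arr, axis, k) {
  r <- (length(k) - 1L) / 2L
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(arr, perm)
  d <- dim(ap)
  n <- d[1]
  band <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    band[cbind(i[ok], j[ok])] <- k[off + r + 1L]
  }
  res <- band %*% matrix(ap, nrow = n)
  dim(res) <- d
  aperm(res, order(perm))
}

#' Per-lesion VOI statistics
#'
#' Extracts the three lesion parameters from an SUV image under a binary
#' mask: `volume_cm3` (voxel count times voxel volume), `suv_mean`
#' (arithmetic mean) and `suv_max` (maximum).
#'
#' @param img An `flt_suv_image`.
#' @param mask Logical/0-1 array of the same shape.
#' @param patient_id,lesion_id,lesion_type,scan_label Identifiers carried
#'   into the output row.
#' @return One-row data frame: identifiers plus `volume_cm3`, `suv_mean`,
#'   `suv_max`.
#' @export
extract_voi_stats <- function(img, mask, patient_id = NA, lesion_id = NA,
                              lesion_type = NA, scan_label = NA) {
  stopifnot(inherits(img, "flt_suv_image"))
  if (!identical(dim(img$values), dim(mask)))
    stop("mask shape does not match the image grid")
  m <- mask > 0
  nvox <- sum(m)
  if (nvox == 0L) stop("empty mask")
  vals <- img$values[m]
  data.frame(patient_id = patient_id, lesion_id = lesion_id,
             lesion_type = lesion_type, scan_label = scan_label,
             volume_cm3 = nvox * prod(img$voxel_size_mm) / 1000,
             suv_mean = mean(vals), suv_max = max(vals))
}

#' Bone-marrow overlap quality control
#'
#' Counts lesion-mask voxels lying inside, or within a face-connected
#' margin of, a bone mask. Proliferating bone marrow carries strong FLT
#' signal; any overlap of a tumour VOI with bone risks contaminating the
#' uptake statistics, so the default passes only at zero violations.
#'
#' @param mask Binary lesion mask.
#' @param bone_mask Binary bone mask, same shape.
#' @param margin_voxels Nonnegative integer: the bone mask is dilated this
#'   many steps with 6-connectivity before counting.
#' @param max_violations Violations tolerated before `pass` turns `FALSE`
#'   (default 0).
#' @return List with `n_violations`, `pass`, `margin_voxels`.
#' @export
check_bone_overlap <- function(mask, bone_mask, margin_voxels = 0L,
                               max_violations = 0L) {
  if (!identical(dim(mask), dim(bone_mask))) stop("shape mismatch")
  b <- bone_mask > 0
  for (s in seq_len(margin_voxels)) b <- dilate6(b)
  n <- sum((mask > 0) & b)
  list(n_violations = n, pass = n <= max_violations,
       margin_voxels = as.integer(margin_voxels))
}

# one step of 6-connected (face-neighbour) binary dilation
dilate6 <- function(b) {
  out <- b
  d <- dim(b)
  shift <- function(x, axis, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[axis]] <- idx[[axis]] - by
    keep <- src[[axis]] >= 1 & src[[axis]] <= d[axis]
    res <- array(FALSE, d)
    tgt <- idx
    tgt[[axis]] <- idx[[axis]][keep]
    src[[axis]] <- src[[axis]][keep]
    res[tgt[[1]], tgt[[2]], tgt[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
    res
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) out <- out | shift(b, axis, by)
  out
}

#' NIfTI image I/O
#'
#' Thin wrappers writing/reading a 3-D array with its voxel geometry as a
#' NIfTI-1 file.
#'
#' @param values 3-D array.
#' @param voxel_size_mm Length-3 voxel dimensions (mm).
#' @param path File path (`.nii` / `.nii.gz`).
#' @return `read_nifti_image` returns a list with `values` and
#'   `voxel_size_mm`.
#' @export
write_nifti_image <- function(values, voxel_size_mm, path) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_image
#' @export
read_nifti_image <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.numeric(img), dim = dim(img)),
       voxel_size_mm = RNifti::pixdim(img)[1:3])
}

#' Scan metadata sidecar I/O (JSON)
#'
#' @param meta An `flt_scan_meta`.
#' @param path File path.
#' @return `read_scan_meta` returns an `flt_scan_meta`.
#' @export
write_scan_meta <- function(meta, path) {
  stopifnot(inherits(meta, "flt_scan_meta"))
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_scan_meta
#' @export
read_scan_meta <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scan_meta(x$patient_id, x$scan_label, x$injected_dose_MBq,
            x$body_weight_kg,
            if (is.null(x$injection_to_frame_min)) NA_real_
            else x$injection_to_frame_min,
            isTRUE(x$decay_corrected))
}
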