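#!/usr/bin/env Rscript
# Stage 2: image-side check of the quantification chain on a digital
# phantom at scanner geometry (2.67 x 2.67 x 2.00 mm voxels, 4-mm
# post-reconstruction smoothing): paint known activities, convert to SUV
# with matched acquisition metadata, extract VOI statistics, and run the
# bone-marrow overlap QC.

suppressPackageStartupMessages(library(fltrt))
dir.create("results", showWarnings = FALSE)

spec <- phantom_spec(
  grid_shape = c(64, 64, 48),
  voxel_size_mm = c(2.67, 2.67, 2.00),
  lesions = list(
    list(center_mm = c(60, 85, 48), semi_axes_mm = c(22, 18, 16),
         activity_kBq_ml = 6.0, type = "primary"),
    list(center_mm = c(115, 60, 48), semi_axes_mm = c(9, 9, 8),
         activity_kBq_ml = 4.0, type = "node")),
  background_activity = 1.0,
  bone_box = list(min_mm = c(140, 40, 30), max_mm = c(165, 120, 70),
                  activity_kBq_ml = 8.0),
  smoothing_fwhm_mm = 4, noise_sd = 0.1)
ph <- generate_phantom(spec, seed = 11L)

# 311 MBq and 77.75 kg give dose/weight 4 MBq/kg: lesion SUVs 1.5 and 1.0
meta <- scan_meta("PHANTOM", "S1", injected_dose_MBq = 311,
                  body_weight_kg = 77.75)
suv <- compute_suv_map(ph$activity, meta, ph$voxel_size_mm)

stats <- do.call(rbind, lapply(seq_along(ph$lesion_masks), function(k) {
  s <- extract_voi_stats(suv, ph$lesion_masks[[k]], patient_id = "PHANTOM",
                         lesion_id = sprintf("L%d", k),
                         lesion_type = ph$lesion_types[k], scan_label = "S1")
  qc <- check_bone_overlap(ph$lesion_masks[[k]], ph$bone_mask,
                           margin_voxels = 1)
  s$true_suv <- c(6.0, 4.0)[k] * 77.75 / 311
  s$bone_qc_pass <- qc$pass
  s$bone_violations <- qc$n_violations
  s
}))
write.csv(stats, "results/phantom_voi_stats.csv", row.names = FALSE)

cat("phantom VOI statistics (smoothing + noise shift means slightly):\n")
print(stats, digits = 4)
cat("Large-lesion SUV_mean stays near truth; the small node is more\n")
cat("affected by the 4-mm kernel, illustrating the size-uptake interaction.\n")
cat("wrote results/phantom_voi_stats.csv\n")
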