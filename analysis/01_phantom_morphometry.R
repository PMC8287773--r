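#!/usr/bin/env Rscript
# Step 1 — synthetic acquisitions and bone-gap morphometry.
#
# Generates paired loaded/unloaded knee phantoms with known ground
# truth, measures the per-slice femur-tibia bone gap (mBGFT) on each,
# and tabulates how well the measurement recovers the truth. The
# acquisition-scale phantom mirrors the in-vivo protocol (2 mm sagittal
# slices, 0.27 mm in-plane pixels); the recovery cohort spans flat and
# curved condyles at a coarser grid for speed.

suppressPackageStartupMessages(library(tfjstiff))
dir.create("results", showWarnings = FALSE)

message("Acquisition-scale phantom (72 x 512 x 512, apex gap 5.99 mm, delta = 0.63 mm;")
message("with a curved condyle the slice-mean mBGFT exceeds the apex gap) ...")
p <- phantom_params(gap_mm = 5.99, delta_mm = 0.63)
ph <- generate_knee_phantom(p)
rr <- roi(ph$truth$roi_slices)
s <- compute_strain(measure_mbgft(ph$unloaded, rr),
                    measure_mbgft(ph$loaded, rr))
print(s)
message(sprintf("truth: mBGFT %.3f mm, delta %.3f mm, strain %.5f",
                ph$truth$mbgft_true_unloaded_mm,
                ph$truth$delta_mbgft_true_mm, ph$truth$strain_true))

message("Recovery cohort: 20 seeded phantoms ...")
rows <- lapply(seq_len(20), function(k) {
  set.seed(100 + k)
  radius <- c(Inf, 25, 40, 60)[1 + k %% 4]
  g0 <- runif(1, 4.8, 7.3); dl <- runif(1, 0.3, 0.9)
  pk <- phantom_params(shape = c(6L, 96L, 96L), spacing = c(2, 0.4, 0.4),
                       condyle_radius = radius, plateau_extent = 24,
                       cartilage_thickness = 1, meniscus_height = 1,
                       bone_height = 6, gap_mm = g0, delta_mm = dl,
                       seed = k)
  phk <- generate_knee_phantom(pk)
  rk <- roi(phk$truth$roi_slices)
  sk <- compute_strain(measure_mbgft(phk$unloaded, rk),
                       measure_mbgft(phk$loaded, rk))
  data.frame(phantom = k, condyle_radius = radius, gap_mm = g0,
             delta_true_mm = phk$truth$delta_mbgft_true_mm,
             delta_measured_mm = sk$delta_mbgft_mm,
             strain_true = phk$truth$strain_true,
             strain_measured = sk$strain)
})
tab <- do.call(rbind, rows)
tab$abs_err_mm <- abs(tab$delta_measured_mm - tab$delta_true_mm)
write.csv(tab, "results/phantom_recovery.csv", row.names = FALSE)
message(sprintf(
  "max |measured - true| delta-mBGFT = %.4f mm (in-plane voxel 0.4 mm) over %d phantoms",
  max(tab$abs_err_mm), nrow(tab)))
message("wrote results/phantom_recovery.csv")
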