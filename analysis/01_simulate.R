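#!/usr/bin/env Rscript
# Builds the study scene: PDD table, cylindrical water phantom (plus a
# lung-insert variant), ROI set and one example partial-arc plan; writes
# the grids and tables under results/01_simulate/.

library(arcdose)

out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

grid <- grid_spec(c(109, 109, 109), 2.5)      # 2.5 mm over the 27 cm phantom
pdd <- make_pdd_table()
phantom <- make_density_phantom("cylindrical", "homogeneous", grid)
lung <- make_density_phantom("cylindrical", "lung_insert", grid,
                             params = list(insert_rho = 0.1,
                                           insert_centre_mm = c(20, 0),
                                           insert_radius_mm = 35))
plan <- make_plan(24, arc = c(0.4, 0.4 + 220 * pi / 180),
                  field_range_cm = c(4, 12), seed = 2024)

cat("PDD table:", length(pdd$field_sizes_cm), "fields x",
    length(pdd$depths_cm), "depths; PDD(10 cm, 10x10) =",
    round(pdd_eval(pdd, 10, 10), 2), "%\n")
write.csv(data.frame(depth_cm = pdd$depths_cm,
                     setNames(as.data.frame(pdd$values),
                              paste0("F", pdd$field_sizes_cm, "cm"))),
          file.path(out, "pdd_table.csv"), row.names = FALSE)

truth <- ground_truth_dose(plan, phantom, pdd, grid)
cat("Ground-truth dose:", paste(grid$shape, collapse = " x "),
    "voxels, max", round(max(truth$values), 3), "Gy\n")
write_dose_grid(truth, file.path(out, "truth_homogeneous"))
write_dose_grid(phantom, file.path(out, "density_homogeneous"))
write_dose_grid(lung, file.path(out, "density_lung_insert"))

rois <- make_roi_set(grid, list(
  list(name = "ptv", role = "PTV", shape = "sphere",
       centre_mm = c(0, 0, 0), radius_mm = 25),
  list(name = "lens_scale", role = "OAR", shape = "sphere",
       centre_mm = c(50, 0, 0), volume_cm3 = 0.2),
  list(name = "organ_scale", role = "OAR", shape = "sphere",
       centre_mm = c(0, 0, 0), volume_cm3 = 50)))
vols <- vapply(rois, function(r) sum(r$mask) * voxel_volume_cm3(grid), 0)
cat("ROI voxelised volumes (cm^3):",
    paste(names(vols), round(vols, 2), collapse = ", "), "\n")

cat("wrote", out, "\n")
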