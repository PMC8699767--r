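#!/usr/bin/env Rscript
# Generate one example synthetic field of each kind used by the analyses
# that follow (nuclear/marker, spindle and round cell bodies, coculture),
# and export them as calibrated TIFFs plus ground-truth tables.

suppressMessages(library(nmjquant))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cat("== Simulating example fields (0.5 um/px, SNR 10) ==\n")

nuc <- generate_nuclei_image(synth_spec(seed = 101))
write_image(nuc$dapi, file.path(out, "nuclei_dapi.tif"))
write_image(nuc$marker, file.path(out, "nuclei_marker.tif"))
readr::write_csv(
  cbind(nuc$truth$nucleus_centers$points[, c("row", "col")],
        positive = nuc$truth$nucleus_positive_flags),
  file.path(out, "nuclei_ground_truth.csv"), progress = FALSE)
cat(sprintf("nuclear field: %d nuclei, %d marker-positive\n",
            n_points(nuc$truth$nucleus_centers),
            sum(nuc$truth$nucleus_positive_flags)))

for (morph in c("spindle", "round")) {
  g <- generate_cell_body_image(synth_spec(cell_morphology = morph, seed = 102))
  write_image(g$stain, file.path(out, sprintf("bodies_%s.tif", morph)))
  cat(sprintf("%s field: %d bodies covering %d px\n", morph,
              g$truth$n_cells, sum(g$truth$cell_body_mask)))
}

cc <- generate_coculture_image(synth_spec(seed = 103))
for (ch in names(cc$channels)) {
  write_image(cc$channels[[ch]], file.path(out, sprintf("coculture_%s.tif", ch)))
}
readr::write_csv(cc$truth$cluster_records,
                 file.path(out, "coculture_cluster_truth.csv"), progress = FALSE)
cat(sprintf("coculture field: %d clusters on %.3f mm2 of myotube\n",
            nrow(cc$truth$cluster_records),
            cc$truth$myotube_area_px2 * 0.25 / 1e6))
cat(sprintf("wrote TIFF channels and ground truth under %s/\n", out))
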