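#!/usr/bin/env Rscript
# Simulate the storage experiment: 120 fruit in 5 storage-time groups of 24,
# one hyperspectral scene each. Writes the ground-truth table, the ROI-mean
# spectra, one example scene (ENVI pair + segmentation mask) and the
# calibration/prediction split under results/.

library(berryhsi)

seed <- 2026L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

message("generating 120 scenes and extracting ROI-mean spectra ...")
dataset <- generate_dataset(120L, 5L, seed = seed, extract_images = TRUE)
saveRDS(dataset, "scratch/dataset.rds")   # cache for the later scripts

write.csv(dataset$truth, "results/truth.csv", row.names = FALSE)
write_spectra_csv(crop_bands(dataset$spectra), "results/spectra_400_1000.csv")

message("per-group quality means (storage drift):")
print(aggregate(cbind(ssc, ph, vc) ~ group, dataset$truth, mean))

# one example scene for inspection
sc <- generate_scene(latent_quality(dataset$truth$ssc[1], dataset$truth$ph[1],
                                    dataset$truth$vc[1], 0L),
                     seed = seed)
write_envi(as_hypercube(sc), "results/example_scene")
cube <- calibrate(as_hypercube(sc), reference_frames(sc))
mask <- segment_superred(cube)
write_mask_png(mask, "results/example_scene_mask.png")
iou <- sum(mask$mask & sc$truth_mask) / sum(mask$mask | sc$truth_mask)
message(sprintf("example scene: %d ROI pixels, IoU against truth mask %.3f",
                mask$pixel_count, iou))

plan <- kennard_stone_split(crop_bands(dataset$spectra)$X,
                            dataset$truth$id, dataset$truth$group)
writeLines(jsonlite::toJSON(unclass(plan), auto_unbox = TRUE, digits = NA),
           "results/split_plan.json")
message(sprintf("Kennard-Stone split: %d calibration / %d prediction",
                length(plan$calibration_ids), length(plan$prediction_ids)))
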