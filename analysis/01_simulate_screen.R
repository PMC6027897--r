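#!/usr/bin/env Rscript
# Step 1 — simulate the pilot screen.
#
# Generates the triplicate 32-plate screen at the area level (the fast
# path used for all screen statistics), with ~1% planted true hits of
# heterogeneous strength and the two artifact processes, plus one fully
# rendered example plate image with ground truth. Outputs go to results/.

suppressMessages(library(larvascreen))
dir.create("results", showWarnings = FALSE)

seed <- 20180507
hits <- sprintf("C%04d", seq(5, 2560, by = 90))
cfg <- screen_config(n_plates = 32, n_replicates = 3, true_hit_ids = hits,
                     hit_rescues = seq(0.3, 0.9, length.out = length(hits)),
                     rng_seed = seed)
areas <- simulate_screen_areas(cfg)
write_area_csv(areas, "results/screen_areas.csv")

cat(sprintf("screen: %d wells (%d plates x 3 replicates), %d planted hits\n",
            nrow(areas), cfg$n_plates, length(hits)))
cat(sprintf("artifact wells: %d high-background, %d low-DMSO\n",
            sum(areas$flag_high_bg), sum(areas$flag_low_dmso)))

# one rendered plate (plate 1 layout, with artifacts) as an image example
lay <- plate_layout(compound_ids = sprintf("C%03d", 1:80))
sim <- simulate_plate_image(lay, artifacts = artifact_model(),
                            seed = substream_seed(seed, 999))
write_plate_png(sim$image, "results/example_plate.png")
utils::write.csv(sim$truth, "results/example_plate_truth.csv",
                 row.names = FALSE)
cat("rendered example plate -> results/example_plate.png\n")
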