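#!/usr/bin/env Rscript
# Step 2 — run the larval-detection algorithm on rendered plates.
#
# Renders a two-genotype validation plate (true mutant/control area ratio
# 0.75), locates the 96-well grid, estimates each well's empty background,
# segments larvae from the difference image, and compares detected areas
# with rendered ground truth. This is the imaging half of the pipeline;
# the screen statistics in step 3 run on well-area tables.

suppressMessages(library(larvascreen))
dir.create("results", showWarnings = FALSE)

seed <- 20180507
lay <- two_genotype_layout(dmso_pct = 0)
sim <- simulate_plate_image(lay, seed = substream_seed(seed, 1))
regions <- locate_well_grid(sim$image)
cutoff <- calibrate_residual_cutoff(n = 96, seed = substream_seed(seed, 2))
meas <- measure_plate(sim$image, regions, residual_cutoff = cutoff)
write_well_measurements(meas, "results/well_measurements.csv", plate_id = 1)

m <- merge(meas, sim$truth[, c("well", "true_area")], by = "well")
relerr <- abs(m$total_area_px - m$true_area) / m$true_area
g <- lay$genotype[match(m$well, lay$well)]
ratio <- mean(m$total_area_px[g == "hom"]) / mean(m$total_area_px[g == "het"])

cat(sprintf("grid offset: (%d, %d) px\n",
            attr(regions, "offset")[1], attr(regions, "offset")[2]))
cat(sprintf("median |detected - true| / true: %.3f\n", median(relerr)))
cat(sprintf("rank correlation detected vs true: %.3f\n",
            cor(m$total_area_px, m$true_area, method = "spearman")))
cat(sprintf("recovered mutant/control area ratio: %.1f%% (true 75%%)\n",
            100 * ratio))
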