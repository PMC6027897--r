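#!/usr/bin/env Rscript
# Step 5 — validation-stage developmental analyses.
#
# Vial-format follow-up of a hit: eclosion timecourses with a 2-day
# mutant delay and its hormone rescue, eclosion-fraction fold change with
# a Student's t-test, larval size comparison, and the bortezomib
# dose-response IC50 shift between genotypes.

suppressMessages(library(larvascreen))
dir.create("results", showWarnings = FALSE)

seed <- 20180507

# eclosion timecourses: heterozygote, untreated mutant (2-day delay,
# 32% survival), hormone-treated mutant (delay halved, survival doubled)
het <- simulate_dev_events(137, days = 9:14, median_day = 10,
                           label = "het", seed = substream_seed(seed, 11))
hom <- simulate_dev_events(150, days = 9:14, median_day = 10, delay = 2,
                           survival = 0.32, label = "hom",
                           seed = substream_seed(seed, 12))
hom20e <- simulate_dev_events(150, days = 9:14, median_day = 10, delay = 1,
                              survival = 0.64, label = "hom+20E",
                              seed = substream_seed(seed, 13))
tc <- lapply(list(het = het, hom = hom, `hom+20E` = hom20e),
             cumulative_fraction)
utils::write.csv(do.call(rbind, Map(cbind, label = names(tc), tc)),
                 "results/eclosion_timecourses.csv", row.names = FALSE)
grDevices::png("results/eclosion_timecourses.png", 640, 480)
plot_timecourses(tc)
grDevices::dev.off()
cat(sprintf("median eclosion day: het %d, hom %d, hom+20E %d\n",
            median_event_day(het), median_event_day(hom),
            median_event_day(hom20e)))

# per-vial eclosion fractions, 10 vials per arm
arms <- with_seed(substream_seed(seed, 14), {
  list(treated = rbinom(10, 25, 0.32 * 4 * 0.32) / 25,   # ~4x rescue
       control = rbinom(10, 25, 0.32 * 0.32) / 25)
})
fc <- eclosion_fold_change(arms$treated, arms$control)
cat(sprintf("eclosion fold change: %.2f (t = %.2f, p = %.2g)\n",
            fc$fold_change, fc$t_statistic, fc$p_value))

# larval size: 20 mutant vs 19 control larvae in dishes
sizes <- with_seed(substream_seed(seed, 15), {
  compare_sizes(rlarva_area(20, 0.75 * 250, 0.15), rlarva_area(19, 250, 0.15))
})
cat(sprintf("mutant/control size ratio: %.2f (p = %.2g)\n",
            sizes$ratio, sizes$p_value))

# bortezomib sensitisation: paired 4PL fits, true 10x IC50 shift
doses <- rep(c(0, 1, 5, 10, 25), each = 8)
f4 <- function(x, top, bottom, ic50, slope)
  bottom + (top - bottom) / (1 + (x / ic50)^slope)
resp <- with_seed(substream_seed(seed, 16), {
  list(mut = f4(doses, 100, 15, 1, 1.5) * (1 + rnorm(length(doses), 0, 0.05)),
       het = f4(doses, 100, 15, 10, 1.5) * (1 + rnorm(length(doses), 0, 0.05)))
})
fm <- fit_dose_response(doses, resp$mut)
fh <- fit_dose_response(doses, resp$het)
dr <- data.frame(genotype = c("hom", "het"),
                 ic50 = c(fm$ic50, fh$ic50),
                 slope = c(fm$slope, fh$slope),
                 unreliable = c(fm$unreliable, fh$unreliable))
utils::write.csv(dr, "results/bortezomib_ic50.csv", row.names = FALSE)
cat(sprintf("bortezomib IC50: hom %.2f uM, het %.2f uM, ratio %.3f (~10x shift)\n",
            fm$ic50, fh$ic50, ic50_ratio(fm, fh)))
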