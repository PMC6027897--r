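# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk except the packaged screen tables.

# Small triplicate screen with heterogeneous planted hits, area-level.
sim_hit_screen <- function(seed, n_plates = 8, hit_every = 45,
                           artifacts = artifact_model()) {
  hits <- sprintf("C%04d", seq(5, 80 * n_plates, by = hit_every))
  cfg <- screen_config(n_plates = n_plates, true_hit_ids = hits,
                       hit_rescues = seq(0.3, 0.9,
                                         length.out = length(hits)),
                       rng_seed = seed)
  areas <- simulate_screen_areas(cfg, artifacts = artifacts)
  list(cfg = cfg, hits = hits, areas = areas)
}

# A rendered two-genotype plate plus its measurements, reused by the
# imaging tests (rendering is the slow step, so build it once per file).
render_measured_plate <- function(seed = 11, dmso_pct = 0,
                                  artifacts = no_artifacts()) {
  lay <- two_genotype_layout(dmso_pct = dmso_pct)
  sim <- simulate_plate_image(lay, seed = seed, artifacts = artifacts)
  regions <- locate_well_grid(sim$image)
  meas <- measure_plate(sim$image, regions)
  merged <- merge(meas, sim$truth[, c("well", "true_area", "overlap_px",
                                      "flag_high_bg")], by = "well")
  merged$genotype <- lay$genotype[match(merged$well, lay$well)]
  list(layout = lay, sim = sim, regions = regions, measurements = merged)
}

# Uniform-intensity well patch of given size, for background oracles.
uniform_well <- function(value = 0.7, half = 50) {
  n <- 2 * half + 1
  loc <- seq(-half, half)
  d <- sqrt(outer(loc^2, rep(1, n)) + outer(rep(1, n), loc^2))
  list(pixels = matrix(value, n, n), disc = d < half,
       analysis = d < 0.95 * half - 1.5, radius = half)
}

# Insert a sharp-edged dark blob (disc) into a well patch.
add_blob <- function(well, depth = 0.3, radius = 12, at = c(0, 0)) {
  n <- nrow(well$pixels)
  half <- (n - 1) / 2
  loc <- seq(-half, half)
  d <- sqrt(outer((loc - at[1])^2, rep(1, n)) +
              outer(rep(1, n), (loc - at[2])^2))
  well$pixels[d <= radius] <- well$pixels[d <= radius] - depth
  well$blob_mask <- d <= radius
  well
}
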