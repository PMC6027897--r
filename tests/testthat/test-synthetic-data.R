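# The generator is first-class code: its ground truth feeds every
# downstream oracle, so its own guarantees are tested here.

test_that("capsule rasterisation matches the analytic stadium area", {
  # tube formula: area = L*W + pi*W^2/4, independent of mild curvature
  cases <- list(c(L = 40, W = 8, curv = 0, th = 0),
                c(L = 40, W = 8, curv = 0.2, th = 0.7),
                c(L = 25, W = 6, curv = -0.15, th = 2.1),
                c(L = 60, W = 10, curv = 0.1, th = 1.0))
  for (cs in cases) {
    rl <- render_larva(larva_spec(cs["L"], cs["W"], curvature = cs["curv"],
                                  orientation = cs["th"]))
    analytic <- cs["L"] * cs["W"] + pi * cs["W"]^2 / 4
    expect_lt(abs(rl$area - analytic) / analytic, 0.05)
    expect_gt(rl$mask_area, 0)
  }
})

test_that("degenerate larva dimensions are rejected", {
  expect_error(larva_spec(0, 8), "length > width > 0")
  expect_error(larva_spec(10, -1), "length > width > 0")
  expect_error(larva_spec(5, 8), "length > width > 0")  # width >= length
})

test_that("rendered larvae stay inside the well disc", {
  geom <- grid_geometry()
  lay <- two_genotype_layout()
  sim <- simulate_plate_image(lay, seed = 3, geometry = geom)
  # every truth pixel was painted inside a disc by construction; check the
  # complement: outside-rim annulus of each well is untouched by larvae
  # (a larva escaping its disc would darken the rim ring or beyond)
  expect_true(all(sim$truth$true_area <= pi * geom$radius^2))
  # and a spec too large for the disc is rejected outright
  big <- larva_spec(2.2 * geom$radius, 10)
  expect_error(
    render_plate(lay, setNames(list(list(big)), lay$well[1]), seed = 1),
    "does not fit|too large")
})

test_that("plate rendering is a pure function of seed and config", {
  lay <- two_genotype_layout()
  a <- simulate_plate_image(lay, seed = 42)
  b <- simulate_plate_image(lay, seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- simulate_plate_image(lay, seed = 43)
  expect_false(identical(a$image, c$image))
})

test_that("per-well ground truth equals the sum of disjoint mask areas", {
  # three larvae at fixed, well-separated positions: union == sum
  geom <- grid_geometry()
  lay <- plate_layout()
  ctr <- geom$centers[1, ]
  specs <- list(
    larva_spec(24, 6, position = c(ctr$cy - 25, ctr$cx), orientation = 0.3),
    larva_spec(24, 6, position = c(ctr$cy + 22, ctr$cx - 18),
               orientation = 1.8),
    larva_spec(24, 6, position = c(ctr$cy + 18, ctr$cx + 22),
               orientation = 2.9))
  masks <- lapply(specs, render_larva)
  sim <- render_plate(lay, setNames(list(specs), ctr$well), seed = 1)
  tr <- sim$truth[sim$truth$well == ctr$well, ]
  expect_identical(tr$overlap_px, 0)
  expect_equal(tr$true_area, sum(vapply(masks, `[[`, 0, "mask_area")))
  expect_identical(tr$n_larvae, 3L)
})

test_that("area tables are reproducible and carry the layout structure", {
  cfg <- screen_config(n_plates = 2, rng_seed = 99)
  a <- simulate_screen_areas(cfg)
  b <- simulate_screen_areas(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 2 * 3 * 96)
  expect_equal(sum(a$role == "TEST"), 2 * 3 * 80)
  # replicates share one compound map
  m <- unique(a[a$role == "TEST", c("plate", "well", "compound_id")])
  expect_equal(nrow(m), 2 * 80)
})

test_that("DMSO size response is flat below onset and non-increasing above", {
  m <- size_model()
  doses <- seq(0, 0.5, by = 0.005)
  f <- dmso_size_factor(doses, m)
  expect_true(all(f[doses <= m$dmso_onset] == 1))
  expect_true(all(diff(f) <= 1e-12))
  # anchor: vehicle MTD reproduces the in-plate genotype ratio
  expect_equal(m$genotype_ratio_untreated * dmso_size_factor(0.1, m),
               m$genotype_ratio_vehicle, tolerance = 1e-10)
  hom <- expected_larva_area(m, "hom", doses)
  expect_true(all(diff(hom) <= 1e-9))
})

test_that("null screens are calibrated: Z mean ~0, SD ~1 across 50+ plates", {
  m0 <- size_model(genotype_ratio_untreated = 1, genotype_ratio_vehicle = 1)
  cfg <- screen_config(n_plates = 18, rng_seed = 202)   # 54 plates total
  ar <- simulate_screen_areas(cfg, model = m0, artifacts = no_artifacts())
  z <- screen_zscores(ar)
  byp <- split(z$z, list(z$rep, z$plate))
  expect_gt(length(byp), 50)
  expect_lt(abs(mean(vapply(byp, mean, 0))), 0.1)
  # per-plate SDs are right-skewed by the n=8 control denominator, so the
  # robust centre is the calibration summary
  expect_gt(median(vapply(byp, sd, 0)), 0.8)
  expect_lt(median(vapply(byp, sd, 0)), 1.2)
})

test_that("with no effects, control groups are statistically exchangeable", {
  # genotype ratio 1, no DMSO effect: NEG (hom+vehicle) and POS1
  # (het+vehicle) are the same distribution; two-sample test should be
  # non-significant at alpha = 0.01 in >= 95% of seeded runs
  m0 <- size_model(genotype_ratio_untreated = 1, genotype_ratio_vehicle = 1)
  p <- vapply(1:100, function(s) {
    cfg <- screen_config(n_plates = 1, n_replicates = 1, rng_seed = 1000 + s)
    ar <- simulate_screen_areas(cfg, model = m0, artifacts = no_artifacts())
    stats::t.test(ar$area[ar$role == "NEG"],
                  ar$area[ar$role == "POS1"])$p.value
  }, 0)
  expect_gte(mean(p > 0.01), 0.95)
})

test_that("null pre-hit rate matches a brute-force Monte-Carlo oracle", {
  # oracle: exceedance of Z > 2 for one test well standardised against 8
  # same-plate negative wells, everything drawn from the null well-total
  # distribution (sum of 3 lognormal larvae)
  B <- 1e5
  p1 <- with_seed(77, {
    draw_well <- function(n) matrix(rlarva_area(3 * n, 250, 0.15), 3)
    mean(vapply(seq_len(B), function(i) {
      neg <- colSums(draw_well(8))
      x <- sum(rlarva_area(3, 250, 0.15))
      (x - mean(neg)) / sd(neg) > 2
    }, TRUE))
  })
  exp_rate <- 3 * p1^2 * (1 - p1) + p1^3   # >= 2 of 3 replicates
  m0 <- size_model(genotype_ratio_untreated = 1, genotype_ratio_vehicle = 1)
  cfg <- screen_config(n_plates = 32, rng_seed = 55)
  ar <- simulate_screen_areas(cfg, model = m0, artifacts = no_artifacts())
  ph <- call_prehits(screen_ztable(ar))
  n <- 80 * 32
  expect_lt(abs(sum(ph$is_prehit) - n * exp_rate),
            3 * sqrt(n * exp_rate * (1 - exp_rate)) + 1)
})

test_that("developmental event tables respect delay and survival", {
  # identical spreads, 2-day shift: medians differ by exactly 2
  e1 <- simulate_dev_events(300, days = 5:20, median_day = 10, seed = 8)
  e2 <- simulate_dev_events(300, days = 5:20, median_day = 10, delay = 2,
                            seed = 8)
  expect_equal(median_event_day(e2) - median_event_day(e1), 2)
  # survival 0.32 recovered within binomial error at n = 200
  ev <- simulate_dev_events(200, survival = 0.32, seed = 4)
  frac <- attr(ev, "n_survivors") / attr(ev, "n_total")
  expect_lt(abs(frac - 0.32), 3 * sqrt(0.32 * 0.68 / 200))
  # full-survival control
  ev1 <- simulate_dev_events(200, survival = 1, seed = 4)
  expect_identical(attr(ev1, "n_survivors"), 200L)
  # zero individuals: empty timecourse, normalisation refuses
  ev0 <- simulate_dev_events(0, seed = 1)
  expect_identical(sum(ev0$count), 0L)
  expect_error(cumulative_fraction(ev0), "positive")
})

test_that("substream seeds are deterministic, distinct and 32-bit safe", {
  s <- substream_seed(123456789, 0:999)
  expect_true(all(s >= 0), all(s < 2^31))
  expect_identical(anyDuplicated(s), 0L)
  expect_identical(substream_seed(1, 5), substream_seed(1, 5))
})
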