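#' Detect larvae in a well by difference segmentation
#'
#' Areas with a high absolute difference between the observed well and its
#' estimated empty background are taken to be larvae: pixels with
#' `|observed - estimate| > diff_threshold` inside the analysis region are
#' labelled into connected components and components smaller than
#' `min_area` are discarded. By default the threshold is `k_mad` times the
#' MAD of the difference image over the analysis region (a per-well
#' fallback; [measure_plate()] pools the MAD over all 96 wells, which is
#' robust to wells dominated by artifacts).
#'
#' @param well A [well_patch()].
#' @param bg A `background_model` from [estimate_empty_background()].
#' @param diff_threshold Intensity threshold; must be positive if given.
#' @param min_area Minimum component area, pixels. The default suits the
#'   simulator's smallest larvae (about a quarter of their area).
#' @param k_mad Multiplier for the MAD-based default threshold.
#' @return A `well_measurement` list: `components` (data frame with
#'   `area`, `cy`, `cx`, `mean_diff`), `total_area`, `n_components`,
#'   `residual_metric`, `threshold`.
#' @export
detect_larvae <- function(well, bg, diff_threshold = NULL, min_area = 30,
                          k_mad = 5) {
  stopifnot(inherits(bg, "background_model"))
  px <- well$pixels
  an <- bg$analysis
  diff <- abs(px - bg$estimate)
  if (is.null(diff_threshold))
    diff_threshold <- k_mad * stats::mad(diff[an], center = 0)
  if (!is.numeric(diff_threshold) || diff_threshold <= 0)
    stop("diff_threshold must be positive")
  seg <- diff > diff_threshold & an
  lab <- EBImage::bwlabel(EBImage::Image(seg * 1))
  lab <- matrix(as.integer(lab), nrow(px), ncol(px))
  comps <- data.frame(area = numeric(0), cy = numeric(0), cx = numeric(0),
                      mean_diff = numeric(0))
  if (max(lab) > 0) {
    for (id in seq_len(max(lab))) {
      idx <- which(lab == id)
      if (length(idx) < min_area) next
      rr <- ((idx - 1) %% nrow(px)) + 1
      cc <- ((idx - 1) %/% nrow(px)) + 1
      comps <- rbind(comps, data.frame(
        area = length(idx), cy = mean(rr), cx = mean(cc),
        mean_diff = mean(diff[idx])))
    }
  }
  structure(list(components = comps, total_area = sum(comps$area),
                 n_components = nrow(comps),
                 residual_metric = bg$residual_metric,
                 threshold = diff_threshold),
            class = "well_measurement")
}

#' Flag a well as high-background
#'
#' True when the background residual metric strictly exceeds the cutoff; a
#' residual exactly at the cutoff is not flagged. The default cutoff should
#' be calibrated as the 99th percentile of clean simulated wells
#' ([calibrate_residual_cutoff()]).
#'
#' @param measurement A `well_measurement` (or any list with
#'   `residual_metric`).
#' @param residual_cutoff Cutoff on the residual metric.
#' @return Logical.
#' @export
flag_high_background <- function(measurement, residual_cutoff) {
  stopifnot(is.numeric(residual_cutoff), length(residual_cutoff) == 1L)
  measurement$residual_metric > residual_cutoff
}

#' Calibrate the high-background residual cutoff on clean simulated wells
#'
#' Renders `n` artifact-free wells spanning the size model's range (empty,
#' heterozygote and homozygote occupancy), measures their background
#' residual metric and returns its 99th percentile.
#'
#' @param n Number of clean wells.
#' @param model A [size_model()].
#' @param geometry A [grid_geometry()].
#' @param seed Integer seed.
#' @param probs Quantile to report.
#' @return The cutoff (named numeric).
#' @export
calibrate_residual_cutoff <- function(n = 100, model = size_model(),
                                      geometry = grid_geometry(), seed = 1L,
                                      probs = 0.99) {
  res <- simulate_wells(n, model = model, geometry = geometry, seed = seed,
                        artifacts = no_artifacts())$measurements$residual_metric
  stats::quantile(res, probs)
}

#' Simulate and measure a batch of single wells
#'
#' Convenience driver for calibration and oracle tests: renders `n`
#' single-well plates' worth of wells (one well each on a minimal 1-well
#' canvas would distort the grid, so wells are cut from small rendered
#' plates) and runs background estimation + detection on each.
#'
#' @param n Number of wells.
#' @param model,geometry,seed,artifacts As elsewhere.
#' @param genotype_mix Probabilities of (empty, het, hom) occupancy.
#' @param larvae_per_well Larvae per occupied well.
#' @param dmso_pct Vehicle dose applied to occupied wells.
#' @return List with `measurements` (data frame incl. `true_area`,
#'   `flag_high_bg_true`) and `cutoff_inputs`.
#' @export
simulate_wells <- function(n, model = size_model(),
                           geometry = grid_geometry(), seed = 1L,
                           artifacts = no_artifacts(),
                           genotype_mix = c(empty = 0.1, het = 0.45,
                                            hom = 0.45),
                           larvae_per_well = 3, dmso_pct = 0.1) {
  n_plates <- ceiling(n / 96)
  out <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    lay <- plate_layout(dmso_pct = dmso_pct, plate_id = p)
    occ <- with_seed(substream_seed(seed, 2L * p), {
      sample(names(genotype_mix), 96, replace = TRUE, prob = genotype_mix)
    })
    lay$genotype <- ifelse(occ == "het", "het", "hom")
    lay2 <- lay
    lay2$compound_id <- NA_character_
    lay2$n_larvae <- ifelse(occ == "empty", 0L, larvae_per_well)
    sim <- simulate_plate_image(
      lay2, model = model, artifacts = artifacts, geometry = geometry,
      seed = substream_seed(seed, 2L * p + 1L),
      larvae_per_well = larvae_per_well)
    regions <- locate_well_grid(sim$image, geometry)
    meas <- measure_plate(sim$image, regions)
    meas$true_area <- sim$truth$true_area[match(meas$well, sim$truth$well)]
    meas$flag_high_bg_true <-
      sim$truth$flag_high_bg[match(meas$well, sim$truth$well)]
    meas$occupied <- occ != "empty"
    meas$plate <- p
    out[[p]] <- meas
  }
  meas <- do.call(rbind, out)[seq_len(min(n, 96 * n_plates)), ]
  list(measurements = meas)
}

#' Measure every well of a plate image
#'
#' Runs background estimation and difference segmentation on all 96 wells.
#' The difference threshold is global: `k_mad` times the MAD of the pooled
#' difference image over all wells, so single artifact-dominated wells
#' cannot inflate their own threshold.
#'
#' @param image Plate image matrix.
#' @param regions Well regions from [locate_well_grid()].
#' @param k_mad Threshold multiplier.
#' @param min_area Minimum component area, pixels.
#' @param edge_margin,grad_k Passed to [estimate_empty_background()].
#' @param residual_cutoff Optional cutoff; when given, adds a
#'   `flag_high_bg` column via [flag_high_background()].
#' @return Data frame with one row per well: `well`, `row`, `col`,
#'   `n_components`, `total_area_px`, `residual_metric` and optionally
#'   `flag_high_bg`.
#' @export
measure_plate <- function(image, regions, k_mad = 5, min_area = 30,
                          edge_margin = 3, grad_k = 5,
                          residual_cutoff = NULL) {
  wells <- vector("list", nrow(regions))
  bgs <- vector("list", nrow(regions))
  diffs <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    w <- well_patch(image, regions[i, ])
    b <- estimate_empty_background(w, edge_margin = edge_margin,
                                   grad_k = grad_k)
    wells[[i]] <- w; bgs[[i]] <- b
    diffs[[i]] <- abs(w$pixels - b$estimate)[b$analysis]
  }
  thr <- k_mad * stats::mad(unlist(diffs), center = 0)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    m <- detect_larvae(wells[[i]], bgs[[i]], diff_threshold = thr,
                       min_area = min_area)
    data.frame(well = regions$well[i], row = regions$row[i],
               col = regions$col[i], n_components = m$n_components,
               total_area_px = m$total_area,
               residual_metric = m$residual_metric,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  if (!is.null(residual_cutoff))
    df$flag_high_bg <- df$residual_metric > residual_cutoff
  attr(df, "diff_threshold") <- thr
  df
}

#' Write per-well measurements as CSV
#'
#' @param measurements Data frame from [measure_plate()].
#' @param path Output path.
#' @param plate_id Optional plate identifier column.
#' @export
write_well_measurements <- function(measurements, path, plate_id = NULL) {
  if (!is.null(plate_id)) measurements$plate <- plate_id
  utils::write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}
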