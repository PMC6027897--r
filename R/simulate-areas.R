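#' Simulate replicate well-area tables for a whole screen
#'
#' Area-level fast path for the statistics of the screen: skips image
#' rendering and draws per-well total larval areas directly from the size
#' model, with the plate layout's control scheme, optional planted true
#' hits, and the two artifact processes. All replicates share one compound
#' map; every plate/replicate runs in its own RNG substream so outputs are a
#' pure function of the configuration and master seed.
#'
#' Columns of the returned table: `rep`, `plate`, `well`, `row`, `col`,
#' `role`, `genotype`, `compound_id`, `substance`, `dose_uM`, `dmso_pct`,
#' `true_area` (biological ground truth; includes the low-DMSO boost, which
#' is a real size change), `area` (measured equivalent; high-background
#' wells are inflated by `bg_area_inflation`), `flag_high_bg`,
#' `flag_low_dmso`, `is_true_hit`.
#'
#' @param config A [screen_config()].
#' @param model A [size_model()].
#' @param artifacts An [artifact_model()]; use [no_artifacts()] for clean
#'   screens.
#' @param substance_map Optional named character vector mapping compound_id
#'   to substance name (for duplicate-substance library wells); defaults to
#'   the compound id itself.
#' @param dmso_pct Vehicle concentration for NEG/TEST/POS1 wells.
#' @return A long data frame with one row per well per replicate.
#' @export
simulate_screen_areas <- function(config, model = size_model(),
                                  artifacts = artifact_model(),
                                  substance_map = NULL, dmso_pct = 0.1) {
  stopifnot(inherits(config, "screen_config"), inherits(model, "size_model"),
            inherits(artifacts, "artifact_model"))
  n_cmpd <- 80L * config$n_plates
  cmpds <- sprintf("C%04d", seq_len(n_cmpd))
  # compound-level artifact propensities and severities, shared by all
  # replicates: how much food a compound leaves uneaten, and how much DMSO
  # a faulty source well loses, are compound properties
  prone <- with_seed(substream_seed(config$rng_seed, 0L), {
    bg <- cmpds[stats::runif(n_cmpd) < artifacts$p_bg_compound]
    ld <- cmpds[stats::runif(n_cmpd) < artifacts$p_ld_compound]
    list(bg = bg, ld = ld,
         bg_infl = stats::setNames(
           1 + (artifacts$bg_area_inflation - 1) *
             stats::rlnorm(length(bg), 0, 0.5), bg),
         ld_boost = stats::setNames(
           stats::runif(length(ld), 1 + 0.3 * (artifacts$low_dmso_size_boost - 1),
                        artifacts$low_dmso_size_boost), ld))
  })
  rescue_of <- function(id) {
    i <- match(id, config$true_hit_ids)
    ifelse(is.na(i), 0,
           if (is.null(config$hit_rescues)) model$hit_rescue
           else config$hit_rescues[i])
  }
  out <- vector("list", config$n_replicates * config$n_plates)
  k <- 0L
  for (rep_i in seq_len(config$n_replicates)) {
    for (plate_i in seq_len(config$n_plates)) {
      lay <- plate_layout(
        compound_ids = cmpds[(plate_i - 1L) * 80L + 1:80],
        dmso_pct = dmso_pct, plate_id = plate_i)
      seed <- substream_seed(config$rng_seed,
                             (rep_i - 1L) * config$n_plates + plate_i)
      tab <- with_seed(seed, {
        rescue <- ifelse(is.na(lay$compound_id), 0, rescue_of(lay$compound_id))
        mu <- vapply(seq_len(96L), function(i)
          expected_larva_area(model, lay$genotype[i], lay$dmso_pct[i],
                              rescue[i]), numeric(1))
        true_area <- vapply(mu, function(m)
          sum(rlarva_area(config$larvae_per_well, m, model$cv)), numeric(1))
        bg_prone <- !is.na(lay$compound_id) & lay$compound_id %in% prone$bg
        ld_prone <- !is.na(lay$compound_id) & lay$compound_id %in% prone$ld
        flag_bg <- stats::runif(96L) < artifacts$p_high_background |
          (bg_prone & stats::runif(96L) < artifacts$penetrance)
        # only vehicle-bearing wells can suffer the low-DMSO artifact
        flag_ld <- (stats::runif(96L) < artifacts$p_low_dmso |
                      (ld_prone & stats::runif(96L) < artifacts$penetrance)) &
          lay$dmso_pct > 0
        boost <- ifelse(flag_ld & lay$genotype == "hom",
                        ifelse(ld_prone,
                               prone$ld_boost[lay$compound_id],
                               artifacts$low_dmso_size_boost), 1)
        boost[is.na(boost)] <- 1
        true_area <- true_area * boost
        infl <- ifelse(flag_bg,
                       ifelse(bg_prone, prone$bg_infl[lay$compound_id],
                              artifacts$bg_area_inflation), 1)
        infl[is.na(infl)] <- 1
        area <- true_area * infl
        cbind(lay, data.frame(true_area = true_area, area = area,
                              flag_high_bg = flag_bg, flag_low_dmso = flag_ld))
      })
      tab$rep <- rep_i
      k <- k + 1L
      out[[k]] <- tab
    }
  }
  df <- do.call(rbind, out)
  df$substance <- if (is.null(substance_map)) df$compound_id else {
    s <- substance_map[df$compound_id]
    ifelse(is.na(s), df$compound_id, unname(s))
  }
  df$is_true_hit <- !is.na(df$compound_id) &
    df$compound_id %in% config$true_hit_ids
  rownames(df) <- NULL
  df[, c("rep", "plate", "well", "row", "col", "role", "genotype",
         "compound_id", "substance", "dose_uM", "dmso_pct", "true_area",
         "area", "flag_high_bg", "flag_low_dmso", "is_true_hit")]
}

#' Write a well-area table as CSV
#'
#' @param areas Data frame from [simulate_screen_areas()] (or the same
#'   columns).
#' @param path Output path.
#' @export
write_area_csv <- function(areas, path) {
  utils::write.csv(areas, path, row.names = FALSE)
  invisible(path)
}
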