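#' Larval size model
#'
#' Parametrises the biology the screen assumes. Larval areas are lognormal
#' with genotype-dependent means: on untreated food, homozygous mutant larvae
#' average `genotype_ratio_untreated` (default 0.75) of the heterozygote
#' mean; the DMSO vehicle acts as a sensitiser so that at the homozygote
#' maximum tolerated dose (`dmso_mtd`, default 0.1% v/v) the in-plate ratio
#' falls to `genotype_ratio_vehicle` (default 0.5). The DMSO effect is a
#' multiplicative Hill-type decline acting on homozygotes only, with no
#' effect at or below `dmso_onset` (default 0.025% v/v); heterozygotes are
#' treated as insensitive over the screened dose range (their adverse-effect
#' threshold lies far above 0.1%). True-hit compounds restore a fraction
#' `hit_rescue` of the homozygote-to-heterozygote deficit.
#'
#' @param het_mean_area Mean heterozygote larval area (pixels).
#' @param genotype_ratio_untreated Homozygote/heterozygote mean-area ratio
#'   without DMSO.
#' @param genotype_ratio_vehicle Ratio under the 0.1% v/v vehicle.
#' @param cv Coefficient of variation of the per-larva lognormal area.
#' @param dmso_onset Dose (% v/v) below which DMSO has no size effect.
#' @param dmso_mtd Homozygote maximum tolerated dose (% v/v).
#' @param dmso_hill Hill slope of the multiplicative size decline.
#' @param dmso_lethal Dose (% v/v) at and above which homozygote lethality
#'   reaches 100% (lethality ramps linearly from `dmso_mtd`).
#' @param hit_rescue Default fractional restoration of homozygote size for
#'   true-hit compounds, in `[0, 1]`.
#' @return A `size_model` list.
#' @export
size_model <- function(het_mean_area = 250,
                       genotype_ratio_untreated = 0.75,
                       genotype_ratio_vehicle = 0.5,
                       cv = 0.15,
                       dmso_onset = 0.025,
                       dmso_mtd = 0.1,
                       dmso_hill = 2,
                       dmso_lethal = 0.4,
                       hit_rescue = 0.8) {
  m <- list(het_mean_area = het_mean_area,
            genotype_ratio_untreated = genotype_ratio_untreated,
            genotype_ratio_vehicle = genotype_ratio_vehicle,
            cv = cv, dmso_onset = dmso_onset, dmso_mtd = dmso_mtd,
            dmso_hill = dmso_hill, dmso_lethal = dmso_lethal,
            hit_rescue = hit_rescue)
  with(m, {
    stopifnot(het_mean_area > 0, cv > 0,
              genotype_ratio_untreated > 0, genotype_ratio_untreated <= 1,
              genotype_ratio_vehicle > 0,
              genotype_ratio_vehicle <= genotype_ratio_untreated,
              dmso_onset >= 0, dmso_mtd > dmso_onset,
              dmso_lethal > dmso_mtd, dmso_hill > 0,
              hit_rescue >= 0, hit_rescue <= 1)
  })
  structure(m, class = "size_model")
}

#' Multiplicative DMSO size factor for homozygotes
#'
#' Hill-type decline anchored so the factor is 1 at or below the onset dose
#' and equals `genotype_ratio_vehicle / genotype_ratio_untreated` at the
#' maximum tolerated dose (the half-effect point of the Hill term). The
#' factor is non-increasing in dose.
#'
#' @param dmso_pct Dose(s) in % v/v.
#' @param model A [size_model()].
#' @return Numeric vector of factors in `(0, 1]`.
#' @export
dmso_size_factor <- function(dmso_pct, model) {
  stopifnot(inherits(model, "size_model"), all(dmso_pct >= 0))
  f_mtd <- model$genotype_ratio_vehicle / model$genotype_ratio_untreated
  amp <- 2 * (1 - f_mtd)            # saturating decline; half-effect at MTD
  d <- pmax(dmso_pct - model$dmso_onset, 0)
  k <- model$dmso_mtd - model$dmso_onset
  theta <- d^model$dmso_hill / (d^model$dmso_hill + k^model$dmso_hill)
  theta[d == 0] <- 0
  1 - amp * theta
}

#' Homozygote death probability under DMSO
#'
#' Zero at or below the maximum tolerated dose, ramping linearly to 1 at
#' `dmso_lethal` (100% homozygote lethality).
#'
#' @inheritParams dmso_size_factor
#' @export
dmso_death_prob <- function(dmso_pct, model) {
  stopifnot(inherits(model, "size_model"))
  pmin(pmax((dmso_pct - model$dmso_mtd) /
              (model$dmso_lethal - model$dmso_mtd), 0), 1)
}

#' Expected larval area for a well condition
#'
#' @param model A [size_model()].
#' @param genotype `"het"` or `"hom"`.
#' @param dmso_pct DMSO dose (% v/v).
#' @param rescue Fractional restoration toward the heterozygote mean (true
#'   hits); default 0.
#' @return Expected per-larva area in pixels.
#' @export
expected_larva_area <- function(model, genotype, dmso_pct = 0, rescue = 0) {
  stopifnot(genotype %in% c("het", "hom"), rescue >= 0, rescue <= 1)
  het <- model$het_mean_area
  if (genotype == "het") return(rep_len(het, length(dmso_pct)))
  hom <- het * model$genotype_ratio_untreated * dmso_size_factor(dmso_pct, model)
  hom + rescue * (het - hom)
}

#' Draw lognormal larval areas with a given mean and CV
#'
#' @param n Number of draws.
#' @param mean_area Target arithmetic mean.
#' @param cv Coefficient of variation.
#' @export
rlarva_area <- function(n, mean_area, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean_area) - sdlog^2 / 2, sdlog = sdlog)
}

#' Artifact model for the two known false-positive processes
#'
#' Uneaten food raises the image background of a well, inflating the
#' measured larval area; dispensing failures / DMSO hydration variability
#' lower the effective DMSO dose, yielding larger (less sensitised) larvae.
#' Each process has two components: a per-well accident rate (independent
#' across replicates) and a compound-level rate — compounds that sicken
#' larvae leave food uneaten in every replicate, and a faulty library
#' source well under-dispenses DMSO in every replicate — expressed in each
#' replicate with probability `penetrance`. The compound-level component is
#' what makes artifact wells reproducible across replicates, and hence a
#' major source of replicated false-positive pre-hits.
#'
#' @param p_high_background Per-well accident probability of an
#'   uneaten-food high-background well.
#' @param food_blob_intensity Fractional darkening at the blob centre
#'   (rendering) and, at the area level, the factor by which measured area
#'   is inflated is `bg_area_inflation`.
#' @param food_blob_extent Gaussian radius of the blob as a fraction of the
#'   well radius.
#' @param bg_area_inflation Multiplier applied to the measured area of a
#'   high-background well in area-level simulations.
#' @param p_low_dmso Per-well accident probability of a low/absent-DMSO
#'   well.
#' @param low_dmso_size_boost Multiplier (> 1) applied to larval size in
#'   low-DMSO wells; the default 1.5 corresponds to losing the vehicle
#'   sensitisation entirely (0.75/0.5).
#' @param p_bg_compound Probability that a library compound induces the
#'   uneaten-food artifact in every replicate.
#' @param p_ld_compound Probability that a library source well
#'   under-dispenses DMSO in every replicate.
#' @param penetrance Probability that a compound-level artifact expresses
#'   in any one replicate well.
#' @return An `artifact_model` list.
#' @export
artifact_model <- function(p_high_background = 0.003,
                           food_blob_intensity = 0.25,
                           food_blob_extent = 0.35,
                           bg_area_inflation = 1.6,
                           p_low_dmso = 0.002,
                           low_dmso_size_boost = 1.5,
                           p_bg_compound = 0.015,
                           p_ld_compound = 0.005,
                           penetrance = 0.95) {
  stopifnot(p_high_background >= 0, p_high_background <= 1,
            p_low_dmso >= 0, p_low_dmso <= 1,
            p_bg_compound >= 0, p_bg_compound <= 1,
            p_ld_compound >= 0, p_ld_compound <= 1,
            penetrance >= 0, penetrance <= 1,
            low_dmso_size_boost > 1,
            food_blob_intensity > 0, food_blob_extent > 0,
            bg_area_inflation > 1)
  structure(list(p_high_background = p_high_background,
                 food_blob_intensity = food_blob_intensity,
                 food_blob_extent = food_blob_extent,
                 bg_area_inflation = bg_area_inflation,
                 p_low_dmso = p_low_dmso,
                 low_dmso_size_boost = low_dmso_size_boost,
                 p_bg_compound = p_bg_compound,
                 p_ld_compound = p_ld_compound,
                 penetrance = penetrance),
            class = "artifact_model")
}

#' No-artifact model
#' @export
no_artifacts <- function() {
  a <- artifact_model()
  a$p_high_background <- 0
  a$p_low_dmso <- 0
  a$p_bg_compound <- 0
  a$p_ld_compound <- 0
  a
}

#' Screen configuration
#'
#' @param n_plates Plates per replicate (the pilot screen ran 32 plates of
#'   an ~2,532-compound library in triplicate).
#' @param n_replicates Biological replicates sharing the compound map.
#' @param larvae_per_well Larvae dispensed per well.
#' @param true_hit_ids Compound identifiers treated as true size-rescuing
#'   hits.
#' @param hit_rescues Optional numeric vector of per-hit rescue fractions
#'   (recycled against `true_hit_ids`); defaults to the size model's
#'   `hit_rescue`.
#' @param rng_seed Master seed; per plate/replicate substreams are derived
#'   with [substream_seed()].
#' @return A `screen_config` list.
#' @export
screen_config <- function(n_plates = 4, n_replicates = 3,
                          larvae_per_well = 3, true_hit_ids = character(),
                          hit_rescues = NULL, rng_seed = 1L) {
  stopifnot(n_plates >= 1, n_replicates >= 1, larvae_per_well >= 1)
  if (!is.null(hit_rescues)) {
    stopifnot(all(hit_rescues >= 0), all(hit_rescues <= 1))
    hit_rescues <- rep_len(hit_rescues, length(true_hit_ids))
  }
  structure(list(n_plates = as.integer(n_plates),
                 n_replicates = as.integer(n_replicates),
                 larvae_per_well = as.integer(larvae_per_well),
                 true_hit_ids = true_hit_ids,
                 hit_rescues = hit_rescues,
                 rng_seed = as.integer(rng_seed)),
            class = "screen_config")
}
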