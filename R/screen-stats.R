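#' Z-prime factor
#'
#' Plate-quality statistic comparing control separation to control spread,
#' using the standard three-sigma definition
#' `1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`. Values are bounded
#' above by 1; values above 0 indicate an assay window wide enough for
#' screening.
#'
#' @param pos_areas Positive-control well areas (>= 2 values).
#' @param neg_areas Negative-control well areas (>= 2 values).
#' @return A single number <= 1.
#' @export
#' @examples
#' zprime(c(10, 10, 10), c(1, 1, 1))  # 1: perfect separation
zprime <- function(pos_areas, neg_areas) {
  if (length(pos_areas) < 2L || length(neg_areas) < 2L)
    stop("need at least 2 values per control group")
  mp <- mean(pos_areas); mn <- mean(neg_areas)
  if (mp == mn) stop("no separation: control group means are equal")
  1 - 3 * (stats::sd(pos_areas) + stats::sd(neg_areas)) / abs(mp - mn)
}

#' Per-well Z-scores against in-plate negative controls
#'
#' `Z = (x - mean(neg)) / sd(neg)` computed per plate, so each test well is
#' standardised against the same-plate negative-control wells (column 1,
#' n = 8 in the default layout). A robust variant using median/MAD is
#' available behind `robust = TRUE` but is not the default.
#'
#' @param test_areas Test-well areas.
#' @param neg_areas Same-plate negative-control areas (>= 2 values,
#'   positive spread).
#' @param robust Use median/MAD instead of mean/SD.
#' @return Numeric vector of Z-scores, one per test well.
#' @export
zscore_wells <- function(test_areas, neg_areas, robust = FALSE) {
  if (length(neg_areas) < 2L)
    stop("need at least 2 negative-control values")
  ctr <- if (robust) stats::median(neg_areas) else mean(neg_areas)
  sc <- if (robust) stats::mad(neg_areas) else stats::sd(neg_areas)
  if (sc == 0) stop("negative-control spread is zero")
  (test_areas - ctr) / sc
}

#' Per-plate control statistics and Z' for a screen table
#'
#' @param areas Long table as from [simulate_screen_areas()] (needs `rep`,
#'   `plate`, `role`, `area`).
#' @param pos_group Which positive-control group defines Z' (`"POS1"`,
#'   heterozygote + vehicle, is the default; `"POS2"` selectable).
#' @return Data frame `rep`, `plate`, `mu_pos`, `sd_pos`, `mu_neg`,
#'   `sd_neg`, `zprime`.
#' @export
plate_stats <- function(areas, pos_group = c("POS1", "POS2")) {
  pos_group <- match.arg(pos_group)
  idx <- split(seq_len(nrow(areas)),
               list(rep = areas$rep, plate = areas$plate), drop = TRUE)
  out <- lapply(idx, function(i) {
    d <- areas[i, ]
    pos <- d$area[d$role == pos_group]
    neg <- d$area[d$role == "NEG"]
    data.frame(rep = d$rep[1], plate = d$plate[1],
               mu_pos = mean(pos), sd_pos = stats::sd(pos),
               mu_neg = mean(neg), sd_neg = stats::sd(neg),
               zprime = zprime(pos, neg))
  })
  df <- do.call(rbind, out)
  df <- df[order(df$rep, df$plate), ]
  rownames(df) <- NULL
  df
}

#' Z-scores for every test well of a screen table
#'
#' @inheritParams plate_stats
#' @param robust Passed to [zscore_wells()].
#' @return The test-well rows of `areas` with a `z` column appended.
#' @export
screen_zscores <- function(areas, robust = FALSE) {
  idx <- split(seq_len(nrow(areas)),
               list(rep = areas$rep, plate = areas$plate), drop = TRUE)
  out <- lapply(idx, function(i) {
    d <- areas[i, ]
    t <- d[d$role == "TEST", ]
    t$z <- zscore_wells(t$area, d$area[d$role == "NEG"], robust = robust)
    t
  })
  df <- do.call(rbind, out)
  df <- df[order(df$rep, df$plate, df$col, df$row), ]
  rownames(df) <- NULL
  df
}

#' Merge per-replicate Z tables into one row per library well
#'
#' Rows are keyed by library well (`compound_id`); duplicate library
#' entries of the same substance remain distinct rows with a shared
#' `substance` field. A compound missing from some replicate keeps its row
#' with `NA` in that replicate's columns (never imputed).
#'
#' @param ztables List of per-replicate data frames with columns
#'   `compound_id`, `z` and optionally `substance`, `well`, `plate`,
#'   `flag_high_bg`, `flag_low_dmso`.
#' @return A `replicate_ztable` data frame with columns `compound_id`,
#'   `substance`, `z_rep1..k`, `flag_high_bg_rep1..k`,
#'   `flag_low_dmso_rep1..k`, `well_rep1..k`.
#' @export
merge_replicates <- function(ztables) {
  stopifnot(is.list(ztables), length(ztables) >= 1L)
  ids <- unique(unlist(lapply(ztables, function(t) t$compound_id)))
  if (!length(ids)) {
    out <- data.frame(compound_id = character(0), substance = character(0))
    class(out) <- c("replicate_ztable", "data.frame")
    return(out)
  }
  out <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
  subst <- rep(NA_character_, length(ids))
  for (k in seq_along(ztables)) {
    t <- ztables[[k]]
    i <- match(ids, t$compound_id)
    out[[paste0("z_rep", k)]] <- t$z[i]
    out[[paste0("flag_high_bg_rep", k)]] <-
      if ("flag_high_bg" %in% names(t)) t$flag_high_bg[i] else NA
    out[[paste0("flag_low_dmso_rep", k)]] <-
      if ("flag_low_dmso" %in% names(t)) t$flag_low_dmso[i] else NA
    out[[paste0("well_rep", k)]] <-
      if ("well" %in% names(t)) t$well[i] else NA_character_
    if ("substance" %in% names(t))
      subst <- ifelse(is.na(subst), t$substance[i], subst)
  }
  out$substance <- ifelse(is.na(subst), out$compound_id, subst)
  out <- out[, c("compound_id", "substance",
                 setdiff(names(out), c("compound_id", "substance")))]
  class(out) <- c("replicate_ztable", "data.frame")
  out
}

#' Squared Pearson correlation between matched replicate Z vectors
#'
#' In `"full"` mode all matched pairs enter; in `"extreme"` mode only pairs
#' where at least one member satisfies `|Z| > extreme_threshold` (strict)
#' are kept — the subset in which replicate agreement is expected to be
#' driven by real modifiers rather than noise. `extreme_rule = "both"`
#' requires both members to be extreme. Controls must be excluded by the
#' caller (test wells only).
#'
#' @param za,zb Matched Z-score vectors.
#' @param mode `"full"` or `"extreme"`.
#' @param extreme_threshold Threshold on |Z|.
#' @param extreme_rule `"either"` (default) or `"both"`.
#' @return Squared Pearson correlation (coefficient of determination).
#' @export
pairwise_r2 <- function(za, zb, mode = c("full", "extreme"),
                        extreme_threshold = 2,
                        extreme_rule = c("either", "both")) {
  mode <- match.arg(mode)
  extreme_rule <- match.arg(extreme_rule)
  stopifnot(length(za) == length(zb))
  ok <- !is.na(za) & !is.na(zb)
  za <- za[ok]; zb <- zb[ok]
  if (mode == "extreme") {
    ea <- abs(za) > extreme_threshold
    eb <- abs(zb) > extreme_threshold
    keep <- if (extreme_rule == "either") ea | eb else ea & eb
    za <- za[keep]; zb <- zb[keep]
  }
  if (length(za) < 3L)
    stop("fewer than 3 matched pairs after subsetting")
  if (stats::sd(za) == 0 || stats::sd(zb) == 0)
    stop("constant vector after subsetting")
  stats::cor(za, zb)^2
}

#' Replicate Z table straight from a screen area table
#'
#' Convenience wrapper: computes per-plate Z-scores for every test well
#' ([screen_zscores()]) and merges the replicates into one row per library
#' well ([merge_replicates()]).
#'
#' @inheritParams screen_zscores
#' @return A `replicate_ztable`.
#' @export
screen_ztable <- function(areas, robust = FALSE) {
  z <- screen_zscores(areas, robust = robust)
  merge_replicates(lapply(split(z, z$rep), function(d)
    data.frame(compound_id = d$compound_id, substance = d$substance,
               well = d$well, plate = d$plate, z = d$z,
               flag_high_bg = d$flag_high_bg,
               flag_low_dmso = d$flag_low_dmso,
               stringsAsFactors = FALSE)))
}
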