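#' Call pre-hits under the two-of-three-replicates rule
#'
#' A library well is a pre-hit when its Z-score strictly exceeds
#' `z_threshold` in at least `min_reps` of the replicates. Each qualifying
#' replicate pair is recorded separately: a compound with `Z > t` in all
#' three replicates qualifies in every pair row, which is why per-pair
#' counts double-count triple-qualifiers relative to the unique compound
#' list. Missing replicates (`NA`) are evaluated on the available pairs
#' only.
#'
#' @param ztable A `replicate_ztable` from [merge_replicates()] (needs
#'   `compound_id`, `substance`, `z_rep1..3`).
#' @param z_threshold Strict threshold on Z (a Z equal to the threshold
#'   does not qualify).
#' @param min_reps Minimum number of qualifying replicates.
#' @return The input with appended columns `n_reps_above`, `qual_12`,
#'   `qual_13`, `qual_23` (logical pair qualification) and `is_prehit`.
#' @export
call_prehits <- function(ztable, z_threshold = 2, min_reps = 2) {
  stopifnot(all(c("z_rep1", "z_rep2", "z_rep3") %in% names(ztable)),
            min_reps >= 1, min_reps <= 3)
  z <- as.matrix(ztable[, c("z_rep1", "z_rep2", "z_rep3")])
  above <- !is.na(z) & z > z_threshold
  if (anyNA(z))
    message(sum(!stats::complete.cases(z)),
            " compound(s) missing a replicate; evaluated on available pairs")
  ztable$n_reps_above <- rowSums(above)
  ztable$qual_12 <- above[, 1] & above[, 2]
  ztable$qual_13 <- above[, 1] & above[, 3]
  ztable$qual_23 <- above[, 2] & above[, 3]
  ztable$is_prehit <- ztable$n_reps_above >= min_reps
  ztable
}

#' Per-pair artifact triage bookkeeping
#'
#' Subtractive triage of pre-hits by replicate pair: within each pair row a
#' pre-hit is removed as high-background if either qualifying replicate
#' well carries the high-background flag, otherwise removed as low/no-DMSO
#' if either qualifying well carries that flag; the remainder is clean.
#' (When both artifact types are present the high-background category takes
#' precedence so that `clean = prehit - high_bg - low_dmso` holds exactly.)
#' A total row sums the three pair rows, so compounds qualifying in all
#' three replicates are counted once per pair row, as in per-pair
#' accounting.
#'
#' @param prehits Output of [call_prehits()] including per-replicate flag
#'   columns `flag_high_bg_rep1..3` and `flag_low_dmso_rep1..3`.
#' @return A `triage_report` data frame with rows `1&2`, `1&3`, `2&3`,
#'   `total` and columns `pair`, `n_prehit`, `n_high_bg`, `n_low_dmso`,
#'   `n_clean`, plus attribute `"clean_ids"` (compound ids clean in at
#'   least one qualifying pair).
#' @export
apply_artifact_filters <- function(prehits) {
  stopifnot(all(c("qual_12", "qual_13", "qual_23") %in% names(prehits)))
  pairs <- list(`1&2` = c(1L, 2L), `1&3` = c(1L, 3L), `2&3` = c(2L, 3L))
  qcol <- c(`1&2` = "qual_12", `1&3` = "qual_13", `2&3` = "qual_23")
  flag_or <- function(df, prefix, i, j) {
    a <- df[[paste0(prefix, i)]]; b <- df[[paste0(prefix, j)]]
    (!is.na(a) & a) | (!is.na(b) & b)
  }
  clean_ids <- character(0)
  rows <- lapply(names(pairs), function(p) {
    i <- pairs[[p]][1]; j <- pairs[[p]][2]
    q <- prehits[[qcol[p]]]
    d <- prehits[q, , drop = FALSE]
    bg <- flag_or(d, "flag_high_bg_rep", i, j)
    ld <- !bg & flag_or(d, "flag_low_dmso_rep", i, j)
    clean_ids <<- union(clean_ids, d$compound_id[!bg & !ld])
    data.frame(pair = p, n_prehit = nrow(d), n_high_bg = sum(bg),
               n_low_dmso = sum(ld), n_clean = sum(!bg & !ld),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- rbind(df, data.frame(pair = "total", n_prehit = sum(df$n_prehit),
                             n_high_bg = sum(df$n_high_bg),
                             n_low_dmso = sum(df$n_low_dmso),
                             n_clean = sum(df$n_clean)))
  attr(df, "clean_ids") <- clean_ids
  class(df) <- c("triage_report", "data.frame")
  df
}

#' Build a triage report from per-pair counts
#'
#' For screens where only aggregate per-pair counts are available (e.g.
#' published triage tables), computes the clean counts and the totals row
#' from the subtractive bookkeeping `clean = prehit - high_bg - low_dmso`.
#'
#' @param counts Data frame with columns `pair`, `n_prehit`, `n_high_bg`,
#'   `n_low_dmso` (one row per replicate pair).
#' @return A `triage_report` as in [apply_artifact_filters()].
#' @export
triage_from_counts <- function(counts) {
  stopifnot(all(c("pair", "n_prehit", "n_high_bg", "n_low_dmso")
                %in% names(counts)))
  df <- counts[, c("pair", "n_prehit", "n_high_bg", "n_low_dmso")]
  df$n_clean <- df$n_prehit - df$n_high_bg - df$n_low_dmso
  if (any(df$n_clean < 0)) stop("flag counts exceed pre-hit counts")
  df <- rbind(df, data.frame(pair = "total", n_prehit = sum(df$n_prehit),
                             n_high_bg = sum(df$n_high_bg),
                             n_low_dmso = sum(df$n_low_dmso),
                             n_clean = sum(df$n_clean)))
  class(df) <- c("triage_report", "data.frame")
  df
}

#' Deduplicate substances case-insensitively
#'
#' Collapses duplicate library wells of the same substance (trimmed,
#' case-insensitive name comparison) to one entry.
#'
#' @param substances Character vector of substance names.
#' @return List with `substances` (first-seen spellings) and `n`.
#' @export
unique_substances <- function(substances) {
  if (!length(substances)) return(list(substances = character(0), n = 0L))
  key <- tolower(trimws(substances))
  keep <- !duplicated(key)
  list(substances = substances[keep], n = sum(keep))
}

#' Screen hit rate
#'
#' @param n_validated Number of validated hits.
#' @param n_library Library size (> 0).
#' @return Percentage, rounded to 2 decimals.
#' @export
#' @examples
#' hit_rate(1, 2532)  # 0.04
hit_rate <- function(n_validated, n_library) {
  stopifnot(n_validated >= 0)
  if (!is.numeric(n_library) || n_library <= 0)
    stop("library size must be positive")
  round(100 * n_validated / n_library, 2)
}

#' Replicate Z-scores of the pilot screen's pre-hit wells
#'
#' Loads the packaged table of the 19 library wells (18 unique substances;
#' thioguanine occupied two wells) that were carried into validation, with
#' their three replicate Z-scores from the primary screen and the retest
#' phase each reached (a status annotation, not recomputed).
#'
#' @return A `replicate_ztable` with `compound_id`, `substance`,
#'   `z_rep1..3`, `retest_phase1..4`.
#' @export
prehit_zscore_table <- function() {
  path <- system.file("extdata", "prehit_zscores.csv",
                      package = "larvascreen", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (k in 1:3) {
    df[[paste0("flag_high_bg_rep", k)]] <- FALSE
    df[[paste0("flag_low_dmso_rep", k)]] <- FALSE
  }
  class(df) <- c("replicate_ztable", "data.frame")
  df
}

#' Per-pair triage counts of the pilot screen
#'
#' Loads the packaged per-replicate-pair pre-hit and artifact counts of the
#' primary screen (pair rows for replicates 1&3, 1&2 and 2&3).
#'
#' @return Data frame `pair`, `n_prehit`, `n_high_bg`, `n_low_dmso`,
#'   `n_manual_pass`.
#' @export
triage_count_table <- function() {
  path <- system.file("extdata", "triage_pair_counts.csv",
                      package = "larvascreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write triage outputs as CSV
#'
#' `write_triage_report` mirrors the per-pair triage table (with a
#' free-text `manual_pass` column defaulting to pass, to be filled from
#' image inspection); `write_prehit_list` writes the pre-hit list with
#' replicate Z-scores.
#'
#' @param report A `triage_report`.
#' @param prehits Output of [call_prehits()].
#' @param path Output path.
#' @export
write_triage_report <- function(report, path) {
  report$manual_pass <- ifelse(report$pair == "total", NA, "pass")
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_triage_report
#' @export
write_prehit_list <- function(prehits, path) {
  keep <- prehits[prehits$is_prehit,
                  c("compound_id", "substance", "z_rep1", "z_rep2", "z_rep3",
                    "n_reps_above")]
  utils::write.csv(keep, path, row.names = FALSE)
  invisible(path)
}
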