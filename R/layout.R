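#' Standard 96-well screening plate layout
#'
#' Builds the screen's fixed control scheme: column 1 holds negative-control
#' wells (`NEG`: homozygous mutant larvae on 0.1% v/v DMSO vehicle), columns
#' 2--11 hold the 80 test wells (`TEST`: homozygous larvae, one library
#' compound each, plus vehicle), wells A12--F12 hold positive control group 1
#' (`POS1`: heterozygous larvae on vehicle) and wells G12--H12 positive
#' control group 2 (`POS2`: homozygous larvae without DMSO). Genotype is
#' implied by role: only `POS1` wells are heterozygous.
#'
#' @param compound_ids Character vector of 80 compound identifiers for the
#'   test wells (row-major across columns 2--11). Defaults to
#'   `C001 ... C080`.
#' @param dose_uM Compound dose in micromolar for test wells (metadata only).
#' @param dmso_pct DMSO vehicle concentration (% v/v) for NEG/TEST/POS1
#'   wells; POS2 wells always get 0.
#' @param plate_id Optional plate identifier stored in the `plate` column.
#' @return A `plate_layout` data frame with one row per well and columns
#'   `plate`, `well`, `row` (letters A--H), `col` (1--12), `role`,
#'   `genotype` (`"hom"`/`"het"`), `compound_id`, `dose_uM`, `dmso_pct`.
#' @export
#' @examples
#' lay <- plate_layout()
#' table(lay$role)
plate_layout <- function(compound_ids = sprintf("C%03d", 1:80),
                         dose_uM = 10, dmso_pct = 0.1, plate_id = 1L) {
  stopifnot(length(compound_ids) == 80L, !anyDuplicated(compound_ids))
  rows <- LETTERS[1:8]
  df <- expand.grid(col = 1:12, row = rows, stringsAsFactors = FALSE)
  df <- df[order(match(df$row, rows), df$col), c("row", "col")]
  df$well <- paste0(df$row, df$col)
  df$role <- "TEST"
  df$role[df$col == 1] <- "NEG"
  df$role[df$col == 12 & df$row %in% LETTERS[1:6]] <- "POS1"
  df$role[df$col == 12 & df$row %in% c("G", "H")] <- "POS2"
  df$genotype <- ifelse(df$role == "POS1", "het", "hom")
  df$compound_id <- NA_character_
  df$compound_id[df$role == "TEST"] <- compound_ids
  df$dose_uM <- ifelse(df$role == "TEST", dose_uM, NA_real_)
  df$dmso_pct <- ifelse(df$role == "POS2", 0, dmso_pct)
  df$plate <- plate_id
  df <- df[, c("plate", "well", "row", "col", "role", "genotype",
               "compound_id", "dose_uM", "dmso_pct")]
  rownames(df) <- NULL
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' Read / write a plate layout as JSON
#'
#' @param layout A `plate_layout` data frame.
#' @param path File path.
#' @return `read_layout_json` returns a `plate_layout`.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(as.data.frame(layout), path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' Two-genotype comparison layout
#'
#' A 96-well layout for head-to-head genotype comparisons on plain food
#' (or a chosen vehicle dose): heterozygote and homozygote wells alternate
#' by column parity, 48 wells per genotype, no compounds. Used for
#' detection-pipeline validation against a known mean-area ratio.
#'
#' @param dmso_pct Vehicle dose for every well (default 0: untreated
#'   regime, homozygote/heterozygote ratio 0.75).
#' @param plate_id Plate identifier.
#' @return A layout data frame compatible with [simulate_plate_image()].
#' @export
two_genotype_layout <- function(dmso_pct = 0, plate_id = 1L) {
  lay <- plate_layout(dmso_pct = dmso_pct, plate_id = plate_id)
  lay$role <- "TEST"
  lay$genotype <- ifelse(lay$col %% 2 == 0, "hom", "het")
  lay$compound_id <- NA_character_
  lay$dose_uM <- NA_real_
  lay
}
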