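# CSV interchange: UTF-8, comma-separated, "." decimal, header required.
# Units are fixed in the column names (_mm, _g, _ml, _pct) so unit drift is
# visible at the schema level.

.read_table <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s (%s): missing required column '%s'", what, path,
                 missing[1]))
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    if (is.character(v)) {
      blank <- !nzchar(trimws(v))
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !blank)
      if (length(bad)) {
        stop(sprintf("%s (%s): non-numeric value '%s' in column '%s' at row %d",
                     what, path, v[bad[1]], col, bad[1]))
      }
      num[blank] <- NA_real_
      df[[col]] <- num
    }
  }
  df
}

#' Read a follicle measurement table
#'
#' Schema: `female_id, ovary_side, follicle_id, diameter_mm, atretic` with
#' optional `dry_mass_g` and `type` (AF/SF/LF).  Unknown columns are kept
#' untouched.
#'
#' @param path CSV path.
#' @return data.frame of follicle records.
#' @export
read_follicles <- function(path) {
  df <- .read_table(path,
                    required = c("female_id", "ovary_side", "follicle_id",
                                 "diameter_mm", "atretic"),
                    numeric_cols = c("diameter_mm", "atretic", "dry_mass_g"),
                    what = "follicles")
  if (any(df$diameter_mm <= 0, na.rm = TRUE)) {
    stop(sprintf("follicles (%s): non-positive diameter_mm at row %d",
                 path, which(df$diameter_mm <= 0)[1]))
  }
  if (!"dry_mass_g" %in% names(df)) df$dry_mass_g <- rep(NA_real_, nrow(df))
  if (!"type" %in% names(df)) df$type <- rep(NA_character_, nrow(df))
  df$type[is.na(df$type) | !nzchar(df$type)] <- NA_character_
  df
}

#' Read an ovary-level table
#'
#' Schema: `female_id, ovary_side, scar_count, mass_g, volume_ml, measured`
#' with optional `oviduct_egg_count`.
#'
#' @param path CSV path.
#' @return data.frame of ovary records.
#' @export
read_ovaries <- function(path) {
  df <- .read_table(path,
                    required = c("female_id", "ovary_side", "scar_count",
                                 "mass_g", "volume_ml", "measured"),
                    numeric_cols = c("scar_count", "mass_g", "volume_ml",
                                     "oviduct_egg_count", "measured"),
                    what = "ovaries")
  if (any(df$scar_count < 0, na.rm = TRUE)) {
    stop(sprintf("ovaries (%s): negative scar_count at row %d",
                 path, which(df$scar_count < 0)[1]))
  }
  if (!"oviduct_egg_count" %in% names(df)) {
    df$oviduct_egg_count <- rep(NA_real_, nrow(df))
  }
  df
}

#' Read a yolk-composition table
#'
#' Schema: `female_id, follicle_id, type, water_pct, om_pct, mineral_pct,
#' lipid_pct, n_pct, p_pct`.  Water is percent of wet mass; the rest are
#' percent of dry mass.
#'
#' @param path CSV path.
#' @return data.frame of composition records.
#' @export
read_composition <- function(path) {
  pct <- c("water_pct", "om_pct", "mineral_pct", "lipid_pct", "n_pct", "p_pct")
  df <- .read_table(path,
                    required = c("female_id", "follicle_id", "type", pct),
                    numeric_cols = pct,
                    what = "composition")
  for (col in pct) {
    bad <- which(df[[col]] < 0 | df[[col]] > 100)
    if (length(bad)) {
      stop(sprintf("composition (%s): %s out of [0, 100] at row %d",
                   path, col, bad[1]))
    }
  }
  df
}

#' Assemble per-female records from follicle and ovary tables
#'
#' Bundles the rows of the two measurement tables into one record per
#' female: a list of measured ovaries, each carrying its scar count and
#' follicle diameters (with atresia flags and any measured dry masses).
#' These records are what the accounting and budget functions consume.
#'
#' @param follicles data.frame as from [read_follicles()].
#' @param ovaries data.frame as from [read_ovaries()].
#' @return named list of `female_record` objects.
#' @export
as_female_records <- function(follicles, ovaries) {
  ids <- unique(ovaries$female_id)
  recs <- lapply(ids, function(fid) {
    orow <- ovaries[ovaries$female_id == fid, , drop = FALSE]
    ovs <- lapply(seq_len(nrow(orow)), function(i) {
      side <- orow$ovary_side[i]
      frow <- follicles[follicles$female_id == fid &
                        follicles$ovary_side == side, , drop = FALSE]
      list(side = side,
           scar_count = orow$scar_count[i],
           diameters = frow$diameter_mm,
           atretic = frow$atretic,
           dry_mass_g = frow$dry_mass_g,
           type = frow$type,
           mass_g = orow$mass_g[i],
           volume_ml = orow$volume_ml[i],
           oviduct_egg_count = orow$oviduct_egg_count[i],
           measured = is.na(orow$measured[i]) || orow$measured[i] != 0)
    })
    structure(list(female_id = fid, ovaries = ovs), class = "female_record")
  })
  names(recs) <- ids
  recs
}
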