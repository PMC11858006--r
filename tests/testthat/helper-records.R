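# Build female_record objects directly, bypassing the CSV layer, for
# focused accounting/budget tests.
make_ovary <- function(side = "left", scars = 0, diameters = numeric(0),
                       dry_mass = NULL, volume = NA_real_, mass = NA_real_,
                       oviduct = NA_real_, measured = TRUE) {
  list(side = side, scar_count = scars, diameters = diameters,
       atretic = rep(0L, length(diameters)),
       dry_mass_g = if (is.null(dry_mass)) rep(NA_real_, length(diameters))
                    else dry_mass,
       type = rep(NA_character_, length(diameters)),
       mass_g = mass, volume_ml = volume, oviduct_egg_count = oviduct,
       measured = measured)
}

make_female <- function(id, ...) {
  structure(list(female_id = id, ovaries = list(...)),
            class = "female_record")
}

# invert a dry-mass target through the default regression so budget tests
# can speak in grams while records carry diameters
diam_for_mass <- function(mass_g, intercept = -10.1, slope = 0.572) {
  (mass_g - intercept) / slope
}

# path to the LP-based dip oracle shipped with the package
dip_oracle_path <- function() {
  system.file("oracles", "dip_lp_oracle.py", package = "vitellus")
}

# run the scipy/HiGHS LP oracle on a list of samples, returning dips
run_dip_oracle <- function(samples) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  writeLines(sprintf('{"samples": [%s]}', paste(
    vapply(samples, function(s)
      paste0("[", paste(formatC(s, digits = 17, format = "g"),
                        collapse = ","), "]"),
      character(1)),
    collapse = ",")), fin)
  status <- system2("python", c(dip_oracle_path(), fin, fout),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("dip LP oracle failed to run")
  txt <- paste(readLines(fout, warn = FALSE), collapse = "")
  as.numeric(strsplit(gsub("\\[|\\]|\\s", "", txt), ",")[[1]])
}
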