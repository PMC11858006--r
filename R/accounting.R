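# Reproductive accounting: scars and dominant follicles -> eggs, clutches,
# season half and clutch frequency.

measured_ovaries <- function(female) {
  stopifnot(inherits(female, "female_record"))
  Filter(function(o) isTRUE(o$measured), female$ovaries)
}

#' Count eggs laid and eggs left for one female
#'
#' Eggs left are the dominant follicles (diameter strictly greater than the
#' threshold) over all measured ovaries; eggs laid are the summed
#' recently-formed ovulatory scars.  When only one ovary was measured, both
#' totals are doubled on the assumption that the two ovaries contribute
#' equally, and the result is flagged as extrapolated.
#'
#' @param female a `female_record` (see [as_female_records()]).
#' @param threshold dominance threshold in mm (strict lower bound).
#' @return list with `eggs_laid`, `eggs_left`, `extrapolated`.
#' @export
count_eggs <- function(female, threshold) {
  ovs <- measured_ovaries(female)
  if (length(ovs) == 0L) stop("no measured ovary for female ", female$female_id)
  eggs_left <- sum(vapply(ovs, function(o) sum(o$diameters > threshold),
                          numeric(1)))
  eggs_laid <- sum(vapply(ovs, function(o) o$scar_count, numeric(1)))
  extrapolated <- length(ovs) == 1L
  if (extrapolated) {
    eggs_left <- 2 * eggs_left
    eggs_laid <- 2 * eggs_laid
  }
  list(eggs_laid = eggs_laid, eggs_left = eggs_left,
       extrapolated = extrapolated)
}

round_half_up <- function(x) floor(x + 0.5)

#' Summarise a female's clutch accounting
#'
#' Converts egg counts to clutches by dividing by the population mean
#' clutch size and rounding half-up to an integer.  A female with at least
#' as many clutches laid as left is in the second half of her nesting
#' season, otherwise the first half.  Clutch frequency is the sum of
#' clutches laid and left.
#'
#' @param eggs_laid,eggs_left non-negative egg counts.
#' @param mean_clutch_size population mean clutch size (default 110 eggs).
#' @param female_id optional identifier carried into the summary.
#' @param extrapolated whether the counts came from a single doubled ovary.
#' @return one-row data.frame: `female_id`, `eggs_laid`, `eggs_left`,
#'   `clutches_laid`, `clutches_left`, `clutch_frequency`, `season_half`,
#'   `extrapolated`.
#' @export
summarize_female <- function(eggs_laid, eggs_left, mean_clutch_size = 110,
                             female_id = NA_character_,
                             extrapolated = FALSE) {
  if (eggs_laid < 0 || eggs_left < 0) stop("egg counts must be non-negative")
  clutches_laid <- round_half_up(eggs_laid / mean_clutch_size)
  clutches_left <- round_half_up(eggs_left / mean_clutch_size)
  data.frame(
    female_id = female_id,
    eggs_laid = eggs_laid, eggs_left = eggs_left,
    clutches_laid = clutches_laid, clutches_left = clutches_left,
    clutch_frequency = clutches_laid + clutches_left,
    season_half = if (clutches_laid >= clutches_left) "second" else "first",
    extrapolated = extrapolated,
    stringsAsFactors = FALSE)
}

#' Reproductive summary for a whole cohort
#'
#' Applies [count_eggs()] and [summarize_female()] to every female and
#' appends the dominant / non-dominant follicle counts used downstream.
#'
#' @param records list of `female_record`s.
#' @param threshold dominance threshold in mm.
#' @param mean_clutch_size population mean clutch size.
#' @return data.frame, one row per female.
#' @export
reproductive_summary <- function(records, threshold, mean_clutch_size = 110) {
  rows <- lapply(records, function(fem) {
    eggs <- count_eggs(fem, threshold)
    s <- summarize_female(eggs$eggs_laid, eggs$eggs_left, mean_clutch_size,
                          female_id = fem$female_id,
                          extrapolated = eggs$extrapolated)
    ovs <- measured_ovaries(fem)
    mult <- if (eggs$extrapolated) 2L else 1L
    s$dominant_n <- mult * sum(vapply(ovs, function(o)
      sum(o$diameters > threshold), numeric(1)))
    s$nondominant_n <- mult * sum(vapply(ovs, function(o)
      sum(o$diameters <= threshold), numeric(1)))
    s
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Left-right ovary symmetry report
#'
#' For females with both ovaries measured, compares left vs right for the
#' dominant follicle count, non-dominant count, ovulatory scars, ovary
#' volume and (where recorded) oviductal egg counts, using the blocked
#' paired comparison ([blocked_two_group()]).  Ovary mass is reported as a
#' mean difference only: its measurement resolution (500 g) typically
#' exceeds the true left-right difference, so no significance test is run.
#'
#' @param records list of `female_record`s.
#' @param threshold dominance threshold in mm.
#' @return data.frame, one row per variable: means by side, mean paired
#'   difference (left minus right), n pairs, statistic and p-value.
#' @export
ovary_symmetry_report <- function(records, threshold) {
  both <- Filter(function(fem) length(measured_ovaries(fem)) == 2L, records)
  if (length(both) < 2L) {
    stop("ovary symmetry report needs at least 2 females with both ovaries ",
         "measured")
  }
  value_of <- function(o, var) {
    switch(var,
           dominant_n = sum(o$diameters > threshold),
           nondominant_n = sum(o$diameters <= threshold),
           scar_count = o$scar_count,
           volume_ml = o$volume_ml,
           mass_g = o$mass_g,
           oviduct_egg_count = o$oviduct_egg_count)
  }
  vars <- c("dominant_n", "nondominant_n", "scar_count", "volume_ml",
            "mass_g", "oviduct_egg_count")
  rows <- lapply(vars, function(var) {
    lr <- vapply(both, function(fem) {
      sides <- vapply(fem$ovaries, `[[`, character(1), "side")
      c(left = as.numeric(value_of(fem$ovaries[[match("left", sides)]], var)),
        right = as.numeric(value_of(fem$ovaries[[match("right", sides)]], var)))
    }, numeric(2))
    keep <- !is.na(lr["left", ]) & !is.na(lr["right", ])
    n <- sum(keep)
    if (n < 3L) {
      if (var %in% c("oviduct_egg_count", "mass_g", "volume_ml")) {
        message("ovary symmetry: skipping '", var,
                "' (fewer than 3 complete pairs)")
        return(NULL)
      }
      stop("ovary symmetry: fewer than 3 complete pairs for variable '",
           var, "'")
    }
    l <- lr["left", keep]; r <- lr["right", keep]
    if (var == "mass_g") {
      # resolution-limited: report only
      return(data.frame(variable = var, n_pairs = n, mean_left = mean(l),
                        mean_right = mean(r), mean_diff = mean(l - r),
                        statistic = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    tab <- data.frame(block = rep(names(both)[keep] %||% seq_len(n), 2),
                      treatment = rep(c("left", "right"), each = n),
                      response = c(l, r), stringsAsFactors = FALSE)
    bt <- blocked_two_group(tab)
    data.frame(variable = var, n_pairs = n, mean_left = mean(l),
               mean_right = mean(r), mean_diff = mean(l - r),
               statistic = bt$statistic, p_value = bt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean pre-ovulatory growth of dominant follicles
#'
#' For each dominant follicle of diameter `d` in a measured ovary with
#' largest dominant diameter `M`, the remaining relative growth is
#' `100 * (M - d) / d` percent (the growth the follicle would undergo to
#' reach the ovary's pre-ovulatory size).  Returns the mean over all
#' dominant follicles of all measured ovaries.  The alternative
#' normalisation `100 * (M - d) / M` (shortfall as a share of the maximum)
#' is available via `relative_to = "max"`.
#'
#' @param female a `female_record`.
#' @param threshold dominance threshold in mm.
#' @param relative_to `"follicle"` (default) or `"max"`.
#' @return mean growth percentage (a single number).
#' @export
follicle_growth_pct <- function(female, threshold,
                                relative_to = c("follicle", "max")) {
  relative_to <- match.arg(relative_to)
  ovs <- measured_ovaries(female)
  growth <- unlist(lapply(ovs, function(o) {
    d <- o$diameters[o$diameters > threshold]
    if (length(d) == 0L) return(NULL)
    M <- max(d)
    if (relative_to == "follicle") 100 * (M - d) / d else 100 * (M - d) / M
  }))
  if (is.null(growth) || length(growth) == 0L) {
    stop("no dominant follicles for female ", female$female_id)
  }
  mean(growth)
}
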