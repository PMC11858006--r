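# Yolk dry-mass, nutrient and energy budgets per female, and their cohort
# aggregation.

#' Energetic conversion constants
#'
#' Standard proximate-composition conversions: crude protein is nitrogen
#' times 6.25; yolk dry mass is converted to organic matter with the mean
#' organic fraction (0.95 g OM per g dry yolk) and then to energy at
#' 29.5 kJ per g of organic matter.
#'
#' @param cp_per_g_n grams of crude protein per gram of nitrogen.
#' @param organic_fraction grams of organic matter per gram of dry yolk.
#' @param energy_per_g_om kJ per gram of organic matter.
#' @param mean_clutch_size eggs per clutch.
#' @return list of class `energetic_constants`.
#' @export
energetic_constants <- function(cp_per_g_n = 6.25, organic_fraction = 0.95,
                                energy_per_g_om = 29.5,
                                mean_clutch_size = 110) {
  vals <- c(cp_per_g_n, organic_fraction, energy_per_g_om, mean_clutch_size)
  if (any(vals <= 0)) stop("all energetic constants must be strictly positive")
  structure(list(cp_per_g_n = cp_per_g_n,
                 organic_fraction = organic_fraction,
                 energy_per_g_om = energy_per_g_om,
                 mean_clutch_size = mean_clutch_size),
            class = "energetic_constants")
}

#' Convert yolk dry mass to energy
#'
#' `energy_kj = dry mass (g) x organic fraction x kJ per g OM`
#' (defaults: `g x 0.95 x 29.5`).
#'
#' @param yolk_g yolk dry mass in grams.
#' @param constants an [energetic_constants()].
#' @return energy in kJ.
#' @export
yolk_energy_kj <- function(yolk_g, constants = energetic_constants()) {
  yolk_g * constants$organic_fraction * constants$energy_per_g_om
}

#' Crude protein from nitrogen mass
#'
#' @param n_g nitrogen in grams.
#' @param constants an [energetic_constants()].
#' @return crude protein in grams (`n_g x 6.25` with defaults).
#' @export
crude_protein_g <- function(n_g, constants = energetic_constants()) {
  n_g * constants$cp_per_g_n
}

#' Linear diameter-to-dry-mass model
#'
#' The working regression predicting follicle dry mass (g) from initial
#' follicle diameter (mm): `dry mass = intercept + slope * diameter`, with
#' defaults -10.1 g and 0.572 g/mm.  Note the line crosses zero near
#' 17.7 mm, so predictions for small (non-dominant) follicles can be
#' negative; the budget functions floor those at 0 g.
#'
#' @param intercept grams.
#' @param slope grams per mm.
#' @param r_squared,residual_sd optional fit diagnostics.
#' @return list of class `dry_weight_model`.
#' @export
dry_weight_model <- function(intercept = -10.1, slope = 0.572,
                             r_squared = NA_real_, residual_sd = NA_real_) {
  structure(list(intercept = intercept, slope = slope,
                 r_squared = r_squared, residual_sd = residual_sd),
            class = "dry_weight_model")
}

#' Predict follicle dry mass from diameter
#'
#' @param diameter_mm follicle diameter(s), mm, strictly positive.
#' @param model a [dry_weight_model()].
#' @return predicted dry mass in grams (possibly negative for small
#'   diameters; callers decide how to treat the negative range).
#' @examples
#' predict_dry_weight(30)  # 7.06 g under the default model
#' @export
predict_dry_weight <- function(diameter_mm, model = dry_weight_model()) {
  if (any(diameter_mm <= 0)) stop("diameters must be positive")
  model$intercept + model$slope * diameter_mm
}

#' Fit the diameter-to-dry-mass regression
#'
#' Ordinary least squares of measured dry mass (g) on diameter (mm).
#'
#' @param diameter_mm numeric vector (at least 3, not all equal).
#' @param dry_mass_g numeric vector of the same length.
#' @return a [dry_weight_model()] with `r_squared` and `residual_sd`.
#' @export
fit_dry_weight_model <- function(diameter_mm, dry_mass_g) {
  keep <- is.finite(diameter_mm) & is.finite(dry_mass_g)
  diameter_mm <- diameter_mm[keep]; dry_mass_g <- dry_mass_g[keep]
  if (length(diameter_mm) < 3L) stop("need at least 3 (diameter, mass) pairs")
  if (length(unique(diameter_mm)) == 1L) stop("degenerate design")
  fit <- lm(dry_mass_g ~ diameter_mm)
  # noiseless calibration pairs are legitimate input: silence the
  # perfect-fit warning from summary.lm
  s <- suppressWarnings(summary(fit))
  dry_weight_model(intercept = unname(coef(fit)[1]),
                   slope = unname(coef(fit)[2]),
                   r_squared = s$r.squared,
                   residual_sd = s$sigma)
}

# per-female composition fractions (of dry mass) from a composition table;
# dominant follicles (SF/LF) only, since those describe deposited yolk
female_composition_means <- function(composition) {
  dom <- composition[composition$type %in% c("SF", "LF"), , drop = FALSE]
  if (nrow(dom) == 0L) return(NULL)
  agg <- aggregate(dom[c("lipid_pct", "n_pct", "p_pct", "mineral_pct")],
                   by = list(female_id = dom$female_id), FUN = mean)
  agg
}

.default_fractions <- c(lipid = 0.326, n = 0.0966, p = 0.0107,
                        mineral = 0.0498)

#' Per-female yolk, nutrient and energy budget
#'
#' Implements the investment-and-resorption accounting: per measured
#' ovary, the dry mass of each dominant follicle (measured where
#' available, otherwise predicted from diameter with negative predictions
#' floored at 0 g) is the yolk already deposited; the gap to the largest
#' dominant follicle of the same ovary is the yolk still to be deposited;
#' the dry mass of non-dominant follicles is the yolk available for
#' resorption.  Totals are summed over two measured ovaries or doubled
#' for one.  Nutrient masses scale the yolk totals by the female's mean
#' lipid/N/P/mineral fractions of dry yolk (cohort means, then cohort-wide
#' defaults, as fallbacks); crude protein and energy use
#' [crude_protein_g()] and [yolk_energy_kj()].  A female is in deficit
#' when the yolk still to deposit exceeds the resorbable yolk.
#'
#' @param female a `female_record`.
#' @param threshold dominance threshold in mm.
#' @param model a [dry_weight_model()].
#' @param constants an [energetic_constants()].
#' @param composition_means optional one-row data.frame (or named list)
#'   with `lipid_pct`, `n_pct`, `p_pct`, `mineral_pct` for this female.
#' @param cohort_fractions optional named fractions used when the female
#'   has no composition data.
#' @param per_ovary_max logical; subtract from the largest dominant
#'   follicle of the same ovary (default) or of the whole female.
#' @return one-row data.frame with yolk masses (g), nutrient masses (g)
#'   and energy (kJ) for each of the three categories, plus `deficit` and
#'   `extrapolated` flags.
#' @export
female_budget <- function(female, threshold, model = dry_weight_model(),
                          constants = energetic_constants(),
                          composition_means = NULL,
                          cohort_fractions = NULL,
                          per_ovary_max = TRUE) {
  ovs <- measured_ovaries(female)
  if (length(ovs) == 0L) stop("no measured ovary for female ", female$female_id)

  follicle_mass <- function(diam, measured) {
    pred <- pmax(predict_dry_weight(diam, model), 0)
    ifelse(!is.na(measured), measured, pred)
  }
  dep <- 0; to_dep <- 0; to_res <- 0; n_dom <- 0L
  dom_masses_all <- numeric(0)
  for (o in ovs) {
    dmy <- if (is.null(o$dry_mass_g)) rep(NA_real_, length(o$diameters))
           else o$dry_mass_g
    is_dom <- o$diameters > threshold
    w_dom <- follicle_mass(o$diameters[is_dom], dmy[is_dom])
    w_non <- follicle_mass(o$diameters[!is_dom], dmy[!is_dom])
    dep <- dep + sum(w_dom)
    to_res <- to_res + sum(w_non)
    n_dom <- n_dom + length(w_dom)
    if (per_ovary_max && length(w_dom)) {
      to_dep <- to_dep + sum(max(w_dom) - w_dom)
    }
    dom_masses_all <- c(dom_masses_all, w_dom)
  }
  if (n_dom == 0L) stop("no dominant follicles for female ", female$female_id)
  if (!per_ovary_max) to_dep <- sum(max(dom_masses_all) - dom_masses_all)

  extrapolated <- length(ovs) == 1L
  if (extrapolated) {
    dep <- 2 * dep; to_dep <- 2 * to_dep; to_res <- 2 * to_res
  }

  fr <- .default_fractions
  if (!is.null(cohort_fractions)) fr[names(cohort_fractions)] <- cohort_fractions
  if (!is.null(composition_means)) {
    fr <- c(lipid = composition_means$lipid_pct / 100,
            n = composition_means$n_pct / 100,
            p = composition_means$p_pct / 100,
            mineral = composition_means$mineral_pct / 100)
  } else {
    message("female ", female$female_id,
            ": no composition data, using cohort mean fractions")
  }

  category <- function(y) {
    data.frame(yolk_g = y,
               lipid_g = y * fr[["lipid"]], n_g = y * fr[["n"]],
               p_g = y * fr[["p"]],
               cp_g = crude_protein_g(y * fr[["n"]], constants),
               mineral_g = y * fr[["mineral"]],
               energy_kj = yolk_energy_kj(y, constants))
  }
  dd <- category(dep); td <- category(to_dep); tr <- category(to_res)
  names(dd) <- paste0("deposited_", names(dd))
  names(td) <- paste0("to_deposit_", names(td))
  names(tr) <- paste0("to_resorb_", names(tr))
  cbind(data.frame(female_id = female$female_id, stringsAsFactors = FALSE),
        dd, td, tr,
        data.frame(deficit = to_dep > to_res, extrapolated = extrapolated))
}

#' Budgets for a whole cohort
#'
#' Runs [female_budget()] for every female, wiring in per-female
#' composition means where available and cohort means otherwise.
#'
#' @param records list of `female_record`s.
#' @param threshold dominance threshold in mm.
#' @param composition optional composition table (see
#'   [read_composition()]).
#' @inheritParams female_budget
#' @return data.frame, one row per female.
#' @export
cohort_budget <- function(records, threshold, composition = NULL,
                          model = dry_weight_model(),
                          constants = energetic_constants(),
                          per_ovary_max = TRUE) {
  fem_means <- if (!is.null(composition) && nrow(composition)) {
    female_composition_means(composition)
  } else NULL
  cohort_fr <- if (!is.null(fem_means)) {
    c(lipid = mean(fem_means$lipid_pct) / 100,
      n = mean(fem_means$n_pct) / 100,
      p = mean(fem_means$p_pct) / 100,
      mineral = mean(fem_means$mineral_pct) / 100)
  } else NULL
  rows <- lapply(records, function(fem) {
    cm <- NULL
    if (!is.null(fem_means)) {
      hit <- fem_means[fem_means$female_id == fem$female_id, , drop = FALSE]
      if (nrow(hit) == 1L) cm <- hit
    }
    female_budget(fem, threshold, model = model, constants = constants,
                  composition_means = cm, cohort_fractions = cohort_fr,
                  per_ovary_max = per_ovary_max)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary of the yolk budgets
#'
#' Mean, SD, min and max of each budget category across females, with
#' nutrient columns computed from the cohort-mean yolk mass times the
#' cohort-mean nutrient fractions, energy from the mean (and the max, for
#' maximum-investment statements) yolk mass, and the fraction of females
#' in deficit.
#'
#' @param budgets data.frame from [cohort_budget()].
#' @param constants an [energetic_constants()].
#' @return list with `summary` (one row per category) and
#'   `deficit_fraction`.
#' @export
cohort_budget_summary <- function(budgets, constants = energetic_constants()) {
  if (is.null(budgets) || nrow(budgets) == 0L) stop("no budgets supplied")
  cat_row <- function(prefix, label) {
    y <- budgets[[paste0(prefix, "_yolk_g")]]
    mean_fr <- function(nut) {
      v <- budgets[[paste0(prefix, "_", nut, "_g")]]
      # recover the cohort-mean fraction actually applied
      ok <- y > 0
      if (!any(ok)) 0 else mean(v[ok] / y[ok])
    }
    m <- mean(y)
    data.frame(category = label, mean_g = m, sd_g = sd(y), min_g = min(y),
               max_g = max(y),
               lipid_g = m * mean_fr("lipid"),
               n_g = m * mean_fr("n"),
               p_g = m * mean_fr("p"),
               cp_g = crude_protein_g(m * mean_fr("n"), constants),
               mineral_g = m * mean_fr("mineral"),
               energy_kj = yolk_energy_kj(m, constants),
               energy_max_kj = yolk_energy_kj(max(y), constants),
               stringsAsFactors = FALSE)
  }
  out <- rbind(cat_row("deposited", "yolk_deposited"),
               cat_row("to_deposit", "yolk_to_be_deposited"),
               cat_row("to_resorb", "yolk_to_be_resorbed"))
  rownames(out) <- NULL
  list(summary = out,
       deficit_fraction = mean(budgets$deficit),
       n = nrow(budgets))
}

#' Seasonal comparison of follicle counts
#'
#' Welch's t test on dominant follicle counts between females in the first
#' and second half of their nesting season, and a Wilcoxon rank-sum test on
#' non-dominant counts.
#'
#' @param summaries data.frame from [reproductive_summary()] (needs
#'   `season_half`, `dominant_n`, `nondominant_n`).
#' @return list of two test results (`dominant`, `nondominant`), each with
#'   `statistic`, `p_value`, `method` and group means.
#' @export
seasonal_follicle_comparison <- function(summaries) {
  halves <- split(summaries, summaries$season_half)
  if (!all(c("first", "second") %in% names(halves)) ||
      any(vapply(halves, nrow, integer(1)) < 2L)) {
    stop("both season halves must be represented by at least 2 females")
  }
  g1 <- halves$first; g2 <- halves$second
  identical_groups <- function(a, b) {
    length(a) == length(b) && all(sort(a) == sort(b)) && sd(c(a, b)) == 0
  }
  dom <- if (identical_groups(g1$dominant_n, g2$dominant_n)) {
    list(statistic = 0, p_value = 1)
  } else {
    tt <- t.test(g1$dominant_n, g2$dominant_n, var.equal = FALSE)
    list(statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  non <- {
    wt <- suppressWarnings(wilcox.test(g1$nondominant_n, g2$nondominant_n))
    list(statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  list(dominant = c(dom, method = "welch_t",
                    mean_first = mean(g1$dominant_n),
                    mean_second = mean(g2$dominant_n)),
       nondominant = c(non, method = "wilcoxon_rank_sum",
                       mean_first = mean(g1$nondominant_n),
                       mean_second = mean(g2$nondominant_n)))
}
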