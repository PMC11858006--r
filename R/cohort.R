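#' Default yolk-composition parameters by follicle type
#'
#' Mean and SD (percent) for each composition variable by follicle type:
#' AF = atretic, SF = small dominant, LF = large dominant follicles.
#' Water is a percentage of wet mass; all other variables are percentages
#' of dry mass.  Values follow the reported composition of a nesting green
#' turtle cohort and are the generator defaults.
#'
#' @return data.frame with columns `type`, `variable`, `mean`, `sd`.
#' @export
default_composition_params <- function() {
  data.frame(
    type = rep(c("AF", "LF", "SF"), each = 6),
    variable = rep(c("water", "om", "mineral", "lipid", "n", "p"), times = 3),
    mean = c(56.5, 95.4, 4.62, 32.6, 9.47, 0.99,   # AF
             47.4, 95.0, 4.95, 32.9, 9.68, 1.07,   # LF
             49.7, 95.0, 5.01, 32.3, 9.65, 1.07),  # SF
    sd = c(8.24, 0.41, 0.41, 4.95, 1.19, 0.10,
           2.16, 1.07, 1.07, 3.14, 0.92, 0.10,
           3.46, 1.09, 1.09, 2.39, 0.79, 0.09),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic nesting cohort
#'
#' Collects the parameters from which [generate_cohort()] simulates a
#' cohort of nesting females: the two-component structure of vitellogenic
#' follicle diameters (a non-dominant component and a dominant component
#' that is itself a two-part mixture), scar counts consistent with a
#' uniform clutch frequency, per-type yolk composition, and a linear
#' diameter-to-dry-mass model.
#'
#' @param n_females number of simulated females.
#' @param mean_clutch_size eggs per clutch (default 110).
#' @param clutch_frequency_range two integers in `[1, 12]`: inclusive range
#'   of clutch frequency, drawn uniformly per female (default `c(3, 9)`).
#' @param nondominant_mean,nondominant_sd diameter (mm) of the non-dominant
#'   component, truncated to `nondominant_bounds` (default 8 and 2.9).
#' @param nondominant_count expected non-dominant follicles per ovary
#'   (Poisson; default 105).
#' @param nondominant_bounds truncation interval (mm), default `c(4, 18)`.
#' @param dominant_components 2 x 3 matrix (mean mm, sd mm, weight) of the
#'   dominant mixture; defaults `(26, 2.1, 0.30)` and `(31, 2.9, 0.70)`.
#' @param dominant_bounds truncation interval (mm), default `c(18, 37)`.
#' @param composition_params data.frame as in
#'   [default_composition_params()].
#' @param dry_mass_intercept,dry_mass_slope,dry_mass_resid_sd linear model
#'   from which measured follicle dry masses (g) are simulated from
#'   diameter (mm); defaults -10.1, 0.572 and 0.5.
#' @param measurement_scenario fraction of females with only one ovary
#'   measured (default 0.25).
#' @param n_sampled_per_type dominant follicles per female with measured
#'   dry mass and composition, for each of SF and LF (default 5).
#' @param af_prob probability a female presents atretic follicles
#'   (default 0.4).
#' @param oviduct_prob probability a female carries a shelled clutch in the
#'   oviducts (default 0.5).
#' @param oviduct_left_fraction expected fraction of oviductal eggs on the
#'   left side (default 0.5; lower it to emulate a left deficit).
#' @param rng_seed integer seed; the whole cohort is a deterministic
#'   function of the specification including this seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_females = 40L,
                        mean_clutch_size = 110,
                        clutch_frequency_range = c(3L, 9L),
                        nondominant_mean = 8, nondominant_sd = 2.9,
                        nondominant_count = 105,
                        nondominant_bounds = c(4, 18),
                        dominant_components = rbind(c(26, 2.1, 0.30),
                                                    c(31, 2.9, 0.70)),
                        dominant_bounds = c(18, 37),
                        composition_params = default_composition_params(),
                        dry_mass_intercept = -10.1,
                        dry_mass_slope = 0.572,
                        dry_mass_resid_sd = 0.5,
                        measurement_scenario = 0.25,
                        n_sampled_per_type = 5L,
                        af_prob = 0.4,
                        oviduct_prob = 0.5,
                        oviduct_left_fraction = 0.5,
                        rng_seed = 1L) {
  spec <- list(n_females = as.integer(n_females),
               mean_clutch_size = mean_clutch_size,
               clutch_frequency_range = as.integer(clutch_frequency_range),
               nondominant_mean = nondominant_mean,
               nondominant_sd = nondominant_sd,
               nondominant_count = nondominant_count,
               nondominant_bounds = nondominant_bounds,
               dominant_components = dominant_components,
               dominant_bounds = dominant_bounds,
               composition_params = composition_params,
               dry_mass_intercept = dry_mass_intercept,
               dry_mass_slope = dry_mass_slope,
               dry_mass_resid_sd = dry_mass_resid_sd,
               measurement_scenario = measurement_scenario,
               n_sampled_per_type = as.integer(n_sampled_per_type),
               af_prob = af_prob,
               oviduct_prob = oviduct_prob,
               oviduct_left_fraction = oviduct_left_fraction,
               rng_seed = as.integer(rng_seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, why) {
    stop(sprintf("invalid cohort spec: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (spec$n_females < 1L) fail("n_females", "must be at least 1")
  if (spec$mean_clutch_size <= 0) fail("mean_clutch_size", "must be positive")
  cfr <- spec$clutch_frequency_range
  if (length(cfr) != 2L || cfr[1] > cfr[2] || cfr[1] < 1L || cfr[2] > 12L) {
    fail("clutch_frequency_range", "must be an increasing pair within [1, 12]")
  }
  if (spec$nondominant_sd < 0) fail("nondominant_sd", "must be >= 0")
  if (spec$nondominant_count <= 0) fail("nondominant_count", "must be positive")
  dc <- spec$dominant_components
  if (!is.matrix(dc) || ncol(dc) != 3L) {
    fail("dominant_components", "must be a matrix with columns mean, sd, weight")
  }
  if (any(dc[, 2] < 0)) fail("dominant_components", "has a negative sd")
  if (abs(sum(dc[, 3]) - 1) > 1e-8) {
    fail("dominant_components", "mixture weights must sum to 1")
  }
  cp <- spec$composition_params
  need <- c("type", "variable", "mean", "sd")
  if (!all(need %in% names(cp))) {
    fail("composition_params", "must have columns type, variable, mean, sd")
  }
  if (any(cp$mean < 0 | cp$mean > 100)) {
    fail("composition_params", "means must be percentages in [0, 100]")
  }
  if (any(cp$sd < 0)) fail("composition_params", "sds must be >= 0")
  if (spec$measurement_scenario < 0 || spec$measurement_scenario > 1) {
    fail("measurement_scenario", "must be a fraction in [0, 1]")
  }
  if (spec$oviduct_left_fraction < 0 || spec$oviduct_left_fraction > 1) {
    fail("oviduct_left_fraction", "must be a fraction in [0, 1]")
  }
  invisible(spec)
}

# truncated-normal draws by inverse-CDF; degenerate sd gives the point mass
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

r_dominant <- function(n, spec) {
  dc <- spec$dominant_components
  comp <- sample.int(nrow(dc), n, replace = TRUE, prob = dc[, 3])
  vapply(comp, function(ci) {
    rtruncnorm(1, dc[ci, 1], dc[ci, 2],
               spec$dominant_bounds[1], spec$dominant_bounds[2])
  }, numeric(1))
}

comp_lookup <- function(spec) {
  cp <- spec$composition_params
  key <- paste(cp$type, cp$variable)
  list(mean = setNames(cp$mean, key), sd = setNames(cp$sd, key))
}

r_composition <- function(type, n, lk) {
  vars <- c("water", "om", "mineral", "lipid", "n", "p")
  out <- lapply(vars, function(v) {
    key <- paste(type, v)
    rtruncnorm(n, lk$mean[[key]], lk$sd[[key]], 0, 100)
  })
  names(out) <- paste0(vars, "_pct")
  as.data.frame(out)
}

#' Generate a synthetic nesting cohort
#'
#' Simulates a cohort of nesting females whose follicle-diameter
#' distributions, ovulatory-scar counts and yolk composition follow the
#' configured statistical structure, together with a ground-truth table
#' for parameter-recovery tests.  Per female: a clutch frequency is drawn
#' uniformly from the configured range and split into clutches laid
#' (uniform on 1 to frequency - 1) and clutches left; scars
#' (`clutches laid x clutch size`) and dominant follicles
#' (`clutches left x clutch size`) are split binomially across the two
#' ovaries; non-dominant follicle counts are Poisson per ovary.  The truth
#' table records both-ovary counts even when the measurement scenario
#' exposes a single ovary.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `ovary_cohort`: data.frames `follicles`,
#'   `ovaries`, `females`, `composition` (measured data only) and `truth`,
#'   plus the generating `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  validate_cohort_spec(spec)
  with_seed(spec$rng_seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  lk <- comp_lookup(spec)
  fol <- list(); ova <- list(); comp <- list(); tru <- list()
  cf_lo <- spec$clutch_frequency_range[1]
  cf_hi <- spec$clutch_frequency_range[2]

  for (f in seq_len(spec$n_females)) {
    fid <- sprintf("F%03d", f)
    cf <- sample(seq.int(cf_lo, cf_hi), 1L)
    laid <- if (cf > 1L) sample(seq_len(cf - 1L), 1L) else 0L
    left <- cf - laid
    eggs_laid <- round(laid * spec$mean_clutch_size)
    eggs_left <- round(left * spec$mean_clutch_size)

    scars_l <- rbinom(1L, eggs_laid, 0.5)
    dom_l <- rbinom(1L, eggs_left, 0.5)
    one_ovary <- runif(1) < spec$measurement_scenario
    measured_sides <- if (one_ovary) sample(c("left", "right"), 1L)
                      else c("left", "right")

    ovary_follicles <- list()
    for (side in c("left", "right")) {
      n_dom <- if (side == "left") dom_l else eggs_left - dom_l
      n_non <- rpois(1L, spec$nondominant_count)
      d_dom <- r_dominant(n_dom, spec)
      d_non <- rtruncnorm(n_non, spec$nondominant_mean, spec$nondominant_sd,
                          spec$nondominant_bounds[1], spec$nondominant_bounds[2])
      ovary_follicles[[side]] <- list(dom = d_dom, non = d_non,
                                      scars = if (side == "left") scars_l
                                              else eggs_laid - scars_l)
    }

    # atretic follicles: a subset of non-dominant follicles in resorption
    has_af <- runif(1) < spec$af_prob
    n_af <- if (has_af) rpois(1L, 3) + 1L else 0L

    ovi <- runif(1) < spec$oviduct_prob
    ovi_total <- if (ovi) round(spec$mean_clutch_size) else NA_integer_
    ovi_left <- if (ovi) rbinom(1L, ovi_total, spec$oviduct_left_fraction)
                else NA_integer_

    # per-side follicle annotations (type, measured dry mass); the sampled
    # follicles live on the first measured side
    ann <- list()
    for (side in c("left", "right")) {
      ofl <- ovary_follicles[[side]]
      diam <- c(ofl$dom, ofl$non)
      n_d <- length(ofl$dom); n_n <- length(ofl$non)
      atre <- c(rep(0L, n_d), rep(0L, n_n))
      type <- rep(NA_character_, length(diam))
      dry <- rep(NA_real_, length(diam))
      if (side == measured_sides[1]) {
        if (n_af > 0L && n_n > 0L) {
          atre[n_d + seq_len(min(n_af, n_n))] <- 1L
        }
        # sample SF (smallest) and LF (largest) dominant follicles plus AF
        if (n_d >= 2L * spec$n_sampled_per_type) {
          o <- order(ofl$dom)
          type[o[seq_len(spec$n_sampled_per_type)]] <- "SF"
          type[o[n_d + 1L - seq_len(spec$n_sampled_per_type)]] <- "LF"
        }
        type[atre == 1L] <- "AF"
        meas <- which(!is.na(type))
        if (length(meas)) {
          mu <- spec$dry_mass_intercept + spec$dry_mass_slope * diam[meas]
          dry[meas] <- pmax(mu + rnorm(length(meas), 0,
                                       spec$dry_mass_resid_sd), 0.01)
        }
      }
      ann[[side]] <- list(diam = diam, n_d = n_d, atre = atre, type = type,
                          dry = dry)
    }

    fol_rows <- list(); comp_rows <- list()
    for (side in measured_sides) {
      ofl <- ovary_follicles[[side]]
      an <- ann[[side]]
      diam <- an$diam; atre <- an$atre; type <- an$type; dry <- an$dry

      meas <- which(!is.na(type))
      if (length(meas)) {
        cdf <- do.call(rbind, lapply(c("AF", "SF", "LF"), function(tp) {
          idx <- meas[type[meas] == tp]
          if (!length(idx)) return(NULL)
          cbind(data.frame(female_id = fid,
                           follicle_id = sprintf("%s_%s_%03d", fid,
                                                 substr(side, 1, 1), idx),
                           type = tp, stringsAsFactors = FALSE),
                r_composition(tp, length(idx), lk))
        }))
        comp_rows[[side]] <- cdf
      }

      fol_rows[[side]] <- data.frame(
        female_id = fid, ovary_side = side,
        follicle_id = sprintf("%s_%s_%03d", fid, substr(side, 1, 1),
                              seq_along(diam)),
        diameter_mm = diam, atretic = atre, dry_mass_g = dry,
        type = type, stringsAsFactors = FALSE)

      vol_ml <- max(50, round(sum((4 / 3) * pi * (diam / 2)^3) / 1000 / 50) * 50)
      ova[[paste(fid, side)]] <- data.frame(
        female_id = fid, ovary_side = side, scar_count = ofl$scars,
        mass_g = max(500, round(vol_ml * 1.05 / 500) * 500),
        volume_ml = vol_ml,
        oviduct_egg_count = if (!ovi) NA_integer_
                            else if (side == "left") ovi_left
                            else ovi_total - ovi_left,
        measured = 1L, stringsAsFactors = FALSE)
    }
    fol[[fid]] <- do.call(rbind, fol_rows)
    if (length(comp_rows)) comp[[fid]] <- do.call(rbind, comp_rows)

    # truth from the full (both-ovary) simulation, independent of scenario;
    # uses the same measured dry masses as the emitted tables so that the
    # truth is consistent with the measurement path by construction
    all_dom <- unlist(lapply(ovary_follicles, `[[`, "dom"))
    all_non <- unlist(lapply(ovary_follicles, `[[`, "non"))
    true_budget <- truth_budget(ann, spec)
    tru[[fid]] <- data.frame(
      female_id = fid, clutches_laid = laid, clutches_left = left,
      clutch_frequency = cf,
      season_half = if (laid < left) "first" else "second",
      dominant_n = length(all_dom), nondominant_n = length(all_non),
      eggs_laid = eggs_laid, eggs_left = eggs_left,
      one_ovary = one_ovary,
      yolk_to_deposit_g = true_budget$to_deposit,
      yolk_to_resorb_g = true_budget$to_resorb,
      deficit = true_budget$to_deposit > true_budget$to_resorb,
      stringsAsFactors = FALSE)
  }

  follicles <- do.call(rbind, fol)
  ovaries <- do.call(rbind, unname(ova))
  rownames(follicles) <- rownames(ovaries) <- NULL
  composition <- if (length(comp)) {
    cdf <- do.call(rbind, unname(comp)); rownames(cdf) <- NULL; cdf
  } else {
    empty <- r_composition("LF", 0L, lk)
    cbind(data.frame(female_id = character(0), follicle_id = character(0),
                     type = character(0), stringsAsFactors = FALSE), empty)
  }
  truth <- do.call(rbind, unname(tru)); rownames(truth) <- NULL
  females <- data.frame(
    female_id = unique(follicles$female_id),
    ovaries_measured = as.integer(table(ovaries$female_id)[
      unique(follicles$female_id)]),
    stringsAsFactors = FALSE)

  structure(list(follicles = follicles, ovaries = ovaries,
                 females = females, composition = composition,
                 truth = truth, spec = spec),
            class = "ovary_cohort")
}

# budget rules applied to the full (both-ovary) truth: measured dry masses
# where the cohort carries them, otherwise predictions with the negative
# range floored at 0; per-ovary largest-follicle subtraction; resorbable
# yolk summed over non-dominant follicles
truth_budget <- function(ann, spec) {
  to_dep <- 0; to_res <- 0
  for (an in ann) {
    pred <- pmax(spec$dry_mass_intercept + spec$dry_mass_slope * an$diam, 0)
    eff <- ifelse(is.na(an$dry), pred, an$dry)
    w <- eff[seq_len(an$n_d)]
    wn <- if (an$n_d < length(eff)) eff[(an$n_d + 1):length(eff)] else
      numeric(0)
    if (length(w)) to_dep <- to_dep + sum(max(w) - w)
    to_res <- to_res + sum(wn)
  }
  list(to_deposit = to_dep, to_resorb = to_res)
}

#' @export
print.ovary_cohort <- function(x, ...) {
  cat(sprintf("Synthetic nesting cohort: %d females, %d follicles, %d ovaries\n",
              nrow(x$females), nrow(x$follicles), nrow(x$ovaries)))
  cat(sprintf("  composition rows: %d; seed %d\n",
              nrow(x$composition), x$spec$rng_seed))
  invisible(x)
}

#' Write cohort tables to CSV
#'
#' Emits `follicles.csv`, `ovaries.csv`, `females.csv` and
#' `composition.csv` in the schemas understood by the package readers
#' ([read_follicles()] and friends); the round trip through the readers is
#' lossless.
#'
#' @param cohort an `ovary_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
emit_tables <- function(cohort, dir) {
  if (!inherits(cohort, "ovary_cohort")) stop("cohort must be an ovary_cohort")
  if (nrow(cohort$follicles) == 0L) stop("cohort is empty")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(follicles = file.path(dir, "follicles.csv"),
             ovaries = file.path(dir, "ovaries.csv"),
             females = file.path(dir, "females.csv"),
             composition = file.path(dir, "composition.csv"))
  for (nm in names(paths)) {
    ok <- tryCatch({
      write.csv(cohort[[nm]], paths[[nm]], row.names = FALSE, na = "")
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop(sprintf("failed to write %s: %s", paths[[nm]],
                   conditionMessage(ok)))
    }
  }
  invisible(paths)
}
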