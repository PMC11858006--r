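# Dry-weight regression, per-female budgets, cohort aggregation,
# energy/protein conversions, seasonal comparisons.

test_that("dry-weight prediction evaluates the working regression", {
  expect_equal(predict_dry_weight(30), 7.06)
  expect_equal(predict_dry_weight(35), 9.92)
  # root of the line: 10.1 / 0.572 mm predicts exactly 0 g
  expect_equal(predict_dry_weight(10.1 / 0.572), 0)
  # below the root the raw prediction is negative
  expect_lt(predict_dry_weight(8), 0)
  expect_error(predict_dry_weight(-2), "positive")
})

test_that("OLS refit recovers the generating line", {
  d <- seq(19, 36, length.out = 20)
  m <- fit_dry_weight_model(d, -10.1 + 0.572 * d)
  expect_equal(m$intercept, -10.1, tolerance = 1e-9)
  expect_equal(m$slope, 0.572, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)

  set.seed(3)
  d2 <- runif(100, 19, 36)
  y2 <- -10.1 + 0.572 * d2 + rnorm(100, 0, 0.5)
  m2 <- fit_dry_weight_model(d2, y2)
  se <- 0.5 / sqrt(sum((d2 - mean(d2))^2))
  expect_lt(abs(m2$slope - 0.572), 3 * se)

  expect_error(fit_dry_weight_model(c(20, 30), c(1, 2)), "at least 3")
  expect_error(fit_dry_weight_model(rep(20, 5), 1:5), "degenerate")
})

test_that("energy and crude-protein conversions are exact arithmetic", {
  k <- energetic_constants()
  expect_equal(yolk_energy_kj(1, k), 0.95 * 29.5)
  for (y in c(2311, 523, 239, 1535, 7.73)) {
    expect_equal(yolk_energy_kj(y, k), y * 0.95 * 29.5)
  }
  for (n in c(224.2, 50.7, 23.2)) {
    expect_equal(crude_protein_g(n, k), n * 6.25)
  }
  expect_error(energetic_constants(organic_fraction = 0), "positive")
})

test_that("female budget implements the stated investment rules", {
  dd <- diam_for_mass(c(7.7, 6.0, 5.0))
  dn <- diam_for_mass(c(1.0, 0.5))
  # diameters below threshold carry the non-dominant masses via measured
  # dry mass so the worked example is exact
  fem <- make_female("W", make_ovary("left",
    diameters = c(dd, 10, 11),
    dry_mass = c(NA, NA, NA, 1.0, 0.5)))
  b <- suppressMessages(female_budget(fem, 18))
  expect_equal(b$deposited_yolk_g, 2 * 18.7)
  expect_equal(b$to_deposit_yolk_g, 2 * ((7.7 - 6.0) + (7.7 - 5.0)))
  expect_equal(b$to_resorb_yolk_g, 2 * 1.5)
  expect_true(b$deficit)
  expect_true(b$extrapolated)
  expect_equal(b$deposited_energy_kj, 2 * 18.7 * 0.95 * 29.5)
  expect_equal(b$deposited_cp_g, b$deposited_n_g * 6.25)

  # all dominant follicles equal: nothing left to deposit
  flat <- make_female("X", make_ovary("left", diameters = rep(30, 4)),
                      make_ovary("right", diameters = rep(28, 3)))
  bf <- suppressMessages(female_budget(flat, 18))
  expect_equal(bf$to_deposit_yolk_g, 0)
  expect_false(bf$extrapolated)

  none <- make_female("Y", make_ovary("left", diameters = c(8, 9)))
  expect_error(suppressMessages(female_budget(none, 18)), "no dominant")
})

test_that("negative predictions are floored: small follicles yield no yolk", {
  fem <- make_female("Z", make_ovary("left", diameters = c(30, 8, 9)),
                     make_ovary("right", diameters = c(28, 10)))
  b <- suppressMessages(female_budget(fem, 18))
  expect_equal(b$to_resorb_yolk_g, 0)  # all non-dominant below the root
  expect_equal(b$deposited_yolk_g, 7.06 + predict_dry_weight(28))
})

test_that("deposited + to-deposit equals count x ovary maximum, and scales", {
  set.seed(8)
  for (r in 1:10) {
    d <- runif(sample(3:12, 1), 19, 36)
    fem <- make_female("P", make_ovary("left", diameters = d),
                       make_ovary("right", scars = 0))
    b <- suppressMessages(female_budget(fem, 18))
    w <- pmax(predict_dry_weight(d), 0)
    expect_equal(b$deposited_yolk_g + b$to_deposit_yolk_g,
                 length(d) * max(w), tolerance = 1e-9)
  }
  # doubling every follicle dry mass doubles masses and energies and
  # preserves the deficit flag
  masses_dom <- c(7, 5, 4); masses_non <- c(0.8, 0.2)
  mk <- function(s) make_female("Q", make_ovary("left",
    diameters = c(diam_for_mass(s * masses_dom), 10, 11),
    dry_mass = c(NA, NA, NA, s * masses_non)))
  b1 <- suppressMessages(female_budget(mk(1), 18))
  b2 <- suppressMessages(female_budget(mk(2), 18))
  for (col in grep("_g$|_kj$", names(b1), value = TRUE)) {
    expect_equal(b2[[col]], 2 * b1[[col]], tolerance = 1e-9)
  }
  expect_equal(b1$deficit, b2$deficit)
})

test_that("per-female composition means drive the nutrient scaling", {
  comp <- data.frame(female_id = "W", follicle_id = c("a", "b"),
                     type = c("SF", "LF"),
                     water_pct = c(49, 47), om_pct = c(95, 95),
                     mineral_pct = c(5, 5), lipid_pct = c(30, 34),
                     n_pct = c(9, 11), p_pct = c(1.0, 1.2),
                     stringsAsFactors = FALSE)
  fem <- make_female("W", make_ovary("left", diameters = c(30, 32)))
  b <- cohort_budget(list(fem), 18, composition = comp)
  expect_equal(b$deposited_lipid_g, b$deposited_yolk_g * 0.32)
  expect_equal(b$deposited_n_g, b$deposited_yolk_g * 0.10)
  expect_equal(b$deposited_p_g, b$deposited_yolk_g * 0.011)
  expect_equal(b$deposited_cp_g, b$deposited_yolk_g * 0.10 * 6.25)
})

test_that("cohort summary aggregates budgets and the deficit fraction", {
  mk <- function(id, dom, non) {
    make_female(id, make_ovary("left",
      diameters = c(diam_for_mass(dom), seq(10, 11, length.out = length(non))),
      dry_mass = c(rep(NA, length(dom)), non)),
      make_ovary("right", scars = 0))
  }
  fems <- list(mk("A", c(10, 5), c(2)),     # to_deposit 5 > to_resorb 2
               mk("B", c(10, 9), c(8)))     # to_deposit 1 < to_resorb 8
  budgets <- suppressMessages(cohort_budget(fems, 18))
  cs <- cohort_budget_summary(budgets)
  expect_equal(cs$deficit_fraction, 0.5)
  expect_equal(cs$summary$mean_g[cs$summary$category == "yolk_to_be_resorbed"],
               5)
  expect_equal(cs$summary$energy_kj,
               cs$summary$mean_g * 0.95 * 29.5, tolerance = 1e-9)
  expect_equal(cs$summary$energy_max_kj,
               cs$summary$max_g * 0.95 * 29.5, tolerance = 1e-9)

  # boundary: no resorbable yolk at all means every female is in deficit
  fems2 <- list(mk("C", c(10, 5), numeric(0)), mk("D", c(9, 3), numeric(0)))
  cs2 <- cohort_budget_summary(suppressMessages(cohort_budget(fems2, 18)))
  expect_equal(cs2$deficit_fraction, 1)
  expect_error(cohort_budget_summary(budgets[0, ]), "no budgets")
})

test_that("deficit fraction is recovered on a mixed synthetic cohort", {
  # a dry-mass model with near-zero intercept gives non-dominant follicles
  # real mass, so both deficit outcomes occur
  sp <- cohort_spec(n_females = 40, rng_seed = 14,
                    dry_mass_intercept = 0, dry_mass_slope = 0.08)
  co <- generate_cohort(sp)
  expect_gt(mean(co$truth$deficit), 0.05)
  expect_lt(mean(co$truth$deficit), 0.95)
  recs <- as_female_records(co$follicles, co$ovaries)
  budgets <- suppressMessages(
    cohort_budget(recs, 18, model = dry_weight_model(0, 0.08)))
  cs <- cohort_budget_summary(budgets)
  expect_lt(abs(cs$deficit_fraction - mean(co$truth$deficit)), 0.1)
})

test_that("seasonal comparisons separate constructed season halves", {
  mk_sum <- function(n1, n2, d1, d2) {
    data.frame(season_half = rep(c("first", "second"), c(n1, n2)),
               dominant_n = c(d1, d2),
               nondominant_n = c(d1, d2) + 5)
  }
  set.seed(6)
  s <- mk_sum(15, 15, round(rnorm(15, 700, 50)), round(rnorm(15, 300, 50)))
  res <- seasonal_follicle_comparison(s)
  expect_lt(res$dominant$p_value, 0.001)
  expect_lt(res$nondominant$p_value, 0.001)

  same <- mk_sum(4, 4, rep(100, 4), rep(100, 4))
  res2 <- seasonal_follicle_comparison(same)
  expect_equal(res2$dominant$statistic, 0)
  expect_equal(res2$dominant$p_value, 1)

  expect_error(seasonal_follicle_comparison(
    data.frame(season_half = "first", dominant_n = 1, nondominant_n = 1)),
    "both season halves")
})

test_that("exact rank-sum tail matches enumeration of arrangements", {
  # {1,2,3} vs {4,5,6}: 1 favourable of choose(6,3)=20 arrangements
  p <- wilcox.test(c(1, 2, 3), c(4, 5, 6), alternative = "less",
                   exact = TRUE)$p.value
  expect_equal(p, 1 / 20)
})
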