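# Egg/clutch accounting, season halves, symmetry, follicle growth.

test_that("egg counts sum measured ovaries and double a single ovary", {
  two <- make_female("A",
    make_ovary("left", scars = 300, diameters = c(rep(25, 180), rep(8, 10))),
    make_ovary("right", scars = 250, diameters = c(rep(25, 170), rep(8, 5))))
  e <- count_eggs(two, 18)
  expect_equal(e$eggs_laid, 550)
  expect_equal(e$eggs_left, 350)
  expect_false(e$extrapolated)

  one <- make_female("B",
    make_ovary("left", scars = 275, diameters = rep(25, 165)))
  e1 <- count_eggs(one, 18)
  expect_equal(e1$eggs_laid, 550)
  expect_equal(e1$eggs_left, 330)
  expect_true(e1$extrapolated)

  zero <- make_female("C", make_ovary("left", scars = 0))
  e0 <- count_eggs(zero, 18)
  expect_equal(c(e0$eggs_laid, e0$eggs_left), c(0, 0))
  expect_true(e0$extrapolated)

  none <- make_female("D", make_ovary("left", measured = FALSE))
  expect_error(count_eggs(none, 18), "no measured ovary")
})

test_that("diameters exactly at the threshold are non-dominant", {
  fem <- make_female("T", make_ovary("left", diameters = c(18, 18.01, 17.9),
                                     scars = 0),
                     make_ovary("right", scars = 0))
  expect_equal(count_eggs(fem, 18)$eggs_left, 1)
})

test_that("clutch conversion rounds half-up and classifies season halves", {
  s <- summarize_female(550, 330)
  expect_equal(s$clutches_laid, 5)
  expect_equal(s$clutches_left, 3)
  expect_equal(s$clutch_frequency, 8)
  expect_equal(s$season_half, "second")

  s2 <- summarize_female(220, 440)
  expect_equal(c(s2$clutches_laid, s2$clutches_left, s2$clutch_frequency),
               c(2, 4, 6))
  expect_equal(s2$season_half, "first")

  # equal clutches laid and left count as the second half
  expect_equal(summarize_female(330, 330)$season_half, "second")

  # half-up rounding at the boundary: 55 eggs is half a clutch, rounds up
  expect_equal(summarize_female(55, 0)$clutches_laid, 1)
  expect_equal(summarize_female(54, 0)$clutches_laid, 0)
  expect_error(summarize_female(-1, 10), "non-negative")
})

test_that("symmetry report returns zero statistics for identical sides", {
  recs <- lapply(1:6, function(i) {
    d <- c(rep(25, 10 + i), rep(8, 20))
    make_female(paste0("F", i),
                make_ovary("left", scars = 100 + i, diameters = d,
                           volume = 1000),
                make_ovary("right", scars = 100 + i, diameters = d,
                           volume = 1000))
  })
  rep_ <- suppressMessages(ovary_symmetry_report(recs, 18))
  tested <- rep_[rep_$variable != "mass_g" &
                 rep_$variable != "oviduct_egg_count", ]
  expect_true(all(tested$statistic == 0))
  expect_true(all(tested$p_value == 1))
  expect_true(all(is.na(rep_$p_value[rep_$variable == "mass_g"])))
})

test_that("a systematic left oviduct deficit is detected", {
  set.seed(5)
  recs <- lapply(1:24, function(i) {
    d <- c(rep(25, 12), rep(8, 15))
    make_female(paste0("F", i),
                make_ovary("left", scars = 100, diameters = d, volume = 1000,
                           oviduct = round(rnorm(1, 45, 3))),
                make_ovary("right", scars = 100, diameters = d, volume = 1000,
                           oviduct = round(rnorm(1, 55, 3))))
  })
  rep_ <- suppressMessages(ovary_symmetry_report(recs, 18))
  ovi <- rep_[rep_$variable == "oviduct_egg_count", ]
  expect_lt(ovi$p_value, 0.05)
  expect_lt(ovi$mean_diff, 0)
})

test_that("symmetry report needs at least two complete females", {
  one <- list(make_female("F1",
                          make_ovary("left", diameters = rep(25, 5)),
                          make_ovary("right", diameters = rep(25, 5))))
  expect_error(ovary_symmetry_report(one, 18), "at least 2 females")
})

test_that("pre-ovulatory growth averages (max - d) / d per ovary", {
  single <- make_female("G", make_ovary("left", diameters = 25))
  expect_equal(follicle_growth_pct(single, 18), 0)

  fem <- make_female("H", make_ovary("left", diameters = c(20, 30)))
  expect_equal(follicle_growth_pct(fem, 18), 25)  # mean of 50% and 0%

  flat <- make_female("I", make_ovary("left", diameters = c(25, 25, 25)))
  expect_equal(follicle_growth_pct(flat, 18), 0)

  # ovary-specific maxima: each ovary contributes its own reference
  two <- make_female("J", make_ovary("left", diameters = c(20, 30)),
                     make_ovary("right", diameters = c(22, 33)))
  expect_equal(follicle_growth_pct(two, 18),
               mean(c(50, 0, 100 * (33 - 22) / 22, 0)))

  # alternative normalisation
  expect_equal(follicle_growth_pct(fem, 18, relative_to = "max"),
               mean(c(100 * 10 / 30, 0)))

  none <- make_female("K", make_ovary("left", diameters = c(8, 9)))
  expect_error(follicle_growth_pct(none, 18), "no dominant")
})

test_that("cohort reproductive summary recovers synthetic truth", {
  co <- generate_cohort(cohort_spec(n_females = 15, rng_seed = 33))
  recs <- as_female_records(co$follicles, co$ovaries)
  summ <- reproductive_summary(recs, 18)
  m <- merge(summ, co$truth, by = "female_id")
  expect_true(all(abs(m$clutch_frequency.x - m$clutch_frequency.y) <= 1))
  exact <- !m$one_ovary
  expect_equal(m$clutch_frequency.x[exact], m$clutch_frequency.y[exact])
  expect_true(all(m$extrapolated == m$one_ovary))
})
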