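# Durbin rank test, pairwise follow-ups, blocked two-group comparison.

make_complete_blocks <- function(b, t, f = function(bl, tr) rnorm(1)) {
  df <- expand.grid(block = paste0("B", seq_len(b)),
                    treatment = paste0("T", seq_len(t)),
                    stringsAsFactors = FALSE)
  df$response <- mapply(f, df$block, df$treatment)
  df
}

test_that("no within-block variation gives T = 0 and p = 1", {
  tab <- make_complete_blocks(5, 3, function(bl, tr) as.numeric(sub("B", "", bl)))
  res <- durbin_test(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("Durbin equals Friedman on complete blocks", {
  set.seed(19)
  for (r in 1:8) {
    b <- sample(4:12, 1); t <- sample(3:5, 1)
    tab <- make_complete_blocks(b, t)
    res <- durbin_test(tab)
    # direct Friedman formula on within-block ranks
    ranks <- ave(tab$response, tab$block, FUN = rank)
    Rj <- tapply(ranks, tab$treatment, sum)
    fried <- 12 / (b * t * (t + 1)) * sum((Rj - b * (t + 1) / 2)^2)
    expect_equal(res$statistic, fried, tolerance = 1e-9)
    # and against the stats implementation
    wide <- matrix(tab$response[order(tab$treatment, tab$block)], nrow = b)
    ft <- stats::friedman.test(wide)
    expect_equal(res$statistic, unname(ft$statistic), tolerance = 1e-9)
    expect_equal(res$df, unname(ft$parameter))
    expect_equal(res$p_value, ft$p.value, tolerance = 1e-9)
  }
})

test_that("chi-square p agrees with within-block permutation in decision", {
  set.seed(29)
  perm_p <- function(tab) {
    obs <- durbin_test(tab)$statistic
    blocks <- split(seq_len(nrow(tab)), tab$block)
    perms <- function() {
      tb <- tab
      for (ix in blocks) tb$response[ix] <- sample(tab$response[ix])
      durbin_test(tb)$statistic
    }
    null <- replicate(400, perms())
    (1 + sum(null >= obs - 1e-12)) / (1 + length(null))
  }
  agree <- 0; total <- 12
  for (r in seq_len(total)) {
    b <- sample(3:5, 1)
    shift <- sample(c(0, 0, 1.5), 1)
    tab <- make_complete_blocks(b, 3, function(bl, tr)
      rnorm(1) + ifelse(tr == "T1", shift, 0))
    pc <- durbin_test(tab)$p_value
    pp <- perm_p(tab)
    agree <- agree + ((pc < 0.10) == (pp < 0.10))
  }
  expect_gte(agree / total, 0.9)
})

test_that("incomplete blocks are pruned and the BIBD case runs", {
  # classic balanced incomplete blocks: t=4 treatments, k=2 per block
  tab <- data.frame(
    block = rep(paste0("B", 1:6), each = 2),
    treatment = c("T1", "T2", "T3", "T4", "T1", "T3",
                  "T2", "T4", "T1", "T4", "T2", "T3"),
    response = c(1, 2, 1, 2, 1, 3, 1, 3, 1, 4, 1, 4))
  res <- durbin_test(tab)
  expect_equal(res$df, 3L)
  expect_true(res$statistic >= 0 && res$p_value <= 1)

  with_single <- rbind(tab, data.frame(block = "B7", treatment = "T1",
                                       response = 5))
  expect_message(durbin_test(with_single), "fewer than 2 treatments")
  expect_error(suppressMessages(durbin_test(
    data.frame(block = c("A", "B"), treatment = c("T1", "T2"),
               response = c(1, 2)))), "no blocks")
})

test_that("pairwise follow-ups isolate a shifted treatment", {
  set.seed(37)
  tab <- make_complete_blocks(20, 3, function(bl, tr)
    rnorm(1) + ifelse(tr == "T3", 10, 0))
  pw <- durbin_all_pairs(tab)
  expect_equal(nrow(pw), 3)
  sig <- pw$p_adjusted < 0.05
  expect_true(all(sig[pw$pair %in% c("T1-T3", "T2-T3")]))
  expect_false(sig[pw$pair == "T1-T2"])
  expect_true(all(pw$p_adjusted >= pw$p_value - 1e-12))

  flat <- make_complete_blocks(8, 3, function(bl, tr)
    as.numeric(sub("B", "", bl)))
  expect_message(out <- durbin_all_pairs(flat), "no pairwise")
  expect_equal(nrow(out), 0)
})

test_that("blocked two-group test is the paired fixed-effect test", {
  set.seed(41)
  b <- 38
  base <- rnorm(b, 49.7, 3)
  tab <- data.frame(block = rep(paste0("B", 1:b), 2),
                    treatment = rep(c("SF", "LF"), each = b),
                    response = c(base, base - rnorm(b, 2.3, 1.0)))
  res <- blocked_two_group(tab)
  expect_lt(res$p_value, 0.001)
  # equals t.test on differences
  d <- tab$response[tab$treatment == "LF"] - tab$response[tab$treatment == "SF"]
  tt <- t.test(d)
  expect_equal(res$p_value, tt$p.value)
  expect_equal(abs(res$statistic), abs(unname(tt$statistic)))

  zero <- data.frame(block = rep(1:5, 2), treatment = rep(c("a", "b"), each = 5),
                     response = rep(1:5, 2))
  rz <- blocked_two_group(zero)
  expect_equal(rz$statistic, 0)
  expect_equal(rz$p_value, 1)

  expect_error(blocked_two_group(
    data.frame(block = 1:2, treatment = c("a", "b"), response = 1:2)),
    "2 treatments|complete blocks")
})

test_that("paired and Durbin decisions agree on a strong two-group shift", {
  set.seed(43)
  b <- 15
  base <- rnorm(b)
  tab <- data.frame(block = rep(paste0("B", 1:b), 2),
                    treatment = rep(c("a", "b"), each = b),
                    response = c(base, base + 5))
  expect_lt(blocked_two_group(tab)$p_value, 0.01)
  expect_lt(durbin_test(tab)$p_value, 0.01)
})
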