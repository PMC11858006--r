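# Rank-based inference for female-blocked designs: Durbin test (which
# reduces to Friedman on complete blocks), pairwise follow-ups with the
# Durbin standard error, and the exact paired test for two treatments.

#' Build and validate a block-design table
#'
#' @param blocks vector of block identifiers (female ids).
#' @param treatments vector of treatment labels (follicle types).
#' @param response numeric response (one value per block x treatment; the
#'   per-female mean when follicle-level data are aggregated).
#' @return data.frame with columns `block`, `treatment`, `response` and
#'   class `block_design`.
#' @export
block_design <- function(blocks, treatments, response) {
  df <- data.frame(block = as.character(blocks),
                   treatment = as.character(treatments),
                   response = as.numeric(response),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$response))) stop("responses must be finite")
  if (anyDuplicated(df[c("block", "treatment")])) {
    stop("at most one response per block x treatment cell")
  }
  class(df) <- c("block_design", "data.frame")
  df
}

as_block_design <- function(table) {
  if (inherits(table, "block_design")) return(table)
  need <- c("block", "treatment", "response")
  if (!all(need %in% names(table))) {
    stop("table must have columns block, treatment, response")
  }
  block_design(table$block, table$treatment, table$response)
}

# drop blocks with fewer than 2 observed treatments; message the count
prune_blocks <- function(df) {
  sizes <- table(df$block)
  drop <- names(sizes)[sizes < 2L]
  if (length(drop)) {
    message(sprintf("dropping %d block(s) with fewer than 2 treatments",
                    length(drop)))
    df <- df[!df$block %in% drop, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no blocks with at least 2 treatments remain")
  df
}

durbin_components <- function(df) {
  df$rank <- ave(df$response, df$block, FUN = function(v) rank(v))  # midranks
  treatments <- sort(unique(df$treatment))
  t_ <- length(treatments)
  blocks <- unique(df$block)
  b <- length(blocks)
  k_by_block <- table(df$block)
  r_j <- table(factor(df$treatment, levels = treatments))
  R_j <- tapply(df$rank, factor(df$treatment, levels = treatments), sum)
  R_j[is.na(R_j)] <- 0
  # expected rank sum per treatment: sum over its blocks of (k_i + 1)/2
  E_j <- vapply(treatments, function(tr) {
    bl <- df$block[df$treatment == tr]
    sum((k_by_block[bl] + 1) / 2)
  }, numeric(1))
  A <- sum(df$rank^2)
  C <- sum(k_by_block * (k_by_block + 1)^2 / 4)
  list(df = df, treatments = treatments, t = t_, b = b,
       k = mean(k_by_block), r = mean(r_j), R_j = as.numeric(R_j),
       E_j = E_j, A = A, C = C)
}

#' Durbin rank test for (balanced incomplete) block designs
#'
#' Within-block midranks; the statistic is
#' `T = (t - 1) * sum_j (R_j - E_j)^2 / (A - C)` where `R_j` is the rank
#' sum of treatment j, `E_j` its null expectation, `A` the sum of squared
#' ranks and `C` the tie-free baseline.  On complete blocks without ties
#' this is exactly the Friedman statistic.  The p-value uses the
#' chi-squared reference with `t - 1` degrees of freedom.  Blocks with
#' fewer than two observed treatments are dropped with a notice.
#'
#' @param table a [block_design()] or a data.frame with columns `block`,
#'   `treatment`, `response`.
#' @return object of class `rank_test`: `statistic`, `df`, `p_value`,
#'   `rank_sums`, `treatments`, plus the design constants.
#' @export
durbin_test <- function(table) {
  df <- prune_blocks(as_block_design(table))
  cmp <- durbin_components(df)
  denom <- cmp$A - cmp$C
  stat <- if (denom <= 0) 0 else
    (cmp$t - 1) * sum((cmp$R_j - cmp$E_j)^2) / denom
  structure(
    list(statistic = stat, df = cmp$t - 1L,
         p_value = if (denom <= 0) 1 else pchisq(stat, cmp$t - 1L,
                                                 lower.tail = FALSE),
         rank_sums = setNames(cmp$R_j, cmp$treatments),
         expected = setNames(cmp$E_j, cmp$treatments),
         treatments = cmp$treatments,
         b = cmp$b, k = cmp$k, r = cmp$r, A = cmp$A, C = cmp$C,
         pairwise = NULL),
    class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Durbin rank test: T = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$pairwise) && nrow(x$pairwise)) {
    cat("Pairwise (Bonferroni):\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' Pairwise treatment comparisons after a significant Durbin test
#'
#' Rank-sum differences scaled by the Durbin standard error and referred to
#' a t distribution with `b*k - b - t + 1` degrees of freedom; p-values are
#' Bonferroni-adjusted across pairs.  If the omnibus test is not
#' significant at `alpha` an empty table is returned with a notice.
#'
#' @inheritParams durbin_test
#' @param alpha omnibus significance gate (default 0.05).
#' @return data.frame with one row per pair: `pair`, `statistic`,
#'   `p_value`, `p_adjusted`.
#' @export
durbin_all_pairs <- function(table, alpha = 0.05) {
  df <- prune_blocks(as_block_design(table))
  omnibus <- durbin_test(df)
  empty <- data.frame(pair = character(0), statistic = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.na(omnibus$p_value) || omnibus$p_value >= alpha) {
    message(sprintf("omnibus Durbin p = %.3g >= alpha = %g: no pairwise tests",
                    omnibus$p_value, alpha))
    return(empty)
  }
  cmp <- durbin_components(df)
  t_ <- cmp$t; b <- cmp$b; k <- cmp$k; r <- cmp$r
  df2 <- b * k - b - t_ + 1
  T1 <- omnibus$statistic
  se <- sqrt(pmax(2 * r * (cmp$A - cmp$C) / df2 * (1 - T1 / (b * (k - 1))), 0))
  pairs <- utils::combn(seq_len(t_), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(pc) {
    i <- pairs[1, pc]; j <- pairs[2, pc]
    stat <- if (se > 0) (cmp$R_j[i] - cmp$R_j[j]) / se else 0
    p <- 2 * pt(-abs(stat), df2)
    data.frame(pair = paste(cmp$treatments[i], cmp$treatments[j], sep = "-"),
               statistic = stat, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, p.adjust(out$p_value, method = "bonferroni"))
  rownames(out) <- NULL
  out
}

#' Blocked comparison of two treatments
#'
#' The exact fixed-effect test of treatment in a two-treatment complete
#' block design with one observation per cell: a paired t test on the
#' per-block differences (`df = blocks - 1`).  Blocks missing either
#' treatment are dropped.  If every paired difference is zero the
#' statistic is 0 and the p-value 1.
#'
#' @inheritParams durbin_test
#' @return list: `statistic`, `df`, `p_value`, `mean_diff` (first treatment
#'   minus second, in sorted label order), `n_blocks`, `treatments`.
#' @export
blocked_two_group <- function(table) {
  df <- as_block_design(table)
  treatments <- sort(unique(df$treatment))
  if (length(treatments) != 2L) {
    stop("blocked_two_group requires exactly 2 treatments")
  }
  wide <- merge(df[df$treatment == treatments[1], c("block", "response")],
                df[df$treatment == treatments[2], c("block", "response")],
                by = "block", suffixes = c("_1", "_2"))
  if (nrow(wide) < 3L) stop("need at least 3 complete blocks")
  d <- wide$response_1 - wide$response_2
  if (sd(d) == 0) {
    # constant differences: the paired t degenerates
    if (mean(d) == 0) {
      return(list(statistic = 0, df = nrow(wide) - 1L, p_value = 1,
                  mean_diff = 0, n_blocks = nrow(wide),
                  treatments = treatments))
    }
    return(list(statistic = sign(mean(d)) * Inf, df = nrow(wide) - 1L,
                p_value = 0, mean_diff = mean(d), n_blocks = nrow(wide),
                treatments = treatments))
  }
  tt <- t.test(d)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d), n_blocks = nrow(wide),
       treatments = treatments)
}
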