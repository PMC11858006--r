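# Yolk-composition comparisons across follicle types in a female-blocked
# design, and the tabulated report.

comp_variables <- c(water = "water_pct", om = "om_pct", mineral = "mineral_pct",
                    lipid = "lipid_pct", n = "n_pct", p = "p_pct")

# per-female mean response per follicle type for one variable
variable_blocks <- function(composition, col) {
  agg <- aggregate(composition[[col]],
                   by = list(block = composition$female_id,
                             treatment = composition$type),
                   FUN = mean)
  names(agg)[3] <- "response"
  agg
}

# keep only females observed for every treatment level present
complete_blocks_only <- function(tab, treatments) {
  counts <- table(tab$block)
  keep <- names(counts)[counts == length(treatments)]
  dropped <- length(counts) - length(keep)
  if (dropped > 0) {
    message(sprintf("composition: dropping %d incomplete block(s)", dropped))
  }
  tab[tab$block %in% keep, , drop = FALSE]
}

#' Yolk-composition report across follicle types
#'
#' For each composition variable: per-type sample sizes (females and
#' follicles), mean percent and SD at the follicle level, and blocked
#' comparisons of the per-female type means.  With three or more follicle
#' types the omnibus test is the Durbin rank test (followed, when
#' significant, by Bonferroni-adjusted pairwise comparisons with the
#' Durbin standard error) on the rank branch, or a female-blocked
#' fixed-effect ANOVA with paired-t follow-ups on the parametric branch.
#' With two types the blocked paired test ([blocked_two_group()]) or its
#' rank analogue is used directly.  The branch per variable follows
#' `gating`: by default water and organic matter take the rank branch and
#' the remaining variables the parametric branch.
#'
#' @param composition data.frame as from [read_composition()].
#' @param alpha significance gate for pairwise follow-ups (default 0.05).
#' @param gating `"default"` (rank for water/om, parametric otherwise),
#'   `"rank"` or `"parametric"` for all variables.
#' @return list with `table` (one row per variable x type, including the
#'   omnibus p-value and decision rule) and `pairwise` (one row per
#'   variable x pair where follow-ups ran).
#' @export
composition_report <- function(composition, alpha = 0.05,
                               gating = c("default", "rank", "parametric")) {
  gating <- match.arg(gating)
  if (nrow(composition) == 0L) stop("empty composition table")
  types <- sort(unique(composition$type))

  tab_rows <- list(); pair_rows <- list()
  for (vn in names(comp_variables)) {
    col <- comp_variables[[vn]]
    if (!col %in% names(composition) || all(is.na(composition[[col]]))) {
      message("composition: variable '", vn, "' absent, skipped")
      next
    }
    sub <- composition[!is.na(composition[[col]]), , drop = FALSE]
    types_v <- sort(unique(sub$type))
    blocks <- variable_blocks(sub, col)
    blocks <- complete_blocks_only(blocks, types_v)
    rule <- if (gating == "default") {
      if (vn %in% c("water", "om")) "rank" else "parametric"
    } else gating

    p_omni <- NA_real_
    n_blocks <- length(unique(blocks$block))
    if (length(types_v) >= 2L && n_blocks >= 3L) {
      if (length(types_v) == 2L) {
        p_omni <- if (rule == "rank") durbin_test(blocks)$p_value
                  else blocked_two_group(blocks)$p_value
        if (!is.na(p_omni) && p_omni < alpha) {
          pair_rows[[vn]] <- data.frame(
            variable = vn, pair = paste(types_v, collapse = "-"),
            p_adjusted = p_omni, rule = rule, stringsAsFactors = FALSE)
        }
      } else if (rule == "rank") {
        p_omni <- durbin_test(blocks)$p_value
        pw <- suppressMessages(durbin_all_pairs(blocks, alpha = alpha))
        if (nrow(pw)) {
          pair_rows[[vn]] <- data.frame(variable = vn, pair = pw$pair,
                                        p_adjusted = pw$p_adjusted,
                                        rule = rule, stringsAsFactors = FALSE)
        }
      } else {
        fit <- aov(response ~ factor(treatment) + factor(block), data = blocks)
        an <- summary(fit)[[1]]
        p_omni <- an[["Pr(>F)"]][1]
        if (!is.na(p_omni) && p_omni < alpha) {
          prs <- utils::combn(types_v, 2)
          pw <- lapply(seq_len(ncol(prs)), function(pc) {
            pairtab <- blocks[blocks$treatment %in% prs[, pc], , drop = FALSE]
            bt <- blocked_two_group(pairtab)
            data.frame(variable = vn,
                       pair = paste(prs[, pc], collapse = "-"),
                       p_adjusted = NA_real_, p_raw = bt$p_value,
                       rule = rule, stringsAsFactors = FALSE)
          })
          pw <- do.call(rbind, pw)
          pw$p_adjusted <- pmin(1, p.adjust(pw$p_raw, "bonferroni"))
          pair_rows[[vn]] <- pw[c("variable", "pair", "p_adjusted", "rule")]
        }
      }
    }

    for (tp in types_v) {
      v <- sub[sub$type == tp, col]
      tab_rows[[paste(vn, tp)]] <- data.frame(
        variable = vn, type = tp,
        n_females = length(unique(sub$female_id[sub$type == tp])),
        n_follicles = length(v),
        mean_pct = if (length(v)) mean(v) else NA_real_,
        sd_pct = if (length(v) > 1) sd(v) else NA_real_,
        p_omnibus = p_omni, rule = rule,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, tab_rows)
  pairwise <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(variable = character(0), pair = character(0),
               p_adjusted = numeric(0), rule = character(0),
               stringsAsFactors = FALSE)
  rownames(tab) <- rownames(pairwise) <- NULL
  list(table = tab, pairwise = pairwise)
}
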