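#' @title Subgroup, period and regimen comparisons
#' @description Within target-drug records, each term's reporting is
#'   compared between two strata (age bands, sex, reporting period, or
#'   mono- vs combination therapy). The effect axis is the log2 odds ratio
#'   of the 2x2 (stratum x term-vs-other) table of (case, PT) records — a
#'   reconstruction of the usual volcano-plot axis, since published figures
#'   rarely define theirs. The p-value is the uncorrected chi-square when
#'   all expected cells are >= 5, else Fisher's exact test. No multiplicity
#'   adjustment gates significance; a Bonferroni column is emitted for the
#'   reader.
#' @name stratified
NULL

# 2x2 per term: (in A, other A, in B, other B); +0.5 on zero cells for the OR
.stratum_2x2 <- function(pairs, stratum, term_col, min_count) {
  tot <- table(factor(stratum, levels = c("A", "B")))
  counts <- pairs %>%
    mutate(.s = stratum) %>%
    group_by(term = .data[[term_col]]) %>%
    summarise(n_in_A = sum(.s == "A"), n_in_B = sum(.s == "B"),
              .groups = "drop") %>%
    mutate(n_other_A = as.integer(tot["A"]) - n_in_A,
           n_other_B = as.integer(tot["B"]) - n_in_B)
  counts[counts$n_in_A + counts$n_in_B >= min_count, ]
}

.compare_2x2 <- function(counts) {
  eff <- p <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    m <- matrix(c(counts$n_in_A[i], counts$n_other_A[i],
                  counts$n_in_B[i], counts$n_other_B[i]), nrow = 2)
    mc <- if (any(m == 0)) m + 0.5 else m
    eff[i] <- log2((mc[1, 1] * mc[2, 2]) / (mc[2, 1] * mc[1, 2]))
    expd <- outer(rowSums(m), colSums(m)) / sum(m)
    p[i] <- if (all(expd >= 5))
      suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
    else fisher.test(m)$p.value
    if (is.na(p[i])) p[i] <- 1
  }
  counts$effect_log2 <- eff
  counts$p_value <- p
  counts$p_bonferroni <- pmin(p * nrow(counts), 1)
  counts$significant <- p < 0.05 & eff != 0
  counts
}

#' Compare term reporting between two strata
#'
#' @param pairs a tibble of (case, term) records within target-drug cases,
#'   with at least the term column and one row per (case, term) record.
#' @param stratum character/factor vector aligned with `pairs` rows, values
#'   `"A"` and `"B"`.
#' @param term_col name of the term column (default `"pt"`).
#' @param min_count terms with fewer than this many records across both
#'   strata are dropped (default 3).
#' @return a tibble `term`, `n_in_A`, `n_other_A`, `n_in_B`, `n_other_B`,
#'   `effect_log2`, `p_value`, `p_bonferroni`, `significant`. Positive
#'   effects mean the term is reported relatively more in stratum A.
#' @export
compare_strata <- function(pairs, stratum, term_col = "pt", min_count = 3) {
  stratum <- as.character(stratum)
  stopifnot(length(stratum) == nrow(pairs), all(stratum %in% c("A", "B")))
  if (!any(stratum == "A") || !any(stratum == "B"))
    abort("degenerate stratifier: one side is empty")
  .compare_2x2(.stratum_2x2(pairs, stratum, term_col, min_count))
}

#' Compare reporting periods (volcano-plot table)
#'
#' Stratum A is `report_year >= cutoff_year`, stratum B the earlier period,
#' so positive effects mean later-period enrichment.
#'
#' @param pairs (case, term) records carrying a `report_year` column.
#' @param cutoff_year first year of the late period (default 2020).
#' @inheritParams compare_strata
#' @return as [compare_strata()].
#' @export
compare_periods <- function(pairs, cutoff_year = 2020, term_col = "pt",
                            min_count = 3) {
  yr <- pairs$report_year
  stopifnot(!is.null(yr))
  compare_strata(pairs[!is.na(yr), ],
                 ifelse(yr[!is.na(yr)] >= cutoff_year, "A", "B"),
                 term_col, min_count)
}

#' Age or sex subgroup comparison of target-drug reports
#'
#' @param ds a cleaned, target-filtered [faers_dataset()].
#' @param by `"age"` (stratum A = `[age_split[1], age_split[2])`, B =
#'   `>= age_split[2]`; missing ages excluded) or `"sex"` (A = male,
#'   B = female; unknown excluded).
#' @param age_split two left-closed band edges, default `c(18, 65)` (the
#'   18-64 vs 65+ convention; `c(18, 60)` gives the 18-60 vs 60+ variant).
#' @inheritParams compare_strata
#' @return as [compare_strata()].
#' @export
compare_subgroups <- function(ds, by = c("age", "sex"), age_split = c(18, 65),
                              min_count = 3) {
  by <- match.arg(by)
  recs <- inner_join(distinct(ds$events[, c("primary_id", "pt")]),
                     ds$cases, by = "primary_id")
  if (by == "age") {
    keep <- !is.na(recs$age_years) & recs$age_years >= age_split[1]
    s <- ifelse(recs$age_years < age_split[2], "A", "B")
  } else {
    keep <- recs$sex %in% c("male", "female")
    s <- ifelse(recs$sex == "male", "A", "B")
  }
  compare_strata(recs[keep, ], s[keep], "pt", min_count)
}

#' Monotherapy versus combination-regimen comparison at SOC level
#'
#' Among target-drug cases, stratum A carries the named comedication (any
#' role) and stratum B does not. Emits a forest-plot-ready table with the
#' odds ratio and its log-normal 95% CI per SOC.
#'
#' @param ds a cleaned, target-filtered [faers_dataset()].
#' @param comedication search string for the comedication.
#' @param map PT-to-SOC tibble ([load_pt_soc_map()]).
#' @inheritParams compare_strata
#' @return as [compare_strata()] plus `or`, `or_lo`, `or_hi`; empty with a
#'   warning when the comedication is absent.
#' @export
compare_regimens <- function(ds, comedication, map, min_count = 3) {
  combo_ids <- match_target_ids(ds$drugs, comedication, role = NULL)
  if (!length(combo_ids)) {
    warn(paste0("comedication '", comedication, "' not found in any report"))
    return(tibble(term = character(0)))
  }
  recs <- distinct(ds$events[, c("primary_id", "pt")])
  recs <- left_join(recs, map, by = "pt")
  recs$soc[is.na(recs$soc)] <- "UNMAPPED"
  s <- ifelse(recs$primary_id %in% combo_ids, "A", "B")
  out <- compare_strata(recs, s, "soc", min_count)
  out$or <- 2^out$effect_log2
  se <- sqrt(1 / pmax(out$n_in_A, 0.5) + 1 / pmax(out$n_other_A, 0.5) +
               1 / pmax(out$n_in_B, 0.5) + 1 / pmax(out$n_other_B, 0.5))
  out$or_lo <- exp(log(out$or) - .z95 * se)
  out$or_hi <- exp(log(out$or) + .z95 * se)
  out
}
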