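#' @title Fourfold contingency tables at PT and SOC level
#' @description For each adverse-event term the classic 2x2 of
#'   disproportionality analysis is assembled: `a` reports with both the
#'   target drug and the term, `b` target-drug reports with other terms,
#'   `c` other-drug reports with the term, `d` everything else. The counting
#'   unit is the distinct (case, PT) pair — one case with several PTs
#'   contributes one unit per PT, and duplicate PT rows within a case
#'   collapse to one. At SOC level each (case, PT) pair contributes to its
#'   PT's organ class, so a case with two PTs in one SOC counts twice there.
#' @name contingency
NULL

#' Load a PT-to-SOC mapping file
#'
#' A simplified two-column stand-in for the MedDRA hierarchy: tab-separated,
#' header `pt<TAB>soc`, exactly one SOC per PT.
#'
#' @param path path to the mapping file.
#' @return a tibble with columns `pt`, `soc`; duplicate identical rows are
#'   collapsed silently, conflicting rows are an error naming the PT.
#' @export
load_pt_soc_map <- function(path) {
  raw <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               data.table = FALSE, showProgress = FALSE)
  if (!all(c("pt", "soc") %in% names(raw)))
    abort("PT/SOC map needs header columns 'pt' and 'soc'")
  map <- distinct(as_tibble(raw[, c("pt", "soc")]))
  dup <- unique(map$pt[duplicated(map$pt)])
  if (length(dup))
    abort(paste0("conflicting SOC mapping for PT(s): ",
                 paste(dup, collapse = ", ")))
  map
}

#' Distinct (case, PT) pairs with a target-drug flag
#'
#' The elementary counting unit for screening: one row per distinct
#' (case, preferred term) pair across the whole database, flagged by whether
#' the case carries the target drug (default in the primary-suspect role).
#' PT strings are compared after trimming; case identity is the deduplicated
#' `case_id`.
#'
#' @param ds a cleaned [faers_dataset()].
#' @param names target drug search strings (case-insensitive substring).
#' @param role role restriction for the target match (default `"PS"`).
#' @return a tibble `case_id`, `pt`, `target` (logical).
#' @export
case_pt_pairs <- function(ds, names, role = "PS") {
  stopifnot(inherits(ds, "faers_dataset"))
  tgt_pid <- match_target_ids(ds$drugs, names, role)
  tgt_case <- unique(ds$cases$case_id[ds$cases$primary_id %in% tgt_pid])
  ev <- inner_join(ds$events,
                   ds$cases[, c("primary_id", "case_id")], by = "primary_id")
  pairs <- distinct(tibble(case_id = ev$case_id, pt = trimws(ev$pt)))
  pairs$target <- pairs$case_id %in% tgt_case
  pairs[pairs$pt != "", ]
}

.fourfold <- function(pairs, term_col) {
  tot_t <- sum(pairs$target)
  tot_o <- sum(!pairs$target)
  tab <- pairs %>%
    group_by(term = .data[[term_col]]) %>%
    summarise(a = sum(target), c = sum(!target), .groups = "drop") %>%
    mutate(b = tot_t - a, d = tot_o - c, N = tot_t + tot_o) %>%
    select(term, a, b, c, d, N) %>%
    arrange(term)
  tab
}

#' Fourfold tables per preferred term
#'
#' @param pairs output of [case_pt_pairs()].
#' @return a tibble `term`, `level` (`"PT"`), `a`, `b`, `c`, `d`, `N`;
#'   empty (with a warning) when no target-drug pair exists. Terms never
#'   reported with the target drug appear with `a = 0`; the `N >= 3`
#'   screening rule downstream excludes them from flags.
#' @export
build_pt_tables <- function(pairs) {
  if (!any(pairs$target)) {
    warn("target drug matches no (case, PT) pair")
    return(tibble(term = character(0), level = character(0), a = integer(0),
                  b = integer(0), c = integer(0), d = integer(0),
                  N = integer(0)))
  }
  out <- .fourfold(pairs, "pt")
  out$level <- "PT"
  out[, c("term", "level", "a", "b", "c", "d", "N")]
}

#' Fourfold tables per system organ class
#'
#' Each (case, PT) pair contributes one unit to its PT's SOC, so the SOC
#' `a` column sums to the total target (case, PT) records. PTs absent from
#' the map are routed to an `"UNMAPPED"` bucket and flagged with a warning.
#'
#' @param pairs output of [case_pt_pairs()].
#' @param map a PT-to-SOC tibble as from [load_pt_soc_map()].
#' @return a tibble like [build_pt_tables()] with `level = "SOC"`.
#' @export
build_soc_tables <- function(pairs, map) {
  m <- left_join(pairs, map, by = "pt")
  n_unmapped <- sum(is.na(m$soc))
  if (n_unmapped > 0)
    warn(paste0(n_unmapped, " (case, PT) pair(s) with unmapped PT -> UNMAPPED"))
  m$soc[is.na(m$soc)] <- "UNMAPPED"
  if (!any(m$target)) {
    warn("target drug matches no (case, PT) pair")
    return(tibble(term = character(0), level = character(0), a = integer(0),
                  b = integer(0), c = integer(0), d = integer(0),
                  N = integer(0)))
  }
  out <- .fourfold(m, "soc")
  out$level <- "SOC"
  out[, c("term", "level", "a", "b", "c", "d", "N")]
}
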