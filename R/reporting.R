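#' @title Descriptive cohort summary and report bundle
#' @description Table-3-style descriptive characteristics of a target-drug
#'   cohort, and a deterministic report bundle assembling every stage's
#'   output with a machine-readable manifest. Percentages are
#'   100 * count / total cases, rounded half-up to one decimal — the
#'   arithmetic printed in published report tables (513/1082 -> 47.4).
#' @name reporting
NULL

.count_pct <- function(x, total, order_by_count = FALSE) {
  tb <- table(x, useNA = "no")
  out <- tibble(category = names(tb), count = as.integer(tb),
                pct = pct_of(as.integer(tb), total))
  if (order_by_count) out <- out[order(-out$count, out$category), ]
  out
}

#' Descriptive cohort summary
#'
#' @param ds a cleaned, target-filtered [faers_dataset()].
#' @param age_edges left-closed age band edges; the default
#'   `c(0, 18, 60, 80, Inf)` yields bands `<18`, `18-60`, `60-80`, `>80`
#'   (left-closed intervals resolve the overlapping printed labels), plus a
#'   `missing` row.
#' @param top_k how many countries to list (default 5).
#' @return a `cohort_summary` list of tibbles (`category`, `count`, `pct`):
#'   `n_cases`, `n_events`, `sex`, `age`, `countries`, `occupation`,
#'   `year`. Within each variable the counts sum to the case total
#'   (countries are top-k only).
#' @export
describe_cohort <- function(ds, age_edges = c(0, 18, 60, 80, Inf),
                            top_k = 5) {
  stopifnot(inherits(ds, "faers_dataset"))
  n <- nrow(ds$cases)
  if (n == 0L) abort("empty dataset")
  cs <- ds$cases
  age_lab <- c(paste0("<", age_edges[2]),
               paste0(age_edges[2:(length(age_edges) - 2)], "-",
                      age_edges[3:(length(age_edges) - 1)]),
               paste0(">", age_edges[length(age_edges) - 1]))
  age_band <- as.character(cut(cs$age_years, breaks = age_edges,
                               labels = age_lab, right = FALSE))
  age_band[is.na(age_band)] <- "missing"
  country <- cs$country
  country[is.na(country)] <- "missing"
  structure(list(
    n_cases = n,
    n_events = nrow(distinct(inner_join(ds$events,
                                        cs[, c("primary_id", "case_id")],
                                        by = "primary_id")[, c("case_id", "pt")])),
    sex = .count_pct(factor(cs$sex, c("male", "female", "unknown")), n),
    age = .count_pct(factor(age_band, c(age_lab, "missing")), n),
    countries = head(.count_pct(country, n, order_by_count = TRUE), top_k),
    occupation = .count_pct(cs$reporter_occupation, n, order_by_count = TRUE),
    year = .count_pct(cs$report_year, n)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d cases, %d (case, PT) records\n",
              x$n_cases, x$n_events))
  for (nm in c("sex", "age", "countries", "occupation", "year")) {
    cat("--", nm, "--\n")
    print(as.data.frame(x[[nm]]), row.names = FALSE)
  }
  invisible(x)
}

#' Assemble a report bundle
#'
#' Writes every stage output (data frames as CSV, lists as JSON) into one
#' directory together with the run configuration, the seed, and a
#' `manifest.json` listing each emitted file with its MD5 — bitwise stable
#' given identical inputs.
#'
#' @param outputs named list of stage outputs; `NULL` entries are an error
#'   naming the missing stage.
#' @param out_dir output directory.
#' @param config run configuration to record (any JSON-serializable list).
#' @param seed the run seed to record.
#' @return the manifest (invisibly), a list `files` of name -> md5.
#' @export
build_report <- function(outputs, out_dir, config = list(), seed = NA) {
  missing <- names(outputs)[vapply(outputs, is.null, logical(1))]
  if (length(missing))
    abort(paste0("missing stage output(s): ", paste(missing, collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(outputs)) {
    obj <- outputs[[nm]]
    if (is.data.frame(obj)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      fwrite(obj, f)
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE, na = "null")
    }
    files <- c(files, f)
  }
  cfgf <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(list(seed = seed, config = config), cfgf,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, na = "null")
  files <- c(files, cfgf)
  manifest <- list(files = as.list(setNames(unname(tools::md5sum(files)),
                                            basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the full signal-detection pipeline
#'
#' clean -> target filter -> contingency -> four-algorithm screening ->
#' time to onset -> period comparison -> regimen comparison -> adjusted OR
#' -> descriptive summary, returning every stage's output (and optionally
#' writing a report bundle).
#'
#' @param ds a raw [faers_dataset()] (pre-cleaning).
#' @param deleted consolidated deletion list.
#' @param target_names target drug search strings.
#' @param map PT-to-SOC tibble.
#' @param comedication comedication for the regimen/regression stages, or
#'   `NULL` to skip them.
#' @param outcome_pt outcome PT for the adjusted-OR stage (`NULL` skips).
#' @param expected_cases optional expected case count for validation.
#' @param out_dir optional report-bundle directory.
#' @param seed seed recorded in the bundle.
#' @return a named list of stage outputs.
#' @export
run_pipeline <- function(ds, deleted = character(0), target_names,
                         map, comedication = NULL, outcome_pt = NULL,
                         expected_cases = NULL, out_dir = NULL, seed = NA) {
  clean <- clean_dataset(ds, deleted)
  validation <- validate_counts(
    filter_target_drug(clean, target_names, "PS"), expected_cases)
  tgt <- filter_target_drug(clean, target_names, "PS")
  pairs <- case_pt_pairs(clean, target_names, "PS")
  pt_tab <- build_pt_tables(pairs)
  soc_tab <- build_soc_tables(pairs, map)
  out <- list(
    validation = validation,
    cohort = describe_cohort(tgt),
    pt_signals = screen_signals(pt_tab),
    soc_signals = screen_signals(soc_tab),
    onset = tryCatch(onset_analysis(tgt, target_names),
                     error = function(e) list(error = conditionMessage(e))))
  tgt_pairs <- inner_join(distinct(tgt$events[, c("primary_id", "pt")]),
                          tgt$cases[, c("primary_id", "report_year")],
                          by = "primary_id")
  out$periods <- tryCatch(compare_periods(tgt_pairs),
                          error = function(e) list(error = conditionMessage(e)))
  if (!is.null(comedication)) {
    out$regimens <- compare_regimens(tgt, comedication, map)
    if (!is.null(outcome_pt))
      out$adjusted <- tryCatch(
        adjusted_ror(tgt, outcome_pt, comedication)$fit$coefficients,
        error = function(e) list(error = conditionMessage(e)))
  }
  if (!is.null(out_dir)) {
    serializable <- lapply(out, function(o)
      if (is.data.frame(o) || is.list(o)) o else list(value = o))
    build_report(serializable, out_dir, seed = seed)
  }
  out
}
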