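#' @title Reading FAERS-style quarterly ASCII tables
#' @description Readers and cleaning steps for the FDA "$"-delimited dialect:
#'   first line is a "$"-separated header, no quoting, dates as `YYYYMMDD`
#'   (partial dates padded). One reader covers all table kinds via a schema
#'   argument; every reader returns a typed tibble and maps unparseable
#'   fields to missing rather than erroring.
#' @name faers_io
NULL

# raw header columns each schema requires (extra columns are carried along raw)
.faers_schemas <- list(
  demo    = c("primaryid", "caseid", "caseversion", "fda_dt", "age",
              "age_cod", "sex", "reporter_country", "occp_cod"),
  drug    = c("primaryid", "drug_seq", "role_cod", "drugname"),
  reac    = c("primaryid", "pt"),
  indi    = c("primaryid", "indi_drug_seq", "indi_pt"),
  outc    = c("primaryid", "outc_cod"),
  ther    = c("primaryid", "dsg_drug_seq", "start_dt"),
  deleted = c("caseid")
)

# multiplicative factors to years per FAERS age code; unknown codes -> NA
.age_code_factor <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
                      DY = 1 / 365.25, HR = 1 / 8766)

.occp_map <- c(MD = "physician", HP = "health_professional", PH = "pharmacist",
               CN = "consumer", OT = "other")

#' Read one FAERS-style ASCII table
#'
#' @param path path to a "$"-delimited file whose first line is the header.
#' @param schema table kind: one of `"demo"`, `"drug"`, `"reac"`, `"indi"`,
#'   `"outc"`, `"ther"`, `"deleted"`.
#' @return a typed tibble; see Details for the columns per schema. Unparseable
#'   dates, ages and role codes become `NA`; rows are never dropped except
#'   reaction rows whose preferred term is empty after trimming.
#' @details Typed columns by schema:
#'   * `demo`: `primary_id`, `case_id`, `case_version` (integer),
#'     `receipt_date` (Date), `age_years` (years, converted from the
#'     `age_cod` unit; outside \[0, 130\] -> `NA`), `sex`
#'     (`male`/`female`/`unknown`), `country`, `reporter_occupation`
#'     (`physician`/`health_professional`/`pharmacist`/`consumer`/`other`/
#'     `missing`), `report_year` (from `receipt_date`).
#'   * `drug`: `primary_id`, `drug_seq`, `role` (PS/SS/C/I), `drug_name`,
#'     `normalized_name` (uppercased, trimmed).
#'   * `reac`: `primary_id`, `pt` (trimmed), `event_date` (Date; the synthetic
#'     dialect carries `event_dt` per reaction row, `NA` when absent).
#'   * `ther`: `primary_id`, `drug_seq`, `start_date` (Date).
#'   * `indi` / `outc`: ids plus the raw term/outcome code.
#'   * `deleted`: a character vector of case ids (set semantics).
#' @export
read_faers_table <- function(path, schema = names(.faers_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  required <- .faers_schemas[[schema]]

  if (file.size(path) == 0L) {
    warn(paste0("empty file: ", path))
    return(.empty_typed(schema))
  }
  raw <- fread(path, sep = "$", header = TRUE, colClasses = "character",
               quote = "", fill = TRUE, data.table = FALSE,
               na.strings = NULL, showProgress = FALSE)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("schema '", schema, "' is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0L) warn(paste0("no data rows in: ", path))
  .type_faers(raw, schema)
}

.type_faers <- function(raw, schema) {
  blank_na <- function(x) { x <- trimws(x); x[x == ""] <- NA_character_; x }
  switch(schema,
    demo = {
      age_num <- suppressWarnings(as.numeric(raw$age))
      fac <- .age_code_factor[toupper(trimws(raw$age_cod))]
      age_years <- age_num * unname(fac)
      age_years[!is.na(age_years) & (age_years < 0 | age_years > 130)] <- NA_real_
      receipt <- parse_faers_date(raw$fda_dt)
      sex_raw <- toupper(trimws(raw$sex))
      occ <- .occp_map[toupper(trimws(raw$occp_cod))]
      occ[is.na(occ)] <- "missing"
      tibble(
        primary_id = trimws(raw$primaryid),
        case_id = trimws(raw$caseid),
        case_version = suppressWarnings(as.integer(raw$caseversion)),
        receipt_date = receipt,
        age_years = age_years,
        sex = ifelse(sex_raw == "M", "male",
                     ifelse(sex_raw == "F", "female", "unknown")),
        country = blank_na(raw$reporter_country),
        reporter_occupation = unname(occ),
        report_year = as.integer(format(receipt, "%Y"))
      )
    },
    drug = {
      role <- toupper(trimws(raw$role_cod))
      role[!role %in% c("PS", "SS", "C", "I")] <- NA_character_
      tibble(
        primary_id = trimws(raw$primaryid),
        drug_seq = suppressWarnings(as.integer(raw$drug_seq)),
        role = role,
        drug_name = raw$drugname,
        normalized_name = normalize_name(raw$drugname)
      )
    },
    reac = {
      out <- tibble(
        primary_id = trimws(raw$primaryid),
        pt = trimws(raw$pt),
        event_date = if ("event_dt" %in% names(raw))
          parse_faers_date(raw$event_dt) else as.Date(rep(NA, nrow(raw)))
      )
      out[out$pt != "", ]
    },
    indi = tibble(
      primary_id = trimws(raw$primaryid),
      drug_seq = suppressWarnings(as.integer(raw$indi_drug_seq)),
      indication = trimws(raw$indi_pt)
    ),
    outc = tibble(
      primary_id = trimws(raw$primaryid),
      outcome = trimws(raw$outc_cod)
    ),
    ther = tibble(
      primary_id = trimws(raw$primaryid),
      drug_seq = suppressWarnings(as.integer(raw$dsg_drug_seq)),
      start_date = parse_faers_date(raw$start_dt)
    ),
    deleted = unique(trimws(raw$caseid))
  )
}

.empty_typed <- function(schema) {
  if (schema == "deleted") return(character(0))
  .type_faers(as.data.frame(
    setNames(rep(list(character(0)), length(.faers_schemas[[schema]])),
             .faers_schemas[[schema]]), stringsAsFactors = FALSE), schema)
}

#' Concatenate per-quarter tables
#'
#' Quarterly extracts of one table kind are stacked by UNION-all semantics:
#' every row is preserved and the output row count is the sum of the inputs.
#' Deletion lists (character vectors) are consolidated by set union instead.
#'
#' @param tables a list of data frames sharing a schema, or of character
#'   vectors (deletion lists).
#' @return one combined table (or one character set).
#' @export
merge_quarters <- function(tables) {
  stopifnot(is.list(tables), length(tables) > 0L)
  if (all(vapply(tables, is.atomic, logical(1)))) {
    return(sort(unique(unlist(tables, use.names = FALSE))))
  }
  cols <- lapply(tables, names)
  ref <- cols[[1]]
  for (i in seq_along(cols)) {
    if (!setequal(cols[[i]], ref)) {
      diff <- union(setdiff(cols[[i]], ref), setdiff(ref, cols[[i]]))
      abort(paste0("schema mismatch between quarters; differing column(s): ",
                   paste(diff, collapse = ", ")))
    }
  }
  as_tibble(rbindlist(lapply(tables, function(t) t[, ref, drop = FALSE])))
}

#' Bundle the entity tables of a spontaneous-report dataset
#'
#' @param cases,drugs,events,therapies typed tibbles as returned by
#'   [read_faers_table()] with schemas `demo`, `drug`, `reac`, `ther`.
#' @return a `faers_dataset`: a list of the four tibbles.
#' @export
faers_dataset <- function(cases, drugs, events,
                          therapies = .empty_typed("ther")) {
  ds <- structure(list(cases = as_tibble(cases), drugs = as_tibble(drugs),
                       events = as_tibble(events),
                       therapies = as_tibble(therapies)),
                  class = "faers_dataset")
  ds
}

#' @export
print.faers_dataset <- function(x, ...) {
  cat("<faers_dataset>\n")
  cat(sprintf("  cases:     %d reports, %d distinct case ids\n",
              nrow(x$cases), length(unique(x$cases$case_id))))
  cat(sprintf("  drugs:     %d rows\n", nrow(x$drugs)))
  cat(sprintf("  events:    %d rows, %d distinct PTs\n",
              nrow(x$events), length(unique(x$events$pt))))
  cat(sprintf("  therapies: %d rows\n", nrow(x$therapies)))
  invisible(x)
}

#' Purge cases flagged on the quarterly deletion lists
#'
#' Removes every report whose case id appears on the consolidated deletion
#' list, then drops the orphaned drug/event/therapy rows. Ids absent from the
#' dataset are ignored.
#'
#' @param ds a [faers_dataset()].
#' @param deleted character vector of case ids to purge.
#' @return the purged `faers_dataset`.
#' @export
remove_deleted_cases <- function(ds, deleted) {
  stopifnot(inherits(ds, "faers_dataset"))
  keep <- !(ds$cases$case_id %in% deleted)
  .subset_cases(ds, ds$cases[keep, ])
}

.subset_cases <- function(ds, cases) {
  ids <- cases$primary_id
  faers_dataset(
    cases,
    ds$drugs[ds$drugs$primary_id %in% ids, ],
    ds$events[ds$events$primary_id %in% ids, ],
    ds$therapies[ds$therapies$primary_id %in% ids, ]
  )
}

#' Collapse repeat submissions of one case to a single report
#'
#' A case may be submitted several times with an incremented version. The
#' survivor per case id is the report with the highest `case_version`, ties
#' broken by latest `receipt_date`, then by largest `primary_id` — a
#' deterministic rule in the spirit of FDA deduplication guidance. Child
#' tables are purged to the surviving reports. Idempotent and independent of
#' input row order.
#'
#' @param ds a [faers_dataset()].
#' @return the deduplicated `faers_dataset`.
#' @export
deduplicate_cases <- function(ds) {
  stopifnot(inherits(ds, "faers_dataset"))
  cs <- ds$cases
  ord <- order(cs$case_id,
               -xtfrm(cs$case_version),
               -xtfrm(cs$receipt_date),
               -primary_id_rank(cs$primary_id))
  cs <- cs[ord, ]
  cs <- cs[!duplicated(cs$case_id), ]
  cs <- cs[order(primary_id_rank(cs$primary_id)), ]
  .subset_cases(ds, cs)
}

#' Flatten a dataset to one analysis table
#'
#' Demographics are INNER-joined to the drug rows (reports without any drug
#' row drop out), then reaction rows are LEFT-joined (reports with drugs but
#' no reactions stay, with missing `pt`). The result has one row per
#' (report, drug, event) combination.
#'
#' @param ds a deduplicated [faers_dataset()].
#' @return a tibble with the demographic, drug and event columns.
#' @export
join_case_level <- function(ds) {
  stopifnot(inherits(ds, "faers_dataset"))
  flat <- inner_join(ds$cases, ds$drugs, by = "primary_id",
                     relationship = "one-to-many")
  left_join(flat, ds$events, by = "primary_id",
            relationship = "many-to-many")
}

# logical: drug rows matching any search string (substring, case-insensitive),
# optionally restricted to role code(s)
match_target_rows <- function(drugs, names, role = "PS") {
  if (length(names) == 0L) abort("target drug name list must be nonempty")
  pat <- paste(vapply(normalize_name(names),
                      function(p) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p),
                      character(1)), collapse = "|")
  hit <- grepl(pat, drugs$normalized_name)
  if (!is.null(role)) hit <- hit & !is.na(drugs$role) & drugs$role %in% role
  hit
}

# primary ids of reports carrying a matching drug
match_target_ids <- function(drugs, names, role = "PS") {
  unique(drugs$primary_id[match_target_rows(drugs, names, role)])
}

#' Restrict a dataset to reports of a target drug
#'
#' Keeps reports having at least one drug row whose normalized name contains
#' any of the search strings (case-insensitive substring match), optionally
#' restricted to a role code (default `"PS"`, primary suspect, as
#' pharmacovigilance analyses usually require).
#'
#' @param ds a [faers_dataset()].
#' @param names nonempty character vector of search strings.
#' @param role role code(s) the matching drug row must carry (`"PS"`, `"SS"`,
#'   `"C"`, `"I"`), or `NULL` for any role.
#' @return the restricted `faers_dataset` (possibly empty).
#' @export
filter_target_drug <- function(ds, names, role = "PS") {
  stopifnot(inherits(ds, "faers_dataset"))
  ids <- match_target_ids(ds$drugs, names, role)
  .subset_cases(ds, ds$cases[ds$cases$primary_id %in% ids, ])
}

#' Check cleaned record counts against expectations
#'
#' Reports actual versus expected row counts per entity table. A mismatch is
#' flagged, never fatal: count validation is a diagnostic, not a gate.
#'
#' @param ds a [faers_dataset()].
#' @param expected `NULL` for an informational report; a single number
#'   (expected case count); or a named vector/list with any of `cases`,
#'   `drugs`, `events`, `therapies`.
#' @return a tibble with columns `table`, `actual`, `expected`, `delta`,
#'   `pass` (`NA` where no expectation was given).
#' @export
validate_counts <- function(ds, expected = NULL) {
  stopifnot(inherits(ds, "faers_dataset"))
  actual <- c(cases = nrow(ds$cases), drugs = nrow(ds$drugs),
              events = nrow(ds$events), therapies = nrow(ds$therapies))
  exp <- setNames(rep(NA_real_, 4L), names(actual))
  if (!is.null(expected)) {
    if (is.null(names(expected))) exp["cases"] <- as.numeric(expected[[1]])
    else exp[names(expected)] <- as.numeric(unlist(expected))
  }
  tibble(
    table = names(actual),
    actual = as.integer(actual),
    expected = unname(exp),
    delta = as.integer(actual) - unname(exp),
    pass = ifelse(is.na(exp), NA, actual == exp)
  )
}

#' Run the standard cleaning chain
#'
#' merge (done by the caller) -> deletion purge -> deduplication. The chain is
#' idempotent: applying it twice equals applying it once.
#'
#' @param ds a [faers_dataset()].
#' @param deleted consolidated deletion list (character vector), possibly empty.
#' @return the cleaned `faers_dataset`.
#' @export
clean_dataset <- function(ds, deleted = character(0)) {
  deduplicate_cases(remove_deleted_cases(ds, deleted))
}

#' Read and clean a directory of quarterly files
#'
#' Expects files named `<SCHEMA><tag>.txt` (e.g. `DEMO2024Q1.txt`) for
#' schemas DEMO, DRUG, REAC, THER and optionally DELETED lists.
#'
#' @param dir directory containing the quarterly files.
#' @return a cleaned [faers_dataset()].
#' @export
read_faers_dir <- function(dir) {
  read_kind <- function(prefix, schema) {
    files <- sort(list.files(dir, pattern = paste0("^", prefix, ".*\\.txt$"),
                             full.names = TRUE, ignore.case = TRUE))
    if (!length(files)) return(.empty_typed(schema))
    merge_quarters(lapply(files, read_faers_table, schema = schema))
  }
  ds <- faers_dataset(read_kind("DEMO", "demo"), read_kind("DRUG", "drug"),
                      read_kind("REAC", "reac"), read_kind("THER", "ther"))
  clean_dataset(ds, read_kind("DELETED", "deleted"))
}
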