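test_that("demo reader types rows, pads partial dates, maps bad fields to NA", {
  f <- write_dollar(c(
    "primaryid$caseid$caseversion$fda_dt$age$age_cod$sex$reporter_country$occp_cod",
    "1001$100$1$20240315$65$YR$M$US$MD",
    "1002$101$1$202402$XX$YR$F$CN$HP"))
  d <- read_faers_table(f, "demo")
  expect_equal(nrow(d), 2L)  # data lines minus header
  expect_equal(d$receipt_date, as.Date(c("2024-03-15", "2024-02-01")))
  expect_equal(d$age_years, c(65, NA))
  expect_equal(d$sex, c("male", "female"))
  expect_equal(d$reporter_occupation, c("physician", "health_professional"))
  expect_equal(d$report_year, c(2024L, 2024L))

  f2 <- write_dollar(c("primaryid$caseid$fda_dt", "1$1$20240101"))
  expect_error(read_faers_table(f2, "demo"), "caseversion")

  f3 <- write_dollar(character(0))
  expect_warning(d3 <- read_faers_table(f3, "demo"), "empty")
  expect_equal(nrow(d3), 0L)
})

test_that("age codes convert to years and out-of-range ages are missing", {
  f <- write_dollar(c(
    "primaryid$caseid$caseversion$fda_dt$age$age_cod$sex$reporter_country$occp_cod",
    "1$1$1$20240101$6$MON$M$US$MD",
    "2$2$1$20240101$7$DEC$F$US$MD",
    "3$3$1$20240101$500$YR$F$US$MD",
    "4$4$1$20240101$40$QQ$F$US$MD"))
  d <- read_faers_table(f, "demo")
  expect_equal(d$age_years, c(0.5, 70, NA, NA))
})

test_that("drug reader keeps the four role codes and normalizes names", {
  f <- write_dollar(c("primaryid$drug_seq$role_cod$drugname",
                      "1$1$PS$ Avycaz (ceftazidime/avibactam) ",
                      "1$2$C$meropenem", "2$1$XX$foo"))
  d <- read_faers_table(f, "drug")
  expect_equal(d$role, c("PS", "C", NA))
  expect_equal(d$normalized_name[1], "AVYCAZ (CEFTAZIDIME/AVIBACTAM)")
})

test_that("reaction reader trims PTs and drops empty ones", {
  f <- write_dollar(c("primaryid$pt$event_dt",
                      "1$ Septic shock $20240105", "1$$", "2$Death$"))
  d <- read_faers_table(f, "reac")
  expect_equal(d$pt, c("Septic shock", "Death"))
  expect_equal(d$event_date, as.Date(c("2024-01-05", NA)))
})

test_that("merge_quarters is additive with empty quarters neutral", {
  t1 <- mk_cases(as.character(1:10))
  t2 <- mk_cases(as.character(11:25))
  expect_equal(nrow(merge_quarters(list(t1, t2))), 25L)
  expect_equal(merge_quarters(list(t1, t1[0, ])), t1)
  expect_error(merge_quarters(list(t1, t1[, -2])), "case_id")
})

test_that("deletion lists consolidate by set union", {
  expect_equal(merge_quarters(list(c("1", "2"), c("2", "3"), "3")),
               c("1", "2", "3"))
})

test_that("deleted cases are purged with their child rows; unknown ids ignored", {
  ds <- faers_dataset(
    mk_cases(as.character(1:5)),
    mk_drugs(as.character(1:5), "DRUGA"),
    mk_events(c("1", "1", "2", "3"), c("X", "Y", "X", "Z")))
  out <- remove_deleted_cases(ds, c("1", "3"))
  expect_equal(nrow(out$cases), 3L)
  expect_equal(sort(unique(out$events$primary_id)), "2")
  expect_equal(remove_deleted_cases(ds, "999")$cases, ds$cases)
  # referential purge: every surviving child id resolves to a case
  expect_true(all(out$events$primary_id %in% out$cases$primary_id))
  expect_true(all(out$drugs$primary_id %in% out$cases$primary_id))
})

test_that("deduplication keeps max version, then latest receipt, then largest id", {
  cs <- rbind(
    mk_cases("11", case_id = "1", case_version = 1),
    mk_cases("12", case_id = "1", case_version = 2),
    mk_cases("21", case_id = "2", case_version = 1,
             receipt_date = as.Date("2023-01-01")),
    mk_cases("22", case_id = "2", case_version = 1,
             receipt_date = as.Date("2024-01-01")),
    mk_cases("31", case_id = "3", case_version = 1),
    mk_cases("39", case_id = "3", case_version = 1))
  ds <- faers_dataset(cs, mk_drugs(cs$primary_id, "D"),
                      mk_events(cs$primary_id, "X"))
  out <- deduplicate_cases(ds)
  expect_equal(sort(out$cases$primary_id), c("12", "22", "39"))
  # idempotent
  expect_equal(deduplicate_cases(out)$cases, out$cases)
})

test_that("cleaning is order-independent and conserves distinct case ids", {
  cs <- rbind(mk_cases(as.character(101:120), case_id = as.character(1:20)),
              mk_cases(as.character(201:210), case_id = as.character(1:10),
                       case_version = 2))
  ds <- faers_dataset(cs, mk_drugs(cs$primary_id, "D"),
                      mk_events(cs$primary_id, "X"))
  ref <- clean_dataset(ds, c("5", "6"))
  set.seed(42)
  for (i in 1:3) {
    perm <- ds
    perm$cases <- perm$cases[sample(nrow(perm$cases)), ]
    perm$events <- perm$events[sample(nrow(perm$events)), ]
    out <- clean_dataset(perm, c("5", "6"))
    expect_equal(out$cases, ref$cases)
  }
  expect_equal(nrow(ref$cases), 18L)  # 20 distinct ids minus 2 deleted
  # applying the chain twice equals once
  twice <- clean_dataset(ref, c("5", "6"))
  expect_equal(twice$cases, ref$cases)
})

test_that("case-level join is INNER on drugs and LEFT on events", {
  ds <- faers_dataset(
    mk_cases(c("1", "2", "3")),
    rbind(mk_drugs("1", c("A", "B"), drug_seq = 1:2),
          mk_drugs("2", "A")),                       # case 3 has no drugs
    rbind(mk_events("1", c("X", "Y", "Z")),
          mk_events("3", "X")))                      # case 2 has no events
  flat <- join_case_level(ds)
  expect_equal(sum(flat$case_id == "1"), 6L)  # 2 drugs x 3 PTs
  expect_equal(sum(flat$case_id == "2"), 1L)  # kept, pt missing
  expect_true(is.na(flat$pt[flat$case_id == "2"]))
  expect_false("3" %in% flat$case_id)         # events but no drugs -> absent
})

test_that("target-drug filter is case-insensitive substring with role gate", {
  ds <- faers_dataset(
    mk_cases(c("1", "2", "3")),
    rbind(mk_drugs("1", "AVYCAZ (ceftazidime/avibactam)", role = "PS"),
          mk_drugs("2", "avibactam", role = "C"),
          mk_drugs("3", "OTHERDRUG", role = "PS")),
    mk_events(c("1", "2", "3"), "X"))
  out <- filter_target_drug(ds, c("Avibactam", "Avycaz"), role = "PS")
  expect_equal(out$cases$primary_id, "1")
  out2 <- filter_target_drug(ds, c("Avibactam"), role = NULL)
  expect_equal(sort(out2$cases$primary_id), c("1", "2"))
  expect_error(filter_target_drug(ds, character(0)), "nonempty")
  expect_equal(nrow(filter_target_drug(ds, "NOSUCH")$cases), 0L)
})

test_that("count validation flags mismatches without aborting", {
  ds <- faers_dataset(mk_cases(as.character(1:1082)),
                      mk_drugs(as.character(1:1082), "D"),
                      mk_events(as.character(1:1082), "X"))
  v <- validate_counts(ds, 1082)
  expect_true(v$pass[v$table == "cases"])
  v2 <- validate_counts(ds, 1080)
  expect_false(v2$pass[v2$table == "cases"])
  expect_equal(v2$delta[v2$table == "cases"], 2L)
  v3 <- validate_counts(ds)
  expect_true(all(is.na(v3$pass)))
})
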