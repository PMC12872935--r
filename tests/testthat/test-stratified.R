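test_that("identical term distributions give null effects", {
  pairs <- tibble::tibble(
    case_id = as.character(1:200),
    pt = rep(c("X", "Y"), 100))
  s <- rep(c("A", "B"), each = 100)
  out <- compare_strata(pairs, s)
  expect_true(all(abs(out$effect_log2) < 1e-9))
  expect_true(all(out$p_value > 0.9))
  expect_false(any(out$significant))
})

test_that("swapping the strata negates the effect", {
  set.seed(21)
  pairs <- tibble::tibble(
    case_id = as.character(1:300),
    pt = sample(c("X", "Y", "Z"), 300, TRUE, c(0.5, 0.3, 0.2)))
  s <- sample(c("A", "B"), 300, TRUE)
  o1 <- compare_strata(pairs, s)
  o2 <- compare_strata(pairs, ifelse(s == "A", "B", "A"))
  expect_equal(o1$effect_log2, -o2$effect_log2[match(o1$term, o2$term)])
  expect_equal(o1$p_value, o2$p_value[match(o1$term, o2$term)],
               tolerance = 1e-12)
})

test_that("a term present in only one stratum gets a finite corrected effect", {
  pairs <- tibble::tibble(
    case_id = as.character(1:60),
    pt = c(rep("ONLY_A", 10), rep("BOTH", 50)))
  s <- c(rep("A", 10), rep(c("A", "B"), 25))
  out <- compare_strata(pairs, s)
  eff <- out$effect_log2[out$term == "ONLY_A"]
  expect_true(is.finite(eff))
  expect_gt(eff, 0)
  # hand check: strata are 35 vs 25 records; +0.5 on every cell gives
  # (10.5, 25.5; 0.5, 25.5) and log2 OR = log2(21)
  expect_equal(eff, log2(21), tolerance = 1e-9)
})

test_that("degenerate stratifiers error", {
  pairs <- tibble::tibble(case_id = "1", pt = "X")
  expect_error(compare_strata(pairs, "A"), "degenerate")
  yr <- tibble::tibble(case_id = as.character(1:10), pt = "X",
                       report_year = 2021L)
  expect_error(compare_periods(yr), "degenerate")  # all in one period
})

test_that("period comparison conserves counts and detects enrichment", {
  set.seed(22)
  n <- 600
  late <- rep(c(TRUE, FALSE), each = n / 2)
  # term E five-fold enriched in the late period; filler terms flat
  pt <- ifelse(runif(n) < ifelse(late, 0.25, 0.05), "E",
               sample(c("F1", "F2", "F3"), n, TRUE))
  pairs <- tibble::tibble(case_id = as.character(1:n), pt = pt,
                          report_year = ifelse(late, 2022L, 2017L))
  out <- compare_periods(pairs, cutoff_year = 2020)
  e <- out[out$term == "E", ]
  expect_gt(e$effect_log2, 0)
  expect_lt(e$p_value, 0.05)
  expect_true(e$significant)
  expect_equal(sum(out$n_in_A + out$n_in_B), n)
})

test_that("age and sex subgroups stratify cases as configured", {
  ids <- as.character(1:8)
  cs <- mk_cases(ids, age_years = c(20, 30, 70, 80, 25, 75, NA, 10),
                 sex = c("male", "male", "female", "female",
                         "male", "female", "unknown", "male"))
  ds <- faers_dataset(cs, mk_drugs(ids, "T", role = "PS"),
                      mk_events(rep(ids, 2), rep(c("X", "Y"), each = 8)))
  out_age <- compare_subgroups(ds, "age", min_count = 1)
  # 18-64 -> A (3 cases), 65+ -> B (3); missing and <18 excluded
  expect_equal(unique(out_age$n_in_A + out_age$n_other_A), 6L)
  out_sex <- compare_subgroups(ds, "sex", min_count = 1)
  expect_equal(unique(out_sex$n_in_A + out_sex$n_other_A), 8L)  # 4 male pairs
})

test_that("regimen comparison flags an injected SOC interaction", {
  set.seed(23)
  n <- 800
  combo <- rep(c(TRUE, FALSE), each = n / 2)
  ids <- as.character(seq_len(n))
  # respiratory-failure-like PT three-fold enriched under the comedication
  pt <- ifelse(runif(n) < ifelse(combo, 0.30, 0.10), "Respiratory failure",
               sample(paste0("PT_", 1:5), n, TRUE))
  drugs <- rbind(mk_drugs(ids, "TARGETX", role = "PS", drug_seq = 1L),
                 mk_drugs(ids[combo], "MEROPENEM", role = "C", drug_seq = 2L))
  ds <- faers_dataset(mk_cases(ids), drugs, mk_events(ids, pt))
  map <- tibble::tibble(pt = c("Respiratory failure", paste0("PT_", 1:5)),
                        soc = c("Respiratory disorders", rep("Other", 5)))
  out <- compare_regimens(ds, "MEROPENEM", map)
  resp <- out[out$term == "Respiratory disorders", ]
  expect_gt(resp$or, 1.5)
  expect_lt(resp$p_value, 0.05)
  expect_true(all(c("or", "or_lo", "or_hi") %in% names(out)))
  expect_true(resp$or_lo > 1)
})

test_that("an absent comedication warns and returns empty", {
  ds <- faers_dataset(mk_cases("1"), mk_drugs("1", "TARGETX"),
                      mk_events("1", "X"))
  map <- tibble::tibble(pt = "X", soc = "S")
  expect_warning(out <- compare_regimens(ds, "NOSUCHDRUG", map), "not found")
  expect_equal(nrow(out), 0L)
})

test_that("type-I error of the stratified test is near nominal under the null", {
  set.seed(24)
  n_terms <- 250
  n <- 6000
  pairs <- tibble::tibble(
    case_id = as.character(seq_len(n)),
    pt = sample(paste0("T", seq_len(n_terms)), n, TRUE))
  s <- sample(c("A", "B"), n, TRUE)
  out <- compare_strata(pairs, s)
  frac <- mean(out$p_value < 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.09)
})
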