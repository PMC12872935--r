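#' @title Synthetic FAERS-like report generator
#' @description Emits quarterly-style tables with known ground truth:
#'   configurable drug-event relative risks, demographic mix, Weibull onset
#'   times, duplicate case versions and deletion-list entries. Background
#'   (drug, PT) pairs are generated with event probabilities independent of
#'   drug exposure (relative risk 1) except for the listed signals, and in a
#'   rare-event regime (per-PT probability at most 2%) so the reporting odds
#'   ratio approximates the injected relative risk.
#' @name synthetic_faers
NULL

#' Configuration for the synthetic report generator
#'
#' Defaults emulate the cohort shape of a ceftazidime/avibactam
#' pharmacovigilance study: roughly 1,000 target-drug reports among ~10x as
#' many background reports, about 2.3 PTs per report, 63.4% missing age, a
#' male:female ratio near 1.8, onset times Weibull with shape 0.7 and scale
#' 8 days (median about 5 days), a strong injected signal on a
#' "Pathogen resistance"-like PT, and a meropenem-like comedication that
#' interacts with a respiratory-failure-like outcome for the regression
#' stage.
#'
#' @param n_cases total number of cases before duplication/deletion.
#' @param target_drug_share fraction of cases exposed to the target drug.
#' @param n_background_drugs size of the background drug dictionary.
#' @param n_pts number of background preferred terms.
#' @param n_socs number of system organ classes the PTs map onto.
#' @param pt_prob_range range of background per-case PT probabilities
#'   (evenly spaced across PTs; all at most 0.02, the rare-event regime).
#' @param signal_specs data frame with columns `pt`, `rr`, `baseline_prob`:
#'   target-drug relative risks to inject (empty for a global null).
#' @param comedication_specs named numeric vector: probability of each
#'   comedication given target-drug exposure.
#' @param sex_probs,age_band_probs,age_bands,age_missing_prob,country_probs,occupation_probs,year_probs
#'   demographic mixture components.
#' @param onset_shape,onset_scale Weibull shape/scale (days) for time to
#'   onset; onset day is the ceiling of the draw, minimum 1.
#' @param onset_date_missing_prob fraction of event rows with the event date
#'   blanked (real reports rarely carry complete timing).
#' @param duplicate_prob fraction of cases submitted twice with an
#'   incremented version.
#' @param deletion_prob fraction of case ids placed on the deletion list.
#' @param regression_spec `NULL`, or a list with `outcome_pt`,
#'   `or_exposure` (true adjusted odds ratio of the first comedication),
#'   `baseline_prob` (background and baseline target prevalence), and true
#'   log-odds effects `beta_age10`, `beta_male`, `beta_neph`; nephrotoxin
#'   co-reporting is generated correlated with the exposure so the crude and
#'   adjusted odds ratios differ.
#' @param seed integer seed; generation is fully reproducible (Mersenne
#'   Twister) and does not disturb the caller's RNG state.
#' @return a `generator_config` list, validated.
#' @export
generator_config <- function(
    n_cases = 10820,
    target_drug_share = 0.1,
    n_background_drugs = 40,
    n_pts = 200,
    n_socs = 24,
    pt_prob_range = c(0.002, 0.02),
    signal_specs = data.frame(pt = "Pathogen resistance", rr = 50,
                              baseline_prob = 0.002),
    comedication_specs = c(MEROPENEM = 0.30, VANCOMYCIN = 0.15),
    sex_probs = c(male = 0.474, female = 0.269, unknown = 0.257),
    age_missing_prob = 0.634,
    age_bands = c(0, 18, 60, 80, 95),
    age_band_probs = c(28, 164, 145, 59) / 396,
    country_probs = c(CN = 0.259, US = 0.120, FR = 0.092, IT = 0.075,
                      ES = 0.053, OTHER = 0.401),
    occupation_probs = c(MD = 0.497, HP = 0.182, CN = 0.153, PH = 0.132,
                         OT = 0.029, missing = 0.007),
    year_probs = setNames(c(13, 25, 65, 75, 137, 117, 124, 120, 162, 188, 56)
                          / 1082, 2015:2025),
    onset_shape = 0.7,
    onset_scale = 8,
    onset_date_missing_prob = 0.5,
    duplicate_prob = 0.05,
    deletion_prob = 0.02,
    regression_spec = list(outcome_pt = "Respiratory failure",
                           or_exposure = 3.26, baseline_prob = 0.05,
                           beta_age10 = 0.15, beta_male = 0.2,
                           beta_neph = 0.6),
    seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(target_drug_share, age_missing_prob, onset_date_missing_prob,
             duplicate_prob, deletion_prob, comedication_specs,
             sex_probs, age_band_probs, country_probs, occupation_probs,
             year_probs, pt_prob_range)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must be in [0, 1]")
  if (onset_shape <= 0 || onset_scale <= 0)
    abort("onset shape and scale must be positive")
  cfg$signal_specs <- as.data.frame(signal_specs)
  if (nrow(cfg$signal_specs) &&
      (!all(c("pt", "rr") %in% names(cfg$signal_specs))))
    abort("signal_specs needs columns pt and rr")
  if (nrow(cfg$signal_specs) && any(cfg$signal_specs$rr <= 0))
    abort("relative risks must be positive")
  if (is.null(cfg$signal_specs$baseline_prob) && nrow(cfg$signal_specs))
    cfg$signal_specs$baseline_prob <- 0.002
  if (nrow(cfg$signal_specs) && target_drug_share == 0)
    abort("signal_specs require a positive target_drug_share")
  structure(cfg, class = "generator_config")
}

# run fn with a private Mersenne-Twister stream; caller's RNG untouched
with_private_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  fn()
}

#' Generate a synthetic FAERS-like dataset
#'
#' @param config a [generator_config()].
#' @param out_dir optional directory; when given, the raw "$"-delimited
#'   tables (`DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt`, `DELETED.txt`),
#'   the PT-to-SOC map (`pt_soc_map.tsv`) and `ground_truth.json` are written
#'   there, byte-identical for a fixed seed.
#' @return a list with `dataset` (a raw [faers_dataset()], duplicates
#'   included), `deleted` (character case-id set), `pt_soc` (tibble `pt`,
#'   `soc`), `ground_truth`, and `config`. Files written to `out_dir`
#'   round-trip through [read_faers_table()] to exactly this dataset.
#' @export
generate_faers <- function(config = generator_config(), out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  res <- with_private_rng(config$seed, function() .generate_impl(config))
  if (!is.null(out_dir)) write_faers_tables(res, out_dir)
  res
}

.generate_impl <- function(cfg) {
  n <- cfg$n_cases
  case_id <- as.character(10000000 + seq_len(n))
  primary_id <- paste0(case_id, "1")
  target <- runif(n) < cfg$target_drug_share
  if (any(target) == FALSE && nrow(cfg$signal_specs))
    abort("no target-drug cases drawn; infeasible configuration")

  sex <- sample(names(cfg$sex_probs), n, TRUE, cfg$sex_probs)
  age <- rep(NA_real_, n)
  has_age <- runif(n) >= cfg$age_missing_prob
  if (any(has_age)) {
    band <- sample(seq_along(cfg$age_band_probs), sum(has_age), TRUE,
                   cfg$age_band_probs)
    lo <- cfg$age_bands[band]; hi <- cfg$age_bands[band + 1L]
    age[has_age] <- round(lo + runif(sum(has_age)) * (hi - lo), 1)
  }
  country <- sample(names(cfg$country_probs), n, TRUE, cfg$country_probs)
  occp <- sample(names(cfg$occupation_probs), n, TRUE, cfg$occupation_probs)
  year <- as.integer(sample(names(cfg$year_probs), n, TRUE, cfg$year_probs))
  # reports in the final year fall in its first quarter, matching a
  # 2015Q1..2025Q1 extraction window
  max_doy <- ifelse(year == max(as.integer(names(cfg$year_probs))), 90L, 365L)
  receipt <- as.Date(paste0(year, "-01-01")) + floor(runif(n) * max_doy)

  # ---- drugs -----------------------------------------------------------
  target_names <- c("AVYCAZ (CEFTAZIDIME/AVIBACTAM)", "ZAVICEFTA",
                    "CEFTAZIDIME-AVIBACTAM")
  bg_names <- sprintf("BGDRUG_%02d", seq_len(cfg$n_background_drugs))
  drug_rows <- list()
  # primary-suspect row per case
  ps_name <- ifelse(target,
                    sample(target_names, n, TRUE),
                    sample(bg_names, n, TRUE))
  drug_rows$ps <- data.frame(idx = seq_len(n), drug_seq = 1L, role_cod = "PS",
                             drugname = ps_name)
  # comedications for target cases (SS/C roles)
  seq_next <- rep(2L, n)
  exposure <- setNames(vector("list", length(cfg$comedication_specs)),
                       names(cfg$comedication_specs))
  for (cm in names(cfg$comedication_specs)) {
    p <- cfg$comedication_specs[[cm]]
    has <- target & runif(n) < p
    exposure[[cm]] <- has
    if (any(has)) {
      drug_rows[[cm]] <- data.frame(
        idx = which(has), drug_seq = seq_next[has],
        role_cod = sample(c("SS", "C"), sum(has), TRUE, c(0.5, 0.5)),
        drugname = cm)
      seq_next[has] <- seq_next[has] + 1L
    }
  }
  # one extra background concomitant for a random half of all cases
  extra <- runif(n) < 0.5
  drug_rows$extra <- data.frame(
    idx = which(extra), drug_seq = seq_next[extra], role_cod = "C",
    drugname = sample(bg_names, sum(extra), TRUE))
  drug <- do.call(rbind, drug_rows)

  # nephrotoxin exposure correlated with the regression exposure drug
  comeds <- names(cfg$comedication_specs)
  expo_drug <- if (length(comeds)) comeds[[1]] else NULL
  neph <- if ("VANCOMYCIN" %in% comeds) exposure[["VANCOMYCIN"]] else rep(FALSE, n)
  if (!is.null(cfg$regression_spec) && !is.null(expo_drug) &&
      "VANCOMYCIN" %in% comeds) {
    # re-draw vancomycin with exposure-dependent probability (confounding)
    p_neph <- ifelse(exposure[[expo_drug]], 0.30, 0.12)
    neph <- target & runif(n) < p_neph
    exposure[["VANCOMYCIN"]] <- neph
    drug <- drug[!(drug$drugname == "VANCOMYCIN"), ]
    if (any(neph)) {
      drug <- rbind(drug, data.frame(
        idx = which(neph), drug_seq = 90L, role_cod = "C",
        drugname = "VANCOMYCIN"))
    }
  }

  # ---- events ----------------------------------------------------------
  pt_names <- sprintf("PT_%03d", seq_len(cfg$n_pts))
  sig <- cfg$signal_specs
  reg <- cfg$regression_spec
  reserved <- c(if (nrow(sig)) sig$pt, if (!is.null(reg)) reg$outcome_pt)
  pt_names <- c(setdiff(reserved, pt_names),
                pt_names[seq_len(cfg$n_pts - length(reserved))])
  base_p <- setNames(seq(cfg$pt_prob_range[1], cfg$pt_prob_range[2],
                         length.out = length(pt_names)), pt_names)
  if (nrow(sig)) base_p[sig$pt] <- sig$baseline_prob
  if (!is.null(reg)) base_p[reg$outcome_pt] <- reg$baseline_prob

  ev_idx <- integer(0); ev_pt <- character(0)
  for (pt in pt_names) {
    p <- rep(base_p[[pt]], n)
    if (nrow(sig) && pt %in% sig$pt) {
      rr <- sig$rr[match(pt, sig$pt)]
      p[target] <- pmin(rr * p[target], 0.95)
    }
    if (!is.null(reg) && pt == reg$outcome_pt) {
      lp <- stats::qlogis(reg$baseline_prob) +
        log(reg$or_exposure) * (if (is.null(expo_drug)) 0 else exposure[[expo_drug]]) +
        reg$beta_age10 * (ifelse(is.na(age), 0, (age - 55) / 10)) +
        reg$beta_male * (sex == "male") +
        reg$beta_neph * neph
      p[target] <- plogis(lp)[target]
    }
    hit <- which(runif(n) < p)
    ev_idx <- c(ev_idx, hit); ev_pt <- c(ev_pt, rep(pt, length(hit)))
  }
  ord <- order(ev_idx, ev_pt)
  ev_idx <- ev_idx[ord]; ev_pt <- ev_pt[ord]

  # therapy start 60 days before receipt; event date = start + onset - 1,
  # with onset day = ceiling of a Weibull draw, floored at 1
  start <- receipt - 60L
  onset <- pmax(1, ceiling(rweibull(length(ev_idx), cfg$onset_shape,
                                    cfg$onset_scale)))
  ev_date <- start[ev_idx] + (onset - 1)
  ev_date[runif(length(ev_idx)) < cfg$onset_date_missing_prob] <- NA

  # ---- duplicates and deletions ---------------------------------------
  dup <- which(runif(n) < cfg$duplicate_prob)
  del_ids <- case_id[runif(n) < cfg$deletion_prob]

  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y%m%d"))
  demo_raw <- data.frame(
    primaryid = primary_id, caseid = case_id, caseversion = "1",
    fda_dt = fmt_date(receipt),
    age = ifelse(is.na(age), "", format(age, trim = TRUE)),
    age_cod = ifelse(is.na(age), "", "YR"),
    sex = c(male = "M", female = "F", unknown = "")[sex],
    reporter_country = country,
    occp_cod = ifelse(occp == "missing", "", occp),
    stringsAsFactors = FALSE)
  drug_raw <- data.frame(
    primaryid = primary_id[drug$idx], drug_seq = as.character(drug$drug_seq),
    role_cod = drug$role_cod, drugname = drug$drugname,
    stringsAsFactors = FALSE)
  reac_raw <- data.frame(
    primaryid = primary_id[ev_idx], pt = ev_pt, event_dt = fmt_date(ev_date),
    stringsAsFactors = FALSE)
  ther_raw <- data.frame(
    primaryid = primary_id, dsg_drug_seq = "1", start_dt = fmt_date(start),
    stringsAsFactors = FALSE)

  if (length(dup)) {
    mk2 <- function(df, idx_col = "primaryid") {
      sub <- df[df[[idx_col]] %in% primary_id[dup], , drop = FALSE]
      sub[[idx_col]] <- paste0(substr(sub[[idx_col]], 1,
                                      nchar(sub[[idx_col]]) - 1L), "2")
      sub
    }
    d2 <- mk2(demo_raw); d2$caseversion <- "2"
    d2$fda_dt <- fmt_date(receipt[dup] + 30L)
    demo_raw <- rbind(demo_raw, d2)
    drug_raw <- rbind(drug_raw, mk2(drug_raw))
    reac_raw <- rbind(reac_raw, mk2(reac_raw))
    ther_raw <- rbind(ther_raw, mk2(ther_raw))
  }

  pt_soc <- tibble(
    pt = pt_names,
    soc = sprintf("SOC_%02d", ((seq_along(pt_names) - 1L) %% cfg$n_socs) + 1L))

  ds <- faers_dataset(.type_faers(demo_raw, "demo"),
                      .type_faers(drug_raw, "drug"),
                      .type_faers(reac_raw, "reac"),
                      .type_faers(ther_raw, "ther"))
  gt <- list(
    signal_specs = cfg$signal_specs,
    background_rr = 1,
    onset = list(shape = cfg$onset_shape, scale = cfg$onset_scale),
    regression = cfg$regression_spec,
    target_names = target_names,
    n_target_cases = sum(target),
    duplicated_case_ids = case_id[dup],
    deleted_case_ids = del_ids,
    pt_probs = as.list(base_p))
  list(dataset = ds, deleted = sort(unique(del_ids)), pt_soc = pt_soc,
       ground_truth = gt, config = cfg,
       raw = list(demo = demo_raw, drug = drug_raw, reac = reac_raw,
                  ther = ther_raw))
}

#' Write a generated dataset as "$"-delimited quarterly-style files
#'
#' @param gen result of [generate_faers()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_faers_tables <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) fwrite(df, file.path(dir, file), sep = "$",
                                  quote = FALSE, col.names = TRUE)
  wr(gen$raw$demo, "DEMO.txt"); wr(gen$raw$drug, "DRUG.txt")
  wr(gen$raw$reac, "REAC.txt"); wr(gen$raw$ther, "THER.txt")
  fwrite(data.frame(caseid = gen$deleted), file.path(dir, "DELETED.txt"),
         sep = "$", quote = FALSE, col.names = TRUE)
  fwrite(gen$pt_soc, file.path(dir, "pt_soc_map.tsv"), sep = "\t",
         quote = FALSE, col.names = TRUE)
  jsonlite::write_json(gen$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' All-null scenario: no injected signals
#'
#' Every (drug, PT) pair has relative risk 1; used for type-I-error
#' calibration of the screening thresholds.
#'
#' @param seed integer seed.
#' @param n_cases number of cases (default 20000).
#' @param n_pts number of PTs (default 200).
#' @return as [generate_faers()].
#' @export
scenario_null <- function(seed, n_cases = 20000, n_pts = 200) {
  generate_faers(generator_config(
    n_cases = n_cases, n_pts = n_pts,
    signal_specs = data.frame(pt = character(0), rr = numeric(0),
                              baseline_prob = numeric(0)),
    regression_spec = NULL,
    duplicate_prob = 0, deletion_prob = 0, seed = seed))
}

#' Reference-cohort scenario
#'
#' Emulates the shape of a published ceftazidime/avibactam cohort: roughly
#' 1,000 target-drug cases, ~2.3 PTs per case, 63.4% missing age,
#' male:female about 1.8, and a relative-risk-50 signal on a
#' "Pathogen resistance"-like PT — the default configuration.
#'
#' @param seed integer seed.
#' @return as [generate_faers()].
#' @export
scenario_paperlike <- function(seed) {
  generate_faers(generator_config(seed = seed))
}

#' Simulate case-level records for adjusted-odds-ratio recovery
#'
#' A standalone logistic scenario with a confounder correlated with the
#' exposure: age (per 10 years, centred) raises both the exposure odds and
#' the outcome odds, so the crude odds ratio is biased away from the true
#' exposure effect and only the adjusted model recovers it.
#'
#' @param n number of records.
#' @param or_exposure true exposure odds ratio (default 3).
#' @param seed integer seed.
#' @return a tibble with `outcome`, `exposure`, `age10`, `sex`, `year`,
#'   `nephrotoxin` columns, ready for [fit_logistic()].
#' @export
simulate_regression_records <- function(n = 5000, or_exposure = 3, seed = 1) {
  with_private_rng(seed, function() {
    age10 <- rnorm(n, 0, 1.5)
    sex <- sample(c("male", "female"), n, TRUE)
    year <- sample(-5:5, n, TRUE)  # reporting-year trend, centred
    neph <- runif(n) < 0.2
    exposure <- runif(n) < plogis(-1 + 0.6 * age10)
    lp <- -2.2 + log(or_exposure) * exposure + 0.35 * age10 +
      0.2 * (sex == "male") + 0.3 * neph
    tibble(outcome = as.integer(runif(n) < plogis(lp)),
           exposure = as.integer(exposure), age10 = age10, sex = sex,
           year = year, nephrotoxin = as.integer(neph))
  })
}
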