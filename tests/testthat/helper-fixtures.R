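# in-code fixtures: tiny typed tables and "$"-dialect files

write_dollar <- function(lines, file = tempfile(fileext = ".txt")) {
  writeLines(lines, file)
  file
}

mk_cases <- function(primary_id, case_id = primary_id,
                     case_version = 1L,
                     receipt_date = as.Date("2024-01-01"),
                     sex = "male", age_years = 50, country = "US",
                     reporter_occupation = "physician") {
  n <- length(primary_id)
  tibble::tibble(
    primary_id = as.character(primary_id),
    case_id = rep_len(as.character(case_id), n),
    case_version = rep_len(as.integer(case_version), n),
    receipt_date = rep_len(as.Date(receipt_date), n),
    age_years = rep_len(as.numeric(age_years), n),
    sex = rep_len(sex, n),
    country = rep_len(country, n),
    reporter_occupation = rep_len(reporter_occupation, n),
    report_year = as.integer(format(rep_len(as.Date(receipt_date), n), "%Y")))
}

mk_drugs <- function(primary_id, drug_name, role = "PS", drug_seq = 1L) {
  n <- max(length(primary_id), length(drug_name))
  tibble::tibble(
    primary_id = rep_len(as.character(primary_id), n),
    drug_seq = rep_len(as.integer(drug_seq), n),
    role = rep_len(role, n),
    drug_name = rep_len(drug_name, n),
    normalized_name = toupper(trimws(rep_len(drug_name, n))))
}

mk_events <- function(primary_id, pt, event_date = as.Date(NA)) {
  n <- max(length(primary_id), length(pt))
  tibble::tibble(
    primary_id = rep_len(as.character(primary_id), n),
    pt = rep_len(pt, n),
    event_date = rep_len(as.Date(event_date), n))
}

mk_ther <- function(primary_id, start_date, drug_seq = 1L) {
  n <- max(length(primary_id), length(start_date))
  tibble::tibble(
    primary_id = rep_len(as.character(primary_id), n),
    drug_seq = rep_len(as.integer(drug_seq), n),
    start_date = rep_len(as.Date(start_date), n))
}

# independently coded fourfold-table arithmetic (scalar, formulas written out)
oracle_stats <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  z <- qnorm(0.975)
  s <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror_ <- (a * d) / (b * c)
  prr_ <- (a * (c + d)) / (c * (a + b))
  chi2_ <- ((a * d - b * c)^2 * N) / ((a + b) * (c + d) * (a + c) * (b + d))
  ebgm_ <- (a * N) / ((a + c) * (a + b))
  ic_ <- log(ebgm_, base = 2)
  sd_ic <- s / log(2)
  list(ror = ror_, ror_lo = ror_ * exp(-z * s), ror_hi = ror_ * exp(z * s),
       prr = prr_, chi2 = chi2_,
       ic = ic_, ic025 = ic_ - 2 * sd_ic, ic975 = ic_ + 2 * sd_ic,
       ebgm = ebgm_, ebgm05 = ebgm_ * exp(-z * s),
       ebgm95 = ebgm_ * exp(z * s))
}

# brute-force (case, PT) pair counting by a double loop over cases and terms
oracle_pt_tables <- function(pairs) {
  pairs <- unique(pairs[, c("case_id", "pt", "target")])
  terms <- sort(unique(pairs$pt))
  tot_t <- sum(pairs$target)
  tot_o <- sum(!pairs$target)
  out <- data.frame(term = terms, a = 0L, b = 0L, c = 0L, d = 0L)
  for (i in seq_along(terms)) {
    a <- 0L; cc <- 0L
    for (j in seq_len(nrow(pairs))) {
      if (pairs$pt[j] == terms[i]) {
        if (pairs$target[j]) a <- a + 1L else cc <- cc + 1L
      }
    }
    out$a[i] <- a; out$c[i] <- cc
    out$b[i] <- tot_t - a; out$d[i] <- tot_o - cc
  }
  out$N <- tot_t + tot_o
  out
}
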