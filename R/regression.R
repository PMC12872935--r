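#' @title Covariate-adjusted reporting odds ratios
#' @description A multivariable logistic model of one outcome PT on a
#'   comedication exposure plus covariates (age per 10 years, sex,
#'   reporting-year trend, nephrotoxin co-reporting) turns the crude
#'   reporting odds ratio into an adjusted one. The fitter is
#'   Newton-Raphson / IRLS with Wald standard errors from the inverse
#'   observed information; with no covariates it reproduces the closed-form
#'   contingency odds ratio exactly.
#' @name regression
NULL

#' Build case-level regression records
#'
#' One record per (deduplicated) case of a target-drug dataset: binary
#' outcome (the outcome PT present among the case's events), binary exposure
#' (comedication present in any role), and covariates.
#'
#' @param ds a cleaned, target-filtered [faers_dataset()].
#' @param outcome_pt the outcome preferred term (exact, case-folded match).
#' @param exposure_drug comedication search string.
#' @param nephrotoxin_list drug search strings counted as nephrotoxins
#'   (default vancomycin plus common aminoglycosides).
#' @param age_policy `"complete"` drops cases with missing age;
#'   `"indicator"` keeps them with age 0 (centred) plus a missingness
#'   indicator column.
#' @return a tibble `outcome`, `exposure`, `age10` (centred, per 10 years),
#'   `sex`, `year` (centred), `nephrotoxin`, and `age_missing` under the
#'   indicator policy; attribute `n_dropped_age` records complete-case
#'   losses.
#' @export
build_records <- function(ds, outcome_pt, exposure_drug,
                          nephrotoxin_list = c("VANCOMYCIN", "GENTAMICIN",
                                               "TOBRAMYCIN", "AMIKACIN"),
                          age_policy = c("complete", "indicator")) {
  age_policy <- match.arg(age_policy)
  stopifnot(inherits(ds, "faers_dataset"))
  if (nrow(ds$cases) == 0L) abort("empty dataset")
  expo_ids <- match_target_ids(ds$drugs, exposure_drug, role = NULL)
  neph_ids <- match_target_ids(ds$drugs, nephrotoxin_list, role = NULL)
  out_ids <- unique(ds$events$primary_id[
    toupper(trimws(ds$events$pt)) == toupper(trimws(outcome_pt))])
  cs <- ds$cases
  rec <- tibble(
    outcome = as.integer(cs$primary_id %in% out_ids),
    exposure = as.integer(cs$primary_id %in% expo_ids),
    age10 = (cs$age_years - 55) / 10,
    sex = cs$sex,
    year = cs$report_year - stats::median(cs$report_year, na.rm = TRUE),
    nephrotoxin = as.integer(cs$primary_id %in% neph_ids))
  n_dropped <- 0L
  if (age_policy == "complete") {
    n_dropped <- sum(is.na(rec$age10))
    rec <- rec[!is.na(rec$age10), ]
  } else {
    rec$age_missing <- as.integer(is.na(rec$age10))
    rec$age10[is.na(rec$age10)] <- 0
  }
  rec <- rec[!is.na(rec$year), ]
  if (length(unique(rec$outcome)) < 2L)
    abort("outcome prevalence is 0 or 1; the model is undefined")
  attr(rec, "n_dropped_age") <- n_dropped
  rec
}

# reference-coded design matrix from a records tibble
.design_matrix <- function(records, covariates) {
  X <- cbind(`(Intercept)` = 1, exposure = records$exposure)
  if ("age10" %in% covariates && "age10" %in% names(records))
    X <- cbind(X, age10 = records$age10)
  if ("age_missing" %in% names(records))
    X <- cbind(X, age_missing = records$age_missing)
  if ("sex" %in% covariates && "sex" %in% names(records)) {
    # reference: female; unknown gets its own indicator when present
    X <- cbind(X, sex_male = as.integer(records$sex == "male"))
    if (any(records$sex == "unknown"))
      X <- cbind(X, sex_unknown = as.integer(records$sex == "unknown"))
  }
  if ("year" %in% covariates && "year" %in% names(records))
    X <- cbind(X, year = records$year)
  if ("nephrotoxin" %in% covariates && "nephrotoxin" %in% names(records))
    X <- cbind(X, nephrotoxin = records$nephrotoxin)
  X
}

#' Fit a logistic regression by Newton-Raphson / IRLS
#'
#' Convergence when the maximum absolute score drops below 1e-8 or the
#' maximum coefficient change below 1e-10, capped at 100 iterations; step
#' halving keeps the log-likelihood nondecreasing. Quasi-separation is
#' reported (with a warning) when any coefficient exceeds 15 on the logit
#' scale. A rank-deficient design is an error naming the collinear column.
#'
#' @param records a records tibble from [build_records()] (or any tibble
#'   with an `outcome` column and the covariate columns), or a numeric
#'   outcome vector when `X` is given.
#' @param covariates which covariates to adjust for (default all of age,
#'   sex, year, nephrotoxin that are present); `character(0)` fits the
#'   exposure-only (crude) model.
#' @param X optional prebuilt design matrix (including intercept) overriding
#'   `covariates`.
#' @return a `logistic_fit`: tibble `coefficients` (`term`, `estimate`,
#'   `se`, `or`, `or_lo`, `or_hi`, `z`, `p_value`), plus `n_used`,
#'   `loglik`, `iterations`, `converged`, `separation_detected`.
#' @export
fit_logistic <- function(records, covariates = c("age10", "sex", "year",
                                                 "nephrotoxin"),
                         X = NULL) {
  if (is.null(X)) {
    y <- records$outcome
    X <- .design_matrix(records, covariates)
  } else {
    y <- if (is.numeric(records)) records else records$outcome
    X <- as.matrix(X)
  }
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), sum(y) > 0, sum(1 - y) > 0)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  p <- ncol(X)
  beta <- rep(0, p)
  ll <- function(b) {
    eta <- drop(X %*% b)
    # numerically stable log(1 + e^eta)
    sum(y * eta - ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30)))))
  }
  ll_old <- ll(beta)
  converged <- FALSE
  it <- 0L
  while (it < 100L) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(X, y - mu))
    W <- mu * (1 - mu)
    info <- crossprod(X * W, X)
    step <- solve(info, score)
    # step halving: never accept a likelihood decrease
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- ll(cand)
      if (ll_new >= ll_old - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    ll_old <- ll_new
    if (max(abs(score)) < 1e-8 || delta < 1e-10) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  info <- crossprod(X * (mu * (1 - mu)), X)
  se <- sqrt(diag(solve(info)))
  separation <- any(abs(beta) > 15)
  if (separation) warn("possible (quasi-)separation: |coefficient| > 15")
  z <- beta / se
  coefs <- tibble(
    term = colnames(X), estimate = unname(beta), se = unname(se),
    or = exp(unname(beta)),
    or_lo = exp(unname(beta) - .z95 * unname(se)),
    or_hi = exp(unname(beta) + .z95 * unname(se)),
    z = unname(z), p_value = 2 * pnorm(-abs(unname(z))))
  structure(list(coefficients = coefs, n_used = length(y),
                 loglik = ll_old, iterations = it, converged = converged,
                 separation_detected = separation),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n=%d loglik=%.2f iters=%d%s%s\n", x$n_used,
              x$loglik, x$iterations,
              if (x$converged) "" else " NOT CONVERGED",
              if (x$separation_detected) " [separation?]" else ""))
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Adjusted reporting odds ratio for one outcome/exposure pair
#'
#' Convenience wrapper: [build_records()] then [fit_logistic()], returning
#' the exposure row (the adjusted OR) together with the full fit.
#'
#' @inheritParams build_records
#' @param covariates passed to [fit_logistic()].
#' @return list `aor` (one-row tibble for the exposure term) and `fit`.
#' @export
adjusted_ror <- function(ds, outcome_pt, exposure_drug,
                         nephrotoxin_list = c("VANCOMYCIN", "GENTAMICIN",
                                              "TOBRAMYCIN", "AMIKACIN"),
                         age_policy = "complete",
                         covariates = c("age10", "sex", "year",
                                        "nephrotoxin")) {
  rec <- build_records(ds, outcome_pt, exposure_drug, nephrotoxin_list,
                       age_policy)
  fit <- fit_logistic(rec, covariates)
  list(aor = fit$coefficients[fit$coefficients$term == "exposure", ],
       fit = fit)
}
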