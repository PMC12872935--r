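#' @title Disproportionality statistics and signal thresholds
#' @description Four algorithms over the fourfold table (a, b, c, d;
#'   N = a+b+c+d):
#'
#'   * ROR = ad/(bc), log-normal 95% CI with
#'     se = sqrt(1/a + 1/b + 1/c + 1/d), z = 1.96.
#'   * PRR = a(c+d)/(c(a+b)) with the uncorrected chi-square
#'     (ad-bc)^2 N / ((a+b)(c+d)(a+c)(b+d)); a log-scale PRR CI is also
#'     reported but does not gate the flag.
#'   * Information component IC = log2(aN / ((a+b)(a+c))), interval
#'     IC +/- 2 sd(IC); by default sd(IC) is the delta-method value
#'     (1/ln 2) sqrt(1/a + 1/b + 1/c + 1/d); `ic_method = "posterior"`
#'     selects the classic BCPNN posterior variance instead.
#'   * EBGM = aN/((a+c)(a+b)) with the same log-normal interval as the ROR —
#'     a closed-form observed/expected ratio, not a shrinkage posterior.
#'
#'   Signal thresholds: ROR lower CI > 1 and N >= 3; PRR >= 2, chi2 >= 4 and
#'   N >= 3; IC025 > 0; EBGM05 > 2. A term is a combined signal when all
#'   four fire. Here N in the threshold sense is the report count `a`.
#'
#'   Zero cells make a statistic non-evaluable by default (its flag is
#'   false); `zero_correction = TRUE` applies the Haldane-Anscombe +0.5 to
#'   every cell instead.
#' @name disproportionality
NULL

.z95 <- 1.959963984540054  # qnorm(0.975)

.cell_se <- function(a, b, c, d) sqrt(1 / a + 1 / b + 1 / c + 1 / d)

# cell counts as doubles: products like (a+b)(c+d)(a+c)(b+d) overflow integers
.as_cells <- function(a, b, c, d)
  list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
       d = as.numeric(d))

#' Reporting odds ratio with log-normal 95% CI
#'
#' @param a,b,c,d fourfold cell counts (vectorized).
#' @return tibble `ror`, `ror_lo`, `ror_hi`; `NA` (non-evaluable) when any
#'   cell needed by the formula is zero.
#' @export
ror <- function(a, b, c, d) {
  ce <- .as_cells(a, b, c, d); a <- ce$a; b <- ce$b; c <- ce$c; d <- ce$d
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  est <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, .cell_se(a, b, c, d), NA_real_)
  tibble(ror = est, ror_lo = exp(log(est) - .z95 * se),
         ror_hi = exp(log(est) + .z95 * se))
}

#' Proportional reporting ratio with uncorrected chi-square
#'
#' @inheritParams ror
#' @return tibble `prr`, `chi2`, `prr_lo`, `prr_hi` (log-scale CI with
#'   se = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)), reported but not used for
#'   flagging); `NA` when a denominator is zero.
#' @export
prr <- function(a, b, c, d) {
  ce <- .as_cells(a, b, c, d); a <- ce$a; b <- ce$b; c <- ce$c; d <- ce$d
  N <- a + b + c + d
  ok <- c > 0 & (a + b) > 0 & (c + d) > 0 & a > 0
  est <- ifelse(ok, a * (c + d) / (c * (a + b)), NA_real_)
  chi2 <- ifelse((a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0,
                 (a * d - b * c)^2 * N /
                   ((a + b) * (c + d) * (a + c) * (b + d)), NA_real_)
  se <- ifelse(ok, sqrt(pmax(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d), 0)),
               NA_real_)
  tibble(prr = est, chi2 = chi2,
         prr_lo = exp(log(est) - .z95 * se),
         prr_hi = exp(log(est) + .z95 * se))
}

#' BCPNN information component
#'
#' @inheritParams ror
#' @param method `"delta"` (default): sd(IC) by the delta method on the log
#'   scale, (1/ln 2) sqrt(1/a + 1/b + 1/c + 1/d) — consistent with the same
#'   variance being used for the ROR and EBGM intervals. `"posterior"`: the
#'   classic BCPNN closed-form posterior variance of IC.
#' @return tibble `ic`, `ic025`, `ic975` (bits); `NA` when `a = 0`.
#' @export
information_component <- function(a, b, c, d, method = c("delta", "posterior")) {
  method <- match.arg(method)
  ce <- .as_cells(a, b, c, d); a <- ce$a; b <- ce$b; c <- ce$c; d <- ce$d
  N <- a + b + c + d
  ok <- a > 0 & (a + b) > 0 & (a + c) > 0
  ic <- ifelse(ok, log2(a * N / ((a + b) * (a + c))), NA_real_)
  if (method == "delta") {
    ok2 <- ok & b > 0 & c > 0 & d > 0
    sd_ic <- ifelse(ok2, .cell_se(a, b, c, d) / log(2), NA_real_)
  } else {
    # classic BCPNN closed-form posterior moments (unit-information prior):
    # E(IC) and V(IC) from the beta-posterior expansion of Bate's network
    ic <- log2((a + 1) * (N + 2) / ((a + b + 1) * (a + c + 1)))
    v <- ((N - a + 1) / ((a + 1) * (N + 3)) +
            (N - (a + b) + 1) / ((a + b + 1) * (N + 3)) +
            (N - (a + c) + 1) / ((a + c + 1) * (N + 3))) / (log(2)^2)
    sd_ic <- sqrt(v)
  }
  tibble(ic = ic, ic025 = ic - 2 * sd_ic, ic975 = ic + 2 * sd_ic)
}

#' Closed-form EBGM with log-normal 95% interval
#'
#' The observed/expected reporting ratio a N / ((a+c)(a+b)) with the same
#' log-normal interval construction as the ROR. This is a deliberate
#' closed-form simplification, not a gamma-Poisson shrinkage posterior.
#'
#' @inheritParams ror
#' @return tibble `ebgm`, `ebgm05`, `ebgm95`; `NA` when non-evaluable.
#' @export
ebgm <- function(a, b, c, d) {
  ce <- .as_cells(a, b, c, d); a <- ce$a; b <- ce$b; c <- ce$c; d <- ce$d
  N <- a + b + c + d
  ok <- a > 0 & (a + b) > 0 & (a + c) > 0
  est <- ifelse(ok, a * N / ((a + c) * (a + b)), NA_real_)
  ok2 <- ok & b > 0 & c > 0 & d > 0
  se <- ifelse(ok2, .cell_se(a, b, c, d), NA_real_)
  tibble(ebgm = est, ebgm05 = exp(log(est) - .z95 * se),
         ebgm95 = exp(log(est) + .z95 * se))
}

#' Compute all four statistics for a set of fourfold tables
#'
#' @param tables tibble with columns `term`, `level`, `a`, `b`, `c`, `d`,
#'   `N` (as from [build_pt_tables()] / [build_soc_tables()]).
#' @param zero_correction apply Haldane-Anscombe +0.5 to every cell of
#'   tables containing a zero (default `FALSE`: such statistics are
#'   non-evaluable).
#' @param ic_method passed to [information_component()].
#' @return a `signal_result` tibble: the inputs plus `n` (= `a`), all
#'   statistics and interval bounds, and the per-algorithm flags
#'   `flag_ror`, `flag_prr`, `flag_ic`, `flag_ebgm` and `flag_all4`.
#' @export
disproportionality <- function(tables, zero_correction = FALSE,
                               ic_method = "delta") {
  stopifnot(all(c("term", "a", "b", "c", "d") %in% names(tables)))
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  if (zero_correction) {
    z <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * z; b <- b + 0.5 * z; c <- c + 0.5 * z; d <- d + 0.5 * z
  }
  out <- bind_cols(
    tibble(term = tables$term,
           level = if ("level" %in% names(tables)) tables$level else NA,
           n = tables$a),
    ror(a, b, c, d), prr(a, b, c, d),
    information_component(a, b, c, d, method = ic_method),
    ebgm(a, b, c, d))
  evaluate_thresholds(out)
}

#' Apply the per-algorithm signal thresholds
#'
#' Boundary semantics: PRR >= 2 and chi2 >= 4 and n >= 3 are inclusive;
#' IC025 > 0 and EBGM05 > 2 and ROR lower CI > 1 are strict. Non-evaluable
#' statistics never flag.
#'
#' @param r a tibble with the statistic columns of [disproportionality()].
#' @return `r` with logical columns `flag_ror`, `flag_prr`, `flag_ic`,
#'   `flag_ebgm`, `flag_all4`.
#' @export
evaluate_thresholds <- function(r) {
  f <- function(x) !is.na(x) & x
  r$flag_ror <- f(r$ror_lo > 1 & r$n >= 3)
  r$flag_prr <- f(r$prr >= 2 & r$chi2 >= 4 & r$n >= 3)
  r$flag_ic <- f(r$ic025 > 0)
  r$flag_ebgm <- f(r$ebgm05 > 2)
  r$flag_all4 <- r$flag_ror & r$flag_prr & r$flag_ic & r$flag_ebgm
  class(r) <- c("signal_result", class(r))
  r
}

#' Screen a set of contingency tables and rank the results
#'
#' @param tables as [disproportionality()].
#' @param sort_by column to rank by (default `"n"`, descending — the
#'   report-count ranking used for "top 30 AEs" style tables); ties broken
#'   by term label.
#' @param ... passed to [disproportionality()].
#' @return a ranked `signal_result` tibble.
#' @export
screen_signals <- function(tables, sort_by = "n", ...) {
  res <- disproportionality(tables, ...)
  res[order(-xtfrm(res[[sort_by]]), res$term), ]
}

#' Format a screening result like a published signal table
#'
#' @param r a `signal_result`.
#' @param total denominator for the `case` percentage column; defaults to
#'   the total (case, term) records across `r` — pass the full-table total
#'   when formatting a subset of rows.
#' @return tibble with `term`, `case` ("count (pct%)"), and the
#'   "estimate (interval)" columns for each algorithm plus the combined
#'   flag.
#' @export
format_signal_table <- function(r, total = sum(r$n)) {
  tot <- total
  fmt <- function(x, lo) sprintf("%.2f(%.2f)", x, lo)
  tibble(
    term = r$term,
    case = sprintf("%d (%.1f%%)", r$n, 100 * r$n / tot),
    `ROR (95% CI)` = sprintf("%.2f(%.2f-%.2f)", r$ror, r$ror_lo, r$ror_hi),
    `PRR(chi2)` = sprintf("%.2f(%.2f)", r$prr, r$chi2),
    `EBGM(EBGM05)` = fmt(r$ebgm, r$ebgm05),
    `IC(IC025)` = fmt(r$ic, r$ic025),
    signal = ifelse(r$flag_all4, "*", ""))
}
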