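test_that("balanced tables give the independence values", {
  r <- ror(25, 25, 25, 25); p <- prr(25, 25, 25, 25)
  i <- information_component(25, 25, 25, 25); e <- ebgm(25, 25, 25, 25)
  expect_equal(r$ror, 1); expect_equal(p$prr, 1); expect_equal(p$chi2, 0)
  expect_equal(i$ic, 0); expect_equal(e$ebgm, 1)
  expect_lt(r$ror_lo, 1); expect_gt(r$ror_hi, 1)
})

test_that("the worked fourfold example evaluates as derived by hand", {
  expect_equal(ror(20, 80, 100, 9800)$ror, 24.5)
  expect_equal(prr(20, 80, 100, 9800)$prr, 19.8)
  expect_equal(prr(20, 80, 100, 9800)$chi2, 301.1, tolerance = 1e-3)
  expect_equal(ebgm(20, 80, 100, 9800)$ebgm, 200000 / 12000)
  expect_equal(information_component(20, 80, 100, 9800)$ic,
               log2(200000 / 12000))
})

test_that("all statistics and bounds match the independent oracle on random tables", {
  set.seed(7)
  n <- 1000
  a <- sample(1:500, n, TRUE); b <- sample(1:5000, n, TRUE)
  c <- sample(1:5000, n, TRUE); d <- sample(1:100000, n, TRUE)
  got <- cbind(ror(a, b, c, d), prr(a, b, c, d),
               information_component(a, b, c, d), ebgm(a, b, c, d))
  worst <- 0
  for (i in seq_len(n)) {
    want <- oracle_stats(a[i], b[i], c[i], d[i])
    for (nm in names(want)) {
      rel <- abs(got[[nm]][i] - want[[nm]]) /
        max(abs(want[[nm]]), .Machine$double.eps)
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("IC equals log2(EBGM) on every evaluable table", {
  set.seed(8)
  a <- sample(1:300, 200, TRUE); b <- sample(1:3000, 200, TRUE)
  c <- sample(1:3000, 200, TRUE); d <- sample(1:50000, 200, TRUE)
  expect_equal(information_component(a, b, c, d)$ic, log2(ebgm(a, b, c, d)$ebgm),
               tolerance = 1e-12)
})

test_that("transposition symmetries hold", {
  x <- c(20, 80, 100, 9800)
  expect_equal(ror(x[3], x[4], x[1], x[2])$ror, 1 / 24.5, tolerance = 1e-12)
  expect_equal(prr(x[1], x[2], x[3], x[4])$chi2,
               prr(x[3], x[4], x[1], x[2])$chi2)  # chi2 invariant
  expect_equal(ebgm(x[1], x[2], x[3], x[4])$ebgm,
               ebgm(x[1], x[3], x[2], x[4])$ebgm)  # b <-> c symmetry
})

test_that("point estimates are nondecreasing in a with b, c, d fixed", {
  a <- 1:50
  expect_true(all(diff(ror(a, 100, 50, 10000)$ror) >= 0))
  expect_true(all(diff(prr(a, 100, 50, 10000)$prr) >= 0))
  expect_true(all(diff(information_component(a, 100, 50, 10000)$ic) >= 0))
  expect_true(all(diff(ebgm(a, 100, 50, 10000)$ebgm) >= 0))
})

test_that("zero cells are non-evaluable by default, finite with the correction", {
  tab <- tibble::tibble(term = "x", level = "PT", a = 5L, b = 0L, c = 3L,
                        d = 100L, N = 108L)
  res <- disproportionality(tab)
  expect_true(is.na(res$ror))
  expect_false(res$flag_ror)
  res2 <- disproportionality(tab, zero_correction = TRUE)
  expect_true(is.finite(res2$ror))
})

test_that("threshold boundary semantics follow the published criteria", {
  base <- tibble::tibble(term = "x", level = "PT", n = 3L,
                         ror = 2, ror_lo = 1.01, ror_hi = 4,
                         prr = 2.0, chi2 = 4.0, prr_lo = 1, prr_hi = 4,
                         ic = 1, ic025 = 0.01, ic975 = 2,
                         ebgm = 3, ebgm05 = 2.01, ebgm95 = 5)
  r <- evaluate_thresholds(base)
  expect_true(r$flag_all4)  # PRR >= 2 and chi2 >= 4 inclusive at boundary

  r2 <- evaluate_thresholds(transform(base, ebgm05 = 2.0))
  expect_false(r2$flag_ebgm)  # EBGM05 > 2 strict

  r3 <- evaluate_thresholds(transform(base, ic025 = 0))
  expect_false(r3$flag_ic)    # IC025 > 0 strict

  r4 <- evaluate_thresholds(transform(base, ror_lo = 1.0))
  expect_false(r4$flag_ror)   # lower CI > 1 strict

  r5 <- evaluate_thresholds(transform(base, n = 2L))
  expect_false(r5$flag_ror); expect_false(r5$flag_prr)  # N >= 3 gate
  r6 <- evaluate_thresholds(transform(base, prr = 1.99))
  expect_false(r6$flag_prr)
})

test_that("screening ranks by count with deterministic term tie-break", {
  tab <- tibble::tibble(term = c("B", "A", "C"), level = "PT",
                        a = c(5L, 5L, 9L), b = c(50L, 50L, 46L),
                        c = c(40L, 40L, 36L), d = c(900L, 900L, 904L),
                        N = 995L)
  res <- screen_signals(tab)
  expect_equal(res$term, c("C", "A", "B"))
  expect_equal(res$n, c(9L, 5L, 5L))
})

test_that("the posterior IC variant shrinks extreme small-count ICs", {
  d1 <- information_component(1, 1, 1, 10000)
  d2 <- information_component(1, 1, 1, 10000, method = "posterior")
  expect_lt(d2$ic, d1$ic)  # shrunk toward 0
  expect_true(is.finite(d2$ic025))
})

test_that("formatted signal tables carry the published column layout", {
  tab <- tibble::tibble(term = "Septic shock", level = "PT", a = 32L,
                        b = 2412L, c = 1200L, d = 700000L, N = 703644L)
  out <- format_signal_table(disproportionality(tab))
  expect_named(out, c("term", "case", "ROR (95% CI)", "PRR(chi2)",
                      "EBGM(EBGM05)", "IC(IC025)", "signal"))
  expect_match(out$`ROR (95% CI)`, "^[0-9.]+\\([0-9.]+-[0-9.]+\\)$")
})
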