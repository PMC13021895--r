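test_that("ROR, PRR, chi-squared and EBGM reproduce hand-computed values", {
  expect_equal(compute_ror(10, 90, 100, 900)$ror, 1.0)
  expect_equal(compute_ror(20, 80, 100, 900)$ror, 2.25)
  expect_equal(compute_prr(25, 25, 25, 25)$prr, 1.0)
  expect_equal(compute_prr(20, 80, 100, 900)$prr, 2.0)
  expect_equal(compute_chi2(20, 80, 100, 900), 9.353741, tolerance = 1e-6)
  expect_equal(compute_chi2(10, 90, 100, 900), 0)
  expect_equal(compute_ebgm(10, 90, 100, 900)$ebgm, 1.0)
  expect_equal(compute_ebgm(20, 80, 100, 900)$ebgm, 20 * 1100 / (120 * 100))
})

test_that("statistics below three reports or with a zero cell are
           not applicable", {
  expect_true(all(is.na(compute_ror(2, 8, 10, 80))))
  expect_true(all(is.na(compute_prr(2, 8, 10, 80))))
  expect_true(all(is.na(compute_ebgm(2, 8, 10, 80))))
  expect_true(all(is.na(compute_ror(5, 0, 10, 80))))
  expect_true(all(is.na(compute_ror(5, 8, 0, 80))))
})

test_that("chi-squared is symmetric under transposition and floors the
           Yates correction at zero", {
  expect_equal(compute_chi2(7, 21, 13, 59), compute_chi2(7, 13, 21, 59))
  # near-independence: |ad-bc| < N/2 must clamp, not go negative
  expect_equal(compute_chi2(10, 90, 101, 900, yates = TRUE), 0)
  expect_equal(compute_chi2(20, 80, 100, 900, yates = TRUE),
               suppressWarnings(
                 stats::chisq.test(matrix(c(20, 80, 100, 900), 2,
                                          byrow = TRUE),
                                   correct = TRUE)$statistic),
               ignore_attr = TRUE)
})

test_that("BCPNN prior terms cancel exactly on the uniform table", {
  res <- compute_bcpnn(25, 25, 25, 25)
  expect_equal(res$ic, 0)
  expect_equal(res$ic_expect, 0)
  expect_true(res$ic_var > 0)
  expect_true(res$ic025 < res$ic_expect)
})

test_that("independence tables give null values for every statistic", {
  # a/N = ((a+b)/N)((a+c)/N)
  tabs <- list(c(10, 90, 100, 900), c(5, 45, 95, 855), c(40, 360, 60, 540))
  for (t in tabs) {
    expect_equal(compute_ror(t[1], t[2], t[3], t[4])$ror, 1.0)
    expect_equal(compute_prr(t[1], t[2], t[3], t[4])$prr, 1.0)
    expect_equal(compute_ebgm(t[1], t[2], t[3], t[4])$ebgm, 1.0)
    expect_equal(compute_bcpnn(t[1], t[2], t[3], t[4])$ic, 0)
    expect_equal(compute_chi2(t[1], t[2], t[3], t[4]), 0)
  }
})

test_that("EBGM equals 2^IC and intervals are log-symmetric", {
  set.seed(404)
  a <- sample(3:50, 50, TRUE); b <- sample(1:1000, 50, TRUE)
  c <- sample(1:1000, 50, TRUE); d <- sample(1:10000, 50, TRUE)
  eb <- compute_ebgm(a, b, c, d)
  ic <- compute_bcpnn(a, b, c, d)
  ror <- compute_ror(a, b, c, d)
  expect_equal(eb$ebgm, 2^ic$ic, tolerance = 1e-14)
  expect_equal(ror$ror_hi, ror$ror^2 / ror$ror_lo, tolerance = 1e-12)
  expect_equal(eb$ebgm95, eb$ebgm^2 / eb$ebgm05, tolerance = 1e-12)
})

test_that("all five statistics increase strictly in a at fixed b, c, d", {
  a <- 3:40
  ror <- compute_ror(a, 100, 50, 1000)$ror
  prr <- compute_prr(a, 100, 50, 1000)$prr
  ic <- compute_bcpnn(a, 100, 50, 1000)$ic
  eb <- compute_ebgm(a, 100, 50, 1000)$ebgm
  expect_true(all(diff(ror) > 0))
  expect_true(all(diff(prr) > 0))
  expect_true(all(diff(ic) > 0))
  expect_true(all(diff(eb) > 0))
})

test_that("statistics match the scalar log-space oracle to 1e-12", {
  set.seed(505)
  n_tab <- 200
  max_rel_err <- 0
  for (i in seq_len(n_tab)) {
    a <- sample(3:1000, 1); b <- sample(1:1e6, 1)
    c <- sample(1:1e6, 1); d <- sample(1:1e6, 1)
    got <- signal_stats(data.frame(event = "e", a = a, b = b, c = c, d = d))
    want <- oracle_stats(a, b, c, d)
    for (f in names(want)) {
      rel <- abs(got[[f]] - want[[f]]) /
        max(abs(want[[f]]), .Machine$double.eps)
      max_rel_err <- max(max_rel_err, rel)
    }
  }
  expect_lt(max_rel_err, 1e-12)
})

test_that("the joint criterion reproduces published-style decisions", {
  # a strongly disproportional SOC row: all four algorithms fire
  strong <- data.frame(event = "Immune system disorders",
                       a = 4571, ror = 6.23, ror_lo = 6.05, prr = 5.88,
                       prr_lo = 5.77, ic025 = 2.5, ebgm05 = 5.7)
  expect_true(evaluate_signal(strong)$signal)
  # a null row: ROR below 1 and negative IC025
  null_row <- data.frame(event = "Pregnancy, puerperium and perinatal",
                         a = 231, ror = 0.98, ror_lo = 0.86, prr = 0.98,
                         prr_lo = 0.85, ic025 = -0.21, ebgm05 = 0.88)
  expect_false(evaluate_signal(null_row)$signal)
})

test_that("threshold boundaries are inclusive for points, strict for
           interval bounds", {
  at_boundary <- data.frame(event = "x", a = 3, ror = 2, ror_lo = 1,
                            prr = 2, prr_lo = 1, ic025 = 0, ebgm05 = 2)
  expect_false(evaluate_signal(at_boundary)$signal)
  just_over <- data.frame(event = "x", a = 3, ror = 2, ror_lo = 1.0001,
                          prr = 2, prr_lo = 1.0001, ic025 = 0.0001,
                          ebgm05 = 2.0001)
  expect_true(evaluate_signal(just_over)$signal)
  # not-applicable statistics fail their criterion
  na_row <- data.frame(event = "x", a = 2, ror = NA_real_, ror_lo = NA_real_,
                       prr = NA_real_, prr_lo = NA_real_, ic025 = 1,
                       ebgm05 = 3)
  expect_false(evaluate_signal(na_row)$signal)
})

test_that("log-symmetric upper bounds are recoverable from point and
           lower values", {
  expect_equal(round(ci_upper_from_lower(6.23, 6.05), 2), 6.42)
  expect_equal(round(ci_upper_from_lower(7.81, 7.55), 2), 8.08)
})

test_that("signal tables render display columns alongside full precision", {
  tab <- data.frame(event = c("E1", "E2"), a = c(20, 2), b = c(80, 8),
                    c = c(100, 10), d = c(900, 80))
  st <- signal_stats(tab)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_table(st, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$ror_display[1],
               sprintf("%.2f (%.2f, %.2f)", st$ror[1], st$ror_lo[1],
                       st$ror_hi[1]))
  expect_true(is.na(back$ror_display[2]) || back$ror_display[2] == "NA")
  expect_equal(back$signal, c(FALSE, FALSE))
})
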