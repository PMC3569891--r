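test_that("two-subject fit matches the hand-computed estimating equation", {
  # subjects Z = (0, 1) with events at t = 1, 2:
  # A = 0.5, b = -0.5 => beta = -1; B0(1) = 1, B0(2) = 3 (worked by hand)
  co <- cohort_data(c(1, 2), c(1, 1),
                    matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "z")))
  f <- suppressWarnings(fit_semiparametric(co))
  expect_equal(unname(f$beta), -1)
  expect_equal(f$baseline$time, c(1, 2))
  expect_equal(f$baseline$value, c(1, 3))
})

test_that("fit matches the fine-grid brute-force oracle on small cohorts", {
  for (s in 1:12) {
    co <- rand_cohort(sample(4:10, 1), p = 1, seed = 100 + s)
    f <- suppressWarnings(fit_semiparametric(co))
    b <- bruteforce_linying(co, grid_step = 1e-4)
    expect_lt(max(abs(f$beta - b)) / max(abs(b), 1), 1e-3)
  }
})

test_that("grid refinement of the oracle converges to the segment-exact fit", {
  co <- rand_cohort(8, p = 1, seed = 77)
  f <- suppressWarnings(fit_semiparametric(co))
  err <- sapply(c(1e-2, 1e-3, 1e-4), function(h)
    max(abs(bruteforce_linying(co, h) - f$beta)))
  expect_lt(err[3], err[1])            # finer grid is closer
  expect_lt(err[3], 1e-3)
})

test_that("degenerate designs are refused with informative errors", {
  co <- cohort_data(c(1, 2, 3), c(1, 1, 0),
                    matrix(0, 3, 1, dimnames = list(NULL, "flat")))
  expect_error(suppressWarnings(fit_semiparametric(co)), "flat")
  expect_error(cohort_data(c(1, 2), c(0, 0), matrix(c(0, 1), 2, 1)),
               "no events")
})

test_that("time rescaling divides beta and baseline increments exactly by c", {
  co <- rand_cohort(40, p = 2, seed = 5)
  f1 <- suppressWarnings(fit_semiparametric(co))
  co2 <- cohort_data(co$time * 3, co$event, co$covariates)
  f2 <- suppressWarnings(fit_semiparametric(co2))
  expect_equal(f2$beta, f1$beta / 3, tolerance = 1e-12)
  expect_equal(f2$baseline$value, f1$baseline$value, tolerance = 1e-12)
  expect_equal(f2$baseline$time, f1$baseline$time * 3)
})

test_that("fit is invariant to subject order", {
  co <- rand_cohort(30, p = 2, seed = 8)
  set.seed(1); perm <- sample(30)
  co2 <- cohort_data(co$time[perm], co$event[perm],
                     co$covariates[perm, , drop = FALSE])
  f1 <- suppressWarnings(fit_semiparametric(co))
  f2 <- suppressWarnings(fit_semiparametric(co2))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
  expect_equal(f1$covariance, f2$covariance, tolerance = 1e-12)
})

test_that("covariance is symmetric with nonnegative diagonal and p in [0,1]", {
  co <- rand_cohort(60, p = 2, seed = 13)
  f <- suppressWarnings(fit_semiparametric(co))
  expect_equal(f$covariance, t(f$covariance))
  expect_true(all(diag(f$covariance) >= 0))
  expect_true(all(f$wald_p >= 0 & f$wald_p <= 1))
})

test_that("predicted cumulative hazard obeys its closed form", {
  co <- rand_cohort(50, p = 1, seed = 21)
  f <- suppressWarnings(fit_semiparametric(co))
  expect_equal(predict_cumulative_hazard(f, 0, 0), 0)
  tq <- f$baseline$time[3]
  expect_equal(predict_cumulative_hazard(f, 0, tq), f$baseline$value[3])
  expect_equal(predict_cumulative_hazard(f, 1, tq),
               f$baseline$value[3] + unname(f$beta) * tq)
})

test_that("baseline variance formula agrees with a nonparametric bootstrap", {
  gen <- suppressMessages(simulate_cohort(
    hpv_scenario(n = 800, seed = 31, confounders = FALSE,
                  observation = "exact")))
  co <- gen$cohort
  f <- suppressWarnings(fit_semiparametric(co))
  t0 <- 4
  se_formula <- sqrt(eval_step_var(f$baseline, t0))
  set.seed(99)
  boot <- replicate(120, {
    ix <- sample(length(co$time), replace = TRUE)
    cb <- cohort_data(co$time[ix], co$event[ix],
                      co$covariates[ix, , drop = FALSE])
    fb <- tryCatch(suppressWarnings(fit_semiparametric(cb)),
                   error = function(e) NULL)
    if (is.null(fb)) NA else eval_step(fb$baseline, t0)
  })
  se_boot <- sd(boot, na.rm = TRUE)
  expect_lt(abs(se_formula - se_boot) / se_boot, 0.30)
})

test_that("trend test tracks an ordinal refit and refuses constants", {
  gen <- suppressMessages(simulate_cohort(hpv_scenario(n = 1200, seed = 17)))
  tt <- trend_test(gen$cohort, "hivcd4")
  expect_true(tt$p.value >= 0 && tt$p.value <= 1)
  expect_gt(unname(tt$estimate), 0)    # positive dose-response truth
  expect_lt(tt$p.value, 0.01)

  # manual ordinal refit gives the same slope
  enc <- gen$cohort$encoding$hivcd4
  D <- gen$cohort$covariates[, enc$columns, drop = FALSE]
  ordv <- drop(D %*% (match(sub("^hivcd4=", "", enc$columns), enc$levels) - 1))
  keep <- setdiff(colnames(gen$cohort$covariates), enc$columns)
  Z2 <- cbind(ord = ordv, gen$cohort$covariates[, keep, drop = FALSE])
  f2 <- suppressWarnings(fit_semiparametric(
    cohort_data(gen$cohort$time, gen$cohort$event, Z2)))
  expect_equal(unname(tt$estimate), unname(f2$beta["ord"]), tolerance = 1e-10)

  co_const <- cohort_data(c(1, 2), c(1, 1),
                          matrix(0, 2, 1, dimnames = list(NULL, "g=b")),
                          encoding = list(g = list(levels = c("a", "b"),
                                                   reference = "a",
                                                   columns = "g=b")))
  expect_error(trend_test(co_const, "g"), "constant")
})

test_that("fit summary CSV has the effect-table layout", {
  co <- rand_cohort(40, p = 2, seed = 3)
  f <- suppressWarnings(fit_semiparametric(co))
  path <- tempfile(fileext = ".csv")
  write_fit_csv(f, path)
  df <- read.csv(path)
  expect_equal(names(df), c("term", "estimate", "se", "p_value"))
  expect_equal(nrow(df), 2)
})
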