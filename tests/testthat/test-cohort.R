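test_that("reference-cell encoding produces the declared dummy layout", {
  raw <- data.frame(
    time = c(1, 2, 3, 4), event = c(1, 0, 1, 1),
    grp = c("HIV-", "CD4>500", "CD4 200-500", "CD4<200"))
  specs <- list(grp = list(levels = c("HIV-", "CD4>500", "CD4 200-500", "CD4<200"),
                           reference = "HIV-"))
  co <- encode_covariates(raw, specs)
  expect_equal(colnames(co$covariates),
               c("grp=CD4>500", "grp=CD4 200-500", "grp=CD4<200"))
  expect_equal(unname(co$covariates[1, ]), c(0, 0, 0))   # reference -> all zero
  expect_equal(unname(co$covariates[4, ]), c(0, 0, 1))
  expect_true(all(co$covariates %in% c(0, 1)))
})

test_that("two factors with 4 and 5 levels contribute p = 3 + 4 columns", {
  set.seed(11)
  raw <- data.frame(time = runif(60, 1, 5), event = rbinom(60, 1, 0.5),
                    a = sample(paste0("a", 1:4), 60, replace = TRUE),
                    b = sample(paste0("b", 1:5), 60, replace = TRUE))
  specs <- list(a = list(levels = paste0("a", 1:4)),
                b = list(levels = paste0("b", 1:5)))
  co <- encode_covariates(raw, specs)
  expect_equal(ncol(co$covariates), 7)
  # cross-check by enumerating the encoding map
  expect_equal(length(unlist(lapply(co$encoding, `[[`, "columns"))), 7)
})

test_that("single-level factor contributes zero columns", {
  raw <- data.frame(time = 1:4, event = c(1, 1, 0, 1), f = rep("only", 4),
                    x = c(0.1, 0.3, 0.2, 0.9))
  co <- encode_covariates(raw, list(f = list(levels = "only")))
  expect_equal(colnames(co$covariates), "x")
  expect_equal(co$encoding$f$columns, character(0))
})

test_that("encoding rejects unknown levels and never-observed levels", {
  raw <- data.frame(time = 1:3, event = c(1, 1, 0), g = c("a", "b", "zz"))
  expect_error(encode_covariates(raw, list(g = list(levels = c("a", "b")))),
               "zz")
  raw2 <- data.frame(time = 1:3, event = c(1, 1, 0), g = c("a", "a", "a"))
  expect_error(encode_covariates(raw2, list(g = list(levels = c("a", "b")))),
               "non-identifiable")
})

test_that("encoding is invariant to row order and drops missing covariates", {
  set.seed(4)
  raw <- data.frame(time = runif(30, 1, 4), event = rbinom(30, 1, 0.6),
                    g = sample(c("x", "y", "z"), 30, replace = TRUE))
  specs <- list(g = list(levels = c("x", "y", "z")))
  co1 <- encode_covariates(raw, specs)
  perm <- sample(30)
  co2 <- encode_covariates(raw[perm, ], specs)
  expect_equal(co2$covariates[order(perm), ], co1$covariates)

  raw$g[3] <- NA
  expect_warning(co3 <- encode_covariates(raw, specs), "dropped 1 record")
  expect_equal(length(co3$time), 29)
})

test_that("cohort invariants are enforced", {
  expect_error(cohort_data(c(0, 1), c(1, 0)), "strictly positive")
  expect_error(cohort_data(c(1, 2), c(1, 2)), "exactly 0 or 1")
  expect_error(cohort_data(c(1, 2), c(0, 0)), "no events")
  expect_silent(cohort_data(c(1, 2), c(0, 0), require_event = FALSE))
})

test_that("midinterval imputation follows the screening rules", {
  v <- data.frame(id = c(1, 1, 2, 2, 2, 3, 3),
                  visit_time = c(1.0, 1.5, 0.5, 1.0, 1.5, 2.0, 4.0),
                  result = c(0, 1, 0, NA, 1, 0, 0))
  out <- midinterval_event_times(v)
  expect_equal(out$time, c(1.25, 1.0, 4.0))   # midpoint; skip-missing midpoint; censor
  expect_equal(out$event, c(1, 1, 0))
})

test_that("midinterval rejects prevalent cases and empty visit histories", {
  expect_error(midinterval_event_times(
    data.frame(id = 1, visit_time = c(0, 0.5), result = c(1, 1))), "prevalent")
  expect_error(midinterval_event_times(
    data.frame(id = 1, visit_time = c(0, 0.5), result = c(NA, NA))),
    "no non-missing")
})

test_that("midinterval time lies strictly between the bracketing visits", {
  set.seed(9)
  for (rep in 1:20) {
    nv <- sample(3:10, 1)
    vt <- cumsum(runif(nv, 0.3, 0.8))
    pos <- sample(2:nv, 1)
    res <- c(rep(0, pos - 1), rep(1, nv - pos + 1))
    miss <- sample(seq_len(nv - 1)[-1], size = min(1, nv - 3))
    res[setdiff(miss, c(1, pos))] <- NA
    out <- midinterval_event_times(data.frame(id = 1, visit_time = vt, result = res))
    lastneg <- max(vt[which(res == 0)])
    firstpos <- min(vt[which(res == 1)])
    expect_gt(out$time, lastneg)
    expect_lt(out$time, firstpos)
  }
})

test_that("cohort CSV round-trips exactly", {
  co <- rand_cohort(25, p = 2, seed = 42)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  co2 <- read_cohort_csv(path)
  expect_equal(co2$time, co$time)
  expect_equal(co2$event, co$event)
  expect_equal(co2$covariates, co$covariates)
})
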