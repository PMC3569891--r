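test_that("generation is reproducible bit-for-bit and order-independent", {
  cfg <- hpv_scenario(n = 300, seed = 71)
  g1 <- suppressMessages(simulate_cohort(cfg))
  g2 <- suppressMessages(simulate_cohort(cfg))
  expect_identical(g1$cohort$time, g2$cohort$time)
  expect_identical(g1$truth, g2$truth)
  # per-subject substreams: the first 300 subjects of a larger cohort are
  # the same subjects
  g3 <- suppressMessages(simulate_cohort(hpv_scenario(n = 400, seed = 71)))
  expect_identical(g3$truth[1:300, ], g1$truth)
})

test_that("inversion sampler reproduces the target cumulative hazard", {
  # H(T|z) ~ unit exponential <=> 1 - exp(-H(T)) ~ uniform, per profile
  cfg <- simulation_config(
    n = 10000,
    baseline = list(breaks = 2, rates = c(0.05, 0.12)),
    factors = list(g = list(levels = c("a", "b"), probs = c(0.5, 0.5))),
    effects = list(`g=b` = list(breaks = 3, rates = c(0.02, 0.1))),
    visit_interval = 0.5, max_followup = 50, dropout_rate = 0, seed = 73)
  gen <- suppressMessages(simulate_cohort(cfg))
  tr <- gen$truth
  H <- function(t, z) {
    base <- 0.05 * pmin(t, 2) + 0.12 * pmax(t - 2, 0)
    eff <- 0.02 * pmin(t, 3) + 0.1 * pmax(t - 3, 0)
    base + if (z == "b") eff else 0
  }
  for (lv in c("a", "b")) {
    u <- 1 - exp(-H(tr$latent_time[tr$g == lv], lv))
    ks <- suppressWarnings(ks.test(u, "punif"))
    expect_lt(unname(ks$statistic), 0.02)
  }
})

test_that("midinterval discretization error is bounded by half a visit interval", {
  gen <- suppressMessages(simulate_cohort(
    hpv_scenario(n = 2000, seed = 79, confounders = FALSE)))
  obs <- data.frame(id = gen$cohort$id, time = gen$cohort$time,
                    event = gen$cohort$event)
  ev <- obs[obs$event == 1, ]
  latent <- gen$truth$latent_time[ev$id]
  expect_lte(mean(abs(ev$time - latent)), 0.25)
  expect_lte(max(abs(ev$time - latent)), 0.25 + 1e-12)
})

test_that("configurations implying a negative hazard are rejected at load", {
  expect_error(simulation_config(
    n = 100, baseline = 0.03,
    factors = list(g = list(levels = c("a", "b"), probs = c(0.5, 0.5))),
    effects = list(`g=b` = -0.05)), "negative hazard")
  expect_error(simulation_config(
    n = 100, baseline = 0.05,
    factors = list(g = list(levels = c("a", "b"), probs = c(0.6, 0.3)))),
    "sum to 1")
  expect_error(simulation_config(
    n = 100, baseline = 0.05,
    factors = list(g = list(levels = c("a", "b"), probs = c(0.5, 0.5))),
    effects = list(`g=zz` = 0.01)), "unknown dummy")
})

test_that("scenario files round-trip through YAML", {
  skip_if_not_installed("yaml")
  cfg <- hpv_scenario(n = 123, seed = 5)
  path <- tempfile(fileext = ".yml")
  write_scenario(cfg, path)
  cfg2 <- read_scenario(path)
  expect_equal(cfg2$n, cfg$n)
  expect_equal(cfg2$effects, cfg$effects)
  g1 <- suppressMessages(simulate_cohort(cfg))
  g2 <- suppressMessages(simulate_cohort(cfg2))
  expect_identical(g1$cohort$time, g2$cohort$time)
})

test_that("full recovery loop: both fits recover a known additive truth", {
  gen <- suppressMessages(simulate_cohort(
    hpv_scenario(n = 2000, seed = 83, confounders = FALSE)))
  truth <- c(0.0343, 0.0779, 0.1395)
  fs <- fit_semiparametric(gen$cohort)
  expect_true(all(abs(fs$beta - truth) <= 3.5 * fs$se))
  fn <- fit_nonparametric(gen$cohort)
  t0 <- min(5, fn$tau)
  Bm <- eval_cumreg(fn, t0)
  for (k in 1:3)
    expect_lt(abs(Bm[1, k + 1] - truth[k] * t0),
              3.5 * sqrt(fn$variance[findInterval(t0, fn$times), k + 1]))
})

test_that("generated truth is attached and consistent with the cohort", {
  gen <- suppressMessages(simulate_cohort(hpv_scenario(n = 200, seed = 89)))
  expect_equal(nrow(gen$truth), 200)
  expect_true(all(gen$cohort$id %in% gen$truth$id))
  # every observed event lies at or before the latent event time ever tested
  # positive: midpoint < first positive visit <= ceiling of latent time
  ev <- gen$cohort$event == 1
  expect_true(all(gen$cohort$time[ev] <=
                    0.5 * ceiling(gen$truth$latent_time[gen$cohort$id[ev]] / 0.5)))
  d <- tempfile()
  write_generated(gen, d, "demo")
  expect_true(file.exists(file.path(d, "demo.csv")))
  expect_true(file.exists(file.path(d, "demo.truth.csv")))
})

test_that("the shipped demo scenario equals the default screening scenario", {
  skip_if_not_installed("yaml")
  path <- system.file("extdata", "hpv_scenario.yml", package = "addhaz")
  expect_true(nzchar(path))
  cfg <- read_scenario(path)
  ref <- hpv_scenario()
  expect_equal(cfg$n, ref$n)
  expect_equal(cfg$baseline$rates, ref$baseline$rates, tolerance = 1e-5)
  expect_equal(cfg$effects, ref$effects)
  expect_equal(cfg$factors, ref$factors)
})
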