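## invert a piecewise-constant-hazard cumulative hazard: find t with H(t) = e.
## rates has length(breaks) + 1 (last segment extends to +Inf); zero-rate
## segments are skipped; targets beyond the total mass map to +Inf.
.invert_pch <- function(e, breaks, rates) {
  nb <- length(breaks)
  cumvals <- c(0, if (nb) cumsum(rates[seq_len(nb)] * diff(c(0, breaks))) else NULL)
  seg <- findInterval(e, cumvals)
  t0 <- c(0, breaks)[seg]
  r <- rates[seg]
  t <- t0 + (e - cumvals[seg]) / r
  zero <- r == 0
  t[zero & e <= cumvals[seg][zero]] <- t0[zero & e <= cumvals[seg][zero]]
  t[zero & e > cumvals[seg][zero]] <- Inf
  t
}

.as_pch <- function(x) {
  if (is.numeric(x) && length(x) == 1) list(breaks = numeric(0), rates = x)
  else {
    stopifnot(is.list(x), !is.null(x$rates),
              length(x$rates) == length(x$breaks) + 1)
    list(breaks = as.numeric(x$breaks), rates = as.numeric(x$rates))
  }
}

## piecewise-constant hazard for one covariate profile: baseline plus the
## active dummy-column effects, merged onto the union of their breakpoints
.profile_hazard <- function(cfg, active_cols) {
  parts <- c(list(cfg$baseline), cfg$effects[active_cols])
  breaks <- sort(unique(unlist(lapply(parts, `[[`, "breaks"))))
  rates <- rep(0, length(breaks) + 1)
  bounds <- c(0, breaks)
  for (pc in parts) {
    seg <- findInterval(bounds, c(0, pc$breaks))
    rates <- rates + pc$rates[seg]
  }
  list(breaks = breaks, rates = rates)
}

#' Simulation scenario for an additive-hazard screening cohort
#'
#' Defines the data-generating truth for [simulate_cohort()]: a
#' piecewise-constant baseline hazard, per-dummy-column additive effects
#' (constant or piecewise-constant in time), categorical covariate mixes, a
#' periodic visit schedule with exponential dropout, and a seed. The
#' configuration is validated at load: the implied hazard must be
#' nonnegative for every supported covariate profile on every time segment.
#'
#' @param n cohort size.
#' @param baseline baseline hazard per year: a single rate or
#'   `list(breaks=, rates=)` (piecewise constant, `length(rates) ==
#'   length(breaks) + 1`).
#' @param factors named list of categorical covariates, each
#'   `list(levels=, probs=, reference=)` (reference defaults to the first
#'   level); dummy columns are named `<factor>=<level>` as in
#'   [encode_covariates()].
#' @param effects named list of additive effects keyed by dummy column name;
#'   each a constant (hazard difference per year) or `list(breaks=, rates=)`
#'   for a time-varying coefficient.
#' @param visit_interval years between scheduled visits (default 0.5,
#'   a semiannual schedule).
#' @param max_followup administrative end of follow-up in years.
#' @param dropout_rate per-year exponential dropout rate (0 = none).
#' @param observation `"visits"` (periodic testing with midinterval
#'   event-time imputation, the screening design) or `"exact"` (latent times
#'   observed directly, censored at dropout/administrative end).
#' @param seed integer seed; each subject gets its own substream derived
#'   from (seed, subject index), so the cohort is reproducible bit-for-bit
#'   and independent of generation order.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(n, baseline = 0.04463, factors = list(),
                              effects = list(), visit_interval = 0.5,
                              max_followup = 10, dropout_rate = 0.05,
                              observation = c("visits", "exact"), seed = 1) {
  observation <- match.arg(observation)
  stopifnot(n >= 1, visit_interval > 0, max_followup > visit_interval,
            dropout_rate >= 0)
  baseline <- .as_pch(baseline)
  effects <- lapply(effects, .as_pch)
  valid_cols <- unlist(lapply(names(factors), function(f) {
    sp <- factors[[f]]
    stopifnot(!is.null(sp$levels), !is.null(sp$probs),
              length(sp$levels) == length(sp$probs))
    if (abs(sum(sp$probs) - 1) > 1e-8)
      stop(sprintf("probabilities of factor '%s' must sum to 1", f))
    ref <- if (!is.null(sp$reference)) sp$reference else sp$levels[1]
    paste(f, setdiff(sp$levels, ref), sep = "=")
  }))
  bad <- setdiff(names(effects), valid_cols)
  if (length(bad))
    stop("effects name unknown dummy column(s): ", paste(bad, collapse = ", "))

  cfg <- structure(list(n = as.integer(n), baseline = baseline,
                        factors = factors, effects = effects,
                        visit_interval = visit_interval,
                        max_followup = max_followup,
                        dropout_rate = dropout_rate,
                        observation = observation, seed = as.integer(seed)),
                   class = "simulation_config")

  ## nonnegativity of h(t|z) for every supported profile
  combos <- .factor_combos(cfg)
  for (k in seq_len(nrow(combos$grid))) {
    hz <- .profile_hazard(cfg, combos$active[[k]])
    if (any(hz$rates < 0))
      stop(sprintf("configuration yields a negative hazard for profile {%s}",
                   paste(sprintf("%s=%s", names(combos$grid),
                                 unlist(combos$grid[k, ])), collapse = ", ")))
  }
  cfg
}

.factor_combos <- function(cfg) {
  if (!length(cfg$factors)) {
    return(list(grid = data.frame(row.names = 1), active = list(character(0))))
  }
  grid <- expand.grid(lapply(cfg$factors, `[[`, "levels"),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  active <- lapply(seq_len(nrow(grid)), function(k) {
    cols <- character(0)
    for (f in names(cfg$factors)) {
      sp <- cfg$factors[[f]]
      ref <- if (!is.null(sp$reference)) sp$reference else sp$levels[1]
      if (grid[k, f] != ref) cols <- c(cols, paste(f, grid[k, f], sep = "="))
    }
    cols
  })
  list(grid = grid, active = active)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation scenario: n = %d, %s observation, visits every %g yr, max %g yr, dropout %g/yr\n",
              x$n, x$observation, x$visit_interval, x$max_followup, x$dropout_rate))
  cat(sprintf("Baseline rate(s): %s; %d additive effect(s); factors: %s\n",
              paste(signif(x$baseline$rates, 4), collapse = "/"),
              length(x$effects),
              if (length(x$factors)) paste(names(x$factors), collapse = ", ") else "none"))
  invisible(x)
}

#' Default screening-cohort scenario
#'
#' A cohort emulating a semiannual HPV-screening design: a four-level host
#' immune-status exposure (reference plus three strata with additive excess
#' hazards 0.0343, 0.0779 and 0.1395 events per woman-year) and a smoking
#' confounder (excess hazards 0.0034 and 0.0224), on a constant baseline
#' hazard of 0.04463/yr so the reference profile's 5-year cumulative
#' incidence is 0.20. Semiannual visits over 10 years with 5%/yr dropout.
#'
#' @param n cohort size (default 2386).
#' @param seed integer seed.
#' @param confounders include the smoking confounder (default TRUE).
#' @param effects excess hazards for the three exposure strata.
#' @param observation passed to [simulation_config()].
#' @param dropout_rate per-year dropout rate.
#' @return a `"simulation_config"`.
#' @export
hpv_scenario <- function(n = 2386, seed = 1, confounders = TRUE,
                          effects = c(0.0343, 0.0779, 0.1395),
                          observation = "visits", dropout_rate = 0.05) {
  stopifnot(length(effects) == 3)
  factors <- list(
    hivcd4 = list(levels = c("HIV-", "CD4>500", "CD4 200-500", "CD4<200"),
                  probs = c(0.30, 0.28, 0.28, 0.14), reference = "HIV-"))
  eff <- list(`hivcd4=CD4>500` = effects[1],
              `hivcd4=CD4 200-500` = effects[2],
              `hivcd4=CD4<200` = effects[3])
  if (confounders) {
    factors$smoking <- list(levels = c("never", "former", "current"),
                            probs = c(0.45, 0.25, 0.30), reference = "never")
    eff$`smoking=former` <- 0.0034
    eff$`smoking=current` <- 0.0224
  }
  simulation_config(n = n, baseline = -log(0.80) / 5, factors = factors,
                    effects = eff, visit_interval = 0.5, max_followup = 10,
                    dropout_rate = dropout_rate, observation = observation,
                    seed = seed)
}

#' Simulate a screening cohort from a known additive hazard
#'
#' Per subject: draws covariate levels, a latent event time by closed-form
#' inversion of the piecewise-constant cumulative hazard H(t|z), and an
#' exponential dropout time; builds the semiannual visit record (a visit's
#' test is positive iff the latent time has passed) and derives the
#' analyzable right-censored cohort by [midinterval_event_times()]. With
#' `observation = "exact"` the latent time is observed directly, censored at
#' min(dropout, administrative end). Each subject uses its own random
#' substream derived from (seed, subject index).
#'
#' Subjects who never attend a post-baseline visit (early dropout) carry no
#' follow-up time and are dropped; their count is reported.
#'
#' @param cfg a [simulation_config].
#' @return An object of class `"generated_cohort"`: list with `cohort` (a
#'   [cohort_data]), `visits` (the visit table, `NULL` for exact
#'   observation), `truth` (per-subject latent event time, dropout time and
#'   covariate levels), `config`, and `n_dropped`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n
  nf <- length(cfg$factors)
  fnames <- names(cfg$factors)

  ## per-subject uniform draws from dedicated substreams
  U <- matrix(NA_real_, n, nf + 2)
  for (i in seq_len(n)) {
    set.seed((cfg$seed %% 60013) * 33013 + i * 7 + 11L)
    U[i, ] <- stats::runif(nf + 2)
  }

  levels_df <- as.data.frame(matrix(NA_character_, n, nf,
                                    dimnames = list(NULL, fnames)),
                             stringsAsFactors = FALSE)
  for (j in seq_len(nf)) {
    sp <- cfg$factors[[j]]
    levels_df[[j]] <- sp$levels[findInterval(U[, j], cumsum(sp$probs),
                                             left.open = TRUE) + 1L]
  }

  ## latent event times by inversion, vectorized within covariate combo
  combos <- .factor_combos(cfg)
  key <- if (nf) do.call(paste, c(levels_df, sep = "\r")) else rep("", n)
  ckey <- if (nf) do.call(paste, c(combos$grid, sep = "\r")) else ""
  cidx <- match(key, ckey)
  Etarget <- -log(U[, nf + 1])
  latent <- numeric(n)
  for (k in unique(cidx)) {
    hz <- .profile_hazard(cfg, combos$active[[k]])
    sel <- cidx == k
    latent[sel] <- .invert_pch(Etarget[sel], hz$breaks, hz$rates)
  }
  dropout <- if (cfg$dropout_rate > 0) -log(U[, nf + 2]) / cfg$dropout_rate else rep(Inf, n)

  truth <- cbind(data.frame(id = seq_len(n), latent_time = latent,
                            dropout_time = dropout), levels_df)

  v <- cfg$visit_interval
  horizon <- pmin(dropout, cfg$max_followup)
  if (cfg$observation == "exact") {
    tt <- pmin(latent, horizon)
    ev <- as.numeric(latent <= horizon)
    keep <- tt > 0
    raw <- data.frame(id = seq_len(n)[keep], time = tt[keep], event = ev[keep])
    visits <- NULL
  } else {
    lastv <- floor(horizon / v) * v                 # last attended scheduled visit
    firstpos <- v * ceiling(latent / v)             # first positive scheduled visit
    observed <- firstpos <= lastv
    endv <- ifelse(observed, firstpos, lastv)
    nv <- as.integer(round(endv / v)) + 1L
    keep <- nv >= 2L                                # must attend a post-baseline visit
    kid <- seq_len(n)[keep]
    nvk <- nv[keep]
    visits <- data.frame(
      id = rep(kid, nvk),
      visit_time = (sequence(nvk) - 1) * v,
      result = 0)
    last_row <- cumsum(nvk)
    visits$result[last_row[observed[keep]]] <- 1
    raw <- midinterval_event_times(visits, admin_end = cfg$max_followup)
  }

  n_dropped <- n - nrow(raw)
  if (n_dropped > 0)
    message(sprintf("simulate_cohort: dropped %d subject(s) with no usable follow-up", n_dropped))
  if (nf) {
    raw <- cbind(raw, levels_df[raw$id, , drop = FALSE])
    specs <- lapply(cfg$factors, function(sp)
      list(levels = sp$levels,
           reference = if (!is.null(sp$reference)) sp$reference else sp$levels[1]))
    cohort <- encode_covariates(raw, specs)
  } else {
    cohort <- cohort_data(raw$time, raw$event, id = raw$id)
  }
  structure(list(cohort = cohort, visits = visits, truth = truth,
                 config = cfg, n_dropped = n_dropped),
            class = "generated_cohort")
}

#' @export
print.generated_cohort <- function(x, ...) {
  cat(sprintf("Generated cohort (%s observation): ", x$config$observation))
  print(x$cohort)
  invisible(x)
}

#' Write a generated cohort and its latent truth
#'
#' Writes `<name>.csv` in the cohort CSV dialect and `<name>.truth.csv` with
#' the per-subject latent event time, dropout time and covariate levels.
#'
#' @param gen a `"generated_cohort"`.
#' @param dir output directory.
#' @param name file stem.
#' @export
write_generated <- function(gen, dir, name = "cohort") {
  stopifnot(inherits(gen, "generated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(gen$cohort, file.path(dir, paste0(name, ".csv")))
  utils::write.csv(gen$truth, file.path(dir, paste0(name, ".truth.csv")),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read / write a scenario file
#'
#' Scenario configurations round-trip through a flat YAML file.
#'
#' @param cfg a [simulation_config].
#' @param path file path.
#' @return [read_scenario()] returns a validated [simulation_config].
#' @export
write_scenario <- function(cfg, path) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for scenario files")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for scenario files")
  x <- yaml::read_yaml(path)
  simulation_config(n = x$n, baseline = x$baseline, factors = x$factors,
                    effects = x$effects, visit_interval = x$visit_interval,
                    max_followup = x$max_followup,
                    dropout_rate = x$dropout_rate,
                    observation = x$observation, seed = x$seed)
}
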