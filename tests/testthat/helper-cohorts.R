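# Deterministic small random cohorts used across tests. A cohort is retried
# with perturbed draws until it has events in both covariate groups, so the
# estimating equations are well posed.
rand_cohort <- function(n, p = 1, seed = 1, max_time = 5) {
  set.seed(seed)
  for (attempt in 1:50) {
    tm <- pmin(round(rexp(n, 0.6) + 0.05, 3), max_time)
    ev <- rbinom(n, 1, 0.7)
    Z <- matrix(rbinom(n * p, 1, 0.5), n, p,
                dimnames = list(NULL, paste0("z", seq_len(p))))
    ok <- sum(ev) >= 2 && all(apply(Z, 2, function(col) length(unique(col)) == 2))
    if (ok && p >= 1) {
      A_ok <- tryCatch({
        suppressWarnings(fit_semiparametric(cohort_data(tm, ev, Z))); TRUE
      }, error = function(e) FALSE)
      if (A_ok) return(cohort_data(tm, ev, Z))
    } else if (ok) {
      return(cohort_data(tm, ev, Z))
    }
  }
  stop("could not build a usable random cohort")
}

rand_cohort_p0 <- function(n, seed = 1) {
  set.seed(seed)
  tm <- round(rexp(n, 0.5) + 0.05, 3)
  ev <- rbinom(n, 1, 0.6)
  if (sum(ev) < 1) ev[1] <- 1
  cohort_data(tm, ev)
}

# Proportional-hazards (multiplicative) truth with a Weibull baseline:
# h(t|z) = lam0 * k * t^(k-1) * exp(beta z). The group hazard difference
# grows like t^(k-1), which a constant-coefficient additive fit cannot
# capture -- the canonical misspecification contrast for the residual check.
sim_weibull_cox <- function(n, lam0 = 0.00219, k = 2.5, beta = 2,
                            admin = 10, dropout = 0.05, seed = 1) {
  set.seed(seed)
  z <- rbinom(n, 1, 0.5)
  T <- (-log(runif(n)) / (lam0 * exp(beta * z)))^(1 / k)
  C <- pmin(if (dropout > 0) rexp(n, dropout) else Inf, admin)
  tm <- pmax(pmin(T, C), 1e-6)
  ev <- as.numeric(T <= C)
  cohort_data(tm, ev, matrix(z, ncol = 1, dimnames = list(NULL, "z")),
              require_event = TRUE)
}
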