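#' Brute-force estimating-equation solver (test oracle)
#'
#' Independent, deliberately naive evaluation of the constant-coefficient
#' estimating equations: the time integral in A is approximated by midpoint
#' Riemann summation on a fine grid, and b is accumulated by an explicit
#' per-event loop over risk-set averages. Intended as a cross-check for
#' [fit_semiparametric()] on small cohorts; the grid-refined value converges
#' to the segment-exact solution.
#'
#' @param cohort a [cohort_data] with at most 50 subjects.
#' @param grid_step Riemann grid step in years (default 1e-4).
#' @return named numeric vector of coefficient estimates.
#' @export
bruteforce_linying <- function(cohort, grid_step = 1e-4) {
  stopifnot(inherits(cohort, "cohort_data"))
  time <- cohort$time; event <- cohort$event; Z <- cohort$covariates
  n <- length(time); p <- ncol(Z)
  if (n > 50) stop("oracle is restricted to n <= 50")
  if (p < 1) stop("needs at least one covariate")

  tmax <- max(time)
  gpts <- seq(grid_step / 2, tmax, by = grid_step)
  Y <- outer(time, gpts, ">=")                       # n x G at-risk indicators
  ng <- colSums(Y)
  ok <- ng > 0
  S1 <- crossprod(Z, Y[, ok, drop = FALSE])          # p x G sums of Z at risk
  w <- as.numeric(Y %*% rep(grid_step, length(gpts)))  # approx total time at risk
  A <- crossprod(Z * sqrt(w)) -
    tcrossprod(S1 * rep(sqrt(grid_step / ng[ok]), each = p))

  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1e-10)
    stop("oracle: design numerically singular")

  b <- numeric(p)
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    b <- b + Z[i, ] - colMeans(Z[risk, , drop = FALSE])
  }
  stats::setNames(drop(solve(A, b)), colnames(Z))
}

#' Brute-force per-event-time least squares (test oracle)
#'
#' Independent enumeration of the time-varying-coefficient increments: at
#' each distinct event time the design matrix (1, z_i) over the at-risk set
#' is built explicitly and the least-squares increment is obtained through a
#' QR solve, stopping when the design loses full column rank. Cross-checks
#' [fit_nonparametric()].
#'
#' @param cohort a [cohort_data] with at most 50 subjects.
#' @return list with `times`, `increments` (one row per event time, columns
#'   intercept then covariates) and `tau`.
#' @export
bruteforce_aalen <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_data"))
  time <- cohort$time; event <- cohort$event; Z <- cohort$covariates
  if (length(time) > 50) stop("oracle is restricted to n <= 50")
  q <- ncol(Z) + 1L
  ets <- sort(unique(time[event == 1]))
  inc <- matrix(NA_real_, 0, q)
  kept <- numeric(0)
  for (s in ets) {
    risk <- which(time >= s)
    X <- cbind(1, Z[risk, , drop = FALSE])
    qrx <- qr(X)
    if (qrx$rank < q) break
    dN <- as.numeric(time[risk] == s & event[risk] == 1)
    inc <- rbind(inc, drop(qr.coef(qrx, dN)))
    kept <- c(kept, s)
  }
  if (!length(kept))
    stop("oracle: design rank deficient at the first event time (tau = 0)")
  colnames(inc) <- c("(baseline)", colnames(Z))
  list(times = kept, increments = inc, tau = kept[length(kept)])
}
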