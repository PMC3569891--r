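#' Fit the nonparametric additive hazard model
#'
#' Fits h(t | Z) = b0(t) + b(t)' Z with all coefficients unspecified
#' functions of time, by ordinary least squares at each distinct event time.
#' The estimated quantities are the cumulative regression functions
#' B_k(t) = int_0^t b_k(s) ds: B_0 is the cumulative baseline hazard and, for
#' an indicator covariate, B_k is the excess cumulative hazard of that group.
#'
#' At each distinct event time s the increment is
#'   dB(s) = (X(s)' X(s))^{-1} X(s)' dN(s),
#' where X(s) has one row (1, z_i) per at-risk subject and dN(s) flags the
#' subjects with an event at s (tied events are aggregated into one
#' increment). The pointwise variance is the cumulative sum of the diagonal
#' of (X'X)^{-1} X' diag(dN) X (X'X)^{-1}. Estimates are produced up to the
#' full-rank horizon tau: the last event time at which X(s) has full column
#' rank (reciprocal condition number >= 1e-10); events after tau are excluded
#' from estimation but kept by the residual diagnostics as censored.
#'
#' @param cohort a [cohort_data] object with at least one event; p = 0
#'   (intercept only) is allowed and collapses to the Nelson-Aalen estimator.
#' @return An object of class `"addhaz_nonp"`: list with `times` (event times
#'   <= tau), `B` (matrix, one column per term, first column `(baseline)`),
#'   `variance` (same shape), `tau`, `n`, `n_events`, `n_events_used`.
#' @seealso [fit_semiparametric()], [pointwise_tests()], [nelson_aalen()]
#' @export
fit_nonparametric <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_data"))
  time <- cohort$time; event <- cohort$event; Z <- cohort$covariates
  if (sum(event) < 1) stop("cohort has no events; fitting is refused")
  n <- length(time); p <- ncol(Z)
  q <- p + 1L
  Xf <- cbind(`(baseline)` = rep(1, n), Z)

  st <- sort(unique(time))
  m <- length(st)
  g <- match(time, st)
  ## suffix (at-risk) cross-products of (1, z) rows, one per distinct time
  X2 <- Xf[, rep(seq_len(q), q), drop = FALSE] * Xf[, rep(seq_len(q), each = q), drop = FALSE]
  S2 <- rowsum(X2, g, reorder = TRUE)
  S2 <- apply(S2[m:1, , drop = FALSE], 2, cumsum)[m:1, , drop = FALSE]
  S2 <- matrix(S2, nrow = m)
  E2 <- matrix(rowsum(X2 * event, g, reorder = TRUE), nrow = m)
  XdN <- matrix(rowsum(Xf * event, g, reorder = TRUE), nrow = m)
  d <- as.numeric(rowsum(event, g, reorder = TRUE))

  ev <- which(d > 0)
  dB <- matrix(NA_real_, length(ev), q)
  dV <- matrix(NA_real_, length(ev), q)
  used <- 0L
  for (k in seq_along(ev)) {
    j <- ev[k]
    XtX <- matrix(S2[j, ], q, q)
    rc <- rcond(XtX)
    if (!is.finite(rc) || rc < 1e-10) break
    dB[k, ] <- solve(XtX, XdN[j, ])
    Vinc <- solve(XtX, t(solve(XtX, matrix(E2[j, ], q, q))))
    dV[k, ] <- diag(Vinc)
    used <- k
  }
  if (used == 0L)
    stop("design matrix is rank deficient at the first event time (tau = 0); no nonparametric fit is possible")
  tau <- st[ev[used]]
  keep <- seq_len(used)
  B <- apply(dB[keep, , drop = FALSE], 2, cumsum)
  B <- matrix(B, ncol = q, dimnames = list(NULL, colnames(Xf)))
  V <- matrix(apply(dV[keep, , drop = FALSE], 2, cumsum), ncol = q,
              dimnames = list(NULL, colnames(Xf)))

  structure(list(times = st[ev[keep]], B = B, variance = V, tau = tau,
                 n = n, n_events = sum(event), n_events_used = sum(d[ev[keep]]),
                 covariate_names = colnames(Z), encoding = cohort$encoding),
            class = "addhaz_nonp")
}

#' @export
print.addhaz_nonp <- function(x, ...) {
  cat(sprintf("Nonparametric additive hazard fit: n = %d, events = %d (%d used), tau = %g\n",
              x$n, x$n_events, x$n_events_used, x$tau))
  cat("Terms:", paste(colnames(x$B), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one cumulative regression function as a step function
#'
#' @param fit an `"addhaz_nonp"` object.
#' @param term column name (`"(baseline)"` or a covariate name) or index.
#' @return a [hazard_step] with the pointwise variance track.
#' @export
cumreg_step <- function(fit, term = "(baseline)") {
  stopifnot(inherits(fit, "addhaz_nonp"))
  hazard_step(fit$times, fit$B[, term], fit$variance[, term])
}

#' Evaluate all cumulative regression functions at given times
#'
#' Right-continuous evaluation of every column of B at `t`; times beyond the
#' full-rank horizon tau are refused (the estimates are undefined there).
#'
#' @param fit an `"addhaz_nonp"` object.
#' @param t evaluation times, all `<= tau`.
#' @return matrix with one row per time, one column per term.
#' @export
eval_cumreg <- function(fit, t) {
  stopifnot(inherits(fit, "addhaz_nonp"))
  if (any(t > fit$tau))
    stop(sprintf("estimates are undefined beyond tau = %g", fit$tau))
  idx <- findInterval(t, fit$times)
  out <- matrix(0, length(t), ncol(fit$B), dimnames = list(NULL, colnames(fit$B)))
  nz <- idx > 0
  out[nz, ] <- fit$B[idx[nz], , drop = FALSE]
  out
}

#' Pointwise Wald tests for the cumulative regression functions
#'
#' For each term k computes z_k = B_k(t) / sqrt(var_k(t)) with a two-sided
#' normal p-value. Terms with zero estimated variance at `t` are flagged and
#' get NA statistics (the test is undefined there).
#'
#' @param fit an `"addhaz_nonp"` object.
#' @param t a single time `<= tau`.
#' @return data.frame with columns `term,estimate,variance,z,p_value,flagged`.
#' @export
pointwise_tests <- function(fit, t) {
  stopifnot(inherits(fit, "addhaz_nonp"), length(t) == 1)
  if (t > fit$tau) stop(sprintf("t exceeds tau = %g", fit$tau))
  idx <- findInterval(t, fit$times)
  if (idx == 0) stop("no events at or before t; tests undefined")
  est <- fit$B[idx, ]
  v <- fit$variance[idx, ]
  flagged <- v <= 0
  z <- ifelse(flagged, NA_real_, est / sqrt(v))
  data.frame(term = colnames(fit$B), estimate = unname(est),
             variance = unname(v), z = unname(z),
             p_value = unname(2 * stats::pnorm(-abs(z))),
             flagged = unname(flagged), row.names = NULL)
}

#' Write cumulative regression functions as long-format CSV
#'
#' Columns `time,term,estimate,variance`, one row per (event time, term).
#'
#' @param fit an `"addhaz_nonp"` object.
#' @param path output path.
#' @export
write_cumreg_csv <- function(fit, path) {
  df <- data.frame(time = rep(fit$times, ncol(fit$B)),
                   term = rep(colnames(fit$B), each = length(fit$times)),
                   estimate = signif(as.vector(fit$B), 6),
                   variance = signif(as.vector(fit$variance), 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
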