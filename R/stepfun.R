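#' Right-continuous cumulative step function
#'
#' Lightweight carrier for cumulative-hazard-type estimates: a function that
#' is 0 before the first jump time and right-continuous thereafter, with an
#' optional pointwise variance track.
#'
#' @param time strictly increasing jump times (> 0).
#' @param value cumulative values at the jump times.
#' @param variance optional pointwise variances at the jump times.
#' @return An object of class `"hazard_step"`.
#' @export
hazard_step <- function(time, value, variance = NULL) {
  stopifnot(length(time) == length(value))
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("jump times must be strictly increasing")
  if (length(time) && any(time < 0))
    stop("jump times must be nonnegative")
  if (!is.null(variance)) {
    stopifnot(length(variance) == length(time))
    if (any(variance < -1e-12, na.rm = TRUE))
      stop("pointwise variances must be nonnegative")
    variance <- pmax(variance, 0)
  }
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 variance = variance),
            class = "hazard_step")
}

#' Evaluate a step function
#'
#' Right-continuous evaluation: the value at `t` is the cumulative value at
#' the last jump time `<= t`, and 0 before the first jump.
#'
#' @param sf a [hazard_step] object.
#' @param t numeric vector of evaluation times (>= 0).
#' @return numeric vector of values.
#' @export
eval_step <- function(sf, t) {
  stopifnot(inherits(sf, "hazard_step"))
  if (any(t < 0)) stop("evaluation times must be nonnegative")
  idx <- findInterval(t, sf$time)
  out <- numeric(length(t))
  out[idx > 0] <- sf$value[idx[idx > 0]]
  out
}

#' Evaluate the pointwise variance of a step function
#'
#' @inheritParams eval_step
#' @return numeric vector of variances (0 before the first jump).
#' @export
eval_step_var <- function(sf, t) {
  stopifnot(inherits(sf, "hazard_step"))
  if (is.null(sf$variance)) stop("step function carries no variance track")
  idx <- findInterval(t, sf$time)
  out <- numeric(length(t))
  out[idx > 0] <- sf$variance[idx[idx > 0]]
  out
}

#' @export
print.hazard_step <- function(x, ...) {
  cat("Right-continuous step function:", length(x$time), "jumps")
  if (length(x$time))
    cat(sprintf(" on (%g, %g], final value %.6g", 0, max(x$time),
                x$value[length(x$value)]))
  cat("\n")
  invisible(x)
}
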