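#' Right-censored cohort container
#'
#' Bundles per-subject follow-up times, event indicators and an encoded
#' (dummy-coded) covariate matrix, together with the encoding map that
#' produced it. Time 0 is enrollment; events are counted in (0, t]. When an
#' event time ties a censoring time, the event is treated as occurring first
#' (the usual counting-process convention).
#'
#' @param time follow-up durations in years (strictly positive, finite).
#' @param event event indicators, each exactly 0 or 1.
#' @param covariates numeric matrix with one row per subject (may have zero
#'   columns); dummy columns must be 0/1.
#' @param id optional subject identifiers (default `seq_along(time)`).
#' @param encoding optional encoding map as produced by [encode_covariates()]:
#'   a named list, one element per factor, each with `levels`, `reference`
#'   and `columns` (the dummy column names, in level order).
#' @param require_event refuse cohorts with zero events (default TRUE; model
#'   fitting is impossible without events).
#' @return An object of class `"cohort_data"` with elements `time`, `event`,
#'   `covariates`, `covariate_names`, `id`, `encoding`.
#' @export
cohort_data <- function(time, event, covariates = NULL, id = NULL,
                        encoding = NULL, require_event = TRUE) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  n <- length(time)
  if (length(event) != n) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("follow-up times must be strictly positive and finite")
  if (!all(event %in% c(0, 1))) stop("event indicators must be exactly 0 or 1")
  if (is.null(covariates)) covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (nrow(covariates) != n) stop("covariate matrix row count differs from n")
  if (anyNA(covariates)) stop("covariate matrix contains missing values; drop or complete records first")
  if (is.null(colnames(covariates)) && ncol(covariates) > 0)
    colnames(covariates) <- paste0("z", seq_len(ncol(covariates)))
  if (require_event && sum(event) < 1)
    stop("cohort has no events; fitting is refused")
  if (is.null(id)) id <- seq_len(n)
  structure(list(time = time, event = event, covariates = covariates,
                 covariate_names = colnames(covariates),
                 id = id, encoding = encoding),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("Cohort: n = %d subjects, %d events, p = %d covariate columns\n",
              length(x$time), sum(x$event), ncol(x$covariates)))
  if (!is.null(x$encoding))
    cat("Factors:", paste(names(x$encoding), collapse = ", "), "\n")
  invisible(x)
}

#' Number of covariate columns of a cohort
#' @param cohort a [cohort_data] object.
#' @return integer p.
#' @export
n_covariates <- function(cohort) ncol(cohort$covariates)

#' Encode categorical covariates by reference-cell dummy coding
#'
#' Builds the encoded design from a raw table of labeled values. Each factor
#' gets treatment (reference-cell) dummies: one 0/1 column per non-reference
#' level, in declared level order; the reference level maps to all-zero
#' columns. Columns not named in `factor_specs` are carried through as
#' numeric covariates. Column order is deterministic: factors in declaration
#' order (levels in declared order), then numeric columns in input order.
#'
#' Records with missing covariate values are dropped with a warning giving
#' the count (no imputation is attempted).
#'
#' @param raw data.frame with columns `time`, `event`, optionally `id`, plus
#'   covariate columns.
#' @param factor_specs named list; one element per categorical column, each a
#'   list with `levels` (character, declared order) and optional `reference`
#'   (default: first level).
#' @param require_event passed to [cohort_data()].
#' @return A [cohort_data] object carrying the encoding map.
#' @export
encode_covariates <- function(raw, factor_specs = list(), require_event = TRUE) {
  raw <- as.data.frame(raw)
  if (!all(c("time", "event") %in% names(raw)))
    stop("raw table must contain `time` and `event` columns")
  covcols <- setdiff(names(raw), c("id", "time", "event"))
  unknown_specs <- setdiff(names(factor_specs), covcols)
  if (length(unknown_specs))
    stop("factor_specs name columns absent from the table: ",
         paste(unknown_specs, collapse = ", "))

  ## drop records with missing covariates (no imputation)
  cc <- if (length(covcols)) stats::complete.cases(raw[covcols]) else rep(TRUE, nrow(raw))
  if (any(!cc)) {
    warning(sprintf("dropped %d record(s) with missing covariate values", sum(!cc)))
    raw <- raw[cc, , drop = FALSE]
  }

  blocks <- list()
  encoding <- list()
  for (fname in names(factor_specs)) {
    spec <- factor_specs[[fname]]
    lv <- as.character(spec$levels)
    ref <- if (!is.null(spec$reference)) as.character(spec$reference) else lv[1]
    if (!ref %in% lv) stop(sprintf("reference level '%s' not among declared levels of '%s'", ref, fname))
    obs <- as.character(raw[[fname]])
    bad <- setdiff(unique(obs), lv)
    if (length(bad))
      stop(sprintf("unknown level(s) in factor '%s': %s", fname,
                   paste(sQuote(bad), collapse = ", ")))
    nonref <- setdiff(lv, ref)
    cols <- if (length(nonref)) paste(fname, nonref, sep = "=") else character(0)
    if (length(nonref)) {
      m <- vapply(nonref, function(l) as.numeric(obs == l), numeric(length(obs)))
      m <- matrix(m, ncol = length(nonref), dimnames = list(NULL, cols))
      zerocol <- colSums(m) == 0
      if (any(zerocol))
        stop(sprintf("factor '%s': level(s) %s never observed (constant zero dummy column, non-identifiable)",
                     fname, paste(sQuote(nonref[zerocol]), collapse = ", ")))
      blocks[[fname]] <- m
    }
    encoding[[fname]] <- list(levels = lv, reference = ref, columns = cols)
  }
  numcols <- setdiff(covcols, names(factor_specs))
  for (nm in numcols) {
    v <- raw[[nm]]
    if (!is.numeric(v))
      stop(sprintf("column '%s' is not numeric and has no factor spec", nm))
    blocks[[nm]] <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, nm))
  }
  Z <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(numeric(0), nrow = nrow(raw), ncol = 0)
  cohort_data(time = raw$time, event = raw$event, covariates = Z,
              id = if ("id" %in% names(raw)) raw$id else NULL,
              encoding = encoding, require_event = require_event)
}

#' Midinterval event times from a longitudinal visit table
#'
#' Converts per-visit binary test results into right-censored time-to-event
#' rows. If a subject ever tests positive, the event time is the midpoint
#' between the last negative visit preceding the first positive visit and
#' that first positive visit, skipping visits with missing results in
#' between. Otherwise the subject is censored at the last visit with a
#' non-missing result (capped at `admin_end` when finite).
#'
#' Subjects whose first non-missing result is positive (prevalent cases) and
#' subjects with no non-missing result are rejected: they must be excluded
#' upstream, mirroring the exclusion of baseline-positive women in periodic
#' screening cohorts.
#'
#' @param visits data.frame with columns `id`, `visit_time` (years from
#'   enrollment, strictly increasing within subject) and `result` (0/1/NA).
#' @param admin_end administrative censoring horizon in years (default Inf).
#' @return data.frame with columns `id`, `time`, `event`.
#' @export
midinterval_event_times <- function(visits, admin_end = Inf) {
  visits <- as.data.frame(visits)
  stopifnot(all(c("id", "visit_time", "result") %in% names(visits)))
  if (!all(visits$result %in% c(0, 1, NA)))
    stop("visit results must be 0, 1 or NA")
  ord <- order(match(visits$id, unique(visits$id)), visits$visit_time)
  visits <- visits[ord, , drop = FALSE]
  out <- lapply(split(seq_len(nrow(visits)), factor(visits$id, levels = unique(visits$id))),
                function(ix) {
    vt <- visits$visit_time[ix]
    if (any(diff(vt) <= 0))
      stop(sprintf("visit times not strictly increasing for subject %s",
                   visits$id[ix[1]]))
    res <- visits$result[ix]
    keep <- !is.na(res)
    if (!any(keep))
      stop(sprintf("subject %s has no non-missing visit result", visits$id[ix[1]]))
    vt <- vt[keep]; res <- res[keep]
    if (res[1] == 1)
      stop(sprintf("subject %s is positive at the first informative visit (prevalent case); exclude upstream",
                   visits$id[ix[1]]))
    pos <- which(res == 1)
    if (length(pos)) {
      fp <- pos[1]
      lastneg <- max(which(res[seq_len(fp - 1)] == 0))
      c(time = (vt[lastneg] + vt[fp]) / 2, event = 1)
    } else {
      c(time = min(vt[length(vt)], admin_end), event = 0)
    }
  })
  data.frame(id = unique(visits$id),
             time = vapply(out, `[[`, numeric(1), "time"),
             event = vapply(out, `[[`, numeric(1), "event"),
             row.names = NULL)
}

#' Read / write cohort tables
#'
#' The cohort CSV dialect has columns `id,time,event,<covariate columns...>`
#' with a header; `event` must be 0/1. Covariate columns are taken as
#' already-encoded numeric columns.
#'
#' @param path file path.
#' @param require_event passed to [cohort_data()].
#' @return [read_cohort_csv()] returns a [cohort_data] object.
#' @export
read_cohort_csv <- function(path, require_event = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("id", "time", "event") %in% names(df)))
  Z <- as.matrix(df[setdiff(names(df), c("id", "time", "event"))])
  cohort_data(df$time, df$event, Z, id = df$id, require_event = require_event)
}

#' @param cohort a [cohort_data] object.
#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- data.frame(id = cohort$id, time = cohort$time, event = cohort$event,
                   check.names = FALSE)
  if (ncol(cohort$covariates))
    df <- cbind(df, as.data.frame(cohort$covariates, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a visit table CSV (`id,visit_time,result`, result in 0/1/NA)
#' @param path file path.
#' @return data.frame suitable for [midinterval_event_times()].
#' @export
read_visit_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("id", "visit_time", "result") %in% names(df)))
  df
}
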