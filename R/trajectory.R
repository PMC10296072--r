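#' Time-dependent variability of a longitudinal covariate
#'
#' Characterizes a covariate's trajectory by a per-visit variability value
#' \eqn{\gamma_i} (covariate units per day):
#' \deqn{\gamma_i = \frac{v_{i+1} - v_i}{t_{i+1} - t_i}, \quad i = 1, 2}
#' \deqn{\gamma_i = \frac{\sum_{j \in R_i} (v_j - \bar v_i)(t_j - \bar t_i)}
#'   {\sum_{j \in R_i} (t_j - \bar t_i)^2}, \quad i = 3, \dots, f}
#' where \eqn{R_i = \{j : t_j \le t_i\}} indexes all visits up to visit
#' \eqn{i}, and \eqn{\bar v_i, \bar t_i} are means over \eqn{R_i}. For
#' \eqn{i \ge 3} this is the least-squares slope of the covariate on time
#' over the history up to visit \eqn{i}, recomputed per visit.
#'
#' The first two values as defined are forward differences (they use the next
#' visit). For honest out-of-sample prediction a causal variant is available:
#' `causal = TRUE` replaces them with backward differences
#' (\eqn{\gamma_2 = (v_2 - v_1)/(t_2 - t_1)}, \eqn{\gamma_1 = 0}: no slope
#' information exists at the first visit).
#'
#' Records with only two visits (sub-record fragments) are accepted:
#' \eqn{\gamma_1} is the difference quotient and \eqn{\gamma_2} repeats it,
#' there being no third visit to difference against.
#'
#' @param times strictly increasing visit times (days).
#' @param values covariate measurements at those visits.
#' @param causal use backward differences for the first two visits.
#' @return numeric vector \eqn{\gamma_1 \dots \gamma_f}, one per visit.
#' @export
variability_gamma <- function(times, values, causal = FALSE) {
  f <- length(times)
  if (length(values) != f) stop("times and values lengths differ")
  if (f < 2) stop("insufficient data: need at least 2 visits")
  if (any(diff(times) <= 0)) stop("degenerate denominator: visit times must be strictly increasing")
  gamma <- numeric(f)
  if (causal) {
    gamma[1] <- 0
    gamma[2] <- (values[2] - values[1]) / (times[2] - times[1])
  } else {
    gamma[1] <- (values[2] - values[1]) / (times[2] - times[1])
    gamma[2] <- if (f >= 3) (values[3] - values[2]) / (times[3] - times[2]) else gamma[1]
  }
  if (f >= 3) {
    for (i in 3:f) {
      tt <- times[1:i]; vv <- values[1:i]
      gamma[i] <- sum((vv - mean(vv)) * (tt - mean(tt))) / sum((tt - mean(tt))^2)
    }
  }
  gamma
}

#' Feature specification for model encodings
#'
#' Declares which covariates enter a model and in what representation:
#' the current measured value and/or the variability slope
#' ([variability_gamma()]) of each time-varying lab, plus static covariates.
#'
#' @param time_varying time-varying lab names (default: the four
#'   characterized predictors creatinine, eGFR, PCRln, HbA1c).
#' @param static static covariate names.
#' @param use_value include the current value of each time-varying lab.
#' @param use_gamma include the variability slope of each time-varying lab
#'   (feature named `<lab>_gamma`).
#' @param causal_gamma compute slopes causally (see [variability_gamma()]).
#' @param normalization `"none"` or `"zscore"` (fitted on training data by
#'   the consumers, see [zscore_normalize()]).
#' @return object of class `feature_spec`; `feature_names(spec)` lists the
#'   resulting model input columns in order.
#' @export
feature_spec <- function(time_varying = c("creatinine", "egfr", "pcrln", "hba1c"),
                         static = c("age", "gender", "hypertension", "diabetes", "cvd"),
                         use_value = TRUE, use_gamma = FALSE,
                         causal_gamma = FALSE,
                         normalization = c("none", "zscore")) {
  normalization <- match.arg(normalization)
  if (!use_value && !use_gamma && length(static) == 0)
    stop("feature spec selects no features")
  if (anyDuplicated(c(time_varying, static)))
    stop("duplicate covariate names")
  structure(list(time_varying = time_varying, static = static,
                 use_value = use_value, use_gamma = use_gamma,
                 causal_gamma = causal_gamma, normalization = normalization),
            class = "feature_spec")
}

#' @rdname feature_spec
#' @param spec a `feature_spec`.
#' @export
feature_names <- function(spec) {
  stopifnot(inherits(spec, "feature_spec"))
  c(if (spec$use_value) spec$time_varying,
    if (spec$use_gamma) paste0(spec$time_varying, "_gamma"),
    spec$static)
}

#' Encode a cohort as counting-process risk intervals
#'
#' Expands each patient into one half-open (start, stop] interval per visit:
#' the interval runs from the visit to the next visit (or to the endpoint for
#' the last visit) and carries the covariate values in force on it — the
#' values measured at the visit (last observation carried forward), optional
#' variability slopes, and the statics. The event flag is 1 only on the final
#' interval of a dialysis patient. Zero-length final intervals (endpoint
#' exactly at the last visit) are merged into the preceding interval's stop.
#' These rows are the unit consumed by the time-dependent Cox model, and
#' interval stops telescope: the row durations of a patient sum to the
#' endpoint day.
#'
#' @param cohort a `ckd_cohort`.
#' @param spec a [feature_spec()].
#' @return data.frame with columns `id`, `start`, `stop`, `event`, then the
#'   features of `feature_names(spec)`.
#' @export
to_counting_process <- function(cohort, spec = feature_spec()) {
  stopifnot(inherits(cohort, "ckd_cohort"), inherits(spec, "feature_spec"))
  pats <- cohort$patients
  out <- vector("list", nrow(pats))
  for (i in seq_len(nrow(pats))) {
    p <- pats[i, ]
    vis <- cohort$visits[cohort$visits$id == p$id, , drop = FALSE]
    vis <- vis[order(vis$day), , drop = FALSE]
    if (p$endpoint_day < vis$day[1]) stop("endpoint before first visit for id ", p$id)
    f <- nrow(vis)
    start <- vis$day
    stop_ <- c(vis$day[-1], p$endpoint_day)
    ev <- c(rep(0L, f - 1L), p$event)
    # drop zero-length trailing interval (endpoint at the last visit)
    keep <- stop_ > start
    if (all(!keep)) stop("patient ", p$id, " has zero follow-up time")
    if (!keep[f] && f > 1L) { ev[f - 1L] <- ev[f] }
    start <- start[keep]; stop_ <- stop_[keep]; ev <- ev[keep]
    row <- data.frame(id = p$id, start = start, stop = stop_, event = ev)
    kept <- which(keep)
    if (spec$use_value)
      for (v in spec$time_varying) row[[v]] <- vis[[v]][kept]
    if (spec$use_gamma)
      for (v in spec$time_varying) {
        g <- if (f >= 2) variability_gamma(vis$day, vis[[v]], causal = spec$causal_gamma)
             else 0
        row[[paste0(v, "_gamma")]] <- g[kept]
      }
    for (v in spec$static) row[[v]] <- p[[v]]
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' Landmark feature matrix (one row per patient)
#'
#' Patient-level covariate summary used by the forest and neural models:
#' statics plus, for each time-varying lab, the last observed value and (if
#' requested) the variability slope at the last visit — the least-squares
#' slope over the full observed trajectory.
#'
#' @inheritParams to_counting_process
#' @return data.frame with `id`, `time` (endpoint day), `event`, then the
#'   features of `feature_names(spec)`.
#' @export
landmark_features <- function(cohort, spec = feature_spec()) {
  stopifnot(inherits(cohort, "ckd_cohort"), inherits(spec, "feature_spec"))
  pats <- cohort$patients
  out <- vector("list", nrow(pats))
  for (i in seq_len(nrow(pats))) {
    p <- pats[i, ]
    vis <- cohort$visits[cohort$visits$id == p$id, , drop = FALSE]
    vis <- vis[order(vis$day), , drop = FALSE]
    row <- data.frame(id = p$id, time = p$endpoint_day, event = p$event)
    if (spec$use_value)
      for (v in spec$time_varying) row[[v]] <- vis[[v]][nrow(vis)]
    if (spec$use_gamma)
      for (v in spec$time_varying) {
        row[[paste0(v, "_gamma")]] <-
          if (nrow(vis) >= 2)
            variability_gamma(vis$day, vis[[v]], causal = spec$causal_gamma)[nrow(vis)]
          else 0
      }
    for (v in spec$static) row[[v]] <- p[[v]]
    out[[i]] <- row
  }
  do.call(rbind, out)
}

is_binary_col <- function(x) all(x %in% c(0, 1))

#' Z-score normalization fitted on training rows
#'
#' Estimates per-feature mean and standard deviation on `train` only and
#' applies the transform to `apply_to` (defaults to `train` itself). Binary
#' 0/1 columns and the bookkeeping columns (`id`, `start`, `stop`, `time`,
#' `event`) are left untouched. A zero-variance continuous feature either
#' stops with an error or is dropped, per `on_constant`.
#'
#' @param train data.frame of training rows.
#' @param apply_to data.frame to transform with the training parameters.
#' @param cols columns to consider (default: all numeric, non-bookkeeping).
#' @param on_constant `"error"` (default) or `"drop"` for zero-variance
#'   features.
#' @return the transformed `apply_to`, with attributes `center` and `scale`
#'   recording the training parameters.
#' @export
zscore_normalize <- function(train, apply_to = train, cols = NULL,
                             on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  if (nrow(train) == 0) stop("empty training rows")
  bookkeeping <- c("id", "start", "stop", "time", "event")
  if (is.null(cols))
    cols <- setdiff(names(train)[vapply(train, is.numeric, logical(1))], bookkeeping)
  cols <- cols[!vapply(train[cols], is_binary_col, logical(1))]
  center <- vapply(train[cols], mean, numeric(1))
  scale <- vapply(train[cols], sd, numeric(1))
  constant <- !is.finite(scale) | scale <= 0
  if (any(constant)) {
    if (on_constant == "error")
      stop("zero-variance feature(s): ", paste(cols[constant], collapse = ", "))
    apply_to <- apply_to[setdiff(names(apply_to), cols[constant])]
    cols <- cols[!constant]; center <- center[!constant]; scale <- scale[!constant]
  }
  for (v in cols) apply_to[[v]] <- (apply_to[[v]] - center[[v]]) / scale[[v]]
  attr(apply_to, "center") <- center
  attr(apply_to, "scale") <- scale
  apply_to
}

#' Simple imputation of missing lab values
#'
#' Fills gaps in the time-varying labs of a cohort read from file. The
#' generator produces complete data, so this is plumbing for external inputs.
#' `carry_forward` uses the latest earlier visit of the same patient, falling
#' back to the patient mean for leading gaps; `mean` uses the patient mean
#' throughout. A covariate missing at every visit of a patient cannot be
#' imputed and is an error.
#'
#' @param cohort a `ckd_cohort`.
#' @param method `"carry_forward"` (default) or `"mean"`.
#' @return the cohort with no missing lab values.
#' @export
impute_simple <- function(cohort, method = c("carry_forward", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "ckd_cohort"))
  tv <- intersect(time_varying_names(), names(cohort$visits))
  for (pid in unique(cohort$visits$id)) {
    sel <- which(cohort$visits$id == pid)
    for (v in tv) {
      x <- cohort$visits[[v]][sel]
      if (!anyNA(x)) next
      if (all(is.na(x)))
        stop("unimputable: '", v, "' missing at every visit of patient ", pid)
      pm <- mean(x, na.rm = TRUE)
      if (method == "mean") {
        x[is.na(x)] <- pm
      } else {
        for (k in seq_along(x)) {
          if (is.na(x[k])) x[k] <- if (k > 1) x[k - 1] else pm
        }
      }
      cohort$visits[[v]][sel] <- x
    }
  }
  cohort
}
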