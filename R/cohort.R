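#' Configuration for the synthetic longitudinal CKD cohort generator
#'
#' Describes a cohort of stage 3-5 chronic kidney disease patients followed
#' roughly every 90 days, with dialysis as the event and right censoring
#' otherwise. Time-varying labs follow patient-specific linear trajectories
#' \eqn{v(t) = a + b t + \varepsilon}; the event hazard is log-linear in the
#' covariate values in force,
#' \eqn{\lambda(t) = \lambda_0 \exp(\sum_k \beta_k v_k(t))}, with values held
#' piecewise-constant between visits, so event times admit exact
#' inverse-transform sampling.
#'
#' @param n_patients number of patients to generate.
#' @param visit_interval_days nominal days between clinic visits (default 90).
#' @param visit_jitter_days uniform jitter applied to each scheduled visit;
#'   must be smaller than half the interval so times stay strictly increasing.
#' @param max_followup_days administrative censoring time (default 2000,
#'   endpoints are observed beyond the primary horizon as in the study design).
#' @param horizon_days primary classification horizon (default 1095, i.e.
#'   progression within 3 years).
#' @param stage_fractions simplex weights over CKD stages 3/4/5; default
#'   matches the study mix 352/69/76 of 497.
#' @param true_beta named log-hazard coefficients. Names may be time-varying
#'   covariates (current measured value), static covariates, or products
#'   `"a:b"` of two such names (interaction on current values).
#' @param baseline_hazard_rate per-day baseline hazard \eqn{\lambda_0}.
#' @param trajectory_params per-covariate trajectory distributions, see
#'   [default_trajectory_params()].
#' @param censor_rate per-day rate of independent exponential random
#'   censoring (0 disables it).
#' @param censor_beta optional named coefficients making the censoring hazard
#'   covariate-dependent (same name conventions as `true_beta`); `NULL` keeps
#'   censoring independent.
#' @param seed integer RNG seed; generation is fully deterministic given it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          visit_interval_days = 90,
                          visit_jitter_days = 7,
                          max_followup_days = 2000,
                          horizon_days = 1095,
                          stage_fractions = c(`3` = 352, `4` = 69, `5` = 76) / 497,
                          true_beta = c(egfr = -0.02, creatinine = 0.38, pcrln = 0.10),
                          baseline_hazard_rate = 4.5e-5,
                          trajectory_params = default_trajectory_params(),
                          censor_rate = 1 / 4000,
                          censor_beta = NULL,
                          seed = 1L) {
  if (length(n_patients) != 1 || n_patients < 1 || n_patients != round(n_patients))
    stop("n_patients must be a positive integer")
  if (abs(sum(stage_fractions) - 1) > 1e-12) stop("stage_fractions must sum to 1")
  if (any(stage_fractions < 0)) stop("stage_fractions must be non-negative")
  if (visit_interval_days <= 0 || max_followup_days <= 0 || horizon_days <= 0 ||
      baseline_hazard_rate <= 0)
    stop("rates, intervals and horizons must be strictly positive")
  if (visit_jitter_days < 0 || visit_jitter_days >= visit_interval_days)
    stop("visit_jitter_days must be non-negative and smaller than visit_interval_days")
  if (censor_rate < 0) stop("censor_rate must be non-negative")
  structure(list(n_patients = as.integer(n_patients),
                 visit_interval_days = visit_interval_days,
                 visit_jitter_days = visit_jitter_days,
                 max_followup_days = max_followup_days,
                 horizon_days = horizon_days,
                 stage_fractions = stage_fractions,
                 true_beta = true_beta,
                 baseline_hazard_rate = baseline_hazard_rate,
                 trajectory_params = trajectory_params,
                 censor_rate = censor_rate,
                 censor_beta = censor_beta,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default trajectory distributions for the synthetic generator
#'
#' Per-covariate intercept/slope/noise distributions. Intercepts of the
#' staging labs (eGFR, serum creatinine, PCRln) are stage-specific and match
#' the published per-stage means and spreads; eGFR intercepts are truncated
#' into the KDIGO band of the drawn stage so baseline staging is consistent.
#' Slopes are per day: on average eGFR declines (about -3 mL/min/1.73m2 per
#' year) and creatinine rises, with between-patient spread so some patients
#' are stable and some progress quickly.
#'
#' @return named list; each element has `intercept_mean` (length 1 or 3, one
#'   per stage), `intercept_sd`, `slope_mean`, `slope_sd`, `noise_sd`,
#'   `lower` (floor for measured values).
#' @export
default_trajectory_params <- function() {
  list(
    egfr = list(intercept_mean = c(44.73, 22.59, 10.15),
                intercept_sd = c(7.0, 3.8, 3.2),
                slope_mean = -3 / 365, slope_sd = 3 / 365,
                noise_sd = 2.0, lower = 1),
    creatinine = list(intercept_mean = c(1.49, 2.56, 6.27),
                      intercept_sd = c(0.25, 0.55, 2.0),
                      slope_mean = 0.3 / 365, slope_sd = 0.4 / 365,
                      noise_sd = 0.15, lower = 0.4),
    pcrln = list(intercept_mean = c(5.63, 6.02, 6.78),
                 intercept_sd = c(1.4, 1.8, 1.8),
                 slope_mean = 0.1 / 365, slope_sd = 0.3 / 365,
                 noise_sd = 0.35, lower = 0),
    hba1c = list(intercept_mean = 6.6, intercept_sd = 1.4,
                 slope_mean = 0, slope_sd = 0.1 / 365,
                 noise_sd = 0.3, lower = 4),
    sbp = list(intercept_mean = 137, intercept_sd = 14,
               slope_mean = 0, slope_sd = 2 / 365,
               noise_sd = 9, lower = 70),
    dbp = list(intercept_mean = 72.5, intercept_sd = 10,
               slope_mean = 0, slope_sd = 1 / 365,
               noise_sd = 6, lower = 35),
    bmi = list(intercept_mean = 26.6, intercept_sd = 4.5,
               slope_mean = 0, slope_sd = 0.5 / 365,
               noise_sd = 0.6, lower = 14)
  )
}

#' CKD stage from baseline eGFR
#'
#' KDIGO bands restricted to the study population: stage 3 for
#' 30 <= eGFR < 60, stage 4 for 15 <= eGFR < 30, stage 5 for eGFR < 15
#' (mL/min/1.73 m2). Stages 1-2 (eGFR >= 60) are outside the study population
#' and rejected.
#'
#' @param egfr baseline eGFR, > 0 (vectorized).
#' @return integer stage in \{3, 4, 5\}.
#' @export
assign_stage <- function(egfr) {
  if (any(egfr <= 0)) stop("eGFR must be positive")
  if (any(egfr >= 60)) stop("eGFR >= 60: stages 1-2 are excluded from this population")
  ifelse(egfr >= 30, 3L, ifelse(egfr >= 15, 4L, 5L))
}

static_names <- function() c("age", "gender", "hypertension", "diabetes", "cvd", "stage")
time_varying_names <- function() c("creatinine", "egfr", "pcrln", "hba1c", "sbp", "dbp", "bmi")

# Linear predictor of a log-linear hazard for one patient's covariates in
# force. `values` is a named numeric vector mixing statics and current
# time-varying values; coefficient names "a:b" denote products.
hazard_lp <- function(beta, values) {
  if (is.null(beta) || length(beta) == 0) return(0)
  lp <- 0
  for (nm in names(beta)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% names(values)))
      stop("unknown covariate in hazard coefficients: ", nm)
    lp <- lp + beta[[nm]] * prod(values[parts])
  }
  lp
}

# Exact inverse-transform sample of an event time under a piecewise-constant
# hazard: `haz` per-day hazards on intervals delimited by `breaks`
# (0 = breaks[1] < ... < breaks[K+1]); the last hazard extends to Inf.
sample_pwc_event <- function(haz, breaks, u = runif(1)) {
  target <- -log(u)
  acc <- 0
  for (k in seq_along(haz)) {
    len <- if (k < length(haz)) breaks[k + 1] - breaks[k] else Inf
    step <- haz[k] * len
    if (acc + step >= target) return(breaks[k] + (target - acc) / haz[k])
    acc <- acc + step
  }
  Inf
}

#' Generate a synthetic longitudinal CKD cohort
#'
#' Draws patients (statics, stage, visit schedule, lab trajectories), then
#' samples the dialysis time from the configured log-linear hazard on the
#' measured covariate values held piecewise-constant between visits, and
#' applies independent random censoring plus administrative censoring at
#' `max_followup_days`. Visits after the endpoint are discarded, so every
#' patient keeps at least the baseline visit and `endpoint_day` is never
#' earlier than the last retained visit.
#'
#' @param config a [cohort_config()].
#' @return object of class `ckd_cohort`: list with
#'   \describe{
#'     \item{patients}{data.frame, one row per patient: `id`, statics
#'       (`age`, `gender`, `hypertension`, `diabetes`, `cvd`, `stage`),
#'       `event` (1 = dialysis) and `endpoint_day`.}
#'     \item{visits}{data.frame, one row per clinic visit: `id`, `day`, and
#'       the measured time-varying labs.}
#'     \item{truth}{data.frame of the latent per-patient trajectory
#'       intercepts/slopes (`a_*`, `b_*`), for oracle checks.}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  tp <- config$trajectory_params
  tv <- names(tp)
  n <- config$n_patients

  patients <- vector("list", n)
  visit_rows <- vector("list", n)
  truth <- vector("list", n)
  hyp_p <- c(0.65, 0.78, 0.81); dia_p <- c(0.59, 0.49, 0.49); cvd_p <- c(0.16, 0.10, 0.02)

  for (i in seq_len(n)) {
    stage_idx <- sample.int(3L, 1L, prob = config$stage_fractions)
    stage <- c(3L, 4L, 5L)[stage_idx]
    age <- min(max(rnorm(1, 80, 12), 40), 103)
    statics <- c(age = age,
                 gender = rbinom(1, 1, 0.65),
                 hypertension = rbinom(1, 1, hyp_p[stage_idx]),
                 diabetes = rbinom(1, 1, dia_p[stage_idx]),
                 cvd = rbinom(1, 1, cvd_p[stage_idx]),
                 stage = stage)

    # latent linear trajectory per time-varying covariate
    a <- numeric(length(tv)); b <- numeric(length(tv)); names(a) <- names(b) <- tv
    for (v in tv) {
      p <- tp[[v]]
      im <- if (length(p$intercept_mean) == 3) p$intercept_mean[stage_idx] else p$intercept_mean
      isd <- if (length(p$intercept_sd) == 3) p$intercept_sd[stage_idx] else p$intercept_sd
      a[v] <- rnorm(1, im, isd)
      b[v] <- rnorm(1, p$slope_mean, p$slope_sd)
    }
    # keep the baseline eGFR inside the drawn stage's KDIGO band
    band <- switch(stage_idx, c(30, 59.9), c(15, 29.9), c(1.5, 14.9))
    a["egfr"] <- min(max(a["egfr"], band[1]), band[2])

    # visit schedule out to administrative censoring
    k <- 0:floor(config$max_followup_days / config$visit_interval_days)
    days <- k * config$visit_interval_days +
      c(0, runif(length(k) - 1, -config$visit_jitter_days, config$visit_jitter_days))
    days <- days[days <= config$max_followup_days]
    days <- days[c(TRUE, diff(days) > 0)]

    vals <- sapply(tv, function(v) {
      p <- tp[[v]]
      pmax(a[v] + b[v] * days + rnorm(length(days), 0, p$noise_sd), p$lower)
    })
    vals <- matrix(vals, nrow = length(days), dimnames = list(NULL, tv))

    # piecewise-constant hazard from the measured values in force
    lp <- vapply(seq_along(days), function(j)
      hazard_lp(config$true_beta, c(statics, vals[j, ])), numeric(1))
    haz <- config$baseline_hazard_rate * exp(lp)
    t_event <- sample_pwc_event(haz, days)

    t_cens <- if (config$censor_rate > 0) {
      if (is.null(config$censor_beta)) rexp(1, config$censor_rate)
      else {
        clp <- vapply(seq_along(days), function(j)
          hazard_lp(config$censor_beta, c(statics, vals[j, ])), numeric(1))
        sample_pwc_event(config$censor_rate * exp(clp), days)
      }
    } else Inf

    endpoint <- min(t_event, t_cens, config$max_followup_days)
    event <- as.integer(t_event <= min(t_cens, config$max_followup_days))
    keep <- days <= endpoint
    keep[1] <- TRUE

    patients[[i]] <- data.frame(id = i, t(statics), event = event,
                                endpoint_day = endpoint)
    visit_rows[[i]] <- data.frame(id = i, day = days[keep],
                                  vals[keep, , drop = FALSE], row.names = NULL)
    truth[[i]] <- data.frame(id = i, t(setNames(a, paste0("a_", tv))),
                             t(setNames(b, paste0("b_", tv))),
                             t_event = t_event)
  }

  structure(list(patients = do.call(rbind, patients),
                 visits = do.call(rbind, visit_rows),
                 truth = do.call(rbind, truth),
                 config = config),
            class = "ckd_cohort")
}

#' @export
print.ckd_cohort <- function(x, ...) {
  np <- nrow(x$patients)
  cat("ckd_cohort:", np, "patients,", nrow(x$visits), "visits,",
      sum(x$patients$event), "dialysis events\n")
  cat("stage mix:", paste(names(table(x$patients$stage)),
                          table(x$patients$stage), sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Exclude patients with insufficient follow-up
#'
#' Drops patients with fewer than `min_visits` clinic visits, mirroring the
#' study's exclusion of records with less than 3 visits. Patient order is
#' preserved and the number removed is reported via a message.
#'
#' @param cohort a `ckd_cohort`.
#' @param min_visits minimum number of visits to retain a patient (>= 1).
#' @return the filtered `ckd_cohort`.
#' @export
apply_exclusions <- function(cohort, min_visits = 3) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  if (min_visits < 1) stop("min_visits must be >= 1")
  counts <- table(cohort$visits$id)
  keep_ids <- as.numeric(names(counts))[counts >= min_visits]
  removed <- nrow(cohort$patients) - sum(cohort$patients$id %in% keep_ids)
  message(sprintf("apply_exclusions: removed %d of %d patients (< %d visits)",
                  removed, nrow(cohort$patients), min_visits))
  cohort$patients <- cohort$patients[cohort$patients$id %in% keep_ids, , drop = FALSE]
  cohort$visits <- cohort$visits[cohort$visits$id %in% keep_ids, , drop = FALSE]
  if (!is.null(cohort$truth))
    cohort$truth <- cohort$truth[cohort$truth$id %in% keep_ids, , drop = FALSE]
  cohort
}

#' Oracle survival function of a generated patient
#'
#' Computes the patient's true survival curve
#' \eqn{S(t) = \exp(-\int_0^t \lambda(s) ds)} implied by the generator's own
#' piecewise-constant hazard on the measured covariate path. Only available
#' for cohorts carrying their generating `config`; used as a ground-truth
#' reference model in validation checks.
#'
#' @param cohort a generated `ckd_cohort`.
#' @param id patient id.
#' @param times evaluation times.
#' @return numeric survival probabilities at `times`.
#' @export
oracle_survival <- function(cohort, id, times) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  if (is.null(cohort$config)) stop("cohort carries no generating config")
  cfg <- cohort$config
  vis <- cohort$visits[cohort$visits$id == id, , drop = FALSE]
  if (nrow(vis) == 0) stop("unknown patient id")
  pat <- cohort$patients[cohort$patients$id == id, , drop = FALSE]
  statics <- unlist(pat[1, static_names()])
  tv <- intersect(time_varying_names(), names(vis))
  lp <- vapply(seq_len(nrow(vis)), function(j)
    hazard_lp(cfg$true_beta, c(statics, unlist(vis[j, tv]))), numeric(1))
  haz <- cfg$baseline_hazard_rate * exp(lp)
  breaks <- vis$day
  vapply(times, function(t) {
    if (t <= 0) return(1)
    ints <- pmax(pmin(t, c(breaks[-1], Inf)) - breaks, 0)
    exp(-sum(haz * ints))
  }, numeric(1))
}
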