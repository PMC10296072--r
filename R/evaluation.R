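derive_seed <- function(seed, k) as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483647L)

apply_norm <- function(df, center, scale) {
  for (v in names(center)) df[[v]] <- (df[[v]] - center[[v]]) / scale[[v]]
  df
}

# survival value of a step curve given as (grid, matrix of rows) at time t,
# right-continuous, 1 before the first grid point
step_at <- function(grid, values, t) {
  if (length(grid) == 0) return(rep(1, nrow(values)))
  idx <- findInterval(t, grid)
  if (idx == 0) rep(1, nrow(values)) else values[, idx]
}

default_cox_spec <- function() feature_spec(normalization = "zscore")
default_rsf_spec <- function() feature_spec(use_gamma = TRUE)
default_ann_spec <- function()
  feature_spec(time_varying = c("creatinine", "egfr", "pcrln", "hba1c", "bmi"))

# Fit one model on the training patients and predict the test patients.
# Returns risk scores (higher = earlier event), survival at the horizon,
# survival at each test patient's own endpoint, and full predicted curves.
fit_predict_one <- function(model, cohort, train_ids, test_ids, seed,
                            horizon_days, cox_spec, rsf_spec, ann_spec,
                            control, mlp) {
  test_pat <- cohort$patients[match(test_ids, cohort$patients$id), ]
  if (model == "cox") {
    rows <- to_counting_process(cohort, cox_spec)
    feats <- feature_names(cox_spec)
    tr <- rows[rows$id %in% train_ids, , drop = FALSE]
    te <- rows[rows$id %in% test_ids, , drop = FALSE]
    if (cox_spec$normalization == "zscore") {
      trn <- zscore_normalize(tr)
      te <- apply_norm(te, attr(trn, "center"), attr(trn, "scale"))
      tr <- trn
    }
    fit <- fit_cox_td(tr, features = feats)
    curves <- lapply(test_ids, function(pid)
      predict_survival_cox(fit, te[te$id == pid, , drop = FALSE]))
    # risk score: linear predictor at the most recent covariates
    risk <- vapply(test_ids, function(pid) {
      pr <- te[te$id == pid, , drop = FALSE]
      drop(as.matrix(pr[nrow(pr), feats]) %*% fit$beta)
    }, numeric(1))
  } else if (model == "rsf") {
    lm_df <- landmark_features(cohort, rsf_spec)
    tr <- lm_df[lm_df$id %in% train_ids, , drop = FALSE]
    te <- lm_df[lm_df$id %in% test_ids, , drop = FALSE]
    fit <- fit_forest(tr, control = control, seed = seed)
    chf <- predict_chf(fit, te)
    risk <- rowSums(chf)
    surv <- exp(-chf)
    curves <- lapply(seq_along(test_ids), function(i)
      new_survcurve(fit$grid, surv[i, ]))
  } else if (model == "ann") {
    lm_df <- landmark_features(cohort, ann_spec)
    feats <- feature_names(ann_spec)
    tr <- lm_df[lm_df$id %in% train_ids, , drop = FALSE]
    te <- lm_df[lm_df$id %in% test_ids, , drop = FALSE]
    trn <- zscore_normalize(tr)
    te <- apply_norm(te, attr(trn, "center"), attr(trn, "scale"))
    horizons <- ann_horizons(horizon_days)
    if (is.null(mlp)) mlp <- mlp_config(seed = seed)
    mlp$input_dim <- length(feats)
    mlp$output_dim <- length(horizons)
    mlp$seed <- seed
    ds <- build_pseudo_dataset(trn, horizons = horizons, features = feats)
    fit <- fit_mlp(ds$x, ds$y, mlp)
    m <- predict_survival_ann(fit, te[feats])
    risk <- 1 - m[, ncol(m)]
    curves <- lapply(seq_along(test_ids), function(i) new_survcurve(horizons, m[i, ]))
  } else stop("unknown model: ", model)
  surv_h <- vapply(curves, function(cv) curve_eval(cv, horizon_days), numeric(1))
  surv_e <- vapply(seq_along(test_ids), function(i)
    curve_eval(curves[[i]], test_pat$endpoint_day[i]), numeric(1))
  list(risk = risk, surv_horizon = surv_h, surv_endpoint = surv_e,
       curves = setNames(curves, test_ids))
}

assign_folds <- function(ids, events, K, seed) {
  n <- length(ids)
  if (K < 2 || K > n) stop("K must be between 2 and the number of patients")
  set.seed(seed)
  for (try in 1:50) {
    fold <- sample(rep_len(seq_len(K), n))
    ev_per_fold <- tapply(events, fold, sum)
    train_ev <- sum(events) - ev_per_fold
    if (all(ev_per_fold >= 1) && all(train_ev >= 1)) {
      if (try > 1) warning("fold assignment redrawn ", try - 1,
                           " time(s) to place an event in every fold")
      return(fold)
    }
  }
  stop("could not draw folds with at least one event each")
}

#' K-fold cross-validated concordance of the three survival models
#'
#' Randomly partitions patients (never interval rows) into K folds; for each
#' fold, features are normalized on the training patients only, each model is
#' fitted on them, and the held-out patients are scored with the pairwise
#' concordance index using the model's risk score (Cox: linear predictor at
#' the most recent covariates; forest: out-of-grid ensemble mortality;
#' network: 1 minus marginal survival at the horizon). Out-of-fold survival
#' predictions at the horizon and at each patient's own endpoint are retained
#' for downstream cut-off classification and probability summaries.
#'
#' @param cohort a `ckd_cohort` (after [apply_exclusions()]).
#' @param models character subset of `c("cox", "rsf", "ann")`, and/or names
#'   of `extra_models`.
#' @param K number of folds (default 5).
#' @param seed seed controlling the partition and all model fits.
#' @param horizon_days classification horizon; defaults to the cohort
#'   config's (1095 otherwise).
#' @param cox_spec,rsf_spec,ann_spec feature specifications per model; the
#'   defaults are z-scored current labs + statics for Cox, current labs +
#'   variability slopes + statics for the forest, and the ten-predictor set
#'   (five labs + five statics) for the network.
#' @param control [rsf_control()] for the forest.
#' @param mlp [mlp_config()] for the network (seed/dims are set per fold).
#' @param extra_models named list of custom scorers
#'   `function(train, test, horizon_days)` over landmark data.frames
#'   returning a list with `risk` (and optionally `surv_horizon`,
#'   `surv_endpoint`); useful as oracle or null reference models.
#' @return object of class `ckd_cv`: `metrics` (fold x model C-indexes),
#'   `mean` (per-model average C), `predictions` (out-of-fold per-patient
#'   table), `folds`, and the call parameters.
#' @export
kfold_cindex <- function(cohort, models = c("cox", "rsf", "ann"), K = 5,
                         seed = 1L, horizon_days = NULL,
                         cox_spec = default_cox_spec(),
                         rsf_spec = default_rsf_spec(),
                         ann_spec = default_ann_spec(),
                         control = rsf_control(), mlp = NULL,
                         extra_models = NULL) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  if (is.null(horizon_days))
    horizon_days <- if (!is.null(cohort$config)) cohort$config$horizon_days else 1095
  pats <- cohort$patients
  fold <- assign_folds(pats$id, pats$event, K, seed)
  lm_plain <- if (!is.null(extra_models))
    landmark_features(cohort, feature_spec(time_varying = time_varying_names(),
                                           use_gamma = TRUE))

  metrics <- list(); preds <- list()
  for (k in seq_len(K)) {
    test_ids <- pats$id[fold == k]
    train_ids <- pats$id[fold != k]
    test_pat <- pats[match(test_ids, pats$id), ]
    for (m in models) {
      sub_seed <- derive_seed(seed, k * 100 + match(m, models))
      if (m %in% c("cox", "rsf", "ann")) {
        fp <- fit_predict_one(m, cohort, train_ids, test_ids, sub_seed,
                              horizon_days, cox_spec, rsf_spec, ann_spec,
                              control, mlp)
      } else if (!is.null(extra_models[[m]])) {
        fp <- extra_models[[m]](lm_plain[lm_plain$id %in% train_ids, , drop = FALSE],
                                lm_plain[lm_plain$id %in% test_ids, , drop = FALSE],
                                horizon_days)
        if (is.null(fp$surv_horizon)) fp$surv_horizon <- rep(NA_real_, length(test_ids))
        if (is.null(fp$surv_endpoint)) fp$surv_endpoint <- rep(NA_real_, length(test_ids))
      } else stop("unknown model: ", m)
      ci <- concordance_index(test_pat$endpoint_day, test_pat$event,
                              fp$risk, direction = "risk")
      metrics[[length(metrics) + 1L]] <- data.frame(fold = k, model = m, cindex = ci)
      preds[[length(preds) + 1L]] <- data.frame(
        id = test_ids, fold = k, model = m, risk = fp$risk,
        surv_horizon = fp$surv_horizon, surv_endpoint = fp$surv_endpoint,
        time = test_pat$endpoint_day, event = test_pat$event)
    }
  }
  metrics <- do.call(rbind, metrics)
  structure(list(metrics = metrics,
                 mean = tapply(metrics$cindex, metrics$model, mean)[unique(metrics$model)],
                 predictions = do.call(rbind, preds),
                 folds = split(pats$id, fold),
                 K = K, seed = seed, horizon_days = horizon_days),
            class = "ckd_cv")
}

#' @export
print.ckd_cv <- function(x, ...) {
  cat(x$K, "-fold cross-validated C-index (seed ", x$seed, ")\n", sep = "")
  wide <- tapply(x$metrics$cindex, list(x$metrics$model, x$metrics$fold), identity)
  wide <- cbind(wide, average = rowMeans(wide))
  print(round(wide, 3))
  invisible(x)
}

#' F1 score from precision and sensitivity
#'
#' \eqn{F_1 = 2 \cdot precision \cdot sensitivity / (precision + sensitivity)};
#' `NA` when the denominator is zero.
#'
#' @param precision,sensitivity values in \[0, 1\] (vectorized).
#' @return F1 score.
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(precision + sensitivity > 0,
         2 * precision * sensitivity / (precision + sensitivity), NA_real_)
}

#' Cut-off classification metrics at the outcome horizon
#'
#' Classifies a patient as "dialysis within the horizon" when the predicted
#' non-dialysis (survival) probability at the horizon falls below the cut-off.
#' Ground truth: positive if the event was observed by the horizon, negative
#' if follow-up passed the horizon event-free; patients censored before the
#' horizon carry no within-horizon outcome and are excluded (their count is
#' reported in the result).
#'
#' @param surv_horizon predicted survival probabilities at the horizon, in
#'   \[0, 1\] (clip network marginals beforehand if using the
#'   direct-marginal head).
#' @param time follow-up times.
#' @param event event indicators.
#' @param cutoff classification threshold on the survival probability.
#' @param horizon_days outcome horizon (default 1095).
#' @return one-row data.frame: `cutoff`, `sensitivity`, `specificity`,
#'   `accuracy`, `precision`, `f1`, the confusion counts `tp/fp/tn/fn`, and
#'   `n_excluded` (censored before the horizon).
#' @export
cutoff_classification <- function(surv_horizon, time, event, cutoff,
                                  horizon_days = 1095) {
  if (any(surv_horizon < 0 | surv_horizon > 1, na.rm = TRUE))
    stop("predictions must lie in [0, 1]")
  pos <- event == 1 & time <= horizon_days
  neg <- time > horizon_days
  usable <- pos | neg
  pred_pos <- surv_horizon < cutoff
  tp <- sum(usable & pos & pred_pos); fn <- sum(usable & pos & !pred_pos)
  fp <- sum(usable & neg & pred_pos); tn <- sum(usable & neg & !pred_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  acc <- (tp + tn) / max(tp + tn + fp + fn, 1)
  data.frame(cutoff = cutoff, sensitivity = sens, specificity = spec,
             accuracy = acc, precision = prec,
             f1 = f1_score(prec, sens),
             tp = tp, fp = fp, tn = tn, fn = fn,
             n_excluded = sum(!usable))
}

#' Cut-off metric table over models and thresholds
#'
#' Applies [cutoff_classification()] to the out-of-fold horizon predictions
#' of a cross-validation run, for each model and cut-off.
#'
#' @param cv a `ckd_cv` from [kfold_cindex()].
#' @param cutoffs probability thresholds (default 0.65, 0.70, 0.75).
#' @return data.frame with one row per model and cut-off.
#' @export
cutoff_table <- function(cv, cutoffs = c(0.65, 0.70, 0.75)) {
  stopifnot(inherits(cv, "ckd_cv"))
  out <- list()
  for (m in unique(cv$predictions$model)) {
    pm <- cv$predictions[cv$predictions$model == m &
                           is.finite(cv$predictions$surv_horizon), , drop = FALSE]
    if (nrow(pm) == 0) next
    for (ct in cutoffs) {
      row <- cutoff_classification(pmin(pmax(pm$surv_horizon, 0), 1),
                                   pm$time, pm$event, ct, cv$horizon_days)
      out[[length(out) + 1L]] <- cbind(model = m, row)
    }
  }
  do.call(rbind, out)
}

#' Individual Kaplan-Meier-style validation of a held-out patient
#'
#' Fits the requested models on every patient except `id`, predicts the
#' held-out patient's non-dialysis probability curve over \[0, endpoint\],
#' and scores consistency with the true outcome at the 0.70 rule: a censored
#' patient is consistently predicted when the curve is at least `cutoff` at
#' the endpoint, a dialysis patient when it is below. Training without the
#' patient is built in, so leakage is impossible by construction.
#'
#' @param cohort a `ckd_cohort`.
#' @param id the held-out patient.
#' @param models models to validate (as in [kfold_cindex()]).
#' @param cutoff consistency threshold (default 0.70).
#' @param seed seed for the model fits.
#' @inheritParams kfold_cindex
#' @return list with `verdicts` (data.frame: model, surv_at_endpoint,
#'   consistent), `curves` (named list of `survcurve` per model), `endpoint_day`
#'   and `event`.
#' @export
individual_km_validation <- function(cohort, id, models = c("cox", "rsf", "ann"),
                                     cutoff = 0.70, seed = 1L,
                                     horizon_days = NULL,
                                     cox_spec = default_cox_spec(),
                                     rsf_spec = default_rsf_spec(),
                                     ann_spec = default_ann_spec(),
                                     control = rsf_control(), mlp = NULL) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  if (!id %in% cohort$patients$id) stop("unknown patient id")
  if (is.null(horizon_days))
    horizon_days <- if (!is.null(cohort$config)) cohort$config$horizon_days else 1095
  pat <- cohort$patients[cohort$patients$id == id, ]
  train_ids <- setdiff(cohort$patients$id, id)
  curves <- list(); rowsv <- list()
  for (m in models) {
    fp <- fit_predict_one(m, cohort, train_ids, id, derive_seed(seed, match(m, models)),
                          horizon_days, cox_spec, rsf_spec, ann_spec, control, mlp)
    se <- fp$surv_endpoint[1]
    curves[[m]] <- fp$curves[[1]]
    rowsv[[m]] <- data.frame(model = m, surv_at_endpoint = se,
                             consistent = if (pat$event == 0) se >= cutoff else se < cutoff)
  }
  list(verdicts = do.call(rbind, rowsv), curves = curves,
       endpoint_day = pat$endpoint_day, event = pat$event, cutoff = cutoff)
}

#' Distribution of out-of-fold predicted probabilities
#'
#' For censored patients, summarizes the predicted non-dialysis (survival)
#' probability at their endpoint; for dialysis patients, the predicted
#' dialysis probability (1 minus survival) at their endpoint. Quartiles per
#' model, the boxplot view of model calibration.
#'
#' @param cv a `ckd_cv` with out-of-fold predictions.
#' @return data.frame: model, group (`nondialysis`/`dialysis`), n, q25,
#'   median, q75.
#' @export
cohort_probability_summary <- function(cv) {
  stopifnot(inherits(cv, "ckd_cv"))
  out <- list()
  for (m in unique(cv$predictions$model)) {
    pm <- cv$predictions[cv$predictions$model == m &
                           is.finite(cv$predictions$surv_endpoint), , drop = FALSE]
    for (grp in c("nondialysis", "dialysis")) {
      sel <- if (grp == "nondialysis") pm$event == 0 else pm$event == 1
      prob <- if (grp == "nondialysis") pm$surv_endpoint[sel] else 1 - pm$surv_endpoint[sel]
      if (length(prob) == 0) next
      qs <- quantile(prob, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      out[[length(out) + 1L]] <- data.frame(model = m, group = grp,
                                            n = length(prob), q25 = qs[1],
                                            median = qs[2], q75 = qs[3])
    }
  }
  do.call(rbind, out)
}

#' Ranked permutation-importance table
#'
#' Descending [vimp()] table; ties broken alphabetically by covariate name.
#'
#' @param model a fitted `ckd_rsf`.
#' @param seed permutation seed.
#' @return data.frame `covariate`, `vimp`, sorted descending.
#' @export
vimp_report <- function(model, seed = 1L) {
  v <- vimp(model, seed = seed)
  df <- data.frame(covariate = names(v), vimp = unname(v))
  df[order(-df$vimp, df$covariate), , drop = FALSE]
}
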