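#' Hyperparameters for the random survival forest
#'
#' @param ntree number of trees (default 100).
#' @param mtry covariates sampled without replacement at each node
#'   (default \eqn{\lceil\sqrt p\rceil}).
#' @param min_node_events minimum events each daughter (and hence each
#'   terminal node) must hold; nodes with fewer than `2 * min_node_events`
#'   events are not split.
#' @param n_split_candidates random thresholds drawn from the observed
#'   in-node values of each tried covariate.
#' @param n_perm permutation repetitions for [vimp()].
#' @return list of class `rsf_control`.
#' @export
rsf_control <- function(ntree = 100, mtry = NULL, min_node_events = 3,
                        n_split_candidates = 10, n_perm = 1) {
  stopifnot(ntree >= 1, min_node_events >= 1, n_split_candidates >= 1, n_perm >= 1)
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 min_node_events = as.integer(min_node_events),
                 n_split_candidates = as.integer(n_split_candidates),
                 n_perm = as.integer(n_perm)),
            class = "rsf_control")
}

# Recursive tree growth on bootstrap rows. Trees are stored as parallel
# vectors (var/thr/left/right/term); terminal payloads are Nelson-Aalen CHFs
# of the in-node bootstrap rows evaluated on the shared training event-time
# grid (in-node KM survival is exp(-CHF) under the ensemble convention).
grow_tree <- function(time, status, X, control, grid) {
  p <- ncol(X)
  mtry <- if (is.null(control$mtry)) ceiling(sqrt(p)) else min(control$mtry, p)
  env <- new.env()
  env$var <- integer(0); env$thr <- numeric(0)
  env$left <- integer(0); env$right <- integer(0); env$term <- integer(0)
  env$chf <- list()
  env$node_idx <- list()  # bootstrap rows reaching each terminal

  na_on_grid <- function(idx) {
    na <- nelson_aalen(time[idx], status[idx])
    curve_eval(na, grid)
  }
  new_node <- function() {
    k <- length(env$var) + 1L
    env$var[k] <- NA_integer_; env$thr[k] <- NA_real_
    env$left[k] <- 0L; env$right[k] <- 0L; env$term[k] <- 0L
    k
  }
  make_terminal <- function(k, idx) {
    env$chf[[length(env$chf) + 1L]] <- na_on_grid(idx)
    env$node_idx[[length(env$chf)]] <- idx
    env$term[k] <- length(env$chf)
  }
  build <- function(idx) {
    k <- new_node()
    if (sum(status[idx]) < 2 * control$min_node_events) {
      make_terminal(k, idx); return(k)
    }
    vars <- sample.int(p, mtry)
    best <- list(L = -1)
    for (v in vars) {
      xv <- X[idx, v]
      ux <- unique(xv)
      if (length(ux) < 2) next
      cands <- if (length(ux) <= control$n_split_candidates) ux
               else sample(ux, control$n_split_candidates)
      res <- .lr_best_split_cpp(time[idx], as.integer(status[idx]), xv,
                                cands, control$min_node_events)
      if (res[3] > 0 && res[2] > best$L) best <- list(v = v, c = res[1], L = res[2])
    }
    if (best$L < 0) { make_terminal(k, idx); return(k) }
    env$var[k] <- best$v; env$thr[k] <- best$c
    lidx <- idx[X[idx, best$v] <= best$c]
    ridx <- idx[X[idx, best$v] > best$c]
    env$left[k] <- build(lidx)
    env$right[k] <- build(ridx)
    k
  }
  build(seq_along(time))
  list(var = env$var, thr = env$thr, left = env$left, right = env$right,
       term = env$term, chf = do.call(rbind, env$chf))
}

# terminal-node index (row of tree$chf) for every row of X
drop_down <- function(tree, X) {
  node <- rep(1L, nrow(X))
  repeat {
    active <- which(tree$term[node] == 0L)
    if (length(active) == 0) break
    v <- tree$var[node[active]]
    thr <- tree$thr[node[active]]
    goes_left <- X[cbind(active, v)] <= thr
    node[active] <- ifelse(goes_left, tree$left[node[active]], tree$right[node[active]])
  }
  tree$term[node]
}

#' Fit a random survival forest with the log-rank split rule
#'
#' Grows `ntree` survival trees on independent bootstrap samples of patients
#' (landmark representation: one feature vector per patient). At each node
#' `mtry` covariates are sampled; for each, up to `n_split_candidates`
#' thresholds drawn from the observed in-node values are scored with the
#' standardized log-rank statistic ([logrank_split_statistic()]; the forest
#' uses a compiled implementation of the same formula) and the best split is
#' taken. Terminal nodes hold the Nelson-Aalen cumulative hazard of their
#' in-node bootstrap rows on the shared grid of training event times; the
#' ensemble CHF is the arithmetic mean over trees. A bootstrap without enough
#' events yields a degenerate single-node tree (allowed).
#'
#' @param data data.frame with columns `time`, `event` and features, one row
#'   per patient (see [landmark_features()]).
#' @param features feature column names (default: all but bookkeeping).
#' @param control an [rsf_control()].
#' @param seed integer seed; the forest is deterministic given it.
#' @return object of class `ckd_rsf`: trees, per-tree `inbag`/`oob` index
#'   lists, the event-time `grid`, `features`, `control`, and the training
#'   `data`.
#' @export
fit_forest <- function(data, features = NULL, control = rsf_control(), seed = 1L) {
  if (is.null(features))
    features <- setdiff(names(data), c("id", "time", "event"))
  n <- nrow(data)
  if (n < 10) stop("fewer than 10 patients: a forest is not meaningful here")
  check_surv_input(data$time, data$event)
  X <- as.matrix(data[features])
  if (any(!is.finite(X))) stop("non-finite feature values")
  set.seed(seed)
  grid <- sort(unique(data$time[data$event == 1]))
  trees <- vector("list", control$ntree)
  inbag <- vector("list", control$ntree)
  oob <- vector("list", control$ntree)
  for (b in seq_len(control$ntree)) {
    idx <- sample.int(n, n, replace = TRUE)
    inbag[[b]] <- idx
    oob[[b]] <- setdiff(seq_len(n), idx)
    trees[[b]] <- grow_tree(data$time[idx], data$event[idx],
                            X[idx, , drop = FALSE], control, grid)
  }
  structure(list(trees = trees, inbag = inbag, oob = oob, grid = grid,
                 features = features, control = control, seed = seed,
                 data = data),
            class = "ckd_rsf")
}

#' @export
print.ckd_rsf <- function(x, ...) {
  cat("Random survival forest:", length(x$trees), "trees,",
      nrow(x$data), "patients,", length(x$features), "features\n")
  cat("terminal nodes per tree (median):",
      median(vapply(x$trees, function(tr) nrow(tr$chf), numeric(1))), "\n")
  invisible(x)
}

feature_matrix <- function(model, newdata) {
  if (!all(model$features %in% names(newdata)))
    stop("feature mismatch: missing ",
         paste(setdiff(model$features, names(newdata)), collapse = ", "))
  as.matrix(newdata[model$features])
}

#' Ensemble cumulative hazard prediction
#'
#' Drops each patient's feature vector down every tree and averages the
#' terminal Nelson-Aalen CHFs.
#'
#' @param model a fitted `ckd_rsf`.
#' @param newdata data.frame containing the model's features.
#' @return matrix (patients x grid times) of ensemble cumulative hazards;
#'   the grid is `model$grid`.
#' @export
predict_chf <- function(model, newdata) {
  stopifnot(inherits(model, "ckd_rsf"))
  X <- feature_matrix(model, newdata)
  acc <- matrix(0, nrow(X), length(model$grid))
  for (tree in model$trees)
    acc <- acc + tree$chf[drop_down(tree, X), , drop = FALSE]
  acc / length(model$trees)
}

#' Ensemble survival prediction from a random survival forest
#'
#' Survival is the exponentiated negative ensemble CHF,
#' \eqn{\hat S(t) = \exp(-\bar H(t))}: non-increasing and in (0, 1].
#'
#' @inheritParams predict_chf
#' @return a `survcurve` for a single patient, otherwise a matrix
#'   (patients x grid times) of survival probabilities.
#' @export
predict_survival_rsf <- function(model, newdata) {
  chf <- predict_chf(model, newdata)
  surv <- exp(-chf)
  if (nrow(surv) == 1) return(new_survcurve(model$grid, drop(surv)))
  surv
}

# OOB ensemble CHF: per patient, averaged over the trees for which the
# patient is out of bag. `X` may carry permuted columns (for VIMP); rows never
# OOB get NA.
oob_chf_matrix <- function(model, X, perm_feature = NULL, perm_within_oob = TRUE) {
  n <- nrow(X)
  acc <- matrix(0, n, length(model$grid))
  cnt <- integer(n)
  for (b in seq_along(model$trees)) {
    ob <- model$oob[[b]]
    if (length(ob) == 0) next
    Xb <- X[ob, , drop = FALSE]
    if (!is.null(perm_feature) && perm_within_oob && length(ob) > 1) {
      j <- match(perm_feature, model$features)
      Xb[, j] <- Xb[sample.int(length(ob)), j]
    }
    tn <- drop_down(model$trees[[b]], Xb)
    acc[ob, ] <- acc[ob, ] + model$trees[[b]]$chf[tn, , drop = FALSE]
    cnt[ob] <- cnt[ob] + 1L
  }
  acc[cnt > 0, ] <- acc[cnt > 0, , drop = FALSE] / cnt[cnt > 0]
  acc[cnt == 0, ] <- NA_real_
  acc
}

oob_mortality <- function(model, perm_feature = NULL) {
  X <- as.matrix(model$data[model$features])
  chf <- oob_chf_matrix(model, X, perm_feature)
  rowSums(chf)
}

#' Out-of-bag prediction error of a survival forest
#'
#' Each patient's risk score is the mortality (out-of-bag ensemble CHF summed
#' over the training event times); the error is 1 minus the concordance index
#' of that risk score. Patients never out of bag are excluded (with a
#' message).
#'
#' @param model a fitted `ckd_rsf`.
#' @return OOB error rate in \[0, 1\].
#' @export
oob_error <- function(model) {
  stopifnot(inherits(model, "ckd_rsf"))
  mort <- oob_mortality(model)
  ok <- is.finite(mort)
  if (!any(ok)) stop("no out-of-bag coverage")
  if (any(!ok)) message(sum(!ok), " patient(s) never out of bag; excluded")
  1 - concordance_index(model$data$time[ok], model$data$event[ok],
                        mort[ok], direction = "risk")
}

#' Permutation variable importance
#'
#' For each covariate, the out-of-bag error is recomputed with that covariate
#' permuted among each tree's out-of-bag rows; the importance is the increase
#' over the baseline OOB error, averaged over `n_perm` repetitions. Positive
#' values mean the covariate carries predictive signal.
#'
#' @param model a fitted `ckd_rsf`.
#' @param seed seed for the permutations.
#' @return named numeric vector of importances (model feature order).
#' @export
vimp <- function(model, seed = 1L) {
  stopifnot(inherits(model, "ckd_rsf"))
  set.seed(seed)
  time <- model$data$time; event <- model$data$event
  base_mort <- oob_mortality(model)
  ok <- is.finite(base_mort)
  base_err <- 1 - concordance_index(time[ok], event[ok], base_mort[ok],
                                    direction = "risk")
  out <- setNames(numeric(length(model$features)), model$features)
  for (v in model$features) {
    errs <- numeric(model$control$n_perm)
    for (r in seq_len(model$control$n_perm)) {
      mort <- oob_mortality(model, perm_feature = v)
      errs[r] <- 1 - concordance_index(time[ok], event[ok], mort[ok],
                                       direction = "risk")
    }
    out[v] <- mean(errs) - base_err
  }
  out
}
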