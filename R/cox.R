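#' Time-dependent Cox proportional hazards model
#'
#' Fits \eqn{\lambda(t \mid \bar v) = \lambda_0(t) e^{\beta' v(t)}} by
#' Newton-Raphson maximization of the counting-process partial likelihood.
#' Rows are half-open (start, stop] risk intervals carrying the covariates in
#' force; the risk set at event time \eqn{t_i} is
#' \eqn{\{rows : start < t_i \le stop\}}. Tied event times are handled by the
#' Breslow approximation by default (Efron available). Newton steps are
#' halved whenever they fail to increase the partial log-likelihood, so the
#' likelihood trace is monotone.
#'
#' @param rows counting-process data.frame from [to_counting_process()]
#'   (columns `id`, `start`, `stop`, `event`, features). Features should
#'   already be normalized if desired (see [zscore_normalize()]).
#' @param features feature column names; default: every column except the
#'   bookkeeping ones.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param tol convergence tolerance on the max-norm of the score vector,
#'   scaled by the magnitude of the partial log-likelihood.
#' @param max_iter maximum Newton iterations.
#' @param beta_max divergence guard: a coefficient exceeding this magnitude
#'   is treated as complete separation (a hazard ratio of e^10 is not a
#'   statement any clinical data can make).
#' @return object of class `cox_td`: list with `beta`, `se` (from the
#'   observed information), `loglik` (trace, final value last), `iter`,
#'   `gradient_norm`, `baseline` (Breslow cumulative baseline hazard, a
#'   `cumhaz_curve`), `features`, and the training `rows` (for the baseline).
#' @export
fit_cox_td <- function(rows, features = NULL,
                       ties = c("breslow", "efron"),
                       tol = 1e-8, max_iter = 50, beta_max = 10) {
  ties <- match.arg(ties)
  if (is.null(features))
    features <- setdiff(names(rows), c("id", "start", "stop", "event"))
  if (length(features) == 0) stop("no features to fit")
  if (sum(rows$event) < 1) stop("need at least one event")
  X <- as.matrix(rows[features])
  if (any(!is.finite(X))) stop("non-finite feature values")
  stopifnot(all(rows$start < rows$stop))

  et <- sort(unique(rows$stop[rows$event == 1]))
  risk_idx <- lapply(et, function(t) which(rows$start < t & rows$stop >= t))
  death_idx <- lapply(et, function(t) which(rows$stop == t & rows$event == 1))

  p <- length(features)
  beta <- numeric(p)
  trace <- numeric(0)

  pll <- function(beta) {
    lp <- drop(X %*% beta)
    ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
    for (k in seq_along(et)) {
      R <- risk_idx[[k]]; D <- death_idx[[k]]; d <- length(D)
      w <- exp(lp[R])
      xR <- X[R, , drop = FALSE]
      if (ties == "breslow") {
        W <- sum(w)
        xbar <- colSums(w * xR) / W
        S2 <- crossprod(xR, w * xR)
        ll <- ll + sum(lp[D]) - d * log(W)
        grad <- grad + colSums(X[D, , drop = FALSE]) - d * xbar
        info <- info + d * (S2 / W - tcrossprod(xbar))
      } else {
        wD <- exp(lp[D]); xD <- X[D, , drop = FALSE]
        W <- sum(w); WD <- sum(wD)
        s1 <- colSums(w * xR); s1D <- colSums(wD * xD)
        S2 <- crossprod(xR, w * xR); S2D <- crossprod(xD, wD * xD)
        ll <- ll + sum(lp[D])
        for (l in seq_len(d)) {
          fr <- (l - 1) / d
          Wl <- W - fr * WD
          s1l <- s1 - fr * s1D
          S2l <- S2 - fr * S2D
          xbar <- s1l / Wl
          ll <- ll - log(Wl)
          grad <- grad - xbar
          info <- info + (S2l / Wl - tcrossprod(xbar))
        }
        grad <- grad + colSums(xD)
      }
    }
    list(ll = ll, grad = grad, info = info)
  }

  cur <- pll(beta)
  trace <- cur$ll
  iter <- 0
  repeat {
    gnorm <- max(abs(cur$grad))
    # scale the gradient tolerance by the likelihood magnitude: the score of
    # a large sample cannot be driven below its floating-point noise floor
    if (gnorm < tol * max(1, abs(cur$ll))) break
    if (iter >= max_iter)
      stop("Cox fit did not converge in ", max_iter,
           " iterations (gradient max-norm ", signif(gnorm, 3),
           "); loglik trace: ", paste(signif(trace, 6), collapse = " "))
    step <- tryCatch(solve(cur$info, cur$grad),
                     error = function(e) stop("singular information matrix: ", conditionMessage(e)))
    h <- 1
    repeat {
      cand <- beta + h * step
      new <- pll(cand)
      if ((is.finite(new$ll) && new$ll >= cur$ll) || h < 1e-10) break
      h <- h / 2
    }
    beta <- beta + h * step
    cur <- new
    if (max(abs(beta)) > beta_max)
      stop("diverging coefficients (|beta| > ", beta_max,
           "): likely complete separation")
    trace <- c(trace, cur$ll)
    iter <- iter + 1
  }

  se <- sqrt(diag(tryCatch(solve(cur$info), error = function(e) matrix(NA, p, p))))
  fit <- structure(list(beta = setNames(drop(beta), features),
                        se = setNames(se, features),
                        loglik = trace, iter = iter,
                        gradient_norm = max(abs(cur$grad)),
                        ties = ties, features = features, rows = rows),
                   class = "cox_td")
  fit$baseline <- breslow_baseline(fit, rows)
  fit
}

#' @export
print.cox_td <- function(x, ...) {
  cat("Time-dependent Cox model (", x$ties, " ties), ",
      x$iter, " Newton iterations\n", sep = "")
  print(data.frame(coef = x$beta, `exp(coef)` = exp(x$beta), se = x$se,
                   check.names = FALSE))
  cat("partial log-likelihood:", tail(x$loglik, 1), "\n")
  invisible(x)
}

#' Breslow estimate of the cumulative baseline hazard
#'
#' \deqn{\hat\Lambda_0(t) = \sum_{t_i \le t}
#'   \frac{d_i}{\sum_{j \in R(t_i)} e^{\beta' v_j(t_i)}}}
#' with the counting-process risk sets of the fit. At \eqn{\beta = 0} this
#' reduces exactly to the Nelson-Aalen estimator.
#'
#' @param fit a `cox_td` fit.
#' @param rows counting-process rows to estimate on (default: training rows).
#' @return a `cumhaz_curve`.
#' @export
breslow_baseline <- function(fit, rows = fit$rows) {
  stopifnot(inherits(fit, "cox_td"))
  X <- as.matrix(rows[fit$features])
  w <- exp(drop(X %*% fit$beta))
  et <- sort(unique(rows$stop[rows$event == 1]))
  inc <- vapply(et, function(t) {
    R <- rows$start < t & rows$stop >= t
    sum(rows$stop == t & rows$event == 1) / sum(w[R])
  }, numeric(1))
  structure(list(time = et, cumhaz = cumsum(inc),
                 n.risk = vapply(et, function(t) sum(rows$start < t & rows$stop >= t), numeric(1)),
                 n.event = vapply(et, function(t) sum(rows$stop == t & rows$event == 1), numeric(1))),
            class = "cumhaz_curve")
}

#' Predicted survival curve from a time-dependent Cox fit
#'
#' \deqn{\hat S(t) = \exp\left(-\int_0^t e^{\beta' v(s)}\, d\hat\Lambda_0(s)\right)}
#' accumulated over the baseline's event times, with the patient's covariates
#' \eqn{v(s)} piecewise constant over the supplied (start, stop] intervals and
#' the last interval's values carried forward beyond the last observation.
#'
#' @param fit a `cox_td` fit.
#' @param patient_rows counting-process rows of one patient (same features as
#'   the fit, same normalization).
#' @return a `survcurve` over the baseline event times.
#' @export
predict_survival_cox <- function(fit, patient_rows) {
  stopifnot(inherits(fit, "cox_td"))
  if (!all(fit$features %in% names(patient_rows)))
    stop("feature mismatch: patient rows lack ",
         paste(setdiff(fit$features, names(patient_rows)), collapse = ", "))
  if (length(unique(patient_rows$id)) > 1) stop("rows of a single patient expected")
  ord <- order(patient_rows$start)
  patient_rows <- patient_rows[ord, , drop = FALSE]
  X <- as.matrix(patient_rows[fit$features])
  w <- exp(drop(X %*% fit$beta))
  bl <- fit$baseline
  if (length(bl$time) == 0) return(new_survcurve(numeric(0), numeric(0)))
  inc0 <- diff(c(0, bl$cumhaz))
  # covariate row in force at each baseline event time s: start < s <= stop,
  # last row carried forward beyond the final stop
  idx <- findInterval(bl$time, patient_rows$start, left.open = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > nrow(patient_rows)] <- nrow(patient_rows)
  cumhaz <- cumsum(unname(w[idx]) * inc0)
  new_survcurve(bl$time, exp(-cumhaz), bl$n.risk, bl$n.event)
}
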