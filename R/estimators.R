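#' Kaplan-Meier product-limit survival estimate
#'
#' Computes the product-limit estimator
#' \deqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}
#' over the distinct event times \eqn{t_i}, where \eqn{d_i} is the number of
#' events and \eqn{n_i} the number at risk at \eqn{t_i}. Censored-only input
#' yields \eqn{\hat S \equiv 1}.
#'
#' @param time non-negative follow-up times (event or censoring).
#' @param status event indicator, 1 = event (dialysis), 0 = right-censored.
#' @return An object of class `survcurve`: a list with `time` (distinct event
#'   times, increasing), `surv` (the step values \eqn{\hat S(t_i)}), `n.risk`
#'   and `n.event`. Evaluate anywhere with [curve_eval()].
#' @seealso [nelson_aalen()], [curve_eval()], [pseudo_values()]
#' @export
kaplan_meier <- function(time, status) {
  check_surv_input(time, status)
  rs <- risk_event_counts(time, status)
  if (length(rs$time) == 0L) {
    return(new_survcurve(numeric(0), numeric(0), integer(0), integer(0)))
  }
  surv <- cumprod(1 - rs$n.event / rs$n.risk)
  new_survcurve(rs$time, surv, rs$n.risk, rs$n.event)
}

#' Nelson-Aalen cumulative hazard estimate
#'
#' \deqn{\hat H(t) = \sum_{t_i \le t} d_i / n_i.}
#'
#' @inheritParams kaplan_meier
#' @return An object of class `cumhaz_curve`: list with `time`, `cumhaz`,
#'   `n.risk`, `n.event`. Evaluate with [curve_eval()].
#' @export
nelson_aalen <- function(time, status) {
  check_surv_input(time, status)
  rs <- risk_event_counts(time, status)
  structure(list(time = rs$time, cumhaz = cumsum(rs$n.event / rs$n.risk),
                 n.risk = rs$n.risk, n.event = rs$n.event),
            class = "cumhaz_curve")
}

# at-risk and event counts at the distinct event times, O(n log n)
risk_event_counts <- function(time, status) {
  et <- sort(unique(time[status == 1]))
  if (length(et) == 0L)
    return(list(time = numeric(0), n.risk = numeric(0), n.event = numeric(0)))
  st <- sort(time)
  n.risk <- length(time) - findInterval(et, st, left.open = TRUE)
  n.event <- as.numeric(table(factor(time[status == 1], levels = et)))
  list(time = et, n.risk = n.risk, n.event = n.event)
}

new_survcurve <- function(time, surv, n.risk = NULL, n.event = NULL) {
  structure(list(time = time, surv = surv, n.risk = n.risk, n.event = n.event),
            class = "survcurve")
}

check_surv_input <- function(time, status) {
  if (length(time) == 0L) stop("empty survival input")
  if (length(time) != length(status)) stop("time and status lengths differ")
  if (any(!is.finite(time)) || any(time < 0)) stop("times must be finite and non-negative")
  if (!all(status %in% c(0, 1))) stop("status must be 0/1")
  invisible(TRUE)
}

#' Evaluate a right-continuous step curve
#'
#' Survival curves and cumulative-hazard curves are right-continuous step
#' functions; before the first jump `survcurve` objects equal 1 and
#' `cumhaz_curve` objects equal 0.
#'
#' @param curve a `survcurve` or `cumhaz_curve`.
#' @param t evaluation times (vectorized).
#' @return numeric vector of curve values at `t`.
#' @export
curve_eval <- function(curve, t) {
  if (inherits(curve, "survcurve")) {
    y <- curve$surv; y0 <- 1
  } else if (inherits(curve, "cumhaz_curve")) {
    y <- curve$cumhaz; y0 <- 0
  } else stop("not a step curve")
  if (length(curve$time) == 0L) return(rep(y0, length(t)))
  idx <- findInterval(t, curve$time)
  out <- c(y0, y)[idx + 1L]
  out
}

#' @export
print.survcurve <- function(x, ...) {
  cat("Kaplan-Meier survival curve:", length(x$time), "event times\n")
  if (length(x$time)) {
    df <- data.frame(time = x$time, n.risk = x$n.risk,
                     n.event = x$n.event, surv = x$surv)
    print(head(df, 10), row.names = FALSE)
    if (length(x$time) > 10) cat("...\n")
  }
  invisible(x)
}

#' Jackknife pseudo survival probabilities
#'
#' For each subject \eqn{j} and horizon \eqn{t}, the pseudo-value
#' \deqn{\hat S_j(t) = N \hat S(t) - (N - 1) \hat S_{-j}(t),}
#' where \eqn{\hat S} is the Kaplan-Meier estimate on the full sample and
#' \eqn{\hat S_{-j}} the estimate with subject \eqn{j} removed. With no
#' censoring the pseudo-value reduces exactly to the indicator
#' \eqn{I(T_j > t)}; under censoring values may fall outside \eqn{[0, 1]} and
#' are deliberately not clipped, since they serve as numeric regression
#' responses.
#'
#' @inheritParams kaplan_meier
#' @param horizons evaluation times (need not be observed times).
#' @return An object of class `pseudo_value_set`: list with `horizons`,
#'   `values` (N x length(horizons) matrix), `marginal` (\eqn{\hat S} at the
#'   horizons) and `N`.
#' @export
pseudo_values <- function(time, status, horizons) {
  check_surv_input(time, status)
  N <- length(time)
  if (N < 2L) stop("pseudo-values need at least 2 subjects")
  if (is.unsorted(horizons, strictly = FALSE)) stop("horizons must be sorted")
  full <- curve_eval(kaplan_meier(time, status), horizons)
  vals <- matrix(NA_real_, N, length(horizons))
  for (j in seq_len(N)) {
    km_j <- kaplan_meier(time[-j], status[-j])
    vals[j, ] <- N * full - (N - 1) * curve_eval(km_j, horizons)
  }
  structure(list(horizons = horizons, values = vals, marginal = full, N = N),
            class = "pseudo_value_set")
}

#' Concordance index for right-censored survival data
#'
#' Pairwise concordance estimator
#' \deqn{\hat C = \frac{\sum_{i \ne j} I(T_j < T_i)\, I(\eta_j < \eta_i)\,
#'   \delta_j}{\sum_{i \ne j} I(T_j < T_i)\, \delta_j},}
#' i.e. a usable pair (the earlier time is an observed event) is concordant
#' when the subject with the earlier event also carries the *smaller* marker.
#' This is the convention for a longevity-type marker (larger marker, longer
#' survival), e.g. a predicted survival probability. For a risk score (larger
#' marker, earlier event: Cox linear predictor, ensemble mortality) use
#' `direction = "risk"`, which negates the marker. Tied markers contribute
#' nothing by default (strict inequalities); `tie_credit = "half"` awards the
#' common 1/2 credit. Tied event times never form usable pairs.
#'
#' A C-index of 1 indicates perfect ranking, 0.5 a random marker.
#'
#' @inheritParams kaplan_meier
#' @param marker numeric prognostic marker, one per subject.
#' @param direction `"longevity"` (default, as the formula is written) or
#'   `"risk"`.
#' @param tie_credit `"none"` (strict) or `"half"`.
#' @return concordance estimate in \[0, 1\].
#' @export
concordance_index <- function(time, status, marker,
                              direction = c("longevity", "risk"),
                              tie_credit = c("none", "half")) {
  direction <- match.arg(direction)
  tie_credit <- match.arg(tie_credit)
  check_surv_input(time, status)
  if (length(marker) != length(time)) stop("marker length mismatch")
  if (any(!is.finite(marker))) stop("markers must be finite")
  eta <- if (direction == "risk") -marker else marker
  num <- 0; den <- 0
  for (j in which(status == 1)) {
    usable <- time > time[j]          # I(T_j < T_i), delta_j = 1
    den <- den + sum(usable)
    num <- num + sum(usable & eta > eta[j])
    if (tie_credit == "half") num <- num + 0.5 * sum(usable & eta == eta[j])
  }
  if (den == 0) stop("no usable pairs: concordance undefined")
  num / den
}

#' Log-rank split statistic for survival-tree node separation
#'
#' Standardized log-rank statistic for splitting a node on covariate value
#' `x` at threshold `split` (left daughter: `x <= split`):
#' \deqn{L = \frac{\left|\sum_i \left(d_{i1} - n_{i1} d_i / n_i\right)\right|}
#'   {\sqrt{\sum_i \frac{n_{i1}}{n_i}\left(1 - \frac{n_{i1}}{n_i}\right)
#'   \frac{n_i - d_i}{n_i - 1} d_i}}}
#' summed over the node's distinct event times; \eqn{d_{i1}, n_{i1}} count
#' events and at-risk subjects in the left daughter. Terms with
#' \eqn{n_i \le 1} are skipped (degenerate variance). Larger L means better
#' node separation; the statistic is symmetric in the two daughters.
#'
#' With `start` supplied, rows are (start, stop] risk intervals and the risk
#' set at \eqn{t_i} is \eqn{\{j : start_j < t_i \le stop_j\}} (late entry);
#' otherwise classical right-censored risk sets are used.
#'
#' @param time follow-up (or interval stop) times.
#' @param status event indicator per subject (or per interval).
#' @param x covariate values in force.
#' @param split candidate threshold.
#' @param start optional interval start times for counting-process rows.
#' @return the statistic L (non-negative scalar); 0 when no events.
#' @export
logrank_split_statistic <- function(time, status, x, split, start = NULL) {
  check_surv_input(time, status)
  if (length(x) != length(time)) stop("covariate length mismatch")
  left <- x <= split
  if (!any(left) || all(left)) stop("degenerate split: one daughter is empty")
  et <- sort(unique(time[status == 1]))
  if (length(et) == 0L) return(0)
  num <- 0; den <- 0
  for (t in et) {
    at_risk <- if (is.null(start)) time >= t else (start < t & time >= t)
    ni <- sum(at_risk)
    if (ni <= 1) next
    ev <- at_risk & time == t & status == 1
    di <- sum(ev)
    ni1 <- sum(at_risk & left)
    di1 <- sum(ev & left)
    num <- num + (di1 - ni1 * di / ni)
    den <- den + (ni1 / ni) * (1 - ni1 / ni) * ((ni - di) / (ni - 1)) * di
  }
  if (den <= 0) return(0)
  abs(num) / sqrt(den)
}

#' Chi-squared test statistic for a 2x2 contingency table
#'
#' Computes the chi-squared statistic for the 2x2 table
#' \preformatted{  a  b
#'   c  d}
#' with the Yates continuity correction (the default, which reproduces the
#' published dialysis-association tables):
#' \deqn{\chi^2 = \frac{n (\max(|ad - bc| - n/2,\ 0))^2}
#'   {(a+b)(c+d)(a+c)(b+d)}.}
#' `correct = FALSE` gives the raw Pearson statistic.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param correct apply the Yates continuity correction (default TRUE).
#' @return the chi-squared statistic.
#' @export
yates_chi_square <- function(a, b, c, d, correct = TRUE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) stop("counts must be non-negative integers")
  n <- sum(cells)
  if (n <= 0) stop("empty table")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero margin: test undefined")
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(dev - n / 2, 0)
  n * dev^2 / prod(margins)
}

#' One-way F statistic from two-group summary statistics
#'
#' Reconstructs the one-way ANOVA F statistic for two groups from their
#' sizes, means and standard deviations:
#' \deqn{F = \frac{\sum_g n_g (m_g - \bar m)^2}
#'   {[(n_1 - 1) s_1^2 + (n_2 - 1) s_2^2] / (n_1 + n_2 - 2)}.}
#' Matches `aov`/`oneway.test` (equal variances) applied to the raw data.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param m1,m2 group means.
#' @param s1,s2 group standard deviations.
#' @return the F statistic (1 and n1+n2-2 df).
#' @export
oneway_f_from_summary <- function(n1, m1, s1, n2, m2, s2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (s1 < 0 || s2 < 0) stop("standard deviations must be non-negative")
  msw <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (msw <= 0) stop("zero pooled variance")
  mbar <- (n1 * m1 + n2 * m2) / (n1 + n2)
  msb <- n1 * (m1 - mbar)^2 + n2 * (m2 - mbar)^2
  msb / msw
}
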