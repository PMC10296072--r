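# Independent brute-force oracles: naive loops written directly from the
# estimator definitions, sharing no code with the package implementations.

km_brute <- function(time, status, t_eval) {
  s <- 1
  for (tt in sort(unique(time[status == 1]))) {
    if (tt > t_eval) break
    n_i <- sum(time >= tt)
    d_i <- sum(time == tt & status == 1)
    s <- s * (1 - d_i / n_i)
  }
  s
}

na_brute <- function(time, status, t_eval) {
  h <- 0
  for (tt in sort(unique(time[status == 1]))) {
    if (tt > t_eval) break
    h <- h + sum(time == tt & status == 1) / sum(time >= tt)
  }
  h
}

# exhaustive ordered-pair enumeration of the concordance estimator for a
# longevity-type marker (earlier event <-> smaller marker is concordant)
cindex_brute <- function(time, status, eta) {
  num <- 0; den <- 0
  n <- length(time)
  for (j in 1:n) for (i in 1:n) {
    if (i == j) next
    if (time[j] < time[i] && status[j] == 1) {
      den <- den + 1
      if (eta[j] < eta[i]) num <- num + 1
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# term-by-term evaluation of the standardized log-rank split statistic
logrank_brute <- function(time, status, x, split, start = NULL) {
  if (is.null(start)) start <- rep(-Inf, length(time))
  num <- 0; den <- 0
  for (tt in sort(unique(time[status == 1]))) {
    risk <- which(start < tt & time >= tt)
    ni <- length(risk)
    if (ni <= 1) next
    di <- 0; di1 <- 0; ni1 <- 0
    for (j in risk) {
      if (x[j] <= split) ni1 <- ni1 + 1
      if (time[j] == tt && status[j] == 1) {
        di <- di + 1
        if (x[j] <= split) di1 <- di1 + 1
      }
    }
    num <- num + (di1 - ni1 * di / ni)
    den <- den + (ni1 / ni) * (1 - ni1 / ni) * ((ni - di) / (ni - 1)) * di
  }
  if (den <= 0) return(0)
  abs(num) / sqrt(den)
}

# random small right-censored fixture, ties possible via rounding
random_fixture <- function(n, tie_prone = TRUE) {
  time <- if (tie_prone) sample(1:6, n, replace = TRUE) else rexp(n)
  status <- rbinom(n, 1, 0.7)
  if (all(status == 0)) status[sample(n, 1)] <- 1
  list(time = time, status = status)
}

# small generated cohort shared across tests
tiny_cohort <- function(n = 60, seed = 42, ...) {
  suppressMessages(apply_exclusions(generate_cohort(cohort_config(n, seed = seed, ...))))
}
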