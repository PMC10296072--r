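# two-group exponential survival data with a known hazard ratio
two_group_data <- function(n, hr, seed, censor = FALSE) {
  set.seed(seed)
  g <- rep(0:1, length.out = n)
  t <- rexp(n, rate = 0.01 * hr^g)
  s <- rep(1L, n)
  if (censor) {
    c_ <- rexp(n, 0.004)
    s <- as.integer(t <= c_)
    t <- pmin(t, c_)
  }
  data.frame(id = 1:n, start = 0, stop = t, event = s, g = g)
}

test_that("a null covariate gets a near-zero coefficient", {
  d <- two_group_data(500, hr = 1, seed = 1)
  fit <- fit_cox_td(d, features = "g")
  expect_lt(abs(fit$beta[["g"]]), 0.15)
})

test_that("the log hazard ratio is recovered on two-group exponential data", {
  d <- two_group_data(2000, hr = 2, seed = 2)
  fit <- fit_cox_td(d, features = "g")
  expect_equal(fit$beta[["g"]], log(2), tolerance = 0.08 / log(2))
  expect_lt(fit$gradient_norm, 1e-8 * abs(tail(fit$loglik, 1)))
})

test_that("estimates match the reference implementation to 1e-4", {
  skip_if_not_installed("survival")
  d <- two_group_data(300, hr = 3, seed = 3, censor = TRUE)
  d$x2 <- rnorm(300)
  fit <- fit_cox_td(d, features = c("g", "x2"))
  ref <- survival::coxph(survival::Surv(stop, event) ~ g + x2, data = d,
                         ties = "breslow")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)

  # tied event times exercise the tie corrections; counting-process rows
  # exercise late entry
  co <- tiny_cohort(100, seed = 4)
  rows <- to_counting_process(co)
  rows$stop <- ceiling(rows$stop / 30) * 30   # force ties on a monthly grid
  rows$start <- floor(rows$start / 30) * 30
  rows <- rows[rows$start < rows$stop, ]
  fml <- survival::Surv(start, stop, event) ~ creatinine + egfr + pcrln +
    hba1c + age + gender + hypertension + diabetes + cvd
  for (tie in c("breslow", "efron")) {
    fit <- fit_cox_td(rows, ties = tie)
    ref <- survival::coxph(fml, data = rows, ties = tie)
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-4)
  }
})

test_that("the partial log-likelihood trace is monotone", {
  co <- tiny_cohort(80, seed = 5)
  fit <- fit_cox_td(zscore_normalize(to_counting_process(co)))
  expect_true(all(diff(fit$loglik) >= -1e-8))
})

test_that("Breslow baseline reduces to Nelson-Aalen at beta = 0 and scales", {
  d <- two_group_data(60, hr = 2, seed = 6, censor = TRUE)
  fit <- fit_cox_td(d, features = "g")
  fit0 <- fit; fit0$beta[] <- 0
  bl0 <- breslow_baseline(fit0, d)
  na <- nelson_aalen(d$stop, d$event)
  expect_equal(bl0$time, na$time)
  expect_equal(bl0$cumhaz, na$cumhaz)
  # adding a constant to a covariate rescales the baseline by exp(-beta*c) ...
  d2 <- d; d2$g <- d2$g + 5
  bl <- breslow_baseline(fit, d)
  bl2 <- breslow_baseline(fit, d2)
  expect_equal(bl2$cumhaz, bl$cumhaz * exp(-fit$beta[["g"]] * 5))
})

test_that("toy baseline increments match a hand-evaluated sum", {
  d <- data.frame(id = 1:4, start = 0, stop = c(1, 2, 3, 4),
                  event = c(1, 1, 0, 1), x = c(0.5, -0.5, 1, 0))
  fit <- fit_cox_td(d, features = "x")
  b <- fit$beta[["x"]]
  w <- exp(b * d$x)
  inc_hand <- c(1 / sum(w), 1 / sum(w[2:4]), 1 / w[4])
  bl <- breslow_baseline(fit, d)
  expect_equal(diff(c(0, bl$cumhaz)), inc_hand)
})

test_that("predictions respect the model structure", {
  co <- tiny_cohort(80, seed = 7)
  rows <- zscore_normalize(to_counting_process(co))
  fit <- fit_cox_td(rows)
  # beta = 0: every patient gets the same curve, exp(-baseline)
  fit0 <- fit; fit0$beta[] <- 0
  fit0$baseline <- breslow_baseline(fit0, rows)
  ids <- co$patients$id[1:5]
  curves0 <- lapply(ids, function(pid)
    predict_survival_cox(fit0, rows[rows$id == pid, ]))
  for (cv in curves0) expect_equal(cv$surv, exp(-fit0$baseline$cumhaz))
  # uniformly higher-risk covariates give a pointwise lower curve
  pr <- rows[rows$id == ids[1], ]
  lp_sign <- sign(fit$beta)
  pr_hi <- pr
  for (v in fit$features) pr_hi[[v]] <- pr[[v]] + lp_sign[[v]]
  lo <- predict_survival_cox(fit, pr)
  hi <- predict_survival_cox(fit, pr_hi)
  expect_true(all(hi$surv <= lo$surv + 1e-12))
  # curves are valid survival functions
  expect_true(all(diff(lo$surv) <= 1e-12) && all(lo$surv >= 0 & lo$surv <= 1))
})

test_that("the piecewise hazard integral matches a hand-accumulated sum", {
  d <- data.frame(id = 1:6, start = 0, stop = c(2, 4, 6, 8, 10, 12),
                  event = c(1, 1, 1, 0, 1, 0), x = c(1, 0, 2, 1, 0, 2))
  fit <- fit_cox_td(d, features = "x")
  patient <- data.frame(id = 99, start = c(0, 3, 7), stop = c(3, 7, 11),
                        event = 0, x = c(0, 1, 2))
  pred <- predict_survival_cox(fit, patient)
  inc <- diff(c(0, fit$baseline$cumhaz))
  b <- fit$beta[["x"]]
  # covariate in force at the baseline event times 2, 4, 6, 10: x = 0,1,1,2
  xf <- c(0, 1, 1, 2)
  expect_equal(pred$surv, exp(-cumsum(exp(b * xf) * inc)))
})

test_that("translation of a covariate leaves predicted curves unchanged", {
  co <- tiny_cohort(60, seed = 8)
  rows <- to_counting_process(co)
  fit <- fit_cox_td(rows)
  rows2 <- rows; rows2$egfr <- rows2$egfr + 100
  fit2 <- fit_cox_td(rows2)
  pid <- co$patients$id[3]
  p1 <- predict_survival_cox(fit, rows[rows$id == pid, ])
  p2 <- predict_survival_cox(fit2, rows2[rows2$id == pid, ])
  expect_equal(p1$surv, p2$surv, tolerance = 1e-6)
})

test_that("separation and non-convergence are reported", {
  # perfectly separating covariate: earlier half all events, marker splits them
  d <- data.frame(id = 1:20, start = 0, stop = c(1:10, 101:110),
                  event = rep(c(1L, 0L), each = 10), x = rep(c(1, 0), each = 10))
  expect_error(fit_cox_td(d, features = "x"), "separation|converge")
  expect_error(fit_cox_td(d[d$event == 0, ], features = "x"), "at least one event")
})
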