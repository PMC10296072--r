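test_that("Kaplan-Meier matches the hand-computed product limit", {
  km <- kaplan_meier(c(2, 4, 5, 7), c(1, 1, 0, 1))
  expect_equal(curve_eval(km, c(2, 4, 6, 7)), c(0.75, 0.5, 0.5, 0))
  expect_equal(curve_eval(km, 1.9), 1)       # right-continuous, 1 before first event
})

test_that("Kaplan-Meier reduces correctly in degenerate cases", {
  expect_equal(curve_eval(kaplan_meier(1:5, rep(0, 5)), c(1, 3, 10)), c(1, 1, 1))
  # without censoring, KM is the empirical survival function
  set.seed(1)
  t <- rexp(40)
  km <- kaplan_meier(t, rep(1, 40))
  grid <- seq(0, max(t), length.out = 17)
  expect_equal(curve_eval(km, grid),
               vapply(grid, function(u) mean(t > u), numeric(1)))
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("Nelson-Aalen matches the hand sum and dominates KM", {
  na <- nelson_aalen(c(2, 4, 7), c(1, 1, 1))
  expect_equal(curve_eval(na, 7), 1/3 + 1/2 + 1)
  expect_equal(curve_eval(nelson_aalen(1:4, rep(0, 4)), 10), 0)
  set.seed(7)
  for (rep in 1:20) {
    fx <- random_fixture(sample(3:30, 1))
    na <- nelson_aalen(fx$time, fx$status)
    km <- kaplan_meier(fx$time, fx$status)
    grid <- sort(unique(fx$time))
    expect_true(all(exp(-curve_eval(na, grid)) >= curve_eval(km, grid) - 1e-12))
  }
})

test_that("step curves agree with the brute-force oracles on random fixtures", {
  set.seed(11)
  for (rep in 1:40) {
    fx <- random_fixture(sample(2:8, 1), tie_prone = rep %% 2 == 0)
    grid <- c(sort(unique(fx$time)), max(fx$time) + 1, 0.5)
    km <- kaplan_meier(fx$time, fx$status)
    na <- nelson_aalen(fx$time, fx$status)
    for (t in grid) {
      expect_equal(curve_eval(km, t), km_brute(fx$time, fx$status, t))
      expect_equal(curve_eval(na, t), na_brute(fx$time, fx$status, t))
    }
  }
})

test_that("pseudo-values reproduce the four-patient worked example", {
  pv <- pseudo_values(1:4, rep(1, 4), 2.5)
  expect_equal(pv$marginal, 0.5)
  # the patient with T = 4: leave-one-out KM at 2.5 is 1/3, pseudo = 4*0.5 - 3/3
  expect_equal(pv$values[4, 1], 1)
  expect_equal(pv$values[, 1], as.numeric(1:4 > 2.5))
})

test_that("pseudo-values obey the jackknife identity and match the survival package", {
  t <- c(1, 2, 2, 3, 5, 6, 8, 9)
  s <- c(1, 0, 1, 1, 0, 1, 0, 1)
  hz <- c(2.5, 4, 7)
  pv <- pseudo_values(t, s, hz)
  # algebraic identity: mean_j S_j(t) = N*S(t) - (N-1)*mean_j S_{-j}(t)
  loo <- sapply(seq_along(t), function(j)
    curve_eval(kaplan_meier(t[-j], s[-j]), hz))
  expect_equal(colMeans(pv$values), 8 * pv$marginal - 7 * rowMeans(loo))
  skip_if_not_installed("survival")
  # independent oracle: rebuild the jackknife from survfit's KM estimates
  sf_at <- function(tt, ss) {
    fit <- survival::survfit(survival::Surv(tt, ss) ~ 1)
    summary(fit, times = hz, extend = TRUE)$surv
  }
  full <- sf_at(t, s)
  oracle <- t(sapply(seq_along(t), function(j) 8 * full - 7 * sf_at(t[-j], s[-j])))
  expect_equal(unname(pv$values), oracle, tolerance = 1e-10)
})

test_that("concordance index handles the printed examples and directions", {
  expect_equal(concordance_index(1:3, rep(1, 3), 1:3), 1)
  expect_equal(concordance_index(1:3, rep(1, 3), 3:1), 0)
  expect_equal(concordance_index(c(1, 2, 3), c(1, 1, 0), c(1, 3, 2)), 2/3)
  # a risk score is the negated longevity marker
  set.seed(3)
  fx <- random_fixture(25, tie_prone = FALSE)
  eta <- rnorm(25)
  expect_equal(concordance_index(fx$time, fx$status, eta, direction = "risk"),
               concordance_index(fx$time, fx$status, -eta))
  expect_error(concordance_index(c(1, 2), c(0, 0), c(1, 2)), "no usable pairs")
})

test_that("concordance index is invariant under strictly monotone marker transforms", {
  set.seed(5)
  for (rep in 1:10) {
    fx <- random_fixture(20, tie_prone = FALSE)
    eta <- rnorm(20)
    c0 <- concordance_index(fx$time, fx$status, eta)
    expect_equal(concordance_index(fx$time, fx$status, exp(3 * eta)), c0)
    expect_equal(concordance_index(fx$time, fx$status, atan(eta) + 10), c0)
  }
})

test_that("a random marker scores near one half", {
  set.seed(19)
  t <- rexp(2000); s <- rbinom(2000, 1, 0.7); eta <- rnorm(2000)
  expect_lt(abs(concordance_index(t, s, eta) - 0.5), 0.03)
})

test_that("concordance matches exhaustive pair enumeration", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    fx <- random_fixture(n)
    eta <- sample(1:4, n, replace = TRUE)  # marker ties on purpose
    cb <- cindex_brute(fx$time, fx$status, eta)
    if (is.na(cb)) {
      expect_error(concordance_index(fx$time, fx$status, eta), "no usable pairs")
    } else {
      expect_equal(concordance_index(fx$time, fx$status, eta), cb)
    }
  }
})

test_that("log-rank split statistic: symmetry, null, and toy-node oracle", {
  # identical event/censor patterns in the two daughters: numerator is zero
  expect_equal(logrank_split_statistic(c(1, 2, 1, 2), c(1, 1, 1, 1),
                                       c(0, 0, 1, 1), 0.5), 0)
  # toy node: A = {1, 3} and B = {2, 4}, all events, split between groups
  t <- c(1, 3, 2, 4); s <- rep(1, 4); x <- c(0, 0, 1, 1)
  expect_equal(logrank_split_statistic(t, s, x, 0.5),
               logrank_brute(t, s, x, 0.5))
  # swapping daughters leaves |L| unchanged
  expect_equal(logrank_split_statistic(t, s, -x, -0.5),
               logrank_split_statistic(t, s, x, 0.5))
  expect_error(logrank_split_statistic(t, s, x, 5), "degenerate split")
})

test_that("log-rank split statistic matches brute force and survdiff", {
  set.seed(29)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    fx <- random_fixture(n)
    x <- rnorm(n)
    split <- median(x)
    if (all(x <= split) || !any(x <= split)) next
    expect_equal(logrank_split_statistic(fx$time, fx$status, x, split),
                 logrank_brute(fx$time, fx$status, x, split))
    # with (start, stop] rows and late entry
    start <- pmax(fx$time - sample(1:3, n, replace = TRUE), 0)
    expect_equal(logrank_split_statistic(fx$time, fx$status, x, split, start = start),
                 logrank_brute(fx$time, fx$status, x, split, start = start))
  }
  skip_if_not_installed("survival")
  set.seed(31)
  t <- c(rexp(30, 1), rexp(30, 2)); s <- rbinom(60, 1, 0.8); g <- rep(0:1, each = 30)
  if (sum(s) > 0) {
    L <- logrank_split_statistic(t, s, g, 0.5)
    sd <- survival::survdiff(survival::Surv(t, s) ~ g)
    expect_equal(L^2, unname(sd$chisq), tolerance = 1e-10)
  }
})

test_that("Yates chi-square reproduces the published dialysis associations", {
  expect_equal(round(yates_chi_square(167, 80, 851, 466), 4), 0.6944)
  expect_equal(round(yates_chi_square(7, 240, 184, 1133), 3), 23.036)
  # the hypertension/diabetes counts give each other's printed statistics
  expect_equal(round(yates_chi_square(194, 53, 918, 399), 2), 7.48)
  expect_equal(round(yates_chi_square(164, 83, 698, 619), 2), 14.55)
  expect_equal(yates_chi_square(10, 20, 5, 10), 0)  # ad = bc, clamped correction
  expect_error(yates_chi_square(0, 0, 3, 4), "zero margin")
})

test_that("chi-square agrees with stats::chisq.test on random tables", {
  set.seed(37)
  for (rep in 1:15) {
    m <- matrix(sample(1:40, 4, replace = TRUE), 2)
    expect_equal(yates_chi_square(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 unname(suppressWarnings(chisq.test(m, correct = TRUE))$statistic))
    expect_equal(yates_chi_square(m[1, 1], m[1, 2], m[2, 1], m[2, 2], correct = FALSE),
                 unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic))
  }
})

test_that("one-way F from summaries matches the published table and aov", {
  expect_equal(oneway_f_from_summary(247, 20.3, 14.19, 1317, 36.72, 13.78),
               292.58, tolerance = 0.02)
  expect_equal(oneway_f_from_summary(247, 75.85, 13.15, 1317, 81.35, 11.77),
               43.649, tolerance = 0.02)
  expect_equal(oneway_f_from_summary(10, 5, 2, 12, 5, 3), 0)
  set.seed(41)
  y1 <- rnorm(9, 1); y2 <- rnorm(14, 2)
  f <- oneway_f_from_summary(9, mean(y1), sd(y1), 14, mean(y2), sd(y2))
  av <- anova(aov(c(y1, y2) ~ factor(rep(1:2, c(9, 14)))))
  expect_equal(f, av$`F value`[1])
})
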