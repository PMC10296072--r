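test_that("cross-validation folds partition the patients deterministically", {
  co <- tiny_cohort(100, seed = 1)
  oracle <- list(oracle = function(train, test, h)
    list(risk = -test$time))
  cv1 <- kfold_cindex(co, models = "oracle", K = 5, seed = 3, extra_models = oracle)
  cv2 <- kfold_cindex(co, models = "oracle", K = 5, seed = 3, extra_models = oracle)
  expect_identical(cv1$folds, cv2$folds)
  all_ids <- sort(as.numeric(unlist(cv1$folds, use.names = FALSE)))
  expect_equal(all_ids, sort(co$patients$id))
  expect_equal(length(all_ids), length(unique(all_ids)))
})

test_that("an oracle risk score scores C = 1 in every fold, a permuted one 0.5", {
  co <- tiny_cohort(600, seed = 5)
  dummies <- list(
    oracle = function(train, test, h) list(risk = -test$time),
    noise = function(train, test, h) list(risk = rnorm(nrow(test))))
  cv <- kfold_cindex(co, models = c("oracle", "noise"), K = 5, seed = 7,
                     extra_models = dummies)
  ms <- cv$metrics
  expect_true(all(ms$cindex[ms$model == "oracle"] == 1))
  expect_lt(abs(mean(ms$cindex[ms$model == "noise"]) - 0.5), 0.05)
})

test_that("cut-off classification satisfies the confusion-matrix identities", {
  set.seed(9)
  n <- 200
  surv <- runif(n)
  time <- rexp(n, 1 / 900)
  event <- rbinom(n, 1, 0.6)
  for (ct in c(0.5, 0.65, 0.7)) {
    m <- cutoff_classification(surv, time, event, ct, horizon_days = 1095)
    # brute-force confusion counter
    tp <- fp <- tn <- fn <- 0; excl <- 0
    for (i in 1:n) {
      truth <- if (event[i] == 1 && time[i] <= 1095) "pos"
               else if (time[i] > 1095) "neg" else NA
      if (is.na(truth)) { excl <- excl + 1; next }
      pred <- surv[i] < ct
      if (truth == "pos" && pred) tp <- tp + 1
      if (truth == "pos" && !pred) fn <- fn + 1
      if (truth == "neg" && pred) fp <- fp + 1
      if (truth == "neg" && !pred) tn <- tn + 1
    }
    expect_equal(c(m$tp, m$fp, m$tn, m$fn, m$n_excluded), c(tp, fp, tn, fn, excl))
    expect_equal(m$sensitivity, tp / (tp + fn))
    expect_equal(m$specificity, tn / (tn + fp))
    expect_equal(m$accuracy, (tp + tn) / (tp + tn + fp + fn))
    expect_equal(m$precision, tp / (tp + fp))
    expect_equal(m$f1, 2 * m$precision * m$sensitivity / (m$precision + m$sensitivity))
  }
  # cutoff 0: nobody classified positive
  m0 <- cutoff_classification(surv, time, event, 0)
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$specificity, 1)
})

test_that("F1 reproduces the published precision/sensitivity identities", {
  expect_equal(round(f1_score(0.567, 0.708), 3), 0.630)
  expect_equal(round(f1_score(0.792, 0.791), 3), 0.791)
  expect_equal(round(f1_score(0.458, 0.917), 2), 0.61)
  expect_true(is.na(f1_score(0, 0)))
})

test_that("probability summaries match an independent quantile routine", {
  co <- tiny_cohort(150, seed = 11)
  oracle <- list(
    oracle = function(train, test, h) {
      se <- vapply(seq_len(nrow(test)), function(i)
        oracle_survival(co, test$id[i], test$time[i]), numeric(1))
      list(risk = 1 - se, surv_endpoint = se,
           surv_horizon = vapply(test$id, function(pid)
             oracle_survival(co, pid, h), numeric(1)))
    },
    flat = function(train, test, h)
      list(risk = rep(0, nrow(test)), surv_endpoint = rep(0.8, nrow(test))))
  cv <- kfold_cindex(co, models = c("oracle", "flat"), K = 3, seed = 13,
                     extra_models = oracle)
  ps <- cohort_probability_summary(cv)
  # manual type-7 quantile on the same values
  pm <- cv$predictions[cv$predictions$model == "oracle" & cv$predictions$event == 0, ]
  manual_q <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h); x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  row <- ps[ps$model == "oracle" & ps$group == "nondialysis", ]
  expect_equal(row$median, manual_q(pm$surv_endpoint, 0.5), tolerance = 1e-12)
  expect_equal(row$q25, manual_q(pm$surv_endpoint, 0.25), tolerance = 1e-12)
  # the generator's own survival separates the outcome groups
  dia <- ps[ps$model == "oracle" & ps$group == "dialysis", ]
  expect_gt(row$median, 1 - dia$median)
  # an all-constant model has zero interquartile range
  flat <- ps[ps$model == "flat" & ps$group == "nondialysis", ]
  expect_equal(flat$q75 - flat$q25, 0)
})

test_that("the generator oracle is consistent with the 0.70 rule for most patients", {
  co <- tiny_cohort(300, seed = 17)
  p <- co$patients
  s_end <- vapply(seq_len(nrow(p)), function(i)
    oracle_survival(co, p$id[i], p$endpoint_day[i]), numeric(1))
  consistent <- ifelse(p$event == 0, s_end >= 0.70, s_end < 0.70)
  expect_gt(mean(consistent), 0.7)
})

test_that("individual validation holds the patient out and scores consistency", {
  co <- tiny_cohort(80, seed = 19)
  ev_id <- co$patients$id[which(co$patients$event == 1)[1]]
  cs_id <- co$patients$id[which(co$patients$event == 0)[1]]
  for (pid in c(ev_id, cs_id)) {
    val <- individual_km_validation(co, pid, models = c("cox", "rsf"),
                                    seed = 21, control = rsf_control(ntree = 20))
    pat <- co$patients[co$patients$id == pid, ]
    expect_equal(val$event, pat$event)
    for (m in c("cox", "rsf")) {
      cv <- val$curves[[m]]
      expect_true(all(diff(cv$surv) <= 1e-12))
      v <- val$verdicts[val$verdicts$model == m, ]
      expect_equal(v$consistent,
                   if (pat$event == 0) v$surv_at_endpoint >= 0.7
                   else v$surv_at_endpoint < 0.7)
    }
  }
  expect_error(individual_km_validation(co, -1), "unknown patient")
})

test_that("the three real models produce finite fold metrics on a small cohort", {
  co <- tiny_cohort(120, seed = 23)
  cv <- kfold_cindex(co, K = 3, seed = 23, control = rsf_control(ntree = 20))
  expect_equal(nrow(cv$metrics), 9L)
  expect_true(all(is.finite(cv$metrics$cindex)))
  expect_true(all(cv$metrics$cindex >= 0 & cv$metrics$cindex <= 1))
  expect_setequal(names(cv$mean), c("cox", "rsf", "ann"))
  tbl <- cutoff_table(cv)
  expect_equal(nrow(tbl), 9L)
  expect_true(all(tbl$accuracy >= 0 & tbl$accuracy <= 1, na.rm = TRUE))
})
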