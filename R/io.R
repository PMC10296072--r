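cohort_csv_columns <- function(cohort) {
  c("id", "day", "event", "endpoint_day", static_names(),
    intersect(time_varying_names(), names(cohort$visits)))
}

fmt_num <- function(x) {
  # shortest decimal representation that round-trips a double exactly
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

#' Write a cohort as long-format CSV
#'
#' One row per clinic visit; the static covariates, event indicator and
#' endpoint day are repeated on every row of a patient. Numeric values are
#' written with 17 significant digits so a write/read round trip reproduces
#' the cohort bit-exactly. UTF-8, comma separator, `.` decimal.
#'
#' @param cohort a `ckd_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  pats <- cohort$patients
  long <- merge(cohort$visits, pats, by = "id", sort = FALSE)
  long <- long[order(long$id, long$day), cohort_csv_columns(cohort), drop = FALSE]
  out <- as.data.frame(lapply(long, function(col)
    if (is.numeric(col)) fmt_num(col) else as.character(col)),
    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- names(long)
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format cohort CSV
#'
#' Expects the columns written by [write_cohort_csv()] (at minimum `id`,
#' `day`, `event`, `endpoint_day`, plus covariates). Rows are grouped by
#' patient and sorted by visit day; patient-level invariants are validated
#' and malformed rows are reported with their file line numbers (header =
#' line 1): duplicated visit days, endpoint before the last visit, and
#' static/endpoint values that conflict within a patient.
#'
#' @param path CSV file path.
#' @return a `ckd_cohort` (without a generating `config`).
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("id", "day", "event", "endpoint_day")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  statics <- intersect(static_names(), names(df))
  labs <- intersect(time_varying_names(), names(df))
  df$.line <- seq_len(nrow(df)) + 1L

  pat_rows <- list(); visit_rows <- list()
  for (pid in unique(df$id)) {
    sub <- df[df$id == pid, , drop = FALSE]
    sub <- sub[order(sub$day), , drop = FALSE]
    if (anyDuplicated(sub$day)) {
      bad <- sub$.line[duplicated(sub$day)]
      stop("duplicated visit day for patient ", pid, " at line(s) ",
           paste(bad, collapse = ", "))
    }
    for (v in c("event", "endpoint_day", statics)) {
      if (length(unique(sub[[v]])) != 1)
        stop("conflicting '", v, "' values within patient ", pid,
             " (lines ", paste(sub$.line, collapse = ", "), ")")
    }
    if (!sub$event[1] %in% c(0, 1))
      stop("event must be 0/1 for patient ", pid, " (line ", sub$.line[1], ")")
    if (sub$endpoint_day[1] < max(sub$day))
      stop("endpoint_day before last visit for patient ", pid,
           " (line ", sub$.line[which.max(sub$day)], ")")
    pat_rows[[length(pat_rows) + 1L]] <-
      cbind(data.frame(id = pid), sub[1, statics, drop = FALSE],
            data.frame(event = as.integer(sub$event[1]),
                       endpoint_day = sub$endpoint_day[1]))
    visit_rows[[length(visit_rows) + 1L]] <-
      cbind(data.frame(id = pid, day = sub$day), sub[, labs, drop = FALSE])
  }
  patients <- do.call(rbind, pat_rows); rownames(patients) <- NULL
  visits <- do.call(rbind, visit_rows); rownames(visits) <- NULL
  structure(list(patients = patients, visits = visits, truth = NULL,
                 config = NULL),
            class = "ckd_cohort")
}

write_report_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (v in names(df)[num]) out[[v]] <- fmt_num(df[[v]])
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end study workflow: obtain a cohort (generate
#' synthetically or read from CSV), apply the minimum-visit exclusion,
#' cross-validate the three time-dependent models, derive cut-off
#' classification metrics and probability summaries from the out-of-fold
#' predictions, fit a full-data forest for the permutation-importance
#' ranking, and write every artifact under `outdir`:
#' \itemize{
#'   \item `cohort.csv` — the analyzed cohort (round-trippable),
#'   \item `cindex.csv` — per-fold and average C-index per model,
#'   \item `cutoff_metrics.csv` — sensitivity/specificity/accuracy/precision/F1
#'     per model and cut-off,
#'   \item `probability_summary.csv` — quartiles of predicted probabilities,
#'   \item `vimp.csv` — descending permutation importances,
#'   \item `run_config.json` — the resolved settings and seed.
#' }
#' Reruns with the same seed produce byte-identical numeric reports.
#'
#' @param generator a [cohort_config()] (exactly one of `generator`/`input`).
#' @param input path to a long-format cohort CSV.
#' @param outdir output directory, created if needed.
#' @param seed mandatory integer seed for every stochastic stage.
#' @param K cross-validation folds.
#' @param cutoffs classification thresholds.
#' @param horizon_days outcome horizon (default: generator's, else 1095).
#' @param min_visits exclusion threshold (default 3).
#' @param models models to run.
#' @param control forest hyperparameters.
#' @param verbose print per-stage progress with timings.
#' @return invisibly, a list with the cohort, the `ckd_cv` object, the metric
#'   tables, the forest and the VIMP ranking.
#' @export
run_pipeline <- function(generator = NULL, input = NULL, outdir, seed,
                         K = 5, cutoffs = c(0.65, 0.70, 0.75),
                         horizon_days = NULL, min_visits = 3,
                         models = c("cox", "rsf", "ann"),
                         control = rsf_control(), verbose = TRUE) {
  if (is.null(generator) == is.null(input))
    stop("exactly one of 'generator' or 'input' must be given")
  if (missing(seed)) stop("seed is mandatory")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, t0) if (verbose)
    message(sprintf("[%s] done in %.1fs", stage, as.numeric(Sys.time()) - t0))

  t0 <- as.numeric(Sys.time())
  cohort <- if (!is.null(generator)) {
    generator$seed <- as.integer(seed)
    generate_cohort(generator)
  } else read_cohort_csv(input)
  say("cohort", t0)

  t0 <- as.numeric(Sys.time())
  cohort <- apply_exclusions(cohort, min_visits = min_visits)
  write_cohort_csv(cohort, file.path(outdir, "cohort.csv"))
  say("exclusions", t0)

  if (is.null(horizon_days))
    horizon_days <- if (!is.null(cohort$config)) cohort$config$horizon_days else 1095

  t0 <- as.numeric(Sys.time())
  cv <- kfold_cindex(cohort, models = models, K = K,
                     seed = derive_seed(seed, 1), horizon_days = horizon_days,
                     control = control)
  wide <- as.data.frame.matrix(
    tapply(cv$metrics$cindex, list(cv$metrics$model, cv$metrics$fold), identity))
  names(wide) <- paste0("fold", names(wide))
  cindex_tbl <- cbind(data.frame(model = rownames(wide)), wide,
                      average = rowMeans(wide))
  rownames(cindex_tbl) <- NULL
  write_report_csv(cindex_tbl, file.path(outdir, "cindex.csv"))
  say("cross-validation", t0)

  t0 <- as.numeric(Sys.time())
  cut_tbl <- cutoff_table(cv, cutoffs)
  write_report_csv(cut_tbl, file.path(outdir, "cutoff_metrics.csv"))
  prob_tbl <- cohort_probability_summary(cv)
  write_report_csv(prob_tbl, file.path(outdir, "probability_summary.csv"))
  say("classification metrics", t0)

  forest <- NULL; vimp_tbl <- NULL
  if ("rsf" %in% models) {
    t0 <- as.numeric(Sys.time())
    lm_df <- landmark_features(cohort, default_rsf_spec())
    forest <- fit_forest(lm_df, control = control, seed = derive_seed(seed, 2))
    vimp_tbl <- vimp_report(forest, seed = derive_seed(seed, 3))
    write_report_csv(vimp_tbl, file.path(outdir, "vimp.csv"))
    say("forest importance", t0)
  }

  resolved <- list(seed = seed, K = K, cutoffs = cutoffs,
                   horizon_days = horizon_days, min_visits = min_visits,
                   models = models,
                   source = if (!is.null(input)) input else "synthetic generator",
                   n_patients = nrow(cohort$patients),
                   n_events = sum(cohort$patients$event),
                   ntree = control$ntree)
  jsonlite::write_json(resolved, file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, cv = cv, cindex = cindex_tbl,
                 cutoff_metrics = cut_tbl, probability_summary = prob_tbl,
                 forest = forest, vimp = vimp_tbl))
}
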