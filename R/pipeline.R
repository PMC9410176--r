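# Orchestration: per-subject marker computation, cohort-level comparison,
# declarative exclusion filters, and run manifests.

#' Compute the full per-subject result row
#'
#' Runs quality control, beat detection and segmentation, then the
#' morphology markers for both analysis modes (one randomly selected beat
#' and the averaged beat) and the V5 interval set measured on the averaged
#' beat with the recording-mean RR for Bazett correction. Subjects failing
#' quality control yield a row with `usable = FALSE` and missing markers;
#' any stage error is captured in the `error` column rather than raised, so
#' one bad recording never aborts a cohort run.
#'
#' @param record an [ecg_record()]
#' @param seed integer seed for the random-beat choice
#' @param modes subset of `c("random", "averaged")`
#' @param ... forwarded to [compute_markers()]
#' @return one-row data.frame
#' @export
run_subject <- function(record, seed = NULL,
                        modes = c("random", "averaged"), ...) {
  row <- data.frame(
    subject_id = record$subject_id, usable = FALSE,
    tcrt_random = NA_real_, tmd_random = NA_real_,
    tmd_pre_random = NA_real_, tmd_post_random = NA_real_,
    tcrt_averaged = NA_real_, tmd_averaged = NA_real_,
    tmd_pre_averaged = NA_real_, tmd_post_averaged = NA_real_,
    qt_ms = NA_real_, qtc_ms = NA_real_, tpe_ms = NA_real_,
    tpe_qt = NA_real_, tpe_qtc = NA_real_, rr_s = NA_real_,
    energy_fraction_3 = NA_real_, n_beats = NA_integer_,
    error = NA_character_, stringsAsFactors = FALSE
  )
  tryCatch({
    qc <- quality_check(record)
    if (!qc$usable) {
      row$error <- "failed quality control"
      return(row)
    }
    peaks <- detect_r_peaks(record)
    beats <- segment_beats(record, peaks)
    row$n_beats <- length(beats)
    row$rr_s <- mean(diff(peaks)) / record$fs
    avg <- average_beat(beats)
    if ("averaged" %in% modes) {
      m <- compute_markers(avg, ...)
      row$tcrt_averaged <- m$tcrt
      row$tmd_averaged <- m$tmd
      row$tmd_pre_averaged <- m$tmd_pre
      row$tmd_post_averaged <- m$tmd_post
      row$energy_fraction_3 <- m$energy_fraction_3
      # interval set from the averaged (template) beat, lead V5
      iv <- tryCatch(
        measure_intervals(avg$samples["V5", ], m$landmarks,
                          rr = row$rr_s, fs = avg$fs),
        error = function(e) NULL
      )
      if (!is.null(iv)) {
        row$qt_ms <- iv$qt; row$qtc_ms <- iv$qtc; row$tpe_ms <- iv$tpe
        row$tpe_qt <- iv$tpe_qt; row$tpe_qtc <- iv$tpe_qtc
      }
    }
    if ("random" %in% modes) {
      rb <- select_random_beat(beats, seed = seed)
      m <- compute_markers(rb, ...)
      row$tcrt_random <- m$tcrt
      row$tmd_random <- m$tmd
      row$tmd_pre_random <- m$tmd_pre
      row$tmd_post_random <- m$tmd_post
      if (is.na(row$energy_fraction_3)) {
        row$energy_fraction_3 <- m$energy_fraction_3
      }
    }
    row$usable <- TRUE
    row
  }, error = function(e) {
    row$error <- conditionMessage(e)
    row
  })
}

#' Run the whole cohort analysis
#'
#' Computes per-subject rows, joins the cohort covariate table, builds the
#' case-control summary table (markers, intervals and clinical covariates)
#' and fits the confounder-adjustment linear model for the averaged-beat
#' TCRT. Fully deterministic given the inputs and `seed` (per-subject
#' random-beat seeds are derived from it). When `out_dir` is set, writes
#' `results.csv`, `summary.csv`, `model.json`, and `manifest.json`.
#'
#' @param records list of [ecg_record()]
#' @param cohort a `cohort_table` with a `subject_id` column matching the
#'   records
#' @param seed integer master seed
#' @param out_dir optional output directory
#' @param model_outcome outcome for [fit_linear_model()]; skipped if the
#'   column is absent or all-NA
#' @param ... forwarded to [run_subject()]
#' @return list with `results`, `summary`, `model`, `manifest`
#' @export
run_cohort <- function(records, cohort, seed = 1, out_dir = NULL,
                       model_outcome = "tcrt_averaged", ...) {
  stopifnot(is.list(records), length(records) >= 1)
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    rows[[i]] <- run_subject(records[[i]], seed = seed + i, ...)
  }
  results <- do.call(rbind, rows)
  if (!any(results$usable)) stop("no usable subjects")
  merged <- merge(cohort, results, by = "subject_id", sort = TRUE)

  marker_cols <- intersect(
    c("tcrt_random", "tmd_random", "tmd_pre_random", "tmd_post_random",
      "tcrt_averaged", "tmd_averaged", "tmd_pre_averaged",
      "tmd_post_averaged", "qt_ms", "qtc_ms", "tpe_ms", "tpe_qt",
      "tpe_qtc", "age", "height", "weight", "bmi", "sbp", "dbp"),
    names(merged))
  binary_cols <- intersect(
    c("dyslipidemia", "hypertension", "fhx_ihd", "aspirin", "acei_arb",
      "ccb", "beta_blocker", "statin", "thiazide", "current_smoker",
      "past_smoker"),
    names(merged))
  usable <- merged[merged$usable %in% TRUE, , drop = FALSE]
  # degenerate cohorts (a group with no usable subject) yield no summary
  summary_tab <- tryCatch(
    build_summary_table(usable, group_col = "group",
                        continuous = marker_cols, binary = binary_cols),
    error = function(e) NULL)
  model <- NULL
  if (model_outcome %in% names(usable) &&
      any(!is.na(usable[[model_outcome]]))) {
    model <- tryCatch(
      suppressMessages(fit_linear_model(usable, model_outcome)),
      error = function(e) NULL)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("repolab")),
    seed = seed,
    n_records = length(records),
    n_usable = sum(results$usable),
    config_hash = config_hash(list(seed = seed, n = length(records),
                                   subjects = results$subject_id)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    if (!is.null(summary_tab)) {
      utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"),
                       row.names = FALSE)
    }
    if (!is.null(model)) {
      jsonlite::write_json(model$coefficients,
                           file.path(out_dir, "model.json"), digits = NA)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(results = results, summary = summary_tab, model = model,
       manifest = manifest)
}

#' Declarative cohort exclusion filters
#'
#' A filter table has columns `column`, `op` (one of `==`, `!=`, `<`, `<=`,
#' `>`, `>=`) and `value`; a subject matching any filter is excluded and is
#' attributed to the first filter it matches, so per-reason counts partition
#' the excluded set.
#'
#' @param cohort a `cohort_table` (or data.frame)
#' @param filters filter data.frame; [default_exclusion_filters()] encodes
#'   the usual cardiovascular screening criteria
#' @return list with `included`, `excluded`, per-reason `counts`, and
#'   `n_included`
#' @export
apply_exclusions <- function(cohort, filters = default_exclusion_filters()) {
  stopifnot(all(c("column", "op", "value") %in% names(filters)))
  n <- nrow(cohort)
  reason <- rep(NA_character_, n)
  for (k in seq_len(nrow(filters))) {
    col <- filters$column[k]
    if (!col %in% names(cohort)) next
    x <- cohort[[col]]
    val <- filters$value[k]
    if (is.logical(x)) val <- as.logical(val)
    if (is.numeric(x)) val <- as.numeric(val)
    hit <- switch(filters$op[k],
      "==" = x == val, "!=" = x != val,
      "<" = x < val, "<=" = x <= val,
      ">" = x > val, ">=" = x >= val,
      stop("unknown filter op: ", filters$op[k]))
    hit[is.na(hit)] <- FALSE
    newly <- hit & is.na(reason)
    reason[newly] <- sprintf("%s %s %s", col, filters$op[k], filters$value[k])
  }
  excluded <- !is.na(reason)
  counts <- table(factor(reason[excluded], levels = unique(reason[excluded])))
  list(included = cohort[!excluded, , drop = FALSE],
       excluded = cbind(cohort[excluded, , drop = FALSE],
                        reason = reason[excluded]),
       counts = counts,
       n_included = sum(!excluded))
}

#' @rdname apply_exclusions
#' @export
default_exclusion_filters <- function() {
  data.frame(
    column = c("age", "pregnant", "history_mi", "angiography", "cabg",
               "fhx_scd", "surgery_or_malignancy", "afib_pacemaker"),
    op = c("<", rep("==", 7)),
    value = c("18", rep("TRUE", 7)),
    stringsAsFactors = FALSE
  )
}

#' Share of a subgroup in percent
#'
#' @param n_sub subgroup count
#' @param n_total total count
#' @param digits rounding for reporting
#' @return percentage
#' @export
group_share <- function(n_sub, n_total, digits = 1) {
  stopifnot(n_total > 0, n_sub >= 0, n_sub <= n_total)
  round(100 * n_sub / n_total, digits)
}
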