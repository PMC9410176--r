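# Reading, writing and validating 12-lead ECG recordings and cohort tables.
#
# Internal canonical amplitude unit is millivolts. Readers convert on load.

# Canonical lead labels and accepted synonyms (case-insensitive after
# stripping spaces). "ML*" labels are the modified limb leads used by some
# ambulatory systems.
.LEAD_CANONICAL <- c("I", "II", "III", "aVR", "aVL", "aVF",
                     "V1", "V2", "V3", "V4", "V5", "V6")

.LEAD_SYNONYMS <- c(
  "i" = "I", "lead_i" = "I", "mli" = "I",
  "ii" = "II", "lead_ii" = "II", "mlii" = "II",
  "iii" = "III", "lead_iii" = "III", "mliii" = "III",
  "avr" = "aVR", "avl" = "aVL", "avf" = "aVF",
  "v1" = "V1", "v2" = "V2", "v3" = "V3",
  "v4" = "V4", "v5" = "V5", "v6" = "V6"
)

# The eight leads carrying independent information; the remaining four are
# fixed linear combinations (Einthoven/Goldberger identities).
.INDEPENDENT_LEADS <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

#' Normalize ECG lead labels to canonical names
#'
#' @param labels character vector of lead labels as found in a file header
#' @return canonical labels; unknown labels are returned unchanged
#' @export
normalize_lead_names <- function(labels) {
  key <- tolower(gsub("[[:space:]]", "", labels))
  out <- .LEAD_SYNONYMS[key]
  ifelse(is.na(out), labels, unname(out))
}

#' Construct a validated ECG recording
#'
#' An `ecg_record` holds uniformly sampled multi-lead ECG amplitudes in
#' millivolts, one column per lead.
#'
#' @param samples numeric matrix, one column per lead, one row per sample (mV)
#' @param lead_names character labels for the columns; normalized on input
#' @param fs sampling rate in Hz
#' @param subject_id opaque identifier
#' @return an object of class `ecg_record` with fields `samples`, `fs`,
#'   `subject_id`; `duration` is derivable as `nrow(samples)/fs`
#' @export
ecg_record <- function(samples, lead_names = colnames(samples), fs,
                       subject_id = "anonymous") {
  samples <- as.matrix(samples)
  if (is.null(lead_names)) stop("lead names are required")
  lead_names <- normalize_lead_names(lead_names)
  if (length(lead_names) != ncol(samples)) {
    stop("lead_names length must match the number of sample columns")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be > 0")
  if (anyDuplicated(lead_names)) stop("duplicated lead names")
  missing <- setdiff(.INDEPENDENT_LEADS, lead_names)
  if (length(missing) > 0) {
    stop("incomplete lead set: missing ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(samples))) stop("non-finite samples in record")
  colnames(samples) <- lead_names
  structure(
    list(samples = samples, fs = fs, subject_id = subject_id),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> subject=%s  %d leads x %d samples  fs=%g Hz  (%.2f s)\n",
              x$subject_id, ncol(x$samples), nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  invisible(x)
}

#' @export
plot.ecg_record <- function(x, leads = c("II", "V5"), ...) {
  t <- seq_len(nrow(x$samples)) / x$fs
  leads <- intersect(leads, colnames(x$samples))
  old <- graphics::par(mfrow = c(length(leads), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (ld in leads) {
    graphics::plot(t, x$samples[, ld], type = "l", xlab = "s",
                   ylab = paste0(ld, " (mV)"), ...)
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param record an `ecg_record`
#' @export
record_duration <- function(record) nrow(record$samples) / record$fs

#' Read a 12-lead ECG recording
#'
#' Two dialects are supported: a lead-per-column CSV with a JSON sidecar
#' (same basename, `.json` extension, declaring at least `fs` and optionally
#' `units` and `subject_id`), and WFDB format-16 records (`.hea`/`.dat`).
#' An optional `time` column in the CSV is checked for uniform sampling.
#'
#' @param path path to the `.csv` or `.hea` file (or WFDB record basename)
#' @param format `"auto"` (by extension), `"csv"` or `"wfdb"`
#' @return an [ecg_record()]
#' @export
read_ecg <- function(path, format = c("auto", "csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path)) "csv" else "wfdb"
  }
  if (format == "csv") read_ecg_csv(path) else read_wfdb(path)
}

read_ecg_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- sub("\\.csv$", ".json", path)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar does not declare fs")
  x <- utils::read.csv(path, check.names = FALSE)
  nm <- normalize_lead_names(names(x))
  names(x) <- nm
  if ("time" %in% nm) {
    dt <- diff(x$time)
    if (length(dt) > 1 && (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
      stop("unsupported format dialect: non-uniform sampling")
    }
    x$time <- NULL
  }
  m <- as.matrix(x)
  units <- if (is.null(meta$units)) "mV" else meta$units
  scale <- switch(units, mV = 1, uV = 1e-3, V = 1e3,
                  stop("unsupported amplitude unit: ", units))
  ecg_record(m * scale, colnames(m), fs = meta$fs,
             subject_id = if (is.null(meta$subject_id)) "anonymous"
                          else meta$subject_id)
}

#' Write a 12-lead ECG recording
#'
#' @param record an [ecg_record()]
#' @param path output path: `.csv` (JSON sidecar written alongside) or WFDB
#'   record basename / `.hea` path
#' @param format `"auto"`, `"csv"` or `"wfdb"`
#' @param gain WFDB analog-to-digital gain in adu/mV (format 16 quantizes to
#'   `1/gain` mV)
#' @return `path`, invisibly
#' @export
write_ecg <- function(record, path, format = c("auto", "csv", "wfdb"),
                      gain = 1000) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path)) "csv" else "wfdb"
  }
  if (format == "csv") {
    utils::write.csv(as.data.frame(record$samples), path, row.names = FALSE)
    jsonlite::write_json(
      list(fs = record$fs, units = "mV", subject_id = record$subject_id),
      sub("\\.csv$", ".json", path), auto_unbox = TRUE
    )
  } else {
    write_wfdb(record, path, gain = gain)
  }
  invisible(path)
}

#' Extract the eight independent leads as a lead-by-sample matrix
#'
#' Of the standard 12 leads only I, II and V1-V6 carry independent
#' information; III, aVR, aVL and aVF are fixed linear combinations. The
#' Einthoven identity III = II - I is checked when lead III is present and a
#' warning is raised if it fails beyond tolerance (a sign of mislabelled or
#' corrupted leads); the output is unchanged.
#'
#' @param record an [ecg_record()]
#' @param einthoven_tol tolerance in mV for the III = II - I consistency check
#' @return 8 x N numeric matrix with rows `I, II, V1..V6`
#' @export
derive_independent_leads <- function(record, einthoven_tol = 0.05) {
  nm <- colnames(record$samples)
  missing <- setdiff(.INDEPENDENT_LEADS, nm)
  if (length(missing) > 0) {
    stop("incomplete lead set: missing ", paste(missing, collapse = ", "))
  }
  if ("III" %in% nm) {
    resid <- max(abs(record$samples[, "III"] -
                       (record$samples[, "II"] - record$samples[, "I"])))
    if (resid > einthoven_tol) {
      warning(sprintf(
        "Einthoven consistency check failed: max |III - (II - I)| = %.3g mV",
        resid))
    }
  }
  t(record$samples[, .INDEPENDENT_LEADS, drop = FALSE])
}

#' Read a cohort covariate table
#'
#' Expects a CSV with one row per subject and at least a `group` column
#' (case/control labels). Recognized clinical columns (age, sex, height,
#' weight, bmi, blood pressures, binary risk-factor and medication flags)
#' are type-coerced; unknown columns are preserved untouched. When height,
#' weight and BMI are all present, BMI is checked against weight/height^2
#' and rows off by 0.1 kg/m^2 or more raise a validation warning.
#'
#' @param path CSV path
#' @return a `data.frame` of class `cohort_table`
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_cohort_table(x)
}

#' @rdname read_cohort
#' @param x a data.frame with cohort covariates
#' @export
as_cohort_table <- function(x) {
  if (!"group" %in% names(x)) stop("no group label")
  if (any(is.na(x$group) | x$group == "")) stop("no group label: missing values")
  binary_cols <- intersect(
    c("dyslipidemia", "hypertension", "fhx_ihd", "aspirin", "acei_arb",
      "ccb", "beta_blocker", "statin", "thiazide", "current_smoker",
      "past_smoker", "history_mi", "angiography", "cabg", "fhx_scd",
      "pregnant", "surgery_or_malignancy", "afib_pacemaker"),
    names(x))
  for (cc in binary_cols) x[[cc]] <- as.logical(x[[cc]])
  num_cols <- intersect(c("age", "height", "weight", "bmi", "sbp", "dbp"),
                        names(x))
  for (cc in num_cols) x[[cc]] <- as.numeric(x[[cc]])
  if (all(c("height", "weight", "bmi") %in% names(x))) {
    ok <- stats::complete.cases(x[, c("height", "weight", "bmi")])
    dev <- abs(x$bmi[ok] - x$weight[ok] / x$height[ok]^2)
    if (any(dev >= 0.1)) {
      warning(sprintf("%d row(s) with BMI inconsistent with weight/height^2",
                      sum(dev >= 0.1)))
    }
  }
  class(x) <- c("cohort_table", "data.frame")
  x
}
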