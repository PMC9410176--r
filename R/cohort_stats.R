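# Case-control statistics layer: mean +/- SEM summaries, 2-SD abnormality
# flag, Kruskal-Wallis and Fisher's exact group comparisons, and the
# multivariable linear model for confounding.

#' Per-group mean and standard error of the mean
#'
#' SEM is `sd/sqrt(n)` with the n-1 denominator for sd. Groups of size 1
#' have undefined SEM and are reported as 0 with a warning.
#'
#' @param values numeric vector
#' @param groups grouping vector of the same length
#' @return data.frame with columns `group`, `n`, `mean`, `sem`
#' @export
summarize_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  out <- lapply(split(values, groups), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) stop("empty group")
    if (length(v) == 1) {
      warning("group of size 1: SEM undefined, reported as 0")
      return(c(n = 1, mean = v, sem = 0))
    }
    c(n = length(v), mean = mean(v), sem = stats::sd(v) / sqrt(length(v)))
  })
  data.frame(group = names(out),
             n = vapply(out, `[[`, numeric(1), "n"),
             mean = vapply(out, `[[`, numeric(1), "mean"),
             sem = vapply(out, `[[`, numeric(1), "sem"),
             row.names = NULL)
}

#' Flag a value as abnormal relative to a reference distribution
#'
#' Abnormal means strictly more than 2 reference standard deviations from
#' the reference mean.
#'
#' @param value numeric value(s) to test
#' @param reference_mean,reference_sd reference distribution parameters
#' @param n_sd abnormality threshold in SD units
#' @return logical
#' @export
flag_abnormal <- function(value, reference_mean, reference_sd, n_sd = 2) {
  if (!is.numeric(reference_sd) || reference_sd <= 0) {
    stop("invalid reference: sd must be > 0")
  }
  abs(value - reference_mean) > n_sd * reference_sd
}

#' Kruskal-Wallis rank test between groups
#'
#' Tie-corrected H statistic. For two-group samples of total size up to
#' `exact_n` the p-value is computed by exhaustive enumeration of all group
#' assignments (the exact permutation distribution of H, where the
#' chi-square approximation is unreliable); larger samples use the
#' chi-square reference distribution on k-1 degrees of freedom via
#' [stats::kruskal.test()]. The degenerate all-identical case is reported
#' as H = 0, p = 1.
#'
#' @param values numeric vector
#' @param groups grouping vector
#' @param exact_n largest two-group total size handled by exact enumeration
#' @return list with `statistic` (H) and `p_value`
#' @export
kruskal_wallis <- function(values, groups, exact_n = 12) {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- as.factor(as.character(groups)[keep])
  if (any(tabulate(groups) == 0) || nlevels(groups) < 2) {
    stop("need >= 2 nonempty groups")
  }
  n <- length(values)
  if (n < 3) stop("need total n >= 3")
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, p_value = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  h_obs <- unname(kt$statistic)
  p <- kt$p.value
  if (nlevels(groups) == 2 && n <= exact_n) {
    r <- rank(values)
    ties <- table(r)
    corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    n1 <- sum(groups == levels(groups)[1])
    h_of <- function(idx) {
      r1 <- sum(r[idx]); r2 <- sum(r) - r1
      (12 / (n * (n + 1)) * (r1^2 / n1 + r2^2 / (n - n1)) - 3 * (n + 1)) / corr
    }
    splits <- utils::combn(n, n1)
    h_all <- apply(splits, 2, h_of)
    p <- mean(h_all >= h_obs - 1e-12)
  }
  list(statistic = h_obs, p_value = p)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one (via [stats::fisher.test()]). A table with a zero
#' margin carries no information and is reported as p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts
#' @return list with `p_value` and the odds-ratio estimate `estimate`
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin: Fisher's exact test is uninformative, p = 1")
    return(list(p_value = 1, estimate = NA_real_))
  }
  ft <- stats::fisher.test(table)
  list(p_value = ft$p.value, estimate = unname(ft$estimate))
}

#' Multivariable linear model for confounder adjustment
#'
#' Ordinary least squares of a marker on the group indicator and clinical
#' covariates, binary covariates coded 0/1, coefficient p-values from the t
#' distribution on n-p degrees of freedom. BMI is structurally near-collinear
#' with height and weight and is dropped by default (with a message). An
#' exactly rank-deficient design raises a "collinear covariates" error
#' naming the aliased columns.
#'
#' @param data data.frame holding the outcome and covariates
#' @param outcome outcome column name (e.g. `"tcrt_averaged"`)
#' @param covariates covariate column names; defaults to the clinical set
#'   present in `data`
#' @param drop_bmi drop `bmi` from the default covariate list
#' @return object of class `linear_model_result`: data.frame `coefficients`
#'   (term, estimate, se, p_value), the `outcome` name and the fitted `model`
#' @export
fit_linear_model <- function(data, outcome, covariates = NULL,
                             drop_bmi = TRUE) {
  default_covs <- c("group", "age", "sex", "height", "weight", "bmi",
                    "dyslipidemia", "hypertension", "fhx_ihd", "aspirin",
                    "acei_arb", "ccb", "beta_blocker", "statin", "thiazide")
  if (is.null(covariates)) {
    covariates <- intersect(default_covs, names(data))
    if (drop_bmi && "bmi" %in% covariates &&
        all(c("height", "weight") %in% covariates)) {
      covariates <- setdiff(covariates, "bmi")
      message("dropping bmi: structurally collinear with height and weight")
    }
  }
  if (any(is.na(data[[outcome]]))) {
    data <- data[!is.na(data[[outcome]]), , drop = FALSE]
  }
  df <- data[, c(outcome, covariates), drop = FALSE]
  for (cc in covariates) {
    if (is.logical(df[[cc]])) df[[cc]] <- as.integer(df[[cc]])
    if (is.character(df[[cc]])) df[[cc]] <- as.factor(df[[cc]])
  }
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(covariates, collapse = " + ")))
  mm <- stats::model.matrix(fml, data = df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("collinear covariates: ", paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(fml, data = df)
  cf <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], p_value = cf[, 4],
                              row.names = NULL),
    outcome = outcome, model = fit
  ), class = "linear_model_result")
}

#' @export
print.linear_model_result <- function(x, ...) {
  cat(sprintf("<linear_model_result> outcome=%s\n", x$outcome))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Render a p-value the way clinical summary tables do
#'
#' `p >= 0.05` is "NS", `p < 0.01` is "<0.01", anything between is shown
#' with two decimals.
#'
#' @param p numeric p-value(s)
#' @return character
#' @export
format_p <- function(p) {
  ifelse(p >= 0.05, "NS", ifelse(p < 0.01, "<0.01", sprintf("%.2f", p)))
}

#' Build a case-control summary table
#'
#' One row per variable: continuous variables get per-group mean +/- SEM and
#' a Kruskal-Wallis p-value; binary variables get per-group percentages and
#' a Fisher's exact p-value. P-values are also rendered as in clinical
#' tables (see [format_p()]).
#'
#' @param data data.frame with one row per subject
#' @param group_col grouping column name
#' @param continuous,binary character vectors of column names; defaults pick
#'   numeric/logical columns automatically (minus identifiers)
#' @return data.frame of class `summary_table` with columns `variable`,
#'   `type`, one summary column per group, `test`, `statistic`, `p_value`,
#'   `p_label`
#' @export
build_summary_table <- function(data, group_col = "group",
                                continuous = NULL, binary = NULL) {
  g <- as.factor(as.character(data[[group_col]]))
  lev <- levels(g)
  if (length(lev) != 2) stop("summary table requires exactly 2 groups")
  skip <- c(group_col, "subject_id", "theta_true")
  if (is.null(continuous)) {
    continuous <- names(data)[vapply(data, is.numeric, logical(1))]
    continuous <- setdiff(continuous, skip)
  }
  if (is.null(binary)) {
    binary <- names(data)[vapply(data, is.logical, logical(1))]
    binary <- setdiff(binary, skip)
  }
  rows <- list()
  for (v in continuous) {
    x <- data[[v]]
    s <- summarize_groups(x[!is.na(x)], g[!is.na(x)])
    kw <- kruskal_wallis(x, g)
    cells <- sprintf("%.2f ± %.2f", s$mean[match(lev, s$group)],
                     s$sem[match(lev, s$group)])
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, type = "continuous",
      g1 = cells[1], g2 = cells[2], test = "kruskal_wallis",
      statistic = kw$statistic, p_value = kw$p_value)
  }
  for (v in binary) {
    x <- as.logical(data[[v]])
    tab <- table(factor(x, levels = c(TRUE, FALSE)), g)
    fe <- fisher_exact(t(tab))
    pct <- 100 * tab["TRUE", lev] / colSums(tab)[lev]
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, type = "binary",
      g1 = sprintf("%.1f", pct[1]), g2 = sprintf("%.1f", pct[2]),
      test = "fisher_exact", statistic = NA_real_, p_value = fe$p_value)
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "g1"] <- lev[1]
  names(out)[names(out) == "g2"] <- lev[2]
  out$p_label <- format_p(out$p_value)
  class(out) <- c("summary_table", "data.frame")
  out
}
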