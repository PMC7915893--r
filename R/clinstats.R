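# Association statistics for the printed clinical cross-tabulations and
# survival cohorts: uncorrected Pearson chi-square, Kaplan-Meier product-
# limit estimation, and the log-rank test. The test machinery itself is
# standard (stats::chisq.test, survival::survfit/survdiff); this module
# fixes the conventions (no continuity correction, df, reporting shape)
# and the file formats.

#' Read a contingency table
#'
#' @param path TSV of counts with row labels in the first column and column
#'   labels in the header.
#' @return Integer matrix with dimnames.
#' @export
read_contingency <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}

#' Uncorrected Pearson chi-square test on a contingency table
#'
#' Computes the classical statistic `sum((O - E)^2 / E)` with expectations
#' from the product of the marginals, df = (r-1)(c-1), and the upper-tail
#' chi-square p-value. No Yates continuity correction is applied: the
#' uncorrected statistic is the convention this toolchain standardizes on
#' for 2 x k cross-tabulations.
#'
#' @param counts Matrix of non-negative counts (>= 2 rows and columns).
#' @return List of class `glyco_test` with `statistic`, `df`, `p_value`,
#'   `method`.
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table needs at least 2 rows and 2 columns")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal row or column")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value),
                 method = "Pearson chi-square (uncorrected)"),
            class = "glyco_test")
}

#' Fisher's exact test on a contingency table
#'
#' Exploratory alternative to [pearson_chi2()] for sparse tables; the
#' uncorrected Pearson test remains the reporting convention.
#'
#' @inheritParams pearson_chi2
#' @return A `glyco_test` list; `statistic` and `df` are `NA` (the exact
#'   test has no chi-square statistic).
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table needs at least 2 rows and 2 columns")
  res <- stats::fisher.test(counts)
  structure(list(statistic = NA_real_, df = NA_integer_,
                 p_value = unname(res$p.value),
                 method = "Fisher's exact test"),
            class = "glyco_test")
}

#' @export
print.glyco_test <- function(x, ...) {
  cat(x$method, "\n", sep = "")
  if (!is.na(x$statistic))
    cat("  statistic = ", format(x$statistic, digits = 6),
        ", df = ", x$df, ",", sep = "")
  cat("  p = ", sprintf("%.3f", x$p_value), "\n", sep = "")
  invisible(x)
}

#' Read a survival cohort table
#'
#' @param path Long-format TSV with columns `subject` (optional), `group`,
#'   `time` (months), `event` (0/1).
#' @return Data frame.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("group", "time", "event"), names(cohort))
  if (length(missing))
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(cohort$time < 0)) stop("negative survival times")
  cohort
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator honoring right-censoring; survival starts at 1
#' and is non-increasing.
#'
#' @param cohort Data frame with columns `group`, `time`, `event`.
#' @return Data frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_estimate <- function(cohort) {
  if (any(cohort$time < 0)) stop("negative survival times")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ group, data = cohort)
  if (is.null(fit$strata)) {
    groups <- rep(unique(cohort$group)[1L], length(fit$time))
  } else {
    groups <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = groups, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank test between two survival groups
#'
#' @param cohort Data frame with columns `group` (exactly two levels),
#'   `time`, `event`.
#' @return A `glyco_test` list (`statistic`, `df = 1`, `p_value`, `method`).
#' @export
logrank <- function(cohort) {
  groups <- unique(cohort$group)
  if (length(groups) != 2L)
    stop("log-rank comparison requires exactly two groups, got ",
         length(groups))
  if (any(table(cohort$group) == 0L)) stop("empty group")
  fit <- survival::survdiff(
    survival::Surv(time, event) ~ group, data = cohort)
  structure(list(statistic = unname(fit$chisq), df = 1L,
                 p_value = stats::pchisq(fit$chisq, 1, lower.tail = FALSE),
                 method = "Log-rank test"),
            class = "glyco_test")
}
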